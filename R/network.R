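#' Build a C-alpha elastic network
#'
#' Connects every pair of nodes at Euclidean distance \code{<= cutoff} by a
#' Hookean spring with uniform spring constant \code{gamma}. The network must
#' form a single connected component; a disconnected network is an error that
#' reports the component sizes.
#'
#' @param struct a \code{\link{cg_structure}}.
#' @param cutoff distance cutoff r_c in Angstrom (default 15).
#' @param gamma uniform spring constant in N/m (default 1; see
#'   \code{\link{calibrate_gamma}} for data-driven values).
#'
#' @return An object of class \code{elastic_network}: list with
#'   \code{structure}, \code{cutoff}, \code{gamma} and an \code{edges}
#'   data frame (i, j, rij) with i < j and distances in Angstrom.
#' @export
build_network <- function(struct, cutoff = 15, gamma = 1) {
  stopifnot(inherits(struct, "cg_structure"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("'cutoff' must be > 0")
  if (!is.numeric(gamma) || gamma <= 0) stop("'gamma' must be > 0")
  d <- as.matrix(stats::dist(struct$xyz))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("no springs at cutoff ", cutoff, " A: network is fully disconnected")
  edges <- data.frame(i = idx[, 1], j = idx[, 2], rij = d[idx])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  if (any(edges$rij <= 0))
    stop("coincident nodes (zero-length spring) in the network")
  g <- igraph::graph_from_edgelist(as.matrix(edges[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, struct$n - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop("elastic network is disconnected at cutoff ", cutoff,
         " A: ", comp$no, " components of sizes ",
         paste(comp$csize, collapse = ", "))
  structure(list(structure = struct, cutoff = cutoff, gamma = gamma,
                 edges = edges),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cat("Elastic network:", x$structure$source_id, "\n")
  cat("  nodes:", x$structure$n, " springs:", nrow(x$edges),
      " cutoff:", x$cutoff, "A  gamma:", x$gamma, "N/m\n")
  invisible(x)
}

#' ANM Hessian (stiffness) matrix
#'
#' Assembles the 3N x 3N second-derivative matrix of the network's elastic
#' energy. For each spring (i, j) the off-diagonal 3x3 block is
#' \code{-gamma/r^2 * (rj - ri)(rj - ri)^T} and each diagonal block is minus
#' the sum of its row's off-diagonal blocks, so rigid translations cost no
#' energy and every row sums to zero.
#'
#' @param network an \code{\link{build_network}} result.
#' @param gamma optional spring constant (N/m) overriding the network's.
#'
#' @return Dense symmetric 3N x 3N matrix in N/m.
#' @export
anm_hessian <- function(network, gamma = NULL) {
  stopifnot(inherits(network, "elastic_network"))
  if (is.null(gamma)) gamma <- network$gamma
  xyz_m <- network$structure$xyz * .const$ang_m
  n <- network$structure$n
  H <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(nrow(network$edges))) {
    i <- network$edges$i[k]; j <- network$edges$j[k]
    dv <- xyz_m[j, ] - xyz_m[i, ]
    blk <- -(gamma / sum(dv^2)) * tcrossprod(dv)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

#' Diagonal mass matrix
#'
#' @param struct a \code{\link{cg_structure}}.
#' @param full if \code{TRUE}, return the dense 3N x 3N matrix; by default
#'   only its diagonal is returned (the matrix is block-diagonal with
#'   \code{m_i * I3} blocks, so the diagonal carries all information).
#' @return Numeric vector of length 3N (or dense 3N x 3N matrix) in kg.
#' @export
mass_matrix <- function(struct, full = FALSE) {
  stopifnot(inherits(struct, "cg_structure"))
  d <- rep(struct$masses * .const$amu_kg, each = 3L)
  if (full) diag(d) else d
}
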