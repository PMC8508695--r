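#' Least-squares rigid-body superposition (Kabsch)
#'
#' Pairs nodes across two structures by (chain, residue number, insertion
#' code) and finds the optimal proper rotation + translation of the mobile
#' structure onto the reference (SVD with reflection correction, so the
#' returned rotation always has determinant +1).
#'
#' @param mobile,reference \code{\link{cg_structure}} objects.
#' @return List with \code{rotation} (3x3, det +1), \code{translation}
#'   (length 3), \code{xyz} (paired mobile coordinates after superposition,
#'   n_pair x 3, Angstrom), \code{rmsd} (Angstrom over paired nodes),
#'   \code{pairs} (data frame of paired node indices \code{i_mobile},
#'   \code{i_reference}).
#' @export
superpose <- function(mobile, reference) {
  stopifnot(inherits(mobile, "cg_structure"),
            inherits(reference, "cg_structure"))
  pairs <- .pair_nodes(mobile, reference)
  if (nrow(pairs) < 3L)
    stop("superposition needs >= 3 paired nodes; found ", nrow(pairs))
  X <- mobile$xyz[pairs$i_mobile, , drop = FALSE]
  Y <- reference$xyz[pairs$i_reference, , drop = FALSE]
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Xfit <- sweep(Xc %*% t(R), 2, yc, "+")
  list(rotation = R, translation = drop(yc - R %*% xc),
       xyz = Xfit, rmsd = sqrt(mean(rowSums((Xfit - Y)^2))), pairs = pairs)
}

.pair_nodes <- function(a, b) {
  ka <- paste(a$chain, a$resno, a$insert, sep = "|")
  kb <- paste(b$chain, b$resno, b$insert, sep = "|")
  common <- intersect(ka, kb)
  data.frame(i_mobile = match(common, ka), i_reference = match(common, kb))
}

#' Conformational-change vector between two end-state structures
#'
#' Superposes the target ("closed") structure onto the reference ("open")
#' one and takes the per-node displacement, flattened to a 3n_pair vector
#' (x1, y1, z1, x2, ...). Node pairing follows \code{\link{superpose}};
#' unpaired residues are reported in the result.
#'
#' @param open reference \code{\link{cg_structure}} (the one the network is
#'   built from).
#' @param closed target \code{\link{cg_structure}}.
#' @return Object of class \code{conformational_change}: list with \code{cc}
#'   (displacement vector, Angstrom), \code{per_node} (n_pair x 3 matrix),
#'   \code{pairs}, \code{superposition_rmsd}, \code{n_unpaired_open},
#'   \code{n_unpaired_closed}, \code{source_ids}.
#' @export
conformational_change <- function(open, closed) {
  fit <- superpose(closed, open)
  per_node <- fit$xyz - open$xyz[fit$pairs$i_reference, , drop = FALSE]
  cc <- as.numeric(t(per_node))
  if (sqrt(sum(cc^2)) < 1e-6)
    warning("conformational-change vector has (near-)zero norm; ",
            "overlap and collectivity will be undefined")
  structure(
    list(cc = cc, per_node = per_node,
         pairs = data.frame(i_open = fit$pairs$i_reference,
                            i_closed = fit$pairs$i_mobile),
         superposition_rmsd = fit$rmsd,
         n_unpaired_open = open$n - nrow(fit$pairs),
         n_unpaired_closed = closed$n - nrow(fit$pairs),
         source_ids = c(open = open$source_id, closed = closed$source_id)),
    class = "conformational_change")
}

#' @export
print.conformational_change <- function(x, ...) {
  cat("Conformational change:", x$source_ids["open"], "->",
      x$source_ids["closed"], "\n")
  cat("  paired nodes:", nrow(x$pairs),
      " (unpaired:", x$n_unpaired_open, "open /",
      x$n_unpaired_closed, "closed )\n")
  cat("  superposition RMSD:", signif(x$superposition_rmsd, 4), "A\n")
  cat("  |CC|:", signif(sqrt(sum(x$cc^2)), 4), "A   collectivity:",
      tryCatch(signif(collectivity(x), 3), error = function(e) NA), "\n")
  invisible(x)
}

#' Overlap between a displacement field and the conformational change
#'
#' Absolute normalized inner product |u'cc| / (|u| |cc|): 1 when the two
#' displacement directions coincide, 0 when orthogonal. Scale- and
#' sign-invariant in both arguments.
#'
#' @param u numeric displacement vector (3N).
#' @param cc a \code{\link{conformational_change}} or numeric vector of the
#'   same length.
#' @return Scalar in [0, 1].
#' @export
overlap <- function(u, cc) {
  v <- if (inherits(cc, "conformational_change")) cc$cc else as.numeric(cc)
  u <- as.numeric(u)
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("overlap is undefined for a zero-norm displacement vector")
  abs(sum(u * v)) / (nu * nv)
}

#' Time-dependent overlap along a trajectory
#'
#' Per-frame overlap of u(t) with the conformational change. Frames whose
#' displacement norm falls below \code{min_norm} (default 1e-6 A) are
#' recorded as NA rather than 0, since the overlap is undefined there.
#'
#' @param trajectory an \code{anm_trajectory}.
#' @param cc a \code{\link{conformational_change}} or numeric vector.
#' @param min_norm displacement-norm floor in Angstrom.
#' @return Object of class \code{overlap_series}: list with \code{times_ps},
#'   \code{overlap} (same length, NA where undefined), \code{max},
#'   \code{t_max_ps}.
#' @export
overlap_series <- function(trajectory, cc, min_norm = 1e-6) {
  stopifnot(inherits(trajectory, "anm_trajectory"))
  v <- if (inherits(cc, "conformational_change")) cc$cc else as.numeric(cc)
  stopifnot(ncol(trajectory$disp) == length(v))
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("overlap is undefined for a zero-norm target vector")
  nu <- sqrt(rowSums(trajectory$disp^2))
  o <- abs(drop(trajectory$disp %*% v)) / (nu * nv)
  o[nu < min_norm] <- NA_real_
  imax <- if (all(is.na(o))) NA_integer_ else which.max(o)
  structure(list(times_ps = trajectory$times_ps, overlap = o,
                 max = if (is.na(imax)) NA_real_ else o[imax],
                 t_max_ps = if (is.na(imax)) NA_real_
                            else trajectory$times_ps[imax]),
            class = "overlap_series")
}

#' Per-frame root-mean-square displacement
#'
#' RMSD(t) = sqrt(mean over nodes of the squared displacement magnitude),
#' in Angstrom.
#'
#' @param trajectory an \code{anm_trajectory}, or a frames x 3N displacement
#'   matrix (Angstrom).
#' @return Numeric vector, one value per frame.
#' @export
rmsd_series <- function(trajectory) {
  u <- if (inherits(trajectory, "anm_trajectory")) trajectory$disp
       else as.matrix(trajectory)
  sqrt(rowSums(u^2) / (ncol(u) / 3))
}

#' Dynamic amplification ratio
#'
#' Maximum dynamic RMSD over the trajectory divided by the RMSD of the
#' response to the same force pattern applied statically.
#'
#' @param trajectory an \code{anm_trajectory}.
#' @param static_u static displacement vector (Angstrom), e.g. from
#'   \code{\link{static_response}} with the trajectory's force pattern.
#' @return Scalar ratio (> 0).
#' @export
dynamic_amplification <- function(trajectory, static_u) {
  r_static <- rmsd_series(matrix(as.numeric(static_u), nrow = 1))
  if (r_static == 0)
    stop("static RMSD is zero; amplification undefined")
  max(rmsd_series(trajectory)) / r_static
}

#' Motion non-linearity from step-direction cosines
#'
#' For each node i and frame t, the cosine between the instantaneous step
#' Delta u_i(t) = u_i(t + dt) - u_i(t) and the initial step Delta u_i(0).
#' A purely linear back-and-forth motion yields only +1 and -1; curvilinear
#' motion sweeps intermediate values. Steps of zero norm give NA.
#'
#' @param trajectory an \code{anm_trajectory} with >= 3 frames.
#' @return N x (frames - 1) matrix of cosines in [-1, 1] (NA where a step
#'   vanishes).
#' @export
cosine_nonlinearity <- function(trajectory) {
  u <- if (inherits(trajectory, "anm_trajectory")) trajectory$disp
       else as.matrix(trajectory)
  if (nrow(u) < 3L) stop("need at least 3 frames")
  du <- diff(u)                          # (frames-1) x 3N
  n <- ncol(u) / 3
  out <- matrix(NA_real_, n, nrow(du))
  for (i in seq_len(n)) {
    cols <- (3 * i - 2):(3 * i)
    di <- du[, cols, drop = FALSE]
    d0 <- di[1, ]
    num <- drop(di %*% d0)
    den <- sqrt(rowSums(di^2)) * sqrt(sum(d0^2))
    ci <- num / den
    ci[den == 0] <- NA_real_
    out[i, ] <- ci
  }
  out
}

#' Principal component analysis of a conformational ensemble
#'
#' Eigendecomposition of the covariance matrix of an s x 3N matrix of
#' conformation coordinates (one conformation per row), components sorted by
#' descending eigenvalue. Scores are the centered data projected on the
#' components; supplementary conformations can be projected afterwards with
#' \code{predict}.
#'
#' @param conformations numeric s x 3N matrix (s >= 2), Angstrom.
#' @return Object of class \code{anm_pca}: list with \code{values}
#'   (eigenvalues, descending), \code{vectors} (3N x 3N components,
#'   columns), \code{scores} (s x 3N), \code{var_fraction}, \code{center}.
#' @export
pca_conformations <- function(conformations) {
  X <- as.matrix(conformations)
  if (nrow(X) < 2L) stop("PCA needs at least 2 conformations")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sigma <- crossprod(Xc) / (nrow(X) - 1)
  ev <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  structure(list(values = vals, vectors = ev$vectors,
                 scores = Xc %*% ev$vectors,
                 var_fraction = vals / sum(vals), center = center),
            class = "anm_pca")
}

#' @export
#' @rdname pca_conformations
#' @param object an \code{anm_pca}.
#' @param newdata conformations (rows, 3N columns) to project onto the
#'   existing components, e.g. the open/closed crystal forms as
#'   supplementary points on a trajectory PCA.
#' @param ... unused.
predict.anm_pca <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(as.numeric(newdata), nrow = 1)
       else as.matrix(newdata)
  sweep(X, 2, object$center) %*% object$vectors
}

#' Collectivity of a displacement field
#'
#' Entropy-based participation measure: with d_i^2 the squared displacement
#' magnitude of node i and alpha fixed by sum_i alpha d_i^2 = 1,
#' kappa = (1/N) exp(-sum_i alpha d_i^2 log(alpha d_i^2)). kappa = 1 when
#' every node moves with equal magnitude; kappa = 1/N when a single node
#' carries all the motion.
#'
#' @param cc a \code{\link{conformational_change}} or numeric 3N
#'   displacement vector.
#' @return Scalar in (0, 1].
#' @export
collectivity <- function(cc) {
  v <- if (inherits(cc, "conformational_change")) cc$cc else as.numeric(cc)
  if (length(v) %% 3L != 0L) stop("displacement vector length must be 3N")
  d2 <- rowSums(matrix(v, ncol = 3, byrow = TRUE)^2)
  tot <- sum(d2)
  if (tot == 0) stop("collectivity is undefined for a zero displacement")
  p <- d2 / tot
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  exp(h) / length(d2)
}

#' Frequency / damping / force-pattern scan
#'
#' Runs the full dynamic-response pipeline over a grid of forcing
#' frequencies, damping ratios and force-pattern seeds. For every triple it
#' records the maximum overlap with the conformational change over the
#' evaluation window, the maximum dynamic RMSD, the static RMSD of the same
#' pattern, and the dynamic amplification ratio. The result is
#' bit-reproducible given the seed list.
#'
#' @param modes a \code{modal_decomposition}.
#' @param cc a \code{\link{conformational_change}} (or numeric vector), or
#'   \code{NULL} to skip overlap scoring.
#' @param frequencies forcing frequencies in THz.
#' @param dampings damping ratios in (0, 1).
#' @param seeds force-pattern seeds.
#' @param amplitude per-component force bound (N).
#' @param window \code{"post_transient"} (default) restricts the overlap /
#'   RMSD maxima to the frames after the transient window;
#'   \code{"full"} uses every frame.
#' @param cycles,dt_per_cycle,transient_ps time-grid settings, see
#'   \code{\link{default_time_grid}}.
#' @return Object of class \code{scan_result}: a data frame with one row per
#'   (freq_thz, damping, seed) and columns \code{max_overlap},
#'   \code{t_max_ps}, \code{max_rmsd}, \code{static_rmsd},
#'   \code{amplification}.
#' @export
frequency_scan <- function(modes, cc, frequencies, dampings, seeds,
                           amplitude = 1e-10, window = "post_transient",
                           cycles = 10, dt_per_cycle = 100,
                           transient_ps = "auto") {
  stopifnot(inherits(modes, "modal_decomposition"))
  window <- match.arg(window, c("post_transient", "full"))
  n <- nrow(modes$modes) / 3
  rows <- vector("list", length(dampings) * length(seeds) *
                   length(frequencies))
  k <- 0L
  for (xi in dampings) {
    for (seed in seeds) {
      pat <- random_force_pattern(n, seed = seed, amplitude = amplitude)
      u_stat <- static_response(modes, pat)
      r_stat <- rmsd_series(matrix(u_stat, nrow = 1))
      for (f in frequencies) {
        exc <- harmonic_excitation(pat, freq_thz = f, damping = xi)
        traj <- synthesize_trajectory(modes, exc, cycles = cycles,
                                      dt_per_cycle = dt_per_cycle,
                                      transient_ps = transient_ps)
        sel <- if (window == "post_transient")
          traj$times_ps >= traj$transient_ps else rep(TRUE, nrow(traj$disp))
        r <- rmsd_series(traj)
        if (!is.null(cc)) {
          os <- overlap_series(traj, cc)
          ow <- os$overlap[sel]
          omax <- if (all(is.na(ow))) NA_real_ else max(ow, na.rm = TRUE)
          tmax <- if (is.na(omax)) NA_real_ else
            traj$times_ps[sel][which.max(ow)]
        } else {
          omax <- NA_real_; tmax <- NA_real_
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          freq_thz = f, damping = xi, seed = seed,
          max_overlap = omax, t_max_ps = tmax,
          max_rmsd = max(r[sel]), static_rmsd = r_stat,
          amplification = max(r[sel]) / r_stat)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", class(out))
  out
}

#' Optimal forcing frequency per (damping, seed)
#'
#' Reduces a scan to the frequency at which each force pattern attains its
#' maximum overlap with the conformational change.
#'
#' @param scan a \code{\link{frequency_scan}} result.
#' @return Data frame with one row per (damping, seed): \code{best_overlap}
#'   and \code{best_freq_thz}.
#' @export
scan_optimal_frequencies <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  sp <- split(as.data.frame(scan), list(scan$damping, scan$seed),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    i <- which.max(d$max_overlap)
    data.frame(damping = d$damping[1], seed = d$seed[1],
               best_overlap = d$max_overlap[i],
               best_freq_thz = d$freq_thz[i])
  }))
  rownames(out) <- NULL
  out[order(out$damping, out$seed), ]
}

#' Scan grid presets
#'
#' \code{"paper"}: 500 frequencies in 0.001-0.5 THz, damping ratios 0.001 /
#' 0.01 / 0.1, 100 force patterns (the full production grid).
#' \code{"desk"}: 25 frequencies, one damping ratio (0.01), 5 seeds -- a
#' grid sized for interactive use and continuous integration.
#'
#' @param name \code{"desk"} or \code{"paper"}.
#' @return List with \code{frequencies}, \code{dampings}, \code{seeds}.
#' @export
scan_preset <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  switch(name,
    desk = list(frequencies = seq(0.001, 0.5, length.out = 25),
                dampings = 0.01, seeds = 1:5),
    paper = list(frequencies = seq(0.001, 0.5, length.out = 500),
                 dampings = c(0.001, 0.01, 0.1), seeds = 1:100))
}
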