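#' Mass-weighted free-vibration modal analysis
#'
#' Solves the generalized symmetric eigenproblem (H - omega^2 M) delta = 0
#' via the equivalent ordinary symmetric problem on M^(-1/2) H M^(-1/2),
#' back-transforming the eigenvectors so that the mode-shape matrix is
#' mass-orthonormal (Delta' M Delta = I). Eigenpairs are sorted by ascending
#' frequency. For an unconstrained connected 3-D network exactly six
#' zero-frequency rigid-body modes are expected (five when all nodes are
#' collinear); any other count is a degeneracy error reporting the eigenvalue
#' gap around the threshold.
#'
#' @param H symmetric 3N x 3N stiffness matrix (N/m), e.g.
#'   \code{\link{anm_hessian}}.
#' @param M mass-matrix diagonal (length-3N vector, kg) or dense diagonal
#'   matrix, e.g. \code{\link{mass_matrix}}.
#' @param n_rigid expected number of zero modes (default 6).
#' @param zero_tol eigenvalue lambda counts as zero when
#'   \code{lambda < zero_tol * max(lambda)} (default 1e-8).
#' @param gamma_used,structure bookkeeping: the spring constant the Hessian
#'   was assembled with, and the generating structure (attached for
#'   downstream trajectory synthesis / B-factor prediction).
#'
#' @return An object of class \code{modal_decomposition}: list with
#'   \code{omega} (rad/s, ascending), \code{freq_thz}, \code{modes}
#'   (3N x 3N mass-orthonormal mode shapes, columns), \code{n_rigid},
#'   \code{mass_diag} (kg), \code{gamma_used}, \code{structure}.
#' @export
modal_analysis <- function(H, M, n_rigid = 6L, zero_tol = 1e-8,
                           gamma_used = NA_real_, structure = NULL) {
  if (is.matrix(M)) M <- diag(M)
  n3 <- length(M)
  stopifnot(is.matrix(H), nrow(H) == n3, ncol(H) == n3, all(M > 0))
  if (max(abs(H - t(H))) > 1e-9 * max(abs(H)))
    stop("'H' is not symmetric")
  s <- 1 / sqrt(M)
  W <- H * tcrossprod(s)            # M^(-1/2) H M^(-1/2)
  W <- (W + t(W)) / 2
  ev <- eigen(W, symmetric = TRUE)
  lam <- rev(ev$values)             # ascending
  vec <- ev$vectors[, rev(seq_len(n3)), drop = FALSE]
  lam_max <- max(lam)
  if (lam_max <= 0) stop("stiffness matrix has no positive eigenvalues")
  n_zero <- sum(lam < zero_tol * lam_max)
  if (n_zero != n_rigid)
    stop(sprintf(paste0(
      "degenerate mode spectrum: %d numerically-zero modes, expected %d ",
      "(eigenvalues around the threshold: %s)"),
      n_zero, n_rigid,
      paste(signif(lam[seq_len(min(n3, max(n_zero, n_rigid) + 2))], 3),
            collapse = ", ")))
  lam[seq_len(n_zero)] <- pmax(lam[seq_len(n_zero)], 0)
  omega <- sqrt(pmax(lam, 0))
  modes <- vec * s                  # back-transform: delta = M^(-1/2) v
  structure(
    list(omega = omega, freq_thz = .omega_to_thz(omega), modes = modes,
         n_rigid = as.integer(n_rigid), mass_diag = M,
         gamma_used = gamma_used, structure = structure),
    class = "modal_decomposition")
}

#' @export
print.modal_decomposition <- function(x, ...) {
  nr <- x$n_rigid
  cat("Modal decomposition:", length(x$omega), "modes (", nr, "rigid )\n")
  cat("  lowest non-rigid frequency:",
      signif(x$freq_thz[nr + 1] * 1000, 4), "GHz\n")
  cat("  highest frequency:", signif(max(x$freq_thz), 4), "THz\n")
  if (!is.na(x$gamma_used)) cat("  gamma:", x$gamma_used, "N/m\n")
  invisible(x)
}

## indices of the internal (non-rigid) modes
.nonrigid <- function(modes) (modes$n_rigid + 1L):length(modes$omega)

## TRUE when all nodes lie on one straight line (rank of centered
## coordinates <= 1); such a network has only 5 rigid-body modes.
.is_collinear <- function(xyz) {
  xc <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(xc, nu = 0, nv = 0)$d
  sv[2] < 1e-8 * max(sv[1], .Machine$double.eps)
}

#' Free-vibration modes of an elastic network
#'
#' Convenience wrapper: assembles Hessian and mass matrix from a network and
#' runs \code{\link{modal_analysis}}, auto-detecting the collinear special
#' case (5 rigid modes instead of 6).
#'
#' @param network an \code{\link{build_network}} result.
#' @param gamma optional spring constant (N/m) overriding the network's.
#' @return A \code{modal_decomposition}.
#' @export
anm_modes <- function(network, gamma = NULL) {
  stopifnot(inherits(network, "elastic_network"))
  if (is.null(gamma)) gamma <- network$gamma
  n_rigid <- if (.is_collinear(network$structure$xyz)) 5L else 6L
  modal_analysis(anm_hessian(network, gamma = gamma),
                 mass_matrix(network$structure),
                 n_rigid = n_rigid, gamma_used = gamma,
                 structure = network$structure)
}

#' Rescale a modal decomposition to a new uniform spring constant
#'
#' With uniform springs the mode shapes are independent of gamma and every
#' omega_n^2 scales linearly with it, so a decomposition computed at one
#' gamma can be rescaled exactly without re-solving the eigenproblem.
#'
#' @param modes a \code{modal_decomposition}.
#' @param gamma new spring constant (N/m).
#' @return The rescaled \code{modal_decomposition}.
#' @export
rescale_gamma <- function(modes, gamma) {
  stopifnot(inherits(modes, "modal_decomposition"), gamma > 0)
  if (is.na(modes$gamma_used))
    stop("decomposition does not record the gamma it was computed at")
  f <- sqrt(gamma / modes$gamma_used)
  modes$omega <- modes$omega * f
  modes$freq_thz <- modes$freq_thz * f
  modes$gamma_used <- gamma
  modes
}

#' Predicted B-factors from the thermal fluctuations of the internal modes
#'
#' Equipartition over the non-rigid modes gives the mean-square fluctuation
#' of node i as kB*T * sum_n |delta_n,i|^2 / omega_n^2 (mass-orthonormal
#' modes), and B_i = (8 pi^2 / 3) times that, reported in A^2.
#'
#' @param modes a \code{modal_decomposition}.
#' @param temperature absolute temperature in K (default 300).
#' @return Numeric vector of N predicted B-factors (A^2).
#' @export
compute_bfactors <- function(modes, temperature = 300) {
  stopifnot(inherits(modes, "modal_decomposition"), temperature > 0)
  nr <- .nonrigid(modes)
  if (any(modes$omega[nr] <= 0))
    stop("zero-frequency mode inside the internal-mode sum")
  n3 <- nrow(modes$modes)
  amp <- modes$modes[, nr, drop = FALSE]^2 %*% (1 / modes$omega[nr]^2)
  msf_m2 <- .const$kB * temperature *
    rowsum(amp, rep(seq_len(n3 / 3), each = 3))  # per-node 3-vector norm
  as.numeric(8 * pi^2 / 3 * msf_m2 / .const$ang_m^2)
}

#' Calibrate the uniform spring constant against experimental B-factors
#'
#' Chooses gamma so that the mean predicted B-factor equals the mean
#' experimental B-factor. Because mode shapes are gamma-independent for
#' uniform springs and every predicted B scales as 1/gamma, the calibration
#' is a single rescaling of a trial solution:
#' gamma = gamma_trial * mean(B_calc(gamma_trial)) / mean(B_exp).
#'
#' @param struct a \code{\link{cg_structure}} carrying experimental
#'   B-factors.
#' @param cutoff network cutoff in Angstrom (default 15).
#' @param temperature temperature for the fluctuation formula, K (default
#'   300). The calibrated gamma scales linearly with this choice.
#' @param gamma_trial trial spring constant, N/m.
#'
#' @return List with \code{gamma} (N/m), \code{modes} (a
#'   \code{modal_decomposition} already rescaled to the calibrated gamma),
#'   \code{network}, \code{bfactors_calc} (at the calibrated gamma),
#'   \code{mean_b_exp}, \code{mean_b_calc}, \code{temperature},
#'   \code{cutoff}.
#' @export
calibrate_gamma <- function(struct, cutoff = 15, temperature = 300,
                            gamma_trial = 1) {
  stopifnot(inherits(struct, "cg_structure"))
  if (is.null(struct$bfactors))
    stop("calibration requires experimental B-factors on the structure")
  net <- build_network(struct, cutoff = cutoff, gamma = gamma_trial)
  modes <- anm_modes(net)
  b_trial <- compute_bfactors(modes, temperature = temperature)
  gamma <- gamma_trial * mean(b_trial) / mean(struct$bfactors)
  modes <- rescale_gamma(modes, gamma)
  net$gamma <- gamma
  b_cal <- b_trial * gamma_trial / gamma
  list(gamma = gamma, modes = modes, network = net,
       bfactors_calc = b_cal,
       mean_b_exp = mean(struct$bfactors), mean_b_calc = mean(b_cal),
       temperature = temperature, cutoff = cutoff)
}
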