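#' Random harmonic force pattern
#'
#' Draws 3N independent force components from
#' Uniform(-amplitude, +amplitude). The pattern is bit-reproducible from its
#' seed (Mersenne-Twister, isolated from the session RNG state).
#'
#' @param n node count N (>= 2).
#' @param seed integer RNG seed recorded on the pattern.
#' @param amplitude per-component bound in newtons (default 1e-10).
#' @return Object of class \code{force_pattern}: list with \code{force}
#'   (length 3N, newtons), \code{amplitude}, \code{seed}.
#' @export
random_force_pattern <- function(n, seed, amplitude = 1e-10) {
  stopifnot(n >= 2, amplitude >= 0)
  f <- .with_seed(seed, stats::runif(3 * n, -amplitude, amplitude))
  structure(list(force = f, amplitude = amplitude, seed = as.integer(seed)),
            class = "force_pattern")
}

## evaluate expr with a private RNG stream, restoring session state after
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Harmonic excitation specification
#'
#' A force pattern oscillating as F sin(omega_F t), with per-mode
#' dimensionless damping. Only the underdamped regime (0 < xi < 1) is
#' supported.
#'
#' @param pattern a \code{\link{random_force_pattern}} result, or a bare
#'   numeric force vector (newtons).
#' @param freq_thz forcing frequency f_F in THz (> 0).
#' @param damping dimensionless damping ratio xi: a scalar applied to every
#'   mode, or a per-mode vector.
#' @return Object of class \code{harmonic_excitation}.
#' @export
harmonic_excitation <- function(pattern, freq_thz, damping) {
  if (is.numeric(pattern))
    pattern <- structure(list(force = pattern, amplitude = max(abs(pattern)),
                              seed = NA_integer_), class = "force_pattern")
  stopifnot(inherits(pattern, "force_pattern"))
  if (!is.numeric(freq_thz) || length(freq_thz) != 1L || freq_thz <= 0)
    stop("'freq_thz' must be a single positive frequency (THz)")
  if (any(damping <= 0) || any(damping >= 1))
    stop("underdamped regime required: all damping ratios must lie in (0, 1)")
  structure(list(pattern = pattern, freq_thz = freq_thz,
                 omega_f = .thz_to_omega(freq_thz), damping = damping),
            class = "harmonic_excitation")
}

#' Static (time-independent) linear response
#'
#' Displacement under a constant force, from the generalized pseudo-inverse
#' of the Hessian restricted to the internal modes:
#' u = sum_n (delta_n' F / omega_n^2) delta_n over non-rigid n, with
#' mass-orthonormal delta_n. Internally verifies that H u reproduces F minus
#' its rigid-body (mass-metric) projection; a force living entirely in the
#' rigid subspace triggers a warning and a zero response.
#'
#' @param modes a \code{modal_decomposition}.
#' @param force a \code{force_pattern} or numeric force vector (newtons).
#' @return Numeric displacement vector of length 3N, in Angstrom.
#' @export
static_response <- function(modes, force) {
  stopifnot(inherits(modes, "modal_decomposition"))
  f <- if (inherits(force, "force_pattern")) force$force else as.numeric(force)
  n3 <- nrow(modes$modes)
  stopifnot(length(f) == n3)
  nr <- .nonrigid(modes)
  proj <- drop(crossprod(modes$modes[, nr, drop = FALSE], f))
  ## compare in the mass-weighted force norm, the metric the modal
  ## coefficients live in, so the threshold is dimensionally consistent
  f_mw <- sqrt(sum(f^2 / modes$mass_diag))
  if (sqrt(sum(proj^2)) <= 1e-10 * max(f_mw, .Machine$double.eps)) {
    warning("force has no component along the internal modes; ",
            "static response excludes rigid motion and is zero")
  }
  u_m <- drop(modes$modes[, nr, drop = FALSE] %*% (proj / modes$omega[nr]^2))
  u_m / .const$ang_m
}

#' Per-mode coefficients of the underdamped driven response
#'
#' For each internal mode n, the steady-state amplitude and phase
#' C_n = (delta_n' F) / (omega_n^2 sqrt((1-beta_n^2)^2 + (2 xi_n beta_n)^2)),
#' phi_n = -atan2(2 xi_n beta_n, 1 - beta_n^2) with beta_n = omega_F /
#' omega_n (the two-argument arctangent keeps phi continuous through
#' resonance: 0 at beta -> 0, -pi/2 at beta = 1, -pi as beta -> Inf), plus
#' the transient constants for a resting start (p_n(0) = 0, p_n'(0) = 0):
#' A_n = -C_n sin(phi_n), B_n = (xi_n omega_n A_n - C_n omega_F cos(phi_n))
#' / omega_dn, with damped frequency omega_dn = omega_n sqrt(1 - xi_n^2).
#'
#' @param modes a \code{modal_decomposition}.
#' @param excitation a \code{\link{harmonic_excitation}}.
#' @return Object of class \code{modal_response}: data-frame-like list of
#'   per-mode vectors \code{omega}, \code{xi}, \code{beta}, \code{C},
#'   \code{phi}, \code{A}, \code{B}, \code{omega_d} (internal modes only),
#'   plus \code{modes} and \code{excitation} references.
#' @export
modal_response_coefficients <- function(modes, excitation) {
  stopifnot(inherits(modes, "modal_decomposition"),
            inherits(excitation, "harmonic_excitation"))
  nr <- .nonrigid(modes)
  omega <- modes$omega[nr]
  xi <- rep_len(excitation$damping, length(omega))
  if (any(xi <= 0) || any(xi >= 1)) stop("damping ratios must lie in (0, 1)")
  wf <- excitation$omega_f
  g <- drop(crossprod(modes$modes[, nr, drop = FALSE],
                      excitation$pattern$force))   # modal forces delta'F
  beta <- wf / omega
  C <- g / (omega^2 * sqrt((1 - beta^2)^2 + (2 * xi * beta)^2))
  phi <- -atan2(2 * xi * beta, 1 - beta^2)
  A <- -C * sin(phi)
  omega_d <- omega * sqrt(1 - xi^2)
  B <- (xi * omega * A - C * wf * cos(phi)) / omega_d
  structure(list(omega = omega, xi = xi, beta = beta, C = C, phi = phi,
                 A = A, B = B, omega_d = omega_d,
                 modes = modes, excitation = excitation),
            class = "modal_response")
}

#' Principal coordinates of the driven response
#'
#' Evaluates the analytic underdamped solution
#' p_n(t) = exp(-xi_n omega_n t) [A_n cos(omega_dn t) + B_n sin(omega_dn t)]
#'        + C_n sin(omega_F t + phi_n)
#' on a time grid, for every internal mode.
#'
#' @param response a \code{\link{modal_response_coefficients}} result.
#' @param times_ps numeric vector of times in picoseconds.
#' @return Matrix of principal coordinates, one row per internal mode, one
#'   column per time point (mass-weighted SI units, kg^(1/2) m).
#' @export
principal_coordinates <- function(response, times_ps) {
  stopifnot(inherits(response, "modal_response"))
  t_s <- times_ps * .const$ps_s
  wf <- response$excitation$omega_f
  n_m <- length(response$omega)
  decay <- exp(-outer(response$xi * response$omega, t_s))
  wd_t <- outer(response$omega_d, t_s)
  p <- decay * (response$A * cos(wd_t) + response$B * sin(wd_t)) +
    response$C * sin(outer(rep(wf, n_m), t_s) + response$phi)
  p
}

#' Default trajectory time grid
#'
#' dt is one hundredth of the forcing period by default; the duration is a
#' transient window (5 damping times of the slowest internal mode, capped at
#' 2000 ps) followed by a fixed number of forcing cycles.
#'
#' @param modes a \code{modal_decomposition}.
#' @param excitation a \code{harmonic_excitation}.
#' @param cycles forcing cycles evaluated after the transient (default 10).
#' @param dt_per_cycle samples per forcing cycle (default 100).
#' @param transient_ps transient window in ps, or \code{"auto"}.
#' @return List with \code{times_ps} (uniform grid starting at 0) and
#'   \code{transient_ps}.
#' @export
default_time_grid <- function(modes, excitation, cycles = 10,
                              dt_per_cycle = 100, transient_ps = "auto") {
  period_ps <- 1 / excitation$freq_thz          # ps, since 1/THz = 1 ps
  if (identical(transient_ps, "auto")) {
    xi1 <- rep_len(excitation$damping, 1L)[1]
    w7 <- modes$omega[modes$n_rigid + 1L]
    transient_ps <- min(5 / (xi1 * w7) / .const$ps_s, 2000)
  }
  dt <- period_ps / dt_per_cycle
  ## snap the transient to the grid so the evaluation window is well defined
  transient_ps <- ceiling(transient_ps / dt) * dt
  times <- seq(0, transient_ps + cycles * period_ps, by = dt)
  list(times_ps = times, transient_ps = transient_ps)
}

#' Synthesize the time-dependent displacement trajectory
#'
#' Superposes the internal modes, u(t) = sum_n p_n(t) delta_n, on a time
#' grid (rigid modes contribute nothing). Displacements are reported in
#' Angstrom relative to the reference structure.
#'
#' @param modes a \code{modal_decomposition}.
#' @param excitation a \code{\link{harmonic_excitation}}.
#' @param times_ps explicit time grid (ps); when \code{NULL} the
#'   \code{\link{default_time_grid}} is used.
#' @param cycles,dt_per_cycle,transient_ps passed to
#'   \code{\link{default_time_grid}} when \code{times_ps} is \code{NULL}.
#' @return Object of class \code{anm_trajectory}: list with \code{times_ps},
#'   \code{disp} (frames x 3N displacement matrix, Angstrom),
#'   \code{transient_ps}, \code{excitation}, \code{structure}.
#' @export
synthesize_trajectory <- function(modes, excitation, times_ps = NULL,
                                  cycles = 10, dt_per_cycle = 100,
                                  transient_ps = "auto") {
  stopifnot(inherits(modes, "modal_decomposition"))
  resp <- modal_response_coefficients(modes, excitation)
  if (is.null(times_ps)) {
    grid <- default_time_grid(modes, excitation, cycles = cycles,
                              dt_per_cycle = dt_per_cycle,
                              transient_ps = transient_ps)
    times_ps <- grid$times_ps
    transient_ps <- grid$transient_ps
  } else if (identical(transient_ps, "auto")) {
    transient_ps <- 0
  }
  p <- principal_coordinates(resp, times_ps)
  nr <- .nonrigid(modes)
  u <- crossprod(p, t(modes$modes[, nr, drop = FALSE]))  # frames x 3N, m
  structure(list(times_ps = times_ps, disp = u / .const$ang_m,
                 transient_ps = transient_ps, excitation = excitation,
                 structure = modes$structure),
            class = "anm_trajectory")
}

#' @export
print.anm_trajectory <- function(x, ...) {
  cat("ANM trajectory:", nrow(x$disp), "frames,",
      ncol(x$disp) / 3, "nodes\n")
  cat("  t:", min(x$times_ps), "-", round(max(x$times_ps), 3),
      "ps  (transient window", round(x$transient_ps, 3), "ps)\n")
  cat("  forcing:", x$excitation$freq_thz, "THz  xi:",
      paste(unique(x$excitation$damping), collapse = ","),
      " pattern seed:", x$excitation$pattern$seed, "\n")
  invisible(x)
}
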