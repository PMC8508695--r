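#' Diatomic toy fixture
#'
#' Two equal masses joined by one spring along the x-axis: the single
#' internal mode has the textbook stretch frequency omega = sqrt(2 gamma/m),
#' and a collinear two-node geometry carries exactly five rigid-body zero
#' modes (rotation about the bond axis stores no elastic energy).
#'
#' @param mass node mass in amu (default 100).
#' @param separation bond length in Angstrom (default 10; must not exceed
#'   the cutoff you intend to use).
#' @param gamma spring constant in N/m used for the analytic expectation.
#' @return List with \code{open} (a \code{\link{cg_structure}}),
#'   \code{analytic} (list with \code{omega} in rad/s and \code{freq_thz}),
#'   \code{recipe}.
#' @export
make_diatomic <- function(mass = 100, separation = 10, gamma = 0.1) {
  stopifnot(mass > 0, separation > 0, gamma > 0)
  s <- cg_structure(xyz = rbind(c(0, 0, 0), c(separation, 0, 0)),
                    masses = mass, resid = c("GLY", "GLY"),
                    source_id = "diatomic")
  omega <- sqrt(2 * gamma / (mass * .const$amu_kg))
  list(open = s,
       analytic = list(omega = omega, freq_thz = .omega_to_thz(omega),
                       gamma = gamma, mass = mass),
       recipe = "diatomic")
}

#' Two-lobe hinge fixture with a known conformational change
#'
#' Builds an open/closed pair emulating a hinged two-domain protein: two
#' compact random clusters of nodes bridged by a short neck, the closed
#' partner obtained by rigidly rotating one lobe about the neck's z-axis by
#' \code{hinge_angle}. The conformational-change vector is known by
#' construction, and the fixture is regenerated with incremented seeds until
#' its lowest internal mode resembles the hinge motion (overlap of mode 7
#' with the change greater than that of a mid-spectrum mode), so that
#' low-frequency forcing is the analytically favoured driver.
#'
#' @param nodes_per_lobe nodes in each lobe (>= 4, default 8).
#' @param hinge_angle closing rotation in degrees (default 20).
#' @param seed RNG seed for the lobe point clouds.
#' @param lobe_radius cluster radius in Angstrom (default 4).
#' @param lobe_offset distance of each lobe centre from the hinge along x,
#'   Angstrom (default 13; with the default 15 A cutoff only the neck
#'   bridges the lobes).
#' @param mass node mass in amu (default 110, a typical residue mass).
#' @param cutoff cutoff used for the generation-time mode check (default 15).
#' @param gamma spring constant for the generation-time check, N/m.
#' @param max_tries regeneration attempts before giving up.
#' @return List with \code{open} and \code{closed}
#'   (\code{\link{cg_structure}} pair), \code{cc} (the
#'   \code{\link{conformational_change}}), \code{hinge_angle}, \code{seed}
#'   (the accepted seed), \code{recipe}.
#' @export
make_hinge <- function(nodes_per_lobe = 8, hinge_angle = 20, seed = 1,
                       lobe_radius = 4, lobe_offset = 13, mass = 110,
                       cutoff = 15, gamma = 0.1, max_tries = 20) {
  stopifnot(nodes_per_lobe >= 4)
  for (try in seq_len(max_tries)) {
    s <- seed + try - 1L
    fx <- .hinge_once(nodes_per_lobe, hinge_angle, s, lobe_radius,
                      lobe_offset, mass)
    if (hinge_angle == 0) return(fx)
    ok <- tryCatch({
      net <- build_network(fx$open, cutoff = cutoff, gamma = gamma)
      modes <- anm_modes(net)
      o7 <- overlap(modes$modes[, modes$n_rigid + 1L], fx$cc)
      mid <- min(modes$n_rigid + 14L, ncol(modes$modes))
      omid <- overlap(modes$modes[, mid], fx$cc)
      o7 > omid && o7 > 0.5
    }, error = function(e) FALSE)
    if (ok) return(fx)
  }
  stop("could not generate a hinge fixture whose lowest mode matches the ",
       "hinge motion in ", max_tries, " attempts")
}

.hinge_once <- function(npl, angle_deg, seed, radius, offset, mass) {
  pts <- .with_seed(seed, {
    lobe <- function(center) {
      p <- matrix(stats::runif(3 * npl, -radius, radius), ncol = 3)
      ## keep points inside the sphere for compactness
      r <- sqrt(rowSums(p^2))
      p <- p * pmin(1, radius / pmax(r, 1e-6))
      sweep(p, 2, center, "+")
    }
    list(a = lobe(c(-offset, 0, 0)), b = lobe(c(offset, 0, 0)))
  })
  ## Each lobe is anchored through a deterministic base triangle to a
  ## 3-node neck triangle. Both attachment sets are non-collinear, so the
  ## hinge carries no zero-energy mechanism (a lobe tied to <= 2 external
  ## points, or to collinear ones, could pivot freely). The neck triangle
  ## is wide in z and narrow in y, leaving the in-plane (xy) bend -- the
  ## direction of the closing rotation -- as the softest internal motion.
  base_tri <- function(x) rbind(c(x, 1.2, 0), c(x, -0.6, 2.6),
                                c(x, -0.6, -2.6))
  neck <- rbind(c(-1.5, 0, 3.5), c(-1.5, 0, -3.5),
                c(1.5, 0, 3.5), c(1.5, 0, -3.5))
  xyz_open <- rbind(pts$a, base_tri(-offset + 4), neck,
                    base_tri(offset - 4), pts$b)
  n <- nrow(xyz_open)
  open <- cg_structure(xyz_open, masses = mass, source_id = "hinge-open")
  ## closed partner: rotate the whole of lobe b (base triangle + random
  ## cluster) rigidly about the z-axis through the neck centre
  th <- angle_deg * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz_closed <- xyz_open
  idx_b <- (npl + 8):n
  xyz_closed[idx_b, ] <- xyz_closed[idx_b, , drop = FALSE] %*% t(Rz)
  closed <- cg_structure(xyz_closed, masses = mass,
                         source_id = "hinge-closed")
  cc <- suppressWarnings(conformational_change(open, closed))
  list(open = open, closed = closed, cc = cc, hinge_angle = angle_deg,
       seed = seed, recipe = "hinge")
}

#' Synthetic experimental B-factor column
#'
#' Generates per-node "experimental" B-factors from the network's own
#' thermal-fluctuation prediction at a known spring constant, optionally
#' degraded by multiplicative lognormal noise. Used for calibration
#' round-trip testing: with zero noise, \code{\link{calibrate_gamma}}
#' recovers the generating gamma exactly.
#'
#' @param struct a \code{\link{cg_structure}}.
#' @param gamma generating spring constant gamma* in N/m.
#' @param temperature K (default 300).
#' @param noise_fraction sdlog of the multiplicative lognormal noise
#'   (0 = noise-free).
#' @param cutoff network cutoff, Angstrom.
#' @param seed RNG seed for the noise draws.
#' @return The input structure with its \code{bfactors} field replaced by
#'   the synthetic column.
#' @export
make_synthetic_bfactors <- function(struct, gamma, temperature = 300,
                                    noise_fraction = 0, cutoff = 15,
                                    seed = 1) {
  stopifnot(inherits(struct, "cg_structure"), gamma > 0,
            noise_fraction >= 0)
  net <- build_network(struct, cutoff = cutoff, gamma = gamma)
  b <- compute_bfactors(anm_modes(net), temperature = temperature)
  if (noise_fraction > 0)
    b <- b * .with_seed(seed,
           stats::rlnorm(length(b), meanlog = 0, sdlog = noise_fraction))
  struct$bfactors <- b
  struct
}
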