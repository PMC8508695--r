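## Shared test fixtures and independent oracles.

## random compact node cloud; every pair within the default cutoff
toy_cloud <- function(n = 5, seed = 42, spread = 6, mass = 100) {
  xyz <- anmdyn:::.with_seed(seed,
    matrix(stats::runif(3 * n, -spread / 2, spread / 2), ncol = 3))
  cg_structure(xyz, masses = mass, source_id = sprintf("cloud%d", n))
}

## minimal hand-written PDB fixture: 3 residues, one with two altlocs
write_tiny_pdb <- function(path, altloc_b_occ = NULL) {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 12.00           C",
    "ATOM      3  CA  GLY A   2      12.685   7.162  -5.034  1.00 14.00           C")
  if (!is.null(altloc_b_occ)) {
    lines <- c(lines[1:2],
      sub("CA  GLY", "CA AGLY", sub("1.00 14.00", "0.40 14.00", lines[3])),
      sprintf("ATOM      4  CA BGLY A   2      12.900   7.000  -5.100  %.2f 15.00           C",
              altloc_b_occ))
  }
  lines <- c(lines,
    "ATOM      5  CA  LYS A   3      14.100   8.100  -5.200  1.00 16.00           C",
    "HETATM    6  O   HOH A   4      18.000   9.000  -5.000  1.00 30.00           O",
    "END")
  writeLines(lines, path)
  path
}

## independent oracle: direct numerical integration of the full coupled
## second-order system M u'' + C u' + H u = F sin(wF t) in coordinate
## space, with the modal damping matrix C = M Delta diag(2 xi w) Delta' M.
## Returns displacements (frames x 3N) in Angstrom at times_ps.
ode_trajectory_oracle <- function(network, modes, excitation, times_ps,
                                  rtol = 1e-11) {
  ps <- 1e-12
  n3 <- nrow(modes$modes)
  M <- mass_matrix(network$structure)
  Delta <- modes$modes
  omega <- modes$omega
  xi <- rep(0, n3)
  nr <- (modes$n_rigid + 1L):n3
  xi[nr] <- rep_len(excitation$damping, length(nr))
  H <- anm_hessian(network)
  Cm <- (Delta * M) %*% ((2 * xi * omega) * t(Delta * M))
  Fv <- excitation$pattern$force
  wf <- excitation$omega_f
  deriv <- function(t, y, parms) {
    u <- y[1:n3]; v <- y[(n3 + 1):(2 * n3)]
    acc <- (Fv * sin(wf * t * ps) - Cm %*% (v / ps) - H %*% u) / M
    list(c(v, ps^2 * acc))
  }
  sol <- deSolve::lsoda(rep(0, 2 * n3), times_ps, deriv, NULL,
                        rtol = rtol, atol = 1e-22)
  u <- sol[, 1 + (1:n3), drop = FALSE]
  ## a random force has a net rigid-body component, so the coordinate-space
  ## solution drifts ballistically; remove that component (mass metric) to
  ## compare against the internal-mode response
  rigid <- Delta[, seq_len(modes$n_rigid), drop = FALSE]
  u <- u - u %*% (M * rigid) %*% t(rigid)
  u / 1e-10                                         # m -> Angstrom
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) /
              max(abs(expected), .Machine$double.eps), tol)
}
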