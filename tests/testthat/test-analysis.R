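rotation_z <- function(deg) {
  th <- deg * pi / 180
  rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
}

test_that("superposition recovers a known rigid transform", {
  ref <- toy_cloud(n = 10, seed = 31, spread = 12)
  R <- rotation_z(35) %*%
    rbind(c(1, 0, 0), c(0, cos(0.4), -sin(0.4)), c(0, sin(0.4), cos(0.4)))
  mob <- ref
  mob$xyz <- sweep(ref$xyz %*% t(R), 2, c(3, -7, 2), "+")
  fit <- superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-8)
  expect_equal(fit$xyz, ref$xyz, tolerance = 1e-8)
})

test_that("reflections are rejected: the fitted rotation is always proper", {
  ref <- toy_cloud(n = 8, seed = 17, spread = 10)
  mirror <- ref
  mirror$xyz[, 1] <- -mirror$xyz[, 1]
  fit <- superpose(mirror, ref)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("the fitted RMSD beats any random rotation", {
  ref <- toy_cloud(n = 10, seed = 3, spread = 9)
  mob <- toy_cloud(n = 10, seed = 4, spread = 9)
  best <- superpose(mob, ref)$rmsd
  yc <- colMeans(ref$xyz)
  for (k in 1:100) {
    R <- anmdyn:::.with_seed(k, {
      q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
      rbind(
        c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]),
          2 * (q[2] * q[4] + q[3] * q[1])),
        c(2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2),
          2 * (q[3] * q[4] - q[2] * q[1])),
        c(2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]),
          1 - 2 * (q[2]^2 + q[3]^2)))
    })
    Xc <- sweep(mob$xyz, 2, colMeans(mob$xyz))
    trial <- sweep(Xc %*% t(R), 2, yc, "+")
    expect_gte(sqrt(mean(rowSums((trial - ref$xyz)^2))), best - 1e-12)
  }
})

test_that("conformational change vanishes for identical or rotated copies", {
  s <- toy_cloud(n = 8, seed = 23, spread = 10)
  expect_warning(cc0 <- conformational_change(s, s), "zero norm")
  expect_lt(sqrt(sum(cc0$cc^2)), 1e-10)
  rot <- s
  rot$xyz <- sweep(s$xyz %*% t(rotation_z(50)), 2, c(1, 2, 3), "+")
  expect_warning(ccr <- conformational_change(s, rot), "zero norm")
  expect_lt(sqrt(sum(ccr$cc^2)), 1e-8)
})

test_that("hinge fixture change is the in-plane bend the recipe constructs", {
  fx <- make_hinge(nodes_per_lobe = 8, hinge_angle = 20, seed = 1)
  d2 <- rowSums(fx$cc$per_node^2)
  ## the closing rotation is about z, so the change is in-plane
  expect_lt(max(abs(fx$cc$per_node[, 3])), 0.15 * max(sqrt(d2)))
  ## zero hinge angle leaves no conformational change
  fx0 <- make_hinge(nodes_per_lobe = 8, hinge_angle = 0, seed = 1)
  expect_lt(sqrt(sum(fx0$cc$cc^2)), 1e-8)
  ## the generation-time contract: the softest mode is the hinge bend
  m <- anm_modes(build_network(fx$open, cutoff = 15, gamma = 0.1))
  expect_gt(overlap(m$modes[, 7], fx$cc), 0.5)
  expect_gt(overlap(m$modes[, 7], fx$cc),
            overlap(m$modes[, 21], fx$cc))
  ## the bend involves both lobes, so it is far more collective than a
  ## single-node displacement on the same fixture
  single <- rep(0, 3 * fx$open$n); single[1:3] <- 1
  expect_gt(collectivity(fx$cc), 5 * collectivity(single))
})

test_that("overlap identities: parallel, orthogonal, scale and sign invariance", {
  v <- c(1, -2, 3, 0.5, 0, -1)
  expect_equal(overlap(2 * v, v), 1)
  expect_equal(overlap(-0.3 * v, v), 1)
  w <- c(2, 1, 0, 0, 0, 0)
  w <- w - v * sum(w * v) / sum(v^2)
  expect_equal(overlap(w, v), 0)
  u <- stats::rnorm(6)
  expect_equal(overlap(5 * u, v), overlap(u, v))
  expect_error(overlap(0 * v, v), "undefined")
})

test_that("overlap series is constant for one mode, varying for two", {
  s <- toy_cloud(n = 5, seed = 2)
  m <- anm_modes(build_network(s, cutoff = 15, gamma = 0.1))
  cc <- stats::rnorm(15)
  f7 <- m$mass_diag * m$modes[, 7]
  f7 <- f7 / max(abs(f7)) * 1e-10
  tr <- synthesize_trajectory(m, harmonic_excitation(f7, 0.05, 0.1),
                              times_ps = seq(1, 60, by = 1))
  os <- overlap_series(tr, cc)
  vals <- os$overlap[!is.na(os$overlap)]
  expect_gt(length(vals), 10)
  expect_lt(diff(range(vals)), 1e-6)
  ## two incommensurate modes -> direction changes over time
  f78 <- m$mass_diag * (m$modes[, 7] + m$modes[, 8])
  f78 <- f78 / max(abs(f78)) * 1e-10
  tr2 <- synthesize_trajectory(m, harmonic_excitation(f78, 0.05, 0.1),
                               times_ps = seq(1, 60, by = 1))
  os2 <- overlap_series(tr2, cc)
  expect_gt(diff(range(os2$overlap, na.rm = TRUE)), 1e-3)
  expect_true(all(os2$overlap >= 0 & os2$overlap <= 1, na.rm = TRUE))
  expect_gte(os2$max + 1e-12, max(os2$overlap, na.rm = TRUE))
})

test_that("RMSD series matches its double-loop definition", {
  u <- matrix(stats::rnorm(4 * 9), nrow = 4)       # 4 frames, 3 nodes
  r <- rmsd_series(u)
  oracle <- sapply(1:4, function(t) {
    acc <- 0
    for (i in 1:3) acc <- acc + sum(u[t, (3 * i - 2):(3 * i)]^2)
    sqrt(acc / 3)
  })
  expect_equal(r, oracle)
  expect_equal(rmsd_series(matrix(rep(c(1, 0, 0), 5), nrow = 1)), 1)
  expect_equal(rmsd_series(matrix(0, 2, 9)), c(0, 0))
})

test_that("cosine non-linearity separates linear from curvilinear motion", {
  ## linear back-and-forth: only +1 / -1
  ts <- seq(0, 4 * pi, length.out = 40)
  u_lin <- outer(sin(ts), c(1, 2, -1, 0.5, 1, 0))
  cl <- cosine_nonlinearity(u_lin)
  expect_true(all(abs(abs(cl[!is.na(cl)]) - 1) < 1e-8))
  ## circular 2-D motion of one node sweeps the full range
  u_circ <- cbind(cos(ts), sin(ts), 0 * ts)
  ccirc <- cosine_nonlinearity(u_circ)
  expect_lt(min(ccirc, na.rm = TRUE), -0.95)
  expect_gt(max(ccirc, na.rm = TRUE), 0.95)
  ## brute-force per-element oracle on a random trajectory
  u <- matrix(stats::rnorm(6 * 12), nrow = 6)
  cn <- cosine_nonlinearity(u)
  for (i in 1:4) for (t in 1:5) {
    di <- u[t + 1, (3 * i - 2):(3 * i)] - u[t, (3 * i - 2):(3 * i)]
    d0 <- u[2, (3 * i - 2):(3 * i)] - u[1, (3 * i - 2):(3 * i)]
    expect_equal(cn[i, t],
                 sum(di * d0) / sqrt(sum(di^2) * sum(d0^2)))
  }
})

test_that("PCA matches the SVD route and reconstructs the data", {
  X <- matrix(stats::rnorm(4 * 6), nrow = 4)
  p <- pca_conformations(X)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- 3                                   # rank = s - 1
  expect_equal(p$values[1:k], unname(pr$sdev[1:k]^2), tolerance = 1e-10)
  expect_equal(unname(abs(colSums(p$vectors[, 1:k] * pr$rotation[, 1:k]))),
               rep(1, k), tolerance = 1e-8)
  expect_equal(sum(p$values), sum(diag(stats::cov(X))))
  expect_equal(p$var_fraction, p$values / sum(p$values))
  ## reconstruction: centered data = scores %*% t(components)
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(Xc - p$scores %*% t(p$vectors))), 1e-8)
  ## variation along a single direction concentrates all variance on PC1
  dir <- stats::rnorm(6)
  X1 <- outer(c(-2, 0.5, 3), dir)
  p1 <- pca_conformations(X1)
  expect_equal(p1$var_fraction[1], 1, tolerance = 1e-12)
  ## supplementary projection is consistent with the training scores
  expect_equal(drop(predict(p, X[2, ])), p$scores[2, ])
  expect_error(pca_conformations(X[1, , drop = FALSE]), "at least 2")
})

test_that("collectivity spans its entropy limits and invariances", {
  n <- 12
  even <- rep(c(1, 0, 0), n)
  expect_equal(collectivity(even), 1)
  single <- rep(0, 3 * n); single[4] <- 2.5
  expect_equal(collectivity(single), 1 / n)
  v <- stats::rnorm(3 * n)
  expect_equal(collectivity(7.3 * v), collectivity(v))
  perm <- sample(n)
  vp <- as.numeric(t(matrix(v, ncol = 3, byrow = TRUE)[perm, ]))
  expect_equal(collectivity(vp), collectivity(v))
  expect_gt(collectivity(even), collectivity(single))
  expect_error(collectivity(rep(0, 3 * n)), "undefined")
})

test_that("scan rows reproduce a direct single run and are deterministic", {
  fx <- make_hinge(seed = 1)
  net <- build_network(fx$open, cutoff = 15, gamma = 0.1)
  m <- anm_modes(net)
  freqs <- c(0.008, 0.3)
  sc1 <- frequency_scan(m, fx$cc, freqs, 0.05, seeds = 4:5,
                        cycles = 3, dt_per_cycle = 40)
  sc2 <- frequency_scan(m, fx$cc, freqs, 0.05, seeds = 4:5,
                        cycles = 3, dt_per_cycle = 40)
  expect_identical(sc1, sc2)                       # bit-reproducible
  expect_equal(nrow(sc1), 4L)
  ## direct recomputation of one grid point
  pat <- random_force_pattern(fx$open$n, seed = 4)
  exc <- harmonic_excitation(pat, 0.008, 0.05)
  tr <- synthesize_trajectory(m, exc, cycles = 3, dt_per_cycle = 40)
  sel <- tr$times_ps >= tr$transient_ps
  os <- overlap_series(tr, fx$cc)
  row <- sc1[sc1$freq_thz == 0.008 & sc1$seed == 4, ]
  expect_equal(row$max_overlap, max(os$overlap[sel], na.rm = TRUE))
  expect_equal(row$max_rmsd, max(rmsd_series(tr)[sel]))
  u_stat <- static_response(m, pat)
  expect_equal(row$static_rmsd, rmsd_series(matrix(u_stat, nrow = 1)))
  expect_equal(row$amplification, row$max_rmsd / row$static_rmsd)
  ## per-pattern optimum reduction
  best <- scan_optimal_frequencies(sc1)
  expect_equal(nrow(best), 2L)
  expect_true(all(best$best_overlap >= 0 & best$best_overlap <= 1))
})
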