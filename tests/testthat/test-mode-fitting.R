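# brute-force rigid superposition: numerical optimization over rotations
brute_superpose_rmsd <- function(P, Q) {
  obj <- function(par) {
    R <- with_angles(par)
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  }
  best <- Inf
  for (start in list(c(0, 0, 0), c(1, 1, 1), c(-1, 2, 0.5))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}
with_angles <- function(a) {
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

test_that("Kabsch superposition recovers exact transforms and beats brute force", {
  s <- make_helix_fixture(7, 3, noise = 0.1, seed = 16)
  # onto itself
  self <- kabsch_superpose(s, s)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)
  # onto a rotated + translated copy
  set.seed(10)
  R <- random_rotation(); shift <- c(4, -2, 7)
  moved <- set_coords(s, sweep(coords(s) %*% R, 2, shift, `+`))
  sup <- kabsch_superpose(s, moved)
  expect_equal(sup$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup$rotation, R, tolerance = 1e-8)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(coords(s), coords(s)[-1, ]), "mismatch")
})

test_that("4-point toy superposition matches the brute-force optimum and bio3d", {
  P <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
  Q <- P; Q[1, ] <- Q[1, ] + c(0.3, -0.2, 0.8)
  got <- kabsch_superpose(P, Q)$rmsd
  expect_equal(got, brute_superpose_rmsd(P, Q), tolerance = 1e-6)
  # independent reference implementation (bio3d rounds to 3 decimals)
  b3 <- bio3d::rmsd(as.vector(t(Q)), as.vector(t(P)), fit = TRUE)
  expect_lt(abs(got - b3), 6e-4)
})

test_that("conformational-change vectors are unit mass-weighted displacements", {
  pair <- make_hinge_pair(12, 3, hinge_residue = 6, angle = 20)
  dv <- change_vector(pair$apo, pair$holo)
  expect_equal(sqrt(sum(dv$yhat^2)), 1, tolerance = 1e-10)
  expect_gt(dv$raw_rmsd, 0)
  # identical structures: typed degenerate error
  expect_error(change_vector(pair$apo, pair$apo),
               class = "cnd_degenerate_displacement")
  # direct construction oracle: superpose holo onto apo, difference,
  # mass-weight, project out the apo rigid-body subspace, normalize
  sup <- kabsch_superpose(pair$holo, pair$apo)
  sm <- rep(sqrt(pair$apo$mass), each = 3)
  y <- as.vector(t(sup$xyz - coords(pair$apo))) * sm
  B <- rigid_body_basis(coords(pair$apo))
  B <- qr.Q(qr(B * sm))
  y <- y - as.vector(B %*% crossprod(B, y))
  expect_equal(dv$yhat, y / sqrt(sum(y^2)), tolerance = 1e-10)
  expect_true(dv$rigid_fraction >= 0 && dv$rigid_fraction < 0.05)
  # well-defined under rigid motion of either input: the displacement norm
  # and superposition RMSD are unchanged
  set.seed(31)
  R <- random_rotation()
  holo2 <- set_coords(pair$holo, sweep(coords(pair$holo) %*% R, 2, c(3, 1, -2), `+`))
  dv2 <- change_vector(pair$apo, holo2)
  expect_equal(dv2$norm, dv$norm, tolerance = 1e-8)
  expect_equal(dv2$raw_rmsd, dv$raw_rmsd, tolerance = 1e-8)
})

test_that("cumulative fitting obeys the orthonormal-basis identities", {
  s <- make_helix_fixture(8, 3, noise = 0.1, seed = 17)
  md <- run_modes(s, "enm")
  nv <- length(md$omega2)
  # yhat equal to mode 1: perfect fit from the first mode
  fit1 <- cumulative_fit(md$vectors[, 1], md, max_modes = 10)
  # residual ~ sqrt(orthonormality error), so the tolerance allows for the
  # square-root amplification of eigenvector round-off
  expect_equal(fit1$curve$rel_rmsd, rep(0, 10), tolerance = 1e-6)
  expect_equal(fit1$curve$coverage[1], 100, tolerance = 1e-6)
  # yhat orthogonal to the first k modes: no fit until they are passed
  fitk <- cumulative_fit(md$vectors[, 8], md, max_modes = 10)
  expect_equal(fitk$curve$rel_rmsd[1:7], rep(1, 7), tolerance = 1e-8)
  # random yhat: Pythagoras, monotonicity, complete-basis exactness
  set.seed(30)
  for (k in 1:5) {
    y <- rnorm(3 * nrow(s)); y <- y / sqrt(sum(y^2))
    # project out rigid-body content so the vibrational basis is complete
    Vfull <- md$vectors
    y <- as.vector(Vfull %*% crossprod(Vfull, y))
    y <- y / sqrt(sum(y^2))
    fit <- cumulative_fit(y, md, max_modes = nv)
    expect_true(all(diff(fit$curve$rel_rmsd) <= 1e-12))
    expect_true(all(fit$curve$rel_rmsd >= 0 & fit$curve$rel_rmsd <= 1))
    nm <- 25
    expect_equal(fit$curve$rel_rmsd[nm]^2 + sum(fit$coefficients[1:nm]^2), 1,
                 tolerance = 1e-10)
    expect_lt(fit$curve$rel_rmsd[nv], 1e-6)
    # coverage + 100 * relRMSD = 100 by construction
    expect_equal(fit$curve$coverage + 100 * fit$curve$rel_rmsd,
                 rep(100, nv), tolerance = 1e-9)
  }
  # alternative coverage formula
  fit2 <- cumulative_fit(md$vectors[, 2], md, max_modes = 5,
                         coverage_formula = "one_minus_r2")
  expect_equal(fit2$curve$coverage[2], 100, tolerance = 1e-6)
})

test_that("trajectory PCA equals a brute-force covariance eigendecomposition", {
  s <- make_helix_fixture(3, 2)  # 6 atoms
  set.seed(8)
  frames <- lapply(1:15, function(k) coords(s) + matrix(rnorm(18, sd = 0.3), ncol = 3))
  tr <- as_trajectory(s, frames)
  pc <- trajectory_pca(tr, superpose = FALSE)
  X <- tr$xyz
  mw <- rep(sqrt(s$mass), each = 3)
  Q <- sweep(sweep(X, 2, colMeans(X)), 2, mw, `*`)
  C <- crossprod(Q) / (nrow(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  k <- length(pc$variances)
  expect_equal(pc$variances, eg$values[1:k], tolerance = 1e-8)
  for (j in 1:3)
    expect_equal(abs(sum(pc$vectors[, j] * eg$vectors[, j])), 1, tolerance = 1e-6)
  # orthonormal principal vectors
  G <- crossprod(pc$vectors)
  expect_lt(max(abs(G - diag(k))), 1e-8)
  # identical frames: degenerate warning, zero variance
  tr0 <- as_trajectory(s, lapply(1:4, function(k) coords(s)))
  expect_warning(pc0 <- trajectory_pca(tr0, superpose = FALSE), "degenerate")
  expect_equal(length(pc0$variances), 0L)
})

test_that("a planted 2-direction Gaussian trajectory is recovered", {
  s <- make_helix_fixture(6, 3)
  n3 <- 3 * nrow(s)
  set.seed(123)
  v1 <- rnorm(n3); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- rnorm(n3); v2 <- v2 - sum(v2 * v1) * v1; v2 <- v2 / sqrt(sum(v2^2))
  inv_mw <- 1 / rep(sqrt(s$mass), each = 3)
  amp <- cbind(rnorm(5000, sd = 2), rnorm(5000, sd = 1))
  X <- t(vapply(seq_len(5000), function(f) {
    as.vector(t(coords(s))) + inv_mw * (amp[f, 1] * v1 + amp[f, 2] * v2)
  }, numeric(n3)))
  pc <- trajectory_pca(as_trajectory(s, X), superpose = FALSE)
  expect_equal(pc$variances[1], 4, tolerance = 0.05 * 4)
  expect_equal(pc$variances[2], 1, tolerance = 0.05)
  expect_gt(abs(sum(pc$vectors[, 1] * v1)), 0.99)
  expect_gt(abs(sum(pc$vectors[, 2] * v2)), 0.99)
})
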