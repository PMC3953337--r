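test_that("contact weight is a sigmoid centered at d_cut", {
  p <- contact_params()
  expect_equal(rho(p$d_cut, p), 0.5)
  expect_equal(rho(0, p), 1, tolerance = 0.1)
  expect_lt(rho(p$d_cut + 10 * p$sigma, p), 1e-4)
  # monotonically non-increasing for several parameter settings
  for (sig in c(0.5, 1, 2, 3)) {
    pp <- contact_params(sigma = sig, d_cut = 5)
    d <- seq(0, 20, by = 0.05)
    expect_true(all(diff(rho(d, pp)) <= 0))
    expect_true(all(rho(d, pp) >= 0 & rho(d, pp) <= 1))
  }
})

test_that("local topology follows the sequence window and chain boundaries", {
  a <- make_helix_fixture(3, 5, chain = "A")
  top <- local_mask(a, w = 1)
  expect_true(isSymmetric(top$theta))
  expect_true(all(!diag(top$theta)))
  # single residue of 5 atoms: all 10 off-diagonal pairs local
  one_res <- as_structure(a[a$resno == 1, c("elety", "elem", "chain", "resno",
                                            "x", "y", "z", "b")])
  expect_equal(nrow(local_mask(one_res, 1)$local_pairs), 10L)
  # 3-residue chain, w = 1: residue 1 / residue 3 pairs are non-local
  i1 <- which(a$resno == 1); i3 <- which(a$resno == 3)
  expect_true(all(!top$theta[i1, i3]))
  expect_true(all(top$theta[i1, which(a$resno == 2)]))
  # cross-chain pairs always non-local
  b <- make_helix_fixture(3, 5, chain = "B")
  two <- as_structure(dplyr::bind_rows(
    a[, c("elety", "elem", "chain", "resno", "x", "y", "z", "b")],
    b[, c("elety", "elem", "chain", "resno", "x", "y", "z", "b")]))
  th2 <- local_mask(two, 1)$theta
  expect_true(all(!th2[two$chain == "A", two$chain == "B"]))
})

test_that("contact numbers match the brute-force all-pairs oracle", {
  p <- contact_params()
  # isolated single residue: no non-local partners at all
  one <- as_structure(tibble::tibble(elety = c("N", "CA", "C"), elem = NA,
                                     chain = "A", resno = 1,
                                     x = c(0, 1.5, 2.4), y = c(0, 0, 1), z = 0,
                                     b = 0))
  expect_equal(contact_numbers(one, params = p)$n_contact, rep(0, 3))
  # two non-local atoms exactly d_cut apart get 0.5 each; the middle residue
  # is local to both ends, so it contributes to neither contact number
  tri <- as_structure(tibble::tibble(elety = "CA", elem = NA, chain = "A",
                                     resno = 1:3, x = c(0, p$d_cut / 2, p$d_cut),
                                     y = c(0, 30, 0), z = 0, b = 0))
  expect_equal(contact_numbers(tri, params = p)$n_contact, c(0.5, 0, 0.5))
  # random fixtures against the double loop, including a 50-atom noisy helix
  for (s in list(make_helix_fixture(8, 4, noise = 0.3, seed = 5),
                 make_helix_fixture(10, 5, noise = 0.1, seed = 11))) {
    expect_equal(contact_numbers(s, params = p)$n_contact,
                 brute_contact_numbers(s, p), tolerance = 1e-12)
  }
})

test_that("diffusion terms contrast an atom against its local neighbours and sum to zero", {
  s <- make_helix_fixture(10, 3, noise = 0.2, seed = 2)
  top <- local_mask(s, 1)
  # uniform contact numbers: no diffusion anywhere
  expect_equal(diffusion_term(s, n = rep(2.5, nrow(s)), topology = top)$diffusion,
               rep(0, nrow(s)))
  # a single spike: positive there, negative on its theta-neighbours
  n_spike <- rep(1, nrow(s)); n_spike[15] <- 5
  D <- diffusion_term(s, n = n_spike, topology = top)$diffusion
  expect_gt(D[15], 0)
  nbrs <- which(top$theta[15, ])
  expect_true(all(D[nbrs] < 0))
  # antisymmetric pair contributions: sum is zero for arbitrary input
  set.seed(1)
  for (rep_i in 1:5) {
    nn <- runif(nrow(s), 0, 10)
    expect_equal(sum(diffusion_term(s, n = nn, topology = top)$diffusion), 0,
                 tolerance = 1e-9)
  }
})

test_that("native multipliers make the native structure a stationary point", {
  for (s in list(helix30(), make_helix_fixture(9, 4, noise = 0.25, seed = 8))) {
    for (p in list(contact_params(), fd_params())) {
      res <- native_multipliers(s, params = p)
      g <- cnd_gradient(s, res)
      scale <- max(p$A * max(pair_dist_ref(s)), 1)
      expect_lt(max(abs(g)) / scale, 1e-10)
      # perturbed evaluation point: gradient no longer vanishes
      x <- as.vector(t(coords(s))); x[5] <- x[5] + 0.3
      expect_gt(max(abs(cnd_gradient(x, res))), 1e-3)
    }
  }
  # B = 0 removes the per-atom multipliers entirely
  res0 <- native_multipliers(helix30(), params = contact_params(B = 1e-12))
  expect_lt(max(abs(res0$mu0)), 1e-6)
  resB <- native_multipliers(helix30(), params = contact_params(B = 1))
  expect_equal(resB$mu0, resB$params$B * resB$D0)
})

test_that("energy is invariant under rigid motions and has the stated breakdown", {
  s <- make_helix_fixture(8, 3, noise = 0.1, seed = 4)
  res <- native_multipliers(s, params = fd_params())
  e0 <- cnd_energy(s, res)
  br <- attr(e0, "breakdown")
  expect_named(br, c("local", "diffusion", "lambda", "mu"))
  expect_equal(sum(br), as.numeric(e0))
  set.seed(7)
  for (k in 1:5) {
    R <- random_rotation()
    shift <- rnorm(3, sd = 10)
    moved <- sweep(coords(s) %*% R, 2, shift, `+`)
    expect_equal(as.numeric(cnd_energy(moved, res)), as.numeric(e0),
                 tolerance = 1e-9)
  }
  expect_error(cnd_energy(coords(s)[-1, ], res), "mismatch")
})

test_that("analytic gradient matches finite differences; net force and torque vanish", {
  s <- make_helix_fixture(8, 3, noise = 0.15, seed = 6)
  res <- native_multipliers(s, params = fd_params())
  set.seed(21)
  for (k in 1:5) {
    x <- as.vector(t(coords(s))) + rnorm(3 * nrow(s), sd = 0.2)
    ga <- cnd_gradient(x, res)
    gn <- fd_gradient(function(v) as.numeric(cnd_energy(v, res)), x, h = 1e-5)
    expect_lt(max(abs(ga - gn)), 1e-4)
    # translational and rotational invariance of the energy
    F <- matrix(ga, ncol = 3, byrow = TRUE)
    expect_lt(max(abs(colSums(F))), 1e-8)
    xyz <- matrix(x, ncol = 3, byrow = TRUE)
    torque <- colSums(cbind(
      xyz[, 2] * F[, 3] - xyz[, 3] * F[, 2],
      xyz[, 3] * F[, 1] - xyz[, 1] * F[, 3],
      xyz[, 1] * F[, 2] - xyz[, 2] * F[, 1]))
    expect_lt(max(abs(torque)), 1e-7)
  }
})

test_that("stationarity holds for 100 random directional derivatives at the native point", {
  s <- helix30()
  res <- native_multipliers(s, params = contact_params())
  e0 <- as.numeric(cnd_energy(s, res))
  g <- cnd_gradient(s, res)
  set.seed(3)
  for (k in 1:100) {
    u <- rnorm(length(g)); u <- u / sqrt(sum(u^2))
    expect_lt(abs(sum(g * u)), 1e-6 * max(1, abs(e0)))
  }
})
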