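# shared fixtures and independent oracles, built in code at test time

helix30 <- function() make_helix_fixture(10, 3)
helix48 <- function() make_helix_fixture(12, 4)

# moderate-scale weights for finite-difference comparisons: the analytic
# Hessian is exactly linear in (A, B) (asserted in test-hessians), so the
# oracle at unit scale extends to any scale
fd_params <- function(A = 10, B = 2) contact_params(A = A, B = B, w = 1, sigma = 2, d_cut = 5)

pair_dist_ref <- function(s) max(stats::dist(coords(s)))

# O(N^2) brute-force contact numbers: plain double loop over all pairs
brute_contact_numbers <- function(structure, params) {
  xyz <- coords(structure)
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sep <- sequence_separation(structure, i, j)
    if (is.finite(sep) && sep <= params$w) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    out[i] <- out[i] + 1 / (1 + exp((d - params$d_cut) / params$sigma))
  }
  out
}

# central finite-difference gradient of a scalar energy
fd_gradient <- function(energy_fn, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    (energy_fn(xp) - energy_fn(xm)) / (2 * h)
  }, numeric(1))
}

# rigid-body basis at a configuration: 3 translations + 3 rotations
rigid_body_basis <- function(xyz) {
  n <- nrow(xyz)
  ctr <- sweep(xyz, 2, colMeans(xyz))
  B <- matrix(0, 3 * n, 6)
  for (a in 1:3) B[seq(a, 3 * n, by = 3), a] <- 1
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (a in 1:3) {
    rot <- t(apply(ctr, 1, function(r) {
      k <- axes[[a]]
      c(k[2] * r[3] - k[3] * r[2], k[3] * r[1] - k[1] * r[3], k[1] * r[2] - k[2] * r[1])
    }))
    B[, 3 + a] <- as.vector(t(rot))
  }
  B
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
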