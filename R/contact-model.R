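#' Contact-number diffusion model parameters
#'
#' `A` weights the local pairwise restraint term, `B` the contact-number
#' diffusion term (both dimensionless weights; only ratios matter for the
#' scale-invariant observables the package reports). `w` is the sequence
#' window in residues defining local pairs (with `w = 1` a local
#' neighbourhood is a tri-peptide segment), `sigma` the steepness of the
#' sigmoidal contact weight in angstroms, and `d_cut` its midpoint in
#' angstroms. Defaults follow the model's calibrated settings
#' (A = 10000, B = 1, w = 1, sigma = 2, d_cut = 5).
#'
#' @param A local-term weight (> 0).
#' @param B diffusion-term weight (>= 0).
#' @param w local window size in residues (>= 0).
#' @param sigma sigmoid steepness in angstroms (> 0).
#' @param d_cut contact cutoff distance in angstroms (> 0).
#' @return A `cnd_params` list.
#' @export
contact_params <- function(A = 10000, B = 1, w = 1, sigma = 2, d_cut = 5) {
  stopifnot(A > 0, B >= 0, w >= 0, sigma > 0, d_cut > 0)
  structure(list(A = A, B = B, w = w, sigma = sigma, d_cut = d_cut),
            class = "cnd_params")
}

#' Sigmoidal contact weight
#'
#' `rho(d) = 1 / (1 + exp((d - d_cut) / sigma))`: a soft, monotonically
#' non-increasing step that is 1 at short range, 1/2 at `d_cut`, and decays
#' to 0 with steepness set by `sigma`.
#'
#' @param d distances in angstroms (>= 0).
#' @param params a [contact_params()] object.
#' @return weights in `[0, 1]`.
#' @export
rho <- function(d, params = contact_params()) {
  stopifnot(all(d >= 0))
  1 / (1 + exp((d - params$d_cut) / params$sigma))
}

# d rho / d d; equals -rho (1 - rho) / sigma for the logistic form
rho_deriv <- function(d, params) {
  r <- 1 / (1 + exp((d - params$d_cut) / params$sigma))
  -r * (1 - r) / params$sigma
}

#' Local-pair topology
#'
#' Two atoms form a local pair when they belong to the same chain and their
#' residues are separated by at most `w` positions along the sequence
#' (self-pairs excluded). Cross-chain pairs are always non-local. The
#' topology is fixed by the native structure's chain layout and never changes
#' with the conformation.
#'
#' @param structure structure table.
#' @param w window size in residues.
#' @return A `cnd_topology` object: `theta` (N x N symmetric logical matrix),
#'   `local_pairs` / `nonlocal_pairs` (two-column index matrices, i < j),
#'   `w`, `n_atoms`.
#' @export
local_mask <- function(structure, w = 1) {
  n <- nrow(structure)
  if (n < 1) abort("empty structure")
  pr <- t(utils::combn(n, 2))
  sep <- sequence_separation(structure, pr[, 1], pr[, 2])
  is_local <- is.finite(sep) & sep <= w
  theta <- matrix(FALSE, n, n)
  theta[pr[is_local, , drop = FALSE]] <- TRUE
  theta <- theta | t(theta)
  out <- list(theta = theta,
              local_pairs = pr[is_local, , drop = FALSE],
              nonlocal_pairs = pr[!is_local, , drop = FALSE],
              w = w, n_atoms = n)
  class(out) <- "cnd_topology"
  out
}

# distances for a set of index pairs
pair_dist <- function(xyz, pairs) {
  if (nrow(pairs) == 0) return(numeric(0))
  dd <- xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE]
  sqrt(rowSums(dd * dd))
}

# full geometric/contact state of a conformation under a fixed topology:
# local distances d_lp, non-local distances d_np, contact numbers n,
# local contact-number differences s (n_i - n_j over local pairs) and the
# diffusion terms D_i = sum_j theta_ij d_ij^2 (n_i - n_j)
cnd_state <- function(xyz, topology, params) {
  lp <- topology$local_pairs
  np <- topology$nonlocal_pairs
  d_lp <- pair_dist(xyz, lp)
  d_np <- pair_dist(xyz, np)
  r_np <- rho(d_np, params)
  n <- numeric(topology$n_atoms)
  if (nrow(np) > 0) {
    n <- n + .accum(topology$n_atoms, np[, 1], r_np) +
      .accum(topology$n_atoms, np[, 2], r_np)
  }
  s <- if (nrow(lp) > 0) n[lp[, 1]] - n[lp[, 2]] else numeric(0)
  D <- .accum(topology$n_atoms, lp[, 1], d_lp^2 * s) -
    .accum(topology$n_atoms, lp[, 2], d_lp^2 * s)
  list(d_lp = d_lp, d_np = d_np, rho_np = r_np, n = n, s = s, D = D)
}

# sum vals into an n-vector (or n x k matrix) by index, tolerating duplicates
.accum <- function(n, idx, vals) {
  if (length(idx) == 0) {
    if (is.matrix(vals)) return(matrix(0, n, ncol(vals))) else return(numeric(n))
  }
  if (is.matrix(vals)) {
    out <- matrix(0, n, ncol(vals))
    rs <- rowsum(vals, idx)
    out[as.integer(rownames(rs)), ] <- rs
    out
  } else {
    out <- numeric(n)
    rs <- rowsum(vals, idx)
    out[as.integer(rownames(rs))] <- rs
    out
  }
}

#' Non-local contact numbers
#'
#' The contact number of atom `i` is the soft count of non-local atoms
#' surrounding it: `n_i = sum over j (theta_ij = 0, j != i) of rho(d_ij)`.
#' Contact numbers are dual to atomic burial/hydrophobicity: core atoms have
#' large `n`, surface atoms small `n`.
#'
#' @param structure structure table.
#' @param topology a [local_mask()]; built from `structure` with `params$w`
#'   when omitted.
#' @param params a [contact_params()].
#' @return tibble with columns `atom`, `res_index`, `n_contact`.
#' @export
contact_numbers <- function(structure, topology = NULL, params = contact_params()) {
  if (is.null(topology)) topology <- local_mask(structure, params$w)
  if (topology$n_atoms != nrow(structure)) abort("topology/structure size mismatch")
  st <- cnd_state(coords(structure), topology, params)
  tibble(atom = structure$atom, res_index = structure$res_index, n_contact = st$n)
}

#' Contact-number diffusion term
#'
#' `D_i = sum_j theta_ij d_ij^2 (n_i - n_j)`: the distance-weighted contrast
#' of an atom's contact number against its sequence-local neighbours. `D_i`
#' is positive when atom `i` is more buried than its neighbours (it then
#' tends to diffuse toward less crowded regions); pair contributions are
#' antisymmetric so the diffusion terms always sum to zero over the chain.
#'
#' @param structure structure table (provides the local pair distances).
#' @param n per-atom contact numbers (vector, or the tibble from
#'   [contact_numbers()]); computed when omitted.
#' @param topology a [local_mask()].
#' @param params a [contact_params()].
#' @return tibble with columns `atom`, `diffusion`.
#' @export
diffusion_term <- function(structure, n = NULL, topology = NULL,
                           params = contact_params()) {
  if (is.null(topology)) topology <- local_mask(structure, params$w)
  if (is.null(n)) n <- contact_numbers(structure, topology, params)
  if (is.data.frame(n)) n <- n$n_contact
  if (length(n) != nrow(structure)) abort("contact-number length mismatch")
  lp <- topology$local_pairs
  d_lp <- pair_dist(coords(structure), lp)
  s <- if (nrow(lp) > 0) n[lp[, 1]] - n[lp[, 2]] else numeric(0)
  D <- .accum(nrow(structure), lp[, 1], d_lp^2 * s) -
    .accum(nrow(structure), lp[, 2], d_lp^2 * s)
  tibble(atom = structure$atom, diffusion = D)
}

#' Native restraints: Lagrange multipliers at the native structure
#'
#' The CND energy contains two autonomous terms (local pairwise repulsion
#' weighted by `A` and contact-number heterogeneity weighted by `B`) and two
#' constraint terms that bias the system to the native structure through
#' Lagrange multipliers: one multiplier `lambda_ij` per local pair and one
#' `mu_i` per atom. Setting the energy Jacobian to zero at the native
#' structure gives the closed forms
#' `lambda_ij^0 = d_ij^0 (A + B (n_i^0 - n_j^0)^2)` and `mu_i^0 = B D_i^0`,
#' which cancel the local-pair and contact-number forces pairwise. The
#' multipliers encode the protein's intrinsic tendency for its specific local
#' structures and native burial pattern; with `B = 0` the per-atom
#' multipliers vanish.
#'
#' @param structure the native structure.
#' @param topology a [local_mask()]; defaults to `params$w`.
#' @param params a [contact_params()].
#' @return A `cnd_restraints` object: native coordinates, `n0`, `D0`,
#'   `lambda0` (per local pair), `mu0` (per atom), the topology and params.
#' @export
native_multipliers <- function(structure, topology = NULL,
                               params = contact_params()) {
  if (is.null(topology)) topology <- local_mask(structure, params$w)
  if (topology$n_atoms != nrow(structure)) abort("topology/structure size mismatch")
  xyz <- coords(structure)
  st <- cnd_state(xyz, topology, params)
  lambda0 <- st$d_lp * (params$A + params$B * st$s^2)
  mu0 <- params$B * st$D
  out <- list(xyz0 = xyz, n0 = st$n, D0 = st$D, lambda0 = lambda0, mu0 = mu0,
              topology = topology, params = params,
              masses = structure$mass, structure = structure)
  class(out) <- "cnd_restraints"
  out
}

#' @export
print.cnd_restraints <- function(x, ...) {
  cat(sprintf(paste0("<cnd_restraints> %d atoms, %d local-pair multipliers, ",
                     "%d per-atom multipliers (A=%g, B=%g, w=%g, sigma=%g, d_cut=%g)\n"),
              x$topology$n_atoms, length(x$lambda0), length(x$mu0),
              x$params$A, x$params$B, x$params$w, x$params$sigma, x$params$d_cut))
  invisible(x)
}

.conf_xyz <- function(conf, n_atoms) {
  if (inherits(conf, "cnd_structure") || is.data.frame(conf)) conf <- coords(conf)
  if (is.null(dim(conf))) conf <- matrix(conf, ncol = 3, byrow = TRUE)
  if (nrow(conf) != n_atoms) abort("conformation/restraints dimension mismatch")
  unname(as.matrix(conf))
}

#' Contact-number diffusion energy
#'
#' Evaluates the CND energy of a conformation under restraints built on the
#' native structure:
#' \deqn{U = \frac12 \sum_{i<j} \theta_{ij} d_{ij}^2 (A + B (n_i - n_j)^2)
#'       - \sum_{i<j} \theta_{ij} \lambda^0_{ij} d_{ij} - \sum_i \mu^0_i n_i}
#' The energy depends on coordinates only through interatomic distances, so
#' it is exactly invariant under rigid translations and rotations, and the
#' native structure is a stationary point by construction of the multipliers.
#'
#' @param conf structure, N x 3 matrix, or length-3N coordinate vector.
#' @param restraints a [native_multipliers()] object.
#' @return scalar energy (dimensionless model units) with a `"breakdown"`
#'   attribute giving the local, diffusion, lambda and mu terms.
#' @export
cnd_energy <- function(conf, restraints) {
  xyz <- .conf_xyz(conf, restraints$topology$n_atoms)
  st <- cnd_state(xyz, restraints$topology, restraints$params)
  A <- restraints$params$A; B <- restraints$params$B
  terms <- c(local = 0.5 * A * sum(st$d_lp^2),
             diffusion = 0.5 * B * sum(st$d_lp^2 * st$s^2),
             lambda = -sum(restraints$lambda0 * st$d_lp),
             mu = -sum(restraints$mu0 * st$n))
  out <- sum(terms)
  attr(out, "breakdown") <- terms
  out
}

#' Gradient of the contact-number diffusion energy
#'
#' Analytic Jacobian of [cnd_energy()] with respect to all 3N Cartesian
#' coordinates. At the native structure it vanishes identically; at any other
#' conformation it matches central finite differences of the energy. Because
#' the energy is a function of distances only, the net force and net torque
#' are always zero.
#'
#' @inheritParams cnd_energy
#' @return numeric length-3N gradient vector (x1, y1, z1, x2, ...).
#' @export
cnd_gradient <- function(conf, restraints) {
  xyz <- .conf_xyz(conf, restraints$topology$n_atoms)
  top <- restraints$topology
  par <- restraints$params
  st <- cnd_state(xyz, top, par)
  n_at <- top$n_atoms
  G <- matrix(0, n_at, 3)
  lp <- top$local_pairs
  if (nrow(lp) > 0) {
    # dU/dd for each local pair times the unit bond vector
    gl <- (par$A + par$B * st$s^2) * st$d_lp - restraints$lambda0
    uv <- (xyz[lp[, 1], , drop = FALSE] - xyz[lp[, 2], , drop = FALSE]) / st$d_lp
    f <- gl * uv
    G <- G + .accum(n_at, lp[, 1], f) - .accum(n_at, lp[, 2], f)
  }
  np <- top$nonlocal_pairs
  if (nrow(np) > 0) {
    # (B D_i - mu_i) + (B D_j - mu_j) couples through d n/d d = rho'
    gcoef <- par$B * st$D - restraints$mu0
    gn <- (gcoef[np[, 1]] + gcoef[np[, 2]]) * rho_deriv(st$d_np, par)
    uv <- (xyz[np[, 1], , drop = FALSE] - xyz[np[, 2], , drop = FALSE]) / st$d_np
    f <- gn * uv
    G <- G + .accum(n_at, np[, 1], f) - .accum(n_at, np[, 2], f)
  }
  as.vector(t(G))
}
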