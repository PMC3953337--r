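# accumulate vals into matrix M at (rows, cols), summing duplicate entries
.add_entries <- function(M, rows, cols, vals) {
  lin <- (cols - 1) * nrow(M) + rows
  rs <- rowsum(vals, lin)
  at <- as.numeric(rownames(rs))
  M[at] <- M[at] + rs[, 1]
  M
}

.new_hessian <- function(H, model, masses, mass_weighted = FALSE) {
  H <- (H + t(H)) / 2
  structure(list(entries = H, model = model, masses = masses,
                 mass_weighted = mass_weighted, n_atoms = length(masses)),
            class = "cnd_hessian")
}

#' @export
print.cnd_hessian <- function(x, ...) {
  cat(sprintf("<cnd_hessian> %s, %d atoms (3N = %d)%s\n", x$model, x$n_atoms,
              3 * x$n_atoms, if (x$mass_weighted) ", mass-weighted" else ""))
  invisible(x)
}

#' Analytic Hessian of the contact-number diffusion energy
#'
#' Second derivative of [cnd_energy()] at the native structure. Because the
#' Lagrange multipliers cancel every first derivative of the energy with
#' respect to the interatomic distances and contact numbers at the native
#' point, the Hessian reduces exactly to the Gauss-Newton form
#' `H = G^T K G`, where `G` stacks the Jacobians of the local pair distances
#' and of the per-atom contact numbers with respect to the Cartesian
#' coordinates, and `K` is the second derivative of the energy in those
#' intermediate variables. The `A`-weighted local term touches only
#' band-diagonal (sequence-local) blocks; every off-band coupling carries a
#' factor of `B`, so with `B = 0` the Hessian is sparse with O(N) nonzero
#' blocks. `H` is exactly linear in `A` and `B`.
#'
#' @param structure the native structure.
#' @param restraints a [native_multipliers()] object; built from `structure`
#'   when omitted.
#' @param topology,params used only when `restraints` is omitted.
#' @return A `cnd_hessian` (not yet mass-weighted).
#' @export
cnd_hessian <- function(structure, restraints = NULL, topology = NULL,
                        params = contact_params()) {
  if (is.null(restraints))
    restraints <- native_multipliers(structure, topology, params)
  top <- restraints$topology
  par <- restraints$params
  if (top$n_atoms != nrow(structure)) abort("restraints/structure size mismatch")
  xyz <- coords(structure)
  if (max(abs(xyz - restraints$xyz0)) > 1e-9)
    abort("cnd_hessian must be evaluated at the native structure used to build the restraints")
  st <- cnd_state(xyz, top, par)
  n_at <- top$n_atoms
  lp <- top$local_pairs
  np <- top$nonlocal_pairs
  n_lp <- nrow(lp)
  nq <- n_lp + n_at
  G <- matrix(0, nq, 3 * n_at)
  if (n_lp > 0) {
    uv <- (xyz[lp[, 1], , drop = FALSE] - xyz[lp[, 2], , drop = FALSE]) / st$d_lp
    al <- seq_len(n_lp)
    for (a in 1:3) {
      G[cbind(al, 3 * (lp[, 1] - 1) + a)] <- uv[, a]
      G[cbind(al, 3 * (lp[, 2] - 1) + a)] <- -uv[, a]
    }
  }
  if (nrow(np) > 0) {
    rp <- rho_deriv(st$d_np, par)
    uvn <- (xyz[np[, 1], , drop = FALSE] - xyz[np[, 2], , drop = FALSE]) / st$d_np
    for (a in 1:3) {
      v <- rp * uvn[, a]
      ci <- 3 * (np[, 1] - 1) + a
      cj <- 3 * (np[, 2] - 1) + a
      # rows n_lp + i and n_lp + j both see +v at atom i's column and -v at j's
      G <- .add_entries(G, n_lp + np[, 1], ci, v)
      G <- .add_entries(G, n_lp + np[, 1], cj, -v)
      G <- .add_entries(G, n_lp + np[, 2], ci, v)
      G <- .add_entries(G, n_lp + np[, 2], cj, -v)
    }
  }
  K <- matrix(0, nq, nq)
  if (n_lp > 0) {
    al <- seq_len(n_lp)
    K[cbind(al, al)] <- par$A + par$B * st$s^2
    cross <- 2 * par$B * st$s * st$d_lp
    K[cbind(al, n_lp + lp[, 1])] <- cross
    K[cbind(al, n_lp + lp[, 2])] <- -cross
    K[cbind(n_lp + lp[, 1], al)] <- cross
    K[cbind(n_lp + lp[, 2], al)] <- -cross
    # graph Laplacian of the local topology weighted by d_ij^2
    w2 <- st$d_lp^2
    L <- matrix(0, n_at, n_at)
    L[lp] <- -w2
    L[lp[, c(2, 1), drop = FALSE]] <- -w2
    diag(L) <- .accum(n_at, lp[, 1], w2) + .accum(n_at, lp[, 2], w2)
    K[(n_lp + 1):nq, (n_lp + 1):nq] <- par$B * L
  }
  H <- crossprod(G, K %*% G)
  .new_hessian(H, "CND", structure$mass)
}

#' Elastic network model parameters
#'
#' @param amplitude overall spring amplitude `A_ENM` (default 1).
#' @param d_cut interaction cutoff / sigmoid midpoint in angstroms.
#' @param sigma steepness of the sigmoidal spring rule in angstroms.
#' @param spring_rule `"sigmoid"` (spring constant `rho(d0)`, the same
#'   sigmoidal family as the contact weight), `"cutoff"` (unit spring for
#'   `d0 <= d_cut`, none beyond), or `"uniform"` (unit spring between every
#'   atom pair regardless of distance; this is the network the
#'   contact-number model reduces to in its all-local limit).
#' @param c_min springs weaker than this are dropped (defines the finite
#'   interaction range of the sigmoid rule).
#' @return An `enm_params` list.
#' @export
enm_params <- function(amplitude = 1, d_cut = 5, sigma = 2,
                       spring_rule = c("sigmoid", "cutoff", "uniform"),
                       c_min = 1e-8) {
  spring_rule <- match.arg(spring_rule)
  stopifnot(amplitude > 0, d_cut > 0, sigma > 0, c_min >= 0)
  structure(list(amplitude = amplitude, d_cut = d_cut, sigma = sigma,
                 spring_rule = spring_rule, c_min = c_min),
            class = "enm_params")
}

#' Build an elastic network model
#'
#' `U = (A_ENM / 2) sum_{i<j} c_ij (d_ij - d_ij^0)^2`, with spring constants
#' `c_ij` given by the spring rule evaluated at the native distances. The
#' model object fixes the spring list; [enm_energy()], [enm_gradient()] and
#' [enm_hessian()] all refer to the same network.
#'
#' @param structure the native structure.
#' @param params an [enm_params()].
#' @return An `enm_model`: spring pair list, constants `cij`, native
#'   distances `d0`, masses, params.
#' @export
enm_model <- function(structure, params = enm_params()) {
  n <- nrow(structure)
  if (n < 2) abort("ENM needs at least two atoms")
  pr <- t(utils::combn(n, 2))
  d0 <- pair_dist(coords(structure), pr)
  cij <- switch(params$spring_rule,
    sigmoid = 1 / (1 + exp((d0 - params$d_cut) / params$sigma)),
    cutoff = as.numeric(d0 <= params$d_cut),
    uniform = rep(1, length(d0)))
  keep <- cij > params$c_min
  structure(list(pairs = pr[keep, , drop = FALSE], cij = cij[keep],
                 d0 = d0[keep], masses = structure$mass,
                 xyz0 = coords(structure), params = params),
            class = "enm_model")
}

#' Elastic network potential energy
#' @param conf structure, N x 3 matrix or length-3N vector.
#' @param model an [enm_model()].
#' @return scalar energy.
#' @export
enm_energy <- function(conf, model) {
  xyz <- .conf_xyz(conf, length(model$masses))
  d <- pair_dist(xyz, model$pairs)
  0.5 * model$params$amplitude * sum(model$cij * (d - model$d0)^2)
}

#' Gradient of the elastic network potential
#' @inheritParams enm_energy
#' @return length-3N gradient vector.
#' @export
enm_gradient <- function(conf, model) {
  xyz <- .conf_xyz(conf, length(model$masses))
  pr <- model$pairs
  d <- pair_dist(xyz, pr)
  g <- model$params$amplitude * model$cij * (d - model$d0)
  uv <- (xyz[pr[, 1], , drop = FALSE] - xyz[pr[, 2], , drop = FALSE]) / d
  f <- g * uv
  n_at <- length(model$masses)
  G <- .accum(n_at, pr[, 1], f) - .accum(n_at, pr[, 2], f)
  as.vector(t(G))
}

#' Analytic Hessian of the elastic network model
#'
#' At the native structure every spring is at its equilibrium length, so each
#' spring contributes the rank-one block `A_ENM c_ij e e^T` along its bond
#' direction; diagonal blocks are minus the sum of the off-diagonal blocks in
#' the same block row (translational invariance).
#'
#' @param structure the native structure, or an [enm_model()].
#' @param params an [enm_params()] (ignored when a model is supplied).
#' @return A `cnd_hessian` with model tag `"ENM"` (not mass-weighted).
#' @export
enm_hessian <- function(structure, params = enm_params()) {
  model <- if (inherits(structure, "enm_model")) structure
           else enm_model(structure, params)
  pr <- model$pairs
  n_at <- length(model$masses)
  uv <- (model$xyz0[pr[, 1], , drop = FALSE] - model$xyz0[pr[, 2], , drop = FALSE]) / model$d0
  H <- matrix(0, 3 * n_at, 3 * n_at)
  k <- model$params$amplitude * model$cij
  for (a in 1:3) for (b in 1:3) {
    blk <- k * uv[, a] * uv[, b]
    ia <- 3 * (pr[, 1] - 1) + a; ib <- 3 * (pr[, 1] - 1) + b
    ja <- 3 * (pr[, 2] - 1) + a; jb <- 3 * (pr[, 2] - 1) + b
    H <- .add_entries(H, ia, ib, blk)
    H <- .add_entries(H, ja, jb, blk)
    H <- .add_entries(H, ia, jb, -blk)
    H <- .add_entries(H, ja, ib, -blk)
  }
  .new_hessian(H, "ENM", model$masses)
}

#' Mass-weight a Hessian
#'
#' `H~_ij = H_ij / sqrt(m_i m_j)` applied per Cartesian coordinate, turning
#' the equations of motion into a standard symmetric eigenproblem whose
#' eigenvalues are the squared angular frequencies.
#'
#' @param H a `cnd_hessian` (not yet mass-weighted).
#' @param masses per-atom masses; defaults to those stored in `H`.
#' @return A mass-weighted `cnd_hessian`.
#' @export
mass_weight <- function(H, masses = NULL) {
  if (H$mass_weighted) abort("Hessian is already mass-weighted")
  if (is.null(masses)) masses <- H$masses
  if (length(masses) != H$n_atoms) abort("mass vector length mismatch")
  if (any(masses <= 0)) abort("masses must be positive")
  inv <- 1 / sqrt(rep(masses, each = 3))
  Hm <- H$entries * tcrossprod(inv)
  .new_hessian(Hm, H$model, masses, mass_weighted = TRUE)
}

#' Central-difference Hessian of a scalar energy function
#'
#' Test oracle: symmetric second derivatives of `energy_fn` by central finite
#' differences, exact for quadratics up to round-off. O((3N)^2) energy
#' evaluations; intended for small fixtures.
#'
#' @param energy_fn function of a length-3N coordinate vector returning a
#'   scalar.
#' @param conf structure, N x 3 matrix or length-3N vector.
#' @param step finite-difference step in angstroms.
#' @return a symmetric 3N x 3N matrix.
#' @export
finite_difference_hessian <- function(energy_fn, conf, step = 1e-4) {
  stopifnot(step > 0)
  if (inherits(conf, "cnd_structure") || is.data.frame(conf)) conf <- coords(conf)
  x <- if (is.null(dim(conf))) as.numeric(conf) else as.vector(t(conf))
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- energy_fn(x)
  ev <- function(dk, hk, dl = 0, hl = 0) {
    y <- x; y[dk] <- y[dk] + hk
    if (dl > 0) y[dl] <- y[dl] + hl
    energy_fn(y)
  }
  for (k in seq_len(n)) {
    H[k, k] <- (ev(k, step) - 2 * f0 + ev(k, -step)) / step^2
    if (k < n) for (l in (k + 1):n) {
      H[k, l] <- (ev(k, step, l, step) - ev(k, step, l, -step) -
                  ev(k, -step, l, step) + ev(k, -step, l, -step)) / (4 * step^2)
      H[l, k] <- H[k, l]
    }
  }
  H
}

#' Equivalence of the contact-number model's all-local limit with a uniform
#' elastic network
#'
#' When the sequence window spans the whole chain every pair is local, all
#' contact numbers vanish, and the multipliers reduce to
#' `lambda_ij^0 = A d_ij^0`; the energy becomes
#' `(A/2) sum (d_ij - d_ij^0)^2` plus a constant -- a uniform-spring elastic
#' network. This check builds both Hessians, mass-weights them, and reports
#' the overlap between their lowest vibrational subspaces and the ratio of
#' their eigenvalues.
#'
#' @param structure a small structure (single chain).
#' @param params a [contact_params()]; only `A` matters in the limit.
#' @param n_modes number of lowest vibrational modes compared.
#' @return list with `overlap` (per-mode squared projection of each limit-CND
#'   mode onto the uniform-ENM subspace), `mean_sq_overlap`, and
#'   `eigenvalue_ratio` (CND / ENM, per mode).
#' @export
cnd_to_enm_limit_check <- function(structure, params = contact_params(),
                                   n_modes = 10) {
  w_full <- max(structure$res_index) + 1
  top <- local_mask(structure, w_full)
  if (nrow(top$nonlocal_pairs) > 0)
    abort("limit check needs a single-chain structure (cross-chain pairs stay non-local)")
  par_full <- contact_params(A = params$A, B = params$B, w = w_full,
                             sigma = params$sigma, d_cut = params$d_cut)
  res <- native_multipliers(structure, top, par_full)
  H_cnd <- mass_weight(cnd_hessian(structure, res))
  H_enm <- mass_weight(enm_hessian(structure,
    enm_params(amplitude = params$A, spring_rule = "uniform")))
  m_cnd <- normal_modes(H_cnd)
  m_enm <- normal_modes(H_enm)
  k <- min(n_modes, ncol(m_cnd$vectors), ncol(m_enm$vectors))
  Vc <- m_cnd$vectors[, seq_len(k), drop = FALSE]
  Ve <- m_enm$vectors[, seq_len(k), drop = FALSE]
  ov <- rowSums((crossprod(Vc, Ve))^2)
  list(overlap = ov, mean_sq_overlap = mean(ov),
       eigenvalue_ratio = m_cnd$omega2[seq_len(k)] / m_enm$omega2[seq_len(k)])
}
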