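#' Kabsch superposition
#'
#' Optimal least-squares rigid-body superposition of one structure onto
#' another via singular value decomposition, constrained to a proper rotation
#' (determinant +1). Unweighted all-atom superposition by default; weights
#' (e.g. masses) optional.
#'
#' @param mobile,target structures (or N x 3 matrices) with equal atom counts
#'   in corresponding order.
#' @param weights optional per-atom weights.
#' @return list with `rotation` (3 x 3, acts on row vectors), `translation`
#'   (length 3), `rmsd` (angstroms, over `weights`), and `xyz` (the
#'   transformed mobile coordinates, N x 3).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  P <- if (is.data.frame(mobile)) coords(mobile) else as.matrix(mobile)
  Q <- if (is.data.frame(target)) coords(target) else as.matrix(target)
  if (nrow(P) != nrow(Q)) abort("atom count mismatch between mobile and target")
  n <- nrow(P)
  w <- if (is.null(weights)) rep(1, n) else weights
  if (length(w) != n || any(w < 0) || sum(w) == 0) abort("invalid weights")
  wf <- w / sum(w)
  cm <- colSums(P * wf); ct <- colSums(Q * wf)
  P0 <- sweep(P, 2, cm); Q0 <- sweep(Q, 2, ct)
  C <- crossprod(P0 * wf, Q0)
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- P0 %*% R
  rmsd <- sqrt(sum(wf * rowSums((fitted - Q0)^2)))
  list(rotation = R, translation = ct - cm %*% R,
       rmsd = rmsd, xyz = sweep(fitted, 2, ct, `+`))
}

# orthonormal basis of the mass-weighted rigid-body subspace at xyz
mass_weighted_rigid_basis <- function(xyz, masses) {
  n <- nrow(xyz)
  sm <- rep(sqrt(masses), each = 3)
  ctr <- sweep(xyz, 2, colSums(xyz * masses) / sum(masses))
  B <- matrix(0, 3 * n, 6)
  for (a in 1:3) B[seq(a, 3 * n, by = 3), a] <- 1
  axes <- diag(3)
  for (a in 1:3) {
    k <- axes[, a]
    rot <- cbind(k[2] * ctr[, 3] - k[3] * ctr[, 2],
                 k[3] * ctr[, 1] - k[1] * ctr[, 3],
                 k[1] * ctr[, 2] - k[2] * ctr[, 1])
    B[, 3 + a] <- as.vector(t(rot))
  }
  qr.Q(qr(B * sm))
}

#' Mass-weighted conformational-change vector
#'
#' The two structures are brought into a common frame by rigid-body
#' superposition of the holo structure onto the apo structure (unweighted,
#' all-atom), so that the displacement is expressed in the frame in which the
#' apo structure's normal modes are defined. The per-atom differences from
#' apo to superposed holo are multiplied coordinate-wise by the square root
#' of the atomic mass; for a finite conformational change a small
#' rigid-body component survives optimal superposition, and it is projected
#' out against the apo structure's mass-weighted rigid-body subspace (the
#' same six directions excluded from the vibrational modes) before
#' normalizing to unit length. The result lives exactly in the span of the
#' vibrational eigenvectors, so least-squares fitting reduces to orthogonal
#' projection and a complete mode basis reproduces it exactly.
#'
#' @param apo,holo structures with identical atom counts and ordering.
#' @param masses per-atom masses; defaults to the apo masses.
#' @param superpose_weights optional weights for the superposition step
#'   (default unweighted, mirroring all-atom RMSD conventions; pass the
#'   masses for a mass-weighted superposition).
#' @param remove_rigid project out the residual rigid-body component
#'   (default TRUE).
#' @return A `cnd_displacement`: `yhat` (unit 3N vector), `raw_rmsd`
#'   (all-atom RMSD of the superposition, in angstroms), `norm` (length of
#'   the unnormalized mass-weighted difference), `rigid_fraction` (squared
#'   norm fraction removed by the rigid-body projection).
#' @export
change_vector <- function(apo, holo, masses = NULL, superpose_weights = NULL,
                          remove_rigid = TRUE) {
  if (nrow(apo) != nrow(holo)) abort("apo/holo atom count mismatch")
  if (is.null(masses)) masses <- apo$mass
  sup <- kabsch_superpose(holo, apo, weights = superpose_weights)
  diff <- sup$xyz - coords(apo)
  y <- as.vector(t(diff)) * rep(sqrt(masses), each = 3)
  nrm0 <- sqrt(sum(y^2))
  rigid_fraction <- 0
  if (remove_rigid && nrm0 > 0) {
    B <- mass_weighted_rigid_basis(coords(apo), masses)
    y <- y - as.vector(B %*% crossprod(B, y))
    rigid_fraction <- 1 - sum(y^2) / nrm0^2
  }
  nrm <- sqrt(sum(y^2))
  if (nrm < 1e-10)
    abort("degenerate conformational change: apo and holo coincide after superposition",
          class = "cnd_degenerate_displacement")
  structure(list(yhat = y / nrm, raw_rmsd = sup$rmsd, norm = nrm,
                 rigid_fraction = rigid_fraction),
            class = "cnd_displacement")
}

#' @export
print.cnd_displacement <- function(x, ...) {
  cat(sprintf("<cnd_displacement> 3N = %d, superposition RMSD %.3f A\n",
              length(x$yhat), x$raw_rmsd))
  invisible(x)
}

#' Cumulative least-squares fit of normal modes to a displacement
#'
#' Approximates a unit mass-weighted displacement by linear combinations of
#' the first `N_m` lowest-frequency modes, for `N_m = 1 .. max_modes`.
#' Because the modes are orthonormal, the least-squares coefficients are the
#' projections `c_i = v_i . yhat` and the residual norm after `N_m` modes --
#' the relative RMSD -- is `sqrt(1 - sum_{i<=N_m} c_i^2)`, bounded between 1
#' (complete failure) and 0 (complete fit) and non-increasing in `N_m`.
#' Coverage is reported as `100 (1 - relRMSD)` by default; the variant
#' `100 (1 - relRMSD^2)` is available via `coverage_formula`. The AUC is the
#' sum of the relative RMSD over the curve (smaller = better fitting).
#'
#' @param yhat a [change_vector()] result, or any unit-norm length-3N vector
#'   in mass-weighted coordinates.
#' @param modes a [normal_modes()] result (vibrational modes only).
#' @param max_modes number of modes in the deepest fit; truncated to the
#'   number available.
#' @param coverage_formula `"one_minus_r"` or `"one_minus_r2"`.
#' @return A `cnd_fit`: `coefficients`, curve tibble (`n_modes`, `rel_rmsd`,
#'   `coverage`), `auc`, `max_modes`, `model`.
#' @export
cumulative_fit <- function(yhat, modes, max_modes = 100,
                           coverage_formula = c("one_minus_r", "one_minus_r2")) {
  coverage_formula <- match.arg(coverage_formula)
  y <- if (inherits(yhat, "cnd_displacement")) yhat$yhat else as.numeric(yhat)
  if (length(y) != nrow(modes$vectors))
    abort("displacement/mode dimension mismatch")
  if (abs(sqrt(sum(y^2)) - 1) > 1e-8) abort("yhat must have unit norm")
  k <- min(max_modes, length(modes$omega2))
  cf <- as.vector(crossprod(modes$vectors[, seq_len(k), drop = FALSE], y))
  resid2 <- pmax(0, 1 - cumsum(cf^2))
  rel <- sqrt(resid2)
  cov <- switch(coverage_formula,
                one_minus_r = 100 * (1 - rel),
                one_minus_r2 = 100 * (1 - resid2))
  out <- list(coefficients = cf,
              curve = tibble(n_modes = seq_len(k), rel_rmsd = rel, coverage = cov),
              auc = sum(rel), max_modes = k, model = modes$model,
              coverage_formula = coverage_formula)
  class(out) <- "cnd_fit"
  out
}

#' @export
print.cnd_fit <- function(x, ...) {
  cat(sprintf("<cnd_fit> %s: %d modes, final coverage %.2f%%, AUC %.3f\n",
              x$model, x$max_modes, x$curve$coverage[x$max_modes], x$auc))
  invisible(x)
}

#' @rdname cumulative_fit
#' @param x a `cnd_fit` object.
#' @param ... unused.
#' @method tidy cnd_fit
#' @export
tidy.cnd_fit <- function(x, ...) x$curve

#' @rdname cumulative_fit
#' @method glance cnd_fit
#' @export
glance.cnd_fit <- function(x, ...) {
  cov_at <- function(n) if (x$max_modes >= n) x$curve$coverage[n] else NA_real_
  tibble(model = x$model, max_modes = x$max_modes, auc = x$auc,
         coverage_5 = cov_at(5), coverage_100 = cov_at(100),
         coverage_final = x$curve$coverage[x$max_modes])
}

#' @rdname cumulative_fit
#' @param object a `cnd_fit` object.
#' @method autoplot cnd_fit
#' @export
autoplot.cnd_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$n_modes, y = .data$rel_rmsd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of lowest-frequency modes N_m",
                  y = "relative RMSD",
                  title = paste(object$model, "cumulative mode fit")) +
    ggplot2::ylim(0, 1)
}

#' Discard equilibration frames from a trajectory
#'
#' @param traj a `cnd_trajectory`.
#' @param n_frames number of leading frames to drop.
#' @return the suffix trajectory.
#' @export
discard_equilibration <- function(traj, n_frames) {
  if (n_frames < 0 || n_frames >= nrow(traj$xyz))
    abort("cannot discard that many frames")
  if (n_frames == 0) return(traj)
  as_trajectory(traj$structure, traj$xyz[-seq_len(n_frames), , drop = FALSE])
}

#' Principal component analysis of a trajectory
#'
#' Each frame is rigid-body superposed onto the mean structure (two passes:
#' onto frame 1, then onto the resulting mean), coordinates are
#' mass-weighted, and the covariance over frames is eigendecomposed.
#' Principal modes are returned in decreasing-variance order as unit vectors
#' in mass-weighted coordinates, directly comparable with normal-mode
#' eigenvectors.
#'
#' @param traj a `cnd_trajectory`.
#' @param masses per-atom masses; defaults to the trajectory structure's.
#' @param superpose superpose frames before the covariance (default TRUE).
#' @return A `cnd_pca`: `vectors` (3N x k, orthonormal), `variances`
#'   (descending), `mean_xyz`, `masses`, `n_frames`.
#' @export
trajectory_pca <- function(traj, masses = NULL, superpose = TRUE) {
  X <- traj$xyz
  if (nrow(X) < 2) abort("need at least two frames for PCA")
  if (is.null(masses)) masses <- traj$structure$mass
  n_at <- length(masses)
  if (ncol(X) != 3 * n_at) abort("trajectory/mass dimension mismatch")
  if (superpose) {
    ref <- matrix(X[1, ], ncol = 3, byrow = TRUE)
    for (pass in 1:2) {
      X <- t(apply(X, 1, function(fr) {
        as.vector(t(kabsch_superpose(matrix(fr, ncol = 3, byrow = TRUE), ref)$xyz))
      }))
      ref <- matrix(colMeans(X), ncol = 3, byrow = TRUE)
    }
  }
  mw <- rep(sqrt(masses), each = 3)
  Q <- sweep(sweep(X, 2, colMeans(X)), 2, mw, `*`)
  if (max(abs(Q)) == 0) warn("degenerate trajectory: all frames identical")
  sv <- svd(Q / sqrt(nrow(X) - 1), nu = 0)
  keep <- sv$d > 0
  out <- list(vectors = sv$v[, keep, drop = FALSE], variances = sv$d[keep]^2,
              mean_xyz = matrix(colMeans(X), ncol = 3, byrow = TRUE),
              masses = masses, n_frames = nrow(X))
  class(out) <- "cnd_pca"
  out
}

#' @export
print.cnd_pca <- function(x, ...) {
  cat(sprintf("<cnd_pca> %d frames, %d principal modes; top variances: %s\n",
              x$n_frames, length(x$variances),
              paste(signif(utils::head(x$variances, 3), 4), collapse = ", ")))
  invisible(x)
}

#' @rdname trajectory_pca
#' @param x a `cnd_pca` object.
#' @param ... unused.
#' @method tidy cnd_pca
#' @export
tidy.cnd_pca <- function(x, ...) {
  tibble(mode = seq_along(x$variances), variance = x$variances,
         variance_fraction = x$variances / sum(x$variances))
}
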