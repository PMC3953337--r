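#' Normal modes of a mass-weighted Hessian
#'
#' Full eigendecomposition of the symmetric mass-weighted Hessian. Modes with
#' `|omega^2|` below `zero_tol` times the largest eigenvalue are flagged as
#' rigid-body modes and excluded from the vibrational indexing; a connected,
#' non-collinear structure has exactly six (three translations, three
#' rotations) and `3N - 6` vibrational modes. Any negative eigenvalue beyond
#' the rigid set is reported in `n_negative` as a diagnostic (stationarity of
#' the native structure does not by itself guarantee a minimum).
#'
#' @param H a mass-weighted `cnd_hessian`.
#' @param zero_tol relative threshold for rigid modes.
#' @return A `cnd_modes` object: `omega2` (vibrational eigenvalues,
#'   ascending), `vectors` (orthonormal mass-weighted eigenvectors, one
#'   column per vibrational mode), `n_zero`, `n_negative`, `masses`, `model`.
#' @export
normal_modes <- function(H, zero_tol = 1e-8) {
  if (!inherits(H, "cnd_hessian")) abort("H must be a cnd_hessian")
  if (!H$mass_weighted)
    abort("H must be mass-weighted (see mass_weight()) before diagonalization")
  eg <- eigen(H$entries, symmetric = TRUE)
  ord <- order(eg$values)
  val <- eg$values[ord]
  vec <- eg$vectors[, ord, drop = FALSE]
  tol <- zero_tol * max(abs(val))
  rigid <- abs(val) < tol
  n_zero <- sum(rigid)
  if (n_zero != 6)
    warn(sprintf("expected 6 rigid-body modes, found %d (disconnected or collinear input?)",
                 n_zero))
  keep <- !rigid
  out <- list(omega2 = val[keep], vectors = vec[, keep, drop = FALSE],
              n_zero = n_zero, n_negative = sum(val[keep] < 0),
              masses = H$masses, model = H$model, n_atoms = H$n_atoms,
              zero_tol = zero_tol)
  class(out) <- "cnd_modes"
  out
}

#' @export
print.cnd_modes <- function(x, ...) {
  cat(sprintf("<cnd_modes> %s: %d vibrational modes (%d atoms, %d rigid removed%s)\n",
              x$model, length(x$omega2), x$n_atoms, x$n_zero,
              if (x$n_negative > 0) sprintf(", %d negative", x$n_negative) else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname normal_modes
#' @param x a `cnd_modes` object.
#' @param ... unused.
#' @method tidy cnd_modes
#' @export
tidy.cnd_modes <- function(x, ...) {
  tibble(mode = seq_along(x$omega2), omega2 = x$omega2,
         variance = ifelse(x$omega2 > 0, 1 / x$omega2, NA_real_))
}

#' @rdname normal_modes
#' @method glance cnd_modes
#' @export
glance.cnd_modes <- function(x, ...) {
  tibble(model = x$model, n_atoms = x$n_atoms, n_modes = length(x$omega2),
         n_zero = x$n_zero, n_negative = x$n_negative)
}

#' Per-atom mean-square fluctuations from normal modes
#'
#' Thermal amplitudes in arbitrary units:
#' `MSF_i = sum_{k in range} |v_k on atom i|^2 / (m_i omega_k^2)`, i.e. the
#' per-atom diagonal of the covariance restricted to the chosen modes. Only
#' scaled or normalized MSF and correlations are ever reported, all of which
#' are invariant to the overall scale.
#'
#' @param modes a [normal_modes()] result.
#' @param mode_range integer indices into the vibrational modes (1 = lowest
#'   frequency); all vibrational modes when `NULL`.
#' @return numeric per-atom MSF vector.
#' @export
msf <- function(modes, mode_range = NULL) {
  if (is.null(mode_range)) mode_range <- seq_along(modes$omega2)
  if (length(mode_range) == 0) abort("empty mode range")
  if (any(mode_range < 1 | mode_range > length(modes$omega2)))
    abort("mode range outside the vibrational modes")
  w2 <- modes$omega2[mode_range]
  if (any(w2 <= 0))
    abort("mode range includes a non-positive eigenvalue; MSF is undefined there")
  V <- modes$vectors[, mode_range, drop = FALSE]
  per_coord <- (V^2) %*% (1 / w2)
  atom_sum <- rowSums(matrix(per_coord, ncol = 3, byrow = TRUE))
  atom_sum / modes$masses
}

#' Average per-atom MSF over residues
#'
#' @param msf per-atom MSF vector.
#' @param structure the structure the modes were computed on.
#' @return tibble with `chain`, `resno`, `res_index`, `msf` (unweighted mean
#'   over the residue's atoms).
#' @export
residue_average_msf <- function(msf, structure) {
  if (length(msf) != nrow(structure)) abort("MSF/structure length mismatch")
  tibble(chain = structure$chain, resno = structure$resno,
         res_index = structure$res_index, msf = msf) %>%
    group_by(.data$chain, .data$resno, .data$res_index) %>%
    summarise(msf = mean(.data$msf), .groups = "drop") %>%
    arrange(.data$chain, .data$res_index)
}

#' Scale one MSF profile to the mean of a reference profile
#'
#' Multiplies `msf` by `mean(reference) / mean(msf)` so the two profiles have
#' equal average, the convention used when overlaying fluctuation profiles
#' from different models.
#'
#' @param msf,reference positive numeric vectors.
#' @return rescaled `msf`.
#' @export
scale_msf <- function(msf, reference) {
  if (mean(msf) <= 0 || mean(reference) <= 0)
    abort("MSF profiles must have positive mean")
  msf * mean(reference) / mean(msf)
}

#' Normalize an MSF profile to unit mean
#'
#' @param msf positive numeric vector.
#' @return unitless vector with mean 1.
#' @export
normalized_msf <- function(msf) {
  if (mean(msf) <= 0) abort("MSF profile must have positive mean")
  msf / mean(msf)
}

#' Cumulative variance captured by the lowest-frequency modes
#'
#' Covariance eigenvalues are `1 / omega_k^2`; sorted descending (i.e. lowest
#' frequency first) their running sum divided by the total gives the fraction
#' of the overall variance captured by the first k modes. The curve is
#' non-decreasing and ends at 1.
#'
#' @param modes a [normal_modes()] result, a `cnd_pca` object, or a positive
#'   numeric vector of `omega^2` values.
#' @return tibble with `n_modes` and `cum_variance`.
#' @export
cumulative_variance <- function(modes) {
  lam <- if (inherits(modes, "cnd_modes")) 1 / modes$omega2
         else if (inherits(modes, "cnd_pca")) modes$variances
         else 1 / as.numeric(modes)
  if (any(lam <= 0)) abort("cumulative variance needs positive eigenvalues")
  lam <- sort(lam, decreasing = TRUE)
  tibble(n_modes = seq_along(lam), cum_variance = cumsum(lam) / sum(lam))
}

#' @rdname cumulative_variance
#' @param object a `cnd_modes` object.
#' @param ... unused.
#' @method autoplot cnd_modes
#' @export
autoplot.cnd_modes <- function(object, ...) {
  cv <- cumulative_variance(object)
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$n_modes, y = .data$cum_variance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of lowest-frequency modes",
                  y = "cumulative variance fraction",
                  title = paste(object$model, "mode spectrum collectivity")) +
    ggplot2::ylim(0, 1)
}
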