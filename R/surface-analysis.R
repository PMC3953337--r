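# van der Waals radii (angstroms) for protein heavy atoms + hydrogen;
# a single published protein radii set (Bondi-type values)
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# deterministic quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley accessible surface area
#'
#' Numerical per-atom solvent-accessible surface area: each atom's
#' solvent-expanded sphere (van der Waals radius + probe radius) is sampled
#' with a deterministic golden-spiral point set; points falling inside any
#' neighbouring atom's expanded sphere are occluded, and the accessible
#' fraction times the sphere area gives the ASA. Deterministic for a fixed
#' point count.
#'
#' @param structure structure table.
#' @param probe probe radius in angstroms (water: 1.4).
#' @param n_sphere_points sample points per atom.
#' @param radii named vector of van der Waals radii overriding the built-in
#'   set.
#' @return tibble with `atom`, `asa` (angstrom^2).
#' @export
shrake_rupley_asa <- function(structure, probe = 1.4, n_sphere_points = 960,
                              radii = NULL) {
  if (nrow(structure) == 0) abort("empty structure")
  rset <- .vdw_radii
  if (!is.null(radii)) rset[names(radii)] <- radii
  key <- toupper(structure$elem)
  unknown <- setdiff(unique(key), names(rset))
  if (length(unknown) > 0)
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(unknown, collapse = ", ")))
  r <- unname(rset[key]) + probe
  xyz <- coords(structure)
  n <- nrow(xyz)
  pts <- .sphere_points(n_sphere_points)
  asa <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nbr <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (length(nbr) == 0) {
      asa[i] <- 4 * pi * r[i]^2
      next
    }
    sp <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_sphere_points)
    for (j in nbr) {
      if (!any(free)) break
      dd <- sweep(sp[free, , drop = FALSE], 2, xyz[j, ])
      free[free] <- rowSums(dd * dd) > r[j]^2
    }
    asa[i] <- 4 * pi * r[i]^2 * sum(free) / n_sphere_points
  }
  tibble(atom = structure$atom, asa = asa)
}

#' Classify atoms as exposed or buried
#'
#' Buried atoms are those with zero accessible surface area; a tolerance
#' `eps` absorbs sampling noise (an atom with `asa < eps` counts as buried).
#'
#' @param asa per-atom ASA vector, or the tibble from [shrake_rupley_asa()].
#' @param eps burial threshold in angstrom^2.
#' @return tibble with `atom`, `asa`, `label` (factor exposed/buried).
#' @export
classify_burial <- function(asa, eps = 1e-6) {
  if (is.data.frame(asa)) {
    atom <- asa$atom; val <- asa$asa
  } else {
    atom <- seq_along(asa); val <- as.numeric(asa)
  }
  if (any(val < 0)) abort("ASA must be non-negative")
  tibble(atom = atom, asa = val,
         label = factor(ifelse(val < eps, "buried", "exposed"),
                        levels = c("exposed", "buried")))
}

#' Mean normalized MSF over exposed and buried atoms
#'
#' @param normalized_msf per-atom normalized MSF (unit mean over all atoms).
#' @param labels a [classify_burial()] tibble (or factor/character vector).
#' @return tibble with one row per group: `label`, `n`, `mean_msf`. A group
#'   with no atoms appears with `n = 0` and `mean_msf = NA`.
#' @export
group_mean_msf <- function(normalized_msf, labels) {
  lab <- if (is.data.frame(labels)) labels$label else labels
  if (length(lab) != length(normalized_msf)) abort("MSF/label length mismatch")
  lab <- factor(lab, levels = c("exposed", "buried"))
  out <- tibble(label = lab, msf = normalized_msf) %>%
    group_by(.data$label, .drop = FALSE) %>%
    summarise(n = dplyr::n(), mean_msf = mean(.data$msf), .groups = "drop")
  if (any(out$n == 0)) warn("empty exposure group")
  out
}

#' Protein atoms in contact with a ligand
#'
#' @param protein,ligand structure tables.
#' @param threshold contact distance in angstroms.
#' @return integer vector of protein atom indices within `threshold` of any
#'   ligand atom (empty if the ligand is empty).
#' @export
ligand_contact_atoms <- function(protein, ligand, threshold = 5) {
  stopifnot(threshold > 0)
  if (is.null(ligand) || nrow(ligand) == 0) return(integer(0))
  P <- coords(protein); L <- coords(ligand)
  d2 <- outer(rowSums(P^2), rowSums(L^2), `+`) - 2 * P %*% t(L)
  which(apply(d2 <= threshold^2 + 1e-12, 1, any))
}

#' Pearson correlation with input validation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return sample Pearson correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("length mismatch")
  if (length(x) < 3) abort("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero variance input")
  stats::cor(x, y)
}

#' Percentile bootstrap confidence interval for a paired statistic
#'
#' Resamples rows of the paired data with replacement and reports the
#' percentile interval of the statistic. Deterministic for a fixed seed (the
#' caller's RNG state is restored).
#'
#' @param x,y paired numeric vectors.
#' @param statistic function of `(x, y)` returning a scalar; defaults to
#'   [pearson_correlation()].
#' @param n_boot number of resamples (>= 100).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return tibble with `estimate`, `lower`, `upper`, `n_boot`.
#' @export
bootstrap_ci <- function(x, y, statistic = pearson_correlation,
                         n_boot = 1000, seed = 1, conf = 0.95) {
  stopifnot(n_boot >= 100, length(x) == length(y))
  est <- statistic(x, y)
  reps <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(x), replace = TRUE)
      tryCatch(statistic(x[idx], y[idx]), error = function(e) NA_real_)
    }, numeric(1))
  })
  qs <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  tibble(estimate = est, lower = qs[1], upper = qs[2], n_boot = n_boot)
}

#' Correlation of model fluctuations with crystallographic B-factors
#'
#' Atomwise Pearson correlation between per-atom MSF and the experimental
#' B-factor column, with a bootstrap confidence interval; residue-averaged
#' comparison available via `by_residue`.
#'
#' @param structure structure table carrying B-factors in column `b`.
#' @param msf_values per-atom MSF from [msf()].
#' @param by_residue average both profiles over residues first.
#' @param n_boot,seed,conf bootstrap settings, see [bootstrap_ci()].
#' @return tibble with `r`, `lower`, `upper`, `n`, `level`.
#' @export
bfactor_correlation <- function(structure, msf_values, by_residue = FALSE,
                                n_boot = 1000, seed = 1, conf = 0.95) {
  if (by_residue) {
    m <- residue_average_msf(msf_values, structure)$msf
    b <- residue_average_msf(structure$b, structure)$msf
  } else {
    m <- msf_values; b <- structure$b
  }
  ci <- bootstrap_ci(m, b, n_boot = n_boot, seed = seed, conf = conf)
  tibble(r = ci$estimate, lower = ci$lower, upper = ci$upper,
         n = length(m), level = if (by_residue) "residue" else "atom")
}
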