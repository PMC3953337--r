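#' End-to-end normal mode computation
#'
#' Runs the full pipeline for one structure under one model: local topology
#' and native restraints (CND) or spring network (ENM), analytic Hessian,
#' mass weighting, diagonalization. Deterministic: the same inputs give the
#' same mode set.
#'
#' @param structure structure table (or a PDB path, read with defaults).
#' @param model `"cnd"` or `"enm"`.
#' @param params a [contact_params()] (CND).
#' @param enm a [enm_params()] (ENM).
#' @param mass_weighted diagonalize the mass-weighted Hessian (the default
#'   for both models); set `FALSE` to use unit masses instead.
#' @return A [normal_modes()] result.
#' @export
run_modes <- function(structure, model = c("cnd", "enm"),
                      params = contact_params(), enm = enm_params(),
                      mass_weighted = TRUE) {
  model <- match.arg(model)
  if (is.character(structure)) structure <- read_structure(structure)
  H <- switch(model,
    cnd = cnd_hessian(structure, native_multipliers(structure, params = params)),
    enm = enm_hessian(structure, enm))
  masses <- if (mass_weighted) structure$mass else rep(1, nrow(structure))
  normal_modes(mass_weight(H, masses))
}

#' Coverage of an apo-holo conformational change by normal modes
#'
#' For each model, fits the apo-to-holo change with the apo structure's
#' modes and the holo-to-apo change with the holo structure's modes, and
#' reports the coverage at the requested mode counts.
#'
#' @param apo,holo matched structures (equal atom counts and ordering).
#' @param params,enm model parameters.
#' @param models character subset of `c("cnd", "enm")`.
#' @param n_modes mode counts at which coverage is reported.
#' @param coverage_formula see [cumulative_fit()].
#' @return tibble with `model`, `modes_from` (apo/holo), `n_modes`,
#'   `coverage`, `rel_rmsd`, `auc`.
#' @export
run_table2 <- function(apo, holo, params = contact_params(),
                       enm = enm_params(), models = c("cnd", "enm"),
                       n_modes = c(5, 100),
                       coverage_formula = "one_minus_r") {
  if (nrow(apo) != nrow(holo)) abort("apo/holo atom count mismatch")
  dir <- list(apo = change_vector(apo, holo), holo = change_vector(holo, apo))
  purrr::map_dfr(models, function(mod) {
    purrr::map_dfr(names(dir), function(from) {
      ms <- run_modes(if (from == "apo") apo else holo, model = mod,
                      params = params, enm = enm)
      fit <- cumulative_fit(dir[[from]], ms, max_modes = max(n_modes),
                            coverage_formula = coverage_formula)
      nm <- pmin(n_modes, fit$max_modes)
      tibble(model = toupper(mod), modes_from = from, n_modes = nm,
             coverage = fit$curve$coverage[nm],
             rel_rmsd = fit$curve$rel_rmsd[nm], auc = fit$auc)
    })
  })
}

#' Parameter sweep over the contact model's free parameters
#'
#' Re-runs the apo-holo coverage analysis and the B-factor correlation over
#' a grid of `A`, `w` and `sigma` values (with `B` fixed), mirroring a
#' grid-search calibration of the contact model.
#'
#' @param apo,holo matched structures.
#' @param A,w,sigma numeric grids.
#' @param B fixed diffusion weight.
#' @param n_modes mode counts for the coverage report.
#' @param n_boot,seed bootstrap settings for the B-factor correlation.
#' @return tibble with one row per grid cell: the parameters, coverage at
#'   each mode count (apo modes), and the B-factor correlation of the apo
#'   structure (all modes).
#' @export
run_parameter_sweep <- function(apo, holo, A = c(1000, 5000, 10000),
                                w = c(1, 3, 5), sigma = c(1, 2, 3), B = 1,
                                n_modes = c(5, 100), n_boot = 200, seed = 1) {
  grid <- tidyr::expand_grid(A = A, w = w, sigma = sigma)
  purrr::pmap_dfr(grid, function(A, w, sigma) {
    par <- contact_params(A = A, B = B, w = w, sigma = sigma)
    ms <- run_modes(apo, model = "cnd", params = par)
    fit <- cumulative_fit(change_vector(apo, holo), ms, max_modes = max(n_modes))
    bc <- bfactor_correlation(apo, msf(ms), n_boot = n_boot, seed = seed)
    nm <- pmin(n_modes, fit$max_modes)
    out <- tibble(A = A, B = B, w = w, sigma = sigma,
                  bfactor_r = bc$r, auc = fit$auc)
    for (k in seq_along(nm))
      out[[paste0("coverage_", n_modes[k])]] <- fit$curve$coverage[nm[k]]
    out
  })
}

#' Overlay mean-square fluctuation profiles
#'
#' @param profiles named list of per-atom MSF vectors (e.g. CND vs ENM),
#'   scaled to a common mean before plotting.
#' @param structure the structure (for residue averaging).
#' @return a ggplot of per-residue MSF by model.
#' @export
plot_msf_profiles <- function(profiles, structure) {
  ref <- profiles[[1]]
  df <- purrr::imap_dfr(profiles, function(p, nm) {
    ra <- residue_average_msf(scale_msf(p, ref), structure)
    ra$model <- nm
    ra
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_index, y = .data$msf,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue index", y = "MSF (arbitrary units)")
}
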