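#' Declare column roles for a subject table
#'
#' Maps columns of a rectangular subject table onto the roles the analysis
#' needs: a binary treatment, an outcome (binary or continuous), the
#' categorical (or continuous) indicators that measure the latent subgroups,
#' and any additional adjustment covariates used only in the propensity and
#' outcome models.
#'
#' @param treatment Name of the binary 0/1 treatment column.
#' @param outcome Name of the outcome column.
#' @param indicators Character vector of indicator column names (each must
#'   show at least two observed levels).
#' @param adjusters Character vector of additional covariate columns used in
#'   the nuisance models but not in the mixture model. May be empty.
#' @param id Optional name of a subject identifier column.
#' @return An object of class `subject_roles`.
#' @export
subject_roles <- function(treatment, outcome, indicators,
                          adjusters = character(), id = NULL) {
  stopifnot(is.character(treatment), length(treatment) == 1L,
            is.character(outcome), length(outcome) == 1L,
            is.character(indicators), length(indicators) >= 1L)
  all_cols <- c(treatment, outcome, indicators, adjusters, id)
  if (anyDuplicated(all_cols)) {
    abort("column roles must not overlap", class = "latentsens_schema_error")
  }
  structure(
    list(treatment = treatment, outcome = outcome,
         indicators = indicators, adjusters = as.character(adjusters),
         id = id),
    class = "subject_roles"
  )
}

#' Read column roles from a JSON configuration file
#'
#' The JSON object uses keys `treatment`, `outcome`, `indicators`,
#' `adjusters` and optionally `id`.
#'
#' @param path Path to a JSON file.
#' @return A [subject_roles()] object.
#' @export
roles_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  subject_roles(treatment = x$treatment, outcome = x$outcome,
                indicators = x$indicators,
                adjusters = x$adjusters %||% character(),
                id = x$id)
}

#' Tuning constants for the sensitivity analysis pipeline
#'
#' Collects every tuning constant used across the pipeline so a whole run is
#' reproducible from one object. Defaults follow common practice for this
#' kind of analysis: 95% Wald intervals, trajectory thresholds 0.99/0.01 on
#' the membership probabilities, and 1000 parametric-bootstrap perturbations.
#'
#' @param alpha Complement of the confidence level (default 0.05).
#' @param u_hi,u_lo Upper and lower membership-probability thresholds that
#'   bound the trajectory window (defaults 0.99 and 0.01).
#' @param B Number of perturbation draws for perturbed intervals.
#' @param band_B Number of perturbation draws for trajectory bands (each draw
#'   costs a full trajectory, so the default is smaller than `B`).
#' @param seed Master seed; every random component derives its own stream
#'   from it.
#' @param n_starts Number of random EM initializations per mixture fit.
#' @param em_tol Relative log-likelihood change declaring EM convergence.
#' @param em_max_iter Maximum EM iterations per start.
#' @param compute_cov Whether [fit_mixture()] computes the parameter
#'   covariance (needed for perturbation; can be switched off for speed when
#'   only point estimates are required).
#' @param boot_cov_resamples Bootstrap resamples used for the fallback
#'   parameter covariance when the observed information is singular.
#' @param penalty_alpha Elastic-net mixing weight (1 = lasso, 0 = ridge).
#' @param penalty_lambda Elastic-net penalty strength: `NULL` selects it by
#'   cross-validation, `0` fits the unpenalized model, a positive number is
#'   used as-is.
#' @param penalize_treatment Whether the treatment main effect is penalized.
#' @param cv_folds Cross-validation folds for the outcome penalty.
#' @param cv_seed Seed for the fold assignment; defaults to `seed` and is
#'   held fixed across trajectory steps so wiggle reflects subject
#'   composition, not fold randomness.
#' @param class_floor Minimum subgroup size below which the effect is
#'   reported as undefined rather than estimated.
#' @param cbps_tol Maximum absolute weighted covariate-mean difference
#'   accepted as covariate balance.
#' @param cbps_max_iter Newton iterations for the balancing equations.
#' @param ps_clip Optional 2-vector clipping fitted propensity scores into
#'   `[eps, 1 - eps]`; `NULL` (default) applies no truncation.
#' @param positivity_bounds Bounds used by [positivity_check()] to count
#'   extreme propensity scores.
#' @param max_steps Cap on the number of trajectory steps evaluated; larger
#'   windows are thinned to an even sub-grid that always keeps the window
#'   ends and the modal size.
#' @param band_grid Number of cumulative-proportion grid points for
#'   trajectory bands.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(alpha = 0.05, u_hi = 0.99, u_lo = 0.01,
                       B = 1000L, band_B = 200L, seed = 1L,
                       n_starts = 20L, em_tol = 1e-8, em_max_iter = 1000L,
                       compute_cov = TRUE, boot_cov_resamples = 200L,
                       penalty_alpha = 0.5, penalty_lambda = NULL,
                       penalize_treatment = TRUE,
                       cv_folds = 10L, cv_seed = NULL,
                       class_floor = 10L,
                       cbps_tol = 1e-8, cbps_max_iter = 50L,
                       ps_clip = NULL,
                       positivity_bounds = c(0.01, 0.99),
                       max_steps = 1000L, band_grid = 21L) {
  stopifnot(alpha > 0, alpha < 1)
  if (!(u_lo >= 0 && u_lo < u_hi && u_hi <= 1)) {
    abort("need 0 <= u_lo < u_hi <= 1", class = "latentsens_config_error")
  }
  stopifnot(B >= 1, n_starts >= 1, em_tol > 0, em_max_iter >= 1,
            penalty_alpha >= 0, penalty_alpha <= 1, class_floor >= 2)
  structure(
    list(alpha = alpha, u_hi = u_hi, u_lo = u_lo,
         B = as.integer(B), band_B = as.integer(band_B),
         seed = as.integer(seed),
         n_starts = as.integer(n_starts), em_tol = em_tol,
         em_max_iter = as.integer(em_max_iter),
         compute_cov = isTRUE(compute_cov),
         boot_cov_resamples = as.integer(boot_cov_resamples),
         penalty_alpha = penalty_alpha, penalty_lambda = penalty_lambda,
         penalize_treatment = isTRUE(penalize_treatment),
         cv_folds = as.integer(cv_folds),
         cv_seed = as.integer(cv_seed %||% seed),
         class_floor = as.integer(class_floor),
         cbps_tol = cbps_tol, cbps_max_iter = as.integer(cbps_max_iter),
         ps_clip = ps_clip,
         positivity_bounds = positivity_bounds,
         max_steps = as.integer(max_steps), band_grid = as.integer(band_grid)),
    class = "run_config"
  )
}

#' Read a run configuration from JSON
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#'
#' @param path Path to a JSON file.
#' @return A [run_config()] object.
#' @export
config_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
          class = "latentsens_config_error")
  }
  do.call(run_config, x)
}
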