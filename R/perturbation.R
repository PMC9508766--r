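#' Perturbed confidence interval for a subgroup effect
#'
#' Parametric bootstrap that propagates the sampling uncertainty of the
#' membership-model parameters into the subgroup effect. Per draw: mixture
#' parameters are drawn from their estimated sampling distribution
#' ([perturb_memberships()]), labels are realigned to the estimated modal
#' labels to guard against label switching, subjects are re-imputed by
#' modal assignment, and a Wald interval is computed under the perturbed
#' memberships (nuisance models refit; the mixture itself is never refit).
#' After `config$B` draws the endpoints are combined by the percentile
#' rule: the combined lower endpoint is the `alpha/2` percentile of the
#' per-draw lower endpoints and the combined upper endpoint the
#' `1 - alpha/2` percentile of the per-draw uppers (linear interpolation
#' between order statistics). Draws whose effect is undefined are skipped
#' and counted.
#'
#' @param data Subject table.
#' @param roles A [subject_roles()] object.
#' @param fit An `lcs_mixture` carrying a parameter covariance.
#' @param class_label Class index `c`.
#' @param config A [run_config()] object (`B`, `alpha`, master `seed`).
#' @param reference Optional precomputed estimated memberships (saves one
#'   posterior computation when looping over classes).
#' @return An object of class `lcs_perturbed`: `per_draw` (tibble with one
#'   row per draw: seed, permutation, agreement, endpoints, defined flag,
#'   reason), `combined` (length-2 vector), `skipped`, `B`, `warnings`.
#' @export
perturbed_interval <- function(data, roles, fit, class_label,
                               config = run_config(), reference = NULL) {
  stopifnot(inherits(fit, "lcs_mixture"))
  ref <- reference %||% posterior_memberships(fit, data)
  B <- config$B
  seeds <- derive_seeds(config$seed + 7L * class_label, B)
  rows <- purrr::map(seq_len(B), function(b) {
    pm <- perturb_memberships(fit, data, seeds[b])
    al <- align_memberships(ref, pm)
    e <- estimate_effect(data, roles, al$membership$modal, class_label,
                         config)
    tibble::tibble(draw = b, seed = seeds[b],
                   permutation = paste(al$permutation, collapse = ","),
                   agreement = al$agreement,
                   tau_hat = e$tau_hat,
                   ci_lower = e$ci[1], ci_upper = e$ci[2],
                   defined = e$defined, reason = e$reason)
  })
  per_draw <- dplyr::bind_rows(rows)
  ok <- per_draw$defined
  warnings <- character(0)
  if (!any(ok)) {
    tally <- table(per_draw$reason)
    abort(paste0("every perturbation draw was undefined: ",
                 paste(sprintf("%s (%d)", names(tally), tally),
                       collapse = ", ")),
          class = "latentsens_perturb_error")
  }
  if (mean(!ok) > 0.2) {
    msg <- sprintf("%.0f%% of perturbation draws were undefined",
                   100 * mean(!ok))
    warn(msg, class = "latentsens_perturb_skips")
    warnings <- c(warnings, msg)
  }
  combined <- c(
    quantile(per_draw$ci_lower[ok], config$alpha / 2, type = 7,
             names = FALSE),
    quantile(per_draw$ci_upper[ok], 1 - config$alpha / 2, type = 7,
             names = FALSE)
  )
  structure(
    list(class_label = class_label, B = B, per_draw = per_draw,
         combined = combined, skipped = sum(!ok), warnings = warnings),
    class = "lcs_perturbed"
  )
}

#' @export
print.lcs_perturbed <- function(x, ...) {
  cat(sprintf(
    "<lcs_perturbed> class %s: B = %d (%d skipped), combined CI (%.4f, %.4f)\n",
    x$class_label, x$B, x$skipped, x$combined[1], x$combined[2]))
  invisible(x)
}

#' Serialize a perturbed interval (all per-draw endpoints) to JSON
#'
#' Keeping every per-draw endpoint allows alternative combination rules
#' (e.g. the conservative union method) to be applied afterwards without
#' recomputation.
#'
#' @param x An `lcs_perturbed`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
perturbed_to_json <- function(x, path) {
  obj <- list(class_label = x$class_label, B = x$B,
              combined = x$combined, skipped = x$skipped,
              warnings = x$warnings, per_draw = x$per_draw)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Combine per-draw intervals with the union rule
#'
#' The union method takes the minimum lower and maximum upper endpoint over
#' all defined draws. It is available as a post-processing alternative to
#' the default percentile rule but is susceptible to a single extreme draw
#' and tends to over-cover.
#'
#' @param x An `lcs_perturbed`.
#' @return Length-2 numeric vector (lower, upper).
#' @export
union_interval <- function(x) {
  stopifnot(inherits(x, "lcs_perturbed"))
  ok <- x$per_draw$defined
  c(min(x$per_draw$ci_lower[ok]), max(x$per_draw$ci_upper[ok]))
}

#' Pointwise perturbed bands for an effect trajectory
#'
#' For each of `config$band_B` perturbation draws a full trajectory is
#' computed on a fixed grid of cumulative proportions (spanning the
#' estimated-membership threshold window and always containing the modal
#' proportion); the band at each grid point is the `alpha/2` to
#' `1 - alpha/2` percentile range of the per-draw point estimates. Grid
#' points where more than half the draws are undefined are masked.
#'
#' @param data Subject table.
#' @param roles A [subject_roles()] object.
#' @param fit An `lcs_mixture` carrying a parameter covariance.
#' @param class_label Class index `c`.
#' @param config A [run_config()] object (`band_B`, `band_grid`, `alpha`,
#'   master `seed`).
#' @return An object of class `lcs_bands`: `band` (tibble with `prop`,
#'   `estimate` from the estimated memberships, `lower`, `upper`,
#'   `n_defined`, `masked`), `B`, `class_label`.
#' @export
trajectory_bands <- function(data, roles, fit, class_label,
                             config = run_config()) {
  stopifnot(inherits(fit, "lcs_mixture"))
  ref <- posterior_memberships(fit, data)
  n <- nrow(data)
  lam <- ref$lambda[, class_label]
  m_star <- max(sum(lam >= config$u_hi), 1L)
  m_dstar <- sum(lam >= config$u_lo)
  m_c <- sum(ref$modal == class_label)
  js_grid <- sort(unique(c(
    round(seq(m_star, m_dstar, length.out = config$band_grid)), m_c)))
  props <- js_grid / n

  traj_at <- function(mem) {
    ordx <- insertion_order(mem, class_label)
    vapply(js_grid, function(j) {
      labels <- integer(n)
      labels[ordx[seq_len(j)]] <- class_label
      e <- estimate_effect(data, roles, labels, class_label, config)
      if (e$defined) e$tau_hat else NA_real_
    }, numeric(1))
  }

  est <- traj_at(ref)
  B <- config$band_B
  seeds <- derive_seeds(config$seed + 13L * class_label + 1000003L, B)
  draws <- matrix(NA_real_, B, length(js_grid))
  for (b in seq_len(B)) {
    pm <- perturb_memberships(fit, data, seeds[b])
    al <- align_memberships(ref, pm)
    draws[b, ] <- traj_at(al$membership)
  }
  n_def <- colSums(!is.na(draws))
  masked <- n_def < B / 2
  lower <- upper <- rep(NA_real_, length(js_grid))
  for (g in seq_along(js_grid)) {
    if (masked[g]) next
    v <- draws[!is.na(draws[, g]), g]
    lower[g] <- quantile(v, config$alpha / 2, type = 7, names = FALSE)
    upper[g] <- quantile(v, 1 - config$alpha / 2, type = 7, names = FALSE)
  }
  structure(
    list(class_label = class_label, B = B,
         band = tibble::tibble(j = js_grid, prop = props, estimate = est,
                               lower = lower, upper = upper,
                               n_defined = n_def, masked = masked)),
    class = "lcs_bands"
  )
}

#' @export
print.lcs_bands <- function(x, ...) {
  cat(sprintf("<lcs_bands> class %s: B = %d, %d grid points (%d masked)\n",
              x$class_label, x$B, nrow(x$band), sum(x$band$masked)))
  invisible(x)
}
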