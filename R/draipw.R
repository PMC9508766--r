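#' Inverse propensity weights for a subgroup
#'
#' `W_i = I(in_class_i) * (Z_i / p_i + (1 - Z_i) / (1 - p_i))`; subjects
#' outside the subgroup get weight exactly 0.
#'
#' @param Z Binary treatment vector.
#' @param p_hat Fitted propensity scores.
#' @param in_class Logical (or 0/1) subgroup indicator.
#' @return Numeric weight vector.
#' @export
ipw_weights <- function(Z, p_hat, in_class) {
  Z <- as.numeric(Z)
  in_class <- as.logical(in_class)
  bad <- in_class & (p_hat <= 0 | p_hat >= 1)
  if (any(bad)) {
    abort(sprintf("undefined weight: propensity score is 0 or 1 for subject(s) %s",
                  paste(head(which(bad), 5L), collapse = ", ")),
          class = "latentsens_weight_error")
  }
  ifelse(in_class, Z / p_hat + (1 - Z) / (1 - p_hat), 0)
}

effect_failure <- function(class_label, m_c, reason, alpha) {
  structure(
    list(class_label = class_label, defined = FALSE, reason = reason,
         m_c = m_c, tau_hat = NA_real_, var_hat = NA_real_,
         ci = c(NA_real_, NA_real_), alpha = alpha, influence = NULL),
    class = "lcs_effect"
  )
}

#' Doubly-robust AIPW subgroup treatment effect
#'
#' Estimates the average treatment effect within one (imputed) subgroup.
#' Propensity scores (covariate-balancing by default) and the penalized
#' saturated outcome model are fitted on the subgroup members only; the
#' point estimate averages the augmented inverse-propensity-weighted
#' contribution over members, its variance is the empirical variance of the
#' centered per-member influence values with denominator
#' `m_c * (m_c - 1)`, and the confidence interval is Wald with the standard
#' normal quantile. Nuisance failures (single arm, separation, undefined
#' weights, too few members) are returned as an undefined effect carrying a
#' machine-readable reason, never as an unhandled error.
#'
#' The whole-sample average treatment effect is obtained by passing an
#' all-ones `class_vector` with `class_label = 1`.
#'
#' @param data Subject table.
#' @param roles A [subject_roles()] object.
#' @param class_vector Length-`n` vector of (imputed) class labels.
#' @param class_label The subgroup to estimate.
#' @param config A [run_config()] object.
#' @param p_hat Optional forced propensity scores for the subgroup members
#'   (scalar or vector over members, in data order); skips the propensity
#'   fit.
#' @param m1,m0 Optional forced outcome predictions under treatment and
#'   control for the subgroup members; skip the outcome fit.
#' @return An object of class `lcs_effect`: `tau_hat`, `var_hat`, `ci`,
#'   `m_c`, `influence` (centered, members in data order), `defined`,
#'   `reason`.
#' @export
estimate_effect <- function(data, roles, class_vector, class_label,
                            config = run_config(),
                            p_hat = NULL, m1 = NULL, m0 = NULL) {
  in_class <- class_vector == class_label
  m_c <- sum(in_class)
  if (m_c == 0L) {
    return(effect_failure(class_label, m_c, "empty-class", config$alpha))
  }
  if (m_c < config$class_floor) {
    return(effect_failure(class_label, m_c, "too-few-members", config$alpha))
  }
  sub <- data[in_class, , drop = FALSE]
  Z <- as.numeric(sub[[roles$treatment]])
  Y <- as.numeric(sub[[roles$outcome]])
  if (length(unique(Z)) < 2L) {
    return(effect_failure(class_label, m_c, "single-arm", config$alpha))
  }

  fit_err <- NULL
  if (is.null(p_hat) || is.null(m1) || is.null(m0)) {
    X <- design_matrix(sub, roles)
    if (is.null(p_hat)) {
      ps <- tryCatch(fit_propensity(X, Z, config), error = function(e) e)
      if (inherits(ps, "error")) {
        reason <- if (inherits(ps, "latentsens_separation_error"))
          "separation" else if (inherits(ps, "latentsens_single_arm_error"))
            "single-arm" else "propensity-failure"
        return(effect_failure(class_label, m_c, reason, config$alpha))
      }
      p_hat <- ps$p_hat
    }
    if (is.null(m1) || is.null(m0)) {
      om <- tryCatch(
        suppressWarnings(fit_outcome(X, Z, Y, config)),
        error = function(e) e
      )
      if (inherits(om, "error")) {
        return(effect_failure(class_label, m_c, "outcome-failure",
                              config$alpha))
      }
      m1 <- om$m1_hat
      m0 <- om$m0_hat
    }
  }
  p_hat <- rep_len(p_hat, m_c)
  m1 <- rep_len(m1, m_c)
  m0 <- rep_len(m0, m_c)
  if (!is.null(config$ps_clip)) {
    p_hat <- pmin(pmax(p_hat, config$ps_clip[1]), config$ps_clip[2])
  }

  W <- tryCatch(ipw_weights(Z, p_hat, rep(TRUE, m_c)),
                error = function(e) e)
  if (inherits(W, "error")) {
    return(effect_failure(class_label, m_c, "undefined-weight", config$alpha))
  }

  term <- (2 * Z - 1) * W * Y -
    (Z - p_hat) * (m1 / p_hat + m0 / (1 - p_hat))
  tau <- mean(term)
  influence <- term - tau
  var_hat <- if (m_c > 1L) sum(influence^2) / (m_c * (m_c - 1)) else NA_real_
  z_a <- qnorm(1 - config$alpha / 2)
  ci <- c(tau - z_a * sqrt(var_hat), tau + z_a * sqrt(var_hat))

  structure(
    list(class_label = class_label, defined = TRUE, reason = NA_character_,
         m_c = m_c, tau_hat = tau, var_hat = var_hat, ci = ci,
         alpha = config$alpha, influence = influence),
    class = "lcs_effect"
  )
}

#' @export
print.lcs_effect <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("<lcs_effect> class %s: undefined (%s), m = %d\n",
                x$class_label, x$reason, x$m_c))
  } else {
    cat(sprintf("<lcs_effect> class %s: tau = %.4f, %d%% CI (%.4f, %.4f), m = %d\n",
                x$class_label, x$tau_hat, round(100 * (1 - x$alpha)),
                x$ci[1], x$ci[2], x$m_c))
  }
  invisible(x)
}

#' Subgroup effects table under modal assignment
#'
#' Estimates the effect in every latent class under the modal memberships
#' and, optionally, in the whole sample, returning a table ordered by the
#' lower endpoint of the confidence interval (undefined rows last).
#'
#' @param data Subject table.
#' @param roles A [subject_roles()] object.
#' @param memberships An `lcs_membership`.
#' @param config A [run_config()] object.
#' @param include_overall Append a whole-sample row labeled `"all"`.
#' @return A tibble with columns `class`, `proportion` (mean membership
#'   probability), `m_c`, `tau_hat`, `se`, `ci_lower`, `ci_upper`,
#'   `defined`, `reason`; the `lcs_effect` objects are in attribute
#'   `"effects"`.
#' @export
estimate_all_effects <- function(data, roles, memberships,
                                 config = run_config(),
                                 include_overall = TRUE) {
  stopifnot(inherits(memberships, "lcs_membership"))
  K <- ncol(memberships$lambda)
  props <- colMeans(memberships$lambda)
  effs <- purrr::map(seq_len(K), function(k) {
    estimate_effect(data, roles, memberships$modal, k, config)
  })
  rows <- purrr::imap(effs, function(e, k) {
    tibble::tibble(class = as.character(k), proportion = props[k],
                   m_c = e$m_c, tau_hat = e$tau_hat,
                   se = sqrt(e$var_hat),
                   ci_lower = e$ci[1], ci_upper = e$ci[2],
                   defined = e$defined, reason = e$reason)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$ci_lower, na.last = TRUE), ]
  if (include_overall) {
    overall <- estimate_effect(data, roles, rep(1L, nrow(data)), 1L, config)
    out <- dplyr::bind_rows(out, tibble::tibble(
      class = "all", proportion = 1, m_c = overall$m_c,
      tau_hat = overall$tau_hat, se = sqrt(overall$var_hat),
      ci_lower = overall$ci[1], ci_upper = overall$ci[2],
      defined = overall$defined, reason = overall$reason))
    effs <- c(effs, list(overall))
  }
  attr(out, "effects") <- effs
  out
}
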