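#' @importFrom generics tidy glance
#' @importFrom tibble as_tibble
#' @importFrom ggplot2 autoplot .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tibble::as_tibble

#' Tidy a fitted mixture model
#'
#' One row per parameter on the natural scale: prevalences, then
#' class-conditional response probabilities (categorical family) or
#' class-specific means and standard deviations (Gaussian family).
#'
#' @param x An `lcs_mixture`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `class`, `indicator`, `level`,
#'   `estimate`.
#' @export
tidy.lcs_mixture <- function(x, ...) {
  rows <- list(tibble::tibble(term = "prevalence",
                              class = seq_len(x$K),
                              indicator = NA_character_,
                              level = NA_character_,
                              estimate = x$pi))
  if (x$family == "categorical") {
    for (k in seq_len(x$K)) {
      for (j in seq_along(x$indicator_names)) {
        lv <- x$levels[[x$indicator_names[j]]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          term = "response_prob", class = k,
          indicator = x$indicator_names[j],
          level = as.character(lv),
          estimate = x$rho[[k]][[j]])
      }
    }
  } else {
    for (k in seq_len(x$K)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = "mean", class = k, indicator = x$indicator_names,
        level = NA_character_, estimate = x$mu[k, ])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = "sd", class = k, indicator = x$indicator_names,
        level = NA_character_, estimate = x$sd[k, ])
    }
  }
  dplyr::bind_rows(rows)
}

#' Model-level summary of a fitted mixture
#'
#' @param x An `lcs_mixture`.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `K`, `loglik`, `n_params`, `aic`,
#'   `bic`, `n`, `cov_method`.
#' @export
glance.lcs_mixture <- function(x, ...) {
  tibble::tibble(family = x$family, K = x$K, loglik = x$loglik,
                 n_params = x$n_params, aic = x$aic, bic = x$bic,
                 n = x$n, cov_method = x$theta_cov_method)
}

#' Tidy a membership matrix
#'
#' @param x An `lcs_membership`.
#' @param ... Unused.
#' @return A tibble with the per-class probabilities and the modal label.
#' @export
tidy.lcs_membership <- function(x, ...) {
  as_tibble(x)
}

#' Tidy a subgroup effect estimate
#'
#' @param x An `lcs_effect`.
#' @param ... Unused.
#' @return A one-row tibble: `class`, `m_c`, `tau_hat`, `se`, `ci_lower`,
#'   `ci_upper`, `defined`, `reason`.
#' @export
tidy.lcs_effect <- function(x, ...) {
  tibble::tibble(class = as.character(x$class_label), m_c = x$m_c,
                 tau_hat = x$tau_hat, se = sqrt(x$var_hat),
                 ci_lower = x$ci[1], ci_upper = x$ci[2],
                 defined = x$defined, reason = x$reason)
}

#' Tidy an effect trajectory (one row per evaluated step)
#'
#' @param x An `lcs_trajectory`.
#' @param ... Unused.
#' @return The step tibble with the class label prepended.
#' @export
tidy.lcs_trajectory <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(class = as.character(x$class_label)),
                   x$steps)
}

#' Window-level summary of a trajectory
#'
#' @param x An `lcs_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: `class`, `n`, `m_star`, `m_c`, `m_dstar`,
#'   `n_steps`, `n_defined`.
#' @export
glance.lcs_trajectory <- function(x, ...) {
  tibble::tibble(class = as.character(x$class_label), n = x$n,
                 m_star = x$m_star, m_c = x$m_c, m_dstar = x$m_dstar,
                 n_steps = nrow(x$steps), n_defined = sum(x$steps$defined))
}

#' Tidy a perturbed interval (one row per draw)
#'
#' @param x An `lcs_perturbed`.
#' @param ... Unused.
#' @return The per-draw tibble with the class label prepended.
#' @export
tidy.lcs_perturbed <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(class = as.character(x$class_label)),
                   x$per_draw)
}

#' Combined-endpoint summary of a perturbed interval
#'
#' @param x An `lcs_perturbed`.
#' @param ... Unused.
#' @return A one-row tibble: `class`, `B`, `skipped`, `ci_lower`,
#'   `ci_upper`.
#' @export
glance.lcs_perturbed <- function(x, ...) {
  tibble::tibble(class = as.character(x$class_label), B = x$B,
                 skipped = x$skipped, ci_lower = x$combined[1],
                 ci_upper = x$combined[2])
}
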