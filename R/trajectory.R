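#' Probability-ordered insertion order for a subgroup
#'
#' Orders subjects by the strength of evidence for belonging to class `c`:
#' subjects whose modal class is `c` come first, in decreasing membership
#' probability; once those are exhausted the remaining subjects follow, in
#' decreasing membership probability for `c`. Ties are broken by lowest
#' subject index. The length-`m_c` prefix of the order is exactly the modal
#' membership set, so the nested partitions pass through the
#' modal-assignment analysis.
#'
#' @param memberships An `lcs_membership`.
#' @param class_label Class index `c`.
#' @return Integer permutation of `1..n` (row indices).
#' @export
insertion_order <- function(memberships, class_label) {
  stopifnot(inherits(memberships, "lcs_membership"))
  lam <- memberships$lambda[, class_label]
  modal_c <- memberships$modal == class_label
  idx1 <- which(modal_c)
  idx2 <- which(!modal_c)
  c(idx1[order(-lam[idx1], idx1)], idx2[order(-lam[idx2], idx2)])
}

#' Trajectory of subgroup effect estimates over nested partitions
#'
#' Walks the probability-ordered nested partitions of a subgroup and
#' re-estimates the subgroup effect at each size `j` inside the threshold
#' window: from `m_star` (subjects with membership probability at least
#' `u_hi`) to `m_dstar` (at least `u_lo`). Nuisance models are refit at
#' every evaluated step; when the window holds more than
#' `config$max_steps` steps an even sub-grid is used that always includes
#' the window ends and the modal size `m_c`. The step at `j = m_c`
#' reproduces the modal-assignment estimate exactly. Undefined steps carry
#' their failure reason.
#'
#' @param data Subject table.
#' @param roles A [subject_roles()] object.
#' @param memberships An `lcs_membership`.
#' @param class_label Class index `c`.
#' @param config A [run_config()] object (thresholds `u_hi`, `u_lo`, step
#'   cap, estimator controls).
#' @return An object of class `lcs_trajectory`: `steps` (tibble with `j`,
#'   `prop`, `tau_hat`, `ci_lower`, `ci_upper`, `defined`, `reason`),
#'   `insertion_order`, `m_c`, `m_star`, `m_dstar`, `n`, `class_label`.
#' @export
effect_trajectory <- function(data, roles, memberships, class_label,
                              config = run_config()) {
  stopifnot(inherits(memberships, "lcs_membership"))
  n <- nrow(memberships$lambda)
  lam <- memberships$lambda[, class_label]
  ord <- insertion_order(memberships, class_label)
  m_c <- sum(memberships$modal == class_label)
  m_star <- sum(lam >= config$u_hi)
  m_dstar <- sum(lam >= config$u_lo)

  js <- seq(max(m_star, 1L), m_dstar)
  if (length(js) > config$max_steps) {
    grid <- unique(round(seq(min(js), max(js),
                             length.out = config$max_steps)))
    js <- sort(unique(c(grid, m_star, m_c, m_dstar)))
    js <- js[js >= max(m_star, 1L) & js <= m_dstar]
  }

  steps <- purrr::map(js, function(j) {
    labels <- integer(n)  # 0 marks "outside the partition"
    labels[ord[seq_len(j)]] <- class_label
    e <- estimate_effect(data, roles, labels, class_label, config)
    tibble::tibble(j = j, prop = j / n,
                   tau_hat = e$tau_hat,
                   ci_lower = e$ci[1], ci_upper = e$ci[2],
                   defined = e$defined, reason = e$reason)
  })

  structure(
    list(class_label = class_label,
         steps = dplyr::bind_rows(steps),
         insertion_order = ord,
         m_c = m_c, m_star = m_star, m_dstar = m_dstar, n = n),
    class = "lcs_trajectory"
  )
}

#' @export
print.lcs_trajectory <- function(x, ...) {
  cat(sprintf(
    "<lcs_trajectory> class %s: window j in [%d, %d], modal m_c = %d, n = %d\n",
    x$class_label, x$m_star, x$m_dstar, x$m_c, x$n))
  cat(sprintf("%d evaluated steps (%d defined)\n",
              nrow(x$steps), sum(x$steps$defined)))
  invisible(x)
}

#' Cumulative membership-probability curve for a subgroup
#'
#' For each threshold value `v` (by default every distinct observed
#' membership probability for the class, in increasing order), the
#' proportion of subjects whose membership probability is at least `v`.
#' The curve is non-increasing in `v` by construction; the modal proportion
#' `m_c / n` is attached as attribute `"modal_prop"` for the vertical
#' reference line in the membership plot.
#'
#' @param memberships An `lcs_membership`.
#' @param class_label Class index `c`.
#' @param grid Optional numeric vector of threshold values overriding the
#'   observed-value grid (useful for very large samples).
#' @return A tibble with columns `threshold` and `proportion`.
#' @export
membership_curve <- function(memberships, class_label, grid = NULL) {
  stopifnot(inherits(memberships, "lcs_membership"))
  lam <- memberships$lambda[, class_label]
  n <- length(lam)
  v <- sort(unique(grid %||% lam))
  prop <- vapply(v, function(t) mean(lam >= t), numeric(1))
  out <- tibble::tibble(threshold = v, proportion = prop)
  attr(out, "modal_prop") <- mean(memberships$modal == class_label)
  out
}
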