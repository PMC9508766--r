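#' Membership probability plot
#'
#' Draws the cumulative-proportion curve of membership probabilities for
#' one subgroup: the horizontal axis is the cumulative proportion of
#' subjects whose membership probability is at least the value on the
#' vertical axis, with a vertical broken line at the modal proportion. A
#' steep, step-like curve indicates a well-separated subgroup; a gentle
#' gradient flags "tentative" subjects with probabilities near 0.5.
#'
#' @param curve Tibble from [membership_curve()].
#' @param modal_prop Modal proportion for the reference line; defaults to
#'   the `"modal_prop"` attribute of `curve`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_membership <- function(curve, modal_prop = NULL, title = NULL) {
  modal_prop <- modal_prop %||% attr(curve, "modal_prop")
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(x = .data$proportion,
                                    y = .data$threshold)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Cumulative proportion of individuals",
                  y = "Membership probability ≥ value",
                  title = title) +
    ggplot2::theme_minimal()
  if (!is.null(modal_prop)) {
    p <- p + ggplot2::geom_vline(xintercept = modal_prop,
                                 linetype = "dashed")
  }
  p
}

#' Treatment effect trajectory plot
#'
#' Point estimates against the cumulative proportion of subjects included
#' in the subgroup. The modal-assignment estimate is marked with an empty
#' circle and a vertical error bar for its Wald interval; perturbed-CI
#' endpoints are horizontal dotted lines (clipped with an annotation when
#' outside `ylim`, as very wide perturbed intervals otherwise flatten the
#' display); the whole-sample effect is a solid gray horizontal line.
#' Undefined steps are left as gaps, never interpolated.
#'
#' @param trajectory An `lcs_trajectory`.
#' @param effect Optional modal-assignment `lcs_effect` (defaults to the
#'   trajectory step at `j = m_c`).
#' @param perturbed Optional `lcs_perturbed` for the dotted endpoint lines.
#' @param sample_ate Optional whole-sample `lcs_effect` for the gray line.
#' @param ylim Optional shared vertical range, so panels for different
#'   classes of one dataset are comparable.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(trajectory, effect = NULL, perturbed = NULL,
                            sample_ate = NULL, ylim = NULL, title = NULL) {
  stopifnot(inherits(trajectory, "lcs_trajectory"))
  steps <- trajectory$steps
  shown <- steps[steps$defined, , drop = FALSE]
  p <- ggplot2::ggplot(shown, ggplot2::aes(x = .data$prop,
                                           y = .data$tau_hat)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Cumulative proportion of individuals",
                  y = "Subgroup treatment effect estimate",
                  title = title) +
    ggplot2::theme_minimal()
  if (!is.null(sample_ate) && isTRUE(sample_ate$defined)) {
    p <- p + ggplot2::geom_hline(yintercept = sample_ate$tau_hat,
                                 color = "gray60", linewidth = 0.8)
  }
  modal_row <- steps[steps$j == trajectory$m_c & steps$defined, ]
  if (is.null(effect) && nrow(modal_row)) {
    effect <- list(defined = TRUE, tau_hat = modal_row$tau_hat[1],
                   ci = c(modal_row$ci_lower[1], modal_row$ci_upper[1]))
  }
  if (!is.null(effect) && isTRUE(effect$defined)) {
    mp <- trajectory$m_c / trajectory$n
    p <- p +
      ggplot2::annotate("errorbar", x = mp, ymin = effect$ci[1],
                        ymax = effect$ci[2], width = 0.02) +
      ggplot2::annotate("point", x = mp, y = effect$tau_hat, shape = 21,
                        size = 3, fill = "white")
  }
  if (!is.null(perturbed)) {
    ends <- perturbed$combined
    for (e in ends) {
      if (is.null(ylim) || (e >= ylim[1] && e <= ylim[2])) {
        p <- p + ggplot2::geom_hline(yintercept = e, linetype = "dotted")
      } else {
        p <- p + ggplot2::labs(
          caption = sprintf(
            "Perturbed CI endpoint %.3f outside the displayed range", e))
      }
    }
  }
  if (!is.null(ylim)) {
    p <- p + ggplot2::coord_cartesian(ylim = ylim)
  }
  p
}

#' @rdname plot_trajectory
#' @param object An `lcs_trajectory`.
#' @param ... Passed to [plot_trajectory()].
#' @export
autoplot.lcs_trajectory <- function(object, ...) {
  plot_trajectory(object, ...)
}

#' Band plot for a perturbed trajectory
#'
#' @param object An `lcs_bands`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lcs_bands <- function(object, ...) {
  b <- object$band[!object$band$masked, , drop = FALSE]
  ggplot2::ggplot(b, ggplot2::aes(x = .data$prop)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "gray80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate)) +
    ggplot2::labs(x = "Cumulative proportion of individuals",
                  y = "Subgroup treatment effect estimate") +
    ggplot2::theme_minimal()
}
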