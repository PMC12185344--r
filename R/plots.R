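#' Plot a choice curve
#'
#' Fraction of left choices against the binned displayed utility difference;
#' a value-sensitive chooser gives a rising sigmoid through 0.5 at zero
#' difference.
#'
#' @param object A `choice_curve` from [bin_choice_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot choice_curve
#' @export
autoplot.choice_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid,
                                       y = .data$frac_left)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "Utility difference (left - right, points)",
                  y = "Fraction choosing left") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot win/loss dimension sensitivity
#' @param object A `dimension_sensitivity` from [dimension_sensitivity()].
#' @param ... Unused.
#' @return A ggplot with one curve per dimension.
#' @method autoplot dimension_sensitivity
#' @export
autoplot.dimension_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$bin_mid, y = .data$frac_left,
                               colour = .data$dimension)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Utility difference on dimension (points)",
                  y = "Fraction choosing left", colour = "Dimension") +
    ggplot2::theme_minimal()
}

#' Plot parameter recovery
#' @param object A `recovery_study` from [parameter_recovery()].
#' @param ... Unused.
#' @return A ggplot: estimated vs true, one facet per parameter.
#' @method autoplot recovery_study
#' @export
autoplot.recovery_study <- function(object, ...) {
  long <- object$table |>
    tidyr::pivot_longer(-"session", names_to = "key") |>
    mutate(parameter = sub("_est$", "", .data$key),
           kind = ifelse(grepl("_est$", .data$key), "estimate", "truth")) |>
    select(-"key") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "True value", y = "Posterior estimate") +
    ggplot2::theme_minimal()
}

#' Coefficient (forest) plot of a location-scale fit
#' @param object A `locscale_fit`.
#' @param ... Unused.
#' @return A ggplot of posterior means with 95% credible intervals.
#' @method autoplot locscale_fit
#' @export
autoplot.locscale_fit <- function(object, ...) {
  dat <- object$summary |> filter(.data$term != "(Intercept)")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$term,
                                    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower,
                                          xmax = .data$ci_upper)) +
    ggplot2::facet_wrap(~submodel, scales = "free") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::labs(x = "Posterior mean (95% CrI)", y = NULL,
                  title = paste("Outcome:", object$outcome)) +
    ggplot2::theme_minimal()
}
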