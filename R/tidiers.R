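# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an optimized mating plan
#'
#' @param x a `mating_plan_result` from [optimize_matings()].
#' @param ... unused.
#' @return tibble with one row per family: parents, `n_crosses`, `usefulness`.
#' @export
tidy.mating_plan_result <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$plan), usefulness = x$report$usefulness)
}

#' @rdname tidy.mating_plan_result
#' @return `glance()`: one-row tibble with `fitness`, `propsd`, `feasible`,
#'   `n_families`, `n_crosses`, `iterations`, `n_evaluated`.
#' @export
glance.mating_plan_result <- function(x, ...) {
  tibble::tibble(fitness = x$fitness, propsd = x$report$propsd,
                 feasible = x$report$feasible, n_families = nrow(x$plan),
                 n_crosses = sum(x$plan$n_crosses),
                 iterations = nrow(x$trace), n_evaluated = x$n_evaluated)
}

#' Glance at an expected-SD estimate
#'
#' @param x an `sd_estimate` from [expected_sample_sd()].
#' @param ... unused.
#' @return one-row tibble with `expected_sd`, `mean_s2`, `var_s2`, `alpha`,
#'   `beta`, `sem`.
#' @export
glance.sd_estimate <- function(x, ...) {
  tibble::tibble(expected_sd = x$expected_sd, mean_s2 = x$mean_s2,
                 var_s2 = x$var_s2, alpha = x$alpha, beta = x$beta,
                 sem = x$sem)
}

#' Plot a cross-prediction table
#'
#' Family mean against within-family SD, colored by usefulness: the classic
#' mean-variance trade-off view of a candidate cross set.
#'
#' @param object a `cross_predictions` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cross_predictions <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$sd, .data$mean,
                                       colour = .data$usefulness)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "predicted within-family SD", y = "predicted family mean",
                  colour = "usefulness",
                  title = paste0("Candidate crosses (", object$scheme[1],
                                 ", ", object$ld_model[1], " LD model)"))
}

#' Plot a cross-validation result
#'
#' @param object a `cross_validation` tibble.
#' @param metric `"accuracy"` or `"nrmse"`.
#' @param ... unused.
#' @return a ggplot: metric per method, faceted by scenario and quantity.
#' @export
autoplot.cross_validation <- function(object, metric = c("accuracy", "nrmse"),
                                      ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(.data$method, .data[[metric]],
                                       fill = .data$effect_set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(quantity ~ scenario, scales = "free_x") +
    ggplot2::labs(x = NULL, y = metric, fill = "effect setting") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot predicted vs realized PropSD under random sampling
#'
#' @param object a `propsd_random` tibble.
#' @param ... unused.
#' @return a ggplot with the identity line.
#' @export
autoplot.propsd_random <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$predicted, .data$realized,
                                       colour = factor(.data$size))) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$realized - .data$realized_sem,
                                        ymax = .data$realized + .data$realized_sem),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "predicted PropSD", y = "realized PropSD (MC mean)",
                  colour = "sample size")
}

#' Plot realized vs predicted losses under selection
#'
#' @param object a `propsd_selection` tibble.
#' @param ... unused.
#' @return a ggplot: boxplots of realized genetic and genic losses per
#'   cutoff, with the mean predicted PropSD as a dashed line.
#' @export
autoplot.propsd_selection <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("genetic_loss", "genic_loss"),
                              names_to = "kind", values_to = "loss")
  pred <- dplyr::summarise(dplyr::group_by(object, .data$cutoff),
                           predicted = mean(.data$predicted), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$cutoff), .data$loss)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(data = pred,
                        ggplot2::aes(yintercept = .data$predicted),
                        linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(x = "PropSD cutoff", y = "realized loss")
}

#' Plot an optimizer fitness trace
#'
#' @param object a `mating_plan_result`.
#' @param ... unused.
#' @return a ggplot of the elite fitness per iteration.
#' @export
autoplot.mating_plan_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$iteration,
                                             .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best fitness")
}
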