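#' Tidy a fitted clamp model
#'
#' @param x A `clamp_fit`.
#' @param ... Unused.
#' @return Tibble with one row per model parameter: `term`, `estimate`,
#'   `estimated` (`FALSE` for `k8` and variant-fixed parameters), and the
#'   log10-space estimate for the free parameters.
#' @export
tidy.clamp_fit <- function(x, ...) {
  p <- unclass(x$params)
  tibble::tibble(term = names(p), estimate = as.numeric(p),
                 estimated = names(p) %in% x$free,
                 log10_estimate = ifelse(names(p) %in% x$free,
                                         log10(as.numeric(p)), NA_real_))
}

#' One-row summary of a fitted clamp model
#'
#' @param x A `clamp_fit`.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `model`, `variant_id`, `rss`, `aic`,
#'   `n`, `K`, `converged`, `seed`.
#' @export
glance.clamp_fit <- function(x, ...) {
  n <- sum(x$n_points)
  tibble::tibble(subject_id = x$subject_id, model = x$model,
                 variant_id = x$variant_id, rss = x$rss,
                 aic = aic_rss(x$rss, n, x$K), n = n, K = x$K,
                 converged = x$converged, seed = x$seed)
}

#' Plot observed versus fitted clamp trajectories
#'
#' @param object A `clamp_fit`.
#' @param ... Unused.
#' @return A ggplot: normalized observations (points) and the fitted model
#'   (lines), one facet per measured variable.
#' @export
autoplot.clamp_fit <- function(object, ...) {
  d <- fitted_trajectories(object)
  long <- tidyr::pivot_longer(d, c("observed", "simulated"),
                              names_to = "source", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_min, .data$value)) +
    ggplot2::geom_point(data = long[long$source == "observed", ],
                        size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = long[long$source == "simulated", ],
                       colour = "#C03050") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "normalized concentration",
                  title = paste("Subject", object$subject_id, "-",
                                toupper(object$model), "fit"))
}

#' Plot a metric-versus-glycemia scatter with SMA lines
#'
#' Log10-log10 scatter of a composite metric against PG120 with the
#' group-wise standardized major axis lines.
#'
#' @param cohort Tibble with `PG120`, `group` and the metric column.
#' @param metric Name of the metric column.
#' @return A ggplot.
#' @export
plot_metric_association <- function(cohort, metric) {
  d <- cohort[cohort[[metric]] > 0 & cohort$PG120 > 0, ]
  d$logm <- log10(d[[metric]])
  d$logp <- log10(d$PG120)
  lines <- metric_glycemia_association(cohort, metric)
  ggplot2::ggplot(d, ggplot2::aes(.data$logm, .data$logp,
                                  colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = .data$group)) +
    ggplot2::labs(x = paste0("log10 ", metric), y = "log10 PG120")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
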