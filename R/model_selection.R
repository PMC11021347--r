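#' Akaike information criterion from a residual sum of squares
#'
#' `AIC = N * log(RSS) + 2 * K` with the natural logarithm, where `N` is the
#' total number of data points entering the objective and `K` the number of
#' estimated parameters. Because `N` is held constant across the compared
#' variants of one subject, the additive constants of the Gaussian
#' log-likelihood cancel and this reduced form orders models identically.
#'
#' @param rss Residual sum of squares (> 0; values below `floor` are floored
#'   with a warning, since a numerically perfect fit has no finite AIC).
#' @param n Total number of data points (>= 1).
#' @param k Number of estimated parameters (>= 1).
#' @param floor Lower guard for `rss`.
#' @return The AIC value.
#' @export
aic_rss <- function(rss, n, k, floor = 1e-300) {
  stopifnot(n >= 1, k >= 1)
  if (any(rss < 0)) stop("RSS must be non-negative", call. = FALSE)
  if (any(rss < floor)) {
    warning("RSS below floor; flooring before taking the logarithm")
    rss <- pmax(rss, floor)
  }
  n * log(rss) + 2 * k
}

#' Enumerate the reduced GIG model variants
#'
#' The family is built from independent structural toggles: whether glucagon
#' acts on glucose (`kGN` free or fixed to zero), which signal suppresses
#' glucagon secretion (saturable insulin, saturable glucose, or both), and
#' whether the insulin-secretion threshold `k6` is free or fixed to zero.
#' The default family has 12 members; `suppressions` can be extended (e.g.
#' with `"inverse_insulin"` and `"constant"`) to grow the family. The
#' enumeration is deterministic and duplicate-free, and each variant carries
#' its number of estimated parameters `K`.
#'
#' @param kGN_free Logical values to toggle glucagon action.
#' @param suppressions Character vector of secretion modes (see
#'   [model_structure()]).
#' @param k6_free Logical values to toggle the secretion threshold.
#' @return Tibble with columns `variant_id`, `kGN_free`, `suppression`,
#'   `k6_free`, `K`.
#' @export
variant_family <- function(kGN_free = c(TRUE, FALSE),
                           suppressions = c("saturable_insulin",
                                            "saturable_glucose", "both"),
                           k6_free = c(TRUE, FALSE)) {
  if (length(suppressions) == 0 || length(kGN_free) == 0 ||
      length(k6_free) == 0) {
    stop("the variant family must have at least one toggle value each",
         call. = FALSE)
  }
  ok <- c("saturable_insulin", "inverse_insulin", "saturable_glucose",
          "both", "constant")
  if (!all(suppressions %in% ok)) {
    stop("unknown suppression mode", call. = FALSE)
  }
  grid <- tidyr::expand_grid(kGN_free = unique(kGN_free),
                             suppression = unique(suppressions),
                             k6_free = unique(k6_free))
  # 10 always-free parameters: k1-k5, k7, kGgS, kGgC, kratio, kCPC
  grid$K <- 10L + grid$kGN_free + grid$k6_free
  grid$variant_id <- sprintf("v%02d", seq_len(nrow(grid)))
  grid[, c("variant_id", "kGN_free", "suppression", "k6_free", "K")]
}

#' Select the cohort-level model variant by AIC
#'
#' For each subject the AIC-optimal variant is the argmin over the fitted
#' family (every subject must be fitted under every variant, with the same
#' total number of data points `N` across variants); the cohort-selected
#' variant is the one optimal for the greatest number of subjects, ties
#' broken by lower mean AIC.
#'
#' @param fits Tibble with one row per subject x variant: columns
#'   `subject_id`, `variant_id`, `rss`, `n` (total data points of that
#'   subject), `K`.
#' @return A list of class `selection_report`: `per_subject` (subject,
#'   winning variant, AIC), `per_variant` (variant, number of subjects for
#'   which it is optimal, mean AIC), and `cohort_variant`.
#' @export
select_cohort_variant <- function(fits) {
  need <- c("subject_id", "variant_id", "rss", "n", "K")
  stopifnot(all(need %in% names(fits)))
  grid <- table(fits$subject_id, fits$variant_id)
  if (any(grid != 1)) {
    stop("incomplete fit grid: every subject needs exactly one fit per ",
         "variant", call. = FALSE)
  }
  n_per_subject <- dplyr::summarise(dplyr::group_by(fits, .data$subject_id),
                                    n_distinct = dplyr::n_distinct(.data$n),
                                    .groups = "drop")
  if (any(n_per_subject$n_distinct != 1)) {
    stop("the total number of data points N must be identical across the ",
         "compared variants of a subject", call. = FALSE)
  }
  fits <- dplyr::mutate(fits, aic = aic_rss(.data$rss, .data$n, .data$K))
  per_subject <- dplyr::slice_min(dplyr::group_by(fits, .data$subject_id),
                                  .data$aic, n = 1, with_ties = FALSE)
  per_subject <- dplyr::ungroup(per_subject)[, c("subject_id", "variant_id",
                                                 "aic")]
  per_variant <- dplyr::summarise(
    dplyr::group_by(fits, .data$variant_id),
    mean_aic = mean(.data$aic), .groups = "drop")
  counts <- table(factor(per_subject$variant_id,
                         levels = per_variant$variant_id))
  per_variant$n_subjects_optimal <-
    as.integer(counts[per_variant$variant_id])
  per_variant <- per_variant[, c("variant_id", "n_subjects_optimal",
                                 "mean_aic")]
  per_variant <- dplyr::arrange(per_variant,
                                dplyr::desc(.data$n_subjects_optimal),
                                .data$mean_aic)
  structure(list(per_subject = per_subject, per_variant = per_variant,
                 cohort_variant = per_variant$variant_id[1]),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> cohort-selected variant:", x$cohort_variant, "\n")
  print(x$per_variant)
  invisible(x)
}
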