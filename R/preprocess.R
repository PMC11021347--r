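#' Trailing 5-minute window average of a 1-minute glucose series
#'
#' The quasi-continuous glucose trace recorded by the bedside closed-loop
#' device is smoothed by averaging, for every minute `t`, the samples falling
#' in `(t - 5, t]`. The first five minutes have no complete window, so the
#' output is five samples shorter than the input.
#'
#' @param x Either a numeric vector of glucose values sampled every minute,
#'   or a data frame with columns `t_min` and `value` on a uniform 1-minute
#'   grid.
#' @return Same shape as the input: a shortened numeric vector, or a tibble
#'   with `t_min` starting five minutes later.
#' @export
window_average_glucose <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("t_min", "value") %in% names(x))) {
      stop("data frame input needs columns t_min and value", call. = FALSE)
    }
    x <- x[order(x$t_min), ]
    if (nrow(x) >= 2 && any(abs(diff(x$t_min) - 1) > 1e-8)) {
      stop("glucose series must be sampled on a uniform 1-minute grid",
           call. = FALSE)
    }
    v <- window_average_glucose(x$value)
    return(tibble::tibble(t_min = x$t_min[-(1:5)], value = v))
  }
  n <- length(x)
  if (n < 6) stop("need at least 6 samples for a 5-minute window",
                  call. = FALSE)
  cs <- cumsum(c(0, x))
  (cs[6:n + 1] - cs[6:n + 1 - 5]) / 5
}

#' Normalize a subject's series by per-variable maxima
#'
#' Each measured variable is divided by its own maximum so that all variables
#' share the unit interval; the maxima are retained so the transform is
#' exactly invertible.
#'
#' @param series Long tibble with columns `subject_id`, `t_min`, `variable`,
#'   `value` (and optionally `units`) for one subject.
#' @return An object of class `normalized_series`: a list with `series` (the
#'   normalized long tibble) and `scales` (tibble of `variable`, `scale`).
#' @export
normalize_series <- function(series) {
  stopifnot(all(c("t_min", "variable", "value") %in% names(series)))
  scales <- dplyr::summarise(dplyr::group_by(series, .data$variable),
                             scale = max(.data$value), .groups = "drop")
  if (any(scales$scale <= 0)) {
    bad <- scales$variable[scales$scale <= 0]
    stop("variable(s) without a positive value cannot be normalized: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(series, scales, by = "variable")
  out$value <- out$value / out$scale
  out$scale <- NULL
  if ("units" %in% names(out)) out$units <- "normalized"
  structure(list(series = out, scales = scales),
            class = "normalized_series")
}

#' Invert [normalize_series()]
#'
#' @param x A `normalized_series` object.
#' @return The de-normalized long tibble.
#' @export
denormalize_series <- function(x) {
  stopifnot(inherits(x, "normalized_series"))
  out <- dplyr::left_join(x$series, x$scales, by = "variable")
  out$value <- out$value * out$scale
  out$scale <- NULL
  out
}

#' Fix the urinary excretion rate constant k8 from urinary glucose
#'
#' The rate constant of the first-order urinary glucose flux (`k8`, alias
#' `ku`) is not estimated: it is computed from the glucose excreted during
#' the first 120 minutes of the clamp via
#' `urinary_glucose = integral_0^120 k8 * Gc * BV dt`, with the integral
#' taken by the trapezoidal rule on the sampling grid (exact for
#' piecewise-linear traces).
#'
#' @param urinary_glucose Glucose excreted over 0-120 min, mg.
#' @param gc Blood glucose samples in mg/dL covering `[0, 120]` min.
#' @param times Sampling times of `gc`, minutes.
#' @param blood_volume Blood volume, dL.
#' @return `k8` in 1/min.
#' @export
estimate_k8 <- function(urinary_glucose, gc, times, blood_volume) {
  stopifnot(length(gc) == length(times), urinary_glucose >= 0,
            blood_volume > 0)
  o <- order(times)
  times <- times[o]; gc <- gc[o]
  if (times[1] > 1e-8 || times[length(times)] < 120 - 1e-8) {
    stop("glucose series must cover [0, 120] minutes", call. = FALSE)
  }
  keep <- times >= 0 & times <= 120
  tt <- times[keep]; g <- gc[keep]
  auc <- sum(diff(tt) * (utils::head(g, -1) + utils::tail(g, -1)) / 2)
  if (auc <= 0) stop("glucose integral over [0, 120] is not positive",
                     call. = FALSE)
  urinary_glucose / (blood_volume * auc)
}

#' Read and write long-format clamp series
#'
#' Tab-delimited long format with columns `subject_id`, `t_min`, `variable`
#' (one of `Gc`, `I`, `Gg`, `CP`, `f1`, `f2`), `value`, `units`.
#'
#' @param path File path.
#' @param series Long tibble as produced by the synthetic cohort generator.
#' @return `read_clamp_series()` returns the long tibble.
#' @name series_io
NULL

#' @rdname series_io
#' @export
read_clamp_series <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), t_min = readr::col_double(),
    variable = readr::col_character(), value = readr::col_double(),
    units = readr::col_character()))
}

#' @rdname series_io
#' @export
write_clamp_series <- function(series, path) {
  readr::write_tsv(series, path)
  invisible(path)
}

#' Read and write the one-row-per-subject record table
#'
#' Columns: `subject_id`, `group`, `body_weight`, `blood_volume`,
#' `urinary_glucose_0_120`, fasting values `G0` (mmol/L), `I0` (pmol/L),
#' `Gg0` (ng/L), `CP0` (nmol/L), clamp steady-state values `Gss`, `Iss`,
#' steady-state glucose infusion `fg` (mg/kg/min), and `PG120` (mmol/L).
#'
#' @param path File path.
#' @param subjects Subject record tibble.
#' @return `read_subject_table()` returns the tibble.
#' @name subject_io
NULL

#' @rdname subject_io
#' @export
read_subject_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(), .default = readr::col_double()))
}

#' @rdname subject_io
#' @export
write_subject_table <- function(subjects, path) {
  readr::write_tsv(subjects, path)
  invisible(path)
}
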