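#' Spearman rank correlation with a t-approximation p value
#'
#' The coefficient is the Pearson correlation of mid-ranks (average ranks on
#' ties). The p value for the null hypothesis of no correlation uses the
#' t-approximation `t = r * sqrt((n-2)/(1-r^2))` with `n - 2` degrees of
#' freedom, which matches common practice at cohort sizes; an exhaustive
#' permutation p value is available for small samples (`n <= 9`).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @param exact Use exhaustive permutation for the p value.
#' @return One-row tibble with `r`, `p`, `n`.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant vector: rank correlation undefined", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  if (exact) {
    if (n > 9) stop("exact permutation p limited to n <= 9", call. = FALSE)
    perms <- permutations_of(n)
    rperm <- apply(perms, 1, function(i) stats::cor(rx, ry[i]))
    p <- mean(abs(rperm) >= abs(r) - 1e-12)
  } else if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(r = r, p = p, n = n)
}

# All permutations of 1..n as a matrix (n! rows); recursion is fine at the
# small n the exact test allows.
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub)))
  }
  do.call(rbind, out)
}

#' Standardized major axis regression
#'
#' Symmetric line fit for the case where both axes carry error:
#' `slope = sign(r) * sd(y) / sd(x)`, intercept through the means. Metric
#' versus glycemia analyses use it on log10 scale.
#'
#' @param x,y Numeric vectors (`n >= 3`, finite, non-degenerate).
#' @return One-row tibble with `slope`, `intercept`, `r`, `n`.
#' @export
sma_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    stop("zero variance on an axis: SMA undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  slope <- (if (r < 0) -1 else 1) * sy / sx
  tibble::tibble(slope = slope, intercept = mean(y) - slope * mean(x),
                 r = r, n = n)
}

# Correlation between the SMA residual and fitted axes at slope b; the SMA
# slope of a sample is exactly the b that zeroes it.
sma_axis_cor <- function(x, y, b) stats::cor(y - b * x, y + b * x)

#' Test for a common standardized major axis slope across groups
#'
#' Likelihood-ratio-style test: the SMA slope of a sample is the `b` that
#' zeroes the correlation between the residual axis `y - b x` and the fitted
#' axis `y + b x`. Under a common slope the Fisher-z transforms of the
#' group-wise residual-axis correlations, evaluated at the common-slope
#' estimate, are asymptotically independent standard normals scaled by
#' `sqrt(n_g - 3)`; their squared sum is compared against a chi-square with
#' `groups - 1` degrees of freedom. A permutation fallback (permuting group
#' labels) is available.
#'
#' @param x,y Numeric vectors.
#' @param group Group labels (at least two groups, each `n >= 3`).
#' @param n_perm If positive, use that many label permutations for the p
#'   value instead of the chi-square reference.
#' @return One-row tibble with `statistic`, `df`, `p`, `common_slope`.
#' @export
sma_common_slope_test <- function(x, y, group, n_perm = 0) {
  stopifnot(length(x) == length(y), length(x) == length(group))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]; group <- group[keep]
  g <- split(seq_along(x), group)
  if (length(g) < 2 || any(lengths(g) < 4)) {
    stop("need >= 2 groups with at least 4 observations each",
         call. = FALSE)
  }
  for (idx in g) {
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) {
      stop("degenerate group: zero variance on an axis", call. = FALSE)
    }
  }
  stat_of <- function(grp_idx) {
    slopes <- vapply(grp_idx, function(i) sma_fit(x[i], y[i])$slope, 0)
    tstat <- function(logb) {
      b <- sign(slopes[1]) * exp(logb)
      sum(vapply(grp_idx, function(i) {
        rr <- sma_axis_cor(x[i], y[i], b)
        (length(i) - 3) * atanh(min(max(rr, -1 + 1e-12), 1 - 1e-12))^2
      }, 0))
    }
    lb <- log(range(abs(slopes)))
    opt <- stats::optimize(tstat, lower = lb[1] - 2, upper = lb[2] + 2)
    list(stat = opt$objective, slope = sign(slopes[1]) * exp(opt$minimum))
  }
  obs <- stat_of(g)
  df <- length(g) - 1
  if (n_perm > 0) {
    cnt <- 0
    for (b in seq_len(n_perm)) {
      perm <- sample(group)
      gp <- split(seq_along(x), perm)
      if (stat_of(gp)$stat >= obs$stat - 1e-12) cnt <- cnt + 1
    }
    p <- (cnt + 1) / (n_perm + 1)
  } else {
    p <- stats::pchisq(obs$stat, df = df, lower.tail = FALSE)
  }
  tibble::tibble(statistic = obs$stat, df = df, p = p,
                 common_slope = obs$slope)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` of predictions against observations.
#'
#' @param observed,predicted Numeric vectors of equal length (`n >= 2`).
#' @return R squared.
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("zero total variance", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Metric-versus-glycemia association on log10 scale
#'
#' Convenience wrapper reproducing the scatter analyses of the cohort
#' studies: Spearman correlation of a metric with PG120 plus an SMA fit of
#' `log10(PG120)` on `log10(metric)`, per group.
#'
#' @param cohort Tibble with columns `PG120`, `group`, and the metric.
#' @param metric Name of the metric column.
#' @return Tibble with one row per group: Spearman `r`, `p`, `n`, SMA
#'   `slope`, `intercept`.
#' @export
metric_glycemia_association <- function(cohort, metric) {
  stopifnot(metric %in% names(cohort), all(c("PG120", "group") %in%
                                             names(cohort)))
  purrr::map_dfr(split(cohort, cohort$group), function(d) {
    ok <- d[[metric]] > 0 & d$PG120 > 0
    sp <- spearman_test(d[[metric]][ok], d$PG120[ok])
    sm <- sma_fit(log10(d[[metric]][ok]), log10(d$PG120[ok]))
    tibble::tibble(group = d$group[1], r = sp$r, p = sp$p, n = sp$n,
                   slope = sm$slope, intercept = sm$intercept)
  })
}
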