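#' Ordinary least-squares regression with confidence intervals
#'
#' Simple linear regression of `y` on `x` with 2.5--97.5% confidence
#' intervals for slope and intercept from the t distribution with n - 2
#' degrees of freedom. Pairs with a missing value in either variable are
#' dropped (listwise deletion).
#'
#' @param x numeric predictor.
#' @param y numeric response of the same length.
#' @return Object of class `regression_result`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci` (2.5--97.5%), `r_squared`, `p_value`
#'   (slope t test), `n`, `residual_sd`.
#' @export
fit_linear_regression <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have the same length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 complete observations", call. = FALSE)
  if (sd(x) == 0)
    stop("degenerate predictor: x is constant", call. = FALSE)
  fit <- lm(y ~ x)
  ci <- confint(fit, level = 0.95)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_ci = unname(ci["x", ]),
                 intercept_ci = unname(ci["(Intercept)", ]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients["x", "Pr(>|t|)"]),
                 n = n,
                 residual_sd = sm$sigma),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(paste0("<regression_result> y = %.4g + %.4g x  (n = %d)\n",
                     "  slope CI [%.4g, %.4g], intercept CI [%.4g, %.4g]\n",
                     "  r^2 = %.3f, p = %.3g\n"),
              x$intercept, x$slope, x$n,
              x$slope_ci[1], x$slope_ci[2],
              x$intercept_ci[1], x$intercept_ci[2],
              x$r_squared, x$p_value))
  invisible(x)
}

#' Two-sample comparison by Student's t test
#'
#' Pooled-variance (Student's) two-sided t test by default, matching the
#' sex comparisons of the reference analysis; Welch's correction is
#' available since group variances often differ. Degenerate inputs (both
#' groups constant) are handled explicitly: equal means give t = 0, p = 1;
#' unequal constant groups give an infinite t with p = 0 and a warning.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pool the variances (default `TRUE`); `FALSE` for Welch.
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`, `method`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  method <- if (var_equal) "student" else "welch"
  if (sd(a) == 0 && sd(b) == 0) {
    df <- length(a) + length(b) - 2
    if (mean(a) == mean(b))
      return(list(t = 0, df = df, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b), method = method))
    warning("zero variance with unequal means: p-value degenerates to 0",
            call. = FALSE)
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p_value = 0,
                mean_a = mean(a), mean_b = mean(b), method = method))
  }
  ht <- t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b),
       method = method)
}

#' Bland--Altman agreement analysis
#'
#' Differences are `predicted - measured`. Reports the mean difference
#' (bias), the SD of the differences, the mean +/- 1 SD range (the
#' convention of the reference analysis) and the conventional
#' mean +/- 1.96 SD limits of agreement, plus a trend regression of the
#' difference on the pairwise mean (proportional-bias check).
#'
#' @param predicted,measured numeric vectors of equal length (n >= 2).
#' @return Object of class `bland_altman`: `mean_difference`, `sd_difference`,
#'   `range_1sd`, `limits_1.96sd`, `trend` (a [fit_linear_regression()]
#'   result, or `NULL` when the pairwise means are constant or n < 3), `n`.
#' @export
bland_altman <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("`predicted` and `measured` must have the same length", call. = FALSE)
  ok <- is.finite(predicted) & is.finite(measured)
  predicted <- predicted[ok]; measured <- measured[ok]
  n <- length(predicted)
  if (n < 2L)
    stop("need at least 2 complete pairs", call. = FALSE)
  d <- predicted - measured
  m <- (predicted + measured) / 2
  md <- mean(d); sdd <- sd(d)
  trend <- if (n >= 3L && sd(m) > 0) fit_linear_regression(m, d) else NULL
  structure(list(mean_difference = md,
                 sd_difference = sdd,
                 range_1sd = c(md - sdd, md + sdd),
                 limits_1.96sd = c(md - 1.96 * sdd, md + 1.96 * sdd),
                 trend = trend,
                 n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("<bland_altman> n = %d\n",
                     "  mean difference %.1f +/- %.1f (1 SD range %.1f to %.1f)\n",
                     "  1.96 SD limits %.1f to %.1f\n"),
              x$n, x$mean_difference, x$sd_difference,
              x$range_1sd[1], x$range_1sd[2],
              x$limits_1.96sd[1], x$limits_1.96sd[2]))
  if (!is.null(x$trend))
    cat(sprintf("  trend: diff = %.4g + %.4g x mean (r^2 = %.3f)\n",
                x$trend$intercept, x$trend$slope, x$trend$r_squared))
  invisible(x)
}

#' Cohort summary table
#'
#' Mean +/- SD of every numeric column for the whole cohort and per sex,
#' with a Student's t p-value per variable for the male/female comparison.
#' With a single-sex cohort the p-value column is NA and a message is
#' emitted. No multiple-testing correction is applied.
#'
#' @param cohort a data.frame with a `sex` column (`"male"`/`"female"`) and
#'   numeric measurement columns; see [generate_cohort()].
#' @param var_equal passed to [compare_groups()].
#' @return A data.frame with columns `variable`, `mean_all`, `sd_all`,
#'   `mean_male`, `sd_male`, `mean_female`, `sd_female`, `p_value`.
#' @export
cohort_summary <- function(cohort, var_equal = TRUE) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("`cohort` must be a non-empty data.frame", call. = FALSE)
  if (!"sex" %in% names(cohort))
    stop("`cohort` must have a `sex` column", call. = FALSE)
  num_cols <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "id")
  is_m <- cohort$sex == "male"
  is_f <- cohort$sex == "female"
  both <- any(is_m) && any(is_f)
  if (!both)
    message("single-sex cohort: male/female p-values omitted")
  rows <- lapply(num_cols, function(v) {
    x <- cohort[[v]]
    p <- if (both && sum(is_m) >= 2 && sum(is_f) >= 2)
      compare_groups(x[is_m], x[is_f], var_equal = var_equal)$p_value
    else NA_real_
    data.frame(variable = v,
               mean_all = mean(x), sd_all = sd(x),
               mean_male = if (any(is_m)) mean(x[is_m]) else NA_real_,
               sd_male = if (sum(is_m) > 1) sd(x[is_m]) else NA_real_,
               mean_female = if (any(is_f)) mean(x[is_f]) else NA_real_,
               sd_female = if (sum(is_f) > 1) sd(x[is_f]) else NA_real_,
               p_value = p)
  })
  do.call(rbind, rows)
}
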