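#' Bland-Altman agreement between predicted and measured diameters
#'
#' Pairwise differences (predicted minus measured) summarized by their mean
#' and sample (n-1) standard deviation; the SD of the differences is the
#' repeatability coefficient. Also reports the fractions of points whose
#' difference lies within 1 and 2 SD of the mean difference (set
#' `center = "zero"` to count from zero instead), the 1.96-SD limits of
#' agreement, and an ordinary least-squares fit of predicted on measured
#' with its R-squared.
#'
#' @param predicted,measured Equal-length numeric vectors (mm), n >= 2.
#' @param center Reference for the within-k-SD counts: the mean difference
#'   (default) or zero.
#' @return An object of class `agreement_stats`: `n`, `mean_diff`,
#'   `sd_diff`, `repeatability`, `frac_within_1sd`, `frac_within_2sd`,
#'   `loa` (mean +/- 1.96 SD), `slope`, `intercept`, `r2`.
#' @export
bland_altman <- function(predicted, measured, center = c("mean", "zero")) {
  center <- match.arg(center)
  if (length(predicted) != length(measured)) {
    stop("predicted and measured must have equal length", call. = FALSE)
  }
  n <- length(predicted)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- predicted - measured
  m <- mean(d)
  s <- stats::sd(d)
  ref <- if (center == "mean") m else 0
  within <- function(k) {
    if (s == 0) return(mean(abs(d - ref) == 0))
    mean(abs(d - ref) <= k * s)
  }
  fit <- if (n >= 3 && stats::sd(measured) > 0) {
    linear_fit_r2(measured, predicted)
  } else {
    list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_)
  }
  structure(
    list(n = n, mean_diff = m, sd_diff = s, repeatability = s,
         frac_within_1sd = within(1), frac_within_2sd = within(2),
         loa = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
         slope = fit$slope, intercept = fit$intercept, r2 = fit$r2),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement>  n = %d, mean diff = %.4g, SD (repeatability) = %.4g\n",
              x$n, x$mean_diff, x$sd_diff))
  cat(sprintf("  within 1 SD: %.0f%%, within 2 SD: %.0f%%; LoA [%.4g, %.4g]\n",
              100 * x$frac_within_1sd, 100 * x$frac_within_2sd,
              x$loa[["lower"]], x$loa[["upper"]]))
  if (!is.na(x$r2)) {
    cat(sprintf("  fit: slope %.4g, intercept %.4g, R2 %.4g\n",
                x$slope, x$intercept, x$r2))
  }
  invisible(x)
}

#' Ordinary least-squares line with R-squared
#'
#' @param x,y Numeric vectors, length >= 3; `x` must vary.
#' @return List with `slope`, `intercept`, `r2` (squared Pearson
#'   correlation; 0 when `y` is constant).
#' @export
linear_fit_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need at least 3 points", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2)
}
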