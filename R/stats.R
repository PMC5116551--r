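#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson coefficient with the two-sided p-value from
#' `t = rho * sqrt(n - 2) / sqrt(1 - rho^2)` on n - 2 degrees of freedom.
#' A perfect correlation (rho = +/-1) is reported with the p-value at the
#' numerical floor rather than 0.
#'
#' @param x,y numeric vectors of equal length n >= 3, each with nonzero
#'   variance.
#' @return an object of class `correlation_result`: list with `rho`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("Pearson correlation needs n >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(errorCondition("undefined correlation: a variable has zero variance",
                        class = c("vortexstab_zero_variance", "error", "condition")))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  p <- max(unname(ct$p.value), .Machine$double.xmin)
  structure(list(rho = unname(ct$estimate), p = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: rho = %.4f, p = %.4g (n = %d)\n",
              x$rho, x$p, x$n))
  invisible(x)
}

#' Two-sample t-test
#'
#' Welch's unequal-variance t-test by default (two-sided); the
#' pooled-variance Student's t-test behind `variant = "pooled"`. When both
#' groups have zero variance: equal means give `t = 0, p = 1` by convention,
#' different means are degenerate and flagged (`t = NA, p = NA`,
#' `degenerate = TRUE`).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return list with `t`, `p`, `df`, `variant` and `degenerate`.
#' @export
two_sample_t <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, df = NA_real_, variant = variant,
                  degenerate = FALSE))
    return(list(t = NA_real_, p = NA_real_, df = NA_real_, variant = variant,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"),
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = unname(tt$p.value),
       df = unname(tt$parameter), variant = variant, degenerate = FALSE)
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference agreement between two measurement pipelines, direction
#' fixed as `b - a`: bias = mean difference, limits of agreement = bias +/-
#' `1.96 * sample STD` of the differences (set `exact_t = TRUE` for the
#' small-sample t multiplier `qt(0.975, n - 1)`).
#'
#' @param a,b paired numeric vectors of equal length n >= 2 (b - a is
#'   reported).
#' @param exact_t use the exact-t multiplier instead of 1.96.
#' @return an object of class `agreement_result`: `bias`, `sd_diff`, `lower`,
#'   `upper`, `multiplier`, `n` and a `pairs` data.frame with per-pair `mean`
#'   and `difference` for plotting.
#' @export
bland_altman <- function(a, b, exact_t = FALSE) {
  if (length(a) != length(b)) stop("paired inputs must have equal length")
  n <- length(a)
  if (n < 2L) stop("Bland-Altman needs n >= 2 pairs")
  d <- b - a
  bias <- mean(d)
  s <- stats::sd(d)
  mult <- if (exact_t) stats::qt(0.975, n - 1) else 1.96
  structure(list(bias = bias, sd_diff = s,
                 lower = bias - mult * s, upper = bias + mult * s,
                 multiplier = mult, n = n,
                 pairs = data.frame(mean = (a + b) / 2, difference = d)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (b - a, n = %d): bias %.4g, limits [%.4g, %.4g]\n",
              x$n, x$bias, x$lower, x$upper))
  invisible(x)
}

#' @export
plot.agreement_result <- function(x, ...) {
  graphics::plot(x$pairs$mean, x$pairs$difference, pch = 16,
                 xlab = "pair mean", ylab = "difference (b - a)",
                 main = "Bland-Altman agreement", ...)
  graphics::abline(h = x$bias, lty = 2)
  graphics::abline(h = c(x$lower, x$upper), lty = 1)
  invisible(x)
}

#' Pearson correlations between many case-metric pairs
#'
#' Convenience for correlating vortex characteristics (mean DVO, core-count
#' variation) against geometric and hemodynamic case metrics held in a tidy
#' data frame (one row per case). Raw p-values by default, matching the
#' convention of reporting uncorrected correlations; Benjamini-Hochberg
#' adjustment available.
#'
#' @param data data.frame, one row per case.
#' @param x_vars,y_vars column names to correlate (all x against all y).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with `x`, `y`, `rho`, `p`, `n` (and `p_adj` if adjusted).
#' @export
pearson_table <- function(data, x_vars, y_vars, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  out <- list()
  for (xv in x_vars) for (yv in y_vars) {
    r <- pearson(data[[xv]], data[[yv]])
    out[[length(out) + 1L]] <- data.frame(x = xv, y = yv, rho = r$rho,
                                          p = r$p, n = r$n)
  }
  tab <- do.call(rbind, out)
  if (adjust == "BH") tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab
}
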