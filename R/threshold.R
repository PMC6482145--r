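#' Live-coral-cover threshold for a positive carbonate budget
#'
#' Fits the ordinary least-squares regression of net carbonate production
#' on live coral cover and inverts it to estimate the cover at which the
#' predicted budget crosses zero. The confidence interval for the
#' crossing point is obtained by inverting the confidence band for the
#' mean response (a Fieller-type interval): the interval bounds are the
#' covers where the lower and upper band lines cross zero, i.e. the
#' roots of
#' \deqn{(b_0 + b_1 x)^2 = t^2 (v_{00} + 2 x v_{01} + x^2 v_{11})}
#' with \eqn{(b_0, b_1)} the coefficient estimates, \eqn{v} their
#' covariance matrix and t the critical value at the requested level.
#'
#' A threshold is only meaningful when production increases with cover,
#' so the crossing point is reported only when the slope is positive and
#' statistically distinguishable from zero at `alpha`; otherwise the fit
#' is returned with `x_intercept_pct = NA` and a diagnostic reason.
#'
#' @param cover Live coral cover values, percent.
#' @param net_G Net carbonate production values, G.
#' @param conf_level Confidence level for the band (default 0.95).
#' @param alpha Significance level for the positive-slope requirement
#'   (default 0.05).
#' @return An object of class `threshold_fit`: a list with `slope`,
#'   `intercept` (and their standard errors), `r_squared`, `n_points`,
#'   `x_intercept_pct`, `ci95` (`lower`, `upper`; may be infinite when
#'   the band does not bound the crossing), `significant`, `reason` and
#'   the underlying `lm` fit.
#' @examples
#' cover <- c(5, 10, 15, 20, 30, 40)
#' cover_threshold(cover, 0.25 * cover - 2.5)$x_intercept_pct # 10
#' @export
cover_threshold <- function(cover, net_G, conf_level = 0.95, alpha = 0.05) {
  if (length(cover) != length(net_G)) {
    stop("cover and net_G must have the same length", call. = FALSE)
  }
  ok <- stats::complete.cases(cover, net_G)
  cover <- cover[ok]
  net_G <- net_G[ok]
  if (length(cover) < 3L) {
    stop("at least 3 (cover, net) points are required", call. = FALSE)
  }
  if (stats::sd(cover) == 0) {
    stop("degenerate regression: cover has zero variance", call. = FALSE)
  }

  fit <- stats::lm(net_G ~ cover)
  b <- stats::coef(fit)
  n <- length(cover)
  sigma2 <- sum(stats::residuals(fit)^2) / (n - 2L)
  # coefficient covariance computed directly; vcov() routes through
  # summary.lm, which warns on perfect fits
  X <- cbind(1, cover)
  V <- sigma2 * solve(crossprod(X))
  r2 <- if (stats::var(net_G) == 0) 1 else
    1 - sum(stats::residuals(fit)^2) / sum((net_G - mean(net_G))^2)

  slope <- unname(b[2L])
  intercept <- unname(b[1L])
  se_slope <- sqrt(V[2L, 2L])

  # perfect fits have zero residual variance; the slope sign then decides
  exact <- sigma2 < .Machine$double.eps * max(1, stats::var(net_G))
  if (exact) {
    # no residual noise: the slope sign decides, up to numeric round-off
    tol <- .Machine$double.eps^0.5 * max(abs(net_G), 1) / stats::sd(cover)
    significant <- slope > tol
  } else {
    tval <- slope / se_slope
    pval <- 2 * stats::pt(abs(tval), df = n - 2L, lower.tail = FALSE)
    significant <- slope > 0 && pval < alpha
  }

  res <- structure(
    list(slope = slope, intercept = intercept,
         se_slope = se_slope, se_intercept = sqrt(V[1L, 1L]),
         r_squared = r2, n_points = n, conf_level = conf_level,
         x_intercept_pct = NA_real_,
         ci95 = c(lower = NA_real_, upper = NA_real_),
         significant = significant, reason = NULL, fit = fit),
    class = "threshold_fit")

  if (!significant) {
    res$reason <- if (slope <= 0)
      "slope is not positive; net production does not increase with cover"
    else
      "slope is not significantly different from zero"
    return(res)
  }

  res$x_intercept_pct <- -intercept / slope

  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2L)
  # roots of (b0 + b1 x)^2 - t^2 (v00 + 2 x v01 + x^2 v11) = 0
  A <- slope^2 - tcrit^2 * V[2L, 2L]
  B <- 2 * (intercept * slope - tcrit^2 * V[1L, 2L])
  C <- intercept^2 - tcrit^2 * V[1L, 1L]
  if (A <= 0) {
    # the band never excludes a zero slope: the crossing is unbounded
    res$ci95 <- c(lower = -Inf, upper = Inf)
    return(res)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) disc <- 0
  roots <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  res$ci95 <- c(lower = roots[1L], upper = roots[2L])
  res
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("<threshold_fit>\n")
  cat(sprintf("  net_G = %.4f + %.4f * cover  (n = %d, R^2 = %.3f)\n",
              x$intercept, x$slope, x$n_points, x$r_squared))
  if (!is.na(x$x_intercept_pct)) {
    cat(sprintf("  budget-positivity threshold: %.1f%% live coral cover\n",
                x$x_intercept_pct))
    cat(sprintf("  %d%% CI (band inversion): [%.1f, %.1f]%%\n",
                round(100 * x$conf_level), x$ci95[["lower"]],
                x$ci95[["upper"]]))
  } else {
    cat("  no threshold reported: ", x$reason, "\n", sep = "")
  }
  invisible(x)
}
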