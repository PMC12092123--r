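#' Convert body length to body mass by a power law
#'
#' Mass (g) is modelled as `coefficient * length^exponent` with length in
#' mm.  The default exponent of 2.6 with unit coefficient is the standard
#' length-to-mass conversion used when only total body lengths are available
#' for spiders; both parameters are configurable.
#'
#' @param length_mm body length(s) in millimetres, > 0.
#' @param exponent power-law exponent (default 2.6).
#' @param coefficient multiplicative coefficient (default 1).
#' @return body mass in grams.
#' @examples
#' lengthToMass(10)  # 10^2.6 ~= 398.1
#' @export
lengthToMass <- function(length_mm, exponent = 2.6, coefficient = 1.0) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0))
    psDomainError("body length must be positive and finite")
  coefficient * length_mm^exponent
}

#' Estimate an allometric scaling exponent by log-log regression
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`.  The slope is the
#' allometric scaling exponent, the intercept is `log10` of the
#' multiplicative coefficient, and the 95% confidence interval comes from
#' the slope's standard error with the usual t quantile.
#'
#' @param x,y positive numeric vectors of equal length, n >= 3.
#' @return a [PowerLawFit-class].
#' @examples
#' x <- c(1, 2, 4, 8)
#' fitLogLogSlope(x, 3 * x^2.6)  # exponent 2.6, coefficient 3
#' @export
fitLogLogSlope <- function(x, y) {
  if (length(x) != length(y))
    psDomainError("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    psDomainError(sprintf("need at least 3 observations, got %d", length(x)))
  if (any(x <= 0) || any(y <= 0))
    psDomainError("all values must be > 0 for a log-log fit")
  if (diff(range(x)) == 0)
    psDomainError("x shows no variation; the slope is undefined")
  fit <- stats::lm(log10(y) ~ log10(x))
  cf <- stats::coef(fit)
  ## slope SE computed directly so an exact (zero-residual) fit yields a
  ## clean zero-width interval
  lx <- log10(x)
  s2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  se <- sqrt(s2 / sum((lx - mean(lx))^2))
  tq <- stats::qt(0.975, df = fit$df.residual)
  slope <- unname(cf["log10(x)"])
  new("PowerLawFit", exponent = slope, intercept = unname(cf["(Intercept)"]),
      ci = c(slope - tq * se, slope + tq * se), se = se,
      n = length(x))
}
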