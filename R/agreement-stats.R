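#' @include AllClasses.R AllGenerics.R
NULL

#' Linear agreement between paired measurement series
#'
#' Ordinary least squares of \code{y} on \code{x} plus the Pearson
#' correlation. In method-comparison use, \code{x} is the candidate method
#' and \code{y} the reference assay; slope and r/r^2 are both reported since
#' "linearity" is quoted either way in the field.
#'
#' @param x,y equal-length numeric series (n >= 3); x must not be constant.
#' @return Named list: slope, intercept, r, r_squared.
#' @export
linearAgreement <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0) stop("x is constant: regression undefined")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  list(slope = unname(stats::coef(fit)[["x"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       r = r, r_squared = r^2)
}

#' Bland-Altman limits of agreement
#'
#' Differences are taken as \code{d = x - y} (method minus reference). The
#' limits of agreement are \code{mean(d) +/- 1.96 sd(d)} with the sample SD
#' (n - 1 denominator).
#'
#' @param x,y equal-length numeric series (n >= 3).
#' @return Named list: mean_diff, sd_diff, loa_low, loa_high,
#'   frac_within_loa.
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("need at least 3 pairs")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  list(mean_diff = m, sd_diff = s, loa_low = lo, loa_high = hi,
       frac_within_loa = mean(d >= lo & d <= hi))
}

#' Full method-comparison summary
#'
#' Combines [linearAgreement()] and [blandAltman()] for a pair of series
#' (candidate method first, reference second).
#'
#' @param method numeric series measured by the candidate method.
#' @param reference paired reference (e.g. clinical assay) values.
#' @return An \linkS4class{AgreementStats}.
#' @export
agreementStats <- function(method, reference) {
  la <- linearAgreement(method, reference)
  ba <- blandAltman(method, reference)
  new("AgreementStats", slope = la$slope, intercept = la$intercept,
      r = la$r, r_squared = la$r_squared, mean_diff = ba$mean_diff,
      sd_diff = ba$sd_diff, loa_low = ba$loa_low, loa_high = ba$loa_high,
      frac_within_loa = ba$frac_within_loa, n = length(method))
}
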