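## Significance tests used when comparing the hinge and shear sets. The
## one-sided pooled two-proportion z-test asks whether the proportion in
## group 1 exceeds that in group 2 by more than chance.

#' One-sided pooled two-proportion z-test
#'
#' Tests H1: p1 > p2 with the pooled-variance statistic
#' \deqn{z = (\hat p_1 - \hat p_2) /
#'   \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)},\quad
#'   \hat p = (s_1 + s_2)/(n_1 + n_2)}
#' and one-sided p-value P(Z >= z) under the standard normal null.
#'
#' @param successes1,n1 successes and size of group 1.
#' @param successes2,n2 successes and size of group 2.
#' @return list with \code{p1}, \code{p2} (sample proportions), \code{z},
#'   \code{pOneSided} and \code{pPercent} (the same p-value as a
#'   percentage).
#' @export
twoProportionZ <- function(successes1, n1, successes2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (successes1 < 0 || successes1 > n1 || successes2 < 0 || successes2 > n2)
    stop("successes must lie in [0, n] for each group")
  p1 <- successes1 / n1; p2 <- successes2 / n2
  pool <- (successes1 + successes2) / (n1 + n2)
  v <- pool * (1 - pool) * (1 / n1 + 1 / n2)
  if (v <= 0)
    stop("z undefined: pooled variance is zero (all or no successes overall)")
  z <- (p1 - p2) / sqrt(v)
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(p1 = p1, p2 = p2, z = z, pOneSided = p, pPercent = 100 * p)
}

#' One-sided Welch z comparison of two means (convenience)
#'
#' Large-sample z statistic for H1: mean1 > mean2 from summary statistics.
#' Provided as a convenience for summary-level comparisons; it is a
#' large-sample approximation, not an exact t-test.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with \code{z}, \code{pOneSided}, \code{pPercent}.
#' @export
welchZ <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 <= 1 || n2 <= 1) stop("group sizes must exceed 1")
  se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
  if (se <= 0) stop("z undefined: zero standard error")
  z <- (mean1 - mean2) / se
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(z = z, pOneSided = p, pPercent = 100 * p)
}

#' Write a proportion-comparison report line
#'
#' Tab-separated \code{label s1 n1 s2 n2 z p_one_sided_percent}.
#'
#' @param label text label for the comparison.
#' @param successes1,n1,successes2,n2 as in \code{\link{twoProportionZ}}.
#' @param path output path; the line is appended when the file exists.
#' @return invisibly, the result of \code{\link{twoProportionZ}}.
#' @export
writeProportionTest <- function(label, successes1, n1, successes2, n2, path) {
  res <- twoProportionZ(successes1, n1, successes2, n2)
  line <- paste(label, successes1, n1, successes2, n2,
                format(res$z, digits = 6),
                format(res$pPercent, digits = 6), sep = "\t")
  cat(line, "\n", sep = "", file = path, append = file.exists(path))
  invisible(res)
}
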