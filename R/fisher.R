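#' Combine p-values with Fisher's method
#'
#' Combines independent p-values by Fisher's method: the statistic
#' \eqn{-2\sum_i \ln p_i} is referred to a chi-square distribution with
#' \eqn{2k} degrees of freedom, where \eqn{k} is the number of non-missing
#' inputs. Missing (`NA`) inputs are dropped and the degrees of freedom
#' reduced accordingly; with no inputs left the result is `NA`.
#'
#' A single p-value is returned unchanged (the chi-square survival function
#' with 2 df evaluated at \eqn{-2\ln p} is \eqn{p} itself). Values of
#' exactly 0 are not valid p-values; values below `floor` are clipped to
#' `floor` before taking logs so that near-zero inputs cannot produce
#' \eqn{-\infty} while their ordering is preserved.
#'
#' @param p Numeric vector of p-values in (0, 1]; `NA` entries are dropped.
#' @param floor Smallest value used in the log; inputs below it are clipped.
#' @return A single combined p-value, or `NA` if all inputs are missing.
#' @examples
#' fisher_combine(c(0.05, 0.05))
#' fisher_combine(0.05) # == 0.05
#' @export
fisher_combine <- function(p, floor = 1e-300) {
  assert_pvals(p)
  p <- p[!is.na(p)]
  k <- length(p)
  if (k == 0L) return(NA_real_)
  stat <- -2 * sum(log(pmax(p, floor)))
  stats::pchisq(stat, df = 2 * k, lower.tail = FALSE)
}

# Row-wise Fisher combination over the columns of a numeric matrix with NAs.
# Returns one combined p per row; NA where a row has no non-missing entry.
fisher_combine_rows <- function(m, floor = 1e-300) {
  assert_pvals(as.vector(m))
  lg <- -2 * log(pmax(m, floor))
  lg[is.na(m)] <- 0
  stat <- rowSums(lg)
  k <- rowSums(!is.na(m))
  out <- stats::pchisq(stat, df = 2 * k, lower.tail = FALSE)
  out[k == 0L] <- NA_real_
  out
}
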