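#' @importFrom stats pchisq phyper p.adjust fisher.test wilcox.test runif
#'   rbeta rnorm sd setNames ks.test
#' @importFrom utils head read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed and a label
#'
#' Deterministically maps a `(master seed, label)` pair to an integer seed
#' below 2^31, so pipeline components can be re-generated independently
#' while all randomness still flows from one master seed.
#'
#' @param master Integer master seed.
#' @param label Character label naming the component.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1000003L
  as.integer((abs(master) * 2654435 + h * 97 + 17) %% .Machine$integer.max)
}

assert_pvals <- function(p, what = "p-value", allow_na = TRUE) {
  bad <- !is.na(p) & (p <= 0 | p > 1)
  if (any(bad)) {
    stop(sprintf("%s out of (0,1]: first offending value %g", what,
                 p[bad][1L]), call. = FALSE)
  }
  if (!allow_na && anyNA(p)) stop(sprintf("missing %s not allowed", what),
                                  call. = FALSE)
  invisible(p)
}
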