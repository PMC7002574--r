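#' Compute coding, non-coding, or combined gene scores
#'
#' Aggregates per-element driver p-values into a single p-value per gene:
#'
#' * **GS-C** — the coding p-value, unchanged.
#' * **GS-N** — Fisher combination of up to three non-coding arguments:
#'   `min(promoter, utr5)` (core promoter and 5' UTR elements overlap, so
#'   only the smaller enters), the 3' UTR p-value, and the minimum p-value
#'   over all enhancers targeting the gene.
#' * **GS-CN** — Fisher combination of the coding p-value together with the
#'   three non-coding arguments.
#'
#' Missing elements are dropped from the combination with a matching
#' reduction in the chi-square degrees of freedom; a gene's score is
#' undefined (`NA`, and absent from the returned vector) only when every
#' contributing element for the mode is missing. When only one of
#' promoter / 5' UTR is present the minimum is taken over the present one.
#'
#' @param table An [element_pvalue_table()].
#' @param mode One of `"GS-C"`, `"GS-N"`, `"GS-CN"`.
#' @param include_enhancers Include enhancer elements in GS-N / GS-CN
#'   (default `TRUE`; switch off to score promoter/UTR elements only).
#' @param floor Clipping floor for near-zero p-values (see
#'   [fisher_combine()]).
#' @return A `gene_score_vector`: a named numeric vector of p-values over
#'   the genes whose score is defined, with the mode in the `"mode"`
#'   attribute.
#' @examples
#' tab <- element_pvalue_table(data.frame(
#'   gene = c("A", "A", "B"),
#'   element_class = c("coding", "promoter", "coding"),
#'   element_id = NA, p_value = c(0.05, 0.05, 0.2)))
#' compute_gene_scores(tab, "GS-CN")
#' @export
compute_gene_scores <- function(table, mode = c("GS-C", "GS-N", "GS-CN"),
                                include_enhancers = TRUE, floor = 1e-300) {
  if (!inherits(table, "element_pvalue_table")) {
    stop("table must be an element_pvalue_table", call. = FALSE)
  }
  mode <- match.arg(mode)
  prom_min <- pmin(table$promoter, table$utr5, na.rm = TRUE)
  enh <- if (include_enhancers) table$enhancer else rep(NA_real_, nrow(table))
  m <- switch(mode,
    "GS-C"  = cbind(table$coding),
    "GS-N"  = cbind(prom_min, table$utr3, enh),
    "GS-CN" = cbind(table$coding, prom_min, table$utr3, enh)
  )
  scores <- if (mode == "GS-C") as.numeric(m) else
    fisher_combine_rows(m, floor = floor)
  names(scores) <- table$gene
  scores <- scores[!is.na(scores)]
  structure(scores, mode = mode, class = "gene_score_vector")
}

#' Non-coding gene score for a single gene record
#'
#' Convenience scalar form of the GS-N score: Fisher combination of
#' `min(promoter, utr5)`, `utr3`, and the minimum enhancer p-value, dropping
#' missing arguments with degrees-of-freedom reduction.
#'
#' @param promoter,utr5,utr3 Element p-values or `NA`.
#' @param enhancers Numeric vector of enhancer p-values (possibly empty).
#' @param floor Clipping floor for near-zero p-values.
#' @return The GS-N p-value, or `NA` when no non-coding element is present.
#' @export
noncoding_score <- function(promoter = NA, utr5 = NA, utr3 = NA,
                            enhancers = numeric(0), floor = 1e-300) {
  prom <- suppressWarnings(min(c(promoter, utr5), na.rm = TRUE))
  if (!is.finite(prom)) prom <- NA_real_
  enh <- if (length(enhancers[!is.na(enhancers)]))
    min(enhancers, na.rm = TRUE) else NA_real_
  fisher_combine(c(prom, utr3, enh), floor = floor)
}

#' Number of elements contributing to each gene's score
#'
#' @param table An [element_pvalue_table()].
#' @inheritParams compute_gene_scores
#' @return Named integer vector over the table's genes.
#' @export
n_elements_used <- function(table, mode = c("GS-C", "GS-N", "GS-CN"),
                            include_enhancers = TRUE) {
  mode <- match.arg(mode)
  prom_min <- pmin(table$promoter, table$utr5, na.rm = TRUE)
  enh <- if (include_enhancers) table$enhancer else rep(NA_real_, nrow(table))
  m <- switch(mode,
    "GS-C"  = cbind(table$coding),
    "GS-N"  = cbind(prom_min, table$utr3, enh),
    "GS-CN" = cbind(table$coding, prom_min, table$utr3, enh)
  )
  stats::setNames(as.integer(rowSums(!is.na(m))), table$gene)
}

#' @export
print.gene_score_vector <- function(x, ...) {
  cat(sprintf("<gene_score_vector> mode %s, %d genes with defined scores\n",
              attr(x, "mode"), length(x)))
  print(utils::head(unclass(x)), ...)
  invisible(x)
}
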