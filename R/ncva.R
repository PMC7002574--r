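#' Permute the non-coding elements of an element table
#'
#' Builds one permutation-null copy of an element p-value table: coding
#' p-values stay fixed while, within each non-coding element class, the
#' p-values are shuffled among the genes that possess that class. Enhancer
#' lists are shuffled as whole per-gene bundles. The missingness pattern
#' and every marginal distribution are therefore preserved exactly.
#'
#' Classes are shuffled in the fixed order promoter, utr5, utr3, enhancer,
#' with one `sample()` call per class, drawing from the current RNG state;
#' callers (notably [ncva_test()]) control reproducibility via `set.seed()`.
#'
#' @param table An [element_pvalue_table()].
#' @return A permuted `element_pvalue_table`.
#' @export
permute_noncoding <- function(table) {
  out <- table
  for (cls in c("promoter", "utr5", "utr3")) {
    has <- which(!is.na(table[[cls]]))
    if (length(has) > 1L) out[[cls]][has] <- table[[cls]][has[sample(length(has))]]
  }
  enh_lists <- attr(table, "enhancers")
  has <- which(!is.na(table$enhancer))
  if (length(has) > 1L) {
    perm <- has[sample(length(has))]
    out$enhancer[has] <- table$enhancer[perm]
    enh_lists[has] <- attr(table, "enhancers")[perm]
    names(enh_lists) <- table$gene
    attr(out, "enhancers") <- enh_lists
  }
  out
}

#' Non-coding value-added (NCVA) permutation test
#'
#' In a combined coding + non-coding (GS-CN) analysis the coding signal
#' typically dominates. The NCVA test asks, gene by gene, whether the
#' non-coding data contribute significantly to the gene's discovery: the
#' observed report \eqn{R_0} is the method's gene set on the observed GS-CN
#' scores; each permutation keeps coding p-values fixed, shuffles the
#' non-coding element p-values across genes ([permute_noncoding()]),
#' recomputes GS-CN, and re-runs the method. A gene reported in the
#' observed data but only rarely on permuted data owes its discovery to its
#' non-coding signal.
#'
#' The per-gene NCVA p-value is the pseudocounted report frequency
#' \eqn{(1 + \#\{b : g \in R_b\}) / (1 + B)}, so its minimum attainable
#' value is \eqn{1/(B+1)}; a threshold of 0.1 therefore requires at least
#' 19 permutations (enforced).
#'
#' @param table An [element_pvalue_table()].
#' @param method A `driver_method`.
#' @param n_permutations Number of permutations \eqn{B} (>= 19).
#' @param threshold NCVA p-value cutoff (default 0.1).
#' @param seed Integer seed; the procedure is bit-reproducible given
#'   `(table, method, n_permutations, seed)`.
#' @param include_enhancers Passed to [compute_gene_scores()].
#' @return An `ncva_result`: list with `p` (named NCVA p-values over
#'   \eqn{R_0}), `genes` (the NCVA set), `observed` (the observed
#'   `method_result`), `n_permutations`, `threshold`, `seed`.
#' @export
ncva_test <- function(table, method, n_permutations = 99L, threshold = 0.1,
                      seed = 1L, include_enhancers = TRUE) {
  stopifnot(inherits(method, "driver_method"))
  if (n_permutations < 19L) {
    stop("n_permutations must be >= 19 so that the minimum attainable ",
         "NCVA p-value 1/(n_permutations+1) is below the 0.1 threshold",
         call. = FALSE)
  }
  observed <- run_method(
    method, compute_gene_scores(table, "GS-CN",
                                include_enhancers = include_enhancers))
  r0 <- observed$genes
  counts <- stats::setNames(integer(length(r0)), r0)
  set.seed(seed)
  for (b in seq_len(n_permutations)) {
    perm <- permute_noncoding(table)
    rb <- tryCatch(
      run_method(method,
                 compute_gene_scores(perm, "GS-CN",
                                     include_enhancers = include_enhancers)
                 )$genes,
      error = function(e) stop(sprintf(
        "method failed on permutation %d: %s", b, conditionMessage(e)),
        call. = FALSE))
    counts <- counts + (r0 %in% rb)
  }
  p <- (1 + counts) / (1 + n_permutations)
  structure(list(p = p, genes = r0[p < threshold], observed = observed,
                 n_permutations = n_permutations, threshold = threshold,
                 seed = seed),
            class = "ncva_result")
}

#' @export
print.ncva_result <- function(x, ...) {
  cat(sprintf(
    "<ncva_result> %d of %d observed gene(s) pass NCVA p < %g (B = %d)\n",
    length(x$genes), length(x$p), x$threshold, x$n_permutations))
  invisible(x)
}

#' Merge a method's non-coding results with its NCVA results
#'
#' A method's NCVA genes augment its gene set on the non-coding-only
#' (GS-N) data: the merged set is the union of the two. Both results must
#' come from the same method.
#'
#' @param gsn_result The method's `method_result` on GS-N scores.
#' @param ncva An `ncva_result` from the same method.
#' @return Character vector: the merged gene set.
#' @export
merge_noncoding_results <- function(gsn_result, ncva) {
  stopifnot(inherits(gsn_result, "method_result"),
            inherits(ncva, "ncva_result"))
  if (!identical(gsn_result$method, ncva$observed$method)) {
    stop(sprintf("method mismatch: GS-N result from '%s', NCVA from '%s'",
                 gsn_result$method, ncva$observed$method), call. = FALSE)
  }
  union(gsn_result$genes, ncva$genes)
}

#' Write an NCVA result as TSV plus run manifest
#'
#' @param ncva An `ncva_result`.
#' @param path Output TSV path (`gene`, `ncva_p`, `in_ncva_set`); a JSON
#'   manifest with the seed and permutation count is written alongside as
#'   `<path>.manifest.json`.
#' @export
write_ncva <- function(ncva, path) {
  df <- data.frame(gene = names(ncva$p), ncva_p = as.numeric(ncva$p),
                   in_ncva_set = names(ncva$p) %in% ncva$genes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = ncva$seed, n_permutations = ncva$n_permutations,
         threshold = ncva$threshold, method = ncva$observed$method),
    paste0(path, ".manifest.json"), auto_unbox = TRUE)
}
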