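#' Benjamini-Hochberg step-up q-values
#'
#' Thin validating wrapper around `stats::p.adjust(method = "BH")`: input
#' order is preserved, q-values are monotone in the sorted p-values and
#' never exceed 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop(sprintf("p-value out of [0,1]: first offending value %g",
                 p[bad][1L]), call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' One-sided Fisher's exact enrichment of a gene set in a reference list
#'
#' Tests whether `query` overlaps `reference` more than expected by chance
#' in `universe` (one-sided, greater), e.g. a consensus driver set against
#' a known-cancer-gene census. The expected overlap under independence is
#' `|query| * |reference| / |universe|`.
#'
#' @param query,reference Gene sets; both are restricted to `universe`.
#' @param universe Non-empty universe gene set. The choice of universe
#'   materially changes the p-value, so it is a required argument.
#' @param set_name Label stored on the record.
#' @return An `enrichment_record` (one-row data frame): `set_name`,
#'   `overlap`, `expected`, `query_size`, `reference_size`,
#'   `universe_size`, `p_value`, `q_value` (`NA` here; filled by
#'   multi-set wrappers).
#' @export
fisher_exact_enrichment <- function(query, reference, universe,
                                    set_name = "reference") {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty", call. = FALSE)
  query <- unique(intersect(query, universe))
  reference <- unique(intersect(reference, universe))
  ov <- length(intersect(query, reference))
  nq <- length(query); nr <- length(reference); nu <- length(universe)
  m <- matrix(c(ov, nq - ov, nr - ov, nu - nq - nr + ov), nrow = 2L)
  p <- stats::fisher.test(m, alternative = "greater")$p.value
  structure(data.frame(
    set_name = set_name, overlap = ov, expected = nq * nr / nu,
    query_size = nq, reference_size = nr, universe_size = nu,
    p_value = p, q_value = NA_real_, stringsAsFactors = FALSE),
    class = c("enrichment_record", "data.frame"))
}

#' Hypergeometric pathway enrichment with BH correction
#'
#' Tests every pathway of a size-filtered [pathway_db()] for one-sided
#' hypergeometric over-representation of `gene_set` and corrects across the
#' tested pathways with Benjamini-Hochberg.
#'
#' @param gene_set Character vector of genes.
#' @param db A `pathway_db`.
#' @param universe Universe genes (default: the database universe).
#' @return Data frame of enrichment records (one row per pathway) sorted by
#'   p-value, with `q_value` filled.
#' @export
pathway_enrichment <- function(gene_set, db, universe = db$universe) {
  stopifnot(inherits(db, "pathway_db"))
  universe <- unique(universe)
  gene_set <- unique(intersect(gene_set, universe))
  rows <- lapply(names(db$sets), function(nm) {
    set <- intersect(db$sets[[nm]], universe)
    ov <- length(intersect(set, gene_set))
    p <- stats::phyper(ov - 1L, length(set),
                       length(universe) - length(set),
                       length(gene_set), lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov,
               expected = length(gene_set) * length(set) / length(universe),
               query_size = length(gene_set), reference_size = length(set),
               universe_size = length(universe), p_value = p,
               q_value = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Resampling enrichment of categorical signature labels
#'
#' Compares the frequency of each signature label among `target_labels`
#' (e.g. most-likely mutational signatures of non-coding mutations in a
#' driver set) with its frequency in size-matched subsets of
#' `background_labels` drawn without replacement. Reports a two-sided
#' empirical p-value per signature. When every subset can be enumerated
#' (`choose(|background|, |target|) <= n_resamples`, or
#' `exhaustive = TRUE`) the null is the exact enumeration and the p-value
#' is the exact proportion; otherwise `n_resamples` Monte-Carlo draws are
#' used with the +1 pseudocount.
#'
#' @param target_labels Character vector of signature assignments.
#' @param background_labels Character vector, at least as long as
#'   `target_labels`.
#' @param n_resamples Number of resamples (> 0).
#' @param seed Integer seed (Monte-Carlo path).
#' @param exhaustive Force exhaustive enumeration.
#' @return Data frame with one row per signature present in either label
#'   set: `signature`, `observed` (count in target), `expected`, `p_value`.
#' @export
signature_enrichment <- function(target_labels, background_labels,
                                 n_resamples = 1000L, seed = 1L,
                                 exhaustive = FALSE) {
  if (n_resamples < 1L) stop("n_resamples must be positive", call. = FALSE)
  nt <- length(target_labels); nb <- length(background_labels)
  if (nb < nt) {
    stop("background smaller than target: cannot resample without ",
         "replacement", call. = FALSE)
  }
  sigs <- sort(unique(c(target_labels, background_labels)))
  obs <- vapply(sigs, function(s) sum(target_labels == s), 0L)
  n_comb <- suppressWarnings(choose(nb, nt))
  if (exhaustive || (is.finite(n_comb) && n_comb <= n_resamples)) {
    idx <- utils::combn(nb, nt)
    null <- apply(idx, 2L, function(j) {
      vapply(sigs, function(s) sum(background_labels[j] == s), 0L)
    })
    null <- matrix(null, nrow = length(sigs))
    p <- vapply(seq_along(sigs), function(i) {
      ge <- mean(null[i, ] >= obs[i]); le <- mean(null[i, ] <= obs[i])
      min(1, 2 * min(ge, le))
    }, 0)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_resamples), function(b) {
      draw <- background_labels[sample.int(nb, nt)]
      vapply(sigs, function(s) sum(draw == s), 0L)
    }, integer(length(sigs)))
    null <- matrix(null, nrow = length(sigs))
    p <- vapply(seq_along(sigs), function(i) {
      ge <- (1 + sum(null[i, ] >= obs[i])) / (1 + ncol(null))
      le <- (1 + sum(null[i, ] <= obs[i])) / (1 + ncol(null))
      min(1, 2 * min(ge, le))
    }, 0)
  }
  data.frame(signature = sigs, observed = as.integer(obs),
             expected = rowMeans(matrix(null, nrow = length(sigs))),
             p_value = p, stringsAsFactors = FALSE)
}

#' Read a reference gene list (one symbol per line)
#'
#' @param path Path to the file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}
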