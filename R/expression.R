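#' In cis mutation-expression test within one cohort
#'
#' Two-sided Wilcoxon rank-sum test comparing a gene's expression between
#' mutated samples `A` and non-mutated samples `B` of a single cohort. The
#' test is skipped (with a reason) when fewer than `min_mut` mutated or
#' `min_nonmut` non-mutated samples carry expression data, mirroring the
#' minimum-power filter for per-tumor-type analysis. The exact null
#' distribution is used when the smaller group has at most `exact_max`
#' samples and there are no ties; otherwise the normal approximation with
#' tie and continuity correction.
#'
#' @param expr Gene-by-sample numeric matrix of non-negative normalized
#'   expression (FPKM-UQ-like).
#' @param gene Gene (row) to test; absent genes are an error.
#' @param mutated,nonmutated Sample (column) names of sets A and B.
#' @param min_mut,min_nonmut Minimum group sizes (default 3 and 3).
#' @param exact_max Largest small-group size for the exact test.
#' @return List with `p` (`NA` when skipped), `skipped`, `reason`,
#'   `n_mut`, `n_nonmut`.
#' @export
cis_test_single_cohort <- function(expr, gene, mutated, nonmutated,
                                   min_mut = 3L, min_nonmut = 3L,
                                   exact_max = 8L) {
  if (!gene %in% rownames(expr)) {
    stop(sprintf("gene '%s' absent from expression matrix", gene),
         call. = FALSE)
  }
  mutated <- intersect(mutated, colnames(expr))
  nonmutated <- setdiff(intersect(nonmutated, colnames(expr)), mutated)
  a <- as.numeric(expr[gene, mutated]); b <- as.numeric(expr[gene, nonmutated])
  if (length(a) < min_mut || length(b) < min_nonmut) {
    return(list(p = NA_real_, skipped = TRUE,
                reason = sprintf("need >= %d mutated and >= %d non-mutated samples (have %d / %d)",
                                 min_mut, min_nonmut, length(a), length(b)),
                n_mut = length(a), n_nonmut = length(b)))
  }
  list(p = ranksum_p(a, b, exact_max), skipped = FALSE, reason = NA_character_,
       n_mut = length(a), n_nonmut = length(b))
}

# Two-sided rank-sum p: exact when feasible, else normal approximation with
# tie and continuity correction.
ranksum_p <- function(a, b, exact_max = 8L) {
  if (length(unique(c(a, b))) == 1L) return(1)  # full tie: no evidence
  ties <- any(duplicated(c(a, b)))
  use_exact <- !ties && min(length(a), length(b)) <= exact_max
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                       correct = TRUE)$p.value)
}

#' In cis mutation-expression test pooled across cohorts
#'
#' Pools evidence across tumor cohorts on a common scale: in every cohort
#' with at least one mutated and one non-mutated expressed sample, all of
#' that cohort's values are converted to z-scores using the mean and
#' unbiased standard deviation of its *non-mutated* samples; the z-scores
#' are then pooled over contributing cohorts and compared between mutated
#' and non-mutated samples with a two-sided Wilcoxon rank-sum test.
#' Cohorts whose non-mutated expression has zero standard deviation are
#' dropped (recorded in `dropped_cohorts`).
#'
#' @param expr Gene-by-sample expression matrix.
#' @param gene Gene to test.
#' @param partitions Named list (by cohort) of lists with elements
#'   `mutated` and `nonmutated` (sample names).
#' @param exact_max Passed to the rank-sum test.
#' @return List with `p` (`NA` when skipped), `skipped`, `reason`,
#'   `n_mut`, `n_nonmut`, `cohorts_used`, `dropped_cohorts`.
#' @export
cis_test_cross_cohort <- function(expr, gene, partitions, exact_max = 8L) {
  if (!gene %in% rownames(expr)) {
    stop(sprintf("gene '%s' absent from expression matrix", gene),
         call. = FALSE)
  }
  za <- numeric(0); zb <- numeric(0)
  used <- character(0); dropped <- character(0)
  for (cohort in names(partitions)) {
    part <- partitions[[cohort]]
    mut <- intersect(part$mutated, colnames(expr))
    non <- setdiff(intersect(part$nonmutated, colnames(expr)), mut)
    if (length(mut) < 1L || length(non) < 1L) next
    mu <- mean(as.numeric(expr[gene, non]))
    sdev <- stats::sd(as.numeric(expr[gene, non]))
    if (is.na(sdev) || sdev == 0) {
      dropped <- c(dropped, cohort)
      next
    }
    za <- c(za, (as.numeric(expr[gene, mut]) - mu) / sdev)
    zb <- c(zb, (as.numeric(expr[gene, non]) - mu) / sdev)
    used <- c(used, cohort)
  }
  if (!length(used)) {
    return(list(p = NA_real_, skipped = TRUE,
                reason = "no cohort with >= 1 mutated and >= 1 non-mutated sample",
                n_mut = 0L, n_nonmut = 0L, cohorts_used = character(0),
                dropped_cohorts = dropped))
  }
  list(p = ranksum_p(za, zb, exact_max), skipped = FALSE,
       reason = NA_character_, n_mut = length(za), n_nonmut = length(zb),
       cohorts_used = used, dropped_cohorts = dropped)
}

#' Run the in cis association screen over a mutation table
#'
#' For every (gene, element class) present in the mutation table and
#' expression matrix, partitions samples into mutated / non-mutated per
#' cohort and runs either the single-cohort test in every eligible cohort
#' or the pooled cross-cohort test.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param cohort_map Data frame `sample`, `cohort` (every expression sample
#'   assigned to exactly one cohort).
#' @param mutations Data frame `gene`, `element_class`, `sample`.
#' @param mode `"per_cohort"` or `"cross_cohort"`.
#' @param ... Passed to the underlying tests.
#' @return Data frame with one row per performed or skipped test: `gene`,
#'   `element_class`, `cohort` (`"all"` for pooled tests), `p_value`,
#'   `skipped`, `reason`, `n_mut`, `n_nonmut`, and `q_value` from
#'   [correct_cis_results()].
#' @export
run_cis_tests <- function(expr, cohort_map, mutations,
                          mode = c("per_cohort", "cross_cohort"), ...) {
  mode <- match.arg(mode)
  stopifnot(all(c("sample", "cohort") %in% names(cohort_map)),
            all(c("gene", "element_class", "sample") %in% names(mutations)))
  if (anyDuplicated(cohort_map$sample)) {
    stop("each sample must map to exactly one cohort", call. = FALSE)
  }
  samples <- intersect(colnames(expr), cohort_map$sample)
  cohort_of <- stats::setNames(cohort_map$cohort, cohort_map$sample)[samples]
  keys <- unique(mutations[, c("gene", "element_class")])
  keys <- keys[keys$gene %in% rownames(expr), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    gene <- keys$gene[i]; cls <- keys$element_class[i]
    mut_samples <- unique(mutations$sample[
      mutations$gene == gene & mutations$element_class == cls])
    mut_samples <- intersect(mut_samples, samples)
    if (mode == "per_cohort") {
      for (cohort in unique(cohort_of)) {
        cs <- samples[cohort_of == cohort]
        res <- cis_test_single_cohort(expr, gene,
                                      intersect(mut_samples, cs),
                                      setdiff(cs, mut_samples), ...)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, element_class = cls, cohort = cohort,
          p_value = res$p, skipped = res$skipped, reason = res$reason,
          n_mut = res$n_mut, n_nonmut = res$n_nonmut,
          stringsAsFactors = FALSE)
      }
    } else {
      parts <- lapply(unique(cohort_of), function(cohort) {
        cs <- samples[cohort_of == cohort]
        list(mutated = intersect(mut_samples, cs),
             nonmutated = setdiff(cs, mut_samples))
      })
      names(parts) <- unique(cohort_of)
      res <- cis_test_cross_cohort(expr, gene, parts, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, element_class = cls, cohort = "all",
        p_value = res$p, skipped = res$skipped, reason = res$reason,
        n_mut = res$n_mut, n_nonmut = res$n_nonmut,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  correct_cis_results(out)
}

#' BH-correct cis association results within each element class
#'
#' Applies [bh_fdr()] separately to the non-skipped tests of each element
#' class, so coding and each non-coding class carry independent FDRs.
#'
#' @param results Data frame with at least `element_class` and `p_value`.
#' @return The input with a `q_value` column (`NA` for skipped tests).
#' @export
correct_cis_results <- function(results) {
  results$q_value <- NA_real_
  for (cls in unique(results$element_class)) {
    sel <- results$element_class == cls & !is.na(results$p_value)
    results$q_value[sel] <- bh_fdr(results$p_value[sel])
  }
  results
}
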