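#' Majority-vote consensus over per-method gene sets
#'
#' A gene enters the consensus when it is reported by at least `threshold`
#' of the methods. Each method contributes at most one vote per gene (its
#' set is deduplicated first). The default threshold is a strict majority,
#' `floor(k/2) + 1` for `k` methods — 4 of 7 for the full ensemble.
#'
#' @param method_sets Named list of character vectors, one reported gene
#'   set per method.
#' @param threshold Minimum number of supporting methods; must lie in
#'   `[1, length(method_sets)]`.
#' @param mode_label Label stored on the result (e.g. `"PID-C"`).
#' @return A `consensus_result`: list with `table` (data frame `gene`,
#'   `votes`, `methods`, `in_consensus`, sorted by decreasing votes),
#'   `genes` (the consensus set), `threshold`, `methods` (roster),
#'   `mode_label`.
#' @examples
#' majority_vote(list(m1 = c("A", "B"), m2 = c("B", "C"), m3 = "B"),
#'               threshold = 2)$genes
#' @export
majority_vote <- function(method_sets, threshold = NULL, mode_label = NA) {
  stopifnot(is.list(method_sets), length(method_sets) >= 1L)
  if (is.null(names(method_sets))) {
    names(method_sets) <- paste0("method", seq_along(method_sets))
  }
  k <- length(method_sets)
  threshold <- threshold %||% (k %/% 2L + 1L)
  if (threshold < 1L || threshold > k) {
    stop(sprintf("threshold %s out of range [1, %d]", threshold, k),
         call. = FALSE)
  }
  method_sets <- lapply(method_sets, function(s) unique(as.character(s)))
  genes <- sort(unique(unlist(method_sets, use.names = FALSE)))
  votes <- stats::setNames(integer(length(genes)), genes)
  who <- stats::setNames(rep("", length(genes)), genes)
  for (nm in names(method_sets)) {
    s <- method_sets[[nm]]
    votes[s] <- votes[s] + 1L
    who[s] <- ifelse(nzchar(who[s]), paste(who[s], nm, sep = ";"), nm)
  }
  tab <- data.frame(gene = genes, votes = as.integer(votes), methods = who,
                    in_consensus = votes >= threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$votes, tab$gene), , drop = FALSE]
  structure(list(table = tab, genes = tab$gene[tab$in_consensus],
                 threshold = threshold, methods = names(method_sets),
                 mode_label = mode_label),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result>%s %d consensus gene(s) at >= %d/%d method votes\n",
    if (is.na(x$mode_label)) "" else paste0(" [", x$mode_label, "]"),
    length(x$genes), x$threshold, length(x$methods)))
  invisible(x)
}

#' Non-coding consensus: per-method GS-N results merged with NCVA
#'
#' Builds the non-coding consensus gene set (the PID-N construction): for
#' each method its GS-N gene set is first merged with its NCVA set
#' ([merge_noncoding_results()]) — one vote per method regardless of
#' whether the gene appears in one or both — then the merged sets are
#' majority-voted.
#'
#' @param gsn_results Named list of `method_result`s on GS-N scores.
#' @param ncva_results Named list of `ncva_result`s with matching names
#'   (same method roster; checked).
#' @param threshold Passed to [majority_vote()].
#' @return A `consensus_result` labelled `"PID-N"`.
#' @export
build_pid_n <- function(gsn_results, ncva_results, threshold = NULL) {
  if (!setequal(names(gsn_results), names(ncva_results))) {
    stop("method rosters of GS-N and NCVA results differ", call. = FALSE)
  }
  merged <- lapply(names(gsn_results), function(nm) {
    merge_noncoding_results(gsn_results[[nm]], ncva_results[[nm]])
  })
  names(merged) <- names(gsn_results)
  majority_vote(merged, threshold = threshold, mode_label = "PID-N")
}

#' Overlap report between two consensus sets
#'
#' @param a,b `consensus_result`s (e.g. PID-C and PID-N).
#' @return List with `intersection`, `only_a`, `only_b` gene vectors and
#'   their sizes.
#' @export
consensus_overlap <- function(a, b) {
  ga <- a$genes; gb <- b$genes
  list(intersection = intersect(ga, gb),
       only_a = setdiff(ga, gb), only_b = setdiff(gb, ga),
       n_intersection = length(intersect(ga, gb)),
       n_a = length(ga), n_b = length(gb))
}

#' Write a consensus table as TSV
#'
#' @param consensus A `consensus_result`.
#' @param path Output path.
#' @export
write_consensus <- function(consensus, path) {
  utils::write.table(consensus$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
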