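ELEMENT_CLASSES <- c("coding", "promoter", "utr5", "utr3", "enhancer")
NONCODING_CLASSES <- c("promoter", "utr5", "utr3", "enhancer")

#' Build a per-gene element p-value table
#'
#' The element p-value table is the pipeline's primary input: for each gene
#' it holds one driver p-value per genomic element class — coding sequence,
#' core promoter, 5' UTR, 3' UTR — plus a set of (enhancer id, p-value)
#' pairs for the enhancers targeting the gene. When several p-values are
#' reported for the same (gene, element) the smallest is kept
#' ([reduce_duplicates()] semantics). Enhancers mapping to more than
#' `max_enhancer_targets` genes are dropped before attachment.
#'
#' @param records Data frame with columns `gene`, `element_class`
#'   (one of coding, promoter, utr5, utr3, enhancer), `element_id`, and
#'   `p_value` in (0, 1]. For enhancer rows, `element_id` is the enhancer id.
#' @param enhancer_map Optional data frame with columns `enhancer_id` and
#'   `target_genes` (comma-separated gene symbols). When supplied, enhancer
#'   rows are attached to every target gene of their enhancer; without it,
#'   enhancer rows attach to the gene in their own `gene` column.
#' @param max_enhancer_targets Enhancers targeting more genes than this are
#'   dropped (with a message).
#' @return An object of class `element_pvalue_table`: a data frame with one
#'   row per gene and columns `gene`, `coding`, `promoter`, `utr5`, `utr3`,
#'   `enhancer` (the per-gene minimum over attached enhancers; `NA` when the
#'   gene has none), carrying the full per-gene enhancer lists in the
#'   `"enhancers"` attribute.
#' @export
element_pvalue_table <- function(records, enhancer_map = NULL,
                                 max_enhancer_targets = 5L) {
  req <- c("gene", "element_class", "p_value")
  if (!all(req %in% names(records))) {
    stop("records must have columns gene, element_class, p_value",
         call. = FALSE)
  }
  bad_class <- setdiff(unique(records$element_class), ELEMENT_CLASSES)
  if (length(bad_class)) {
    stop("unknown element class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  assert_pvals(records$p_value, allow_na = FALSE)
  if (is.null(records$element_id)) records$element_id <- NA_character_

  enh <- records[records$element_class == "enhancer", , drop = FALSE]
  oth <- records[records$element_class != "enhancer", , drop = FALSE]

  if (!is.null(enhancer_map) && nrow(enh)) {
    targets <- strsplit(as.character(enhancer_map$target_genes), ",",
                        fixed = TRUE)
    targets <- lapply(targets, trimws)
    keep <- lengths(targets) <= max_enhancer_targets
    if (any(!keep)) {
      message(sum(!keep), " enhancer(s) with > ", max_enhancer_targets,
              " gene targets dropped")
    }
    map <- data.frame(
      enhancer_id = rep(enhancer_map$enhancer_id[keep],
                        lengths(targets[keep])),
      gene = unlist(targets[keep], use.names = FALSE),
      stringsAsFactors = FALSE
    )
    hits <- merge(enh[, c("element_id", "p_value")], map,
                  by.x = "element_id", by.y = "enhancer_id")
    enh <- data.frame(gene = hits$gene, element_class = "enhancer",
                      element_id = hits$element_id, p_value = hits$p_value,
                      stringsAsFactors = FALSE)
  }

  # duplicate (gene, element) p-values -> keep the minimum; for enhancers the
  # minimum is taken per (gene, enhancer id) so distinct enhancers survive
  genes <- sort(unique(c(oth$gene, enh$gene)))
  tab <- data.frame(gene = genes, coding = NA_real_, promoter = NA_real_,
                    utr5 = NA_real_, utr3 = NA_real_, enhancer = NA_real_,
                    stringsAsFactors = FALSE)
  for (cls in c("coding", "promoter", "utr5", "utr3")) {
    sub <- oth[oth$element_class == cls, , drop = FALSE]
    if (!nrow(sub)) next
    mins <- tapply(sub$p_value, sub$gene, min)
    tab[[cls]][match(names(mins), tab$gene)] <- as.numeric(mins)
  }

  enh_lists <- stats::setNames(vector("list", length(genes)), genes)
  if (nrow(enh)) {
    enh$element_id[is.na(enh$element_id)] <-
      paste0("enh", seq_len(sum(is.na(enh$element_id))))
    key <- paste(enh$gene, enh$element_id, sep = "\r")
    mins <- tapply(enh$p_value, key, min)
    parts <- strsplit(names(mins), "\r", fixed = TRUE)
    g <- vapply(parts, `[[`, "", 1L)
    id <- vapply(parts, `[[`, "", 2L)
    for (gn in unique(g)) {
      sel <- g == gn
      enh_lists[[gn]] <- stats::setNames(as.numeric(mins[sel]), id[sel])
    }
    enh_min <- vapply(enh_lists, function(x) if (length(x)) min(x) else
      NA_real_, 0)
    tab$enhancer <- as.numeric(enh_min[tab$gene])
  }

  attr(tab, "enhancers") <- enh_lists
  class(tab) <- c("element_pvalue_table", "data.frame")
  tab
}

#' Reduce duplicate element p-values to their minimum
#'
#' When the upstream driver analysis reports several p-values for the same
#' genomic element, the smallest reported p-value is used. This is applied
#' automatically by [element_pvalue_table()]; the function is exposed for
#' raw record frames.
#'
#' @param records Raw records as for [element_pvalue_table()].
#' @param ... Passed on to [element_pvalue_table()].
#' @return An `element_pvalue_table`.
#' @export
reduce_duplicates <- function(records, ...) {
  element_pvalue_table(records, ...)
}

#' Per-gene enhancer p-value lists of a table
#'
#' @param table An `element_pvalue_table`.
#' @return Named list (by gene) of named numeric vectors (by enhancer id).
#' @export
enhancer_lists <- function(table) {
  attr(table, "enhancers")
}
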