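#' Read a per-element driver p-value TSV
#'
#' Expects header columns `gene`, `element_class`, `element_id`, `p_value`.
#' Rows are validated before table construction: an unknown element class
#' or a p-value outside (0, 1] raises a parse error naming the offending
#' file line (the header is line 1).
#'
#' @param path Path to the TSV.
#' @param enhancer_map Optional enhancer map data frame (see
#'   [read_enhancer_map()]); enhancers with more than
#'   `max_enhancer_targets` targets are dropped with a message.
#' @param max_enhancer_targets Enhancer target filter.
#' @return An [element_pvalue_table()].
#' @export
read_element_table <- function(path, enhancer_map = NULL,
                               max_enhancer_targets = 5L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "element_class", "p_value")
  if (!all(req %in% names(df))) {
    stop("element p-value TSV needs columns gene, element_class, p_value",
         call. = FALSE)
  }
  line <- seq_len(nrow(df)) + 1L
  bad <- which(!df$element_class %in% ELEMENT_CLASSES)
  if (length(bad)) {
    stop(sprintf("line %d: unknown element class '%s'", line[bad[1L]],
                 df$element_class[bad[1L]]), call. = FALSE)
  }
  bad <- which(is.na(df$p_value) | df$p_value <= 0 | df$p_value > 1)
  if (length(bad)) {
    stop(sprintf("line %d: p_value %s outside (0,1]", line[bad[1L]],
                 format(df$p_value[bad[1L]])), call. = FALSE)
  }
  element_pvalue_table(df, enhancer_map = enhancer_map,
                       max_enhancer_targets = max_enhancer_targets)
}

#' Write an element p-value table as long-format TSV
#'
#' @param table An `element_pvalue_table`.
#' @param path Output path.
#' @export
write_element_table <- function(table, path) {
  rows <- list()
  for (cls in c("coding", "promoter", "utr5", "utr3")) {
    has <- !is.na(table[[cls]])
    if (any(has)) {
      rows[[cls]] <- data.frame(gene = table$gene[has], element_class = cls,
                                element_id = paste0(cls, "_",
                                                    table$gene[has]),
                                p_value = table[[cls]][has],
                                stringsAsFactors = FALSE)
    }
  }
  enh <- enhancer_lists(table)
  lens <- lengths(enh)
  if (any(lens > 0)) {
    rows[["enhancer"]] <- data.frame(
      gene = rep(names(enh), lens), element_class = "enhancer",
      element_id = unlist(lapply(enh, names), use.names = FALSE),
      p_value = unlist(enh, use.names = FALSE), stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read an enhancer-to-target-gene map TSV
#'
#' Header columns `enhancer_id` and `target_genes` (comma-separated).
#'
#' @param path Path to the TSV.
#' @return Data frame `enhancer_id`, `target_genes`.
#' @export
read_enhancer_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("enhancer_id", "target_genes") %in% names(df))) {
    stop("enhancer map TSV needs columns enhancer_id, target_genes",
         call. = FALSE)
  }
  df
}

#' Read a gene-by-sample expression TSV
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (any(m < 0, na.rm = TRUE)) {
    stop("expression matrix contains negative values", call. = FALSE)
  }
  m
}

#' Read a sample-to-cohort map TSV
#'
#' @param path Path to a TSV with columns `sample`, `cohort`.
#' @return Data frame; duplicate sample assignments are an error.
#' @export
read_cohort_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "cohort") %in% names(df))) {
    stop("cohort map TSV needs columns sample, cohort", call. = FALSE)
  }
  dup <- which(duplicated(df$sample))
  if (length(dup)) {
    stop(sprintf("line %d: sample '%s' assigned to more than one cohort",
                 dup[1L] + 1L, df$sample[dup[1L]]), call. = FALSE)
  }
  df
}

#' Read a mutation occurrence TSV
#'
#' @param path Path to a TSV with columns `gene`, `element_class`,
#'   `sample`.
#' @return Data frame.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "element_class", "sample") %in% names(df))) {
    stop("mutation TSV needs columns gene, element_class, sample",
         call. = FALSE)
  }
  bad <- which(!df$element_class %in% ELEMENT_CLASSES)
  if (length(bad)) {
    stop(sprintf("line %d: unknown element class '%s'", bad[1L] + 1L,
                 df$element_class[bad[1L]]), call. = FALSE)
  }
  df
}

#' Load and validate a directory of pipeline inputs
#'
#' Reads the files written by [write_scenario()] (any may be absent except
#' the element table) and returns the validated in-memory objects.
#'
#' @param dir Input directory.
#' @return List with `table`, `enhancer_map`, `network`, `pathways`,
#'   `expression`, `cohort_map`, `mutations`, `truth` (components absent
#'   on disk are `NULL`).
#' @export
load_inputs <- function(dir) {
  pick <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) p else NULL
  }
  emap <- if (!is.null(pick("enhancer_map.tsv")))
    read_enhancer_map(pick("enhancer_map.tsv")) else NULL
  if (is.null(pick("elements.tsv"))) {
    stop("elements.tsv not found in ", dir, call. = FALSE)
  }
  truth_path <- pick("truth.tsv")
  list(
    table = read_element_table(pick("elements.tsv"), enhancer_map = emap),
    enhancer_map = emap,
    network = if (!is.null(pick("network.tsv")))
      read_network(pick("network.tsv")) else NULL,
    pathways = if (!is.null(pick("pathways.gmt")))
      read_gmt(pick("pathways.gmt")) else NULL,
    expression = if (!is.null(pick("expression.tsv")))
      read_expression(pick("expression.tsv")) else NULL,
    cohort_map = if (!is.null(pick("cohorts.tsv")))
      read_cohort_map(pick("cohorts.tsv")) else NULL,
    mutations = if (!is.null(pick("mutations.tsv")))
      read_mutations(pick("mutations.tsv")) else NULL,
    truth = if (!is.null(truth_path))
      utils::read.delim(truth_path, stringsAsFactors = FALSE) else NULL)
}

#' Write a gene score vector as TSV
#'
#' Columns `gene`, `mode`, `score`, `n_elements_used`.
#'
#' @param scores A `gene_score_vector`.
#' @param table The `element_pvalue_table` the scores came from.
#' @param path Output path.
#' @param ... Passed to [n_elements_used()].
#' @export
write_scores <- function(scores, table, path, ...) {
  mode <- attr(scores, "mode")
  k <- n_elements_used(table, mode, ...)
  df <- data.frame(gene = names(scores), mode = mode,
                   score = as.numeric(scores),
                   n_elements_used = as.integer(k[names(scores)]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
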