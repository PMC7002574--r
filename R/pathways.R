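#' Build a pathway database
#'
#' A pathway database is a named list of gene sets together with a gene
#' universe. Sets smaller than `min_size` or larger than `max_size` genes
#' are removed at construction, matching the usual pathway-database filter
#' for enrichment analysis.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param universe Character vector of genes; defaults to the union of all
#'   sets.
#' @param min_size,max_size Inclusive size bounds applied after restricting
#'   each set to the universe.
#' @return An object of class `pathway_db` with elements `sets` and
#'   `universe`.
#' @export
pathway_db <- function(sets, universe = NULL, min_size = 3L,
                       max_size = 1000L) {
  stopifnot(is.list(sets))
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be uniquely named", call. = FALSE)
  }
  universe <- unique(universe %||% unlist(sets, use.names = FALSE))
  sets <- lapply(sets, function(s) unique(intersect(s, universe)))
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_size & sizes <= max_size]
  structure(list(sets = sets, universe = universe), class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d gene sets over %d universe genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to a GMT file.
#' @param ... Passed to [pathway_db()] (e.g. `universe`, size bounds).
#' @return A `pathway_db`.
#' @export
read_gmt <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", bad[1L]),
         call. = FALSE)
  }
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  pathway_db(sets, ...)
}

#' Write gene sets in GMT format
#'
#' @param db A `pathway_db`.
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$sets), function(nm) {
    paste(c(nm, "na", db$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}
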