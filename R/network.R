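#' Build an undirected gene-interaction network
#'
#' Wraps an edge list into a simple undirected [igraph::graph] over gene
#' identifiers: self-loops and duplicate edges are dropped (with a message
#' when any are found), matching the treatment of high-confidence
#' protein-interaction networks as simple undirected graphs.
#'
#' @param edges Two-column data frame (or matrix) of gene identifiers.
#' @param nodes Optional extra node names to include as isolated vertices.
#' @return An undirected simple `igraph` graph.
#' @export
interaction_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges needs two columns", call. = FALSE)
  a <- as.character(edges[[1L]]); b <- as.character(edges[[2L]])
  loops <- a == b
  verts <- unique(c(a, b, as.character(nodes %||% character(0))))
  g <- igraph::graph_from_data_frame(
    data.frame(a = a[!loops], b = b[!loops], stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  n_dup <- sum(igraph::count_multiple(g) > 1) / 2
  if (any(loops) || n_dup > 0) {
    message(sum(loops), " self-loop(s) and ", n_dup,
            " duplicate edge(s) dropped at network load")
  }
  igraph::simplify(g)
}

#' Read an interaction network from edge-list TSV or SIF
#'
#' Edge-list files have a header with columns `gene_a`, `gene_b`; SIF files
#' have no header and rows of the form `source<tab>relation<tab>target...`
#' (one row may carry several targets).
#'
#' @param path Path to the file.
#' @param format `"tsv"`, `"sif"`, or `"auto"` (by file extension).
#' @return An undirected simple `igraph` graph.
#' @export
read_network <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_a", "gene_b") %in% names(df))) {
      stop("edge-list TSV needs columns gene_a, gene_b", call. = FALSE)
    }
    return(interaction_network(df[, c("gene_a", "gene_b")]))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[\t ]+")
  edges <- do.call(rbind, lapply(parts, function(x) {
    if (length(x) < 3L) return(NULL)
    cbind(x[1L], x[-(1:2)])
  }))
  singles <- unlist(lapply(parts, function(x) if (length(x) == 1L) x else
    NULL))
  interaction_network(edges %||% matrix(character(0), 0, 2),
                      nodes = singles)
}

#' Write a network as edge-list TSV
#'
#' @param network An `igraph` graph.
#' @param path Output path.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network)
  utils::write.table(
    data.frame(gene_a = el[, 1L], gene_b = el[, 2L]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}
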