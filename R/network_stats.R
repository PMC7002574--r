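#' Does a gene improve its network-neighborhood score?
#'
#' Compares the Fisher-combined score of a gene's first-order neighborhood
#' with (\eqn{p^{with}}, over \eqn{N(g) \cup \{g\}}) and without
#' (\eqn{p^{without}}, over \eqn{N(g)}) the gene's own score. The gene
#' *improves* its neighborhood when \eqn{p^{with} < p^{without}}: its own
#' score contributes to the neighborhood's signal rather than riding on its
#' neighbors'. For a degree-0 gene \eqn{p^{without} = 1} by convention.
#' Neighbors without a defined score are dropped with degrees-of-freedom
#' reduction.
#'
#' @param gene Gene identifier; must be a network node with a defined score.
#' @param scores A `gene_score_vector` (or named numeric).
#' @param network An `igraph` interaction network.
#' @return List with `gene`, `p_with`, `p_without`, `improves`.
#' @export
neighborhood_improvement <- function(gene, scores, network) {
  if (!gene %in% igraph::V(network)$name) {
    stop(sprintf("gene '%s' is not a node of the network", gene),
         call. = FALSE)
  }
  if (!gene %in% names(scores) || is.na(scores[[gene]])) {
    stop(sprintf("gene '%s' has no defined score", gene), call. = FALSE)
  }
  nb <- igraph::neighbors(network, gene)$name
  p_nb <- as.numeric(scores[intersect(nb, names(scores))])
  p_wo <- if (length(p_nb[!is.na(p_nb)])) fisher_combine(p_nb) else 1
  p_wi <- fisher_combine(c(p_nb, scores[[gene]]))
  list(gene = gene, p_with = p_wi, p_without = p_wo,
       improves = p_wi < p_wo)
}

# Vectorized improve-status for every scored node of the network.
improvement_status <- function(scores, network) {
  adj <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  vnames <- rownames(adj)
  p <- stats::setNames(rep(NA_real_, length(vnames)), vnames)
  common <- intersect(vnames, names(scores))
  p[common] <- as.numeric(scores[common])
  lg <- -2 * log(pmax(p, 1e-300)); lg[is.na(p)] <- 0
  kz <- as.numeric(!is.na(p))
  s_wo <- as.numeric(adj %*% lg); k_wo <- as.numeric(adj %*% kz)
  p_wo <- stats::pchisq(s_wo, df = 2 * k_wo, lower.tail = FALSE)
  p_wo[k_wo == 0] <- 1
  p_wi <- stats::pchisq(s_wo + lg, df = 2 * (k_wo + kz), lower.tail = FALSE)
  improves <- !is.na(p) & p_wi < p_wo
  stats::setNames(improves, vnames)
}

#' Null distribution of neighborhood-improvement counts
#'
#' How many genes of a random gene set improve their network neighborhoods?
#' Samples `n_trials` gene sets of size `set_size` uniformly at random from
#' the network's nodes and counts improving genes in each, giving the null
#' against which the improvement count of an observed gene set (e.g. a
#' consensus driver set) is compared. The empirical p-value for
#' `observed_count` uses the +1 pseudocount, so it lies in
#' `[1/(n_trials+1), 1]`.
#'
#' @param network An `igraph` interaction network.
#' @param scores A `gene_score_vector`.
#' @param set_size Size of the sampled gene sets (<= number of nodes).
#' @param n_trials Number of random sets (> 0).
#' @param seed Integer seed.
#' @param observed_count Optional observed improvement count.
#' @return A `permutation_enrichment`: list with `observed`, `expected`,
#'   `p`, `n_permutations`, `seed`, and the sampled `null` counts.
#' @export
improvement_count_null <- function(network, scores, set_size, n_trials,
                                   seed = 1L, observed_count = NULL) {
  if (n_trials < 1L) stop("n_trials must be positive", call. = FALSE)
  vnames <- igraph::V(network)$name
  if (set_size > length(vnames)) {
    stop("set_size exceeds the number of network nodes", call. = FALSE)
  }
  status <- improvement_status(scores, network)
  set.seed(seed)
  null <- vapply(seq_len(n_trials), function(i) {
    sum(status[sample(vnames, set_size)])
  }, 0L)
  permutation_enrichment(observed_count, null, seed,
                         alternative = "greater")
}

permutation_enrichment <- function(observed, null, seed,
                                   alternative = "greater") {
  p <- if (is.null(observed)) NA_real_ else {
    n <- length(null)
    switch(alternative,
      greater = (1 + sum(null >= observed)) / (1 + n),
      less = (1 + sum(null <= observed)) / (1 + n),
      two.sided = min(1, 2 * min((1 + sum(null >= observed)) / (1 + n),
                                 (1 + sum(null <= observed)) / (1 + n))))
  }
  structure(list(observed = observed, expected = mean(null), p = p,
                 n_permutations = length(null), seed = seed, null = null),
            class = "permutation_enrichment")
}

#' @export
print.permutation_enrichment <- function(x, ...) {
  cat(sprintf(
    "<permutation_enrichment> observed %s vs %.3g expected (p = %.3g, %d permutations)\n",
    format(x$observed), x$expected, x$p, x$n_permutations))
  invisible(x)
}

#' Sample a degree-preserving random network
#'
#' Draws an approximately uniform sample from the graphs sharing the input
#' network's exact degree sequence, via `n_swaps_factor * |E|` attempted
#' double-edge swaps that reject any swap creating a self-loop or parallel
#' edge. Node identities and degrees are preserved exactly.
#'
#' @param network An `igraph` graph with at least 2 edges.
#' @param n_swaps_factor Attempted swaps per edge (default 10).
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @return A rewired `igraph` graph with the identical degree sequence.
#' @export
degree_preserving_sample <- function(network, n_swaps_factor = 10,
                                     seed = NULL) {
  if (igraph::ecount(network) < 2L) {
    stop("network must have at least 2 edges", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  igraph::rewire(network, igraph::keeping_degseq(
    loops = FALSE, niter = ceiling(n_swaps_factor * igraph::ecount(network))))
}

count_set_edges <- function(network, set_a, set_b = NULL) {
  el <- igraph::as_edgelist(network, names = TRUE)
  if (is.null(set_b)) {
    sum(el[, 1L] %in% set_a & el[, 2L] %in% set_a)
  } else {
    # edges with one endpoint in each set; an edge inside the intersection
    # satisfies both orientations but is one row, so it counts once
    sum((el[, 1L] %in% set_a & el[, 2L] %in% set_b) |
        (el[, 1L] %in% set_b & el[, 2L] %in% set_a))
  }
}

#' Degree-preserving interaction enrichment between gene sets
#'
#' Counts interactions within a gene set (`set_b = NULL`) or between two
#' gene sets (edges with one endpoint in each; an edge with both endpoints
#' in the intersection of overlapping sets counts once) and compares the
#' observed count against degree-preserving random networks
#' ([degree_preserving_sample()]), yielding a one-sided (greater) empirical
#' p-value with the +1 pseudocount.
#'
#' @param network An `igraph` interaction network.
#' @param set_a,set_b Gene sets (subsets of nodes; `set_b` optional).
#' @param n_permutations Number of random networks.
#' @param seed Integer seed.
#' @param n_swaps_factor Passed to [degree_preserving_sample()].
#' @return A `permutation_enrichment`.
#' @export
interaction_enrichment <- function(network, set_a, set_b = NULL,
                                   n_permutations = 1000L, seed = 1L,
                                   n_swaps_factor = 10) {
  set_a <- intersect(set_a, igraph::V(network)$name)
  if (!is.null(set_b)) set_b <- intersect(set_b, igraph::V(network)$name)
  observed <- count_set_edges(network, set_a, set_b)
  set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(i) {
    g <- degree_preserving_sample(network, n_swaps_factor)
    count_set_edges(g, set_a, set_b)
  }, 0)
  permutation_enrichment(observed, null, seed, alternative = "greater")
}

#' Largest connected subnetwork induced by a gene set
#'
#' Size and membership of the largest connected component of the subgraph
#' induced by `gene_set` (restricted to genes present in the network).
#'
#' @param network An `igraph` interaction network.
#' @param gene_set Character vector of genes.
#' @return List with `size` and `members`.
#' @export
largest_connected_subnetwork <- function(network, gene_set) {
  nodes <- intersect(gene_set, igraph::V(network)$name)
  if (!length(nodes)) return(list(size = 0L, members = character(0)))
  sub <- igraph::induced_subgraph(network, nodes)
  comp <- igraph::components(sub)
  big <- which.max(comp$csize)
  list(size = as.integer(max(comp$csize)),
       members = igraph::V(sub)$name[comp$membership == big])
}

#' Null distribution of largest-connected-subnetwork sizes
#'
#' Companion null for [largest_connected_subnetwork()]: samples uniform
#' random gene sets of the same size and records the largest induced
#' component size of each, giving a one-sided (greater) empirical p-value
#' for the observed size.
#'
#' @param network An `igraph` interaction network.
#' @param set_size Size of the sampled gene sets.
#' @param n_trials Number of random sets.
#' @param seed Integer seed.
#' @param observed_size Optional observed component size.
#' @return A `permutation_enrichment`.
#' @export
subnetwork_size_null <- function(network, set_size, n_trials, seed = 1L,
                                 observed_size = NULL) {
  if (n_trials < 1L) stop("n_trials must be positive", call. = FALSE)
  vnames <- igraph::V(network)$name
  set.seed(seed)
  null <- vapply(seq_len(n_trials), function(i) {
    largest_connected_subnetwork(network, sample(vnames, set_size))$size
  }, 0L)
  permutation_enrichment(observed_size, null, seed, alternative = "greater")
}
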