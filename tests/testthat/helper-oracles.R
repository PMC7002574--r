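# Independent oracles used to cross-check the package's statistics. These
# deliberately avoid the code paths (and where possible the library
# routines) they are used to verify.

# chi-square survival function for even df = 2k, via the closed-form
# finite series exp(-x/2) * sum_{j<k} (x/2)^j / j!  — no pchisq call.
chisq_surv_even <- function(x, k) {
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

oracle_fisher <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  chisq_surv_even(-2 * sum(log(p)), length(p))
}

# exhaustive hypergeometric upper tail P(X >= ov) for overlap of a size
# n_draws query with a size n_set reference in n_universe genes
oracle_hyper_tail <- function(ov, n_set, n_universe, n_draws) {
  i <- ov:min(n_set, n_draws)
  sum(choose(n_set, i) * choose(n_universe - n_set, n_draws - i)) /
    choose(n_universe, n_draws)
}

# exact two-sided rank-sum p by enumeration of all C(n, nA) assignments
oracle_ranksum <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  nA <- length(a)
  r <- rank(pool)
  wobs <- sum(r[seq_len(nA)])
  w <- apply(utils::combn(n, nA), 2, function(j) sum(r[j]))
  min(1, 2 * min(mean(w >= wobs), mean(w <= wobs)))
}

# independent BH step-up implementation (cummin over decreasing p)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(p[o] * n / (n:1)))[order(o)]
}

# largest connected component among `nodes` of an undirected edge list,
# by breadth-first search on an adjacency list
oracle_lcc_size <- function(edges, nodes) {
  edges <- edges[edges[, 1] %in% nodes & edges[, 2] %in% nodes, ,
                 drop = FALSE]
  adj <- lapply(stats::setNames(nm = nodes), function(v) {
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
  })
  seen <- character(0)
  best <- 0L
  for (v in nodes) {
    if (v %in% seen) next
    queue <- v
    comp <- character(0)
    while (length(queue)) {
      u <- queue[1L]
      queue <- queue[-1L]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    seen <- c(seen, comp)
    best <- max(best, length(comp))
  }
  best
}

# all simple labeled graphs on `verts` matching a degree sequence:
# enumerate subsets of the possible edges, return list of edge matrices
oracle_degree_matched_graphs <- function(verts, deg) {
  pairs <- t(utils::combn(verts, 2L))
  m <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(m - 1))))
    d <- stats::setNames(numeric(length(verts)), verts)
    for (i in which(sel)) {
      d[pairs[i, 1]] <- d[pairs[i, 1]] + 1
      d[pairs[i, 2]] <- d[pairs[i, 2]] + 1
    }
    if (all(d[verts] == deg)) out[[length(out) + 1L]] <-
        pairs[sel, , drop = FALSE]
  }
  out
}

# wrap a named numeric p-value vector as a score vector
make_scores <- function(p, mode = "GS-CN") {
  structure(p, mode = mode, class = "gene_score_vector")
}

# small element table from per-class named vectors (NA = missing)
make_table <- function(coding = NULL, promoter = NULL, utr5 = NULL,
                       utr3 = NULL, enhancers = list()) {
  rows <- list()
  add <- function(v, cls) {
    v <- v[!is.na(v)]
    if (length(v)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        gene = names(v), element_class = cls,
        element_id = paste0(cls, "_", names(v)), p_value = as.numeric(v),
        stringsAsFactors = FALSE)
    }
  }
  add(coding, "coding"); add(promoter, "promoter")
  add(utr5, "utr5"); add(utr3, "utr3")
  for (g in names(enhancers)) {
    e <- enhancers[[g]]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, element_class = "enhancer",
      element_id = names(e) %||% paste0("e_", g, "_", seq_along(e)),
      p_value = as.numeric(e), stringsAsFactors = FALSE)
  }
  element_pvalue_table(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# compact scenario configuration used across tests
small_config <- function(seed, ...) {
  args <- list(n_genes = 400L, n_drivers = 20L, n_modules = 2L,
               n_pathways = 30L, pathway_size_range = c(5L, 15L),
               n_cohorts = 1L, cohort_size = 10L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario_config, args)
}
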