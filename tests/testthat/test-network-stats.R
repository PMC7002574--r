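test_that("a gene with p = 1 never improves its neighborhood", {
  # adding -2 log(1) = 0 raises the degrees of freedom without raising the
  # statistic, so p_with > p_without is analytically forced
  set.seed(31)
  for (i in 1:10) {
    genes <- sprintf("G%02d", 1:15)
    g <- igraph::sample_gnp(15, 0.3)
    igraph::V(g)$name <- genes
    p <- stats::setNames(runif(15, 0.01, 0.9), genes)
    gene <- genes[which(igraph::degree(g, genes) > 0)[1]]
    p[gene] <- 1
    res <- neighborhood_improvement(gene, make_scores(p), g)
    expect_false(res$improves)
  }
})

test_that("star-center improvement matches the chi-square oracle", {
  net <- interaction_network(cbind("C", c("N1", "N2")))
  p <- make_scores(c(C = 0.01, N1 = 0.5, N2 = 0.5))
  res <- neighborhood_improvement("C", p, net)
  expect_equal(res$p_with, oracle_fisher(c(0.01, 0.5, 0.5)),
               tolerance = 1e-12)
  expect_equal(res$p_without, oracle_fisher(c(0.5, 0.5)), tolerance = 1e-12)
  expect_true(res$improves)
})

test_that("isolated genes improve by the degree-0 convention", {
  net <- interaction_network(cbind("A", "B"), nodes = "Z")
  res <- neighborhood_improvement("Z", make_scores(c(Z = 0.5)), net)
  expect_equal(res$p_without, 1)
  expect_true(res$improves)
  expect_error(neighborhood_improvement("Q", make_scores(c(Q = 0.5)), net),
               "not a node")
})

test_that("degree-preserving sampling conserves the degree multiset", {
  # K3 is rigid: the only degree-matched graph is K3 itself
  k3 <- interaction_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
  s <- degree_preserving_sample(k3, seed = 1)
  expect_setequal(apply(igraph::as_edgelist(s), 1,
                        function(e) paste(sort(e), collapse = "-")),
                  c("a-b", "b-c", "a-c"))
  # path a-b-c keeps its degree sequence
  path <- interaction_network(cbind(c("a", "b"), c("b", "c")))
  sp <- degree_preserving_sample(path, seed = 2)
  expect_identical(sort(igraph::degree(sp)[c("a", "b", "c")]),
                   sort(igraph::degree(path)[c("a", "b", "c")]))
  # 100-node graph: per-node degrees identical before and after
  set.seed(32)
  g <- igraph::sample_gnm(100, 250)
  igraph::V(g)$name <- sprintf("G%03d", 1:100)
  sg <- degree_preserving_sample(g, seed = 3)
  expect_identical(igraph::degree(sg)[igraph::V(g)$name],
                   igraph::degree(g)[igraph::V(g)$name])
  expect_true(igraph::is_simple(sg))
  expect_error(degree_preserving_sample(interaction_network(cbind("a",
                                                                  "b"))),
               "at least 2")
})

test_that("interaction enrichment on rigid and empty sets is exact", {
  k3 <- interaction_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
  res <- interaction_enrichment(k3, c("a", "b", "c"),
                                n_permutations = 50, seed = 4)
  expect_equal(res$observed, 3)
  expect_equal(res$expected, 3)
  expect_equal(res$p, 1)  # every permuted graph reaches the observed count
  # a set with no internal edges: observed 0, one-sided p = 1
  net <- interaction_network(cbind(c("a", "c"), c("b", "d")))
  res0 <- interaction_enrichment(net, c("a", "c"), n_permutations = 50,
                                 seed = 5)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p, 1)
})

test_that("interaction enrichment matches exhaustive degree-matched enumeration", {
  # 5-node toy: degrees a=3 b=2 c=2 d=2 e=1
  verts <- c("a", "b", "c", "d", "e")
  edges <- cbind(c("a", "a", "a", "b", "d"), c("b", "c", "d", "c", "e"))
  net <- interaction_network(edges)
  deg <- igraph::degree(net)[verts]
  matched <- oracle_degree_matched_graphs(verts, deg)
  expect_gt(length(matched), 1)
  count_in <- function(em, set) {
    sum(em[, 1] %in% set & em[, 2] %in% set)
  }
  exp_within <- mean(vapply(matched, count_in, 0, set = c("a", "b", "c")))
  obs <- 3  # a-b, a-c, b-c in the observed graph
  p_exact <- mean(vapply(matched, count_in, 0,
                         set = c("a", "b", "c")) >= obs)
  res <- interaction_enrichment(net, c("a", "b", "c"),
                                n_permutations = 2000, seed = 6)
  expect_equal(res$observed, obs)
  # Monte-Carlo error of the null mean over 2000 swaps chains
  expect_lt(abs(res$expected - exp_within), 0.15)
  expect_lt(abs(res$p - p_exact), 0.1)
  # between-set counting: edges spanning the two sets count once each
  res_b <- interaction_enrichment(net, c("a", "b"), c("c", "d", "e"),
                                  n_permutations = 10, seed = 7)
  expect_equal(res_b$observed, 3)  # a-c, a-d, b-c
  # overlapping sets: an edge inside the intersection counts once
  res_o <- interaction_enrichment(net, c("a", "b", "c"), c("a", "b", "e"),
                                  n_permutations = 10, seed = 8)
  # edges with one endpoint in each set: a-b (once), a-c, b-c = 3
  expect_equal(res_o$observed, 3)
})

test_that("improvement-count null matches the closed form for flat scores", {
  # identical scores 0.5: nodes with degree >= 1 never improve (each extra
  # 0.5 adds 1.386 to the statistic but 2 to the expected chi-square),
  # isolated nodes always do; the null count is hypergeometric in the
  # number of isolated nodes
  genes <- sprintf("G%02d", 1:30)
  edges <- cbind(genes[1:20], genes[c(2:20, 1)])  # 20-cycle, 10 isolated
  net <- interaction_network(edges, nodes = genes)
  scores <- make_scores(stats::setNames(rep(0.5, 30), genes))
  # whole-node-set sample: the count is exactly the number of isolated nodes
  res_all <- improvement_count_null(net, scores, set_size = 30,
                                    n_trials = 20, seed = 9,
                                    observed_count = 10)
  expect_equal(res_all$expected, 10)
  expect_equal(res_all$p, 1)
  # random sets of 6: expected = 6 * 10/30 = 2
  res6 <- improvement_count_null(net, scores, set_size = 6,
                                 n_trials = 4000, seed = 10)
  expect_lt(abs(res6$expected - 2), 3 * sqrt(2 * (2/3) / 4000) * 2)
  expect_error(improvement_count_null(net, scores, set_size = 6,
                                      n_trials = 0), "positive")
})

test_that("unreachable observed counts hit the pseudocount bound", {
  genes <- sprintf("G%02d", 1:10)
  edges <- t(utils::combn(genes[1:9], 2))  # 9-clique + 1 isolated node
  net <- interaction_network(edges, nodes = genes)
  scores <- make_scores(stats::setNames(rep(0.5, 10), genes))
  # only the isolated node improves, so a null count of 2 is unattainable
  res <- improvement_count_null(net, scores, set_size = 2, n_trials = 50,
                                seed = 11, observed_count = 2)
  expect_equal(res$p, 1 / 51)
})

test_that("empirical p-values are super-uniform under their own null", {
  genes <- sprintf("G%02d", 1:30)
  set.seed(33)
  g <- igraph::sample_gnm(30, 60)
  igraph::V(g)$name <- genes
  scores <- make_scores(stats::setNames(runif(30), genes))
  status <- pidnet:::improvement_status(scores, g)
  set.seed(34)
  draws <- replicate(200, sum(status[sample(genes, 8)]))
  ps <- vapply(draws, function(obs) {
    improvement_count_null(g, scores, 8, n_trials = 99, seed = 35,
                           observed_count = obs)$p
  }, 0)
  for (t in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 200) + 0.02)
  }
})

test_that("largest connected subnetwork agrees with a BFS oracle", {
  expect_equal(largest_connected_subnetwork(
    interaction_network(cbind("a", "b")), c("x", "y"))$size, 0L)
  res2 <- largest_connected_subnetwork(interaction_network(cbind("a", "b")),
                                       c("a", "b"))
  expect_equal(res2$size, 2L)
  expect_setequal(res2$members, c("a", "b"))
  set.seed(36)
  g <- igraph::sample_gnm(60, 80)
  igraph::V(g)$name <- sprintf("G%02d", 1:60)
  el <- igraph::as_edgelist(g)
  for (i in 1:5) {
    pick <- sample(igraph::V(g)$name, 20)
    expect_equal(largest_connected_subnetwork(g, pick)$size,
                 oracle_lcc_size(el, pick))
  }
  # companion null gives a valid enrichment record
  nul <- subnetwork_size_null(g, 20, n_trials = 50, seed = 12,
                              observed_size = 20)
  expect_gte(nul$p, 1 / 51)
  expect_lte(nul$p, 1)
})
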