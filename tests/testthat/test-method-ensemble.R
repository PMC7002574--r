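# shared fixture: a pathway database whose one small pathway holds all of
# the strong-signal genes in a 100-gene universe
seeded_pathway_fixture <- function() {
  genes <- sprintf("G%03d", 1:100)
  sets <- list(hit = genes[1:10],
               bland1 = genes[11:30], bland2 = genes[31:50],
               bland3 = genes[51:70])
  db <- pathway_db(sets, universe = genes)
  scores <- make_scores(
    stats::setNames(c(rep(1e-6, 5), seq(0.5, 1, length.out = 95)), genes),
    mode = "GS-C")
  list(genes = genes, db = db, scores = scores)
}

test_that("hypergeometric method reports seed genes of enriched pathways", {
  fx <- seeded_pathway_fixture()
  res <- run_method(hypergeometric_method(fx$db), fx$scores)
  # all 5 seeds sit in the 10-gene pathway: enrichment is overwhelming
  expect_setequal(res$genes, fx$genes[1:5])
  expect_identical(res$mode, "GS-C")
  # the pathway's hypergeometric p agrees with exhaustive tail summation
  expect_lt(oracle_hyper_tail(5, 10, 100, 5), 1e-4)
})

test_that("hypergeometric method returns empty results without signal", {
  fx <- seeded_pathway_fixture()
  flat <- make_scores(stats::setNames(seq(0.2, 1, length.out = 100),
                                      fx$genes), "GS-C")
  expect_length(run_method(hypergeometric_method(fx$db), flat)$genes, 0)
})

test_that("seeds spread one-per-pathway yield no enriched pathway", {
  # 50 pathways of 100 genes each; each pathway holds exactly one seed
  genes <- sprintf("G%04d", 1:5000)
  sets <- split(genes, rep(1:50, each = 100))
  names(sets) <- paste0("pw", 1:50)
  p <- stats::setNames(rep(0.99, 5000), genes)
  seeds <- vapply(sets, `[`, "", 1L)          # first gene of each pathway
  p[seeds] <- 1e-9
  res <- run_method(hypergeometric_method(pathway_db(sets,
                                                     universe = genes)),
                    make_scores(p, "GS-C"))
  # one seed among 100 pathway genes is never enrichment: hypergeometric
  # P(X >= 1) ~ 0.64 for every pathway
  expect_gte(oracle_hyper_tail(1, 100, 5000, 50), 0.5)
  expect_length(res$genes, 0)
})

test_that("empty pathway database is a configuration error", {
  expect_error(hypergeometric_method(pathway_db(list(tiny = c("A", "B")))),
               "empty")
})

test_that("neighborhood method reports a high-signal star center", {
  # star of 5 strong neighbors in a 1000-gene uniform background
  genes <- sprintf("G%04d", 1:1000)
  edges <- cbind("G0001", genes[2:6])
  net <- interaction_network(edges, nodes = genes)
  set.seed(7)
  p <- stats::setNames(runif(1000, 0.05, 1), genes)
  p[genes[1:6]] <- 1e-6
  res <- run_method(neighborhood_method(net), make_scores(p, "GS-CN"))
  expect_true("G0001" %in% res$genes)
  # star center's neighborhood p from the oracle is astronomically small
  expect_lt(oracle_fisher(rep(1e-6, 6)), 1e-27)
})

test_that("neighborhood method on flat maximal scores reports nothing", {
  net <- interaction_network(cbind(c("A", "B"), c("B", "C")))
  flat <- make_scores(c(A = 1, B = 1, C = 1), "GS-CN")
  expect_length(run_method(neighborhood_method(net), flat)$genes, 0)
})

test_that("degree-0 genes use their own score as neighborhood score", {
  # documented convention: isolated high-signal genes are reportable
  genes <- sprintf("G%03d", 1:200)
  net <- interaction_network(cbind(genes[1], genes[2]), nodes = genes)
  set.seed(8)
  p <- stats::setNames(runif(200, 0.1, 1), genes)
  p["G100"] <- 1e-9  # isolated
  res <- run_method(neighborhood_method(net), make_scores(p, "GS-CN"))
  expect_true("G100" %in% res$genes)
})

test_that("reported sets are deterministic and monotone in the threshold", {
  sc <- generate_scenario(small_config(3))
  s <- compute_gene_scores(sc$table, "GS-CN")
  prev_h <- prev_n <- NULL
  for (thr in c(0.02, 0.1, 0.3)) {
    h <- run_method(hypergeometric_method(sc$pathways,
                                          report_threshold = thr,
                                          seed_threshold = thr), s)$genes
    n <- run_method(neighborhood_method(sc$network,
                                        report_threshold = thr), s)$genes
    if (!is.null(prev_h)) {
      expect_true(all(prev_h %in% h))
      expect_true(all(prev_n %in% n))
    }
    prev_h <- h; prev_n <- n
  }
  again <- run_method(neighborhood_method(sc$network,
                                          report_threshold = 0.3), s)$genes
  expect_identical(sort(again), sort(prev_n))
})

test_that("calibration flags methods that report heavily on random data", {
  genes <- sprintf("G%03d", 1:200)
  set.seed(9)
  scores <- make_scores(stats::setNames(runif(200), genes), "GS-C")
  # a method that always reports its top 50 genes is miscalibrated
  top50 <- driver_method("top50", function(s) {
    names(s)[order(as.numeric(s))][1:50]
  })
  cal <- calibrate_method(top50, scores, n_randomizations = 10, seed = 1)
  expect_equal(cal$calibration$mean_size, 50)
  expect_true(cal$calibration$miscalibrated)
  # an empty-report method has mean 0 and is not flagged
  silent <- driver_method("silent", function(s) character(0))
  cal <- calibrate_method(silent, scores, n_randomizations = 10, seed = 1)
  expect_equal(cal$calibration$mean_size, 0)
  expect_false(cal$calibration$miscalibrated)
  expect_error(calibrate_method(silent, scores, n_randomizations = 5),
               "n_randomizations")
})

test_that("hypergeometric method stays quiet on randomized uniform scores", {
  fx <- seeded_pathway_fixture()
  cal <- calibrate_method(hypergeometric_method(fx$db), fx$scores,
                          n_randomizations = 20, seed = 2)
  expect_lte(cal$calibration$mean_size, 2)
})

test_that("reference methods report little to nothing on null scenarios", {
  # no planted signal: the hypergeometric method is empty in nearly every
  # replicate; the neighborhood method's BH step rejects with probability
  # ~ alpha under the global null, so its reports are rare and tiny
  empty_h <- 0L
  sizes_n <- integer(20)
  for (r in 1:20) {
    sc <- generate_scenario(small_config(r, n_drivers = 0L, n_modules = 0L,
                                         module_fraction = 0))
    s <- compute_gene_scores(sc$table, "GS-C")
    empty_h <- empty_h +
      (length(run_method(hypergeometric_method(sc$pathways), s)$genes) == 0L)
    sizes_n[r] <- length(run_method(neighborhood_method(sc$network),
                                    s)$genes)
  }
  expect_gte(empty_h / 20, 0.95)
  expect_lte(mean(sizes_n), 2)
  expect_equal(median(sizes_n), 0)
})

test_that("external replay adapter reports its stored list per mode", {
  adapter <- external_method("replay", list("GS-C" = c("A", "B"),
                                            "GS-N" = "C"))
  s <- make_scores(c(A = 0.1, B = 0.2, C = 0.3), "GS-C")
  expect_setequal(run_method(adapter, s)$genes, c("A", "B"))
  attr(s, "mode") <- "GS-N"
  expect_setequal(run_method(adapter, s)$genes, "C")
  # genes without a defined score are never reported
  s2 <- make_scores(c(A = 0.1), "GS-C")
  expect_setequal(run_method(adapter, s2)$genes, "A")
})
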