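# a simple deterministic method for NCVA plumbing tests: report genes with
# GS-CN score below a cutoff
cutoff_method <- function(cut = 1e-3) {
  driver_method("cutoff", function(s) names(s)[as.numeric(s) < cut])
}

test_that("NCVA is a no-op when non-coding p-values are constant", {
  genes <- sprintf("G%02d", 1:20)
  set.seed(11)
  tab <- make_table(coding = stats::setNames(runif(20)^4, genes),
                    promoter = stats::setNames(rep(0.3, 20), genes),
                    utr3 = stats::setNames(rep(0.5, 20), genes))
  res <- ncva_test(tab, cutoff_method(0.01), n_permutations = 19, seed = 1)
  expect_gt(length(res$p), 0)          # some genes are reported
  expect_true(all(res$p == 1))         # every permutation reproduces R0
  expect_length(res$genes, 0)
})

test_that("NCVA of an empty-report method is empty", {
  tab <- make_table(coding = c(A = 0.5, B = 0.2),
                    promoter = c(A = 0.1, B = 0.9))
  res <- ncva_test(tab, driver_method("silent", function(s) character(0)),
                   n_permutations = 19, seed = 1)
  expect_length(res$p, 0)
  expect_length(res$genes, 0)
})

test_that("too few permutations for the threshold are rejected", {
  tab <- make_table(coding = c(A = 0.5), promoter = c(A = 0.1))
  expect_error(ncva_test(tab, cutoff_method(), n_permutations = 10),
               ">= 19")
})

test_that("NCVA p-values match a naive full-materialization oracle", {
  # 10-gene toy: one gene with promoter p = 1e-8, the rest uniform;
  # neighborhood method on a small fixed graph; 99 permutations
  genes <- sprintf("G%02d", 1:10)
  set.seed(12)
  coding <- stats::setNames(runif(10), genes)
  promoter <- stats::setNames(runif(10), genes)
  promoter["G03"] <- 1e-8
  utr3 <- stats::setNames(runif(10), genes)
  utr3[c(2, 5)] <- NA  # exercise missingness in the permutation unit
  enh <- list(G01 = c(ea = 0.4), G07 = c(eb = 0.2, ec = 0.6))
  tab <- make_table(coding = coding, promoter = promoter, utr3 = utr3,
                    enhancers = enh)
  edges <- cbind(c("G01", "G02", "G03", "G03", "G05", "G07", "G08"),
                 c("G02", "G03", "G04", "G05", "G06", "G08", "G09"))
  net <- interaction_network(edges, nodes = genes)
  method <- neighborhood_method(net, report_threshold = 0.2)
  res <- ncva_test(tab, method, n_permutations = 99, seed = 31)
  expect_true("G03" %in% names(res$p))
  expect_true("G03" %in% res$genes)

  # --- naive oracle: re-derive every permuted table and re-run a
  # hand-rolled neighborhood method (own Fisher series, own BH) ----------
  nb_of <- lapply(stats::setNames(nm = genes), function(g)
    setdiff(unique(c(edges[edges[, 1] == g, 2], edges[edges[, 2] == g, 1])),
            g))
  naive_gscn <- function(tb) {
    out <- sapply(seq_along(genes), function(i) {
      pm <- suppressWarnings(min(tb$promoter[i], tb$utr5[i], na.rm = TRUE))
      if (!is.finite(pm)) pm <- NA_real_
      oracle_fisher(c(tb$coding[i], pm, tb$utr3[i], tb$enhancer[i]))
    })
    stats::setNames(out, genes)
  }
  naive_report <- function(p) {
    p_wi <- p_wo <- stats::setNames(numeric(length(genes)), genes)
    for (g in genes) {
      pn <- p[nb_of[[g]]]
      p_wo[g] <- if (length(pn)) oracle_fisher(pn) else 1
      p_wi[g] <- oracle_fisher(c(pn, p[g]))
    }
    q <- oracle_bh(p_wi)
    genes[q < 0.2 & p_wi < p_wo]
  }
  r0 <- naive_report(naive_gscn(tab))
  expect_setequal(r0, res$observed$genes)
  counts <- stats::setNames(integer(length(r0)), r0)
  set.seed(31)
  for (b in 1:99) {
    ptab <- tab
    for (cls in c("promoter", "utr5", "utr3")) {
      has <- which(!is.na(tab[[cls]]))
      if (length(has) > 1)
        ptab[[cls]][has] <- tab[[cls]][has[sample(length(has))]]
    }
    has <- which(!is.na(tab$enhancer))
    if (length(has) > 1) {
      perm <- has[sample(length(has))]
      ptab$enhancer[has] <- tab$enhancer[perm]
    }
    rb <- naive_report(naive_gscn(ptab))
    counts <- counts + (r0 %in% rb)
  }
  p_naive <- (1 + counts) / 100
  expect_equal(p_naive[names(res$p)], res$p, tolerance = 1e-12)
})

test_that("NCVA is bit-reproducible for a fixed seed", {
  sc <- generate_scenario(small_config(5))
  m <- hypergeometric_method(sc$pathways)
  a <- ncva_test(sc$table, m, n_permutations = 19, seed = 9)
  b <- ncva_test(sc$table, m, n_permutations = 19, seed = 9)
  expect_identical(a$p, b$p)
  expect_identical(a$genes, b$genes)
})

test_that("merging GS-N with NCVA results takes the union per method", {
  gsn <- method_result("m1", "GS-N", sprintf("A%02d", 1:62))
  ncva_ok <- structure(list(genes = sprintf("B%02d", 1:31),
                            observed = method_result("m1", "GS-CN",
                                                     character(0))),
                       class = "ncva_result")
  merged <- merge_noncoding_results(gsn, ncva_ok)
  expect_length(merged, 93)  # disjoint 62 + 31
  # empty NCVA leaves the GS-N set unchanged
  ncva_empty <- structure(list(genes = character(0),
                               observed = method_result("m1", "GS-CN",
                                                        character(0))),
                          class = "ncva_result")
  expect_setequal(merge_noncoding_results(gsn, ncva_empty), gsn$genes)
  # identical sets merge to themselves
  ncva_same <- structure(list(genes = gsn$genes,
                              observed = method_result("m1", "GS-CN",
                                                       character(0))),
                         class = "ncva_result")
  expect_setequal(merge_noncoding_results(gsn, ncva_same), gsn$genes)
  # results from different methods must not be merged
  ncva_other <- structure(list(genes = "X",
                               observed = method_result("m2", "GS-CN",
                                                        character(0))),
                          class = "ncva_result")
  expect_error(merge_noncoding_results(gsn, ncva_other), "mismatch")
})

test_that("NCVA TSV writer emits the per-gene table and manifest", {
  tab <- make_table(coding = c(A = 0.5, B = 1e-8), promoter = c(A = 1e-6,
                                                                B = 0.4))
  res <- ncva_test(tab, cutoff_method(0.05), n_permutations = 19, seed = 2)
  out <- file.path(tempdir(), "ncva.tsv")
  write_ncva(res, out)
  df <- read.delim(out)
  expect_identical(sort(df$gene), sort(names(res$p)))
  manifest <- jsonlite::read_json(paste0(out, ".manifest.json"))
  expect_equal(manifest$n_permutations, 19)
  expect_equal(manifest$seed, 2)
})
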