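#' Configuration for a synthetic driver-discovery scenario
#'
#' Describes a complete synthetic study: per-element driver p-values with a
#' long-tailed signal (mostly uniform nulls, a minority of planted drivers
#' with small Beta(a, 1) p-values), a scale-free interaction network built
#' from a configuration model over a truncated power-law degree sequence, a
#' pathway database containing the planted modules, cohort-structured
#' log-scale expression with additive cis effects in mutated samples, and a
#' mutation occurrence table. A fraction of the planted drivers is
#' co-located in network/pathway modules, emulating drivers that cluster in
#' a small number of pathways and interacting subnetworks.
#'
#' @param n_genes Number of genes.
#' @param n_drivers Number of planted driver genes.
#' @param driver_profile Proportions of planted drivers with coding-only,
#'   non-coding-only, and mixed element signal (named numeric summing
#'   to 1).
#' @param signal_a Beta(a, 1) shape for planted element p-values, in
#'   (0, 1]; `a = 1` reduces planted elements to the uniform null.
#' @param module_fraction Fraction of planted drivers co-located in
#'   modules that are simultaneously pathways and dense network
#'   communities.
#' @param n_modules Number of planted modules.
#' @param module_extra_genes Null genes added to each module.
#' @param module_edge_prob Edge probability between module members (on top
#'   of a spanning path keeping each module connected).
#' @param n_pathways Background pathways in the database.
#' @param pathway_size_range Inclusive size range for background pathways
#'   (bounded to `[3, 1000]`).
#' @param degree_exponent,degree_max Truncated power-law degree
#'   distribution `P(d) ~ d^-exponent`, `d` in `[1, degree_max]`.
#' @param element_prob Named presence probabilities for `promoter`,
#'   `utr5`, `utr3` elements.
#' @param enhancer_rate Expected number of enhancers per gene (Poisson,
#'   capped at 3).
#' @param n_cohorts,cohort_size Expression cohorts and samples per cohort.
#' @param expr_mu_mean,expr_mu_sd,expr_sd Per-gene baseline log2-expression
#'   mean law N(`expr_mu_mean`, `expr_mu_sd`) and within-gene s.d.
#' @param cis_delta Additive cis effect for mutated samples, in units of
#'   `expr_sd` on the log2 scale.
#' @param n_mut_per_driver Mutated samples per planted driver.
#' @param background_mut_rate Fraction of null genes receiving a random
#'   (effect-free) mutation.
#' @param seed Master seed; all component seeds derive from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_genes = 10000L,
                            n_drivers = 100L,
                            driver_profile = c(coding = 0.5,
                                               noncoding = 0.5,
                                               mixed = 0),
                            signal_a = 0.05,
                            module_fraction = 0.6,
                            n_modules = 4L,
                            module_extra_genes = 5L,
                            module_edge_prob = 0.3,
                            n_pathways = 200L,
                            pathway_size_range = c(10L, 50L),
                            degree_exponent = 2.5,
                            degree_max = 50L,
                            element_prob = c(promoter = 0.9, utr5 = 0.5,
                                             utr3 = 0.7),
                            enhancer_rate = 0.3,
                            n_cohorts = 3L,
                            cohort_size = 50L,
                            expr_mu_mean = 5, expr_mu_sd = 2, expr_sd = 1,
                            cis_delta = 2,
                            n_mut_per_driver = 8L,
                            background_mut_rate = 0.01,
                            seed = 42L) {
  cfg <- as.list(environment())
  stopifnot(n_genes > 0, n_drivers >= 0, n_drivers <= n_genes,
            signal_a > 0, signal_a <= 1,
            module_fraction >= 0, module_fraction <= 1,
            abs(sum(driver_profile) - 1) < 1e-8)
  structure(cfg, class = "scenario_config")
}

sample_powerlaw_degrees <- function(n, exponent, dmax) {
  dmax <- min(dmax, n - 1L)  # a simple graph cannot exceed degree n-1
  d <- seq_len(dmax)
  w <- d^(-exponent)
  deg <- sample(d, n, replace = TRUE, prob = w / sum(w))
  if (sum(deg) %% 2L == 1L) deg[which.max(deg)] <- deg[which.max(deg)] + 1L
  deg
}

#' Generate a synthetic scenario
#'
#' Produces a fully populated scenario from a [scenario_config()];
#' bit-identical for identical config (the master seed is part of the
#' config). An infeasible degree sequence is re-drawn up to 10 times.
#'
#' @param config A `scenario_config`.
#' @return A `synthetic_scenario`: list with `table`
#'   (an [element_pvalue_table()]), `enhancer_map`, `network` (igraph),
#'   `pathways` (a [pathway_db()]), `expression` (gene x sample matrix),
#'   `cohort_map`, `mutations`, `truth` (data frame `gene`,
#'   `planted_class`), `modules` (list of module gene sets), and `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  genes <- sprintf("g%05d", seq_len(config$n_genes))

  # --- truth labels -------------------------------------------------------
  set.seed(derive_seed(config$seed, "truth"))
  drivers <- sample(genes, config$n_drivers)
  prof <- config$driver_profile
  n_each <- round(prof * config$n_drivers)
  n_each[1L] <- config$n_drivers - sum(n_each[-1L])
  planted_class <- rep(names(prof), times = n_each)
  truth <- data.frame(gene = drivers, planted_class = planted_class,
                      stringsAsFactors = FALSE)

  # --- modules ------------------------------------------------------------
  set.seed(derive_seed(config$seed, "modules"))
  n_coloc <- round(config$module_fraction * config$n_drivers)
  modules <- list()
  if (n_coloc > 0 && config$n_modules > 0) {
    coloc <- sample(drivers, n_coloc)
    grp <- rep(seq_len(config$n_modules), length.out = n_coloc)
    nulls <- setdiff(genes, drivers)
    for (m in seq_len(config$n_modules)) {
      extra <- sample(nulls, config$module_extra_genes)
      nulls <- setdiff(nulls, extra)
      modules[[paste0("module_", m)]] <- c(coloc[grp == m], extra)
    }
  }

  # --- network ------------------------------------------------------------
  set.seed(derive_seed(config$seed, "network"))
  g <- NULL
  for (try in 1:10) {
    deg <- sample_powerlaw_degrees(config$n_genes, config$degree_exponent,
                                   config$degree_max)
    # deterministic realization, then randomized by double-edge swaps:
    # robust for any graphical sequence and approximately uniform
    g <- tryCatch(igraph::realize_degseq(deg, method = "smallest"),
                  error = function(e) NULL)
    if (!is.null(g)) break
  }
  if (is.null(g)) stop("could not realize a simple graph from the degree ",
                       "sequence after 10 retries", call. = FALSE)
  g <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = 10 * igraph::ecount(g)))
  igraph::V(g)$name <- genes
  module_edges <- NULL
  for (members in modules) {
    k <- length(members)
    if (k < 2L) next
    path <- cbind(members[-k], members[-1L])  # spanning path: connected
    pairs <- t(utils::combn(members, 2L))
    pairs <- pairs[stats::runif(nrow(pairs)) < config$module_edge_prob, ,
                   drop = FALSE]
    module_edges <- rbind(module_edges, path, pairs)
  }
  if (!is.null(module_edges)) {
    g <- igraph::add_edges(g, as.vector(t(module_edges)))
  }
  network <- igraph::simplify(g)

  # --- pathways -----------------------------------------------------------
  set.seed(derive_seed(config$seed, "pathways"))
  lo <- max(3L, config$pathway_size_range[1L])
  hi <- min(1000L, config$pathway_size_range[2L])
  sets <- lapply(seq_len(config$n_pathways), function(i) {
    sample(genes, sample(lo:hi, 1L))
  })
  names(sets) <- sprintf("pathway_%03d", seq_len(config$n_pathways))
  pathways <- pathway_db(c(sets, modules), universe = genes)

  # --- element p-values ---------------------------------------------------
  set.seed(derive_seed(config$seed, "elements"))
  n <- config$n_genes
  present <- function(prob) stats::runif(n) < prob
  tab <- data.frame(gene = genes,
                    coding = stats::runif(n),
                    promoter = ifelse(present(config$element_prob[["promoter"]]),
                                      stats::runif(n), NA_real_),
                    utr5 = ifelse(present(config$element_prob[["utr5"]]),
                                  stats::runif(n), NA_real_),
                    utr3 = ifelse(present(config$element_prob[["utr3"]]),
                                  stats::runif(n), NA_real_),
                    enhancer = NA_real_, stringsAsFactors = FALSE)
  n_enh <- pmin(stats::rpois(n, config$enhancer_rate), 3L)
  enh_lists <- stats::setNames(vector("list", n), genes)
  enh_rows <- list()
  eid <- 0L
  for (i in which(n_enh > 0L)) {
    ids <- sprintf("e%06d", eid + seq_len(n_enh[i]))
    eid <- eid + n_enh[i]
    pv <- stats::runif(n_enh[i])
    enh_lists[[i]] <- stats::setNames(pv, ids)
    enh_rows[[length(enh_rows) + 1L]] <-
      data.frame(enhancer_id = ids, target_genes = genes[i],
                 stringsAsFactors = FALSE)
  }
  enhancer_map <- if (length(enh_rows)) do.call(rbind, enh_rows) else
    data.frame(enhancer_id = character(0), target_genes = character(0))
  # planted signal: coding and/or promoter p ~ Beta(a, 1)
  idx <- match(truth$gene, genes)
  sig <- function(k) stats::rbeta(k, config$signal_a, 1)
  is_coding <- truth$planted_class %in% c("coding", "mixed")
  is_nc <- truth$planted_class %in% c("noncoding", "mixed")
  tab$coding[idx[is_coding]] <- sig(sum(is_coding))
  tab$promoter[idx[is_nc]] <- sig(sum(is_nc))  # forces promoter presence
  tab$enhancer <- vapply(enh_lists, function(x)
    if (length(x)) min(x) else NA_real_, 0)
  attr(tab, "enhancers") <- enh_lists
  class(tab) <- c("element_pvalue_table", "data.frame")

  # --- expression, cohorts, mutations -------------------------------------
  set.seed(derive_seed(config$seed, "expression"))
  n_samples <- config$n_cohorts * config$cohort_size
  samples <- sprintf("s%04d", seq_len(n_samples))
  cohorts <- rep(sprintf("cohort_%d", seq_len(config$n_cohorts)),
                 each = config$cohort_size)
  cohort_map <- data.frame(sample = samples, cohort = cohorts,
                           stringsAsFactors = FALSE)
  mu <- stats::rnorm(n, config$expr_mu_mean, config$expr_mu_sd)
  shift <- matrix(stats::rnorm(n * config$n_cohorts, 0, 1), nrow = n)
  logexpr <- matrix(stats::rnorm(n * n_samples, 0, config$expr_sd),
                    nrow = n, dimnames = list(genes, samples))
  logexpr <- logexpr + mu + shift[, match(cohorts, unique(cohorts))]

  set.seed(derive_seed(config$seed, "mutations"))
  mut_rows <- list()
  for (i in seq_len(nrow(truth))) {
    gene <- truth$gene[i]
    cls <- if (truth$planted_class[i] == "coding") "coding" else "promoter"
    ms <- sample(samples, min(config$n_mut_per_driver, n_samples))
    logexpr[gene, ms] <- logexpr[gene, ms] +
      config$cis_delta * config$expr_sd
    mut_rows[[length(mut_rows) + 1L]] <-
      data.frame(gene = gene, element_class = cls, sample = ms,
                 stringsAsFactors = FALSE)
  }
  bg <- sample(setdiff(genes, truth$gene),
               round(config$background_mut_rate * n))
  for (gene in bg) {
    mut_rows[[length(mut_rows) + 1L]] <- data.frame(
      gene = gene,
      element_class = sample(c("coding", "promoter", "utr3"), 1L),
      sample = sample(samples, sample(1:2, 1L)), stringsAsFactors = FALSE)
  }
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(gene = character(0), element_class = character(0),
               sample = character(0))

  structure(list(table = tab, enhancer_map = enhancer_map,
                 network = network, pathways = pathways,
                 expression = 2^logexpr, cohort_map = cohort_map,
                 mutations = mutations, truth = truth, modules = modules,
                 config = config),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scenario> %d genes, %d planted driver(s), %d pathways, %d network edges\n",
    nrow(x$table), nrow(x$truth), length(x$pathways$sets),
    igraph::ecount(x$network)))
  invisible(x)
}

#' Randomize a scenario into a signal-free null copy
#'
#' Replaces every present element p-value with a fresh Uniform(0, 1) draw
#' while preserving all structure — network, pathways, expression,
#' missingness pattern, enhancer attachment — and clears the truth labels.
#' This is the randomized-data input used to calibrate methods.
#'
#' @param scenario A `synthetic_scenario`.
#' @param seed Integer seed.
#' @return A `synthetic_scenario` with no planted signal.
#' @export
null_randomize <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(seed)
  tab <- scenario$table
  for (cls in c("coding", "promoter", "utr5", "utr3")) {
    has <- !is.na(tab[[cls]])
    tab[[cls]][has] <- stats::runif(sum(has))
  }
  enh <- attr(tab, "enhancers")
  for (i in seq_along(enh)) {
    if (length(enh[[i]])) {
      enh[[i]][] <- stats::runif(length(enh[[i]]))
    }
  }
  tab$enhancer <- vapply(enh, function(x) if (length(x)) min(x) else
    NA_real_, 0)
  attr(tab, "enhancers") <- enh
  out <- scenario
  out$table <- tab
  out$truth <- out$truth[0, , drop = FALSE]
  out
}

#' Serialize a scenario to the pipeline's on-disk formats
#'
#' Writes the element p-value TSV, enhancer map TSV, network edge-list TSV,
#' pathway GMT, expression TSV (genes x samples), cohort map TSV, mutation
#' TSV, and `truth.tsv` into a directory.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(elements = file.path(dir, "elements.tsv"),
             enhancer_map = file.path(dir, "enhancer_map.tsv"),
             network = file.path(dir, "network.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             expression = file.path(dir, "expression.tsv"),
             cohorts = file.path(dir, "cohorts.tsv"),
             mutations = file.path(dir, "mutations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_element_table(scenario$table, paths["elements"])
  utils::write.table(scenario$enhancer_map, paths["enhancer_map"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(scenario$network, paths["network"])
  write_gmt(scenario$pathways, paths["pathways"])
  expr <- data.frame(gene = rownames(scenario$expression),
                     scenario$expression, check.names = FALSE)
  utils::write.table(expr, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scenario$cohort_map, paths["cohorts"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scenario$mutations, paths["mutations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scenario$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
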