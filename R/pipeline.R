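#' Run the full consensus driver-prioritization pipeline
#'
#' Orchestrates the complete analysis on in-memory inputs: gene scores
#' (GS-C, GS-N, GS-CN) from the element table; every method of the
#' ensemble on each mode, with randomized-data calibration; the NCVA
#' permutation test per method; majority-vote consensus into PID-C
#' (coding), PID-N (non-coding merged with NCVA) and GS-CN sets; and,
#' when the inputs carry a network, the network validation statistics of
#' the consensus sets.
#'
#' @param inputs List with `table` (required [element_pvalue_table()]) and
#'   optional `network`, `pathways`, `truth` — e.g. a
#'   [generate_scenario()] result or [load_inputs()] output.
#' @param methods Named list of `driver_method`s; defaults to the two
#'   reference methods built from `inputs$pathways` and `inputs$network`.
#' @param vote_threshold Consensus vote threshold (default strict
#'   majority).
#' @param n_permutations NCVA permutations.
#' @param ncva_threshold NCVA p-value cutoff.
#' @param n_calibration Randomizations per method calibration (0 skips
#'   calibration).
#' @param include_enhancers Passed to [compute_gene_scores()].
#' @param network_stats Compute interaction enrichment and connected
#'   subnetwork statistics of the consensus sets (needs `inputs$network`).
#' @param n_network_permutations Permutations for the network statistics.
#' @param seed Master seed; per-stage seeds derive from it.
#' @return A `pipeline_result`: list with `scores` (per mode),
#'   `method_results` (per mode, per method), `ncva` (per method),
#'   `pid_c`, `pid_n`, `gs_cn_consensus`, `overlap`, `network_stats`
#'   (or `NULL`), `recovery` (precision/recall against `inputs$truth`, or
#'   `NULL`), and `manifest`.
#' @export
run_pipeline <- function(inputs, methods = NULL, vote_threshold = NULL,
                         n_permutations = 99L, ncva_threshold = 0.1,
                         n_calibration = 0L, include_enhancers = TRUE,
                         network_stats = FALSE,
                         n_network_permutations = 200L, seed = 1L) {
  t0 <- Sys.time()
  if (is.null(inputs$table)) stop("inputs$table is required", call. = FALSE)
  if (is.null(methods)) {
    methods <- list()
    if (!is.null(inputs$pathways)) {
      methods$hypergeometric <- hypergeometric_method(inputs$pathways)
    }
    if (!is.null(inputs$network)) {
      methods$neighborhood <- neighborhood_method(inputs$network)
    }
  }
  if (!length(methods)) stop("no methods to run", call. = FALSE)
  k <- length(methods)
  vote_threshold <- vote_threshold %||% (k %/% 2L + 1L)
  if (vote_threshold < 1L || vote_threshold > k) {
    stop(sprintf(
      "vote threshold %d infeasible for %d method(s): configuration error",
      vote_threshold, k), call. = FALSE)
  }

  timings <- c()
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    out
  }

  scores <- stage("scores", lapply(
    stats::setNames(c("GS-C", "GS-N", "GS-CN"),
                    c("GS-C", "GS-N", "GS-CN")),
    function(m) compute_gene_scores(inputs$table, m,
                                    include_enhancers = include_enhancers)))

  method_results <- stage("methods", lapply(scores, function(s) {
    lapply(methods, run_method, scores = s)
  }))

  if (n_calibration > 0L) {
    method_results <- stage("calibration", lapply(
      names(method_results), function(mode) {
        res <- method_results[[mode]]
        for (nm in names(res)) {
          res[[nm]] <- calibrate_method(
            methods[[nm]], scores[[mode]],
            n_randomizations = n_calibration,
            seed = derive_seed(seed, paste0("calib-", mode, "-", nm)),
            observed = res[[nm]])
        }
        res
      }))
    names(method_results) <- names(scores)
  }

  ncva <- stage("ncva", lapply(names(methods), function(nm) {
    ncva_test(inputs$table, methods[[nm]],
              n_permutations = n_permutations,
              threshold = ncva_threshold,
              seed = derive_seed(seed, paste0("ncva-", nm)),
              include_enhancers = include_enhancers)
  }))
  names(ncva) <- names(methods)

  pid_c <- stage("consensus", majority_vote(
    lapply(method_results[["GS-C"]], `[[`, "genes"),
    threshold = vote_threshold, mode_label = "PID-C"))
  pid_n <- build_pid_n(method_results[["GS-N"]], ncva,
                       threshold = vote_threshold)
  gs_cn <- majority_vote(lapply(method_results[["GS-CN"]], `[[`, "genes"),
                         threshold = vote_threshold, mode_label = "GS-CN")
  overlap <- consensus_overlap(pid_c, pid_n)

  nstats <- NULL
  if (network_stats && !is.null(inputs$network)) {
    nstats <- stage("network_stats", {
      net <- inputs$network
      consensus_all <- union(pid_c$genes, pid_n$genes)
      res <- list()
      if (length(pid_c$genes) >= 2L) {
        res$pid_c_interactions <- interaction_enrichment(
          net, pid_c$genes, n_permutations = n_network_permutations,
          seed = derive_seed(seed, "net-pidc"))
      }
      if (length(pid_n$genes) >= 2L) {
        res$pid_n_interactions <- interaction_enrichment(
          net, pid_n$genes, n_permutations = n_network_permutations,
          seed = derive_seed(seed, "net-pidn"))
      }
      if (length(pid_c$genes) >= 1L && length(pid_n$genes) >= 1L) {
        res$between_interactions <- interaction_enrichment(
          net, pid_c$genes, pid_n$genes,
          n_permutations = n_network_permutations,
          seed = derive_seed(seed, "net-between"))
      }
      if (length(consensus_all)) {
        lcc <- largest_connected_subnetwork(net, consensus_all)
        res$largest_subnetwork <- lcc
        res$largest_subnetwork_null <- subnetwork_size_null(
          net, length(consensus_all), n_trials = n_network_permutations,
          seed = derive_seed(seed, "net-lcc"),
          observed_size = lcc$size)
      }
      res
    })
  }

  recovery <- NULL
  if (!is.null(inputs$truth) && nrow(inputs$truth)) {
    found <- union(pid_c$genes, pid_n$genes)
    planted <- inputs$truth$gene
    recovery <- list(
      n_found = length(found),
      precision = if (length(found)) mean(found %in% planted) else
        NA_real_,
      recall = mean(planted %in% found))
  }

  manifest <- list(
    tool = "pidnet", version = as.character(utils::packageVersion("pidnet")),
    seed = seed, vote_threshold = vote_threshold,
    n_permutations = n_permutations, ncva_threshold = ncva_threshold,
    n_calibration = n_calibration, include_enhancers = include_enhancers,
    methods = names(methods),
    n_genes = nrow(inputs$table),
    timings_sec = as.list(timings),
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(list(scores = scores, method_results = method_results,
                 ncva = ncva, pid_c = pid_c, pid_n = pid_n,
                 gs_cn_consensus = gs_cn, overlap = overlap,
                 network_stats = nstats, recovery = recovery,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> PID-C: %d gene(s); PID-N: %d gene(s); overlap: %d\n",
    length(x$pid_c$genes), length(x$pid_n$genes),
    x$overlap$n_intersection))
  if (!is.null(x$recovery)) {
    cat(sprintf("  planted-driver recovery: precision %.3f, recall %.3f\n",
                x$recovery$precision, x$recovery$recall))
  }
  invisible(x)
}

#' Write pipeline results and manifest to a directory
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @param table The input element table (for score TSVs); optional.
#' @return Invisibly, the output directory.
#' @export
write_pipeline_results <- function(result, dir, table = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(table)) {
    for (mode in names(result$scores)) {
      write_scores(result$scores[[mode]], table,
                   file.path(dir, paste0("scores_", gsub("-", "", mode),
                                         ".tsv")))
    }
  }
  write_consensus(result$pid_c, file.path(dir, "pid_c.tsv"))
  write_consensus(result$pid_n, file.path(dir, "pid_n.tsv"))
  for (nm in names(result$ncva)) {
    write_ncva(result$ncva[[nm]], file.path(dir, paste0("ncva_", nm,
                                                        ".tsv")))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
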