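#' Prioritization method interface
#'
#' A *driver method* is a named function from a [compute_gene_scores()]
#' score vector to a `method_result`. The consensus machinery only ever
#' sees this interface, so published pathway/network algorithms can be
#' plugged in alongside the two reference methods shipped here
#' ([hypergeometric_method()], [neighborhood_method()]) and the replay
#' adapter ([external_method()]).
#'
#' @param name Method name.
#' @param fn Function `(scores) -> character vector of reported genes` or
#'   `(scores) -> method_result`.
#' @return An object of class `driver_method`.
#' @export
driver_method <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  structure(list(name = name, fn = fn), class = "driver_method")
}

#' Run a driver method on a score vector
#'
#' @param method A `driver_method`.
#' @param scores A `gene_score_vector`.
#' @return A `method_result`: list with `method`, `mode`, `genes`,
#'   `evidence` (named numeric, possibly empty), `calibration` (`NULL`
#'   until [calibrate_method()] is attached).
#' @export
run_method <- function(method, scores) {
  stopifnot(inherits(method, "driver_method"))
  out <- method$fn(scores)
  if (inherits(out, "method_result")) {
    out$method <- method$name
    return(out)
  }
  method_result(method$name, attr(scores, "mode") %||% NA_character_,
                genes = as.character(out))
}

#' @rdname run_method
#' @param mode Score mode label.
#' @param genes Reported gene set.
#' @param evidence Optional named numeric per-gene p/FDR evidence.
#' @param calibration Optional calibration record.
#' @export
method_result <- function(method, mode, genes, evidence = NULL,
                          calibration = NULL) {
  structure(list(method = method, mode = mode,
                 genes = unique(as.character(genes)),
                 evidence = evidence, calibration = calibration),
            class = "method_result")
}

#' @export
print.method_result <- function(x, ...) {
  cat(sprintf("<method_result> %s on %s: %d gene(s)%s\n", x$method, x$mode,
              length(x$genes),
              if (is.null(x$calibration)) "" else " [calibrated]"))
  invisible(x)
}

#' Reference pathway method: seeded hypergeometric enrichment
#'
#' A reconstruction of a simple pathway-based prioritization: (i) *seed*
#' genes are those whose gene score passes a Benjamini-Hochberg FDR
#' threshold; (ii) every pathway is tested for one-sided hypergeometric
#' enrichment of seed genes against the database universe; (iii) the
#' reported genes are the seed genes belonging to at least one pathway with
#' pathway-level BH FDR below `report_threshold`.
#'
#' @param db A [pathway_db()]; must be non-empty after size filtering.
#' @param seed_threshold BH FDR cutoff turning scores into seed genes.
#' @param report_threshold BH FDR cutoff on pathway enrichment p-values.
#' @return A `driver_method`.
#' @export
hypergeometric_method <- function(db, seed_threshold = 0.1,
                                  report_threshold = 0.1) {
  stopifnot(inherits(db, "pathway_db"))
  if (!length(db$sets)) {
    stop("pathway database is empty after size filtering", call. = FALSE)
  }
  fn <- function(scores) {
    mode <- attr(scores, "mode") %||% NA_character_
    universe <- intersect(db$universe, names(scores))
    s <- scores[universe]
    if (!length(s)) return(method_result("hypergeometric", mode,
                                         character(0)))
    q <- stats::p.adjust(as.numeric(s), method = "BH")
    seeds <- universe[q < seed_threshold]
    if (!length(seeds)) {
      return(method_result("hypergeometric", mode, character(0)))
    }
    n_univ <- length(universe)
    res <- vapply(db$sets, function(set) {
      set <- intersect(set, universe)
      ov <- length(intersect(set, seeds))
      p <- stats::phyper(ov - 1L, length(set), n_univ - length(set),
                         length(seeds), lower.tail = FALSE)
      c(ov = ov, p = p)
    }, c(ov = 0, p = 0))
    path_q <- stats::p.adjust(res["p", ], method = "BH")
    sig_sets <- db$sets[path_q < report_threshold]
    genes <- intersect(seeds, unique(unlist(sig_sets, use.names = FALSE)))
    method_result("hypergeometric", mode, genes,
                  evidence = stats::setNames(as.numeric(q), universe)[genes])
  }
  driver_method("hypergeometric", fn)
}

#' Reference network method: Fisher neighborhood scoring
#'
#' Scores each gene by the Fisher combination of the gene scores of its
#' first-order network neighborhood including the gene itself
#' (\eqn{p^{with}}). A gene is reported when (i) the BH FDR of its
#' neighborhood score is below `report_threshold` and (ii) its own score
#' *improves* the neighborhood, i.e. \eqn{p^{with} < p^{without}} where
#' \eqn{p^{without}} omits the gene. Neighbors without a defined score are
#' dropped with degrees-of-freedom reduction. Degree-0 genes use the
#' convention `neighborhood = {g}`: their neighborhood score equals their
#' own score and \eqn{p^{without} = 1}, so isolated high-signal genes are
#' not discarded. Scored genes absent from the network are skipped (their
#' count is reported via a message).
#'
#' @param network An `igraph` interaction network.
#' @param report_threshold BH FDR cutoff on neighborhood scores.
#' @param quiet Suppress the skipped-gene message.
#' @return A `driver_method`.
#' @export
neighborhood_method <- function(network, report_threshold = 0.1,
                                quiet = TRUE) {
  stopifnot(igraph::is_igraph(network))
  adj <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  vnames <- rownames(adj)
  fn <- function(scores) {
    mode <- attr(scores, "mode") %||% NA_character_
    n_skip <- sum(!(names(scores) %in% vnames))
    if (n_skip && !quiet) {
      message(n_skip, " scored gene(s) absent from the network, skipped")
    }
    p <- stats::setNames(rep(NA_real_, length(vnames)), vnames)
    common <- intersect(vnames, names(scores))
    if (!length(common)) return(method_result("neighborhood", mode,
                                              character(0)))
    p[common] <- as.numeric(scores[common])
    lg <- -2 * log(pmax(p, 1e-300)); lg[is.na(p)] <- 0
    kz <- as.numeric(!is.na(p))
    s_wo <- as.numeric(adj %*% lg)
    k_wo <- as.numeric(adj %*% kz)
    s_wi <- s_wo + lg; k_wi <- k_wo + kz
    p_wi <- stats::pchisq(s_wi, df = 2 * k_wi, lower.tail = FALSE)
    p_wo <- stats::pchisq(s_wo, df = 2 * k_wo, lower.tail = FALSE)
    p_wo[k_wo == 0] <- 1
    cand <- !is.na(p)  # only genes with a defined own score are reportable
    q <- stats::p.adjust(p_wi[cand], method = "BH")
    rep_sel <- q < report_threshold & (p_wi < p_wo)[cand]
    genes <- vnames[cand][rep_sel]
    method_result("neighborhood", mode, genes,
                  evidence = stats::setNames(q, vnames[cand])[genes])
  }
  driver_method("neighborhood", fn)
}

#' Replay adapter for an external method's reported gene lists
#'
#' Wraps precomputed gene lists (e.g. a published method's output read with
#' [read_external_results()]) as a `driver_method`, so external results can
#' enter calibration and consensus through the same interface. The adapter
#' reports the stored list for the mode of the score vector it is handed;
#' mode `"*"` replays the same list for every mode.
#'
#' @param name Method name.
#' @param genes_by_mode Named list `mode -> character vector`, or a single
#'   character vector (treated as mode `"*"`).
#' @return A `driver_method`.
#' @export
external_method <- function(name, genes_by_mode) {
  if (is.character(genes_by_mode)) genes_by_mode <- list("*" = genes_by_mode)
  fn <- function(scores) {
    mode <- attr(scores, "mode") %||% "*"
    genes <- genes_by_mode[[mode]] %||% genes_by_mode[["*"]] %||%
      character(0)
    method_result(name, mode, intersect(genes, names(scores)))
  }
  driver_method(name, fn)
}

#' Read external-method result lists
#'
#' TSV with header columns `method`, `mode`, `gene`.
#'
#' @param path Path to the TSV file.
#' @return Named list of [external_method()] adapters, one per method.
#' @export
read_external_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("method", "mode", "gene") %in% names(df))) {
    stop("external results TSV needs columns method, mode, gene",
         call. = FALSE)
  }
  out <- lapply(split(df, df$method), function(sub) {
    external_method(sub$method[1L],
                    lapply(split(sub$gene, sub$mode), unique))
  })
  out
}

#' Calibrate a method on randomized data
#'
#' Runs the method on score vectors whose values have been permuted
#' uniformly across genes and records the mean and maximum reported-set
#' size over the randomizations. A method is flagged *miscalibrated* when
#' the mean randomized set size exceeds `flag_fraction` of the observed set
#' size — such a method reports similarly sized gene lists on data with no
#' gene-level signal, so its observed list carries little evidence.
#'
#' @param method A `driver_method`.
#' @param scores The observed `gene_score_vector`.
#' @param n_randomizations Number of permutations (>= 10).
#' @param seed Integer seed.
#' @param flag_fraction Miscalibration threshold as a fraction of the
#'   observed set size.
#' @param observed Optional precomputed observed `method_result`.
#' @return The observed `method_result` with `$calibration` set to a list
#'   with `n_randomizations`, `mean_size`, `max_size`, `observed_size`,
#'   `miscalibrated`, `seed`.
#' @export
calibrate_method <- function(method, scores, n_randomizations = 20L,
                             seed = 1L, flag_fraction = 0.1,
                             observed = NULL) {
  stopifnot(n_randomizations >= 10L)
  observed <- observed %||% run_method(method, scores)
  sizes <- integer(n_randomizations)
  mode <- attr(scores, "mode")
  set.seed(seed)
  for (b in seq_len(n_randomizations)) {
    perm <- structure(sample(as.numeric(scores)), names = names(scores),
                      mode = mode, class = "gene_score_vector")
    sizes[b] <- length(run_method(method, perm)$genes)
  }
  obs_size <- length(observed$genes)
  observed$calibration <- list(
    n_randomizations = n_randomizations,
    mean_size = mean(sizes), max_size = max(sizes),
    observed_size = obs_size,
    miscalibrated = mean(sizes) > flag_fraction * max(obs_size, 1L),
    seed = seed)
  observed
}
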