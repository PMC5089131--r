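#' Infer an ensemble association network
#'
#' The single entry point tying the pipeline together: preprocessing,
#' initial network computation (measure scoring + thresholding), assessment
#' of significance (renormalized permutation null, bootstrap confidence
#' distribution, parametric p-value, Brown/Fisher p-value merging,
#' multiple-testing correction), and voting-based edge merging. Returns a
#' classed fit object carrying the final annotated network together with
#' every intermediate the run produced.
#'
#' Different association measures make different mistakes; requiring
#' support from several of them (minsupport voting) or combining their
#' dependent p-values (Brown's method) filters out measure-specific false
#' positives. The permutation null is computed with a renormalization step:
#' permuted rows are placed back into the full relative-abundance matrix and
#' columns re-closed to unit sum, so the null carries the same
#' compositional bias as the observed scores.
#'
#' @param x an [abundance_table()], or a numeric object-by-sample matrix.
#' @param measures measure ids (see [compute_measure()]).
#' @param metadata optional sample-metadata [abundance_table()] merged in as
#'   extra rows (see [merge_feature_rows()]).
#' @param match_samples align metadata sample ids by name.
#' @param row_minocc minimum non-zero occurrence per row (0 = off).
#' @param keep_filtered_sum keep the sum of filtered rows as a pseudo-row.
#' @param col_norm divide each entry by its column sum.
#' @param rarefy_depth rarefy columns to this depth (NULL = off).
#' @param higher_taxa append higher-level taxon rows from lineages.
#' @param parent_child_exclusion drop pairs within one lineage.
#' @param group_mode `"all"`, `"between_groups_only"` or
#'   `"within_groups_only"`.
#' @param threshold_mode `"top_and_bottom"`, `"top"` or `"manual"`.
#' @param edge_number edges per side per measure for automatic thresholds.
#' @param upper,lower manual thresholds (named vectors accepted, one entry
#'   per measure).
#' @param significance `"none"`, `"permutation"` (empirical add-one tail) or
#'   `"reboot"` (parametric permutation-vs-bootstrap distance).
#' @param iterations resampling iterations for each distribution.
#' @param renormalize renormalize the permuted matrix (compositionality
#'   correction).
#' @param pmerge `"brown"`, `"fisher"` or `"none"` (no combination: an
#'   edge's p is the smallest of its measure-specific p-values).
#' @param multitest `"benjaminihochberg"`, `"bonferroni"` or `"none"`.
#' @param q_threshold keep edges with corrected q at or below this.
#' @param stability_level optional bootstrap stability-filter level (e.g.
#'   0.95); NULL = off.
#' @param minsupport minimum number of supporting measures per edge.
#' @param intersection require support from every measure.
#' @param multigraph return the measure-specific multigraph instead of a
#'   merged network.
#' @param positive_only drop negative and unsigned edges from the final
#'   network.
#' @param seed integer seed driving all resampling streams.
#' @param save_null,load_null,save_boot,load_boot paths for persisting /
#'   reusing permutation and bootstrap stores (the two-launch protocol).
#' @return an object of class `assocnet` with elements `network` (final
#'   [assoc_network]), `candidates`, `score_sets`, `pairs`, `edge_stats`
#'   (per-measure and merged p/q), `table` (preprocessed), `report`, `call`.
#' @examples
#' sim <- simulate_community(n_taxa = 20, n_samples = 30, n_pos = 3,
#'                           n_neg = 2, seed = 7)
#' fit <- assocnet(sim$table, measures = c("spearman", "bray_curtis"),
#'                 col_norm = TRUE, threshold_mode = "top_and_bottom",
#'                 edge_number = 10, minsupport = 2, seed = 7)
#' fit
#' @export
assocnet <- function(x,
                     measures = c("spearman", "bray_curtis"),
                     metadata = NULL, match_samples = FALSE,
                     row_minocc = 0, keep_filtered_sum = FALSE,
                     col_norm = FALSE, rarefy_depth = NULL,
                     higher_taxa = FALSE, parent_child_exclusion = FALSE,
                     group_mode = "all",
                     threshold_mode = "top_and_bottom", edge_number = 1000L,
                     upper = NULL, lower = NULL,
                     significance = c("none", "permutation", "reboot"),
                     iterations = 100L, renormalize = FALSE,
                     pmerge = c("brown", "fisher", "none"),
                     multitest = c("benjaminihochberg", "bonferroni", "none"),
                     q_threshold = 0.05, stability_level = NULL,
                     minsupport = 1L, intersection = FALSE,
                     multigraph = FALSE, positive_only = FALSE,
                     seed = 1L,
                     save_null = NULL, load_null = NULL,
                     save_boot = NULL, load_boot = NULL) {
  significance <- match.arg(significance)
  pmerge <- match.arg(pmerge)
  multitest <- match.arg(multitest)
  report <- new_run_report()
  if (is.matrix(x)) x <- abundance_table(x)
  stopifnot(inherits(x, "abundance_table"))

  # -- preprocessing ---------------------------------------------------
  table <- x
  if (!is.null(metadata))
    table <- merge_feature_rows(table, metadata, match_samples = match_samples)
  report$counts$rows_in <- nrow(table$values)
  if (row_minocc > 0)
    table <- filter_min_occurrence(table, row_minocc,
                                   keep_sum = keep_filtered_sum)
  if (!is.null(rarefy_depth))
    table <- rarefy_columns(table, depth = rarefy_depth,
                            seed = derive_seed(seed, 3L))
  if (higher_taxa) table <- aggregate_higher_taxa(table)
  if (col_norm) table <- normalize_columns(table)
  report$counts$rows_after_preprocess <- nrow(table$values)

  # -- initial network: scoring + thresholds ---------------------------
  pairs <- eligible_pairs(table, group_mode = group_mode,
                          parent_child_exclusion = parent_child_exclusion)
  report$counts$eligible_pairs <- nrow(pairs)
  score_sets <- score_all_pairs(table, measures, pairs)
  candidates <- list()
  for (m in measures) {
    candidates[[m]] <- select_edges(
      score_sets[[m]], mode = threshold_mode, edge_number = edge_number,
      upper = scalar_for(upper, m), lower = scalar_for(lower, m))
    report$counts[[paste0("candidates_", m)]] <- nrow(candidates[[m]])
  }
  initial_pairs <- unique(do.call(rbind, lapply(unname(candidates),
                                                function(d) d[c("a", "b")])))
  initial_pairs <- initial_pairs[order(initial_pairs$a, initial_pairs$b), ,
                                 drop = FALSE]
  report$counts$initial_edges <- nrow(initial_pairs)
  if (nrow(initial_pairs) == 0) stop("no candidate edges; relax thresholds")

  # -- significance ----------------------------------------------------
  edge_stats <- NULL
  if (significance != "none") {
    null_store <- if (!is.null(load_null)) read_resampling_store(load_null)
      else permutation_distribution(table, measures, initial_pairs,
                                    iterations = iterations,
                                    renormalize = renormalize, seed = seed)
    check_store(null_store, "permutation", measures, initial_pairs)
    if (!is.null(save_null)) write_resampling_store(null_store, save_null)
    boot_store <- NULL
    if (significance == "reboot") {
      boot_store <- if (!is.null(load_boot)) read_resampling_store(load_boot)
        else bootstrap_distribution(table, measures, initial_pairs,
                                    iterations = iterations, seed = seed)
      check_store(boot_store, "bootstrap", measures, initial_pairs)
      if (!is.null(save_boot)) write_resampling_store(boot_store, save_boot)
    }
    edge_stats <- compute_edge_stats(score_sets, candidates, initial_pairs,
                                     null_store, boot_store, significance,
                                     pmerge, multitest, stability_level,
                                     q_threshold = q_threshold)
    surviving <- edge_stats$pairs[edge_stats$pairs$keep, c("a", "b")]
    report$counts$significant_edges <- nrow(surviving)
    skey <- paste(surviving$a, surviving$b, sep = "\r")
    candidates <- lapply(candidates, function(d)
      d[paste(d$a, d$b, sep = "\r") %in% skey, , drop = FALSE])
    if (!is.null(q_threshold) && nrow(surviving) == 0)
      warning("no edge passed the significance threshold")
  }

  # -- merging / voting ------------------------------------------------
  if (multigraph) {
    network <- build_multigraph(candidates)
  } else {
    edge_pv <- if (!is.null(edge_stats))
      edge_stats$pairs[c("a", "b", "p", "q")] else NULL
    network <- merge_edges(candidates, minsupport = minsupport,
                           intersection = intersection,
                           edge_pvalues = edge_pv)
  }
  network <- annotate_nodes(network, table)
  if (positive_only) network <- filter_positive_edges(network)
  report$counts$final_edges <- nrow(network$edges)
  report$counts$final_nodes <- nrow(network$nodes)

  structure(list(network = network, candidates = candidates,
                 score_sets = score_sets, pairs = pairs,
                 edge_stats = edge_stats, table = table, report = report,
                 measures = measures, seed = as.integer(seed),
                 call = match.call()),
            class = "assocnet")
}

scalar_for <- function(x, measure) {
  if (is.null(x)) return(NULL)
  if (!is.null(names(x))) {
    if (measure %in% names(x)) unname(x[[measure]]) else NULL
  } else as.numeric(x)[1L]
}

check_store <- function(store, kind, measures, pairs) {
  if (!identical(store$kind, kind))
    stop("loaded store has kind '", store$kind, "', expected '", kind, "'")
  if (!setequal(store$measures, measures))
    stop("loaded store covers measures {",
         paste(store$measures, collapse = ", "), "}, run uses {",
         paste(measures, collapse = ", "), "}")
  want <- as.vector(outer(paste(pairs$a, pairs$b, sep = "||"), measures,
                          paste, sep = "||"))
  missing <- setdiff(want, names(store$scores))
  if (length(missing) > 0)
    stop("loaded store is missing ", length(missing),
         " (pair, measure) series, e.g. ", missing[1L])
}

# Per-(pair, measure) p-values, per-pair merged p and corrected q over the
# initial network's edges, plus the keep decision.
compute_edge_stats <- function(score_sets, candidates, initial_pairs,
                               null_store, boot_store, significance,
                               pmerge, multitest, stability_level,
                               q_threshold = 0.05) {
  measures <- names(score_sets)
  r_all <- if (length(measures) > 1)
    measure_correlation(score_sets, initial_pairs) else NULL
  cand_key <- lapply(candidates, function(d) paste(d$a, d$b, sep = "\r"))
  per_measure <- list()
  n <- nrow(initial_pairs)
  merged_p <- rep(NA_real_, n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    a <- initial_pairs$a[i]; b <- initial_pairs$b[i]
    k <- paste(a, b, sep = "\r")
    contrib <- measures[vapply(measures, function(m) k %in% cand_key[[m]],
                               logical(1))]
    ps <- numeric(0)
    for (m in contrib) {
      cd <- candidates[[m]]
      row <- which(cand_key[[m]] == k)[1L]
      obs <- cd$score[row]; sgn <- cd$sign[row]
      null <- null_store$scores[[pair_key(a, b, m)]]
      p <- if (significance == "reboot") {
        boot <- boot_store$scores[[pair_key(a, b, m)]]
        if (!is.null(stability_level) &&
            !stability_filter(mean(null, na.rm = TRUE), boot,
                              level = stability_level)) keep[i] <- FALSE
        reboot_pvalue(null, boot)
      } else {
        permutation_pvalue(obs, null,
                           tail = candidate_tail(score_sets[[m]]$direction,
                                                 sgn))
      }
      ps[m] <- p
      per_measure[[length(per_measure) + 1L]] <-
        data.frame(a = a, b = b, measure = m, observed = obs, sign = sgn,
                   p = p, stringsAsFactors = FALSE)
    }
    merged_p[i] <- if (length(ps) == 0) NA_real_
      else if (length(ps) == 1L || pmerge == "none") min(ps)
      else merge_pvalues(unname(ps), method = pmerge,
                         r = r_all[names(ps), names(ps), drop = FALSE])
  }
  q <- if (multitest == "none") merged_p
       else correct_multiple_testing(merged_p[!is.na(merged_p)],
                                     method = multitest,
                                     m = sum(!is.na(merged_p)))
  qq <- rep(NA_real_, n); qq[!is.na(merged_p)] <- q
  keep <- keep & !is.na(qq) & qq <= q_threshold
  list(pairs = data.frame(a = initial_pairs$a, b = initial_pairs$b,
                          p = merged_p, q = qq, keep = keep,
                          stringsAsFactors = FALSE),
       per_measure = do.call(rbind, per_measure))
}

new_run_report <- function() {
  structure(list(started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 counts = list(), warnings = character(0)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run report (", x$started, ")\n", sep = "")
  for (nm in names(x$counts))
    cat(sprintf("  %-28s %s\n", nm, x$counts[[nm]]))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
print.assocnet <- function(x, ...) {
  cat("Ensemble association network fit\n")
  cat("  measures:", paste(x$measures, collapse = ", "), "\n")
  print(x$network)
  invisible(x)
}

#' @export
summary.assocnet <- function(object, ...) {
  cat("Ensemble association network fit\n")
  cat("  measures:", paste(object$measures, collapse = ", "), "\n")
  cat("  table:", nrow(object$table$values), "objects x",
      ncol(object$table$values), "samples |",
      nrow(object$pairs), "eligible pairs\n")
  for (m in names(object$candidates))
    cat(sprintf("  candidates[%s]: %d\n", m, nrow(object$candidates[[m]])))
  if (!is.null(object$edge_stats)) {
    es <- object$edge_stats$pairs
    cat(sprintf("  initial edges: %d | significant (q <= threshold): %d\n",
                nrow(es), sum(es$keep)))
  }
  print(object$network)
  if (nrow(object$network$edges) > 0) {
    cat("  strongest edges:\n")
    e <- object$network$edges
    e <- e[order(e$weight), , drop = FALSE]
    show <- utils::head(e[, intersect(c("source", "target", "sign",
                                        "weight", "p", "q", "support"),
                                      names(e))], 5L)
    print(show, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.assocnet <- function(x, ...) plot(x$network, ...)
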