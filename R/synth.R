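#' Simulate a sequencing-style community with planted associations
#'
#' Generates an OTU-by-sample count table mimicking a 16S survey. Latent
#' per-taxon abundances are log-normal; each planted pair shares a latent
#' sample factor with loadings of equal (co-presence) or opposite (mutual
#' exclusion) sign, so the latent log-abundance correlation of a planted
#' pair is `effect` in magnitude. Every sample then draws a sequencing
#' depth uniformly from `depth_range` and its counts from a multinomial
#' over the latent relative abundances — the closure that makes real
#' sequencing counts compositional is therefore present, not just
#' approximated. Optional zero-inflation thins counts to mimic
#' under-detection; optional random taxonomy assignment supports
#' parent-child-exclusion tests.
#'
#' @param n_taxa number of taxa (>= 10).
#' @param n_samples number of samples (>= 10).
#' @param n_pos,n_neg number of planted co-presence / mutual-exclusion
#'   pairs (disjoint, over distinct taxa).
#' @param effect latent log-scale correlation magnitude of planted pairs
#'   (default 0.9, a strong association).
#' @param depth_range per-sample sequencing depth range (uniform draw).
#' @param zero_inflation probability of zeroing any count cell (extra
#'   dropout on top of sampling zeros; default 0).
#' @param taxonomy assign a random nested taxonomy (kingdom..genus) to the
#'   taxa.
#' @param seed integer seed; same seed, same table.
#' @return list with `table` (an [abundance_table()]) and `truth` (list
#'   with `edges` data.frame `a`, `b`, `sign`, `effect`, and `params`).
#' @export
simulate_community <- function(n_taxa = 100L, n_samples = 100L,
                               n_pos = 20L, n_neg = 20L, effect = 0.9,
                               depth_range = c(5000L, 20000L),
                               zero_inflation = 0, taxonomy = FALSE,
                               seed = 1L) {
  stopifnot(n_taxa >= 10L, n_samples >= 10L, effect > 0, effect <= 1)
  n_planted <- n_pos + n_neg
  if (2L * n_planted > n_taxa)
    stop("more planted pairs than available disjoint taxon pairs")
  set.seed(derive_seed(seed, 4L))
  ids <- sprintf("OTU_%03d", seq_len(n_taxa))
  base <- stats::rnorm(n_taxa, mean = 0, sd = 1.5)   # taxon size spread
  names(base) <- ids
  noise_sd <- 1
  lat <- matrix(stats::rnorm(n_taxa * n_samples, sd = noise_sd),
                nrow = n_taxa, dimnames = list(ids, sprintf("S%03d",
                                                            seq_len(n_samples))))
  # planted pairs over disjoint taxa, chosen at random
  planted_taxa <- sample(ids, 2L * n_planted)
  loading <- sqrt(effect)
  resid <- sqrt(1 - effect)
  edges <- data.frame(a = character(0), b = character(0), sign = character(0),
                      effect = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(n_planted)) {
    ta <- planted_taxa[2L * i - 1L]; tb <- planted_taxa[2L * i]
    sgn <- if (i <= n_pos) 1 else -1
    # associated partners share a characteristic abundance, so the planted
    # effect shows up in profile similarity (Bray-Curtis) as well as in
    # rank correlation, as a strong ecological association would
    base[tb] <- base[ta]
    f <- stats::rnorm(n_samples)
    lat[ta, ] <- loading * f + resid * stats::rnorm(n_samples)
    lat[tb, ] <- sgn * loading * f + resid * stats::rnorm(n_samples)
    pair <- sort(c(ta, tb))
    edges <- rbind(edges, data.frame(
      a = pair[1L], b = pair[2L],
      sign = if (sgn > 0) "positive" else "negative",
      effect = effect, stringsAsFactors = FALSE))
  }
  abun <- exp(base + lat)     # log-normal latent abundances
  depths <- sample(seq(depth_range[1L], depth_range[2L]), n_samples,
                   replace = TRUE)
  counts <- matrix(0, n_taxa, n_samples, dimnames = dimnames(lat))
  for (j in seq_len(n_samples))
    counts[, j] <- stats::rmultinom(1L, depths[j], abun[, j])
  if (zero_inflation > 0) {
    drop <- matrix(stats::runif(n_taxa * n_samples) < zero_inflation,
                   n_taxa, n_samples)
    counts[drop] <- 0
  }
  lineage <- NULL
  if (taxonomy) {
    # random nested taxonomy: 3 phyla, 2 classes each, ... down to genus
    lineage <- list()
    n_phy <- 3L
    for (i in seq_len(n_taxa)) {
      phy <- sample.int(n_phy, 1L)
      cls <- sample.int(2L, 1L); ord <- sample.int(2L, 1L)
      fam <- sample.int(2L, 1L); gen <- sample.int(3L, 1L)
      lineage[[ids[i]]] <- parse_lineage(sprintf(
        "k__Bacteria; p__P%d; c__P%dC%d; o__P%dC%dO%d; f__P%dC%dO%dF%d; g__P%dC%dO%dF%dG%d",
        phy, phy, cls, phy, cls, ord, phy, cls, ord, fam,
        phy, cls, ord, fam, gen))
    }
  }
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  list(table = abundance_table(counts, lineage = lineage),
       truth = list(edges = edges,
                    params = list(n_taxa = n_taxa, n_samples = n_samples,
                                  n_pos = n_pos, n_neg = n_neg,
                                  effect = effect,
                                  depth_range = depth_range,
                                  depths = depths,
                                  zero_inflation = zero_inflation,
                                  seed = seed)))
}

#' Evaluate recovery of planted associations
#'
#' Compares an inferred network against the generator's planted truth:
#' precision and recall over edge identity, sign accuracy on the recovered
#' planted edges, and the AUROC of the edge ranking (merged q-value when
#' present, else combined weight) against the planted labels over all
#' candidate pairs considered. Pairs absent from the network rank last.
#'
#' @param network an [assoc_network] inferred from the simulated table.
#' @param truth the `truth` element of [simulate_community()].
#' @param pvalues optional data.frame `a`, `b`, `p` (e.g. the fit's
#'   `edge_stats$pairs`) ranking all initial-network edges by merged
#'   p-value; when given, the AUROC is computed on this ranking instead of
#'   the final network's edge weights.
#' @param universe optional data.frame `a`,`b` of all pairs over which the
#'   AUROC ranking is evaluated; defaults to all planted pairs plus all
#'   ranked pairs.
#' @return list with `precision`, `recall`, `sign_accuracy`, `auroc`,
#'   `n_recovered`.
#' @export
evaluate_recovery <- function(network, truth, pvalues = NULL,
                              universe = NULL) {
  e <- network$edges
  tkey <- paste(truth$edges$a, truth$edges$b, sep = "\r")
  ekey <- if (nrow(e) > 0) paste(e$source, e$target, sep = "\r") else character(0)
  tp <- intersect(ekey, tkey)
  precision <- if (length(ekey) == 0) NA_real_ else length(tp) / length(ekey)
  recall <- length(tp) / length(tkey)
  sign_acc <- NA_real_
  if (length(tp) > 0) {
    es <- e$sign[match(tp, ekey)]
    ts <- truth$edges$sign[match(tp, tkey)]
    sign_acc <- mean(es == ts)
  }
  ranked <- if (!is.null(pvalues))
    data.frame(a = pvalues$a, b = pvalues$b, strength = -pvalues$p,
               stringsAsFactors = FALSE)
  else if (nrow(e) > 0)
    data.frame(a = e$source, b = e$target,
               strength = if ("q" %in% names(e) && any(!is.na(e$q))) -e$q
                          else -e$weight,
               stringsAsFactors = FALSE)
  else data.frame(a = character(0), b = character(0), strength = numeric(0),
                  stringsAsFactors = FALSE)
  if (is.null(universe))
    universe <- unique(rbind(truth$edges[c("a", "b")],
                             ranked[c("a", "b")]))
  ukey <- paste(universe$a, universe$b, sep = "\r")
  labels <- ukey %in% tkey
  # ranking score: smaller p/q = stronger edge; unranked pairs come last
  strength <- rep(-Inf, length(ukey))
  idx <- match(paste(ranked$a, ranked$b, sep = "\r"), ukey)
  strength[idx[!is.na(idx)]] <- ranked$strength[!is.na(idx)]
  list(precision = precision, recall = recall, sign_accuracy = sign_acc,
       auroc = auroc(strength, labels), n_recovered = length(tp))
}

# Rank-based (Wilcoxon) AUROC: probability that a random true edge
# outranks a random non-edge, ties counted half.
auroc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Recovery benchmark on a simulated community
#'
#' End-to-end validation run: simulates a 100-taxon, 100-sample community
#' with 20 planted co-presence and 20 planted mutual-exclusion pairs at
#' strong effect, infers a network with the spearman + bray_curtis ensemble
#' (column normalization, automatic top-and-bottom thresholds, renormalized
#' permutation null and bootstrap with 100 iterations each, Brown merging,
#' Benjamini-Hochberg correction at q <= 0.05, minsupport 2) and scores the
#' recovery.
#'
#' @param seed integer seed.
#' @param n_taxa,n_samples community size.
#' @param iterations resampling iterations per distribution.
#' @param edge_number automatic threshold edges per side per measure.
#' @return list with `fit`, `metrics` (from [evaluate_recovery()]), `truth`.
#' @export
recovery_benchmark <- function(seed = 1L, n_taxa = 100L, n_samples = 100L,
                               iterations = 100L, edge_number = 250L) {
  sim <- simulate_community(n_taxa = n_taxa, n_samples = n_samples,
                            n_pos = 20L, n_neg = 20L, effect = 0.9,
                            seed = seed)
  fit <- assocnet(sim$table, measures = c("spearman", "bray_curtis"),
                  col_norm = TRUE, threshold_mode = "top_and_bottom",
                  edge_number = edge_number, significance = "reboot",
                  iterations = iterations, renormalize = TRUE,
                  pmerge = "brown", multitest = "benjaminihochberg",
                  q_threshold = 0.05, minsupport = 2L, seed = seed)
  metrics <- evaluate_recovery(fit$network, sim$truth,
                               pvalues = fit$edge_stats$pairs)
  list(fit = fit, metrics = metrics, truth = sim$truth)
}

#' Write a simulated community to TSV files
#'
#' Command-line face of the generator: writes the count table and the
#' planted-truth edge list as tab-delimited files.
#'
#' @param sim result of [simulate_community()].
#' @param table_path,truth_path output paths.
#' @export
write_simulation <- function(sim, table_path, truth_path) {
  v <- sim$table$values
  utils::write.table(data.frame(id = rownames(v), v, check.names = FALSE),
                     table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$edges, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table_path)
}
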