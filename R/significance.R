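# Sub-seeds for the independent RNG streams (permutation, bootstrap,
# generator), derived from the single user seed by a fixed affine counter
# scheme, kept within 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% 2147483647)
}

pair_key <- function(a, b, measure) paste(a, b, measure, sep = "||")

#' Permutation (null) score distributions, optionally renormalized
#'
#' For each candidate pair and iteration, the two rows' values are
#' independently permuted across samples, breaking any association while
#' preserving each row's value distribution. With `renormalize`, the
#' permuted pair is placed back into the full matrix (including the
#' `filtered_sum` pseudo-row) and every column is renormalized to unit sum
#' before scoring; this mitigates the compositionality bias of relative
#' abundances, whose closure otherwise induces spurious negative
#' correlations that a plain permutation null does not reproduce.
#'
#' The two permutations of an iteration are shared across measures, so the
#' per-measure null scores of one edge remain coupled (as the observed
#' scores are).
#'
#' @param table preprocessed [abundance_table()] (column-normalized when
#'   `renormalize` is used).
#' @param measures measure ids to score.
#' @param pairs data.frame `a`,`b` of pairs needing null distributions.
#' @param iterations number of permutations per pair.
#' @param renormalize renormalize columns of the permuted matrix before
#'   scoring.
#' @param seed integer seed; identical seeds give identical distributions.
#' @return a `resampling_store`: list with `kind`, `iterations`, `seed`,
#'   `measures`, and `scores` (named list keyed by `a||b||measure`, each an
#'   iteration-long numeric vector).
#' @export
permutation_distribution <- function(table, measures, pairs, iterations = 100L,
                                     renormalize = FALSE, seed = 1L) {
  stopifnot(iterations >= 1L)
  v <- table$values
  n <- ncol(v)
  cs_full <- colSums(v, na.rm = TRUE)
  if (renormalize && any(abs(cs_full - 1) > 1e-6)) {
    warning("renormalize requested on a table without unit column sums; ",
            "applying raw column sums")
  }
  ord <- order(pairs$a, pairs$b)
  pairs <- pairs[ord, , drop = FALSE]
  set.seed(derive_seed(seed, 1L))
  scores <- vector("list", nrow(pairs) * length(measures))
  keys <- character(length(scores))
  slot <- 0L
  for (i in seq_len(nrow(pairs))) {
    xi <- v[pairs$a[i], ]; xj <- v[pairs$b[i], ]
    res <- matrix(NA_real_, nrow = iterations, ncol = length(measures))
    for (t in seq_len(iterations)) {
      pi <- xi[sample.int(n)]
      pj <- xj[sample.int(n)]
      if (renormalize) {
        # column sums after swapping the permuted pair into the full matrix
        ncs <- cs_full - ifelse(is.na(xi), 0, xi) - ifelse(is.na(xj), 0, xj) +
          ifelse(is.na(pi), 0, pi) + ifelse(is.na(pj), 0, pj)
        ncs[ncs == 0] <- NA_real_
        pi <- pi / ncs; pj <- pj / ncs
      }
      pc <- pairwise_complete(pi, pj)
      if (pc$usable)
        for (mi in seq_along(measures))
          res[t, mi] <- compute_measure(measures[mi], pc$x, pc$y)
    }
    for (mi in seq_along(measures)) {
      slot <- slot + 1L
      keys[slot] <- pair_key(pairs$a[i], pairs$b[i], measures[mi])
      scores[[slot]] <- res[, mi]
    }
  }
  names(scores) <- keys
  structure(list(kind = "permutation", iterations = as.integer(iterations),
                 seed = as.integer(seed), measures = measures,
                 scores = scores),
            class = "resampling_store")
}

#' Bootstrap (confidence) score distributions
#'
#' Per iteration, one sample-index draw with replacement is shared across
#' all pairs (preserving the cross-edge and cross-measure dependence that
#' Brown's covariance estimate relies on); every pair's measures are then
#' recomputed on the resampled columns.
#'
#' @inheritParams permutation_distribution
#' @return a `resampling_store` of kind `"bootstrap"`.
#' @export
bootstrap_distribution <- function(table, measures, pairs, iterations = 100L,
                                   seed = 1L) {
  stopifnot(iterations >= 1L)
  v <- table$values
  n <- ncol(v)
  ord <- order(pairs$a, pairs$b)
  pairs <- pairs[ord, , drop = FALSE]
  set.seed(derive_seed(seed, 2L))
  draws <- matrix(sample.int(n, n * iterations, replace = TRUE),
                  nrow = iterations)
  res <- array(NA_real_,
               dim = c(iterations, nrow(pairs), length(measures)))
  for (t in seq_len(iterations)) {
    idx <- draws[t, ]
    for (i in seq_len(nrow(pairs))) {
      pc <- pairwise_complete(v[pairs$a[i], idx], v[pairs$b[i], idx])
      if (!pc$usable) next
      for (mi in seq_along(measures))
        res[t, i, mi] <- compute_measure(measures[mi], pc$x, pc$y)
    }
  }
  scores <- list()
  for (i in seq_len(nrow(pairs)))
    for (mi in seq_along(measures))
      scores[[pair_key(pairs$a[i], pairs$b[i], measures[mi])]] <- res[, i, mi]
  structure(list(kind = "bootstrap", iterations = as.integer(iterations),
                 seed = as.integer(seed), measures = measures,
                 scores = scores),
            class = "resampling_store")
}

#' @export
print.resampling_store <- function(x, ...) {
  cat(sprintf("resampling_store (%s): %d iterations, %d (pair, measure) series, seed %d\n",
              x$kind, x$iterations, length(x$scores), x$seed))
  invisible(x)
}

#' Persist a resampling store to a tab-delimited file
#'
#' Header line carries kind, iterations, seed and measures; one row per
#' (source, target, measure) with the full score series. Numbers are written
#' with 17 significant digits so that reading the store back reproduces the
#' scores bit-for-bit (the two-launch protocol depends on this).
#'
#' @param store a `resampling_store`.
#' @param path output file.
#' @export
write_resampling_store <- function(store, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s iterations=%d seed=%d measures=%s",
                     store$kind, store$iterations, store$seed,
                     paste(store$measures, collapse = ",")), con)
  writeLines(paste(c("source", "target", "measure",
                     paste0("score_", seq_len(store$iterations))),
                   collapse = "\t"), con)
  keys <- sort(names(store$scores))
  for (k in keys) {
    parts <- strsplit(k, "||", fixed = TRUE)[[1L]]
    writeLines(paste(c(parts, sprintf("%.17g", store$scores[[k]])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a resampling store written by [write_resampling_store()]
#'
#' @param path store file.
#' @return a `resampling_store`.
#' @export
read_resampling_store <- function(path) {
  if (!file.exists(path)) stop("resampling store not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1L]
  if (!startsWith(hdr, "# kind="))
    stop("not a resampling store file: ", path)
  get_field <- function(name) {
    m <- regmatches(hdr, regexec(paste0(name, "=([^ ]+)"), hdr))[[1L]]
    if (length(m) < 2) stop("store header missing field '", name, "'")
    m[2L]
  }
  kind <- get_field("kind")
  iterations <- as.integer(get_field("iterations"))
  seed <- as.integer(get_field("seed"))
  measures <- strsplit(get_field("measures"), ",", fixed = TRUE)[[1L]]
  scores <- list()
  for (ln in lines[-(1:2)]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    scores[[pair_key(parts[1L], parts[2L], parts[3L])]] <-
      as.numeric(parts[-(1:3)])
  }
  structure(list(kind = kind, iterations = iterations, seed = seed,
                 measures = measures, scores = scores),
            class = "resampling_store")
}

#' Empirical permutation p-value (add-one tail)
#'
#' p = (1 + number of null scores at or beyond the observed score, in the
#' tested direction) / (iterations + 1); always in
#' \[1/(iterations+1), 1\].
#'
#' @param observed observed score.
#' @param null_scores numeric vector of permutation scores (NAs dropped).
#' @param tail `"upper"` (null >= observed counts against), `"lower"`, or
#'   `"two_sided"` (absolute deviation from the null mean).
#' @return p-value.
#' @export
permutation_pvalue <- function(observed, null_scores,
                               tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  null_scores <- null_scores[!is.na(null_scores)]
  if (length(null_scores) == 0) stop("empty null distribution")
  extreme <- switch(tail,
    upper = sum(null_scores >= observed),
    lower = sum(null_scores <= observed),
    two_sided = sum(abs(null_scores - mean(null_scores)) >=
                    abs(observed - mean(null_scores))))
  (1 + extreme) / (length(null_scores) + 1)
}

# Tail tested for a signed candidate given the measure direction: positive
# similarity edges sit in the upper tail of the null, negative in the lower;
# reversed for dissimilarities; dependency always upper; p-value-scale
# measures (hypergeometric) always lower.
candidate_tail <- function(direction, sign) {
  switch(direction,
    similarity = if (sign == "negative") "lower" else "upper",
    dissimilarity = if (sign == "negative") "upper" else "lower",
    dependency = "upper",
    pvalue = "lower")
}

#' Parametric permutation-vs-bootstrap (ReBoot-style) p-value
#'
#' Fits a normal distribution to the permutation null and measures how far
#' the bootstrap distribution's mean lies from it: with null mean m0 and
#' null standard deviation s0, and bootstrap mean mb,
#' p = 2 * Phi(-|mb - m0| / s0), clamped to (1e-300, 1\]. Because the
#' statistic is a distance between two fitted distributions rather than a
#' single empirical tail count, moderate iteration numbers (~100) already
#' give stable p-values.
#'
#' @param null_scores permutation scores (the null distribution).
#' @param bootstrap_scores bootstrap scores (the confidence distribution).
#' @param method `"null_sd"` (default: distance scaled by the null standard
#'   deviation) or `"boot_sd"` (scaled by the bootstrap standard deviation).
#' @return p-value in (0, 1\].
#' @export
reboot_pvalue <- function(null_scores, bootstrap_scores,
                          method = c("null_sd", "boot_sd")) {
  method <- match.arg(method)
  null_scores <- null_scores[!is.na(null_scores)]
  bootstrap_scores <- bootstrap_scores[!is.na(bootstrap_scores)]
  if (length(null_scores) == 0 || length(bootstrap_scores) == 0)
    stop("empty resampling distribution")
  mu0 <- mean(null_scores)
  s <- if (method == "null_sd") stats::sd(null_scores)
       else stats::sd(bootstrap_scores)
  if (is.na(s) || s == 0) {
    warning("degenerate resampling distribution (zero spread); p = 1")
    return(1)
  }
  mb <- mean(bootstrap_scores)
  p <- 2 * stats::pnorm(-abs(mb - mu0) / s)
  min(max(p, 1e-300), 1)
}

#' Bootstrap stability filter
#'
#' Optionally discards an edge whose permutation-null mean lies inside the
#' central `level` percentile interval of its bootstrap distribution, i.e.
#' whose observed association is not stably separated from the null under
#' resampling. Combining the permutation test with this bootstrap check is
#' more stringent than permutation alone.
#'
#' @param null_mean mean of the permutation null scores.
#' @param bootstrap_scores bootstrap score distribution.
#' @param level central interval mass (default 0.95).
#' @return `TRUE` to keep the edge.
#' @export
stability_filter <- function(null_mean, bootstrap_scores, level = 0.95) {
  bootstrap_scores <- bootstrap_scores[!is.na(bootstrap_scores)]
  if (length(bootstrap_scores) == 0) stop("empty bootstrap distribution")
  lo <- (1 - level) / 2
  qs <- stats::quantile(bootstrap_scores, c(lo, 1 - lo), names = FALSE,
                        type = 7)
  null_mean < qs[1L] || null_mean > qs[2L]
}

# Brown's polynomial approximation of cov(-2 ln p_i, -2 ln p_j) from the
# correlation r between the underlying statistics (separate fits for
# positive and negative r; cov(r = 1) = 4, the chi-square(2) variance).
brown_covariance <- function(r) {
  ifelse(r >= 0,
         r * (3.263 + r * (0.710 + 0.027 * r)),
         r * (3.27 + 0.71 * r))
}

#' Merge dependent per-measure p-values for one edge
#'
#' Fisher's method sums X = -2 * sum(log p) and refers it to a chi-square
#' with 2k degrees of freedom, assuming independent measures. Brown's method
#' keeps the same statistic but matches the first two moments of a scaled
#' chi-square c * chisq(f) to the true null of X under dependence:
#' E = 2k, Var = 4k + 2 * sum_{i<j} cov_ij, f = 2 E^2 / Var, c = Var / (2 E),
#' with cov_ij obtained from Brown's polynomial approximation applied to the
#' correlation r_ij between measures. With all r_ij = 0 Brown reduces
#' exactly to Fisher; with perfectly redundant measures it returns
#' (approximately) the single-measure p-value instead of overcounting
#' evidence. A single p-value is returned unchanged.
#'
#' @param p vector of k p-values in (0, 1].
#' @param method `"brown"` or `"fisher"`.
#' @param r k x k correlation matrix between the measures' score vectors
#'   (similarity-oriented), required for `"brown"` with k >= 2; ignored for
#'   `"fisher"`.
#' @return merged p-value.
#' @export
merge_pvalues <- function(p, method = c("brown", "fisher"), r = NULL) {
  method <- match.arg(method)
  if (any(p <= 0 | p > 1 | is.na(p)))
    stop("p-values must lie in (0, 1]")
  k <- length(p)
  if (k == 1L) return(p)
  X <- -2 * sum(log(p))
  if (method == "fisher")
    return(stats::pchisq(X, df = 2 * k, lower.tail = FALSE))
  if (is.null(r)) r <- diag(k)
  stopifnot(nrow(r) == k, ncol(r) == k)
  covs <- brown_covariance(r[upper.tri(r)])
  covs[is.na(covs)] <- 0
  E <- 2 * k
  V <- 4 * k + 2 * sum(covs)
  V <- max(V, 1e-12)
  f <- 2 * E^2 / V
  cc <- V / (2 * E)
  min(stats::pchisq(X / cc, df = f, lower.tail = FALSE), 1)
}

#' Multiple-testing correction over the initial network's edges
#'
#' Bonferroni (q = min(1, m p)) or Benjamini-Hochberg step-up q-values with
#' enforced monotonicity; `m` is the number of edges in the initial network,
#' the only hypotheses tested.
#'
#' @param p vector of edge p-values in (0, 1].
#' @param method `"benjaminihochberg"` or `"bonferroni"`.
#' @param m number of tests (defaults to `length(p)`).
#' @return vector of q-values, elementwise >= p.
#' @export
correct_multiple_testing <- function(p,
                                     method = c("benjaminihochberg",
                                                "bonferroni"),
                                     m = length(p)) {
  method <- match.arg(method)
  if (any(p <= 0 | p > 1 | is.na(p)))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = switch(method,
                                     benjaminihochberg = "BH",
                                     bonferroni = "bonferroni"), n = m)
}

# Similarity-oriented copy of a score vector: dissimilarities are negated so
# that, for every measure, larger means stronger co-presence. Used for the
# Brown correlation estimate and for combined edge weights. P-value-scale
# measures are mapped through -log so small p-values become large scores.
orient_scores <- function(scores, measure) {
  switch(measure_direction(measure),
         similarity = scores,
         dependency = scores,
         dissimilarity = -scores,
         pvalue = -log(pmax(scores, 1e-300)))
}

# Empirical between-measure correlation matrix across the initial network's
# edges, feeding Brown's covariance approximation.
measure_correlation <- function(score_sets, pairs) {
  measures <- names(score_sets)
  k <- length(measures)
  key <- function(df) paste(df$a, df$b, sep = "\r")
  want <- paste(pairs$a, pairs$b, sep = "\r")
  mat <- sapply(measures, function(m) {
    sc <- score_sets[[m]]$scores
    orient_scores(sc$score[match(want, key(sc))], m)
  })
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = k)
  r <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  dimnames(r) <- list(measures, measures)
  r
}
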