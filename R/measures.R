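# Measure registry. Direction drives sign assignment and significance tails:
#   similarity    -- high score = co-presence, low = mutual exclusion
#   dissimilarity -- reversed: low score = co-presence, high = exclusion
#   dependency    -- unsigned (mutual information)
#   pvalue        -- similarity reported on a p-value scale (hypergeometric:
#                    smaller = stronger co-presence)
.MEASURES <- c(pearson = "similarity", spearman = "similarity",
               kendall = "similarity", steinhaus = "similarity",
               bray_curtis = "dissimilarity", kullback_leibler = "dissimilarity",
               euclidean = "dissimilarity", jaccard = "dissimilarity",
               mutual_information = "dependency", hypergeometric = "pvalue")

#' Direction of an association measure
#'
#' @param measure measure id (see [compute_measure()]).
#' @return `"similarity"`, `"dissimilarity"`, `"dependency"` or `"pvalue"`.
#' @export
measure_direction <- function(measure) {
  if (!measure %in% names(.MEASURES)) stop("unknown measure: ", measure)
  unname(.MEASURES[[measure]])
}

#' Compute one association measure for a pair of rows
#'
#' Supported measures and definitions:
#' \describe{
#'   \item{pearson, spearman, kendall}{product-moment correlation, rank
#'     correlation, and tie-corrected Kendall tau-b, in \[-1, 1\].}
#'   \item{mutual_information}{plug-in estimate on equal-frequency
#'     discretized data (ceiling(sqrt(n)) bins), nonnegative; in nats by
#'     default (`unit = "bits"` for log2). A general dependency measure with
#'     no sign.}
#'   \item{bray_curtis}{sum(|x-y|) / sum(x+y), in \[0, 1\]; requires
#'     nonnegative input.}
#'   \item{steinhaus}{the similarity 1 - bray_curtis.}
#'   \item{kullback_leibler}{symmetrized KL divergence
#'     (KL(p||q) + KL(q||p)) / 2 on pseudocounted, renormalized probability
#'     vectors; the pseudocount (smallest nonzero value of the pair, 1e-6
#'     fallback) avoids infinite terms at zeros.}
#'   \item{euclidean}{l2 distance.}
#'   \item{jaccard}{1 - |x AND y| / |x OR y| on presence/absence (numeric
#'     input auto-binarized at > 0).}
#'   \item{hypergeometric}{upper-tail probability of observing at least the
#'     seen co-presence count given the two presence marginals and n
#'     (incidence data; auto-binarized).}
#' }
#'
#' Vectors must be pairwise-complete (no NA) and of equal length. Constant
#' or too-short (n < 3) vectors make correlations unusable (NA); the
#' pipeline-level minimum of 3 complete samples per pair is enforced by
#' [pairwise_complete()]. Returns `NA_real_` for unusable pairs rather than
#' erroring.
#'
#' @param measure measure id.
#' @param x,y numeric vectors.
#' @param unit for mutual_information: `"nats"` (default) or `"bits"`.
#' @return a single numeric score, or `NA_real_` if unusable.
#' @export
compute_measure <- function(measure, x, y, unit = "nats") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("apply pairwise_complete() before scoring")
  # canonical argument order: every measure is mathematically symmetric, but
  # floating-point summation is not; fixing the order makes symmetry exact
  d <- which(x != y)
  if (length(d) > 0 && y[d[1L]] < x[d[1L]]) { tmp <- x; x <- y; y <- tmp }
  switch(measure,
    pearson = safe_cor(x, y, "pearson"),
    spearman = safe_cor(x, y, "spearman"),
    kendall = safe_cor(x, y, "kendall"),
    bray_curtis = bray_curtis(x, y),
    steinhaus = 1 - bray_curtis(x, y),
    kullback_leibler = kld_symmetric(x, y),
    euclidean = sqrt(sum((x - y)^2)),
    jaccard = jaccard_distance(x, y),
    hypergeometric = hypergeometric_copresence(x, y),
    mutual_information = mutual_information(x, y, unit = unit),
    stop("unknown measure: ", measure)
  )
}

safe_cor <- function(x, y, method) {
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  stats::cor(x, y, method = method)
}

bray_curtis <- function(x, y) {
  if (any(x < 0) || any(y < 0))
    stop("bray_curtis is not defined for negative values")
  tot <- sum(x + y)
  if (tot == 0) return(NA_real_)
  sum(abs(x - y)) / tot
}

kld_symmetric <- function(x, y) {
  if (any(x < 0) || any(y < 0))
    stop("kullback_leibler is not defined for negative values")
  nz <- c(x[x > 0], y[y > 0])
  pc <- if (length(nz) > 0) min(nz) else 1e-6
  p <- (x + pc) / sum(x + pc)
  q <- (y + pc) / sum(y + pc)
  0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
}

jaccard_distance <- function(x, y) {
  xb <- x > 0; yb <- y > 0
  u <- sum(xb | yb)
  if (u == 0) return(NA_real_)
  1 - sum(xb & yb) / u
}

hypergeometric_copresence <- function(x, y) {
  xb <- x > 0; yb <- y > 0
  n <- length(x)
  k <- sum(xb & yb)
  m1 <- sum(xb); m2 <- sum(yb)
  # P(X >= k) for X ~ Hypergeometric(m1 white, n - m1 black, m2 drawn)
  stats::phyper(k - 1L, m1, n - m1, m2, lower.tail = FALSE)
}

# Equal-frequency discretization into ceiling(sqrt(n)) bins (plug-in /
# maximum-likelihood entropy estimator). Ties broken by first occurrence so
# identical vectors discretize identically.
discretize_ef <- function(x, nbins) {
  r <- rank(x, ties.method = "first")
  ceiling(r * nbins / length(x))
}

mutual_information <- function(x, y, nbins = NULL, unit = "nats") {
  n <- length(x)
  if (is.null(nbins)) nbins <- ceiling(sqrt(n))
  bx <- discretize_ef(x, nbins); by <- discretize_ef(y, nbins)
  joint <- table(bx, by) / n
  px <- rowSums(joint); py <- colSums(joint)
  ind <- outer(px, py)
  nzero <- joint > 0
  mi <- sum(joint[nzero] * log(joint[nzero] / ind[nzero]))
  mi <- max(mi, 0)
  if (unit == "bits") mi / log(2) else mi
}

#' Score all eligible pairs under each selected measure
#'
#' Produces one score set per measure over exactly the eligible pairs.
#' Missing values are handled per pair via [pairwise_complete()]; pairs with
#' fewer than 3 complete samples, or degenerate for the measure (constant
#' vector for a correlation), get an `NA` score and are recorded as
#' unusable, never silently dropped.
#'
#' When the table is complete (no missing cells) the correlation measures
#' and the distance-based measures are computed matrix-wise for speed; the
#' result is identical to the per-pair path.
#'
#' @param table a preprocessed [abundance_table()].
#' @param measures character vector of measure ids.
#' @param pairs data.frame from [eligible_pairs()] (or any `a`/`b` pair
#'   frame over the table's rows).
#' @return named list of `score_set` objects, one per measure: each is a
#'   list with `measure`, `direction`, and `scores` (data.frame `a`, `b`,
#'   `score`).
#' @export
score_all_pairs <- function(table, measures, pairs) {
  if (nrow(pairs) == 0) stop("no eligible pairs to score")
  bad <- setdiff(measures, names(.MEASURES))
  if (length(bad) > 0) stop("unknown measure: ", bad[1L])
  v <- table$values
  complete <- !anyNA(v)
  out <- list()
  for (m in measures) {
    sc <- if (complete) score_pairs_fast(v, m, pairs)
          else score_pairs_slow(v, m, pairs)
    out[[m]] <- structure(
      list(measure = m, direction = measure_direction(m),
           scores = data.frame(a = pairs$a, b = pairs$b, score = sc,
                               stringsAsFactors = FALSE)),
      class = "score_set")
  }
  out
}

score_pairs_slow <- function(v, measure, pairs) {
  vapply(seq_len(nrow(pairs)), function(i) {
    pc <- pairwise_complete(v[pairs$a[i], ], v[pairs$b[i], ])
    if (!pc$usable) return(NA_real_)
    compute_measure(measure, pc$x, pc$y)
  }, numeric(1))
}

score_pairs_fast <- function(v, measure, pairs) {
  ia <- match(pairs$a, rownames(v)); ib <- match(pairs$b, rownames(v))
  if (measure %in% c("pearson", "spearman", "kendall")) {
    cm <- suppressWarnings(stats::cor(t(v), method = measure))
    sc <- cm[cbind(ia, ib)]
    const <- apply(v, 1L, stats::sd) == 0
    sc[const[ia] | const[ib]] <- NA_real_
    sc
  } else if (measure %in% c("bray_curtis", "steinhaus")) {
    man <- as.matrix(stats::dist(v, method = "manhattan"))
    rs <- rowSums(v)
    tot <- outer(rs, rs, "+")
    bc <- man[cbind(ia, ib)] / tot[cbind(ia, ib)]
    bc[tot[cbind(ia, ib)] == 0] <- NA_real_
    if (measure == "steinhaus") 1 - bc else bc
  } else if (measure == "euclidean") {
    eu <- as.matrix(stats::dist(v))
    eu[cbind(ia, ib)]
  } else {
    score_pairs_slow(v, measure, pairs)
  }
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("score_set '%s' (%s): %d pairs, %d unusable\n", x$measure,
              x$direction, nrow(x$scores), sum(is.na(x$scores$score))))
  invisible(x)
}
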