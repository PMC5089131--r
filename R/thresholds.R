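#' Turn a score set into signed edge candidates
#'
#' Manual mode applies fixed score thresholds; automatic mode selects the
#' top- and/or bottom-scoring `edge_number` pairs per measure (the threshold
#' is effectively the k-th order statistic). Sign assignment follows the
#' measure's direction:
#' \itemize{
#'   \item similarity measures: high scores are co-presence (positive), low
#'     scores mutual exclusion (negative);
#'   \item dissimilarity measures: reversed — the bottom of the distribution
#'     is co-presence, the top mutual exclusion;
#'   \item mutual information: top edges only, unsigned (no bottom tail has
#'     meaning for a dependency measure; `top_and_bottom` degrades to `top`
#'     with a message);
#'   \item hypergeometric: pairs at or below the p-value threshold `upper`
#'     (or the `edge_number` smallest p-values) are positive co-presence
#'     edges.
#' }
#' Ties at the k-th order statistic are broken by lexicographic pair id so
#' automatic mode returns exactly `edge_number` candidates per side,
#' deterministically. Unusable (NA) scores never become candidates.
#'
#' @param score_set one element of [score_all_pairs()]'s result.
#' @param mode `"manual"`, `"top"` or `"top_and_bottom"`.
#' @param edge_number number of edges per side for automatic modes.
#' @param upper,lower manual thresholds (for the hypergeometric measure,
#'   `upper` is the p-value cutoff).
#' @return data.frame of candidates: `a`, `b`, `measure`, `score`, `sign`
#'   (`"positive"`, `"negative"` or `"unsigned"`).
#' @export
select_edges <- function(score_set, mode = c("top_and_bottom", "top", "manual"),
                         edge_number = NULL, upper = NULL, lower = NULL) {
  mode <- match.arg(mode)
  sc <- score_set$scores
  usable <- sc[!is.na(sc$score), , drop = FALSE]
  dir <- score_set$direction
  key <- paste(usable$a, usable$b, sep = "\r")

  cand <- function(rows, sign) {
    if (length(rows) == 0) return(empty_candidate_frame())
    data.frame(a = usable$a[rows], b = usable$b[rows],
               measure = score_set$measure, score = usable$score[rows],
               sign = sign, stringsAsFactors = FALSE)
  }

  if (mode == "manual") {
    if (dir == "dependency") {
      if (is.null(upper)) stop("manual mode requires 'upper' for ",
                               score_set$measure)
      return(cand(which(usable$score >= upper), "unsigned"))
    }
    if (dir == "pvalue") {
      if (is.null(upper)) stop("manual mode requires a p-value 'upper' for ",
                               score_set$measure)
      return(cand(which(usable$score <= upper), "positive"))
    }
    if (!is.null(upper) && !is.null(lower) && upper < lower)
      stop("'upper' must be >= 'lower'")
    pos <- neg <- integer(0)
    if (dir == "similarity") {
      if (!is.null(upper)) pos <- which(usable$score >= upper)
      if (!is.null(lower)) neg <- which(usable$score <= lower)
    } else {  # dissimilarity: low score = co-presence
      if (!is.null(lower)) pos <- which(usable$score <= lower)
      if (!is.null(upper)) neg <- which(usable$score >= upper)
    }
    return(rbind(cand(pos, "positive"), cand(neg, "negative")))
  }

  # automatic modes
  if (is.null(edge_number) || edge_number < 1)
    stop("automatic threshold mode requires edge_number >= 1")
  if (edge_number > nrow(usable))
    stop(sprintf("edge_number (%d) exceeds usable pairs (%d) for measure %s",
                 edge_number, nrow(usable), score_set$measure))
  k <- edge_number
  # deterministic order statistics: score, then lexicographic pair id
  ord_desc <- order(-usable$score, key)
  ord_asc <- order(usable$score, key)
  top_rows <- ord_desc[seq_len(k)]
  bot_rows <- ord_asc[seq_len(k)]

  if (dir == "dependency") {
    if (mode == "top_and_bottom")
      message("top_and_bottom degrades to top for unsigned measure ",
              score_set$measure)
    return(cand(top_rows, "unsigned"))
  }
  if (dir == "pvalue") {
    if (mode == "top_and_bottom")
      message("top_and_bottom degrades to top (smallest p-values) for ",
              score_set$measure)
    return(cand(bot_rows, "positive"))
  }
  if (dir == "dissimilarity") { tmp <- top_rows; top_rows <- bot_rows; bot_rows <- tmp }
  out <- cand(top_rows, "positive")
  if (mode == "top_and_bottom") {
    neg <- cand(bot_rows, "negative")
    # a pair cannot credibly sit in both tails; drop any overlap from both
    overlap <- intersect(paste(out$a, out$b), paste(neg$a, neg$b))
    if (length(overlap) > 0) {
      out <- out[!paste(out$a, out$b) %in% overlap, , drop = FALSE]
      neg <- neg[!paste(neg$a, neg$b) %in% overlap, , drop = FALSE]
    }
    out <- rbind(out, neg)
  }
  out
}

empty_candidate_frame <- function() {
  data.frame(a = character(0), b = character(0), measure = character(0),
             score = numeric(0), sign = character(0), stringsAsFactors = FALSE)
}
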