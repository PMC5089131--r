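#' Assemble a multigraph from per-measure edge candidates
#'
#' One edge per (pair, measure); no merging, no voting. Useful for
#' inspecting which measures support which association before combining
#' them.
#'
#' @param candidates_by_measure named list of candidate data.frames from
#'   [select_edges()].
#' @return an [assoc_network] with `multigraph = TRUE`; edge rows carry
#'   `measure`, `score`, `sign`.
#' @export
build_multigraph <- function(candidates_by_measure) {
  if (length(candidates_by_measure) == 0) stop("no candidate sets")
  all <- do.call(rbind, unname(candidates_by_measure))
  edges <- data.frame(source = all$a, target = all$b, sign = all$sign,
                      weight = all$score, measure = all$measure,
                      score = all$score, stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target, edges$measure), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$source, edges$target)))
  assoc_network(nodes = data.frame(id = ids, stringsAsFactors = FALSE),
                edges = edges, multigraph = TRUE)
}

#' Merge per-measure candidates into a single voted network
#'
#' Majority voting via minimum support: a pair is retained when at least
#' `minsupport` measures proposed it (`intersection` means support by every
#' selected measure). Sign resolution: unsigned contributors (mutual
#' information) are neutral and the merged sign comes from the signed
#' contributors; if signed contributors disagree on the sign the edge is
#' discarded outright, whatever its support. Edge p/q-values computed by the
#' significance stage are attached when supplied.
#'
#' @param candidates_by_measure named list of candidate data.frames from
#'   [select_edges()] (or the significance-surviving subset of them).
#' @param minsupport minimum number of supporting measures.
#' @param intersection require support from all measures
#'   (overrides `minsupport`).
#' @param edge_pvalues optional data.frame `a`, `b`, `p`, `q` from the
#'   significance stage.
#' @return an [assoc_network]; edge rows carry `sign`, `weight`, `support`,
#'   `measures` (comma-joined), one `score_<measure>` column per measure,
#'   and `p`/`q` when available.
#' @export
merge_edges <- function(candidates_by_measure, minsupport = 1L,
                        intersection = FALSE, edge_pvalues = NULL) {
  k <- length(candidates_by_measure)
  if (k == 0) stop("no candidate sets")
  if (intersection) minsupport <- k
  if (minsupport > k)
    stop(sprintf("minsupport (%d) exceeds number of measures (%d)",
                 minsupport, k))
  measures <- names(candidates_by_measure)
  all <- do.call(rbind, unname(candidates_by_measure))
  if (nrow(all) == 0)
    return(assoc_network(nodes = data.frame(id = character(0),
                                            stringsAsFactors = FALSE),
                         edges = empty_edge_frame()))
  key <- paste(all$a, all$b, sep = "\r")
  rows <- split(seq_len(nrow(all)), key)
  out <- vector("list", length(rows))
  keep <- logical(length(rows))
  for (i in seq_along(rows)) {
    sub <- all[rows[[i]], , drop = FALSE]
    support <- length(unique(sub$measure))
    signs <- unique(sub$sign[sub$sign != "unsigned"])
    if (length(signs) > 1) next               # sign conflict: discard
    if (support < minsupport) next
    sign <- if (length(signs) == 1) signs else "unsigned"
    rec <- list(source = sub$a[1L], target = sub$b[1L], sign = sign,
                support = support,
                measures = paste(sort(unique(sub$measure)), collapse = ","))
    for (m in measures)
      rec[[paste0("score_", m)]] <-
        if (m %in% sub$measure) sub$score[match(m, sub$measure)] else NA_real_
    out[[i]] <- rec
    keep[i] <- TRUE
  }
  out <- out[keep]
  if (length(out) == 0)
    return(assoc_network(nodes = data.frame(id = character(0),
                                            stringsAsFactors = FALSE),
                         edges = empty_edge_frame()))
  edges <- do.call(rbind, lapply(out, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (!is.null(edge_pvalues)) {
    idx <- match(paste(edges$source, edges$target, sep = "\r"),
                 paste(edge_pvalues$a, edge_pvalues$b, sep = "\r"))
    edges$p <- edge_pvalues$p[idx]
    edges$q <- edge_pvalues$q[idx]
  }
  edges$weight <- vapply(seq_len(nrow(edges)), function(i)
    combined_edge_weight(edges[i, , drop = FALSE], measures), numeric(1))
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$source, edges$target)))
  assoc_network(nodes = data.frame(id = ids, stringsAsFactors = FALSE),
                edges = edges)
}

#' Combined display weight of a merged edge
#'
#' The merged, multiple-testing-corrected p-value (q) when the significance
#' stage ran — small q, strong edge — else the mean of the contributing
#' measures' similarity-oriented scores (dissimilarities negated so all
#' measures point the same way).
#'
#' @param edge_row one-row data.frame as produced by [merge_edges()].
#' @param measures measure ids whose `score_<measure>` columns may exist.
#' @return numeric weight.
#' @export
combined_edge_weight <- function(edge_row, measures) {
  if (!is.null(edge_row$q) && !is.na(edge_row$q)) return(edge_row$q)
  sc <- vapply(measures, function(m) {
    col <- paste0("score_", m)
    if (col %in% names(edge_row)) edge_row[[col]] else NA_real_
  }, numeric(1))
  mean(sc[!is.na(sc)])
}

#' Construct an association network
#'
#' Undirected network of objects with attribute-carrying nodes and signed,
#' weighted edges. After merging there are no self-loops and no parallel
#' edges; a multigraph (one edge per supporting measure) is marked as such.
#'
#' @param nodes data.frame with at least column `id` (unique).
#' @param edges data.frame with at least `source`, `target`; typically also
#'   `sign`, `weight`, `p`, `q`, `support`, `measures`, `score_*`.
#' @param multigraph whether parallel measure-specific edges are allowed.
#' @return object of class `assoc_network`.
#' @export
assoc_network <- function(nodes, edges = empty_edge_frame(),
                          multigraph = FALSE) {
  stopifnot(is.data.frame(nodes), "id" %in% names(nodes))
  if (anyDuplicated(nodes$id)) stop("duplicated node id")
  if (nrow(edges) > 0) {
    if (any(edges$source == edges$target)) stop("self-loop edge")
    missing <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing) > 0)
      stop("edge endpoint missing from node set: ", missing[1L])
    if (!multigraph && anyDuplicated(paste(edges$source, edges$target)))
      stop("parallel edges in a merged network")
  }
  structure(list(nodes = nodes, edges = edges, multigraph = multigraph),
            class = "assoc_network")
}

empty_edge_frame <- function() {
  data.frame(source = character(0), target = character(0),
             sign = character(0), weight = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("assoc_network%s: %d nodes, %d edges\n",
              if (x$multigraph) " (multigraph)" else "",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0 && "sign" %in% names(x$edges)) {
    tab <- table(x$edges$sign)
    cat("  signs:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Annotate nodes with degrees, abundance summaries and lineage ranks
#'
#' Adds per node: total degree, positive/negative/unsigned degree, total row
#' sum, prevalence (number of samples where the object was observed, i.e.
#' non-zero and not missing), node type (taxon / metadata / higher-level
#' rank), and one attribute per taxonomic rank from the row's lineage.
#' Idempotent. Nodes absent from the table keep bare attributes with a
#' warning.
#'
#' @param network an [assoc_network].
#' @param table the [abundance_table()] the network was inferred from.
#' @return annotated [assoc_network].
#' @export
annotate_nodes <- function(network, table) {
  nodes <- data.frame(id = network$nodes$id, stringsAsFactors = FALSE)
  e <- network$edges
  deg <- function(sign_filter = NULL) {
    ends <- c(e$source, e$target)
    if (!is.null(sign_filter) && nrow(e) > 0)
      ends <- c(e$source[e$sign %in% sign_filter],
                e$target[e$sign %in% sign_filter])
    tab <- table(ends)
    out <- rep(0L, nrow(nodes))
    out[match(names(tab), nodes$id)] <- as.integer(tab)
    out
  }
  nodes$degree <- deg()
  nodes$posdegree <- deg("positive")
  nodes$negdegree <- deg("negative")
  nodes$unsigneddegree <- deg("unsigned")
  v <- table$values
  idx <- match(nodes$id, rownames(v))
  if (anyNA(idx))
    warning("nodes absent from the table: ",
            paste(nodes$id[is.na(idx)], collapse = ", "))
  nodes$rowsum <- ifelse(is.na(idx), NA_real_,
                         rowSums(v, na.rm = TRUE)[idx])
  nodes$prevalence <- ifelse(is.na(idx), NA_integer_,
                             rowSums(v != 0 & !is.na(v))[idx])
  nodes$nodetype <- ifelse(is.na(idx), NA_character_, ifelse(
    table$group[idx] == "metadata", "metadata",
    ifelse(table$level[idx] %in% .RANKS, "highertaxon", "taxon")))
  nodes$level <- ifelse(is.na(idx), NA_character_, table$level[idx])
  for (rank in .RANKS) {
    vals <- vapply(seq_len(nrow(nodes)), function(i) {
      if (is.na(idx[i])) return(NA_character_)
      l <- table$lineage[[nodes$id[i]]]
      if (!is.null(l) && rank %in% names(l)) l[[rank]] else NA_character_
    }, character(1))
    if (any(!is.na(vals))) nodes[[rank]] <- vals
  }
  network$nodes <- nodes
  network
}

#' Keep only positive edges
#'
#' Removes negative edges and unsigned edges without positive support, then
#' drops isolated nodes. Used to expose co-presence cluster structure
#' (mutual-exclusion edges otherwise tie antagonistic clusters together).
#' Idempotent.
#'
#' @param network an [assoc_network] with signed edges.
#' @return filtered [assoc_network].
#' @export
filter_positive_edges <- function(network) {
  e <- network$edges
  if (nrow(e) > 0) e <- e[e$sign == "positive", , drop = FALSE]
  ids <- sort(unique(c(e$source, e$target)))
  nodes <- network$nodes[network$nodes$id %in% ids, , drop = FALSE]
  rownames(e) <- NULL; rownames(nodes) <- NULL
  out <- network
  out$nodes <- nodes
  out$edges <- e
  out
}
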