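#' Filter rows by minimum occurrence
#'
#' Removes rows observed (non-zero, non-missing) in fewer than `row_minocc`
#' samples. With `keep_sum`, a pseudo-row holding the column-wise sum of the
#' removed rows is appended (group `"filtered_sum"`); it never enters edge
#' inference but participates in column normalization and in permutation
#' renormalization, preserving the compositional denominator.
#'
#' @param table an [abundance_table()].
#' @param row_minocc minimum number of non-zero, non-missing cells per row.
#' @param keep_sum keep the sum of the filtered rows as a pseudo-row.
#' @return filtered [abundance_table()].
#' @export
filter_min_occurrence <- function(table, row_minocc, keep_sum = FALSE) {
  stopifnot(row_minocc >= 0)
  v <- table$values
  occ <- rowSums(v != 0 & !is.na(v))
  # metadata rows are not taxa; the occurrence filter does not apply to them
  keep <- occ >= row_minocc | table$group == "metadata"
  if (!any(keep)) stop("all rows removed by row_minocc = ", row_minocc)
  removed <- rownames(v)[!keep]
  out <- subset_table(table, rows = rownames(v)[keep])
  if (keep_sum && length(removed) > 0) {
    s <- colSums(v[removed, , drop = FALSE], na.rm = TRUE)
    out <- append_row(out, "filtered_sum", s, group = "filtered_sum",
                      level = "aggregate")
  }
  out
}

#' Divide each entry by its column sum
#'
#' Converts counts to relative abundances: each non-missing cell is divided
#' by the sum over the column's non-missing cells, so column sums become 1.
#' This corrects for sequencing-depth differences but makes the data
#' compositional, which the renormalized permutation null accounts for.
#'
#' @param table an [abundance_table()].
#' @return normalized [abundance_table()].
#' @export
normalize_columns <- function(table) {
  v <- table$values
  cs <- colSums(v, na.rm = TRUE)
  if (any(cs == 0))
    stop("zero-sum sample column: ", colnames(v)[cs == 0][1L])
  out <- table
  out$values <- sweep(v, 2L, cs, "/")
  out
}

#' Rarefy columns to a common depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads, the standard alternative to column normalization for
#' sequencing-depth correction. Requires integer counts.
#'
#' @param table an [abundance_table()] with integer counts (no missing
#'   values).
#' @param depth target depth per sample; default is the minimum column sum.
#' @param seed integer seed for reproducibility.
#' @return rarefied [abundance_table()].
#' @export
rarefy_columns <- function(table, depth = NULL, seed = 1L) {
  v <- table$values
  if (anyNA(v)) stop("rarefaction requires complete integer counts")
  if (any(v != round(v))) stop("rarefaction requires integer counts")
  cs <- colSums(v)
  if (is.null(depth)) depth <- min(cs)
  if (any(cs < depth))
    stop("column sum below rarefaction depth: ", colnames(v)[cs < depth][1L])
  set.seed(seed)
  out <- table
  for (j in seq_len(ncol(v))) {
    drawn <- sample(rep.int(seq_len(nrow(v)), v[, j]), depth)
    out$values[, j] <- tabulate(drawn, nbins = nrow(v))
  }
  out
}

#' Append higher-level taxon rows
#'
#' For each rank from kingdom down to genus and each taxon name observed at
#' that rank, appends a row equal to the column-wise sum of its member OTU
#' rows, carrying the truncated lineage and `level = rank`. Original feature
#' rows are relabelled `level = "OTU"`. Enables inference of links between
#' higher-level taxa (e.g. an order and a genus of different lineages);
#' combine with parent-child exclusion to prevent trivial within-lineage
#' edges.
#'
#' @param table an [abundance_table()] whose rows carry lineages.
#' @return augmented [abundance_table()].
#' @export
aggregate_higher_taxa <- function(table) {
  v <- table$values
  otu_ids <- rownames(v)[table$group %in% "default"]
  has_lin <- otu_ids[!vapply(table$lineage[otu_ids], is.null, logical(1)) &
                     lengths(table$lineage[otu_ids]) > 0]
  out <- table
  out$level[otu_ids] <- "OTU"
  if (length(has_lin) == 0) return(out)
  for (ri in seq_len(match("genus", .RANKS))) {
    rank <- .RANKS[ri]
    member_names <- vapply(table$lineage[has_lin], function(l) {
      if (rank %in% names(l)) l[[rank]] else NA_character_
    }, character(1))
    for (taxon in sort(unique(member_names[!is.na(member_names)]))) {
      members <- has_lin[!is.na(member_names) & member_names == taxon]
      agg <- colSums(v[members, , drop = FALSE], na.rm = TRUE)
      # truncated lineage of the first member defines the aggregate's path
      lin <- table$lineage[[members[1L]]]
      lin <- lin[names(lin) %in% .RANKS[seq_len(ri)]]
      id <- if (taxon %in% rownames(out$values))
        paste0(rank, "__", taxon) else taxon
      out <- append_row(out, id, agg, lineage = lin, group = "default",
                        level = rank)
    }
  }
  out
}

#' Parent-child relationship between two taxonomic paths
#'
#' Two rows are in a parent-child (ancestor-descendant) relationship when
#' one full taxonomic path is a proper prefix of the other; such pairs are
#' trivially correlated (the parent contains the child's counts) and are
#' excluded from inference when parent-child exclusion is on.
#'
#' @param path_a,path_b character vectors as returned by the internal path
#'   builder: the lineage truncated at the row's level, with feature rows
#'   additionally carrying their own id as last element.
#' @return logical flag.
#' @export
is_parent_child <- function(path_a, path_b) {
  la <- length(path_a); lb <- length(path_b)
  if (la == 0 || lb == 0 || la == lb) return(FALSE)
  n <- min(la, lb)
  identical(path_a[seq_len(n)], path_b[seq_len(n)])
}

#' Enumerate row pairs eligible for association scoring
#'
#' Applies the pair constraints: the object-group mode (`all`,
#' `between_groups_only` for bipartite networks, `within_groups_only`) and
#' optional parent-child exclusion. Sample-metadata rows are always eligible
#' to pair with taxon rows and with each other regardless of group mode; the
#' `filtered_sum` pseudo-row never pairs.
#'
#' @param table an [abundance_table()].
#' @param group_mode one of `"all"`, `"between_groups_only"`,
#'   `"within_groups_only"`.
#' @param parent_child_exclusion drop pairs within one taxonomic lineage.
#' @return data.frame with character columns `a`, `b` (a < b
#'   lexicographically).
#' @export
eligible_pairs <- function(table, group_mode = "all",
                           parent_child_exclusion = FALSE) {
  group_mode <- match.arg(group_mode,
                          c("all", "between_groups_only", "within_groups_only"))
  ids <- rownames(table$values)[table$group != "filtered_sum"]
  if (length(ids) < 2) stop("fewer than two scorable rows")
  ids <- sort(ids)
  cmb <- utils::combn(ids, 2L)
  a <- cmb[1L, ]; b <- cmb[2L, ]
  ga <- table$group[a]; gb <- table$group[b]
  is_meta <- ga == "metadata" | gb == "metadata"
  keep <- switch(group_mode,
                 all = rep(TRUE, length(a)),
                 between_groups_only = ga != gb,
                 within_groups_only = ga == gb)
  keep <- keep | is_meta
  if (parent_child_exclusion) {
    paths <- lapply(ids, function(id) lineage_path(table, id))
    names(paths) <- ids
    pc <- mapply(function(x, y) is_parent_child(paths[[x]], paths[[y]]), a, b)
    keep <- keep & !pc
  }
  data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE)
}

#' Reduce two value sequences to pairwise-complete positions
#'
#' Positions where either value is missing are dropped from both. Pairs with
#' fewer than 3 complete positions are unusable for scoring (correlation is
#' undefined below that).
#'
#' @param x,y equal-length numeric vectors, possibly with `NA`.
#' @return list with `x`, `y` (complete positions) and `usable` flag.
#' @export
pairwise_complete <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  list(x = x[ok], y = y[ok], usable = sum(ok) >= 3L)
}
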