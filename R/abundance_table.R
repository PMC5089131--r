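# Canonical taxonomic ranks, kingdom to species, plus greengenes-style
# single-letter prefixes used in QIIME-era lineage strings.
.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
.RANK_PREFIX <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                  f = "family", g = "genus", s = "species")

#' Construct an abundance table
#'
#' The central data container: an object-by-sample numeric matrix with
#' per-row metadata. Rows are the observed objects (OTUs, higher-level taxa,
#' sample-metadata variables), columns are samples. Cells hold nonnegative
#' abundances/counts or `NA` for missing observations.
#'
#' @param values numeric matrix with unique row and column names. `NA` marks
#'   a missing observation.
#' @param lineage optional named list mapping row ids to lineages (named
#'   character vectors as returned by [parse_lineage()]).
#' @param group optional named character vector of object groups per row;
#'   rows without an entry get group `"default"`. Group `"metadata"` marks
#'   sample-metadata rows, `"filtered_sum"` the pseudo-row holding the sum of
#'   filtered-out rows.
#' @param level optional named character vector of taxonomic levels per row;
#'   defaults to `"feature"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, lineage = NULL, group = NULL, level = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  rid <- rownames(values); cid <- colnames(values)
  if (is.null(rid) || is.null(cid))
    stop("'values' must have row and column names")
  if (anyDuplicated(rid))
    stop("duplicated row id: ", rid[duplicated(rid)][1L])
  if (anyDuplicated(cid))
    stop("duplicated column id: ", cid[duplicated(cid)][1L])
  if (any(values < 0, na.rm = TRUE))
    stop("abundance values must be nonnegative")
  grp <- rep("default", nrow(values)); names(grp) <- rid
  if (!is.null(group)) grp[names(group)] <- unname(group)
  lev <- rep("feature", nrow(values)); names(lev) <- rid
  if (!is.null(level)) lev[names(level)] <- unname(level)
  lin <- vector("list", nrow(values)); names(lin) <- rid
  if (!is.null(lineage)) lin[names(lineage)] <- lineage
  structure(list(values = values, lineage = lin, group = grp, level = lev),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  v <- x$values
  cat(sprintf("abundance_table: %d objects x %d samples\n", nrow(v), ncol(v)))
  nmiss <- sum(is.na(v))
  if (nmiss > 0) cat(sprintf("  missing cells: %d\n", nmiss))
  tab <- table(x$group)
  cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  nlin <- sum(!vapply(x$lineage, is.null, logical(1)))
  if (nlin > 0) cat(sprintf("  rows with lineage: %d\n", nlin))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

# Subset rows/columns keeping metadata aligned.
subset_table <- function(table, rows = NULL, cols = NULL) {
  v <- table$values
  if (is.null(rows)) rows <- rownames(v)
  if (is.null(cols)) cols <- colnames(v)
  abundance_table(v[rows, cols, drop = FALSE],
                  lineage = table$lineage[rows],
                  group = table$group[rows],
                  level = table$level[rows])
}

# Append one row (numeric vector over the table's samples).
append_row <- function(table, id, row, lineage = NULL, group = "default",
                       level = "feature") {
  v <- rbind(table$values, matrix(row, nrow = 1, dimnames = list(id, NULL)))
  lin <- table$lineage; lin[[id]] <- lineage
  grp <- c(table$group, structure(group, names = id))
  lev <- c(table$level, structure(level, names = id))
  abundance_table(v, lineage = lin, group = grp, level = lev)
}

#' Parse a taxonomic lineage string
#'
#' Accepts semicolon-separated lineages with or without greengenes-style rank
#' prefixes (`k__`, `p__`, `c__`, `o__`, `f__`, `g__`, `s__`). Prefix-less
#' tokens are assigned ranks positionally from kingdom downwards. Empty
#' tokens such as `"g__"` are dropped. The parser is lenient: an unparseable
#' string yields an empty lineage with a warning rather than an error.
#'
#' @param x a lineage string, or a character vector of per-rank names (as
#'   found in biom observation metadata).
#' @return named character vector; names are canonical ranks in order.
#' @examples
#' parse_lineage("k__Bacteria; p__Firmicutes; c__Bacilli")
#' parse_lineage("Bacteria;Firmicutes")
#' @export
parse_lineage <- function(x) {
  if (is.null(x) || length(x) == 0) return(empty_lineage())
  tokens <- if (length(x) > 1) as.character(x) else
    strsplit(as.character(x), ";", fixed = TRUE)[[1L]]
  tokens <- trimws(tokens)
  ranks <- character(0); nms <- character(0)
  pos <- 0L  # positional fallback cursor
  for (tok in tokens) {
    pos <- pos + 1L
    # rank prefix: single letter + one-or-two underscores (tolerates the
    # occasional "s_" typo seen in the wild)
    m <- regmatches(tok, regexec("^([kpcofgs])_{1,2}(.*)$", tok))[[1L]]
    if (length(m) == 3L) {
      rank <- .RANK_PREFIX[[m[2L]]]
      name <- trimws(m[3L])
    } else if (nzchar(tok) && pos <= length(.RANKS)) {
      rank <- .RANKS[pos]
      name <- tok
    } else next
    if (!nzchar(name)) next                  # empty token, e.g. "g__"
    if (rank %in% ranks) next                # no rank repeated
    ranks <- c(ranks, rank); nms <- c(nms, name)
  }
  if (length(ranks) == 0L) {
    if (any(nzchar(tokens)))
      warning("could not parse lineage: ", paste(x, collapse = ";"))
    return(empty_lineage())
  }
  ord <- order(match(ranks, .RANKS))
  structure(nms[ord], names = ranks[ord])
}

empty_lineage <- function() structure(character(0), names = character(0))

#' Render a lineage back to its canonical string form
#'
#' Inverse of [parse_lineage()] on its own output (idempotent round trip).
#' @param lineage named character vector of ranks.
#' @return single string with greengenes-style prefixes.
#' @export
format_lineage <- function(lineage) {
  if (is.null(lineage) || length(lineage) == 0) return("")
  pfx <- names(.RANK_PREFIX)[match(names(lineage), .RANK_PREFIX)]
  paste(paste0(pfx, "__", lineage), collapse = "; ")
}

# Full taxonomic path of a row, used by parent-child exclusion: the lineage
# truncated at the row's own level, with the row's name at that level as the
# last element. For feature-level rows (OTUs) the row id itself is appended,
# so two OTUs sharing a complete lineage remain distinguishable siblings.
lineage_path <- function(table, id) {
  lin <- table$lineage[[id]]
  if (is.null(lin) || length(lin) == 0) return(character(0))
  lev <- table$level[[id]]
  if (lev %in% .RANKS) {
    keep <- .RANKS[seq_len(match(lev, .RANKS))]
    unname(lin[names(lin) %in% keep])
  } else {
    c(unname(lin), id)
  }
}
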