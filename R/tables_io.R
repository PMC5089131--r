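# Tokens treated as missing values in TSV input (case-insensitive).
.NA_TOKENS <- c("", "na", "nan")

#' Read an object-by-sample table from TSV
#'
#' First row holds sample ids, first column object ids. Cells must be
#' numeric, empty, or an explicit NA token (`NA`/`NaN`, case-insensitive);
#' empty/NA cells become missing values.
#'
#' @param path path to a tab-delimited file.
#' @param transpose if `TRUE`, rows and columns are swapped before
#'   interpretation (the file's rows become samples).
#' @return an [abundance_table()].
#' @export
read_tsv_table <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  rid <- as.character(raw[[1L]])
  cid <- colnames(raw)[-1L]
  if (anyDuplicated(rid))
    stop("duplicated row id in ", path, ": ", rid[duplicated(rid)][1L])
  if (anyDuplicated(cid))
    stop("duplicated column id in ", path, ": ", cid[duplicated(cid)][1L])
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  dimnames(cells) <- list(rid, cid)
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                 dimnames = dimnames(cells)))
  bad <- is.na(vals) & !(tolower(trimws(cells)) %in% .NA_TOKENS)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 rid[w[1L]], cid[w[2L]], cells[w[1L], w[2L]]))
  }
  if (transpose) vals <- t(vals)
  abundance_table(vals)
}

#' Read a biom file (JSON 1.0 dialect)
#'
#' Observation ids become row ids, sample ids column ids. An observation
#' metadata field `taxonomy` (list of per-rank names or a semicolon string)
#' is parsed with [parse_lineage()] and stored as row lineage. Both dense and
#' sparse biom matrices are supported through the `biomformat` package; HDF5
#' biom files are read when the installed `biomformat` stack supports them.
#'
#' @param path path to a biom file.
#' @return an [abundance_table()] with lineages where provided.
#' @export
read_biom <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  b <- tryCatch(biomformat::read_biom(path),
                error = function(e) stop("malformed biom file '", path,
                                         "': ", conditionMessage(e)))
  vals <- as(biomformat::biom_data(b), "matrix")
  storage.mode(vals) <- "double"
  lin <- NULL
  om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  if (!is.null(om)) {
    # biomformat returns either a data.frame (taxonomy1..taxonomyN columns)
    # or a per-observation list of named vectors / lists
    tax_of <- function(meta) {
      tx <- NULL
      if (is.list(meta) && !is.null(meta[["taxonomy"]])) {
        tx <- unlist(meta[["taxonomy"]], use.names = FALSE)
      } else if (!is.null(names(meta)) &&
                 any(grepl("^taxonomy", names(meta)))) {
        tx <- unlist(meta[grepl("^taxonomy", names(meta))],
                     use.names = FALSE)
      } else if (is.character(meta) && is.null(names(meta))) {
        tx <- meta
      }
      tx <- tx[!is.na(tx)]
      if (length(tx) == 0) NULL else parse_lineage(tx)
    }
    ids <- if (is.data.frame(om)) rownames(om) else names(om)
    lin <- list()
    for (i in seq_along(ids)) {
      m <- if (is.data.frame(om)) unlist(om[i, , drop = FALSE]) else om[[i]]
      if (is.null(m)) next
      lx <- tax_of(m)
      if (!is.null(lx) && length(lx) > 0) lin[[ids[i]]] <- lx
    }
    if (length(lin) == 0) lin <- NULL
  }
  abundance_table(vals, lineage = lin)
}

#' Merge sample-metadata rows into an abundance table
#'
#' Converts a sample-metadata table (samples in rows after optional
#' transposition, variables in columns of the source file) into extra rows of
#' the main table, tagged with group `"metadata"`. With `match_samples`,
#' sample ids are aligned by name and samples absent from either side are
#' dropped (with a message); otherwise identical column order is required.
#'
#' @param table main [abundance_table()].
#' @param metadata_table an [abundance_table()] holding the metadata
#'   (typically from [read_tsv_table()] with `transpose = TRUE`).
#' @param match_samples align sample ids by name (intersection).
#' @return merged [abundance_table()].
#' @export
merge_feature_rows <- function(table, metadata_table, match_samples = FALSE) {
  main <- table$values; meta <- metadata_table$values
  if (match_samples) {
    common <- intersect(colnames(main), colnames(meta))
    if (length(common) == 0)
      stop("no overlapping samples between table and metadata")
    dropped <- (ncol(main) - length(common)) + (ncol(meta) - length(common))
    if (dropped > 0)
      message(sprintf("merge_feature_rows: dropped %d non-overlapping sample(s)",
                      dropped))
    main <- main[, common, drop = FALSE]
    meta <- meta[, common, drop = FALSE]
  } else {
    if (!identical(colnames(main), colnames(meta)))
      stop("sample ids differ; enable match_samples to align by name")
  }
  v <- rbind(main, meta)
  if (anyDuplicated(rownames(v)))
    stop("duplicated row id after merge: ",
         rownames(v)[duplicated(rownames(v))][1L])
  grp <- c(table$group[rownames(main)],
           structure(rep("metadata", nrow(meta)), names = rownames(meta)))
  lev <- c(table$level[rownames(main)],
           structure(rep("metadata", nrow(meta)), names = rownames(meta)))
  abundance_table(v, lineage = table$lineage[rownames(main)],
                  group = grp, level = lev)
}

#' Summarize input matrix properties with preprocessing recommendations
#'
#' Reports dimensions, sparsity, missing-value count and column-sum spread,
#' plus rule-based recommendations: unequal column sums suggest column
#' normalization (sequencing-depth correction); many mostly-zero rows suggest
#' a minimum-occurrence filter.
#'
#' @param table an [abundance_table()].
#' @return a list of class `matrix_properties` with fields `dims`,
#'   `zero_fraction`, `missing_count`, `min_col_sum`, `max_col_sum`,
#'   `recommendations` (character vector).
#' @export
matrix_properties <- function(table) {
  v <- table$values
  cs <- colSums(v, na.rm = TRUE)
  zero_frac <- mean(v == 0, na.rm = TRUE)
  if (is.nan(zero_frac)) zero_frac <- 0
  rec <- character(0)
  if (ncol(v) > 1 && max(cs) > 0 && (max(cs) - min(cs)) / max(cs) > 0.01)
    rec <- c(rec, "column sums are unequal: consider column normalization or rarefaction to correct for sampling depth")
  row_occ <- rowSums(v != 0, na.rm = TRUE)
  if (nrow(v) > 0 && mean(row_occ < ncol(v) / 2) > 0.25)
    rec <- c(rec, "many rows are mostly zero: consider a minimum-occurrence row filter")
  if (anyNA(v))
    rec <- c(rec, "missing values present: association scores will use pairwise-complete samples")
  structure(list(dims = dim(v), zero_fraction = zero_frac,
                 missing_count = sum(is.na(v)),
                 min_col_sum = min(cs), max_col_sum = max(cs),
                 recommendations = rec),
            class = "matrix_properties")
}

#' @export
print.matrix_properties <- function(x, ...) {
  cat(sprintf("matrix: %d x %d | zeros: %.1f%% | missing: %d | column sums: [%g, %g]\n",
              x$dims[1], x$dims[2], 100 * x$zero_fraction, x$missing_count,
              x$min_col_sum, x$max_col_sum))
  for (r in x$recommendations) cat(" -", r, "\n")
  invisible(x)
}

#' Import a network from an adjacency matrix
#'
#' Reads a square labelled numeric matrix (TSV); every nonzero off-diagonal
#' cell in the upper triangle becomes an undirected weighted edge. Symmetric
#' input is assumed; on asymmetry the upper triangle wins and a warning is
#' emitted.
#'
#' @param path path to a tab-delimited square matrix with matching row and
#'   column labels.
#' @return an [assoc_network] object.
#' @export
read_adjacency_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, header = TRUE, row.names = 1L,
                                   check.names = FALSE))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop(sprintf("adjacency matrix must be square, got %d x %d",
                 nrow(m), ncol(m)))
  if (!isTRUE(all.equal(unname(m[lower.tri(m)]), unname(t(m)[lower.tri(m)]))))
    warning("asymmetric adjacency matrix: using the upper triangle")
  ids <- rownames(m)
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  edges <- empty_edge_frame()
  if (nrow(idx) > 0) {
    edges <- data.frame(source = ids[idx[, 1L]], target = ids[idx[, 2L]],
                        sign = ifelse(m[idx] > 0, "positive", "negative"),
                        weight = m[idx], stringsAsFactors = FALSE)
  }
  assoc_network(nodes = data.frame(id = ids, stringsAsFactors = FALSE),
                edges = edges)
}
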