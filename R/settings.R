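# Known settings keys, their defaults, and types. One key per pipeline
# option; the command-line flags mirror these 1:1 (underscores -> dashes).
.SETTINGS_SPEC <- list(
  input              = list(default = "",        type = "character"),
  format             = list(default = "tsv",     type = "character"),
  transpose          = list(default = "false",   type = "logical"),
  features           = list(default = "",        type = "character"),
  match_samples      = list(default = "false",   type = "logical"),
  row_minocc         = list(default = "0",       type = "integer"),
  keep_filtered_sum  = list(default = "false",   type = "logical"),
  col_norm           = list(default = "false",   type = "logical"),
  rarefy_depth       = list(default = "",        type = "integer"),
  higher_taxa        = list(default = "false",   type = "logical"),
  parent_child_exclusion = list(default = "false", type = "logical"),
  group_mode         = list(default = "all",     type = "character"),
  measures           = list(default = "spearman", type = "character"),
  threshold_mode     = list(default = "top_and_bottom", type = "character"),
  edge_number        = list(default = "1000",    type = "integer"),
  upper              = list(default = "",        type = "numeric"),
  lower              = list(default = "",        type = "numeric"),
  resample           = list(default = "none",    type = "character"),
  iterations         = list(default = "100",     type = "integer"),
  renormalize        = list(default = "false",   type = "logical"),
  save_null          = list(default = "",        type = "character"),
  load_null          = list(default = "",        type = "character"),
  save_boot          = list(default = "",        type = "character"),
  load_boot          = list(default = "",        type = "character"),
  pmerge             = list(default = "none",    type = "character"),
  multitest          = list(default = "none",    type = "character"),
  q_threshold        = list(default = "0.05",    type = "numeric"),
  stability_filter   = list(default = "",        type = "numeric"),
  minsupport         = list(default = "1",       type = "integer"),
  multigraph         = list(default = "false",   type = "logical"),
  positive_only      = list(default = "false",   type = "logical"),
  output             = list(default = "",        type = "character"),
  output_format      = list(default = "edge_tsv", type = "character"),
  export_settings    = list(default = "",        type = "character"),
  seed               = list(default = "1",       type = "integer")
)

#' Default settings bundle
#'
#' A settings bundle is a flat named character vector covering every pipeline
#' option; it round-trips exactly through [write_settings()] /
#' [read_settings()] and can be rendered as a shell call with
#' [generate_command_line()].
#'
#' @return named character vector of all options at their defaults.
#' @export
default_settings <- function() {
  vapply(.SETTINGS_SPEC, function(s) s$default, character(1))
}

#' Write a settings bundle to a key=value file
#'
#' One `key=value` per line, `#` comments allowed, UTF-8.
#' @param settings named character vector (unknown keys rejected).
#' @param path output file.
#' @export
write_settings <- function(settings, path) {
  unknown <- setdiff(names(settings), names(.SETTINGS_SPEC))
  if (length(unknown) > 0)
    stop("unknown settings key: ", unknown[1L])
  lines <- paste0(names(settings), "=", unname(settings))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a settings bundle from a key=value file
#'
#' @param path settings file written by [write_settings()] (or by hand).
#' @return named character vector; keys absent from the file keep defaults.
#' @export
read_settings <- function(path) {
  if (!file.exists(path)) stop("settings file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- default_settings()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 1) stop("malformed settings line: ", ln)
    key <- substr(ln, 1L, eq - 1L)
    val <- substr(ln, eq + 1L, nchar(ln))
    if (!key %in% names(.SETTINGS_SPEC))
      stop("unknown settings key: ", key)
    out[[key]] <- val
  }
  out
}

#' Render a settings bundle as a command-line call
#'
#' Produces a runnable invocation of the package's command-line driver
#' (`inst/scripts/assocnet.R`) reproducing the run: every non-default option
#' appears as a `--flag value` pair (flags use dashes where keys use
#' underscores).
#'
#' @param settings named character vector of options.
#' @return single string.
#' @export
generate_command_line <- function(settings) {
  defaults <- default_settings()
  parts <- "Rscript assocnet.R"
  for (key in names(.SETTINGS_SPEC)) {
    val <- settings[[key]]
    if (is.null(val) || identical(val, defaults[[key]])) next
    flag <- paste0("--", gsub("_", "-", key, fixed = TRUE))
    if (.SETTINGS_SPEC[[key]]$type == "logical") {
      if (tolower(val) == "true") parts <- c(parts, flag)
    } else {
      parts <- c(parts, flag, shQuote(val))
    }
  }
  paste(parts, collapse = " ")
}

# Typed accessors for the string-valued bundle.
setting_chr <- function(settings, key) {
  v <- settings[[key]]
  if (is.null(v)) .SETTINGS_SPEC[[key]]$default else v
}
setting_lgl <- function(settings, key)
  tolower(setting_chr(settings, key)) %in% c("true", "t", "1", "yes")
setting_int <- function(settings, key) {
  v <- setting_chr(settings, key)
  if (!nzchar(v)) NULL else as.integer(v)
}
setting_num <- function(settings, key) {
  v <- setting_chr(settings, key)
  if (!nzchar(v)) NULL else as.numeric(v)
}
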