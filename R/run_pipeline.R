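#' Run the full pipeline from a settings bundle
#'
#' Settings-file / command-line face of [assocnet()]: reads the input table
#' (TSV or biom) and optional sample-metadata file, executes preprocessing,
#' scoring, thresholding, significance assessment, merging and annotation,
#' writes the requested outputs, and returns the fit together with a run
#' report. On failure an error report (error message plus the settings
#' snapshot) is written next to the output file before the error
#' propagates.
#'
#' The two-launch protocol is driven entirely by settings: launch one with
#' `resample=shuffle_rows`, `renormalize=true`, `save_null=FILE`; launch two
#' with `resample=bootstrap`, `load_null=FILE`, `pmerge=brown`,
#' `multitest=benjaminihochberg`. With both stores loaded the network is
#' regenerated without any resampling (see [quick_regenerate()]).
#'
#' @param settings named character vector as from [default_settings()] /
#'   [read_settings()].
#' @return invisibly, a list with `fit` (the [assocnet()] object) and
#'   `report`.
#' @export
run_pipeline <- function(settings) {
  full <- default_settings()
  full[names(settings)] <- settings
  settings <- full
  run <- function() {
    input <- setting_chr(settings, "input")
    if (!file.exists(input)) stop("input file not found: ", input)
    table <- switch(setting_chr(settings, "format"),
                    tsv = read_tsv_table(input,
                                         transpose = setting_lgl(settings,
                                                                 "transpose")),
                    biom = read_biom(input),
                    stop("unknown input format: ",
                         setting_chr(settings, "format")))
    metadata <- NULL
    feat <- setting_chr(settings, "features")
    if (nzchar(feat))
      metadata <- read_tsv_table(feat, transpose = TRUE)
    resample <- setting_chr(settings, "resample")
    significance <- switch(resample,
                           none = "none",
                           shuffle_rows = "permutation",
                           bootstrap = "reboot",
                           stop("unknown resample method: ", resample))
    # bootstrap significance needs a permutation null: either loaded or
    # (single-process run) computed alongside
    opt_path <- function(key) {
      v <- setting_chr(settings, key)
      if (nzchar(v)) v else NULL
    }
    fit <- assocnet(
      table,
      measures = strsplit(setting_chr(settings, "measures"), ",",
                          fixed = TRUE)[[1L]],
      metadata = metadata,
      match_samples = setting_lgl(settings, "match_samples"),
      row_minocc = setting_int(settings, "row_minocc"),
      keep_filtered_sum = setting_lgl(settings, "keep_filtered_sum"),
      col_norm = setting_lgl(settings, "col_norm"),
      rarefy_depth = setting_int(settings, "rarefy_depth"),
      higher_taxa = setting_lgl(settings, "higher_taxa"),
      parent_child_exclusion = setting_lgl(settings,
                                           "parent_child_exclusion"),
      group_mode = setting_chr(settings, "group_mode"),
      threshold_mode = setting_chr(settings, "threshold_mode"),
      edge_number = setting_int(settings, "edge_number"),
      upper = setting_num(settings, "upper"),
      lower = setting_num(settings, "lower"),
      significance = significance,
      iterations = setting_int(settings, "iterations"),
      renormalize = setting_lgl(settings, "renormalize"),
      pmerge = setting_chr(settings, "pmerge"),
      multitest = if (setting_chr(settings, "multitest") == "bh")
        "benjaminihochberg" else setting_chr(settings, "multitest"),
      q_threshold = setting_num(settings, "q_threshold"),
      stability_level = setting_num(settings, "stability_filter"),
      minsupport = setting_int(settings, "minsupport"),
      multigraph = setting_lgl(settings, "multigraph"),
      positive_only = setting_lgl(settings, "positive_only"),
      seed = setting_int(settings, "seed"),
      save_null = opt_path("save_null"), load_null = opt_path("load_null"),
      save_boot = opt_path("save_boot"), load_boot = opt_path("load_boot"))
    out <- setting_chr(settings, "output")
    if (nzchar(out))
      write_network(fit$network, out,
                    format = setting_chr(settings, "output_format"))
    exp <- setting_chr(settings, "export_settings")
    if (nzchar(exp)) write_settings(settings, exp)
    fit
  }
  fit <- tryCatch(run(), error = function(e) {
    out <- setting_chr(settings, "output")
    report_path <- if (nzchar(out)) paste0(out, ".error.txt")
      else file.path(tempdir(), "assocnet_error_report.txt")
    writeLines(c("assocnet error report",
                 paste0("error: ", conditionMessage(e)),
                 "settings:",
                 paste0("  ", names(settings), "=", unname(settings))),
               report_path)
    stop(conditionMessage(e), call. = FALSE)
  })
  fit$report$settings <- settings
  invisible(list(fit = fit, report = fit$report))
}

#' Quickly regenerate a network from saved resampling stores
#'
#' Once permutation and bootstrap distributions have been computed and
#' saved, the final network can be regenerated without any resampling —
#' e.g. to re-run with only positive edges kept, or a different voting or
#' correction setting — and is bit-identical to the original run where the
#' settings agree.
#'
#' @param settings settings bundle with both `load_null` and `load_boot`
#'   set.
#' @return the regenerated [assocnet()] fit (invisibly, within the
#'   [run_pipeline()] result list).
#' @export
quick_regenerate <- function(settings) {
  if (!nzchar(setting_chr(settings, "load_null")) ||
      !nzchar(setting_chr(settings, "load_boot")))
    stop("quick_regenerate needs both load_null and load_boot")
  settings[["resample"]] <- "bootstrap"
  run_pipeline(settings)
}
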