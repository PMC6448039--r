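#' Write / read a feature table as CSV with a JSON parameter sidecar
#'
#' The CSV holds the label columns (`animal`, `nerve`, `trial`) followed by
#' the 35 feature columns `e1_n1_latency` ... `e7_hf_integral`. Extraction
#' or generation parameters, when supplied, are written next to it as
#' `<path>.params.json`.
#'
#' @param table Feature table.
#' @param path Output CSV path.
#' @param params Optional named list of parameters for the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, params = NULL) {
  utils::write.csv(table, path, row.names = FALSE)
  if (!is.null(params))
    jsonlite::write_json(params, paste0(path, ".params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$nerve <- factor(tab$nerve, levels = NERVES)
  tab
}

#' Serialize a learnability result to JSON
#'
#' @param result A `learnability_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_learnability_result <- function(result, path) {
  out <- list(
    inputs = result$inputs,
    input_columns = result$input_columns,
    scheme = result$scheme,
    confusion = as.data.frame(result$confusion),
    fl_mean = result$fl_mean,
    fl_sem = result$fl_sem,
    per_animal_fl = as.list(result$per_animal_fl),
    n_repeats = result$n_repeats,
    n_trials = result$n_trials
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
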