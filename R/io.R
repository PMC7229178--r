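#' Read and write dimer-model parameter sets
#'
#' Parameter files hold three blocks, `I` (totals), `K` (binding constants)
#' and `alpha` (conductances), keyed by the usual subscripts, e.g.
#' `K: {K11: 14, K12: 19, ...}`. YAML (`.yml`/`.yaml`) and JSON (`.json`)
#' are supported, chosen by file extension.
#'
#' @param path file path.
#' @return `read_orai_params()`: list with `I`, `K`, `alpha` as validated
#'   parameter objects.
#' @export
read_orai_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("I", "K", "alpha")
  if (!all(need %in% names(raw))) {
    stop("parameter file must contain blocks: ", paste(need, collapse = ", "))
  }
  list(I = do.call(isoform_totals, as.list(raw$I[c("I1", "I2", "I3")])),
       K = do.call(binding_constants,
                   as.list(raw$K[c("K11", "K12", "K13", "K22", "K23", "K33")])),
       alpha = do.call(dimer_conductances,
                       as.list(raw$alpha[c("a11", "a12", "a13", "a22", "a23", "a33")])))
}

#' @rdname read_orai_params
#' @param params list with `I`, `K`, `alpha` (as from
#'   [orai_reference_params()]).
#' @export
write_orai_params <- function(params, path) {
  out <- list(I = as.list(unclass(params$I)),
              K = as.list(unclass(params$K)),
              alpha = as.list(unclass(params$alpha)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Read and write long-format trace tables
#'
#' The trace dialect shared by the generator and the classifier: one row
#' per sample with columns `cell_id`, `time_s`, `value`.
#'
#' @param path CSV file path.
#' @return `read_traces_csv()`: data.frame with the three columns.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_s", "value")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' @rdname read_traces_csv
#' @param traces data.frame with columns `cell_id`, `time_s`, `value`.
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(traces[c("cell_id", "time_s", "value")], path,
                   row.names = FALSE)
  invisible(path)
}
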