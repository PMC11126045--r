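#' Write / read a curve as CSV
#'
#' Two-column CSV (`time_min`, `value`) at full double precision.
#'
#' @param path File path.
#' @param values Curve values.
#' @param grid The [time_grid()] providing times.
#' @export
write_curve_csv <- function(path, values, grid = time_grid()) {
  df <- data.frame(time_min = format(grid$t, digits = 17),
                   value = format(values, digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_curve_csv
#' @return `read_curve_csv`: list with `time_min` and `value` vectors.
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  list(time_min = as.numeric(df$time_min), value = as.numeric(df$value))
}

#' Serialize a record or dataset to JSON
#'
#' Records are written with full double precision so that a save/load round
#' trip reproduces every field exactly. Datasets are stored as a manifest
#' (the generating [dataset_spec()], from which they can be regenerated
#' deterministically) plus, optionally, the records themselves.
#'
#' @param x A `curve_set` or `curve_dataset`.
#' @param path Output file (`.json`).
#' @param records For datasets: also embed all records (large)?
#' @export
save_json <- function(x, path, records = FALSE) {
  if (inherits(x, "curve_dataset") && !records) {
    x <- list(class = "curve_dataset_manifest", spec = unclass(x$spec),
              n = c(train = length(x$train), val = length(x$val),
                    test = length(x$test)))
  }
  writeLines(jsonlite::serializeJSON(x, digits = NA), path)
}

#' @rdname save_json
#' @return The deserialized object; a manifest is re-expanded through
#'   [make_dataset()] when the records were not embedded.
#' @export
load_json <- function(path) {
  x <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  if (is.list(x) && identical(x$class, "curve_dataset_manifest")) {
    spec <- do.call(dataset_spec, x$spec[setdiff(names(x$spec), NULL)])
    return(make_dataset(spec))
  }
  x
}

#' Save / load a trained network
#'
#' The fitted model (weights, history, configuration) is stored as a single
#' JSON file at full precision.
#'
#' @param object An [aif_lstm()] fit.
#' @param path File path (`.json`).
#' @export
save_model <- function(object, path) {
  writeLines(jsonlite::serializeJSON(object, digits = NA), path)
}

#' @rdname save_model
#' @return The restored `aif_lstm` object.
#' @export
load_model <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}
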