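#' Read and write trace tables as CSV
#'
#' The CSV schema is the trace-table schema shared by [simulate_axon()] and
#' [track()]: columns `frame`, `time_min`, `area_um2`, `intensity_au`,
#' `position_um`, `length_um`, `present` (plus any extra columns such as
#' `axon_id`, preserved as-is).
#'
#' @param trace A trace table (or a bound tibble of several, with an id
#'   column).
#' @param path File path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv` the
#'   tibble.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(trace, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("frame", "time_min", "area_um2", "intensity_au", "position_um",
            "length_um", "present")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("not a trace CSV; missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  class(tr) <- c("trace_table", class(tr))
  tr
}

#' Read and write axon ground truth as JSON sidecars
#'
#' @param truth An `axon_truth` object.
#' @param path File path.
#' @return `write_truth_json` returns `path` invisibly; `read_truth_json`
#'   the `axon_truth` list.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "axon_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$events <- tibble::as_tibble(as.data.frame(x$events))
  if (is.null(x$crossing_time_min)) x$crossing_time_min <- NA_real_
  structure(x, class = "axon_truth")
}
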