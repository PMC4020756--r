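#' Read a delimited signal matrix
#'
#' Reads channels x samples data from CSV or TSV (delimiter sniffed from
#' the first line unless given). A header row is detected and skipped
#' automatically.
#'
#' @param path file path.
#' @param sep field separator; NULL to sniff "," vs tab vs whitespace.
#' @return A \code{\link{signal_matrix}}.
#' @export
read_signal_matrix <- function(path, sep = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (grepl(",", first, fixed = TRUE)) ","
           else if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  }
  fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(fields[nzchar(fields)]))))
  m <- as.matrix(utils::read.table(path, sep = sep, header = header,
                                   comment.char = "#"))
  dimnames(m) <- NULL
  signal_matrix(m)
}

#' Read a one-row reference trace
#'
#' @param path delimited text file holding one row (or one column) of
#'   numbers.
#' @param sep field separator (sniffed when NULL).
#' @return A \code{\link{reference_signal}}.
#' @export
read_reference <- function(path, sep = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (grepl(",", first, fixed = TRUE)) ","
           else if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  }
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   comment.char = "#"))
  reference_signal(as.numeric(t(m)))
}

#' Write an extraction result to CSV (+ trace)
#'
#' Writes the extracted source as a one-row CSV, and optionally the
#' per-iteration trace (iteration, mu, delta, closeness, step angle).
#'
#' @param result an \code{"icar_extraction"}.
#' @param path output CSV path for the source.
#' @param trace_path optional CSV path for the iteration trace.
#' @export
write_extraction <- function(result, path, trace_path = NULL) {
  utils::write.table(matrix(result$source, nrow = 1), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(trace_path)) {
    tr <- data.frame(iteration = seq_along(result$mu_trace),
                     mu = result$mu_trace, delta = result$delta_trace,
                     closeness = result$closeness_trace,
                     theta = result$theta_trace)
    utils::write.csv(tr, trace_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a recovery report (sources CSV + JSON sidecar)
#'
#' @param report an \code{"icar_recovery"}.
#' @param sources_path CSV path, one recovered source per row.
#' @param sidecar_path JSON path for statuses, kurtosis, noise flags,
#'   threshold and iteration counts.
#' @export
write_recovery_report <- function(report, sources_path, sidecar_path) {
  if (!is.null(report$sources))
    utils::write.table(report$sources, sources_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  else file.create(sources_path)
  meta <- list(
    n_components = length(report$results),
    stop_reason = report$stop_reason,
    statuses = vapply(report$results, `[[`, "", "status"),
    iterations = vapply(report$results, `[[`, 0L, "iterations"),
    restarts = vapply(report$results, `[[`, 0L, "restarts"),
    xi = if (length(report$results)) report$results[[1]]$xi else NA,
    kurtosis = report$per_ic_kurtosis,
    noise_flags = report$noise_flags)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(sidecar_path)
}
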