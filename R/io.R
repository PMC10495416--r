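#' Read a segment from a delimited file
#'
#' One row per channel, one column per time point; comma- or tab-delimited,
#' no header by default. This is the on-disk exchange format for segments
#' (raw EDF/BDF parsing is out of scope; export preprocessed windows to
#' CSV first).
#'
#' @param path File path.
#' @param sampling_rate Hz.
#' @param channel_names Optional channel labels.
#' @param sep Field separator (`","` or `"\t"`); guessed from the file
#'   extension when `NULL` (`.tsv`/`.txt` -> tab, else comma).
#' @return An [eeg_segment()].
#' @export
read_segment <- function(path, sampling_rate = 256, channel_names = NULL,
                         sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  eeg_segment(m, sampling_rate = sampling_rate,
              channel_names = channel_names)
}

#' @rdname read_segment
#' @param segment An [eeg_segment()].
#' @export
write_segment <- function(segment, path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  utils::write.table(segment$values, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a labelled stream from a directory of segment files
#'
#' Expects a labels CSV with columns `file` and `label`; each `file` is a
#' delimited channels-by-time matrix relative to `dir`. Samples are taken
#' in the row order of the labels table.
#'
#' @param dir Directory containing the segment files.
#' @param labels_file Path to the labels CSV (default `labels.csv` in
#'   `dir`).
#' @param sampling_rate Hz for all segments.
#' @param channel_names Optional channel labels applied to every segment.
#' @return A stream tibble (`index`, `label`, `generator_class`, `segment`)
#'   as consumed by [run_online()] / [run_batch()].
#' @export
read_stream_dir <- function(dir, labels_file = file.path(dir, "labels.csv"),
                            sampling_rate = 256, channel_names = NULL) {
  lab <- utils::read.csv(labels_file, stringsAsFactors = FALSE)
  if (!all(c("file", "label") %in% names(lab))) {
    stop("Labels file must have columns `file` and `label`.", call. = FALSE)
  }
  segs <- purrr::map(lab$file, function(f) {
    read_segment(file.path(dir, f), sampling_rate = sampling_rate,
                 channel_names = channel_names)
  })
  out <- tibble::tibble(index = seq_len(nrow(lab)),
                        label = as.character(lab$label),
                        generator_class = as.character(lab$label),
                        segment = segs)
  class(out) <- c("onsnn_stream", class(out))
  out
}

#' Write a stream to a directory of segment CSVs plus labels.csv
#'
#' Inverse of [read_stream_dir()]; also the output format of the `simulate`
#' command-line verb.
#'
#' @param stream A stream tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stream_dir <- function(stream, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("sample_%03d.csv", stream$index)
  purrr::walk2(stream$segment, files, function(seg, f) {
    write_segment(seg, file.path(dir, f))
  })
  utils::write.csv(data.frame(file = files, label = stream$label),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Persist a run's artefacts
#'
#' Writes `outcomes.csv`, `trace.csv`, `repository.csv`, `repository.json`,
#' `weights.csv` and `summary.json` for an `onsnn_result` into `dir`.
#'
#' @param result An `onsnn_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_dir <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(result$trace, file.path(dir, "trace.csv"),
                   row.names = FALSE)
  write_repository_csv(result$repository, file.path(dir, "repository.csv"))
  write_repository_json(result$repository, file.path(dir, "repository.json"))
  write_weights_csv(result$weights, file.path(dir, "weights.csv"))
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
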