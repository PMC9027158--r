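#' Write and read delimited numeric matrices
#'
#' Plain tab-separated text, full double precision, no row names; the
#' header row carries channel (column) names.  Writing then reading
#' reproduces values exactly.
#'
#' @param x numeric matrix.
#' @param path file path.
#' @return \code{read_matrix_file} returns a numeric matrix.
#' @export
write_matrix_file <- function(x, path) {
  x <- as.matrix(x)
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !is.null(colnames(x)))
  invisible(path)
}

#' @rdname write_matrix_file
#' @param header whether the file has a header row (default TRUE).
#' @export
read_matrix_file <- function(path, header = TRUE) {
  df <- tryCatch(
    utils::read.table(path, header = header, sep = "\t",
                      colClasses = "numeric", check.names = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  as.matrix(df)
}

#' Write a dataset of records plus manifest to a directory
#'
#' One delimited matrix per record (rows = samples, columns = channels)
#' and a \code{manifest.csv} with columns
#' \code{path, subject_id, label, fs, channels} (channels
#' semicolon-separated).
#'
#' @param records list of [signal_record()] objects.
#' @param dir output directory, created if needed.
#' @return path of the written manifest.
#' @export
write_dataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    fname <- paste0(r$subject_id, ".tsv")
    write_matrix_file(r$samples, file.path(dir, fname))
    data.frame(path = fname, subject_id = r$subject_id, label = r$label,
               fs = r$fs, channels = paste(r$channel_names, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load records listed in a manifest
#'
#' @param manifest_path path to a \code{manifest.csv} written by
#'   [write_dataset()] (columns \code{path, subject_id, label, fs,
#'   channels}); record paths are resolved relative to the manifest.
#' @return list of [signal_record()] objects.
#' @export
load_records <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("path", "subject_id", "label", "fs", "channels")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(manifest$subject_id)) {
    stop("manifest has duplicate subject_id rows", call. = FALSE)
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- read_matrix_file(file.path(base, manifest$path[i]))
    signal_record(m, fs = manifest$fs[i],
                  subject_id = manifest$subject_id[i],
                  label = manifest$label[i],
                  channel_names = strsplit(manifest$channels[i], ";")[[1L]])
  })
}

#' Write a machine-readable pipeline report
#'
#' JSON with the configuration (including every seed), per-channel
#' selected sizes and metrics, and voted results per validation scheme.
#'
#' @param pipeline a \code{cgp_pipeline} from [run_pipeline()].
#' @param path output path.
#' @export
write_report <- function(pipeline, path) {
  stopifnot(inherits(pipeline, "cgp_pipeline"))
  voting <- lapply(pipeline$voting, function(v) {
    list(channel_order = v$channel_order,
         sizes = v$sizes, voted_accuracy = v$voted_accuracy,
         best_c = v$best_c,
         metrics = v$metrics[c("acc", "sen", "spe", "geo")])
  })
  rep <- list(
    config = unclass(pipeline$config),
    n_segments = length(pipeline$labels),
    n_subjects = length(unique(pipeline$subjects)),
    channel_table = pipeline$channel_table,
    voting = voting,
    timings = as.list(pipeline$timings))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
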