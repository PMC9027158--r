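#' Multichannel signal record
#'
#' Container for one subject's recording: a numeric sample matrix
#' (time x channels), the sampling rate, a subject identifier, a class
#' label (0 = control, 1 = case) and channel names.
#'
#' @param samples numeric matrix, rows = samples, columns = channels.
#' @param fs sampling rate in Hz, positive.
#' @param subject_id scalar identifier.
#' @param label class label, 0 or 1.
#' @param channel_names optional character vector, one per column.
#' @return an object of class \code{signal_record}.
#' @export
signal_record <- function(samples, fs, subject_id, label,
                          channel_names = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (anyNA(samples)) stop("samples contain missing values", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  if (ncol(samples) < 1L) stop("need at least one channel", call. = FALSE)
  if (!label %in% c(0, 1)) stop("label must be 0 or 1", call. = FALSE)
  if (is.null(channel_names)) {
    channel_names <- colnames(samples)
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(ncol(samples)))
    }
  }
  if (length(channel_names) != ncol(samples)) {
    stop("channel_names length must match channel count", call. = FALSE)
  }
  colnames(samples) <- channel_names
  structure(
    list(samples = samples, fs = fs,
         subject_id = as.character(subject_id),
         label = as.integer(label), channel_names = channel_names),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat("signal_record: subject", x$subject_id,
      "| label", x$label,
      "|", nrow(x$samples), "samples x", ncol(x$samples), "channels @",
      x$fs, "Hz\n")
  invisible(x)
}

#' Split a record into fixed-length, non-overlapping segments
#'
#' Consecutive windows of exactly \code{segment_len} samples are cut from
#' every channel; a trailing remainder shorter than one segment is
#' discarded.  At 250 Hz the default 6250 samples correspond to 25 s
#' epochs.
#'
#' @param record a [signal_record()].
#' @param segment_len segment length in samples (default 6250).
#' @return a list with \code{segments} (list over channels, each a
#'   numeric matrix segment_len x n_segments), \code{n_segments},
#'   \code{subject_id}, \code{label}.  If the record is shorter than one
#'   segment, \code{n_segments} is 0 and a warning is raised.
#' @export
segment_record <- function(record, segment_len = 6250L) {
  stopifnot(inherits(record, "signal_record"))
  segment_len <- as.integer(segment_len)
  if (segment_len < 1L) stop("segment_len must be positive", call. = FALSE)
  n <- nrow(record$samples)
  k <- n %/% segment_len
  if (k == 0L) {
    warning("record shorter than one segment; no segments produced",
            call. = FALSE)
  }
  keep <- seq_len(k * segment_len)
  segs <- lapply(seq_len(ncol(record$samples)), function(ch) {
    if (k == 0L) {
      matrix(numeric(0), nrow = segment_len, ncol = 0)
    } else {
      matrix(record$samples[keep, ch], nrow = segment_len, ncol = k)
    }
  })
  names(segs) <- record$channel_names
  list(segments = segs, n_segments = k,
       subject_id = record$subject_id, label = record$label)
}

#' Maximum absolute pooling
#'
#' Downsample a signal by taking the largest absolute value in each
#' consecutive non-overlapping block of \code{b} samples; a trailing
#' partial block is dropped.
#'
#' @param signal numeric vector.
#' @param b block size, \code{1 <= b <= length(signal)}.
#' @return numeric vector of length \code{floor(length(signal)/b)}.
#' @examples
#' map_pool(c(1, -3, 2, 5), 2)  # 3 5
#' @export
map_pool <- function(signal, b) {
  b <- as.integer(b)
  if (b < 1L) stop("block size b must be >= 1", call. = FALSE)
  n <- length(signal)
  if (b > n) stop("block size b exceeds signal length", call. = FALSE)
  k <- n %/% b
  a <- abs(signal[seq_len(k * b)])
  if (b == 1L) return(a)
  apply(matrix(a, nrow = b, ncol = k), 2L, max)
}

#' Single-level pattern histogram features
#'
#' Slides a window of length \code{p-1} with stride 1 over the signal.
#' In every window, each pattern compares its \code{bit_width}
#' center-symmetric position pairs: bit \code{k} is 1 when the value at
#' the pair's first position minus the value at its second position is
#' \code{>= 0}, else 0.  The bits form a code in
#' \code{0..2^bit_width - 1}; codes are histogrammed per pattern and the
#' histograms concatenated in group order.
#'
#' @param signal numeric vector, length at least \code{p-1}.
#' @param patterns a \code{cgp_pattern_set} from [build_pattern_pairs()].
#' @return integer vector of length \code{H * 2^bit_width} (2048 for
#'   p = 17); per-pattern histogram counts summing to the window count
#'   \code{length(signal) - p + 2}.
#' @export
cgp_extract <- function(signal, patterns) {
  stopifnot(inherits(patterns, "cgp_pattern_set"))
  p <- patterns$p
  wlen <- p - 1L
  n <- length(signal)
  if (n < wlen) {
    stop("signal shorter than one window (need >= ", wlen, " samples)",
         call. = FALSE)
  }
  nw <- n - wlen + 1L
  nbin <- 2L^patterns$bit_width
  h_count <- nrow(patterns$left)
  weights <- 2^(seq_len(patterns$bit_width) - 1L)
  idx0 <- 0:(nw - 1L)
  out <- integer(h_count * nbin)
  for (h in seq_len(h_count)) {
    codes <- numeric(nw)
    for (k in seq_len(patterns$bit_width)) {
      codes <- codes +
        weights[k] * (signal[idx0 + patterns$left[h, k]] >=
                        signal[idx0 + patterns$right[h, k]])
    }
    out[(h - 1L) * nbin + seq_len(nbin)] <- tabulate(codes + 1L, nbin)
  }
  out
}

#' Multilevel merged pattern features
#'
#' Decomposes the raw signal by maximum absolute pooling with block sizes
#' 2, 4 and 8 (each applied to the raw signal, not cascaded), extracts
#' single-level features from the raw signal and the three pooled
#' signals, and concatenates them raw, D1, D2, D3.
#'
#' @param signal numeric vector of length at least 128 so the coarsest
#'   level still spans one window.
#' @param patterns a \code{cgp_pattern_set}.
#' @param map_blocks pooling block sizes (default \code{c(2, 4, 8)}).
#' @return integer vector of length \code{(1 + length(map_blocks)) * H *
#'   2^bit_width} (8192 for p = 17 with the default blocks).
#' @export
extract_multilevel <- function(signal, patterns, map_blocks = c(2L, 4L, 8L)) {
  wlen <- patterns$p - 1L
  need <- max(map_blocks) * wlen
  if (length(signal) < need) {
    stop("signal too short for level with block size ", max(map_blocks),
         ": need >= ", need, " samples", call. = FALSE)
  }
  levels <- c(list(signal), lapply(map_blocks, function(b) map_pool(signal, b)))
  unlist(lapply(levels, cgp_extract, patterns = patterns), use.names = FALSE)
}

#' Per-channel feature matrices for a set of records
#'
#' Segments every record and extracts the merged multilevel feature
#' vector of each segment, per channel.
#'
#' @param records list of [signal_record()] objects with identical
#'   channel layout.
#' @param patterns a \code{cgp_pattern_set}.
#' @param segment_len segment length in samples.
#' @param map_blocks pooling block sizes.
#' @return list with \code{features} (list over channels of numeric
#'   matrices, rows = segments), \code{labels}, \code{subjects} (one
#'   entry per segment, shared across channels) and \code{channel_names}.
#' @export
extract_feature_matrix <- function(records, patterns, segment_len = 6250L,
                                   map_blocks = c(2L, 4L, 8L)) {
  stopifnot(length(records) >= 1L)
  ch_names <- records[[1L]]$channel_names
  segd <- lapply(records, segment_record, segment_len = segment_len)
  labels <- unlist(lapply(segd, function(s) rep(s$label, s$n_segments)))
  subjects <- unlist(lapply(segd, function(s) rep(s$subject_id, s$n_segments)))
  feats <- lapply(seq_along(ch_names), function(ch) {
    rows <- lapply(segd, function(s) {
      if (s$n_segments == 0L) return(NULL)
      t(apply(s$segments[[ch]], 2L, extract_multilevel,
              patterns = patterns, map_blocks = map_blocks))
    })
    do.call(rbind, rows)
  })
  names(feats) <- ch_names
  list(features = feats, labels = as.integer(labels),
       subjects = as.character(subjects), channel_names = ch_names)
}
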