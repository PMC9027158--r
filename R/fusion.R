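#' Iterative hard majority voting across channel predictions
#'
#' Channels are ranked by their individual accuracy (ties toward the
#' lower channel index).  For every ensemble size c from \code{c_min} up
#' to the channel count, the top-c channels vote per segment by the mode
#' of their predicted labels (mode ties toward the smallest label value),
#' and the size with the highest voted accuracy is kept (ties toward the
#' smallest c).
#'
#' @param preds matrix of predicted labels, rows = segments, columns =
#'   channels (or a list of equal-length label vectors).
#' @param truth true labels, one per segment.
#' @param c_min smallest ensemble size to evaluate (default 3).
#' @param positive positive-class label for the reported metrics.
#' @return object of class \code{cgp_voting}: list with
#'   \code{channel_order} (descending accuracy), \code{channel_accuracy}
#'   (in input order), \code{sizes}, \code{voted_accuracy} per size,
#'   \code{best_c}, \code{voted_labels} at \code{best_c} and
#'   \code{metrics} (a \code{cgp_metrics}).
#' @export
ihmv <- function(preds, truth, c_min = 3L, positive = 1L) {
  if (is.list(preds) && !is.matrix(preds)) {
    lens <- lengths(preds)
    if (length(unique(lens)) != 1L) {
      stop("channels predict different segment counts", call. = FALSE)
    }
    preds <- do.call(cbind, preds)
  }
  preds <- as.matrix(preds)
  if (nrow(preds) != length(truth)) {
    stop("prediction rows and truth length differ", call. = FALSE)
  }
  n_ch <- ncol(preds)
  c_min <- as.integer(c_min)
  if (n_ch < c_min) {
    stop("need at least c_min = ", c_min, " channels", call. = FALSE)
  }
  ch_acc <- colMeans(preds == truth)
  ord <- order(-ch_acc)  # stable: ties keep lower channel index first
  sizes <- c_min:n_ch
  voted <- lapply(sizes, function(cc) {
    label_mode_rows(preds[, ord[seq_len(cc)], drop = FALSE])
  })
  acc <- vapply(voted, function(v) mean(v == truth), numeric(1))
  best_i <- which.max(acc)  # ties -> smallest c (first index)
  best_labels <- voted[[best_i]]
  structure(
    list(channel_order = ord,
         channel_accuracy = ch_acc,
         sizes = sizes,
         voted_accuracy = acc,
         best_c = sizes[best_i],
         voted_labels = best_labels,
         metrics = compute_metrics(
           confusion_counts(truth, best_labels, positive))),
    class = "cgp_voting"
  )
}

#' @export
print.cgp_voting <- function(x, ...) {
  cat("Iterative hard majority voting over", length(x$channel_accuracy),
      "channels\n")
  cat("  best ensemble size:", x$best_c,
      sprintf("(voted accuracy %.2f%%)\n", 100 * max(x$voted_accuracy)))
  print(x$metrics)
  invisible(x)
}

# per-row mode of integer labels; ties -> smallest label value
label_mode_rows <- function(m) {
  vals <- sort(unique(as.vector(m)))
  counts <- vapply(vals, function(v) rowSums(m == v), numeric(nrow(m)))
  counts <- matrix(counts, nrow = nrow(m))
  vals[max.col(counts, ties.method = "first")]
}
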