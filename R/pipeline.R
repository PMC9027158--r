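#' Pipeline configuration
#'
#' Bundles every tunable of the classification pipeline with its default:
#' modulus 17 (eight patterns, 8-bit codes), 25 s segments at 250 Hz
#' (6250 samples), pooling blocks 2/4/8, candidate subset range 100-1000,
#' 1-NN with 10 folds, voting from 3 channels up, positive class 1.
#'
#' @param p prime modulus for the pattern generator.
#' @param segment_len segment length in samples.
#' @param map_blocks pooling block sizes.
#' @param inca_low,inca_high candidate subset-size range.
#' @param folds cross-validation folds.
#' @param c_min smallest voting ensemble.
#' @param schemes validation schemes to run, subset of
#'   \code{c("10fold", "loso")}.
#' @param positive positive-class label for sensitivity/specificity.
#' @param seed master seed; per-channel and per-stage seeds are derived
#'   from it.
#' @param nca_max_iter NCA gradient iterations.
#' @return list of class \code{cgp_config}.
#' @export
pipeline_config <- function(p = 17L, segment_len = 6250L,
                            map_blocks = c(2L, 4L, 8L),
                            inca_low = 100L, inca_high = 1000L,
                            folds = 10L, c_min = 3L,
                            schemes = c("10fold", "loso"),
                            positive = 1L, seed = 1L, nca_max_iter = 60L) {
  schemes <- match.arg(schemes, c("10fold", "loso"), several.ok = TRUE)
  structure(
    list(p = as.integer(p), segment_len = as.integer(segment_len),
         map_blocks = as.integer(map_blocks),
         inca_low = as.integer(inca_low), inca_high = as.integer(inca_high),
         folds = as.integer(folds), c_min = as.integer(c_min),
         schemes = schemes, positive = positive,
         seed = as.integer(seed), nca_max_iter = as.integer(nca_max_iter)),
    class = "cgp_config"
  )
}

#' Run the full channel-wise classification pipeline
#'
#' Segments every record, extracts merged multilevel pattern features per
#' channel, selects features per channel by iterative NCA, classifies with
#' 1-NN under the configured validation schemes, and fuses the per-channel
#' prediction vectors by iterative hard majority voting.
#'
#' @param records list of [signal_record()] objects sharing a channel
#'   layout, e.g. from [simulate_dataset()] or [load_records()].
#' @param config a [pipeline_config()].
#' @param verbose log stage progress to stderr (default FALSE).
#' @return object of class \code{cgp_pipeline}: list with
#'   \code{channels} (per-channel list: selection, predictions and
#'   metrics per scheme), \code{channel_table} (data frame of per-channel
#'   metrics), \code{voting} (per scheme, a \code{cgp_voting}),
#'   \code{labels}, \code{subjects}, \code{config}, \code{timings}.
#' @export
run_pipeline <- function(records, config = pipeline_config(),
                         verbose = FALSE) {
  stopifnot(inherits(config, "cgp_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()

  t0 <- tic()
  patterns <- build_pattern_pairs(generate_group_table(config$p))
  fx <- extract_feature_matrix(records, patterns,
                               segment_len = config$segment_len,
                               map_blocks = config$map_blocks)
  timings["extract"] <- tic() - t0
  say("extracted %d segments x %d features on %d channels (%.1fs)",
      length(fx$labels), ncol(fx$features[[1L]]),
      length(fx$features), timings[["extract"]])
  if (length(fx$labels) == 0L) stop("no segments extracted", call. = FALSE)

  n_ch <- length(fx$features)
  channels <- vector("list", n_ch)
  names(channels) <- fx$channel_names
  t0 <- tic()
  for (ch in seq_len(n_ch)) {
    res <- tryCatch({
      sel <- inca_select(fx$features[[ch]], fx$labels,
                         low = config$inca_low, high = config$inca_high,
                         seed = config$seed + ch, folds = config$folds,
                         nca_max_iter = config$nca_max_iter)
      Xs <- fx$features[[ch]][, sel$chosen_indices, drop = FALSE]
      out <- list(selection = sel, cv = list(), metrics = list())
      for (sc in config$schemes) {
        cv <- if (sc == "10fold") {
          crossval_10fold(Xs, fx$labels,
                          seed = config$seed + 10000L + ch,
                          folds = config$folds, subjects = fx$subjects)
        } else {
          crossval_loso(Xs, fx$labels, fx$subjects)
        }
        out$cv[[sc]] <- cv
        out$metrics[[sc]] <- compute_metrics(cv, positive = config$positive)
      }
      out
    }, error = function(e) {
      stop("channel ", fx$channel_names[ch], ", selection/classification: ",
           conditionMessage(e), call. = FALSE)
    })
    channels[[ch]] <- res
    say("channel %s: %d features, %s", fx$channel_names[ch],
        res$selection$chosen_size,
        paste(vapply(config$schemes, function(sc)
          sprintf("%s acc %.1f%%", sc, 100 * res$metrics[[sc]]$acc),
          character(1)), collapse = ", "))
  }
  timings["channels"] <- tic() - t0

  t0 <- tic()
  voting <- list()
  for (sc in config$schemes) {
    preds <- vapply(channels, function(x) x$cv[[sc]]$prediction,
                    integer(length(fx$labels)))
    voting[[sc]] <- ihmv(preds, fx$labels, c_min = config$c_min,
                         positive = config$positive)
  }
  timings["voting"] <- tic() - t0

  ch_table <- do.call(rbind, lapply(seq_len(n_ch), function(ch) {
    rows <- lapply(config$schemes, function(sc) {
      m <- channels[[ch]]$metrics[[sc]]
      data.frame(channel = fx$channel_names[ch], scheme = sc,
                 n_features = channels[[ch]]$selection$chosen_size,
                 acc = m$acc, sen = m$sen, spe = m$spe, geo = m$geo,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))

  structure(
    list(channels = channels, channel_table = ch_table, voting = voting,
         labels = fx$labels, subjects = fx$subjects,
         channel_names = fx$channel_names,
         config = config, timings = timings),
    class = "cgp_pipeline"
  )
}

#' @export
print.cgp_pipeline <- function(x, ...) {
  cat("Channel-wise pattern classification pipeline\n")
  cat("  ", length(x$channel_names), "channels,", length(x$labels),
      "segments,", length(unique(x$subjects)), "subjects\n")
  for (sc in names(x$voting)) {
    v <- x$voting[[sc]]
    cat(sprintf("  %s: best channel acc %.2f%%, voted acc %.2f%% (c = %d)\n",
                sc, 100 * max(v$channel_accuracy),
                100 * max(v$voted_accuracy), v$best_c))
  }
  invisible(x)
}

#' @export
summary.cgp_pipeline <- function(object, ...) {
  tab <- object$channel_table
  tab[c("acc", "sen", "spe", "geo")] <-
    lapply(tab[c("acc", "sen", "spe", "geo")], function(v) round(100 * v, 2))
  cat("Per-channel results (%):\n")
  print(tab, row.names = FALSE)
  cat("\nVoted results (%):\n")
  for (sc in names(object$voting)) {
    v <- object$voting[[sc]]
    m <- v$metrics
    cat(sprintf("  %-6s c = %-2d acc %.2f sen %.2f spe %.2f geo %.2f\n",
                sc, v$best_c, 100 * m$acc, 100 * m$sen, 100 * m$spe,
                100 * m$geo))
  }
  invisible(object)
}
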