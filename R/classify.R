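#' 1-nearest-neighbor prediction on standardized features
#'
#' Both sets are standardized column-wise using the training mean and
#' standard deviation (zero-variance columns get a unit divisor), and each
#' test point receives the label of its Euclidean-nearest training point.
#' Exact distance ties go to the training sample with the lowest index.
#'
#' @param train_X,train_y training feature matrix and labels.
#' @param test_X test feature matrix with matching columns.
#' @param standardize standardize by training statistics (default TRUE).
#' @return vector of predicted labels, one per test row.
#' @export
knn_predict <- function(train_X, train_y, test_X, standardize = TRUE) {
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X)
  if (nrow(train_X) == 0L) stop("empty training set", call. = FALSE)
  if (ncol(train_X) != ncol(test_X)) {
    stop("train and test feature dimensions differ", call. = FALSE)
  }
  if (standardize) {
    st <- standardize_cols(train_X)
    train_X <- st$x
    test_X <- standardize_cols(test_X, mu = st$mu, sd = st$sd)$x
  }
  D <- sqdist(test_X, train_X)
  nn <- max.col(-D, ties.method = "first")
  train_y[nn]
}

#' Stratified k-fold cross-validated 1-NN predictions
#'
#' Segment-level stratified folds: every sample is predicted exactly once
#' by a classifier trained on the remaining folds.  Note that when several
#' segments come from the same subject this scheme lets a subject span
#' train and test folds; [crossval_loso()] is the leakage-free
#' alternative.
#'
#' @param X feature matrix, rows = segments.
#' @param y class labels (both classes must be present).
#' @param seed integer seed for the fold split.
#' @param folds number of folds (default 10).
#' @param subjects optional per-segment subject ids carried into the
#'   result for bookkeeping.
#' @return an object of class \code{cgp_cv}: data frame with columns
#'   \code{truth}, \code{prediction}, \code{round} (fold id) and
#'   \code{subject}, plus scheme metadata.
#' @export
crossval_10fold <- function(X, y, seed = 1L, folds = 10L, subjects = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) < folds) stop("fewer samples than folds", call. = FALSE)
  if (length(unique(y)) < 2L) stop("need both classes present", call. = FALSE)
  fold_id <- stratified_folds(y, folds, seed)
  pred <- integer(length(y))
  for (fd in seq_len(max(fold_id))) {
    te <- which(fold_id == fd)
    tr <- which(fold_id != fd)
    if (length(unique(y[tr])) < 2L) {
      stop("a class is absent from a training split", call. = FALSE)
    }
    pred[te] <- knn_predict(X[tr, , drop = FALSE], y[tr],
                            X[te, , drop = FALSE])
  }
  cv_result(truth = y, prediction = pred, round = fold_id,
            subject = subjects, scheme = "10fold")
}

#' Leave-one-subject-out cross-validated 1-NN predictions
#'
#' One round per distinct subject: all of that subject's segments form
#' the test set and every other subject's segments the training set, so
#' train and test never share a subject.
#'
#' @param X feature matrix, rows = segments.
#' @param y class labels.
#' @param subjects per-segment subject identifiers (>= 2 distinct).
#' @return an object of class \code{cgp_cv} (see [crossval_10fold()]);
#'   \code{round} is the held-out subject's ordinal.
#' @export
crossval_loso <- function(X, y, subjects) {
  X <- as.matrix(X)
  y <- as.integer(y)
  subjects <- as.character(subjects)
  stopifnot(length(subjects) == nrow(X))
  subj_levels <- unique(subjects)
  if (length(subj_levels) < 2L) {
    stop("leave-one-subject-out needs >= 2 subjects", call. = FALSE)
  }
  pred <- integer(length(y))
  round_id <- integer(length(y))
  for (s in seq_along(subj_levels)) {
    te <- which(subjects == subj_levels[s])
    tr <- which(subjects != subj_levels[s])
    if (length(unique(y[tr])) < 2L) {
      stop("a class is absent from a training split", call. = FALSE)
    }
    pred[te] <- knn_predict(X[tr, , drop = FALSE], y[tr],
                            X[te, , drop = FALSE])
    round_id[te] <- s
  }
  cv_result(truth = y, prediction = pred, round = round_id,
            subject = subjects, scheme = "loso")
}

#' Nested cross-validation: feature selection refit inside every split
#'
#' The flat pipeline ([run_pipeline()]) selects features once on the full
#' data before cross-validation, mirroring common practice in hand-crafted
#' feature pipelines; with many more features than segments that selection
#' step leaks label information into the reported accuracy.  This variant
#' reruns the iterative NCA selection on each training split only, so the
#' held-out predictions measure genuine generalization.
#'
#' @param X feature matrix, rows = segments.
#' @param y class labels.
#' @param scheme \code{"10fold"} (stratified segment-level folds) or
#'   \code{"loso"} (leave one subject out).
#' @param subjects per-segment subject ids (required for \code{"loso"}).
#' @param seed integer seed for fold assignment and the NCA fit.
#' @param folds folds for the \code{"10fold"} scheme.
#' @param low,high candidate subset-size range passed to [inca_select()].
#' @param nca_max_iter NCA gradient iterations per split.
#' @return a \code{cgp_cv} object (see [crossval_10fold()]) with the
#'   per-round chosen subset sizes in attribute \code{chosen_sizes}.
#' @export
crossval_nested <- function(X, y, scheme = c("10fold", "loso"),
                            subjects = NULL, seed = 1L, folds = 10L,
                            low = 100L, high = 1000L, nca_max_iter = 60L) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (scheme == "loso") {
    if (is.null(subjects)) stop("loso needs subject ids", call. = FALSE)
    round_id <- match(subjects, unique(subjects))
  } else {
    round_id <- stratified_folds(y, folds, seed)
  }
  pred <- integer(length(y))
  sizes <- integer(max(round_id))
  for (rd in seq_len(max(round_id))) {
    te <- which(round_id == rd)
    tr <- which(round_id != rd)
    if (length(unique(y[tr])) < 2L) {
      stop("a class is absent from a training split", call. = FALSE)
    }
    sel <- inca_select(X[tr, , drop = FALSE], y[tr], low = low, high = high,
                       seed = as.integer(seed) + rd, folds = folds,
                       nca_max_iter = nca_max_iter)
    sizes[rd] <- sel$chosen_size
    keep <- sel$chosen_indices
    pred[te] <- knn_predict(X[tr, keep, drop = FALSE], y[tr],
                            X[te, keep, drop = FALSE])
  }
  out <- cv_result(truth = y, prediction = pred, round = round_id,
                   subject = subjects, scheme = paste0("nested-", scheme))
  attr(out, "chosen_sizes") <- sizes
  out
}

cv_result <- function(truth, prediction, round, subject, scheme) {
  if (is.null(subject)) subject <- NA_character_
  structure(
    data.frame(truth = truth, prediction = prediction,
               round = round, subject = subject,
               stringsAsFactors = FALSE),
    scheme = scheme, class = c("cgp_cv", "data.frame")
  )
}

#' @export
print.cgp_cv <- function(x, ...) {
  cat("Cross-validated predictions (", attr(x, "scheme"), "): ",
      nrow(x), " segments, ", length(unique(x$round)), " rounds, accuracy ",
      sprintf("%.2f%%", 100 * mean(x$prediction == x$truth)), "\n", sep = "")
  invisible(x)
}

#' Confusion counts for a binary prediction vector
#'
#' @param truth,prediction label vectors; \code{positive} marks the
#'   positive class (default 1, the case class).
#' @return list with \code{tp}, \code{fn}, \code{tn}, \code{fp}.
#' @export
confusion_counts <- function(truth, prediction, positive = 1L) {
  stopifnot(length(truth) == length(prediction))
  pos <- truth == positive
  list(tp = sum(pos & prediction == positive),
       fn = sum(pos & prediction != positive),
       tn = sum(!pos & prediction != positive),
       fp = sum(!pos & prediction == positive))
}

#' Accuracy, sensitivity, specificity and geometric mean
#'
#' \code{acc = (tp+tn)/total}, \code{sen = tp/(tp+fn)},
#' \code{spe = tn/(tn+fp)}, \code{geo = sqrt(sen * spe)}.  Sensitivity is
#' undefined (NA, with a flag) when no positive samples were evaluated,
#' likewise specificity; they are never silently reported as zero.
#'
#' @param counts confusion counts from [confusion_counts()], or a
#'   \code{cgp_cv} object (then \code{positive} selects the positive
#'   class).
#' @param positive positive-class label when \code{counts} is a
#'   \code{cgp_cv}.
#' @return object of class \code{cgp_metrics}: list with \code{acc},
#'   \code{sen}, \code{spe}, \code{geo} as proportions in [0, 1],
#'   \code{counts} and \code{undefined} (character vector naming any
#'   undefined metric).
#' @export
compute_metrics <- function(counts, positive = 1L) {
  if (inherits(counts, "cgp_cv")) {
    counts <- confusion_counts(counts$truth, counts$prediction, positive)
  }
  total <- counts$tp + counts$fn + counts$tn + counts$fp
  if (total == 0L) stop("no evaluated samples", call. = FALSE)
  undefined <- character(0)
  sen <- if (counts$tp + counts$fn == 0L) {
    undefined <- c(undefined, "sen"); NA_real_
  } else counts$tp / (counts$tp + counts$fn)
  spe <- if (counts$tn + counts$fp == 0L) {
    undefined <- c(undefined, "spe"); NA_real_
  } else counts$tn / (counts$tn + counts$fp)
  geo <- if (anyNA(c(sen, spe))) {
    undefined <- c(undefined, "geo"); NA_real_
  } else sqrt(sen * spe)
  structure(
    list(acc = (counts$tp + counts$tn) / total,
         sen = sen, spe = spe, geo = geo,
         counts = counts, undefined = unique(undefined)),
    class = "cgp_metrics"
  )
}

#' @export
print.cgp_metrics <- function(x, digits = 2, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else
    sprintf(paste0("%.", digits, "f%%"), 100 * v)
  cat("acc ", pct(x$acc), " | sen ", pct(x$sen), " | spe ", pct(x$spe),
      " | geo ", pct(x$geo), "\n", sep = "")
  invisible(x)
}
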