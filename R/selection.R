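#' Neighborhood component analysis feature weights
#'
#' Diagonal (per-feature) NCA: weights are fitted by full-batch gradient
#' ascent on the expected leave-one-out accuracy of a stochastic nearest
#' neighbor classifier, with an L2 penalty on the weights.  The soft
#' neighbor assignment for sample i puts probability proportional to
#' \code{exp(-d_ij / s)} on sample j, where \code{d_ij} is the squared
#' Euclidean distance after scaling feature f by \code{w_f}, and the
#' length scale \code{s} is fixed at the mean pairwise distance of the
#' standardized data so the soft assignment starts informative regardless
#' of dimensionality.  Features are standardized to zero mean and unit
#' variance internally; returned weights refer to the original column
#' order.
#'
#' @param X numeric matrix, rows = samples, columns = features.
#' @param y class labels, at least two classes with >= 2 samples each.
#' @param seed integer seed (the optimizer is deterministic; the seed is
#'   fixed for reproducibility of any tie handling).
#' @param lambda L2 regularization strength; default \code{1/nrow(X)}.
#' @param max_iter gradient ascent iterations (default 60).
#' @param eta initial step size (default 0.1), adapted multiplicatively.
#' @return numeric vector of nonnegative per-feature weights (squared
#'   fitted scalings).
#' @export
nca_weights <- function(X, y, seed = 1L, lambda = NULL, max_iter = 60L,
                        eta = 0.1) {
  X <- as.matrix(X)
  y <- as.integer(as.factor(y))
  n <- nrow(X)
  if (length(unique(y)) < 2L) {
    stop("nca_weights needs at least two classes", call. = FALSE)
  }
  if (min(table(y)) < 2L) {
    stop("nca_weights needs >= 2 samples per class", call. = FALSE)
  }
  if (is.null(lambda)) lambda <- 1 / n
  set.seed(as.integer(seed))

  Z <- standardize_cols(X)$x
  Z2 <- Z * Z
  same <- outer(y, y, "==")
  diag(same) <- FALSE

  # fixed softmax length scale: mean pairwise squared distance at unit weights
  D0 <- sqdist(Z, Z)
  s <- mean(D0[upper.tri(D0)])
  if (!is.finite(s) || s <= 0) s <- 1

  w <- rep(1, ncol(Z))
  obj_old <- -Inf
  for (it in seq_len(max_iter)) {
    Dw <- sqdist(sweep(Z, 2L, w, "*"), NULL) / s
    P <- soft_neighbor_probs(Dw)
    p_i <- rowSums(P * same)
    obj <- sum(p_i) - lambda * sum(w^2)
    A <- P * p_i - P * same
    rs <- rowSums(A)
    cs <- colSums(A)
    # t_f = sum_{i,k} A_ik (z_if - z_kf)^2, expanded so BLAS does the work
    t_f <- drop(rs %*% Z2) + drop(cs %*% Z2) - 2 * colSums(Z * (A %*% Z))
    grad <- 2 * w * (t_f / s) - 2 * lambda * w
    if (obj < obj_old) eta <- eta / 2 else eta <- eta * 1.05
    w <- w + eta * grad
    obj_old <- obj
  }
  w^2
}

#' Iterative NCA feature selection
#'
#' Features are ranked by descending NCA weight; for every candidate
#' subset size f in \code{low..high} (clamped to the available feature
#' count) the top-f prefix is scored by the misclassification rate of a
#' 1-nearest-neighbor classifier under stratified k-fold cross-validation,
#' and the size with the minimum loss is selected (ties broken toward the
#' smaller subset).
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y class labels.
#' @param low,high inclusive candidate-size range (defaults 100 and 1000).
#' @param seed integer seed controlling the NCA fit and the fold split.
#' @param folds number of cross-validation folds (default 10).
#' @param nca_max_iter iterations passed to [nca_weights()].
#' @return an object of class \code{cgp_selection}: list with
#'   \code{ranked_indices}, \code{candidate_sizes}, \code{candidate_losses},
#'   \code{chosen_size}, \code{chosen_indices}, \code{weights}.
#' @export
inca_select <- function(X, y, low = 100L, high = 1000L, seed = 1L,
                        folds = 10L, nca_max_iter = 60L) {
  X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty feature matrix", call. = FALSE)
  if (ncol(X) < 2L) stop("need at least two features", call. = FALSE)
  if (low < 1L || high < low) stop("need 1 <= low <= high", call. = FALSE)
  d <- ncol(X)
  lo <- min(as.integer(low), d)
  hi <- min(as.integer(high), d)
  sizes <- lo:hi

  w <- nca_weights(X, y, seed = seed, max_iter = nca_max_iter)
  ranked <- order(w, decreasing = TRUE)

  y <- as.integer(y)
  fold_id <- stratified_folds(y, folds, seed = as.integer(seed) + 1L)
  n <- nrow(X)
  errs <- numeric(length(sizes))
  Xr <- X[, ranked[seq_len(hi)], drop = FALSE]
  for (fd in seq_len(max(fold_id))) {
    te <- which(fold_id == fd)
    tr <- which(fold_id != fd)
    st <- standardize_cols(Xr[tr, , drop = FALSE])
    Ztr <- st$x
    Zte <- sweep(sweep(Xr[te, , drop = FALSE], 2L, st$mu, "-"), 2L, st$sd, "/")
    # grow the pairwise distance one ranked feature at a time
    D <- matrix(0, nrow = length(te), ncol = length(tr))
    for (f in seq_len(hi)) {
      D <- D + (outer(Zte[, f], Ztr[, f], "-"))^2
      if (f >= lo) {
        nn <- max.col(-D, ties.method = "first")
        errs[f - lo + 1L] <- errs[f - lo + 1L] + sum(y[tr][nn] != y[te])
      }
    }
  }
  losses <- errs / n
  best <- sizes[which.min(losses)]
  structure(
    list(ranked_indices = ranked,
         candidate_sizes = sizes,
         candidate_losses = losses,
         chosen_size = best,
         chosen_indices = ranked[seq_len(best)],
         weights = w),
    class = "cgp_selection"
  )
}

#' @export
print.cgp_selection <- function(x, ...) {
  cat("Iterative NCA selection\n")
  cat("  candidate sizes:", min(x$candidate_sizes), "-", max(x$candidate_sizes),
      "(", length(x$candidate_sizes), "evaluated )\n")
  cat("  chosen size:", x$chosen_size,
      sprintf("(CV loss %.4f)\n", min(x$candidate_losses)))
  invisible(x)
}

# squared Euclidean distances between rows; B = NULL means self-distances
sqdist <- function(A, B = NULL) {
  if (is.null(B)) B <- A
  an <- rowSums(A * A)
  bn <- rowSums(B * B)
  D <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

# row-stochastic soft assignment from a squared-distance matrix,
# excluding self-assignment; numerically stabilized
soft_neighbor_probs <- function(D) {
  diag(D) <- Inf
  m <- apply(D, 1L, min)
  m[!is.finite(m)] <- 0
  E <- exp(-(D - m))
  E[!is.finite(E)] <- 0
  rs <- rowSums(E)
  rs[rs == 0] <- 1
  E / rs
}

standardize_cols <- function(X, mu = NULL, sd = NULL) {
  if (is.null(mu)) mu <- colMeans(X)
  if (is.null(sd)) {
    sd <- apply(X, 2L, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1  # constant feature: unit divisor
  }
  list(x = sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/"), mu = mu, sd = sd)
}

# seeded stratified fold assignment at the sample level
stratified_folds <- function(y, folds, seed) {
  set.seed(as.integer(seed))
  fold_id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}
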