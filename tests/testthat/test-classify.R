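test_that("1-NN predicts by nearest standardized neighbor with a stable tie rule", {
  set.seed(11)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(1L, 0L), 10)
  expect_identical(knn_predict(X, y, X), y)  # self-distance 0
  expect_identical(knn_predict(matrix(c(0, 10)), c(1L, 2L), matrix(1)), 1L)
  # two equidistant neighbors with different labels -> earlier sample wins
  tr <- matrix(c(-1, 1), ncol = 1)
  expect_identical(knn_predict(tr, c(5L, 9L), matrix(0), standardize = FALSE), 5L)
  # zero-variance feature gets a unit divisor instead of NaN distances
  Xz <- cbind(rnorm(10), 3)
  expect_silent(p <- knn_predict(Xz, rep(0:1, 5), Xz))
  expect_identical(p, rep(0:1, 5))
  expect_error(knn_predict(X, y, matrix(0, 1, 3)), "dimensions differ")
})

test_that("standardization uses training statistics only", {
  set.seed(12)
  tr <- matrix(rnorm(60), 30, 2)
  ytr <- rep(0:1, 15)
  te <- matrix(rnorm(20), 10, 2)
  # manual reference using train mean/sd
  mu <- colMeans(tr); sd_ <- apply(tr, 2, sd)
  trs <- scale(tr, mu, sd_); tes <- scale(te, mu, sd_)
  d <- as.matrix(dist(rbind(tes, trs)))[1:10, 11:40]
  ref <- ytr[apply(d, 1, which.min)]
  expect_identical(knn_predict(tr, ytr, te), ref)
  # translating the whole test set must move it relative to the training
  # cloud (it would be silently undone if test statistics were used)
  shifted <- knn_predict(tr, seq_len(30), te + 100)
  expect_true(all(shifted == shifted[1]))
})

test_that("stratified 10-fold predicts every segment once and finds separable classes", {
  sep <- make_separable_X(n_per_class = 30)
  cv <- crossval_10fold(sep$X, sep$y, seed = 1)
  expect_equal(nrow(cv), 60L)
  expect_equal(sort(unique(cv$round)), 1:10)
  expect_true(all(table(cv$round, cv$truth) >= 1))  # stratification
  expect_equal(mean(cv$prediction == cv$truth), 1)
  # permuted labels: accuracy within the 99% binomial band around 0.5
  set.seed(13)
  yperm <- sample(sep$y)
  cvp <- crossval_10fold(sep$X, yperm, seed = 2)
  acc <- mean(cvp$prediction == cvp$truth)
  half_width <- qnorm(0.995) * sqrt(0.25 / 60)
  expect_gte(acc, 0.5 - half_width)
  expect_lte(acc, 0.5 + half_width)
})

test_that("LOSO holds out whole subjects and never mixes them", {
  set.seed(14)
  n <- 56
  subjects <- rep(sprintf("s%02d", 1:28), each = 2)
  y <- rep(rep(0:1, each = 2), 14)
  X <- matrix(rnorm(n * 5), n, 5)
  cv <- crossval_loso(X, y, subjects)
  expect_equal(length(unique(cv$round)), 28L)  # one round per subject
  expect_equal(nrow(cv), n)
  # disjointness: each subject appears in exactly one round
  expect_true(all(tapply(cv$round, cv$subject, function(r) length(unique(r))) == 1))
  # a subject duplicating another subject's rows is predicted perfectly
  X2 <- X; X2[subjects == "s02", ] <- X[subjects == "s01", ]
  y2 <- y; y2[subjects == "s02"] <- y[subjects == "s01"]
  cv2 <- crossval_loso(X2, y2, subjects)
  expect_true(all(cv2$prediction[cv2$subject == "s02"] ==
                    cv2$truth[cv2$subject == "s02"]))
  expect_error(crossval_loso(X, y, rep("only", n)), ">= 2 subjects")
})

test_that("subject-specific offsets inflate segment-level folds but not LOSO", {
  set.seed(15)
  n_subj <- 20; seg_per <- 6
  subjects <- rep(sprintf("s%02d", 1:n_subj), each = seg_per)
  y <- rep(rep(0:1, n_subj / 2), each = seg_per)  # no real signal
  offs <- matrix(rnorm(n_subj * 8, sd = 5), n_subj, 8)
  X <- offs[rep(1:n_subj, each = seg_per), ] + matrix(rnorm(n_subj * seg_per * 8), ncol = 8)
  acc10 <- mean(with(crossval_10fold(X, y, seed = 3), prediction == truth))
  accloso <- mean(with(crossval_loso(X, y, subjects), prediction == truth))
  expect_gte(acc10, 0.9)   # segment-level folds retrieve same-subject rows
  half_width <- qnorm(0.995) * sqrt(0.25 / (n_subj * seg_per))
  expect_lte(accloso, 0.5 + half_width + 0.1)  # near chance without the subject
  expect_gte(acc10 - accloso, 0.25)
})

test_that("metrics follow their defining formulas and flag undefined cases", {
  m <- compute_metrics(list(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(m$acc, 0.85)
  expect_equal(m$sen, 0.9)
  expect_equal(m$spe, 0.8)
  expect_equal(m$geo, sqrt(0.72))
  m2 <- compute_metrics(list(tp = 1, fn = 1, tn = 1, fp = 1))
  expect_equal(unlist(m2[c("acc", "sen", "spe", "geo")]),
               c(acc = 0.5, sen = 0.5, spe = 0.5, geo = 0.5))
  # acc = (sen*P + spe*N)/(P+N), checked on random confusion tables
  set.seed(16)
  for (i in 1:20) {
    cts <- as.list(rpois(4, 20) + 1)
    names(cts) <- c("tp", "fn", "tn", "fp")
    m <- compute_metrics(cts)
    P <- cts$tp + cts$fn; N <- cts$tn + cts$fp
    expect_equal(m$acc, (m$sen * P + m$spe * N) / (P + N))
    expect_equal(m$geo, sqrt(m$sen * m$spe))
  }
  m3 <- compute_metrics(list(tp = 0, fn = 0, tn = 5, fp = 1))
  expect_true(is.na(m3$sen) && is.na(m3$geo))
  expect_setequal(m3$undefined, c("sen", "geo"))
  expect_error(compute_metrics(list(tp = 0, fn = 0, tn = 0, fp = 0)), "no evaluated")
})

test_that("confusion counts agree with prediction vectors", {
  truth <- c(1, 1, 1, 0, 0, 0)
  pred <- c(1, 0, 1, 0, 1, 0)
  cc <- confusion_counts(truth, pred)
  expect_equal(cc, list(tp = 2L, fn = 1L, tn = 2L, fp = 1L))
  expect_equal(compute_metrics(cc)$acc, 4 / 6)
  expect_equal(sum(unlist(cc)), length(truth))
})
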