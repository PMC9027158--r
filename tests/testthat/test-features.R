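test_that("segmentation cuts non-overlapping windows and drops the remainder", {
  rec <- signal_record(matrix(seq_len(25100), ncol = 1), fs = 250,
                       subject_id = "s1", label = 0)
  sg <- segment_record(rec, 6250L)
  expect_equal(sg$n_segments, 4L)
  expect_equal(dim(sg$segments[[1]]), c(6250L, 4L))
  expect_equal(sg$segments[[1]][, 1], as.numeric(1:6250))
  expect_equal(sg$segments[[1]][, 4], as.numeric(18751:25000))  # last 100 dropped

  rec1 <- signal_record(matrix(rnorm(6250), ncol = 1), 250, "s2", 1)
  sg1 <- segment_record(rec1, 6250L)
  expect_equal(sg1$n_segments, 1L)
  expect_equal(sg1$segments[[1]][, 1], rec1$samples[, 1])
  expect_equal(sg1$label, 1L)

  short <- signal_record(matrix(rnorm(100), ncol = 1), 250, "s3", 0)
  expect_warning(sg0 <- segment_record(short, 6250L), "shorter")
  expect_equal(sg0$n_segments, 0L)
})

test_that("maximum absolute pooling matches its definition", {
  expect_equal(map_pool(c(1, -3, 2, 5), 2), c(3, 5))
  expect_equal(map_pool(rep(0, 7), 2), c(0, 0, 0))
  x <- rnorm(100)
  expect_equal(map_pool(x, 1), abs(x))
  expect_error(map_pool(rnorm(3), 4), "exceeds")
  # contraction and constancy, over random cases
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(sample(10:200, 1))
    b <- sample(1:5, 1)
    out <- map_pool(x, b)
    expect_length(out, length(x) %/% b)
    expect_lte(max(out), max(abs(x)))
    expect_true(all(out >= 0))
  }
  expect_equal(map_pool(rep(-2.5, 12), 4), rep(2.5, 3))
})

test_that("pattern extraction produces conserved 2048-bin histograms", {
  # constant signal: every difference is 0, sign(0) = 1, so every bit is 1
  fv <- cgp_extract(rep(7, 100), patterns17)
  expect_length(fv, 2048L)
  hs <- matrix(fv, nrow = 256)
  expect_true(all(hs[256, ] == 85))
  expect_true(all(hs[-256, ] == 0))
  expect_equal(sum(fv), 8 * 85)

  set.seed(2)
  for (L in c(16, 31, 200)) {
    fv <- cgp_extract(rnorm(L), patterns17)
    expect_length(fv, 2048L)
    expect_equal(colSums(matrix(fv, nrow = 256)), rep(L - 15, 8))
  }
  # strictly increasing window: for the first group every left index
  # exceeds its right partner, so all bits are 1 -> code 255
  fv <- cgp_extract(1:16, patterns17)
  expect_equal(fv[256], 1L)
  expect_error(cgp_extract(rnorm(10), patterns17), "shorter")
})

test_that("production extractor matches the naive per-window reference", {
  set.seed(3)
  for (i in 1:25) {
    x <- rnorm(sample(16:150, 1))
    expect_identical(cgp_extract(x, patterns17),
                     naive_cgp_extract(x, patterns17))
  }
  # including signals with ties, which exercise the >= 0 convention
  for (i in 1:10) {
    x <- sample(0:3, sample(20:60, 1), replace = TRUE)
    expect_identical(cgp_extract(x, patterns17),
                     naive_cgp_extract(x, patterns17))
  }
})

test_that("multilevel extraction pools the raw signal and concatenates four levels", {
  set.seed(4)
  x <- rnorm(6250)
  fv <- extract_multilevel(x, patterns17)
  expect_length(fv, 8192L)
  expect_identical(fv[1:2048], cgp_extract(x, patterns17))
  # levels come from the raw signal, not cascaded pooling
  expect_identical(fv[2049:4096], cgp_extract(map_pool(x, 2), patterns17))
  expect_identical(fv[4097:6144], cgp_extract(map_pool(x, 4), patterns17))
  expect_identical(fv[6145:8192], cgp_extract(map_pool(x, 8), patterns17))
  expect_identical(extract_multilevel(x, patterns17), fv)  # deterministic

  cf <- extract_multilevel(rep(1, 256), patterns17)
  hs <- matrix(cf, nrow = 256)
  expect_true(all(hs[256, ] > 0) && all(hs[-256, ] == 0))
  expect_error(extract_multilevel(rnorm(100), patterns17), "too short")
})

test_that("feature matrices stack segments with aligned labels and subjects", {
  set.seed(5)
  recs <- list(
    signal_record(matrix(rnorm(600 * 2), ncol = 2), 10, "a", 0),
    signal_record(matrix(rnorm(900 * 2), ncol = 2), 10, "b", 1))
  fx <- extract_feature_matrix(recs, patterns17, segment_len = 300L)
  expect_length(fx$features, 2L)
  expect_equal(dim(fx$features[[1]]), c(5L, 8192L))
  expect_equal(fx$labels, c(0L, 0L, 1L, 1L, 1L))
  expect_equal(fx$subjects, c("a", "a", "b", "b", "b"))
  # rows match direct extraction of the corresponding segment
  expect_equal(fx$features[[2]][3, ],
               extract_multilevel(recs[[2]]$samples[1:300, 2], patterns17))
})
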