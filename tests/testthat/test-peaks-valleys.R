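test_that("peak/valley detection matches the stated examples", {
  pv <- find_peaks_valleys(c(0, 1, 0, 1, 0))
  expect_equal(pv$peaks, c(1, 3))
  expect_equal(pv$valleys, 2)
  # plateau: single peak at the floor-midpoint
  expect_equal(find_peaks_valleys(c(0, 1, 1, 0))$peaks, 1)
  expect_equal(find_peaks_valleys(c(0, 1, 1, 1, 0))$peaks, 2)
  # monotone and constant series have no extrema
  expect_equal(length(find_peaks_valleys(1:10)$peaks), 0)
  expect_equal(length(find_peaks_valleys(rep(2, 5))$valleys), 0)
  expect_error(find_peaks_valleys(c(1, 2)), "too short")
})

test_that("plateau handling matches brute force on all short 0/1 series", {
  for (n in 3:6) {
    grid <- expand.grid(rep(list(0:1), n))
    for (r in seq_len(nrow(grid))) {
      x <- as.numeric(grid[r, ])
      got <- find_peaks_valleys(x)
      want <- oracle_peaks_valleys(x)
      expect_equal(got$peaks, as.numeric(want$peaks %||% numeric(0)),
                   info = paste(x, collapse = ""))
      expect_equal(got$valleys, as.numeric(want$valleys %||% numeric(0)),
                   info = paste(x, collapse = ""))
    }
  }
})

test_that("peaks and valleys alternate on arbitrary series", {
  set.seed(61)
  for (i in 1:50) {
    x <- cumsum(rnorm(60))
    pv <- find_peaks_valleys(x)
    expect_lte(abs(length(pv$peaks) - length(pv$valleys)), 1)
    all_t <- sort(c(pv$peaks, pv$valleys))
    kinds <- ifelse(all_t %in% pv$peaks, "p", "v")
    if (length(kinds) > 1) {
      expect_true(all(kinds[-1] != kinds[-length(kinds)]))
    }
  }
})

test_that("the pipeline is invariant to a constant BOLD offset", {
  set.seed(62)
  x <- as.numeric(stats::filter(rnorm(120), rep(1 / 4, 4), sides = 2))
  x[is.na(x)] <- 0
  a <- find_peaks_valleys(x)
  b <- find_peaks_valleys(x + 100)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$valleys, b$valleys)
})

test_that("word attachment windows are one TR wide, left-closed", {
  pv <- structure(list(peaks = 10, valleys = numeric(0), tr = 1),
                  class = "peak_valley_set")
  ev <- event_table(data.frame(
    word = c("hit", "early", "edge_lo", "edge_hi"),
    onset = c(5.0, 4.4, 4.5, 5.5),
    offset = c(5.3, 4.6, 4.8, 5.8),
    class = "concrete", stringsAsFactors = FALSE))
  w <- words_at_lag(pv, ev, lag = 5)
  expect_setequal(w$peak_words, c("hit", "edge_lo"))  # [4.5, 5.5)
  expect_false("early" %in% w$peak_words)
  expect_false("edge_hi" %in% w$peak_words)
})

test_that("binarization thresholds at mean + 1 SD, inclusive, high tail only", {
  n <- probe_norms("Visual")  # Visual column: mean 2, sample SD 1
  expect_equal(unname(attr(n, "dim_means")["Visual"]), 2, tolerance = 1e-3)
  expect_equal(unname(attr(n, "dim_sds")["Visual"]), 1, tolerance = 1e-2)
  b <- binarize_dimension(c("probe1", "probe2", "probe3"), n, "Visual")
  expect_equal(as.integer(b), c(1, 0, 0))

  # exact boundary: corpus (1,2,3) has mean 2, SD 1; rating 3 = mean + 1 SD
  m <- matrix(2.5, 3, 13, dimnames = list(NULL, NORM_DIMENSIONS))
  m <- m + matrix(rnorm(39, 0, 0.01), 3)
  m[, "Haptic"] <- c(1, 2, 3)
  n2 <- norms_table(data.frame(word = c("lo", "mid", "hi"), m,
                               check.names = FALSE))
  expect_equal(as.integer(binarize_dimension(c("hi", "mid"), n2, "Haptic")),
               c(1, 0))
  # OOV words are skipped and counted
  b3 <- binarize_dimension(c("hi", "zebra"), n2, "Haptic")
  expect_equal(length(b3), 1)
  expect_equal(attr(b3, "n_oov"), 1)
})

test_that("kruskal_wallis matches oracles exactly", {
  # constructed case: three 0s vs three 1s gives H = 5 under tie correction
  kw <- kruskal_wallis(c(0, 0, 0), c(1, 1, 1))
  expect_equal(kw$h, 5.0, tolerance = 1e-12)

  # identical arrays: H = 0; all-tied: degenerate H = 0, p = 1
  expect_equal(kruskal_wallis(c(1, 0, 1), c(1, 0, 1))$h, 0, tolerance = 1e-12)
  deg <- kruskal_wallis(c(1, 1), c(1, 1, 1))
  expect_equal(deg$h, 0)
  expect_equal(deg$p, 1)

  # exhaustive: every binary split of 6 observations, vs the rank-formula
  # oracle and vs stats::kruskal.test
  grid <- expand.grid(rep(list(0:1), 6))
  for (r in seq_len(nrow(grid))) {
    x <- as.numeric(grid[r, ])
    for (cut in 1:5) {
      a <- x[1:cut]; b <- x[(cut + 1):6]
      got <- kruskal_wallis(a, b)
      expect_equal(got$h, oracle_kw(a, b), tolerance = 1e-12)
      if (length(unique(x)) > 1) {
        ref <- suppressWarnings(
          kruskal.test(list(a, b)))
        expect_equal(got$h, unname(ref$statistic), tolerance = 1e-12)
        expect_equal(got$p, ref$p.value, tolerance = 1e-12)
      }
    }
  }

  # symmetry and within-array permutation invariance
  set.seed(63)
  a <- rbinom(10, 1, 0.4); b <- rbinom(7, 1, 0.7)
  expect_equal(kruskal_wallis(a, b)$h, kruskal_wallis(b, a)$h)
  expect_equal(kruskal_wallis(sample(a), b)$h, kruskal_wallis(a, b)$h)
  expect_error(kruskal_wallis(numeric(0), 1), "non-empty")
})

test_that("cluster series averaging is the voxelwise mean", {
  arr <- array(0, c(2, 1, 1, 5))
  arr[1, 1, 1, ] <- 1:5
  arr[2, 1, 1, ] <- -(1:5)
  bold <- volume_grid(arr, tr = 1)
  sel <- array(TRUE, c(2, 1, 1))
  expect_equal(average_cluster_series(bold, sel), rep(0, 5))
  sel1 <- array(c(TRUE, FALSE), c(2, 1, 1))
  expect_equal(average_cluster_series(bold, sel1), 1:5)
  expect_error(average_cluster_series(bold, array(FALSE, c(2, 1, 1))),
               "empty")
})

test_that("planted dimensions are recovered and unplanted ones are not", {
  hits <- 0; false_rate <- 0; runs <- 12
  for (s in seq_len(runs)) {
    d <- generate_pv_data(dimension = "Valence", delay = 5, seed = 500 + s)
    res <- run_peak_valley(d$bold, list(c1 = array(TRUE, c(1, 1, 1))),
                           d$events, d$norms, lags = 5)
    tst <- res$tests
    hits <- hits + tst$associated[tst$dimension == "Valence"]
    false_rate <- false_rate +
      mean(tst$associated[tst$dimension != "Valence"], na.rm = TRUE)
  }
  expect_gte(hits / runs, 0.8)
  expect_lte(false_rate / runs, 0.15)
})

test_that("low-word extrema are flagged and not tested", {
  d <- generate_pv_data(run_length = 60, seed = 77)  # very few extrema
  res <- run_peak_valley(d$bold, list(c1 = array(TRUE, c(1, 1, 1))),
                         d$events, d$norms, lags = 4)
  if (any(!res$tests$tested)) {
    expect_true(all(is.na(res$tests$h[!res$tests$tested])))
  }
  expect_equal(nrow(res$tests), 13)
})
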