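#' Average the in-cluster BOLD series
#'
#' @param bold a 4D `volume_grid`.
#' @param cluster logical 3D array or voxel indices selecting the cluster.
#' @return numeric series (one value per TR).
#' @export
average_cluster_series <- function(bold, cluster) {
  shape <- dim(bold$data)[1:3]
  idx <- if (is.logical(cluster)) which(cluster & bold$mask) else
    cluster[bold$mask[cluster]]
  if (length(idx) == 0) stop("cluster is empty (or outside the mask)", call. = FALSE)
  nT <- dim(bold$data)[4]
  flat <- matrix(bold$data, prod(shape), nT)
  colMeans(flat[idx, , drop = FALSE])
}

#' Find peaks and valleys of a series by discrete differencing
#'
#' A peak is a sign change of the first difference from positive to negative,
#' a valley the reverse. A run of zero differences (plateau) is treated as a
#' single extremum at the floor-midpoint of the plateau. Endpoints are never
#' extrema. Times are reported in seconds (index i of the series corresponds
#' to `(i-1)*tr` seconds).
#'
#' @param x numeric series (length >= 3).
#' @param tr sampling interval in seconds.
#' @return A `peak_valley_set`: list with `peaks` and `valleys` (times, s).
#' @export
find_peaks_valleys <- function(x, tr = 1) {
  if (length(x) < 3) stop("series too short (need length >= 3)", call. = FALSE)
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  peaks <- integer(0); valleys <- integer(0)
  if (length(nz) >= 2) {
    for (q in seq_len(length(nz) - 1L)) {
      i <- nz[q]; j <- nz[q + 1L]
      if (s[i] == s[j]) next
      # plateau spans 0-based series indices i..(j-1); take its floor-midpoint
      mid0 <- (i + j - 1L) %/% 2L
      if (s[i] > 0) peaks <- c(peaks, mid0) else valleys <- c(valleys, mid0)
    }
  }
  structure(list(peaks = peaks * tr, valleys = valleys * tr, tr = tr),
            class = "peak_valley_set")
}

#' @export
print.peak_valley_set <- function(x, ...) {
  cat(sprintf("<peak_valley_set> %d peaks, %d valleys\n",
              length(x$peaks), length(x$valleys)))
  invisible(x)
}

#' Words lagged behind peaks and valleys
#'
#' For an extremum at time t and lag L, collects words whose onset falls in
#' the one-TR window `[t - L - tr/2, t - L + tr/2)`.
#'
#' @param pv a `peak_valley_set`.
#' @param events an `event_table`.
#' @param lag hemodynamic lag in seconds (typically 4, 5 or 6).
#' @param tr window width in seconds.
#' @return list with character vectors `peak_words` and `valley_words`
#'   (repetition preserved).
#' @export
words_at_lag <- function(pv, events, lag, tr = 1) {
  collect <- function(times) {
    unlist(lapply(times, function(t) {
      lo <- t - lag - tr / 2; hi <- t - lag + tr / 2
      events$word[events$onset >= lo & events$onset < hi]
    }), use.names = FALSE)
  }
  list(peak_words = collect(pv$peaks), valley_words = collect(pv$valleys))
}

#' Binarize words against an experiential dimension
#'
#' 1 if the word's rating on the dimension is at least one corpus SD above the
#' corpus mean ("highly rated"), else 0. Out-of-vocabulary words are skipped
#' and counted.
#'
#' @param words character vector.
#' @param norms a `norms_table`.
#' @param dimension one of the 13 dimension names.
#' @return 0/1 integer vector with attribute `n_oov`.
#' @export
binarize_dimension <- function(words, norms, dimension) {
  dimension <- match.arg(dimension, NORM_DIMENSIONS)
  r <- norm_ratings(norms, words, dimension)
  mu <- attr(norms, "dim_means")[dimension]
  sdv <- attr(norms, "dim_sds")[dimension]
  structure(as.integer(r >= mu + sdv), n_oov = attr(r, "n_oov"))
}

#' Tie-corrected Kruskal-Wallis rank test for two arrays
#'
#' H computed on pooled ranks with the tie correction
#' `1 - sum(t^3 - t) / (N^3 - N)`; p from the chi-squared distribution with
#' k - 1 = 1 degree of freedom. When every pooled value is identical the test
#' is degenerate and returns H = 0, p = 1.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with `h` and `p`.
#' @export
kruskal_wallis <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both arrays must be non-empty", call. = FALSE)
  }
  x <- c(a, b)
  g <- rep(1:2, c(length(a), length(b)))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_i <- tabulate(g)
  h0 <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) return(list(h = 0, p = 1))
  h <- h0 / corr
  list(h = h, p = pchisq(h, df = 1, lower.tail = FALSE))
}

#' Peaks-and-valleys reverse correlation over experiential dimensions
#'
#' For each cluster and lag: average the in-cluster series, locate peaks and
#' valleys, attach lagged words, binarize both word lists against each of the
#' 13 experiential dimensions, and run the tie-corrected Kruskal-Wallis test.
#' A dimension is "associated" with a cluster when p < 0.05 and the peak array
#' mean exceeds the valley array mean (more high-rated words at peaks).
#' Extremum types with fewer than `min_words` attached words are flagged
#' low-n and not tested. Lag agreement is the cosine similarity between the
#' 13-long binary association vectors of two lags.
#'
#' @param bold a 4D `volume_grid`.
#' @param clusters named list of cluster selectors (logical arrays or voxel
#'   indices), or a labeled cluster array from [multithreshold_merge()].
#' @param events an `event_table`.
#' @param norms a `norms_table`.
#' @param lags lags in seconds (default 4, 5, 6).
#' @param alpha per-dimension significance level (uncorrected, exploratory).
#' @param min_words minimum attached words per extremum type.
#' @return A `peak_valley_result`: `tests` (cluster x lag x dimension rows)
#'   and `lag_agreement` (per cluster and lag pair).
#' @export
run_peak_valley <- function(bold, clusters, events, norms, lags = c(4, 5, 6),
                            alpha = 0.05, min_words = 5) {
  if (!is.list(clusters)) clusters <- list(cluster1 = clusters)
  if (is.null(names(clusters))) {
    names(clusters) <- paste0("cluster", seq_along(clusters))
  }
  tests <- list()
  assoc <- list()
  for (cl in names(clusters)) {
    series <- average_cluster_series(bold, clusters[[cl]])
    pv <- find_peaks_valleys(series, tr = bold$tr)
    for (lag in lags) {
      w <- words_at_lag(pv, events, lag, tr = bold$tr)
      enough <- length(w$peak_words) >= min_words &&
        length(w$valley_words) >= min_words
      avec <- setNames(rep(0L, length(NORM_DIMENSIONS)), NORM_DIMENSIONS)
      for (dim_ in NORM_DIMENSIONS) {
        if (!enough) {
          tests[[length(tests) + 1L]] <- data.frame(
            cluster = cl, lag = lag, dimension = dim_, h = NA_real_,
            p = NA_real_, mean_peak = NA_real_, mean_valley = NA_real_,
            associated = FALSE, tested = FALSE,
            n_peak = length(w$peak_words), n_valley = length(w$valley_words))
          next
        }
        pa <- binarize_dimension(w$peak_words, norms, dim_)
        va <- binarize_dimension(w$valley_words, norms, dim_)
        kw <- kruskal_wallis(pa, va)
        direction <- mean(pa) > mean(va)
        is_assoc <- kw$p < alpha && direction
        avec[dim_] <- as.integer(is_assoc)
        tests[[length(tests) + 1L]] <- data.frame(
          cluster = cl, lag = lag, dimension = dim_, h = kw$h, p = kw$p,
          mean_peak = mean(pa), mean_valley = mean(va),
          associated = is_assoc, tested = TRUE,
          n_peak = length(pa), n_valley = length(va))
      }
      assoc[[paste(cl, lag, sep = "|")]] <- avec
    }
  }
  agree <- list()
  for (cl in names(clusters)) {
    combs <- utils::combn(lags, 2)
    for (j in seq_len(ncol(combs))) {
      v1 <- assoc[[paste(cl, combs[1, j], sep = "|")]]
      v2 <- assoc[[paste(cl, combs[2, j], sep = "|")]]
      cs <- if (is.null(v1) || is.null(v2) || sum(v1) == 0 || sum(v2) == 0)
        NA_real_ else cosine_sim(v1, v2)
      agree[[length(agree) + 1L]] <- data.frame(
        cluster = cl, lag1 = combs[1, j], lag2 = combs[2, j], cosine = cs)
    }
  }
  structure(list(tests = do.call(rbind, tests),
                 lag_agreement = do.call(rbind, agree),
                 association = assoc),
            class = "peak_valley_result")
}

#' @export
print.peak_valley_result <- function(x, ...) {
  n_assoc <- sum(x$tests$associated, na.rm = TRUE)
  cat(sprintf("<peak_valley_result> %d tests, %d associations\n",
              nrow(x$tests), n_assoc))
  if (n_assoc > 0) {
    print(x$tests[x$tests$associated,
                  c("cluster", "lag", "dimension", "h", "p")])
  }
  invisible(x)
}
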