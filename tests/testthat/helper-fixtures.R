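# Small fixtures built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_events_df <- function() {
  data.frame(
    word = c("apple", "justice", "chair"),
    onset = c(1.0, 2.5, 4.0),
    offset = c(1.4, 3.0, 4.5),
    class = c("concrete", "abstract", "concrete"),
    rating = c(4.1, 1.2, 3.8),
    stringsAsFactors = FALSE)
}

write_tiny_events <- function(df = tiny_events_df()) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Norms corpus engineered so one dimension has mean 2 and (sample) SD 1:
# ratings 3.5, 1.0, 2.9 for the probe words plus three fillers.
probe_norms <- function(dimension = "Visual") {
  ratings <- c(3.5, 1.0, 2.9, 1.752, 1.752, 1.096)
  words <- c("probe1", "probe2", "probe3", "fill1", "fill2", "fill3")
  m <- matrix(2.5, nrow = 6, ncol = 13, dimnames = list(NULL, NORM_DIMENSIONS))
  m[, "Arousal"] <- 1:6  # keep every SD positive
  m[, "Valence"] <- c(1, 2, 3, 1, 2, 3)
  for (d in setdiff(NORM_DIMENSIONS, c(dimension, "Arousal", "Valence"))) {
    m[, d] <- c(1, 2, 3, 2, 2, 2)
  }
  m[, dimension] <- ratings
  norms_table(data.frame(word = words, m, check.names = FALSE,
                         stringsAsFactors = FALSE))
}

# Orthonormal toy embedding.
toy_embeddings <- function() {
  m <- rbind(cat = c(1, 0), dog = c(0, 1), mixed = c(1, 1) / sqrt(2),
             anti = c(-1, 0))
  embedding_table(m)
}

toy_labels <- function(times, labels, conf = 0.95) {
  label_stream(data.frame(time = times, label = labels,
                          confidence = rep_len(conf, length(times)),
                          stringsAsFactors = FALSE))
}

# Independent brute-force peak/valley finder: compress equal-value runs, then
# compare each interior run with its neighbours. Returns 0-based times of the
# floor-midpoint of each extremal run.
oracle_peaks_valleys <- function(x) {
  runs <- rle(x)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  peaks <- c(); valleys <- c()
  if (length(runs$values) >= 3) {
    for (k in 2:(length(runs$values) - 1)) {
      v <- runs$values[k]
      mid0 <- (starts[k] - 1 + ends[k] - 1) %/% 2
      if (v > runs$values[k - 1] && v > runs$values[k + 1]) peaks <- c(peaks, mid0)
      if (v < runs$values[k - 1] && v < runs$values[k + 1]) valleys <- c(valleys, mid0)
    }
  }
  list(peaks = peaks, valleys = valleys)
}

# Independent tie-corrected Kruskal-Wallis from the textbook rank formula.
oracle_kw <- function(a, b) {
  x <- c(a, b); g <- rep(1:2, c(length(a), length(b)))
  N <- length(x); r <- rank(x)
  Rbar <- tapply(r, g, mean); n_i <- tabulate(g)
  h0 <- 12 / (N * (N + 1)) * sum(n_i * (Rbar - mean(r))^2)
  tt <- table(x)
  corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (corr <= 0) return(0)
  h0 / corr
}
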