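#' Filter an object-label stream by prediction confidence
#'
#' Keeps rows with confidence at or above the cutoff (inclusive at 0.9 by
#' default: "90% or greater").
#'
#' @param labels a `label_stream`.
#' @param min_confidence inclusive lower bound.
#' @return filtered `label_stream`.
#' @export
filter_labels <- function(labels, min_confidence = 0.9) {
  out <- labels[labels$confidence >= min_confidence, , drop = FALSE]
  label_stream(as.data.frame(out), cadence = attr(labels, "cadence"))
}

#' Exclude over-recognized labels
#'
#' Removes every appearance of labels whose total appearance count is at
#' least `sd_mult` (population) standard deviations above the mean per-label
#' count. (On real movie streams this removes ubiquitous generic labels such
#' as "person", "chair" and "tie".)
#'
#' @param labels a `label_stream`.
#' @param sd_mult the SD multiplier (default 3).
#' @return list with `labels` (filtered stream), `excluded` (data.frame of
#'   removed labels and counts), `mean_count`, `sd_count`.
#' @export
exclude_frequent_labels <- function(labels, sd_mult = 3) {
  counts <- table(labels$label)
  if (length(counts) < 2) stop("need at least 2 distinct labels", call. = FALSE)
  mu <- mean(counts)
  sdev <- sqrt(mean((as.numeric(counts) - mu)^2))  # population SD
  cut <- mu + sd_mult * sdev
  bad <- names(counts)[as.numeric(counts) >= cut & as.numeric(counts) > mu]
  out <- labels[!labels$label %in% bad, , drop = FALSE]
  list(labels = label_stream(as.data.frame(out), attr(labels, "cadence")),
       excluded = data.frame(label = bad,
                             count = as.integer(counts[bad])),
       mean_count = mu, sd_count = sdev)
}

#' Context vector for a word onset
#'
#' Unweighted mean of the embedding vectors of every label appearance (with
#' repetition) whose time falls in `[onset - window, onset)`. Labels missing
#' from the vocabulary fall back to the average of their constituent tokens'
#' vectors, else are skipped.
#'
#' @param labels a `label_stream` (already confidence-filtered and
#'   frequency-excluded).
#' @param onset word onset in seconds.
#' @param embeddings an `embedding_table`.
#' @param window context window length in seconds (default 2).
#' @return numeric vector, or `NULL` (undefined context: no usable labels or
#'   a zero-norm average) with attribute-free semantics handled by callers.
#' @export
context_vector <- function(labels, onset, embeddings, window = 2) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  inwin <- labels$label[labels$time >= onset - window & labels$time < onset]
  if (length(inwin) == 0) return(NULL)
  vecs <- lapply(inwin, function(l) embedding_vector(embeddings, l))
  vecs <- vecs[!vapply(vecs, is.null, logical(1))]
  if (length(vecs) == 0) return(NULL)
  v <- colMeans(do.call(rbind, vecs))
  if (sqrt(sum(v^2)) == 0) return(NULL)
  v
}

#' Contextual situatedness score
#'
#' Cosine similarity between a word's embedding and its context vector.
#'
#' @param word token.
#' @param context numeric context vector.
#' @param embeddings an `embedding_table`.
#' @return c in `[-1, 1]` (`NA` for out-of-vocabulary words).
#' @export
situatedness_score <- function(word, context, embeddings) {
  wv <- embedding_vector(embeddings, word)
  if (is.null(wv)) return(NA_real_)
  cosine_sim(wv, context)
}

#' Score contextual situatedness for every word event
#'
#' Full pipeline: confidence filtering (>= 0.9), frequency exclusion (3 SD),
#' a 2-s pre-onset context window averaged over label embeddings, cosine
#' similarity with the word embedding, and condition assignment: situated
#' (c > 0.6), displaced (c < 0.4), excluded otherwise (including the
#' boundary values). Words with undefined context or out-of-vocabulary
#' embeddings are excluded and counted.
#'
#' @param events an `event_table` (only concrete/abstract events are scored).
#' @param labels a raw `label_stream`.
#' @param embeddings an `embedding_table`.
#' @param window context window (s).
#' @param min_confidence confidence cutoff.
#' @param sd_mult frequency-exclusion SD multiplier.
#' @param situated_cut,displaced_cut classification thresholds (strict
#'   inequalities).
#' @return A `situatedness_result`: data.frame (word, onset, class, c,
#'   condition, n_labels) with attributes `excluded_labels`, `n_oov`,
#'   `n_undefined`, `n_negative`.
#' @export
score_situatedness <- function(events, labels, embeddings, window = 2,
                               min_confidence = 0.9, sd_mult = 3,
                               situated_cut = 0.6, displaced_cut = 0.4) {
  keep <- filter_labels(labels, min_confidence)
  excl <- exclude_frequent_labels(keep, sd_mult)
  stream <- excl$labels
  ev <- events[events$class %in% c("concrete", "abstract"), , drop = FALSE]
  n_oov <- 0L; n_undef <- 0L
  rows <- lapply(seq_len(nrow(ev)), function(k) {
    ctx <- context_vector(stream, ev$onset[k], embeddings, window)
    if (is.null(ctx)) {
      n_undef <<- n_undef + 1L
      return(data.frame(word = ev$word[k], onset = ev$onset[k],
                        class = ev$class[k], c = NA_real_,
                        condition = "excluded", n_labels = 0L))
    }
    n_lab <- sum(stream$time >= ev$onset[k] - window & stream$time < ev$onset[k])
    sc <- situatedness_score(ev$word[k], ctx, embeddings)
    if (is.na(sc)) {
      n_oov <<- n_oov + 1L
      cond <- "excluded"
    } else {
      cond <- if (sc > situated_cut) "situated" else
        if (sc < displaced_cut) "displaced" else "excluded"
    }
    data.frame(word = ev$word[k], onset = ev$onset[k], class = ev$class[k],
               c = sc, condition = cond, n_labels = n_lab)
  })
  out <- do.call(rbind, rows)
  structure(out, excluded_labels = excl$excluded, n_oov = n_oov,
            n_undefined = n_undef,
            n_negative = sum(out$c < 0, na.rm = TRUE),
            class = c("situatedness_result", "data.frame"))
}

#' Balance the four word-type x context conditions
#'
#' Splits scored words into concrete-situated, concrete-displaced,
#' abstract-situated and abstract-displaced, and subsamples every cell
#' (without replacement, seeded) to the smallest cell's size.
#'
#' @param result a `situatedness_result`.
#' @param seed subsampling seed.
#' @return A `condition_sets`: named list of four data.frames plus `n`.
#' @export
classify_and_balance <- function(result, seed = 1L) {
  cells <- list(
    concrete_situated = result[result$class == "concrete" &
                                 result$condition == "situated", ],
    concrete_displaced = result[result$class == "concrete" &
                                  result$condition == "displaced", ],
    abstract_situated = result[result$class == "abstract" &
                                 result$condition == "situated", ],
    abstract_displaced = result[result$class == "abstract" &
                                  result$condition == "displaced", ])
  sizes <- vapply(cells, nrow, integer(1))
  if (any(sizes == 0)) {
    stop("empty condition cell(s): ",
         paste(names(sizes)[sizes == 0], collapse = ", "), call. = FALSE)
  }
  n <- min(sizes)
  set.seed(seed)
  balanced <- lapply(cells, function(cc) {
    cc[sort(sample(nrow(cc), n)), , drop = FALSE]
  })
  structure(c(balanced, list(n = n, seed = seed)), class = "condition_sets")
}

#' @export
print.condition_sets <- function(x, ...) {
  cat(sprintf("<condition_sets> %d words per condition (seed %d)\n", x$n, x$seed))
  invisible(x)
}
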