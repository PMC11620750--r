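#' Experiential norm dimensions
#'
#' The 13 experiential dimensions used throughout: 11 sensorimotor dimensions
#' plus valence and arousal.
#'
#' @export
NORM_DIMENSIONS <- c(
  "Auditory", "Gustatory", "Haptic", "Interoception", "Visual",
  "Hand_Arm", "Foot_Leg", "Torso", "Mouth", "Head", "Olfactory",
  "Valence", "Arousal"
)

EVENT_CLASSES <- c("concrete", "abstract", "other")

#' Construct a word-event table
#'
#' Timestamped word events with a class label and per-event amplitude
#' modulators. Times are seconds from run start. Events are sorted by onset;
#' every column other than `word`, `onset`, `offset`, `class` is treated as a
#' modulator and must be finite.
#'
#' @param df data.frame with columns `word`, `onset`, `offset`, `class` and
#'   any number of numeric modulator columns (e.g. `rating`, `luminance`,
#'   `loudness`, `duration`, `frequency`, `speaking_rate`).
#' @param run,participant,movie identifier strings stored as attributes.
#' @return An `event_table` (a validated, sorted data.frame).
#' @export
event_table <- function(df, run = "run1", participant = "sub1", movie = "movie1") {
  required <- c("word", "onset", "offset", "class")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("event table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$onset <- suppressWarnings(as.numeric(df$onset))
  df$offset <- suppressWarnings(as.numeric(df$offset))
  bad <- which(!is.finite(df$onset))
  if (length(bad) > 0) {
    stop("non-numeric or non-finite onset at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(!df$class %in% EVENT_CLASSES)) {
    stop("event class must be one of: ", paste(EVENT_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$onset >= df$offset)) {
    stop("every event must satisfy onset < offset (violated at row(s) ",
         paste(which(df$onset >= df$offset), collapse = ", "), ")",
         call. = FALSE)
  }
  mods <- setdiff(names(df), required)
  for (m in mods) {
    df[[m]] <- as.numeric(df[[m]])
    if (any(!is.finite(df[[m]]))) {
      stop("modulator '", m, "' has non-finite values", call. = FALSE)
    }
  }
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            modulators = mods, run = run, participant = participant,
            movie = movie, class = c("event_table", "data.frame"))
}

#' Read a word-event table from TSV/CSV
#'
#' @param path file path. Header row required; columns `word`, `onset`,
#'   `offset`, `class` are mandatory, all other columns are kept as modulators.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param ... passed to [event_table()] (run/participant/movie ids).
#' @return An `event_table`.
#' @export
read_events <- function(path, dialect = c("tsv", "csv"), ...) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  event_table(df, ...)
}

#' @export
write_events <- function(events, path) {
  write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct an experiential norms table
#'
#' Word-by-dimension ratings on the 13 experiential dimensions
#' ([NORM_DIMENSIONS]). Per-dimension corpus mean and SD are computed over all
#' rows at construction and stored as attributes; word lookup is case-folded.
#'
#' @param df data.frame with a `word` column and exactly the 13 dimension
#'   columns.
#' @return A `norms_table`.
#' @export
norms_table <- function(df) {
  if (!"word" %in% names(df)) stop("norms table needs a 'word' column", call. = FALSE)
  dims <- setdiff(names(df), "word")
  unknown <- setdiff(dims, NORM_DIMENSIONS)
  if (length(unknown) > 0) {
    stop("unknown norm dimension(s): ", paste(unknown, collapse = ", "),
         "; legal names are: ", paste(NORM_DIMENSIONS, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(dims, NORM_DIMENSIONS)) {
    stop("norms table must contain all 13 dimensions; missing: ",
         paste(setdiff(NORM_DIMENSIONS, dims), collapse = ", "), call. = FALSE)
  }
  df <- df[, c("word", NORM_DIMENSIONS)]
  df$word <- tolower(df$word)
  mu <- vapply(df[NORM_DIMENSIONS], mean, numeric(1))
  sdv <- vapply(df[NORM_DIMENSIONS], function(x) sd(x), numeric(1))
  if (any(!is.finite(sdv)) || any(sdv <= 0)) {
    stop("every norm dimension must have SD > 0", call. = FALSE)
  }
  structure(df, dim_means = mu, dim_sds = sdv,
            class = c("norms_table", "data.frame"))
}

#' @rdname norms_table
#' @param path CSV file with `word` plus the 13 dimension columns.
#' @export
read_norms <- function(path) {
  norms_table(read.delim(path, sep = ",", stringsAsFactors = FALSE,
                         check.names = FALSE))
}

#' @export
write_norms <- function(norms, path) {
  write.table(as.data.frame(norms), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Look up norm ratings for words
#'
#' Case-folded lookup; out-of-vocabulary words are dropped and counted
#' (attribute `n_oov`), never imputed.
#'
#' @param norms a `norms_table`.
#' @param words character vector.
#' @param dimension one of the 13 dimension names.
#' @return numeric ratings for in-vocabulary words, with attribute `n_oov`.
#' @export
norm_ratings <- function(norms, words, dimension) {
  dimension <- match.arg(dimension, NORM_DIMENSIONS)
  i <- match(tolower(words), norms$word)
  oov <- sum(is.na(i))
  r <- norms[[dimension]][i[!is.na(i)]]
  structure(r, n_oov = oov)
}

#' Construct / read a word-embedding table
#'
#' Plain-text format: one row per token, `token v1 v2 ... vd`, whitespace
#' delimited, no header. All vectors must share the same dimension; lookup is
#' case-folded.
#'
#' @param mat numeric matrix with one row per token; rownames are tokens.
#' @return An `embedding_table` (matrix with attribute `d`).
#' @export
embedding_table <- function(mat) {
  if (is.null(rownames(mat)) || any(nchar(rownames(mat)) == 0)) {
    stop("embedding table needs non-empty token rownames", call. = FALSE)
  }
  rownames(mat) <- tolower(rownames(mat))
  structure(mat, d = ncol(mat), class = c("embedding_table", class(mat)))
}

#' @rdname embedding_table
#' @param path whitespace-delimited text file.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(trimws(lines), "[ \t]+")
  lens <- lengths(parts)
  if (length(unique(lens)) != 1) {
    stop("embedding rows have inconsistent lengths (rows ",
         paste(head(which(lens != lens[1]), 5), collapse = ", "), " ...)",
         call. = FALSE)
  }
  tokens <- vapply(parts, `[[`, character(1), 1)
  vals <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(lens[1] - 1L)))
  rownames(vals) <- tokens
  embedding_table(vals)
}

#' @export
write_embeddings <- function(emb, path) {
  txt <- vapply(seq_len(nrow(emb)), function(i) {
    paste(c(rownames(emb)[i], format(emb[i, ], digits = 17, trim = TRUE)),
          collapse = " ")
  }, character(1))
  writeLines(txt, path)
  invisible(path)
}

# Case-folded embedding lookup; multi-word labels fall back to the average of
# their constituent tokens' vectors. NULL when fully out of vocabulary.
embedding_vector <- function(emb, token) {
  token <- tolower(token)
  i <- match(token, rownames(emb))
  if (!is.na(i)) return(emb[i, ])
  parts <- strsplit(token, "[ _]+")[[1]]
  if (length(parts) > 1) {
    j <- match(parts, rownames(emb))
    j <- j[!is.na(j)]
    if (length(j) > 0) return(colMeans(emb[j, , drop = FALSE]))
  }
  NULL
}

#' Construct / read a per-frame object-label stream
#'
#' Rows of (time s, label, confidence in `[0, 1]`), non-decreasing in time,
#' with a nominal frame cadence (default 0.16 s, i.e. a prediction every 4th
#' video frame at 25 fps).
#'
#' @param df data.frame with columns `time`, `label`, `confidence`.
#' @param cadence nominal prediction-frame spacing in seconds.
#' @return A `label_stream`.
#' @export
label_stream <- function(df, cadence = 0.16) {
  req <- c("time", "label", "confidence")
  if (!all(req %in% names(df))) {
    stop("label stream needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  df$time <- as.numeric(df$time)
  df$confidence <- as.numeric(df$confidence)
  if (is.unsorted(df$time)) {
    stop("label times must be non-decreasing", call. = FALSE)
  }
  if (any(df$confidence < 0 | df$confidence > 1, na.rm = TRUE)) {
    stop("confidence must lie in [0, 1]", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df[req], cadence = cadence, class = c("label_stream", "data.frame"))
}

#' @rdname label_stream
#' @param path TSV file with header `time`, `label`, `confidence`.
#' @export
read_labels <- function(path, cadence = 0.16) {
  label_stream(read.delim(path, sep = "\t", stringsAsFactors = FALSE), cadence)
}

#' @export
write_labels <- function(labels, path) {
  write.table(as.data.frame(labels), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct a volume grid
#'
#' A 3D or 4D voxel array with a voxel-to-world affine, an analysis mask and,
#' for 4D data, the repetition time. Voxel indices are 0-based in world
#' computations (NIfTI convention); volume t covers `[t, t + TR)` seconds.
#'
#' @param data 3D or 4D numeric array.
#' @param affine 4x4 voxel-to-world matrix (default: identity spacing).
#' @param mask logical array matching the spatial shape; defaults to finite,
#'   non-NaN voxels (of the first volume for 4D data).
#' @param tr repetition time in seconds (4D only).
#' @return A `volume_grid`.
#' @export
volume_grid <- function(data, affine = NULL, mask = NULL, tr = 1) {
  nd <- length(dim(data))
  if (nd < 3 || nd > 4) {
    stop("unsupported volume shape: need 3D or 4D, got ", nd, "D", call. = FALSE)
  }
  spatial <- dim(data)[1:3]
  if (is.null(affine)) {
    affine <- diag(4)
  }
  if (is.null(mask)) {
    first <- if (nd == 4) data[, , , 1, drop = FALSE] else data
    mask <- array(is.finite(as.vector(first)), dim = spatial)
  }
  if (!identical(dim(mask), spatial)) {
    stop("mask shape must equal the spatial shape of the data", call. = FALSE)
  }
  structure(list(data = data, affine = affine, mask = mask,
                 tr = if (nd == 4) tr else NA_real_),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume_grid> ", paste(d, collapse = " x "),
      if (length(d) == 4) sprintf(" (TR %gs)", x$tr) else "",
      "; ", sum(x$mask), " voxels in mask\n", sep = "")
  invisible(x)
}

#' Read / write NIfTI-1 volumes
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return A `volume_grid`; round trips preserve data, shape and affine.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd < 3 || nd > 4) {
    stop("unsupported NIfTI shape: need 3D or 4D, got ", nd, "D", call. = FALSE)
  }
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  tr <- if (nd == 4) RNifti::pixdim(img)[4] else 1
  arr <- array(as.numeric(img), dim = dim(img))
  volume_grid(arr, affine = aff, tr = tr)
}

#' @rdname read_volume
#' @param vol a `volume_grid`.
#' @export
write_volume <- function(vol, path) {
  nd <- length(dim(vol$data))
  pix <- c(0, abs(diag(vol$affine)[1:3]),
           if (nd == 4 && is.finite(vol$tr)) vol$tr else 1, 0, 0, 0)
  img <- RNifti::asNifti(vol$data, reference = list(pixdim = pix),
                         datatype = "double")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
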