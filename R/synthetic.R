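#' Simulation configuration
#'
#' Parameters of the synthetic naturalistic-stimulus generator. Defaults
#' emulate the study conditions of the movie-watching data the pipeline is
#' designed for: TR 1 s, concrete/abstract concreteness-rating means 3.22 and
#' 1.83 (0-5 scale), shared log-frequency distribution (mean 3.61), luminance
#' means 0.72 vs 0.65, loudness 0.69 vs 0.77, a 20-s impulse response, and
#' AR(1) noise.
#'
#' @param run_length run length in seconds.
#' @param tr repetition time in seconds.
#' @param n_per_class word events per class (concrete and abstract).
#' @param rating_means,rating_sds named (concrete/abstract) concreteness-rating
#'   moments on the 0-5 scale.
#' @param freq_mean,freq_sd log word-frequency distribution (shared across
#'   classes unless `freq_offset` is nonzero).
#' @param freq_offset additive log-frequency offset for concrete words.
#' @param luminance_means,loudness_means named per-class means of the visual
#'   and acoustic nuisance modulators (values in `[0, 1]`).
#' @param nuisance_sd common SD of luminance/loudness around their means.
#' @param min_gap minimum spacing between consecutive word onsets in seconds;
#'   the default (2.25 s) keeps each word's 2-s pre-onset context window clear
#'   of the preceding word.
#' @param irf_peak,irf_undershoot shape of the true double-gamma IRF: peak
#'   latency in seconds and relative undershoot amplitude.
#' @param beta_onset amplitude of the unmodulated (onset) response.
#' @param beta_interest amplitude-modulation weight of the concreteness rating
#'   (signal units per rating point, after within-class centering).
#' @param beta_nuisance named modulation weights for nuisance modulators
#'   (default all zero).
#' @param ar AR(1) coefficient of the noise.
#' @param snr effect signal-to-noise ratio: sd of the amplitude-modulated
#'   (interest) signal component divided by the noise sd. Ignored when
#'   `noise_sd` is given directly.
#' @param noise_sd optional explicit noise sd.
#' @param grid_shape spatial grid of the simulated BOLD (default a single
#'   voxel, i.e. an ROI series).
#' @param active_voxels flat voxel indices carrying the interest modulation
#'   (`NULL` = all voxels); inactive voxels receive only the onset response.
#' @param embedding_dim word-embedding dimensionality.
#' @param situated_fraction fraction of word events planted as situated (the
#'   rest are displaced).
#' @param seed random seed (mandatory; every generator is a pure function of
#'   config and seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(run_length = 600, tr = 1, n_per_class = 80,
                       rating_means = c(concrete = 3.22, abstract = 1.83),
                       rating_sds = c(concrete = 0.5, abstract = 0.5),
                       freq_mean = 3.61, freq_sd = 1.0, freq_offset = 0,
                       luminance_means = c(concrete = 0.72, abstract = 0.65),
                       loudness_means = c(concrete = 0.69, abstract = 0.77),
                       nuisance_sd = 0.12, min_gap = 2.25,
                       irf_peak = 5, irf_undershoot = 0.35,
                       beta_onset = 1, beta_interest = 1,
                       beta_nuisance = NULL,
                       ar = 0.3, snr = 1, noise_sd = NULL,
                       grid_shape = c(1, 1, 1), active_voxels = NULL,
                       embedding_dim = 50, situated_fraction = 0.5,
                       seed = 1L) {
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  if (any(rating_sds <= 0) || nuisance_sd <= 0 || freq_sd <= 0) {
    stop("all SDs must be > 0", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# True IRF: difference of gammas with configurable peak latency, normalized to
# peak amplitude 1, support [0, 20] s. Deliberately not in the estimator's
# basis family, so recovery tests are not circular.
true_irf <- function(t, peak = 5, undershoot = 0.35) {
  h <- dgamma(t, shape = peak + 1, rate = 1) -
    undershoot * dgamma(t, shape = 3 * peak + 1, rate = 1)
  tt <- seq(0, 20, by = 0.05)
  hh <- dgamma(tt, shape = peak + 1, rate = 1) -
    undershoot * dgamma(tt, shape = 3 * peak + 1, rate = 1)
  out <- h / max(hh)
  out[t < 0 | t > 20] <- 0
  out
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a synthetic word-event table
#'
#' Equal numbers of concrete and abstract word events with non-overlapping
#' spans, class-specific concreteness-rating distributions, shared frequency
#' distribution, and the standard nuisance modulators (luminance, loudness,
#' duration, log frequency, speaking rate).
#'
#' @param config a [sim_config()].
#' @return An `event_table`.
#' @export
generate_events <- function(config) {
  set.seed(derive_seed(config$seed, "events"))
  n <- config$n_per_class
  n_tot <- 2L * n
  durations <- runif(n_tot, 0.15, 0.6)
  need <- n_tot * config$min_gap + 25  # spacing plus IRF tail margin
  if (need > config$run_length) {
    stop("requested ", n_tot, " events exceed run capacity (need ",
         round(need), " s, run is ", config$run_length, " s)", call. = FALSE)
  }
  slack <- config$run_length - 25 - n_tot * config$min_gap
  gaps <- runif(n_tot)
  gaps <- gaps / sum(gaps) * slack
  onsets <- config$min_gap + cumsum(config$min_gap + gaps) - config$min_gap
  onsets <- onsets - onsets[1] + 2  # first word at 2 s
  classes <- sample(rep(c("concrete", "abstract"), n))
  rating <- ifelse(classes == "concrete",
                   rtrunc_norm(n_tot, config$rating_means["concrete"],
                               config$rating_sds["concrete"], 0, 5),
                   rtrunc_norm(n_tot, config$rating_means["abstract"],
                               config$rating_sds["abstract"], 0, 5))
  luminance <- rtrunc_norm(n_tot, config$luminance_means[classes],
                           config$nuisance_sd, 0, 1)
  loudness <- rtrunc_norm(n_tot, config$loudness_means[classes],
                          config$nuisance_sd, 0, 1)
  frequency <- rnorm(n_tot, config$freq_mean, config$freq_sd) +
    ifelse(classes == "concrete", config$freq_offset, 0)
  n_phonemes <- pmax(2, round(runif(n_tot, 2, 8)))
  speaking_rate <- n_phonemes / durations
  words <- paste0("w", seq_len(n_tot), "_", substr(classes, 1, 1))
  event_table(data.frame(
    word = words, onset = onsets, offset = onsets + durations,
    class = classes, rating = rating, luminance = luminance,
    loudness = loudness, duration = durations, frequency = frequency,
    speaking_rate = speaking_rate, stringsAsFactors = FALSE))
}

#' Simulate amplitude-modulated BOLD from a word-event table
#'
#' Forward model: each event contributes the true IRF scaled by
#' `beta_onset + sum_m beta_m * (modulator_m - class mean)`; responses
#' superpose; AR(1) noise is added. The exact per-set modulation weights, the
#' true IRF sampled at the basis knots, and the noise sd are returned for
#' recovery scoring.
#'
#' @param events an `event_table`.
#' @param config a [sim_config()]. Noise sd is `config$noise_sd` if given,
#'   otherwise calibrated so that sd(modulated interest signal)/sd(noise) =
#'   `config$snr`.
#' @return list with `bold` (a 4D `volume_grid`), `truth` (irf at knots,
#'   betas, noise_sd, clean signal, modulated component).
#' @export
simulate_bold <- function(events, config) {
  set.seed(derive_seed(config$seed, "bold"))
  if (config$run_length < 20) stop("IRF longer than run", call. = FALSE)
  times <- seq(0, config$run_length - config$tr, by = config$tr)
  nT <- length(times)
  sets <- ifelse(events$class == "other", "remaining", as.character(events$class))
  base <- numeric(nT)      # onset + nuisance-modulated signal
  modded <- numeric(nT)    # interest-modulated component
  for (s in unique(sets)) {
    ev <- events[sets == s, , drop = FALSE]
    amp_base <- rep(config$beta_onset, nrow(ev))
    for (m in names(config$beta_nuisance)) {
      amp_base <- amp_base +
        config$beta_nuisance[[m]] * (ev[[m]] - mean(ev[[m]]))
    }
    amp_int <- if (s %in% c("concrete", "abstract")) {
      config$beta_interest * (ev$rating - mean(ev$rating))
    } else rep(0, nrow(ev))
    for (k in seq_len(nrow(ev))) {
      rel <- times - ev$onset[k]
      keep <- rel >= 0 & rel <= 20
      if (!any(keep)) next
      h <- true_irf(rel[keep], config$irf_peak, config$irf_undershoot)
      base[keep] <- base[keep] + amp_base[k] * h
      modded[keep] <- modded[keep] + amp_int[k] * h
    }
  }
  clean <- base + modded
  noise_sd <- if (!is.null(config$noise_sd)) config$noise_sd else {
    ms <- sd(modded)
    if (ms == 0) 1 else ms / config$snr
  }
  nvox <- prod(config$grid_shape)
  data <- array(0, dim = c(config$grid_shape, nT))
  flat <- matrix(0, nvox, nT)
  active <- config$active_voxels
  if (is.null(active)) active <- seq_len(nvox)
  innov_sd <- noise_sd * sqrt(1 - config$ar^2)
  for (v in seq_len(nvox)) {
    eps <- if (noise_sd > 0) {
      e <- stats::filter(rnorm(nT + 50, 0, innov_sd), config$ar,
                         method = "recursive")
      as.numeric(e)[-(1:50)]
    } else numeric(nT)
    flat[v, ] <- base + (if (v %in% active) modded else 0) + eps
  }
  data <- array(t(flat), dim = c(nT, config$grid_shape))
  data <- aperm(data, c(2, 3, 4, 1))
  bold <- volume_grid(data, tr = config$tr)
  truth <- list(
    irf_knots = true_irf(0:20, config$irf_peak, config$irf_undershoot),
    beta_onset = config$beta_onset, beta_interest = config$beta_interest,
    beta_nuisance = config$beta_nuisance, noise_sd = noise_sd,
    clean = clean, modulated = modded)
  list(bold = bold, truth = truth)
}

#' Generate synthetic semantics: norms, embeddings, label stream
#'
#' Builds every semantic input with planted ground truth. Each concrete or
#' abstract word is planted "situated" (its 2-s pre-onset label window is
#' filled with embedding neighbours of the word, so the context average has
#' high cosine similarity to the word vector) or "displaced" (window filled
#' with unrelated background objects). The label stream runs at the prediction
#' cadence (0.16 s). Norms draw every dimension from a common distribution,
#' except that designated words are planted at least one SD above the corpus
#' mean on a designated dimension so reverse-correlation recovery is testable.
#'
#' @param events an `event_table`.
#' @param config a [sim_config()].
#' @param plant_norms optional list(`dimension`, `words`) to plant high norm
#'   ratings.
#' @param plant_outlier_label optional label name to plant with an extreme
#'   appearance count (for testing frequency exclusion).
#' @param cadence label-stream cadence in seconds.
#' @return list with `norms`, `embeddings`, `labels`, and `truth`
#'   (data.frame word/condition plus planting records).
#' @export
generate_semantics <- function(events, config, plant_norms = NULL,
                               plant_outlier_label = NULL, cadence = 0.16) {
  set.seed(derive_seed(config$seed, "semantics"))
  d <- config$embedding_dim
  if (d < 2) stop("embedding dimension must be at least 2", call. = FALSE)
  ev <- events[events$class %in% c("concrete", "abstract"), , drop = FALSE]
  words <- ev$word
  n_bg <- 40L
  bg <- paste0("obj", seq_len(n_bg))

  unit <- function(v) v / sqrt(sum(v^2))
  rand_unit <- function() unit(rnorm(d))
  vocab <- list()
  for (w in words) vocab[[tolower(w)]] <- rand_unit()
  for (b in bg) vocab[[b]] <- rand_unit()

  cond <- ifelse(runif(nrow(ev)) < config$situated_fraction,
                 "situated", "displaced")
  # Context label pools: situated words get 3 neighbour tokens, displaced get
  # background objects.
  pools <- vector("list", nrow(ev))
  for (k in seq_len(nrow(ev))) {
    w <- tolower(ev$word[k])
    if (cond[k] == "situated") {
      nb <- paste0(w, "_ctx", 1:3)
      for (t2 in nb) vocab[[t2]] <- unit(vocab[[w]] + 0.05 * rnorm(d))
      pools[[k]] <- nb
    } else {
      pools[[k]] <- sample(bg, 3)
    }
  }
  if (!is.null(plant_outlier_label)) vocab[[plant_outlier_label]] <- rand_unit()

  emb <- embedding_table(do.call(rbind, vocab))

  # Label stream at the prediction cadence; frames in a word's 2-s pre-onset
  # window draw from that word's pool, other frames show background objects.
  frames <- seq(0, config$run_length, by = cadence)
  owner <- rep(NA_integer_, length(frames))
  for (k in seq_len(nrow(ev))) {
    inwin <- which(frames >= ev$onset[k] - 2 & frames < ev$onset[k])
    owner[inwin] <- k
  }
  lab <- character(length(frames))
  for (i in seq_along(frames)) {
    lab[i] <- if (is.na(owner[i])) sample(bg, 1) else {
      p <- pools[[owner[i]]]
      p[1 + (i %% length(p))]
    }
  }
  confidence <- runif(length(frames), 0.9, 1)
  low <- sample(length(frames), round(0.1 * length(frames)))
  confidence[low] <- runif(length(low), 0.75, 0.9)
  lab_df <- data.frame(time = frames, label = lab, confidence = confidence,
                       stringsAsFactors = FALSE)
  if (!is.null(plant_outlier_label)) {
    extra <- data.frame(time = rep(frames, 4),
                        label = plant_outlier_label, confidence = 0.99)
    lab_df <- rbind(lab_df, extra)
    lab_df <- lab_df[order(lab_df$time), ]
  }
  labels <- label_stream(lab_df, cadence = cadence)

  # Norms: common N(2.5, 1) ratings on the 0-5 scale, planted words pushed
  # >= 2 SD above the mean on the designated dimension.
  vocab_words <- unique(tolower(words))
  ratings <- matrix(rtrunc_norm(length(vocab_words) * 13, 2.5, 1, 0, 5),
                    nrow = length(vocab_words))
  colnames(ratings) <- NORM_DIMENSIONS
  norms_df <- data.frame(word = vocab_words, ratings, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(plant_norms)) {
    dim_ <- match.arg(plant_norms$dimension, NORM_DIMENSIONS)
    i <- match(tolower(plant_norms$words), norms_df$word)
    i <- i[!is.na(i)]
    norms_df[[dim_]][i] <- rtrunc_norm(length(i), 4.7, 0.15, 4.3, 5)
  }
  norms <- norms_table(norms_df)

  truth <- data.frame(word = tolower(words), onset = ev$onset,
                      class = ev$class, condition = cond,
                      stringsAsFactors = FALSE)
  list(norms = norms, embeddings = emb, labels = labels, truth = truth,
       plant_norms = plant_norms, outlier_label = plant_outlier_label)
}

#' Simulate smoothness-matched null volumes
#'
#' Independent zero-mean, exactly unit-variance Gaussian random fields,
#' optionally smoothed with an isotropic Gaussian kernel (circular FFT
#' convolution with a unit-sum-of-squares kernel).
#'
#' @param shape 3D grid shape.
#' @param fwhm smoothing-kernel FWHM in voxel units (0 = white noise).
#' @param n number of fields.
#' @param seed random seed.
#' @return list of `n` 3D arrays.
#' @export
simulate_null_volumes <- function(shape, fwhm, n, seed) {
  if (fwhm < 0) stop("FWHM must be >= 0", call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n), function(i) gaussian_random_field(shape, fwhm))
}

#' Generate a planted peaks-and-valleys dataset
#'
#' Builds a smooth BOLD-like cluster series, locates its peaks and valleys,
#' and plants word events a hemodynamic delay before each extremum: words
#' preceding peaks are rated high (at least one corpus SD above the mean) on
#' the designated dimension, words preceding valleys draw baseline ratings.
#' Onsets are jittered uniformly within `+/- jitter` seconds of the nominal
#' delay, mimicking the continuous onsets of natural speech.
#'
#' @param run_length series length in seconds (TR 1 s).
#' @param dimension the planted experiential dimension.
#' @param delay true word-to-extremum delay in seconds.
#' @param jitter onset jitter half-width in seconds.
#' @param smooth_sd temporal smoothing (s) of the underlying noise, which
#'   sets the extremum density.
#' @param n_background extra vocabulary words with baseline ratings (keeps
#'   the corpus mean/SD stable).
#' @param seed random seed.
#' @return list with `bold` (1-voxel 4D `volume_grid`), `events`, `norms`,
#'   and `truth` (planted dimension, delay, extremum times).
#' @export
generate_pv_data <- function(run_length = 600, dimension = "Valence",
                             delay = 5, jitter = 0.5, smooth_sd = 1.5,
                             n_background = 120, seed = 1L) {
  set.seed(seed)
  dimension <- match.arg(dimension, NORM_DIMENSIONS)
  nT <- run_length
  pad <- 4 * smooth_sd
  w <- rnorm(nT + 2 * pad)
  kern <- dnorm(seq(-pad, pad), 0, smooth_sd)
  x <- as.numeric(stats::filter(w, kern / sum(kern), sides = 2))
  x <- x[(pad + 1):(pad + nT)]
  pv <- find_peaks_valleys(x, tr = 1)

  plant_word <- function(times, prefix) {
    ok <- times - delay - jitter > 0
    data.frame(time = times[ok],
               word = paste0(prefix, seq_len(sum(ok))),
               stringsAsFactors = FALSE)
  }
  pk <- plant_word(pv$peaks, "pk")
  vl <- plant_word(pv$valleys, "vl")
  onset <- c(pk$time, vl$time) - delay + runif(nrow(pk) + nrow(vl),
                                               -jitter, jitter)
  words <- c(pk$word, vl$word)
  ev <- event_table(data.frame(
    word = words, onset = onset, offset = onset + 0.3,
    class = "concrete", stringsAsFactors = FALSE))

  vocab <- c(words, paste0("bg", seq_len(n_background)))
  ratings <- matrix(rtrunc_norm(length(vocab) * 13, 2.5, 1, 0, 5),
                    nrow = length(vocab))
  colnames(ratings) <- NORM_DIMENSIONS
  ratings[seq_len(nrow(pk)), dimension] <-
    rtrunc_norm(nrow(pk), 4.7, 0.15, 4.3, 5)
  norms <- norms_table(data.frame(word = vocab, ratings,
                                  stringsAsFactors = FALSE,
                                  check.names = FALSE))
  bold <- volume_grid(array(x, dim = c(1, 1, 1, nT)), tr = 1)
  list(bold = bold, events = ev, norms = norms,
       truth = list(dimension = dimension, delay = delay,
                    peaks = pv$peaks, valleys = pv$valleys))
}

#' Generate synthetic group-level beta data
#'
#' Per-subject condition betas for group-model validation: a random intercept
#' per participant, optional covariate effects, and a planted condition (or
#' interaction) effect at designated voxels.
#'
#' @param n_subjects number of participants.
#' @param n_voxels number of voxels/ROIs.
#' @param cells data.frame of within-subject cells (e.g. contrast x time), one
#'   row per cell; replicated per subject.
#' @param effect named list: `voxels` (indices), `column` (a cell column
#'   name), `level` (level receiving the shift), `size` (shift in residual-sd
#'   units).
#' @param sd_subject,sd_resid random-intercept and residual SDs.
#' @param seed random seed.
#' @return long data.frame: participant, age, gender, movie, cell columns,
#'   voxel, beta.
#' @export
generate_group_data <- function(n_subjects, n_voxels, cells,
                                effect = NULL, sd_subject = 0.5,
                                sd_resid = 1, seed = 1L) {
  set.seed(seed)
  age <- round(rnorm(n_subjects, 35, 12))
  gender <- sample(c("f", "m"), n_subjects, replace = TRUE)
  movie <- sample(paste0("movie", 1:10), n_subjects, replace = TRUE)
  subj_int <- rnorm(n_subjects, 0, sd_subject)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    cc <- cells[rep(seq_len(nrow(cells)), each = 1), , drop = FALSE]
    for (v in seq_len(n_voxels)) {
      mu <- subj_int[s]
      shift <- numeric(nrow(cc))
      if (!is.null(effect) && v %in% effect$voxels) {
        if (!is.null(effect$interaction)) {
          # crossover: + size where both factors at designated levels, - size
          # where exactly one is
          a <- cc[[effect$interaction$col1]] == effect$interaction$lev1
          b <- cc[[effect$interaction$col2]] == effect$interaction$lev2
          shift <- effect$size * sd_resid * ifelse(a == b, 1, -1)
        } else {
          shift <- ifelse(cc[[effect$column]] == effect$level,
                          effect$size * sd_resid, 0)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant = paste0("sub", s), age = age[s], gender = gender[s],
        movie = movie[s], cc, voxel = v,
        beta = mu + shift + rnorm(nrow(cc), 0, sd_resid),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
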