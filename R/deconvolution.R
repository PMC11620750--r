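#' Build an impulse-response basis set
#'
#' Basis functions for estimating an impulse-response function (IRF) over a
#' post-onset window (default 0-20 s) at regular knots (default every 1 s).
#' `"csplin"` is a cardinal cubic-spline basis (each function is the natural
#' cubic spline that is 1 at its own knot and 0 at all others, so coefficients
#' are the IRF values at the knots, with cubic interpolation between them);
#' `"tent"` is the piecewise-linear analogue. Both families are interpolating:
#' evaluated at the knots, the basis matrix is the identity.
#'
#' @param kind `"csplin"` or `"tent"`.
#' @param window IRF window length in seconds (knots at `0, step, ..., window`).
#' @param step knot spacing in seconds.
#' @param tr repetition time of the series the basis will be sampled on; must
#'   not exceed `step` (knots would be unresolvable).
#' @return An `irf_basis` object.
#' @export
build_basis <- function(kind = c("csplin", "tent"), window = 20, step = 1, tr = 1) {
  kind <- match.arg(kind)
  if (window %% step != 0) stop("window must be divisible by step", call. = FALSE)
  if (tr > step) {
    stop("TR (", tr, ") exceeds the knot step (", step,
         "): knots cannot be resolved", call. = FALSE)
  }
  knots <- seq(0, window, by = step)
  funs <- NULL
  if (kind == "csplin") {
    funs <- lapply(seq_along(knots), function(j) {
      e <- numeric(length(knots)); e[j] <- 1
      stats::splinefun(knots, e, method = "natural")
    })
  }
  structure(list(kind = kind, window = window, step = step, tr = tr,
                 knots = knots, n_basis = length(knots), funs = funs),
            class = "irf_basis")
}

#' @export
print.irf_basis <- function(x, ...) {
  cat(sprintf("<irf_basis> %s, window [0, %g] s, %d knots every %g s\n",
              x$kind, x$window, x$n_basis, x$step))
  invisible(x)
}

#' Evaluate basis functions at arbitrary times
#'
#' @param basis an `irf_basis`.
#' @param t numeric vector of times (seconds since event onset).
#' @return `length(t)` x `n_basis` matrix; zero outside `[0, window]`.
#' @export
basis_matrix <- function(basis, t) {
  n <- basis$n_basis
  out <- matrix(0, length(t), n)
  inside <- t >= 0 & t <= basis$window
  if (!any(inside)) return(out)
  ti <- t[inside]
  if (basis$kind == "tent") {
    for (j in seq_len(n)) {
      out[inside, j] <- pmax(0, 1 - abs(ti - basis$knots[j]) / basis$step)
    }
  } else {
    for (j in seq_len(n)) {
      out[inside, j] <- basis$funs[[j]](ti)
    }
  }
  out
}

#' Evaluate an IRF from basis coefficients
#'
#' @param basis an `irf_basis`.
#' @param coefs coefficient vector (one per knot).
#' @param t times at which to evaluate (default: the knots).
#' @return numeric vector of IRF values.
#' @export
evaluate_irf <- function(basis, coefs, t = basis$knots) {
  as.numeric(basis_matrix(basis, t) %*% coefs)
}

default_nuisance <- c("luminance", "loudness", "duration", "frequency",
                      "speaking_rate")

#' Build an amplitude-modulated deconvolution design matrix
#'
#' One regressor set per word class present in the events (concrete, abstract,
#' remaining = class "other"), each with an onset component (unit impulses
#' spread by the basis) and one column block per modulator (impulses scaled by
#' the modulator value centered to zero mean within the set). An optional
#' "no-speech" set places onset-only impulses at every TR not covered by any
#' word. Legendre drift polynomials are appended per run.
#'
#' @param events an `event_table`.
#' @param basis an `irf_basis`.
#' @param interest name of the modulator of interest (default `"rating"`, the
#'   concreteness/abstractness rating); `NULL` for none.
#' @param nuisance names of nuisance modulator columns; defaults to the
#'   luminance/loudness/duration/frequency/speaking-rate set where present.
#' @param run_length run length in seconds.
#' @param tr repetition time in seconds.
#' @param set_by optional factor/character vector (one per event) overriding
#'   the class-based regressor-set assignment (e.g. word_type x context cells).
#' @param include_no_speech include the no-speech onset-only set.
#' @param drift_order polynomial drift order (Legendre, per run).
#' @return A `deconv_design` with elements `X` (time x columns), `labels`
#'   (data.frame set/component/basis per column), `basis`, `tr`, `times`.
#' @export
build_design <- function(events, basis, interest = "rating",
                         nuisance = intersect(default_nuisance,
                                              attr(events, "modulators")),
                         run_length, tr = 1, set_by = NULL,
                         include_no_speech = TRUE, drift_order = 2L) {
  if (any(events$onset > run_length)) {
    stop("events extend beyond the run", call. = FALSE)
  }
  mods <- c(interest, nuisance)
  missing_mods <- setdiff(mods, names(events))
  if (length(missing_mods) > 0) {
    stop("modulator column(s) not in events: ",
         paste(missing_mods, collapse = ", "), call. = FALSE)
  }
  sets <- if (is.null(set_by)) {
    ifelse(events$class == "other", "remaining", as.character(events$class))
  } else {
    as.character(set_by)
  }
  times <- seq(0, run_length - tr, by = tr)
  nT <- length(times)

  cols <- list(); labels <- list()
  add_block <- function(onsets, weights, set, component) {
    B <- matrix(0, nT, basis$n_basis)
    for (k in seq_along(onsets)) {
      rel <- times - onsets[k]
      keep <- rel >= 0 & rel <= basis$window
      if (!any(keep)) next
      B[keep, ] <- B[keep, ] + weights[k] * basis_matrix(basis, rel[keep])
    }
    cols[[length(cols) + 1L]] <<- B
    labels[[length(labels) + 1L]] <<- data.frame(
      set = set, component = component, basis = seq_len(basis$n_basis),
      stringsAsFactors = FALSE)
  }

  for (s in unique(sets)) {
    ev <- events[sets == s, , drop = FALSE]
    add_block(ev$onset, rep(1, nrow(ev)), s, "onset")
    for (m in mods) {
      v <- ev[[m]]
      if (any(is.na(v))) {
        stop("event '", ev$word[which(is.na(v))[1]], "' has missing modulator '",
             m, "'", call. = FALSE)
      }
      add_block(ev$onset, v - mean(v), s,
                if (!is.null(interest) && m == interest) "interest" else m)
    }
  }

  if (include_no_speech) {
    covered <- rep(FALSE, nT)
    for (k in seq_len(nrow(events))) {
      covered <- covered | (times >= events$onset[k] - tr / 2 &
                            times < events$offset[k] + tr / 2)
    }
    gaps <- times[!covered]
    if (length(gaps) > 0) add_block(gaps, rep(1, length(gaps)), "no-speech", "onset")
  }

  X <- do.call(cbind, cols)
  lab <- do.call(rbind, labels)
  D <- legendre_drift(nT, drift_order)
  X <- cbind(X, D)
  lab <- rbind(lab, data.frame(set = "drift", component = colnames(D),
                               basis = NA_integer_, stringsAsFactors = FALSE))
  colnames(X) <- paste(lab$set, lab$component,
                       ifelse(is.na(lab$basis), "", lab$basis), sep = ".")
  structure(list(X = X, labels = lab, basis = basis, tr = tr, times = times,
                 interest = interest, nuisance = nuisance),
            class = "deconv_design")
}

#' @export
print.deconv_design <- function(x, ...) {
  cat(sprintf("<deconv_design> %d timepoints x %d columns (%s basis); sets: %s\n",
              nrow(x$X), ncol(x$X), x$basis$kind,
              paste(setdiff(unique(x$labels$set), "drift"), collapse = ", ")))
  invisible(x)
}

#' Fit the amplitude-modulated deconvolution model
#'
#' Ordinary least squares of one or more BOLD series on the deconvolution
#' design. Residual autocorrelation is deliberately left to the group stage;
#' the single-subject fit handles slow drift through the design's polynomial
#' columns.
#'
#' @param design a `deconv_design`.
#' @param y numeric vector (one series) or matrix (time x voxels).
#' @param max_condition condition-number threshold above which the design is
#'   declared collinear (error names the dependent columns).
#' @return An `irf_fit`: coefficients (columns x voxels), residuals, residual
#'   variance, degrees of freedom, condition number.
#' @export
fit_deconvolution <- function(design, y, max_condition = 1e8) {
  X <- design$X
  y <- as.matrix(y)
  if (nrow(y) != nrow(X)) {
    stop("series length (", nrow(y), ") does not match design rows (",
         nrow(X), ")", call. = FALSE)
  }
  if (nrow(X) <= ncol(X)) {
    stop("no residual degrees of freedom: ", nrow(X), " timepoints for ",
         ncol(X), " columns", call. = FALSE)
  }
  sv <- svd(X, nu = 0, nv = 0)$d
  cond <- sv[1] / sv[length(sv)]
  if (!is.finite(cond) || cond > max_condition) {
    qrx <- qr(X)
    dep <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    if (length(dep) == 0) dep <- "(near-collinear basis columns)"
    stop("design is rank deficient or ill-conditioned (condition number ",
         format(cond, digits = 3), "); dependent columns: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  fit <- lm.fit(X, y)
  res <- as.matrix(fit$residuals)
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  R <- qr.R(qr(X))
  XtX_inv <- chol2inv(R)
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  structure(list(coefficients = as.matrix(fit$coefficients),
                 labels = design$labels, basis = design$basis,
                 residuals = res, sigma2 = sigma2, df = df,
                 XtX_inv = XtX_inv, condition = cond,
                 interest = design$interest),
            class = "irf_fit")
}

#' @export
coef.irf_fit <- function(object, ...) object$coefficients

#' @export
residuals.irf_fit <- function(object, ...) object$residuals

#' @export
print.irf_fit <- function(x, ...) {
  cat(sprintf("<irf_fit> %d columns x %d series; df = %d; condition = %.3g\n",
              nrow(x$coefficients), ncol(x$coefficients), x$df, x$condition))
  invisible(x)
}

# Column indices of a (set, component) block, ordered by basis index.
block_columns <- function(fit, set, component) {
  i <- which(fit$labels$set == set & fit$labels$component == component)
  if (length(i) == 0) {
    stop("no design block for set '", set, "', component '", component, "'",
         call. = FALSE)
  }
  i[order(fit$labels$basis[i])]
}

#' Extract an estimated IRF
#'
#' @param fit an `irf_fit`.
#' @param set regressor-set name (e.g. `"concrete"`).
#' @param component `"onset"`, `"interest"`, or a nuisance modulator name.
#' @param t evaluation times (default the basis knots).
#' @param series which series (voxel) to use.
#' @return numeric IRF values at `t`.
#' @export
irf_estimate <- function(fit, set, component = "interest", t = fit$basis$knots,
                         series = 1L) {
  i <- block_columns(fit, set, component)
  evaluate_irf(fit$basis, fit$coefficients[i, series], t)
}

#' Per-timepoint t-tests of a single modulated IRF
#'
#' Tests the evaluated IRF of one (set, component) block against zero at each
#' timepoint, using the OLS standard errors.
#'
#' @param fit an `irf_fit`.
#' @param set regressor-set name.
#' @param component component name (default `"interest"`).
#' @param times timepoints in seconds (default `1:window`).
#' @param series which fitted series to use.
#' @return data.frame: `time`, `estimate`, `se`, `tval`, `pval`.
#' @export
modulator_ttests <- function(fit, set, component = "interest",
                             times = seq(fit$basis$step, fit$basis$window,
                                         by = fit$basis$step),
                             series = 1L) {
  i <- block_columns(fit, set, component)
  B <- basis_matrix(fit$basis, times)
  cvec <- matrix(0, length(times), nrow(fit$coefficients))
  cvec[, i] <- B
  est <- as.numeric(cvec %*% fit$coefficients[, series])
  se <- sqrt(fit$sigma2[series] * rowSums((cvec %*% fit$XtX_inv) * cvec))
  tval <- est / se
  data.frame(time = times, estimate = est, se = se, tval = tval,
             pval = 2 * pt(-abs(tval), fit$df))
}

#' Per-timepoint contrasts between two regressor sets
#'
#' Differences of the evaluated modulated IRFs of two sets at `t = 1, ..., 20`
#' seconds (by default), with delta-method standard errors from the OLS fit,
#' plus the per-side area under the curve (the sum of the evaluated IRF over
#' the contrast timepoints).
#'
#' @param fit an `irf_fit`.
#' @param set1,set2 regressor sets to contrast (positive = `set1` higher).
#' @param component which component to contrast (default `"interest"`).
#' @param times contrast timepoints in seconds (default `1:window`, i.e. 20
#'   values for the standard 20-s window).
#' @param series which fitted series (voxel) to use.
#' @return A `contrast_series` data.frame with columns `time`, `estimate`,
#'   `se`, `tval`, `pval`, plus attributes `auc` (named per-side sums) and
#'   `df`.
#' @export
contrast_series <- function(fit, set1, set2, component = "interest",
                            times = seq(fit$basis$step, fit$basis$window,
                                        by = fit$basis$step),
                            series = 1L) {
  i1 <- block_columns(fit, set1, component)
  i2 <- block_columns(fit, set2, component)
  B <- basis_matrix(fit$basis, times)
  cvec <- matrix(0, length(times), nrow(fit$coefficients))
  cvec[, i1] <- B
  cvec[, i2] <- -B
  beta <- fit$coefficients[, series]
  est <- as.numeric(cvec %*% beta)
  se <- sqrt(fit$sigma2[series] * rowSums((cvec %*% fit$XtX_inv) * cvec))
  tval <- est / se
  auc <- c(sum(B %*% beta[i1]), sum(B %*% beta[i2]))
  names(auc) <- c(set1, set2)
  out <- data.frame(time = times, estimate = est, se = se, tval = tval,
                    pval = 2 * pt(-abs(tval), fit$df))
  structure(out, auc = auc, df = fit$df, sets = c(set1, set2),
            class = c("contrast_series", "data.frame"))
}
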