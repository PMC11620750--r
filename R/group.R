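#' Fit the voxelwise group-level mixed-effects model
#'
#' For each voxel, per-subject betas are modeled with a linear mixed-effects
#' model (REML) with a random intercept per participant. Two designs are
#' supported: the across-context design (`contrast` = concrete/abstract by
#' `time` = 20 levels; fixed effects `contrast*time + age + gender + movie`)
#' and the context design (`word_type * context * time + age + gender +
#' movie`). Covariates and factors that are constant in the data are dropped
#' automatically, so degenerate designs (one timepoint, no covariates) reduce
#' to the obvious smaller model. Within-subject residuals can optionally
#' follow an AR(1) process over the time factor. Voxels where the mixed model
#' fails to converge fall back to the degenerate no-random-effect fit and are
#' counted.
#'
#' @param data long data.frame with columns `participant`, `voxel`, `beta`,
#'   the cell factors (`contrast` and `time`, or `word_type`, `context`,
#'   `time`), and optionally `age`, `gender`, `movie`.
#' @param design `"contrast"` or `"context"`.
#' @param ar1 model within-subject residuals as AR(1) over the time factor.
#' @return A `group_fit`: per-voxel fixed effects, covariances, df, residual
#'   matrix (voxel x observation) for smoothness estimation, fallback count.
#' @export
fit_group <- function(data, design = c("contrast", "context"), ar1 = FALSE) {
  design <- match.arg(design)
  factors <- if (design == "contrast") c("contrast", "time") else
    c("word_type", "context", "time")
  needed <- c("participant", "voxel", "beta")
  if (!all(needed %in% names(data))) {
    stop("data needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (length(unique(data$participant)) < 3) {
    stop("need at least 3 subjects", call. = FALSE)
  }
  data$participant <- factor(data$participant)
  for (f in intersect(c(factors, "gender", "movie"), names(data))) {
    data[[f]] <- factor(data[[f]])
  }
  if ("age" %in% names(data)) {
    data$age <- data$age - mean(data$age[!duplicated(data$participant)])
  }

  # keep only terms that vary
  varies <- function(v) v %in% names(data) && length(unique(data[[v]])) > 1
  fac <- Filter(varies, factors)
  cov <- Filter(varies, c("age", "gender", "movie"))
  fixed_terms <- c(if (length(fac) > 0) paste(fac, collapse = "*"), cov)
  if (length(fixed_terms) == 0) fixed_terms <- "1"
  fml <- as.formula(paste("beta ~", paste(fixed_terms, collapse = " + ")))

  voxels <- sort(unique(data$voxel))
  fits <- vector("list", length(voxels))
  resid_mat <- NULL
  fallback <- 0L
  for (vi in seq_along(voxels)) {
    dv <- data[data$voxel == voxels[vi], , drop = FALSE]
    dv <- dv[order(dv$participant), , drop = FALSE]
    corr <- NULL
    if (ar1 && "time" %in% fac) {
      dv$time_num <- as.numeric(as.character(dv$time))
      if (any(is.na(dv$time_num))) dv$time_num <- as.numeric(dv$time)
      inner <- setdiff(fac, "time")
      dv$cell_grp <- if (length(inner) > 0) {
        interaction(dv$participant, do.call(interaction, dv[inner]), drop = TRUE)
      } else dv$participant
      corr <- nlme::corAR1(form = ~ time_num | participant/cell_grp)
    }
    # strict tolerances first (needed for exact degenerate-design reductions),
    # then the stock control as a convergence retry
    fit <- tryCatch(
      nlme::lme(fml, random = ~ 1 | participant, data = dv,
                method = "REML", correlation = corr,
                control = nlme::lmeControl(returnObject = FALSE,
                                           opt = "nlminb", msMaxIter = 500,
                                           niterEM = 0, tolerance = 1e-12,
                                           msTol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        nlme::lme(fml, random = ~ 1 | participant, data = dv,
                  method = "REML", correlation = corr,
                  control = nlme::lmeControl(returnObject = FALSE)),
        error = function(e) NULL)
    }
    if (is.null(fit)) {
      fallback <- fallback + 1L
      fit0 <- if (is.null(corr)) stats::lm(fml, data = dv) else
        tryCatch(nlme::gls(fml, data = dv, correlation = corr, method = "REML"),
                 error = function(e) stats::lm(fml, data = dv))
      beta <- coef(fit0)
      if (inherits(fit0, "gls")) beta <- fit0$coefficients
      V <- vcov(fit0)
      dfree <- nrow(dv) - length(beta)
      res <- residuals(fit0)
    } else {
      beta <- nlme::fixef(fit)
      V <- vcov(fit)
      dfree <- min(fit$fixDF$X)
      res <- residuals(fit, level = 0)
    }
    if (is.null(resid_mat)) {
      resid_mat <- matrix(NA_real_, length(voxels), length(res))
    }
    resid_mat[vi, seq_along(res)] <- res
    fits[[vi]] <- list(beta = beta, vcov = V, df = dfree)
  }
  structure(list(fits = fits, voxels = voxels, formula = fml,
                 factors = fac, covariates = cov, data1 = data[
                   data$voxel == voxels[1], , drop = FALSE],
                 residuals = resid_mat, fallback_count = fallback,
                 design = design, ar1 = ar1),
            class = "group_fit")
}

#' @export
print.group_fit <- function(x, ...) {
  cat(sprintf("<group_fit> %s design, %d voxels, fixed: %s%s; %d fallback fit(s)\n",
              x$design, length(x$voxels), deparse(x$formula[[3]]),
              if (x$ar1) " + AR(1) residuals" else "", x$fallback_count))
  invisible(x)
}

# Fixed-effect contrast row for a cell (named list factor -> level), averaged
# over the levels of any varying factor not pinned by the cell. Built from the
# model matrix so it respects whatever contrasts coding lme used.
cell_row <- function(fit, cell) {
  d1 <- fit$data1
  grid <- list()
  for (f in fit$factors) {
    grid[[f]] <- if (f %in% names(cell)) cell[[f]] else levels(d1[[f]])
  }
  gd <- expand.grid(grid, stringsAsFactors = FALSE)
  for (f in fit$factors) gd[[f]] <- factor(gd[[f]], levels = levels(d1[[f]]))
  for (cv in fit$covariates) {
    gd[[cv]] <- if (is.factor(d1[[cv]])) factor(levels(d1[[cv]])[1],
                                                levels = levels(d1[[cv]]))
    else 0
  }
  gd$beta <- 0
  mm <- model.matrix(fit$formula, gd)
  colMeans(mm)
}

#' General linear test on a group fit
#'
#' Tests a difference between two cells of the design (each a named list of
#' factor levels; factors left out are averaged over — used to collapse over
#' time). Sign convention: positive means the first cell is higher.
#'
#' @param fit a `group_fit`.
#' @param cell_a,cell_b named lists, e.g. `list(contrast = "concrete", time =
#'   "3")` or `list(word_type = "abstract", context = "situated")`.
#' @return data.frame per voxel: `voxel`, `estimate`, `se`, `tval`, `df`,
#'   `zval`.
#' @export
glt <- function(fit, cell_a, cell_b) {
  ca <- cell_row(fit, cell_a)
  cb <- cell_row(fit, cell_b)
  cvec <- ca - cb
  out <- lapply(seq_along(fit$voxels), function(vi) {
    f <- fit$fits[[vi]]
    keep <- names(f$beta)
    cv <- cvec[keep]
    if (any(is.na(cv))) stop("contrast is not estimable in this design",
                             call. = FALSE)
    est <- sum(cv * f$beta)
    se <- sqrt(as.numeric(t(cv) %*% f$vcov %*% cv))
    tval <- est / se
    lp <- pt(abs(tval), f$df, lower.tail = FALSE, log.p = TRUE)
    z <- -sign(tval) * qnorm(lp, log.p = TRUE)
    data.frame(voxel = fit$voxels[vi], estimate = est, se = se,
               tval = tval, df = f$df, zval = z)
  })
  do.call(rbind, out)
}

#' Word-type by context interaction test
#'
#' Double difference (abstract: situated - displaced) minus (concrete:
#' situated - displaced), collapsed over time.
#'
#' @param fit a `group_fit` of the context design.
#' @return per-voxel GLT data.frame.
#' @export
glt_interaction <- function(fit) {
  cvec <- (cell_row(fit, list(word_type = "abstract", context = "situated")) -
             cell_row(fit, list(word_type = "abstract", context = "displaced"))) -
    (cell_row(fit, list(word_type = "concrete", context = "situated")) -
       cell_row(fit, list(word_type = "concrete", context = "displaced")))
  out <- lapply(seq_along(fit$voxels), function(vi) {
    f <- fit$fits[[vi]]
    cv <- cvec[names(f$beta)]
    est <- sum(cv * f$beta)
    se <- sqrt(as.numeric(t(cv) %*% f$vcov %*% cv))
    tval <- est / se
    lp <- pt(abs(tval), f$df, lower.tail = FALSE, log.p = TRUE)
    data.frame(voxel = fit$voxels[vi], estimate = est, se = se, tval = tval,
               df = f$df, zval = -sign(tval) * qnorm(lp, log.p = TRUE),
               pval = 2 * exp(lp))
  })
  do.call(rbind, out)
}

#' Per-timepoint concrete-vs-abstract z maps
#'
#' Runs the 20 per-timepoint general linear tests of the across-context
#' design (one contrast of concrete minus abstract at each time level).
#'
#' @param fit a `group_fit` of the contrast design.
#' @return data.frame: voxel x time with estimate/se/t/z columns.
#' @export
glt_timepoints <- function(fit) {
  times <- levels(fit$data1$time)
  out <- lapply(times, function(tt) {
    g <- glt(fit, list(contrast = "concrete", time = tt),
             list(contrast = "abstract", time = tt))
    g$time <- tt
    g
  })
  do.call(rbind, out)
}

#' The four collapsed-over-time context contrasts
#'
#' Abstract situated vs abstract displaced, concrete situated vs concrete
#' displaced, abstract situated vs concrete situated, abstract displaced vs
#' concrete displaced; each averaged over the time factor.
#'
#' @param fit a `group_fit` of the context design.
#' @return named list of per-voxel GLT data.frames.
#' @export
glt_context <- function(fit) {
  cells <- list(
    abstract_sit_vs_disp = list(
      a = list(word_type = "abstract", context = "situated"),
      b = list(word_type = "abstract", context = "displaced")),
    concrete_sit_vs_disp = list(
      a = list(word_type = "concrete", context = "situated"),
      b = list(word_type = "concrete", context = "displaced")),
    sit_abstract_vs_concrete = list(
      a = list(word_type = "abstract", context = "situated"),
      b = list(word_type = "concrete", context = "situated")),
    disp_abstract_vs_concrete = list(
      a = list(word_type = "abstract", context = "displaced"),
      b = list(word_type = "concrete", context = "displaced")))
  lapply(cells, function(cc) glt(fit, cc$a, cc$b))
}
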