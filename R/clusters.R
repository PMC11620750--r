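CLUSTER_PVALS <- c(0.05, 0.02, 0.01, 0.005, 0.002, 0.001, 0.0005, 0.0002, 0.0001)

# 26-connectivity half-neighbourhood offsets (13 of the 26, one per pair).
half_offsets_26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  as.matrix(g[g$dz > 0 | (g$dz == 0 & g$dy > 0) |
                (g$dz == 0 & g$dy == 0 & g$dx > 0), ])
})

#' Label connected components of a voxel set
#'
#' 26-connectivity (faces, edges and corners) in 3D.
#'
#' @param inset logical 3D array marking the voxels to cluster.
#' @return list with `labels` (integer array, 0 outside) and `sizes` (voxels
#'   per cluster, decreasing).
#' @export
label_clusters <- function(inset) {
  shape <- dim(inset)
  idx <- which(inset)
  n <- length(idx)
  if (n == 0) {
    return(list(labels = array(0L, shape), sizes = integer(0)))
  }
  node <- array(0L, shape)
  node[idx] <- seq_len(n)
  edges <- list()
  for (r in seq_len(nrow(half_offsets_26))) {
    o <- half_offsets_26[r, ]
    sx <- seq(max(1, 1 + o[1]), min(shape[1], shape[1] + o[1]))
    sy <- seq(max(1, 1 + o[2]), min(shape[2], shape[2] + o[2]))
    sz <- seq(max(1, 1 + o[3]), min(shape[3], shape[3] + o[3]))
    a <- node[sx, sy, sz, drop = FALSE]
    b <- node[sx - o[1], sy - o[2], sz - o[3], drop = FALSE]
    both <- a > 0L & b > 0L
    if (any(both)) edges[[length(edges) + 1L]] <- cbind(a[both], b[both])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges) > 0) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, as.vector(t(e)))
  }
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  labels <- array(0L, shape)
  labels[idx] <- relabel[memb]
  list(labels = labels, sizes = sizes[ord])
}

#' Estimate the spatial autocorrelation (smoothness) of residual maps
#'
#' Computes the isotropic spatial autocorrelation function of one or more
#' residual volumes at integer voxel lags (averaged over the three axes and
#' over volumes), and summarizes it on two scales: `fwhm`, the half-width of
#' the ACF itself (the resolution FWHM; 1 voxel for white noise), and
#' `kernel_fwhm`, the FWHM of the equivalent Gaussian smoothing kernel that,
#' applied to white noise, reproduces that ACF (0 for white noise). The null
#' simulator consumes `kernel_fwhm`, so estimation and simulation are
#' mutually consistent. A mixed Gaussian + exponential ACF model
#' `a*exp(-r^2/(2b^2)) + (1-a)*exp(-r/c)` can additionally be fit.
#'
#' @param vols a 3D array, a list of 3D arrays, or a 4D array of residual
#'   volumes.
#' @param mask logical 3D array; statistics are restricted to the mask.
#' @param max_lag largest lag (voxels) at which to measure the ACF.
#' @param mixed also fit the mixed Gaussian+exponential model.
#' @return An `acf_model`: `fwhm`, `kernel_fwhm`, `acf` (by lag), `fit_resid`,
#'   optionally `mixed` (a, b, c).
#' @export
estimate_acf <- function(vols, mask = NULL, max_lag = 6L, mixed = FALSE) {
  if (is.array(vols) && length(dim(vols)) == 4) {
    vols <- lapply(seq_len(dim(vols)[4]), function(i) vols[, , , i])
  }
  if (is.array(vols)) vols <- list(vols)
  shape <- dim(vols[[1]])
  if (is.null(mask)) mask <- array(TRUE, shape)
  if (sum(mask) < 100) {
    stop("mask has fewer than 100 voxels; smoothness fit is unstable",
         call. = FALSE)
  }
  max_lag <- min(max_lag, min(shape) - 1L)

  lag_corr <- function(x, axis, lag) {
    n <- shape[axis]
    pre <- lapply(seq_along(shape), function(a) seq_len(shape[a]))
    post <- pre
    pre[[axis]] <- seq_len(n - lag)
    post[[axis]] <- seq(lag + 1, n)
    a <- do.call(`[`, c(list(x), pre, list(drop = FALSE)))
    b <- do.call(`[`, c(list(x), post, list(drop = FALSE)))
    ma <- do.call(`[`, c(list(mask), pre, list(drop = FALSE)))
    mb <- do.call(`[`, c(list(mask), post, list(drop = FALSE)))
    ok <- ma & mb
    if (sum(ok) < 3) return(NA_real_)
    cor(a[ok], b[ok])
  }
  rho <- vapply(0:max_lag, function(l) {
    if (l == 0) return(1)
    mean(vapply(vols, function(v) {
      mean(vapply(1:3, function(ax) lag_corr(v, ax, l), numeric(1)),
           na.rm = TRUE)
    }, numeric(1)))
  }, numeric(1))
  names(rho) <- 0:max_lag

  # ACF half-width: interpolated radius of the 0.5 crossing, doubled.
  below <- which(rho < 0.5)
  if (length(below) == 0) {
    w_half <- max_lag  # smoother than measurable; report the bound
  } else {
    j <- below[1]
    r1 <- j - 2; r2 <- j - 1  # lags (0-based) bracketing the crossing
    w_half <- r1 + (rho[j - 1] - 0.5) / (rho[j - 1] - rho[j])
  }
  fwhm <- 2 * w_half
  # Invert to the equivalent applied kernel: ACF variance = 2*sigma_k^2 + 1/6
  # (kernel autocorrelation plus the voxel-sampling box).
  s2_acf <- (fwhm / (2 * sqrt(2 * log(2))))^2
  kernel_fwhm <- sigma_to_fwhm(sqrt(max(s2_acf - 1 / 6, 0) / 2))

  gauss_pred <- exp(-(0:max_lag)^2 * 4 * log(2) / max(fwhm, 1e-6)^2)
  out <- list(fwhm = as.numeric(fwhm), kernel_fwhm = as.numeric(kernel_fwhm),
              acf = rho, fit_resid = sqrt(mean((rho - gauss_pred)^2)))
  if (mixed) {
    obj <- function(p) {
      a <- 1 / (1 + exp(-p[1])); b <- exp(p[2]); cc <- exp(p[3])
      pred <- a * exp(-(0:max_lag)^2 / (2 * b^2)) +
        (1 - a) * exp(-(0:max_lag) / cc)
      sum((pred - rho)^2)
    }
    op <- optim(c(0, log(max(fwhm / 2.355, 0.5)), 0), obj)
    out$mixed <- c(a = 1 / (1 + exp(-op$par[1])), b = exp(op$par[2]),
                   c = exp(op$par[3]))
  }
  structure(out, class = "acf_model")
}

#' @export
print.acf_model <- function(x, ...) {
  cat(sprintf("<acf_model> resolution FWHM %.2f vox, kernel FWHM %.2f vox\n",
              x$fwhm, x$kernel_fwhm))
  invisible(x)
}

#' Monte-Carlo cluster-size thresholds at nine voxelwise p-values
#'
#' Simulates smoothness-matched null z-fields and finds, for each voxelwise
#' two-sided p threshold, the smallest cluster size k such that the
#' probability of any noise-only cluster of size >= k (positive or negative,
#' 26-connectivity) is at most `alpha`. Monotonicity (non-increasing k as p
#' decreases) is enforced.
#'
#' @param acf an `acf_model` (or a number, taken as the kernel FWHM).
#' @param shape 3D grid shape.
#' @param mask logical array (default: all voxels).
#' @param n_iter number of null simulations (>= 1000 recommended for
#'   production use).
#' @param alpha corrected (family-wise) alpha.
#' @param pvals voxelwise p-values (default the standard nine).
#' @param seed random seed.
#' @return A `cluster_thresholds` data.frame: `p`, `z_cut`, `k`.
#' @export
simulate_thresholds <- function(acf, shape, mask = NULL, n_iter = 1000,
                                alpha = 0.01, pvals = CLUSTER_PVALS,
                                seed = 1L) {
  kfwhm <- if (inherits(acf, "acf_model")) acf$kernel_fwhm else as.numeric(acf)
  if (is.null(mask)) mask <- array(TRUE, shape)
  zcuts <- qnorm(1 - pvals / 2)
  set.seed(seed)
  maxes <- matrix(0L, n_iter, length(pvals))
  for (it in seq_len(n_iter)) {
    z <- gaussian_random_field(shape, kfwhm)
    z[!mask] <- 0
    maxes[it, ] <- vapply(zcuts, function(zc) {
      mpos <- max(c(0L, label_clusters(z >= zc & mask)$sizes))
      mneg <- max(c(0L, label_clusters(z <= -zc & mask)$sizes))
      max(mpos, mneg)
    }, integer(1))
  }
  k <- vapply(seq_along(pvals), function(j) {
    m <- maxes[, j]
    kk <- 1L
    while (mean(m >= kk) > alpha) kk <- kk + 1L
    kk
  }, integer(1))
  # stricter voxelwise p never needs a larger cluster
  for (j in seq_along(k)[-1]) k[j] <- min(k[j], k[j - 1])
  structure(data.frame(p = pvals, z_cut = zcuts, k = k),
            n_iter = n_iter, alpha = alpha, kernel_fwhm = kfwhm,
            class = c("cluster_thresholds", "data.frame"))
}

#' Multi-threshold cluster correction and cluster table
#'
#' A voxel survives if, at one or more of the voxelwise thresholds, it belongs
#' to a cluster meeting that threshold's minimum size. Positive and negative
#' voxels are clustered separately on `|z| >=` each cut. Surviving voxels keep
#' their original z; final connected components smaller than `min_size`
#' (default 20 voxels) are dropped. The cluster table reports size, peak |z|,
#' |z|-weighted center of mass in world coordinates, and sign.
#'
#' @param statmap a `volume_grid` of z values (3D).
#' @param thresholds a `cluster_thresholds` table.
#' @param min_size minimum final cluster size in voxels.
#' @return list with `map` (a `volume_grid`, z kept at survivors, 0 elsewhere)
#'   and `clusters` (data.frame).
#' @export
multithreshold_merge <- function(statmap, thresholds, min_size = 20) {
  z <- statmap$data
  mask <- statmap$mask
  shape <- dim(z)
  surv <- array(FALSE, shape)
  for (j in seq_len(nrow(thresholds))) {
    zc <- thresholds$z_cut[j]; k <- thresholds$k[j]
    for (sgn in c(1, -1)) {
      lab <- label_clusters((sgn * z >= zc) & mask)
      if (length(lab$sizes) == 0) next
      keep_ids <- which(lab$sizes >= k)
      if (length(keep_ids) > 0) surv <- surv | (lab$labels %in% keep_ids &
                                                  lab$labels > 0)
    }
  }
  dim(surv) <- shape
  rows <- list()
  final <- array(FALSE, shape)
  for (sgn in c(1, -1)) {
    lab <- label_clusters(surv & (sgn * z > 0))
    for (cid in seq_along(lab$sizes)) {
      if (lab$sizes[cid] < min_size) next
      idx <- which(lab$labels == cid)
      final[idx] <- TRUE
      com <- center_of_mass(idx, z[idx], shape, statmap$affine)
      rows[[length(rows) + 1L]] <- data.frame(
        size = lab$sizes[cid], peak_z = max(abs(z[idx])),
        com_x = com[1], com_y = com[2], com_z = com[3],
        sign = if (sgn > 0) "positive" else "negative")
    }
  }
  clusters <- if (length(rows) > 0) {
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$size), , drop = FALSE]
    tab <- cbind(id = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
    tab
  } else {
    data.frame(id = integer(0), size = integer(0), peak_z = numeric(0),
               com_x = numeric(0), com_y = numeric(0), com_z = numeric(0),
               sign = character(0))
  }
  zout <- z
  zout[!final] <- 0
  list(map = volume_grid(zout, affine = statmap$affine, mask = mask),
       clusters = clusters)
}

#' Spatial cosine similarity between two unthresholded maps
#'
#' @param a,b `volume_grid`s or numeric arrays on the same grid.
#' @param mask logical array (default: the intersection of both masks, or all
#'   voxels for plain arrays).
#' @return cosine similarity in `[-1, 1]`.
#' @export
spatial_cosine <- function(a, b, mask = NULL) {
  if (inherits(a, "volume_grid")) {
    if (is.null(mask)) mask <- a$mask & (if (inherits(b, "volume_grid")) b$mask else TRUE)
    a <- a$data
  }
  if (inherits(b, "volume_grid")) b <- b$data
  if (!identical(dim(a), dim(b))) stop("maps are not on a shared grid", call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  cosine_sim(a[mask], b[mask])
}
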