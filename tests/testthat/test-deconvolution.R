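test_that("basis sets interpolate: identity at knots, 21 knots for 20 s", {
  for (kind in c("tent", "csplin")) {
    b <- build_basis(kind)
    expect_equal(b$n_basis, 21)
    B <- basis_matrix(b, b$knots)
    expect_equal(B, diag(21), tolerance = 1e-12)
  }
  # unit tent coefficient vector evaluates to the unit triangle
  b <- build_basis("tent")
  co <- numeric(21); co[6] <- 1   # knot at 5 s
  expect_equal(evaluate_irf(b, co, c(4, 4.5, 5, 5.5, 6)),
               c(0, 0.5, 1, 0.5, 0))
  expect_error(build_basis("tent", tr = 2), "TR")
  expect_error(build_basis("tent", window = 20, step = 3), "divisible")
})

test_that("csplin reproduces a cubic polynomial at the knots", {
  b <- build_basis("csplin")
  f <- function(t) 0.3 * t^3 - 2 * t^2 + t - 4
  co <- f(b$knots)  # cardinal basis: coefficients are knot values
  expect_equal(evaluate_irf(b, co, b$knots), f(b$knots), tolerance = 1e-10)
})

test_that("design centers modulators within set and is time invariant", {
  b <- build_basis("tent")
  df <- data.frame(word = "w1", onset = 5, offset = 5.3, class = "concrete",
                   rating = 3.7)
  ev <- event_table(df)
  d <- build_design(ev, b, run_length = 60, include_no_speech = FALSE)
  # single event: its rating is the set mean, so the interest column is 0
  icol <- d$X[, d$labels$component == "interest"]
  expect_equal(max(abs(icol)), 0)

  df2 <- rbind(df, data.frame(word = "w2", onset = 35, offset = 35.3,
                              class = "concrete", rating = 3.7))
  ev2 <- event_table(df2)
  d2 <- build_design(ev2, b, run_length = 80, include_no_speech = FALSE,
                     drift_order = 0L)
  on <- d2$X[, d2$labels$component == "onset"]
  expect_equal(unname(on[6:26, ]), unname(on[36:56, ]))  # identical, 30 s apart
})

test_that("missing modulators and unknown columns are reported by name", {
  b <- build_basis("tent")
  ev <- event_table(tiny_events_df())
  expect_error(build_design(ev, b, interest = "rating",
                            nuisance = "luminance", run_length = 60),
               "luminance")
})

test_that("noise-free tent-generated data is recovered to machine precision", {
  set.seed(21)
  cfg <- sim_config(n_per_class = 30, run_length = 300, seed = 4)
  ev <- generate_events(cfg)
  b <- build_basis("tent")
  d <- build_design(ev, b, run_length = 300, nuisance = character(0))
  beta <- rnorm(ncol(d$X))
  y <- as.numeric(d$X %*% beta)
  fit <- fit_deconvolution(d, y)
  expect_equal(unname(fit$coefficients[, 1]), beta, tolerance = 1e-9)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("tent and csplin fits agree when responses are sampled on knots", {
  # with onsets on the TR grid every basis function is sampled at its knots,
  # where both families interpolate, so the two designs and fits coincide
  set.seed(22)
  onsets <- sort(sample(seq(2, 270), 40))
  ev <- event_table(data.frame(
    word = paste0("w", seq_along(onsets)), onset = onsets,
    offset = onsets + 0.5,
    class = rep(c("concrete", "abstract"), 20),
    rating = rnorm(40, 2.5, 0.8), stringsAsFactors = FALSE))
  y <- NULL
  fits <- lapply(c("tent", "csplin"), function(kind) {
    d <- build_design(ev, build_basis(kind), run_length = 300,
                      nuisance = character(0), include_no_speech = FALSE)
    if (is.null(y)) {
      beta <- rnorm(ncol(d$X))
      y <<- as.numeric(d$X %*% beta)  # piecewise linear on the knots
    }
    fit_deconvolution(d, y)
  })
  it <- irf_estimate(fits[[1]], "concrete", "interest", t = 0:20)
  ic <- irf_estimate(fits[[2]], "concrete", "interest", t = 0:20)
  expect_equal(it, ic, tolerance = 1e-8)
})

test_that("centering invariance: adding a constant to modulators leaves beta", {
  cfg <- sim_config(n_per_class = 20, run_length = 250, seed = 8,
                    noise_sd = 0.5)
  ev <- generate_events(cfg)
  sim <- simulate_bold(ev, cfg)
  y <- as.vector(sim$bold$data)
  b <- build_basis("csplin")
  d1 <- build_design(ev, b, run_length = 250, nuisance = character(0))
  ev2 <- ev
  ev2$rating <- ev2$rating + 10
  d2 <- build_design(event_table(as.data.frame(ev2)), b,
                     run_length = 250, nuisance = character(0))
  f1 <- fit_deconvolution(d1, y)
  f2 <- fit_deconvolution(d2, y)
  i <- which(f1$labels$set == "concrete" & f1$labels$component == "interest")
  expect_equal(f1$coefficients[i, 1], f2$coefficients[i, 1], tolerance = 1e-8)
})

test_that("rank-deficient designs error with named columns", {
  b <- build_basis("tent")
  ev <- event_table(tiny_events_df())
  d <- build_design(ev, b, run_length = 60, include_no_speech = FALSE,
                    interest = NULL, nuisance = character(0))
  d$X <- cbind(d$X, dup = d$X[, 5])
  d$labels <- rbind(d$labels, data.frame(set = "dup", component = "onset",
                                         basis = 5L))
  expect_error(fit_deconvolution(d, rnorm(nrow(d$X))), "condition number")
})

test_that("estimator is unbiased on white-noise simulations", {
  errs <- sapply(1:20, function(s) {
    cfg <- sim_config(n_per_class = 40, run_length = 400, seed = 300 + s,
                      ar = 0, noise_sd = 1)
    ev <- generate_events(cfg)
    sim <- simulate_bold(ev, cfg)
    d <- build_design(ev, build_basis("csplin"), run_length = 400)
    fit <- fit_deconvolution(d, as.vector(sim$bold$data))
    est <- (irf_estimate(fit, "concrete", "interest", t = 1:20) +
              irf_estimate(fit, "abstract", "interest", t = 1:20)) / 2
    mean(est - sim$truth$irf_knots[2:21])
  })
  sem <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 3 * sem + 1e-3)
})

test_that("permuted modulator values yield null-calibrated t statistics", {
  set.seed(77)
  rates <- sapply(1:15, function(s) {
    cfg <- sim_config(n_per_class = 40, run_length = 400, seed = 400 + s,
                      ar = 0)
    ev <- generate_events(cfg)
    sim <- simulate_bold(ev, cfg)
    ev2 <- as.data.frame(ev)
    ev2$rating <- sample(ev2$rating)  # break the rating-response link
    d <- build_design(event_table(ev2), build_basis("csplin"),
                      run_length = 400)
    fit <- fit_deconvolution(d, as.vector(sim$bold$data))
    tt <- rbind(modulator_ttests(fit, "concrete"),
                modulator_ttests(fit, "abstract"))
    mean(tt$pval < 0.05)
  })
  expect_gt(mean(rates), 0.01)
  expect_lt(mean(rates), 0.12)
})

test_that("contrast series: symmetry, shift, and tent AUC quadrature", {
  cfg <- sim_config(n_per_class = 25, run_length = 300, seed = 14)
  ev <- generate_events(cfg)
  b <- build_basis("tent")
  d <- build_design(ev, b, run_length = 300, nuisance = character(0))
  # construct y from identical interest IRFs on both sides
  beta <- numeric(ncol(d$X))
  lab <- d$labels
  shape <- pmax(0, 1 - abs(1:21 - 8) / 4)
  for (s in c("concrete", "abstract")) {
    beta[lab$set == s & lab$component == "interest"] <- shape
  }
  fit <- fit_deconvolution(d, as.numeric(d$X %*% beta))
  cs <- contrast_series(fit, "concrete", "abstract")
  expect_equal(nrow(cs), 20)
  expect_equal(max(abs(cs$estimate)), 0, tolerance = 1e-9)

  # time-shifted IRF flips the contrast sign at the crossing
  beta2 <- beta
  shifted <- pmax(0, 1 - abs(1:21 - 10) / 4)  # +2 s latency for concrete
  beta2[lab$set == "concrete" & lab$component == "interest"] <- shifted
  fit2 <- fit_deconvolution(d, as.numeric(d$X %*% beta2))
  cs2 <- contrast_series(fit2, "concrete", "abstract")
  early <- cs2$estimate[cs2$time == 6]   # rising side: abstract leads
  late <- cs2$estimate[cs2$time == 10]   # concrete peak
  expect_lt(early, 0)
  expect_gt(late, 0)

  # unit tent at knot 10: AUC over t=1..20 is 1 under the knot-sum rule
  beta3 <- numeric(ncol(d$X))
  beta3[which(lab$set == "concrete" & lab$component == "interest")[11]] <- 1
  fit3 <- fit_deconvolution(d, as.numeric(d$X %*% beta3))
  cs3 <- contrast_series(fit3, "concrete", "abstract")
  expect_equal(unname(attr(cs3, "auc")["concrete"]), 1)
  expect_error(contrast_series(fit3, "concrete", "nope"), "no design block")
})
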