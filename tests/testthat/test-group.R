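test_that("degenerate two-condition design reduces to the paired t-test", {
  cells <- expand.grid(contrast = c("concrete", "abstract"), time = 1)
  d <- generate_group_data(12, 2, cells,
                           effect = list(voxels = 1, column = "contrast",
                                         level = "concrete", size = 0.8),
                           seed = 4)
  d <- d[, c("participant", "contrast", "time", "voxel", "beta")]
  g <- fit_group(d, design = "contrast")
  gl <- glt(g, list(contrast = "concrete"), list(contrast = "abstract"))
  for (v in 1:2) {
    dv <- d[d$voxel == v, ]
    wide <- reshape(dv, idvar = "participant", timevar = "contrast",
                    direction = "wide")
    tt <- t.test(wide$beta.concrete, wide$beta.abstract, paired = TRUE)
    expect_equal(gl$tval[v], unname(tt$statistic), tolerance = 1e-8)
    expect_equal(gl$df[v], unname(tt$parameter))
  }
})

test_that("GLTs are antisymmetric and zero on self-contrasts", {
  cells <- expand.grid(contrast = c("concrete", "abstract"), time = 1:3)
  d <- generate_group_data(8, 3, cells, seed = 5)
  g <- fit_group(d, design = "contrast")
  a <- glt(g, list(contrast = "concrete"), list(contrast = "abstract"))
  b <- glt(g, list(contrast = "abstract"), list(contrast = "concrete"))
  expect_equal(a$zval, -b$zval)
  z0 <- glt(g, list(contrast = "concrete"), list(contrast = "concrete"))
  expect_equal(z0$estimate, rep(0, 3))
})

test_that("balanced fixed-effect estimates match the OLS solution", {
  cells <- expand.grid(contrast = c("concrete", "abstract"), time = 1:4)
  d <- generate_group_data(10, 1, cells, seed = 6)
  g <- fit_group(d, design = "contrast", ar1 = FALSE)
  gl <- glt(g, list(contrast = "concrete"), list(contrast = "abstract"))
  # in this balanced design the OLS estimate is the difference of cell means
  cd <- mean(d$beta[d$contrast == "concrete"]) -
    mean(d$beta[d$contrast == "abstract"])
  expect_equal(gl$estimate, cd, tolerance = 1e-8)
})

test_that("planted-contrast power tracks the analytic paired power", {
  dsize <- 0.6; n_sub <- 30; K <- 40
  hits <- sapply(seq_len(K), function(k) {
    cells <- expand.grid(contrast = c("concrete", "abstract"), time = 1)
    d <- generate_group_data(n_sub, 1, cells,
                             effect = list(voxels = 1, column = "contrast",
                                           level = "concrete", size = dsize),
                             sd_subject = 0.5, sd_resid = 1, seed = 6000 + k)
    d <- d[, c("participant", "contrast", "time", "voxel", "beta")]
    g <- fit_group(d, design = "contrast")
    gl <- glt(g, list(contrast = "concrete"), list(contrast = "abstract"))
    abs(gl$tval) > qt(0.975, gl$df)
  })
  analytic <- power.t.test(n = n_sub, delta = dsize, sd = sqrt(2),
                           type = "paired")$power
  ci <- binom.test(sum(hits), K)$conf.int
  expect_gte(analytic, ci[1] - 0.02)
  expect_lte(analytic, ci[2] + 0.02)
})

test_that("type-I error of the group GLT is nominal on null data", {
  K <- 60
  p <- sapply(seq_len(K), function(k) {
    cells <- expand.grid(contrast = c("concrete", "abstract"), time = 1)
    d <- generate_group_data(10, 1, cells, seed = 7000 + k)
    d <- d[, c("participant", "contrast", "time", "voxel", "beta")]
    g <- fit_group(d, design = "contrast")
    gl <- glt(g, list(contrast = "concrete"), list(contrast = "abstract"))
    2 * pt(-abs(gl$tval), gl$df)
  })
  rate <- mean(p < 0.05)
  expect_lt(rate, 0.15)  # 60 draws: nominal 0.05 stays well below this
})

test_that("permuting participant labels destroys a planted effect", {
  cells <- expand.grid(contrast = c("concrete", "abstract"), time = 1)
  K <- 30
  set.seed(99)
  hits <- sapply(seq_len(K), function(k) {
    d <- generate_group_data(12, 1, cells,
                             effect = list(voxels = 1, column = "contrast",
                                           level = "concrete", size = 1.0),
                             seed = 8000 + k)
    d <- d[, c("participant", "contrast", "time", "voxel", "beta")]
    # shuffle condition labels within participant, killing the pairing
    for (s in unique(d$participant)) {
      i <- which(d$participant == s)
      d$beta[i] <- sample(d$beta[i])
    }
    g <- fit_group(d, design = "contrast")
    gl <- glt(g, list(contrast = "concrete"), list(contrast = "abstract"))
    abs(gl$tval) > qt(0.975, gl$df)
  })
  expect_lt(mean(hits), 0.25)
})

test_that("context-model interaction GLT finds planted crossover voxels", {
  cells <- expand.grid(word_type = c("abstract", "concrete"),
                       context = c("situated", "displaced"), time = 1:5)
  d <- generate_group_data(14, 8, cells,
                           effect = list(voxels = 1:2, size = 0.7,
                                         interaction = list(
                                           col1 = "word_type",
                                           lev1 = "abstract",
                                           col2 = "context",
                                           lev2 = "situated")),
                           seed = 12)
  g <- fit_group(d, design = "context")
  gi <- glt_interaction(g)
  expect_true(all(gi$pval[1:2] < 0.05))
  expect_true(mean(gi$pval[3:8] < 0.05) <= 0.25)
  g4 <- glt_context(g)
  expect_named(g4, c("abstract_sit_vs_disp", "concrete_sit_vs_disp",
                     "sit_abstract_vs_concrete", "disp_abstract_vs_concrete"))
  # crossover: the two situated/displaced simple effects have opposite signs
  expect_gt(g4$abstract_sit_vs_disp$estimate[1], 0)
  expect_lt(g4$concrete_sit_vs_disp$estimate[1], 0)
})

test_that("inestimable contrasts and undersized groups error", {
  cells <- expand.grid(contrast = c("concrete", "abstract"), time = 1)
  d <- generate_group_data(3, 1, cells, seed = 2)
  expect_error(fit_group(d[d$participant %in% c("sub1", "sub2"), ]),
               "3 subjects")
})
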