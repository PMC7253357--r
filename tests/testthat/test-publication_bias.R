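fix <- load_fixture()
fix_eff <- study_effects(fix)

test_that("Egger regression behaves at its analytic anchors", {
  # identical true effect, varying SE: standardized effect is an exact
  # linear function of precision, so the intercept is exactly zero
  se <- c(0.1, 0.2, 0.3, 0.5)
  collinear <- make_effects(rep(0.4, 4), se^2)
  eg <- egger_test(collinear)
  expect_equal(eg$intercept, 0, tolerance = 1e-10)
  expect_equal(eg$p, 1)

  # small studies all inflated: positive bias intercept
  skew <- make_effects(c(0.1, 0.12, 0.9, 1.1), c(0.01, 0.012, 0.3, 0.35))
  expect_gt(egger_test(skew)$intercept, 0)

  expect_error(egger_test(collinear[1:2, ]), "at least 3")
  expect_error(egger_test(make_effects(c(0.1, 0.2, 0.3), rep(0.04, 3))),
               "singular")
})

test_that("Egger p exceeds 0.05 on every analysed fixture stratum", {
  expect_gt(egger_test(fix_eff)$p, 0.05)
  expect_gt(egger_test(study_effects(fix[fix$ancestry == "Asian", ]))$p, 0.05)
  expect_gt(egger_test(study_effects(fix[fix$ancestry == "Caucasian", ]))$p, 0.05)
})

test_that("funnel coordinates are complete, centred and order invariant", {
  pooled <- pool_fixed_iv(fix_eff)
  fd <- funnel_data(fix_eff, pooled)
  expect_equal(nrow(fd$points), 8L)
  expect_true(all(fd$points$y > 0))
  # no fixture study falls outside the pseudo-95% guide lines
  expect_true(all(abs(fd$points$x - fd$centre) <= 1.959964 * fd$points$y))

  perm <- funnel_data(fix_eff[sample(8), ], pooled)
  expect_equal(perm$points[order(perm$points$study_label), ],
               fd$points[order(fd$points$study_label), ], ignore_attr = TRUE)

  solo <- make_effects(pooled$pooled_log_or, 0.05)
  fd1 <- funnel_data(solo, pooled)
  expect_equal(fd1$points$x, fd$centre)
})

test_that("trim-and-fill leaves symmetric sets untouched, bit for bit", {
  sym <- make_effects(0.5 + c(-0.4, -0.2, 0, 0.2, 0.4), rep(0.04, 5))
  for (side in c("left", "right")) {
    tf <- trim_and_fill(sym, side = side)
    expect_equal(tf$k0, 0L)
    expect_equal(nrow(tf$filled), 0L)
    expect_identical(tf$adjusted, pool_fixed_iv(sym))
  }
})

test_that("trim-and-fill detects planted rightmost studies and mirrors them", {
  sym <- make_effects(0.5 + c(-0.3, -0.15, 0, 0.15, 0.3), rep(0.04, 5))
  extra <- make_effects(c(1.6, 1.9), c(0.05, 0.06), c("x1", "x2"))
  eff <- rbind(sym, extra)

  tf <- trim_and_fill(eff, estimator = "R0", side = "right")
  expect_gte(tf$k0, 1L)
  expect_equal(nrow(tf$filled), tf$k0)
  # the imputation shifts the pooled estimate back toward the symmetric core
  expect_lt(tf$adjusted$pooled_log_or, pool_fixed_iv(eff)$pooled_log_or)

  # imputed studies are mirror images about the trimmed pooled value,
  # with the extreme studies' variances copied
  trimmed <- eff[order(eff$log_or, decreasing = TRUE)[-seq_len(tf$k0)], ]
  mu_t <- pool_fixed_iv(trimmed)$pooled_log_or
  extremes <- sort(eff$log_or, decreasing = TRUE)[seq_len(tf$k0)]
  expect_equal(sort(tf$filled$log_or), sort(2 * mu_t - extremes),
               tolerance = 1e-10)
  expect_equal(sort(tf$filled$var),
               sort(eff$var[order(eff$log_or, decreasing = TRUE)[seq_len(tf$k0)]]))

  # full-iteration brute-force oracle reproduces k0 and the adjusted pooling
  o <- oracle_trimfill(eff$log_or, eff$var, "R0")
  expect_equal(tf$k0, o$k0)
  expect_equal(tf$adjusted$pooled_log_or, o$mu_adjusted, tolerance = 1e-12)

  skip_if_not_installed("metafor")
  # metafor's `side` names where studies are imputed (the light side)
  ref <- metafor::trimfill(metafor::rma(yi = eff$log_or, vi = eff$var,
                                        method = "FE"),
                           estimator = "R0", side = "left")
  expect_equal(tf$k0, ref$k0)
  expect_equal(tf$adjusted$pooled_log_or, as.numeric(ref$beta), tolerance = 1e-8)
})

test_that("both estimators agree with the oracle and metafor on random sets", {
  skip_if_not_installed("metafor")
  set.seed(77)
  for (rep in 1:5) {
    k_extra <- sample(0:3, 1)
    y <- c(rnorm(8, 0.2, 0.15), 0.8 + 0.3 * seq_len(k_extra))
    v <- runif(8 + k_extra, 0.02, 0.08)
    eff <- make_effects(y, v)
    for (est in c("L0", "R0")) {
      tf <- trim_and_fill(eff, estimator = est, side = "right")
      o <- oracle_trimfill(y, v, est)
      expect_equal(tf$k0, o$k0)
      expect_equal(tf$adjusted$pooled_log_or, o$mu_adjusted, tolerance = 1e-12)
      ref <- metafor::trimfill(metafor::rma(yi = y, vi = v, method = "FE"),
                               estimator = est, side = "left")
      expect_equal(tf$k0, ref$k0)
      expect_equal(tf$adjusted$pooled_log_or, as.numeric(ref$beta),
                   tolerance = 1e-8)
    }
  }
})

test_that("fixture results stay significant after trim-and-fill", {
  tf <- trim_and_fill(fix_eff)
  expect_gt(tf$adjusted$or, 1)
  expect_gt(tf$adjusted$ci_low, 1)
  expect_error(trim_and_fill(fix_eff[1:2, ]), "at least 3")
})
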