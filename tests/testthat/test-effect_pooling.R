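fix <- load_fixture()
fix_eff <- study_effects(fix)
fix_tabs <- lapply(seq_len(nrow(fix)), function(i) build_contingency(fix[i, ]))

test_that("per-study odds ratios and Woolf variances match direct formulas", {
  wang <- study_effect(build_contingency(fix[2, ]))
  expect_equal(exp(wang$log_or), 2.025, tolerance = 1e-12)
  expect_equal(wang$var, 1 / 81 + 1 / 20 + 1 / 32 + 1 / 16, tolerance = 1e-12)
  expect_equal(wang$se, sqrt(wang$var))
  expect_equal(wang$ci_low, exp(wang$log_or - 1.959964 * wang$se))
  expect_equal(wang$ci_high, exp(wang$log_or + 1.959964 * wang$se))

  lang <- study_effect(build_contingency(fix[1, ]))
  expect_equal(exp(lang$log_or), 432 / 810, tolerance = 1e-12)

  sym <- study_effect(structure(list(a = 10, b = 10, c = 10, d = 10,
                                     corrected = FALSE, label = "sym"),
                                class = "two_by_two"))
  expect_equal(sym$log_or, 0)
})

test_that("continuity-correction policies handle zero cells as specified", {
  zt <- structure(list(a = 10, b = 0, c = 8, d = 4, corrected = FALSE,
                       label = "zero"), class = "two_by_two")
  expect_error(study_effect(zt, "none"), "zero cell")
  half <- study_effect(zt, "add_half_if_zero")
  expect_equal(half$log_or, log(10.5 * 4.5 / (0.5 * 8.5)))
  expect_equal(half$var, 1 / 10.5 + 1 / 0.5 + 1 / 8.5 + 1 / 4.5)
  expect_true(half$corrected)

  clean <- structure(list(a = 10, b = 5, c = 8, d = 4, corrected = FALSE,
                          label = "clean"), class = "two_by_two")
  expect_false(study_effect(clean, "add_half_if_zero")$corrected)
  always <- study_effect(clean, "always_half")
  expect_equal(always$log_or, log(10.5 * 4.5 / (5.5 * 8.5)))

  degenerate <- structure(list(a = 0, b = 0, c = 8, d = 4, corrected = FALSE,
                               label = "deg"), class = "two_by_two")
  expect_error(study_effect(degenerate, "always_half"), "zero total")
})

test_that("inverse-variance pooling matches the brute-force oracle and metafor", {
  pooled <- pool_fixed_iv(fix_eff)
  oracle <- oracle_iv_pool(fix_eff$log_or, fix_eff$var)
  expect_equal(pooled$pooled_log_or, oracle$mu, tolerance = 1e-12)
  expect_equal(pooled$se, oracle$se, tolerance = 1e-12)
  expect_equal(pooled$or, oracle$or, tolerance = 1e-12)
  expect_equal(pooled$p, oracle$p, tolerance = 1e-12)

  skip_if_not_installed("metafor")
  ref <- metafor::rma(yi = fix_eff$log_or, vi = fix_eff$var, method = "FE")
  expect_equal(pooled$pooled_log_or, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(pooled$se, ref$se, tolerance = 1e-10)
})

test_that("pooling is a k=1 identity and is order invariant", {
  single <- pool_fixed_iv(fix_eff[3, ])
  expect_equal(single$pooled_log_or, fix_eff$log_or[3])
  expect_equal(single$se, sqrt(fix_eff$var[3]))

  set.seed(11)
  for (rep in 1:5) {
    perm <- sample(nrow(fix_eff))
    expect_equal(pool_fixed_iv(fix_eff[perm, ])$pooled_log_or,
                 pool_fixed_iv(fix_eff)$pooled_log_or, tolerance = 1e-14)
    expect_equal(pool_random_dl(fix_eff[perm, ])$p,
                 pool_random_dl(fix_eff)$p, tolerance = 1e-14)
  }
  expect_error(pool_fixed_iv(fix_eff[0, ]), "empty")
})

test_that("Mantel-Haenszel pooling matches the hand-computed stratified ratio", {
  mh <- pool_fixed_mh(fix_tabs)
  cells <- t(vapply(fix_tabs, function(t) c(t$a, t$b, t$c, t$d), numeric(4)))
  expect_equal(mh$or, oracle_mh_pool(cells), tolerance = 1e-12)
  expect_equal(mh$or, 138.1489 / 111.8659, tolerance = 1e-4)

  # single table: MH equals the crude OR; duplicated table leaves it unchanged
  one <- pool_fixed_mh(fix_tabs[[2]])
  expect_equal(one$or, 2.025, tolerance = 1e-12)
  two <- pool_fixed_mh(fix_tabs[c(2, 2)])
  expect_equal(two$or, 2.025, tolerance = 1e-12)

  # on this dense fixture MH and IV agree within 1% relative
  iv <- pool_fixed_iv(fix_eff)
  expect_lt(abs(mh$or - iv$or) / iv$or, 0.01)
})

test_that("DerSimonian-Laird pooling matches the oracle and truncates to fixed", {
  asian_eff <- study_effects(fix[fix$ancestry == "Asian", ])
  rd <- pool_random_dl(asian_eff)
  oracle <- oracle_dl_pool(asian_eff$log_or, asian_eff$var)
  expect_equal(rd$pooled_log_or, oracle$mu, tolerance = 1e-12)
  expect_equal(rd$tau2, oracle$tau2, tolerance = 1e-12)

  # Q below its df: random-effects collapses onto fixed-effects exactly
  all_rd <- pool_random_dl(fix_eff)
  all_iv <- pool_fixed_iv(fix_eff)
  expect_equal(all_rd$tau2, 0)
  expect_equal(all_rd$pooled_log_or, all_iv$pooled_log_or)
  expect_equal(all_rd$se, all_iv$se)

  # two identical effects: no heterogeneity, pooled equals the common value
  eq <- make_effects(c(0.3, 0.3), c(0.04, 0.04))
  rd_eq <- pool_random_dl(eq)
  expect_equal(rd_eq$tau2, 0)
  expect_equal(rd_eq$pooled_log_or, 0.3)

  expect_error(pool_random_dl(fix_eff[1, ]), "at least 2")

  skip_if_not_installed("metafor")
  ref <- metafor::rma(yi = asian_eff$log_or, vi = asian_eff$var, method = "DL")
  expect_equal(rd$pooled_log_or, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(rd$tau2, ref$tau2, tolerance = 1e-10)
})

test_that("random-effects intervals are never narrower than fixed-effects", {
  set.seed(202)
  for (rep in 1:20) {
    k <- sample(2:10, 1)
    eff <- make_effects(rnorm(k, 0.2, 0.4), runif(k, 0.01, 0.3))
    fx <- pool_fixed_iv(eff)
    rd <- pool_random_dl(eff)
    expect_gte(rd$se, fx$se - 1e-12)
    expect_gte(log(rd$ci_high) - log(rd$ci_low),
               log(fx$ci_high) - log(fx$ci_low) - 1e-12)
  }
})

test_that("heterogeneity statistics match their definitions", {
  het <- heterogeneity(fix_eff)
  expect_equal(het$q, 6.69714, tolerance = 1e-4)
  expect_equal(het$df, 7L)
  expect_identical(het$i2, 0)

  asian <- heterogeneity(study_effects(fix[fix$ancestry == "Asian", ]))
  expect_equal(asian$i2, 5.558, tolerance = 1e-3)
  expect_equal(asian$p_q, 0.34685, tolerance = 1e-4)

  reps <- make_effects(rep(0.2, 4), rep(0.05, 4))
  same <- heterogeneity(reps)
  expect_equal(same$q, 0)
  expect_identical(same$i2, 0)
  expect_equal(same$p_q, 1)

  expect_error(heterogeneity(fix_eff[1, ]), "at least 2")
})

test_that("small-k pooling agrees with an exhaustive re-computation", {
  # independent brute force over every pair and triple of fixture studies
  for (idx in list(c(1, 2), c(3, 7), c(1, 4, 8), c(2, 5, 6))) {
    eff <- fix_eff[idx, ]
    o_iv <- oracle_iv_pool(eff$log_or, eff$var)
    o_dl <- oracle_dl_pool(eff$log_or, eff$var)
    expect_equal(pool_fixed_iv(eff)$or, o_iv$or, tolerance = 1e-12)
    expect_equal(pool_random_dl(eff)$pooled_log_or, o_dl$mu, tolerance = 1e-12)
    expect_equal(heterogeneity(eff)$q, o_dl$q, tolerance = 1e-12)
  }
})
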