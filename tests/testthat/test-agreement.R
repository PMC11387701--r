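# ICC, Bland-Altman, percent agreement, sample size, reliability report.

test_that("ICC worked example: offset columns", {
  x <- cbind(1:4, 2:5)
  # MSE = 0: consistency is perfect, absolute agreement pays for the offset
  expect_equal(icc(x, type = "consistency")$estimate, 1)
  a <- icc(x, type = "absolute-agreement")
  expect_equal(a$estimate, 10 / 13, tolerance = 1e-12)
  expect_equal(a$ms$MSR, 10 / 3, tolerance = 1e-12)
  expect_equal(a$ms$MSC, 2, tolerance = 1e-12)
  expect_equal(a$ms$MSE, 0, tolerance = 1e-12)
})

test_that("identical columns give ICC 1 with a degenerate-free CI", {
  x <- cbind(c(3, 7, 1, 9, 4), c(3, 7, 1, 9, 4))
  for (ty in c("absolute-agreement", "consistency")) {
    r <- icc(x, type = ty)
    expect_equal(r$estimate, 1)
    expect_equal(unname(r$ci95), c(1, 1))
    expect_identical(r$rating, "excellent")
  }
})

test_that("ICC matches the direct ANOVA-summation oracle on random matrices", {
  mats <- with_seed_local(21, replicate(100, {
    matrix(rnorm(20, 50, 10), 10, 2) + matrix(rnorm(10, 0, 6), 10, 2)
  }, simplify = FALSE))
  for (x in mats) {
    expect_equal(icc(x, type = "absolute-agreement")$estimate,
                 oracle_icc(x, "absolute"), tolerance = 1e-10)
    expect_equal(icc(x, type = "consistency")$estimate,
                 oracle_icc(x, "consistency"), tolerance = 1e-10)
  }
})

test_that("absolute agreement never exceeds consistency; offsets separate them", {
  # the ordering holds whenever subjects truly differ and raters carry a
  # systematic component (MSR > MSE and MSC > MSE), the situation
  # absolute-agreement ICCs exist to penalize
  mats <- with_seed_local(8, replicate(30, {
    m <- matrix(rnorm(24, 10, 2), 8, 3) + matrix(rnorm(8, 0, 9), 8, 3)
    sweep(m, 2, c(-4, 1, 5), `+`)
  }, simplify = FALSE))
  for (x in mats) {
    a <- icc(x, type = "absolute-agreement")$estimate
    c_ <- icc(x, type = "consistency")$estimate
    expect_lte(a, c_ + 1e-12)
    # constant added to one column: consistency invariant, absolute drops
    y <- x; y[, 2] <- y[, 2] + 5
    expect_equal(icc(y, type = "consistency")$estimate, c_, tolerance = 1e-10)
    expect_lt(icc(y, type = "absolute-agreement")$estimate, a)
  }
})

test_that("ICC handles missing rows, degenerate sizes and zero variance", {
  x <- cbind(c(1, 2, 3, 4, NA), c(1.1, 2.2, 2.9, 4.2, 5))
  r <- icc(x)
  expect_identical(r$n_used, 4L)
  expect_identical(r$n_dropped, 1L)
  expect_error(icc(cbind(1:4)), class = "hipmorph_insufficient_data")
  expect_error(icc(matrix(c(1, NA, NA, 2), 2, 2)),
               class = "hipmorph_insufficient_data")
  z <- icc(matrix(5, 4, 2))
  expect_true(is.na(z$estimate))
  expect_match(z$reason, "variance")
})

test_that("ICC confidence intervals bracket the estimate", {
  mats <- with_seed_local(13, replicate(20, matrix(rnorm(30, 20, 5), 10, 3) +
                                          matrix(rnorm(10, 0, 4), 10, 3),
                                        simplify = FALSE))
  for (x in mats) for (ty in c("absolute-agreement", "consistency")) {
    r <- icc(x, type = ty)
    expect_lte(r$ci95[1], r$estimate + 1e-12)
    expect_gte(r$ci95[2], r$estimate - 1e-12)
    expect_gte(r$estimate, -1)
    expect_lte(r$estimate, 1)
  }
})

test_that("ICC rating bands follow the printed ranges", {
  expect_identical(rate_icc(0.49), "poor")
  expect_identical(rate_icc(0.50), "moderate")
  expect_identical(rate_icc(0.75), "moderate")
  expect_identical(rate_icc(0.755), "good")   # band gap goes to the higher band
  expect_identical(rate_icc(0.90), "good")
  expect_identical(rate_icc(0.91), "excellent")
})

test_that("Bland-Altman arithmetic, symmetry and systematic-error rules", {
  # x = y: zero bias, zero-width limits, no systematic error
  x <- c(10, 12, 14, 16)
  b0 <- bland_altman(x, x, kind = "angle")
  expect_equal(b0$bias, 0)
  expect_equal(unname(b0$loa), c(0, 0))
  expect_false(b0$systematic_error)

  # differences 1..4: bias 2.5, sd sqrt(5/3), loa (-0.030, 5.030)
  b <- bland_altman(x + 1:4, x, kind = "angle")
  expect_equal(b$bias, 2.5)
  expect_equal(b$sd_diff, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(unname(b$loa), 2.5 + c(-1, 1) * 1.96 * sqrt(5 / 3),
               tolerance = 1e-12)

  # angle rule: |bias| > 2.5 deg
  expect_true(bland_altman(x + 2.6, x, kind = "angle")$systematic_error)
  expect_false(bland_altman(x + 2.4, x, kind = "angle")$systematic_error)
  # ratio rule: |bias| > 1% of the grand mean of pair averages
  y <- c(300, 310, 290, 305)
  expect_true(bland_altman(y + 4, y, kind = "ratio")$systematic_error)
  expect_false(bland_altman(y + 2, y, kind = "ratio")$systematic_error)

  # antisymmetry of the bias
  expect_equal(bland_altman(x + 1:4, x)$bias, -bland_altman(x, x + 1:4)$bias)

  # incomplete pairs dropped; fewer than 3 left is an error
  expect_error(bland_altman(c(1, 2, NA), c(1, 2, 3)),
               class = "hipmorph_insufficient_data")
})

test_that("percent agreement and its rating bands", {
  pa <- percent_agreement(rep(TRUE, 8), rep(TRUE, 8))
  expect_equal(pa$percent, 100)
  expect_identical(pa$rating, "excellent")
  half <- percent_agreement(c(rep(TRUE, 15), rep(FALSE, 15)), rep(TRUE, 30))
  expect_equal(half$percent, 50)
  expect_identical(half$rating, "moderate")
  none <- percent_agreement(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(none$percent, 0)
  expect_identical(none$rating, "poor")
  expect_identical(percent_agreement(c(rep(TRUE, 71), rep(FALSE, 29)),
                                     rep(TRUE, 100))$rating, "good")
  expect_error(percent_agreement(NA, TRUE), class = "hipmorph_insufficient_data")
})

test_that("ICC sample size: closed form value and monotonicities", {
  # alpha 0.05 one-sided, beta 0.20, k = 2, rho 0.75 -> 0.90, by direct
  # evaluation of the closed form: 1 + 2(1.6449+0.8416)^2*2/ln(7/19)^2 = 25.8
  expect_identical(icc_sample_size(0.75, 0.90, k = 2), 26L)
  # the validation study design (expected reliability 0.8-0.9) needed ~27;
  # the formula at the optimistic end of that range is of the same magnitude
  expect_lt(abs(icc_sample_size(0.75, 0.90, k = 2) - 27L), 5L)
  # more optimistic alternative -> smaller n
  expect_lt(icc_sample_size(0.75, 0.95, k = 2), icc_sample_size(0.75, 0.85, k = 2))
  # more power -> larger n
  expect_gt(icc_sample_size(0.75, 0.90, k = 2, beta = 0.05),
            icc_sample_size(0.75, 0.90, k = 2, beta = 0.20))
  expect_error(icc_sample_size(0.9, 0.8), class = "hipmorph_config")
})

test_that("reliability report: identical sources, reduced n, misalignment", {
  study <- simulate_study(study_spec(n_hips = 8, observer_sds = c(0, 0),
                                     rounds = 1, seed = 2))
  b1 <- study$batches$obs1_round1
  b2 <- study$batches$obs2_round1
  rep0 <- reliability_report(list(a = b1, b = b2))
  expect_true(all(rep0$icc$icc == 1))
  expect_true(all(rep0$bland_altman$bias == 0))
  expect_true(all(rep0$diagnosis$percent_agreement == 100, na.rm = TRUE))
  expect_identical(nrow(rep0$icc), 8L)   # one row per measurement

  # an all-NSA-missing source reduces n for the NSA row only
  b3 <- b2; b3$nsa_deg[1:3] <- NA
  rep1 <- reliability_report(list(a = b1, b = b3))
  expect_identical(rep1$icc$n_used[rep1$icc$measurement == "nsa_deg"], 5L)
  expect_identical(rep1$icc$n_dropped[rep1$icc$measurement == "nsa_deg"], 3L)
  expect_identical(rep1$icc$n_used[rep1$icc$measurement == "lcea_deg"], 8L)

  # misaligned hips are reported
  b4 <- b2; b4$image_id[1] <- "zzz"
  expect_error(reliability_report(list(a = b1, b = b4)), "zzz",
               class = "hipmorph_config")
  # single-hip studies cannot support reliability statistics
  expect_error(reliability_report(list(a = b1[1, ], b = b2[1, ])),
               class = "hipmorph_insufficient_data")
})
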