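test_that("pearson_r matches hand-computed values and flags degeneracy", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_warning(r <- pearson_r(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_true(is.na(r))
  expect_warning(r2 <- pearson_r(c(1, 2), c(2, 1)), "fewer than 3")
  expect_true(is.na(r2))
})

test_that("r is invariant to positive affine transforms", {
  withr::with_seed(10, {
    x <- rnorm(30); y <- rnorm(30)
    r0 <- pearson_r(x, y)
    expect_equal(pearson_r(3 * x + 5, y), r0)
    expect_equal(pearson_r(x, 0.2 * y - 7), r0)
  })
})

test_that("average_and_cv matches the hand-computed example", {
  ac <- average_and_cv(c(0.8, 0.8, 0.9))
  expect_equal(ac$mean, 5 / 6)
  expect_equal(ac$cv_pct, 100 * sd(c(0.8, 0.8, 0.9)) / (5 / 6))
  expect_equal(ac$cv_pct, 6.9282, tolerance = 1e-4)
  expect_equal(average_and_cv(c(2, 2, 2))$cv_pct, 0)
  expect_error(average_and_cv(0.5), "at least 2")
})

test_that("ICC(2,1) is exact in the limits and matches its generating model", {
  withr::with_seed(11, {
    subj <- rnorm(20, 10, 2)
    m <- cbind(subj, subj, subj)
    expect_equal(icc_absolute_agreement(m), 1)
    # variance ratio 9:1 -> ICC = 0.9
    subj <- rnorm(2000, 0, 3)
    noise <- matrix(rnorm(6000), 2000, 3)
    icc <- icc_absolute_agreement(subj + noise)
    expect_equal(icc, 0.9, tolerance = 0.02)
    # absolute agreement penalizes a constant offset in one rater
    shifted <- subj + noise
    shifted[, 2] <- shifted[, 2] + 2
    expect_lt(icc_absolute_agreement(shifted), icc)
    # pure noise: near-zero ICC
    expect_lt(abs(icc_absolute_agreement(matrix(rnorm(1500), 500, 3))), 0.1)
  })
  expect_error(icc_absolute_agreement(matrix(1:8, 4, 2)), "at least 5")
})

test_that("bland_altman matches hand computations and is antisymmetric", {
  ba0 <- bland_altman(1:5, 1:5)
  expect_equal(ba0$mean_abs_diff, 0)
  expect_equal(ba0$sd_abs_diff, 0)
  expect_equal(ba0$cv_pct, 0)
  ba <- bland_altman(c(1, 2, 3), c(2, 2, 2))
  expect_equal(ba$mean_abs_diff, 2 / 3)
  expect_equal(ba$sd_abs_diff, sd(c(1, 0, 1)))
  expect_equal(ba$cv_pct, 100 * (1 / sqrt(2)) / 2)
  withr::with_seed(12, {
    x <- rnorm(20, 10); y <- rnorm(20, 10)
    expect_equal(bland_altman(x, y)$bias, -bland_altman(y, x)$bias)
  })
})

test_that("agreement_study detects an exact duplicate method", {
  withr::with_seed(13, {
    base <- rnorm(30, 1.1, 0.3)
    ft <- make_feature_table(list(a = base, b = base, c = base + rnorm(30, 0, 0.2)))
  })
  ag <- agreement_study(ft)
  ab <- ag$pairs[ag$pairs$pair == "a-b", ]
  expect_equal(ab$r, 1)
  expect_equal(ab$ba_mean_abs_diff, 0)
  expect_lt(max(abs(ag$pairs$r[ag$pairs$pair != "a-b"])), 1)
  expect_equal(ag$icc$n, 30L)
})

test_that("ranking covers every metric exactly once on complete data", {
  withr::with_seed(14, {
    tabs <- lapply(reported_metrics(), function(m) {
      base <- rnorm(24, 10)
      make_feature_table(list(a = base + rnorm(24, 0, 0.5),
                              b = base + rnorm(24, 0, 0.5),
                              c = base + rnorm(24, 0, 0.5)), metric = m)
    })
  })
  ft <- do.call(rbind, tabs)
  class(ft) <- c("feature_table", class(ft))
  ag <- agreement_study(ft)
  expect_setequal(ag$summary$metric, reported_metrics())
  expect_identical(sort(ag$summary$rank), 1:16)
  # 3 pairs x 1 site x 16 metrics
  expect_identical(nrow(ag$pairs), 48L)
})

test_that("undefined cells are excluded from averages, not imputed", {
  withr::with_seed(15, {
    base <- rnorm(30, 5)
    ft1 <- make_feature_table(list(a = base, b = base + rnorm(30, 0, 0.1),
                                   c = base + rnorm(30, 0, 0.1)),
                              metric = "D_t_mean", site = "A")
    ft2 <- make_feature_table(list(a = rep(1, 30), b = rep(2, 30),
                                   c = base), metric = "D_t_mean", site = "B")
  })
  ft <- rbind(ft1, ft2)
  class(ft) <- c("feature_table", class(ft))
  ag <- suppressWarnings(agreement_study(ft))
  dt <- ag$summary[ag$summary$metric == "D_t_mean", ]
  # site B constant columns yield NA r: only defined cells averaged
  defined <- ag$pairs$r[is.finite(ag$pairs$r)]
  expect_equal(dt$mean_r, mean(defined))
  expect_identical(dt$n_cells, length(defined))
})
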