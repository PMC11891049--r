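test_that("histogram counts, exclusion and boundary closure are exact", {
  spec <- histogram_spec("D_p")
  h <- build_histogram(c(0.005, 0.2, 0.05), spec)
  expect_identical(h$n_used, 2L)
  expect_identical(h$n_excluded, 1L)
  expect_equal(h$n_used / h$n_total, 2 / 3, tolerance = 1e-12)
  expect_identical(sum(h$counts), h$n_used)
  # value exactly at range_max goes into the (closed) last bin
  h2 <- build_histogram(0.1, spec)
  expect_identical(h2$counts[100], 1L)
  # empty input: all-zero counts
  h0 <- build_histogram(numeric(0), spec)
  expect_identical(sum(h0$counts), 0L)
  expect_identical(first_order_features(h0)$flag, "empty")
})

test_that("uniform draws fill the fixed-range bins evenly", {
  vals <- withr::with_seed(6, runif(1e4, 0, 0.003))
  h <- build_histogram(vals, histogram_spec("D_t"))
  expect_identical(h$n_used, 10000L)
  expect_lt(max(h$counts) / min(h$counts), 2)
})

test_that("features reproduce hand-computed moments of {1,1,1,5}", {
  # 8 unit bins centered on 1..8; data mass 3 at center 1, 1 at center 5
  spec <- histogram_spec(range_min = 0.5, range_max = 8.5, n_bins = 8)
  h <- build_histogram(c(1, 1, 1, 5), spec)
  expect_identical(h$counts, c(3L, 0L, 0L, 0L, 1L, 0L, 0L, 0L))
  f <- first_order_features(h)
  expect_equal(f$mean, 2)
  expect_equal(f$variance, 3)
  expect_equal(f$skewness, 6 / 3^1.5)
  expect_equal(f$kurtosis, 21 / 9)
  expect_equal(f$minimum, 1)
  expect_equal(f$maximum, 5)
  # excess-kurtosis switch
  expect_equal(first_order_features(h, excess = TRUE)$kurtosis, 21 / 9 - 3)
})

test_that("a constant map collapses to one bin and is flagged degenerate", {
  h <- build_histogram(rep(0.001, 7), histogram_spec("D_t"))
  f <- first_order_features(h)
  # 0.001 falls in bin 34 of [0, 0.003]/100: center 33.5 * 3e-5
  expect_equal(f$minimum, 0.001005)
  expect_equal(f$maximum, 0.001005)
  expect_equal(f$mean, 0.001005)
  expect_identical(f$variance, 0)
  expect_identical(f$skewness, 0)
  expect_identical(f$kurtosis, 0)
  expect_identical(f$flag, "degenerate")
})

test_that("binned moments track raw moments to within quantization", {
  spec <- histogram_spec("D_t")
  halfw <- spec_half_width <- (0.003 / 100) / 2
  vals <- withr::with_seed(8, rnorm(1000, 0.0015, 10 * 0.003 / 100))
  vals <- vals[vals >= 0 & vals <= 0.003]
  f <- first_order_features(build_histogram(vals, spec))
  expect_lt(abs(f$mean - mean(vals)), halfw)
  expect_lt(abs(f$minimum - min(vals)), halfw)
  expect_lt(abs(f$maximum - max(vals)), halfw)
  bw <- 0.003 / 100
  raw_var <- mean((vals - mean(vals))^2)
  expect_lt(abs(f$variance - raw_var), bw^2 / 4 + bw * sd(vals))
})

test_that("conservation and scale equivariance hold on random value sets", {
  withr::with_seed(9, {
    for (i in 1:25) {
      n <- sample(3:200, 1)
      vals <- rnorm(n, 0.05, 0.04) # spills outside [0, 0.1]
      spec <- histogram_spec("D_p")
      h <- build_histogram(vals, spec)
      expect_identical(h$n_used + h$n_excluded, n)
      f <- first_order_features(h)
      # scale values and range by c: min/max/mean scale, skew/kurt invariant
      cc <- 7.5
      spec2 <- histogram_spec(range_min = 0, range_max = 0.1 * cc)
      f2 <- first_order_features(build_histogram(vals * cc, spec2))
      expect_equal(f2$mean, f$mean * cc)
      expect_equal(f2$minimum, f$minimum * cc)
      expect_equal(f2$variance, f$variance * cc^2)
      expect_equal(f2$skewness, f$skewness)
      expect_equal(f2$kurtosis, f$kurtosis)
      if (f$n_used >= 2 && f$variance > 0) {
        expect_gte(f$kurtosis, f$skewness^2 + 1 - 1e-12)
      }
    }
  })
})

test_that("per-parameter exclusion drives utilization independently", {
  sC <- site_bvalue_scheme("C")
  Y <- make_noisy_voxels(60, 0.1, 0.01, 0.001, sC, snr = 10, seed = 16)
  map <- fit_roi(Y, sC, "seg_a")
  ff <- features_for_map(map)
  fp <- ff[ff$parameter == "f_p", ]
  dp <- ff[ff$parameter == "D_p", ]
  expect_equal(fp$utilization, 1)        # f_p clipped into [0,1]: always used
  expect_lt(dp$utilization, 1)           # seg_a rejects out-of-range D_p
  expect_identical(dp$n_used, sum(map$in_range_D_p))
})

test_that("oracle features of a homogeneous lesion equal the truth", {
  sB <- site_bvalue_scheme("B")
  clean <- ivim_signal(ivim_params(0.123, 0.015, 0.0011, S0 = 50), sB$b_values)
  Y <- matrix(clean, 4, length(clean), byrow = TRUE)
  map <- fit_roi(Y, sB, "oracle")
  ff <- features_for_map(map)
  expect_equal(ff$mean[ff$parameter == "D_t"], 0.0011,
               tolerance = (0.003 / 100) / 2 / 0.0011)
  expect_equal(ff$mean[ff$parameter == "f_p"], 0.123,
               tolerance = (1 / 100) / 2 / 0.123)
  expect_equal(ff$utilization, rep(1, 3))
})

test_that("feature_table emits the 16 reported metrics per patient-method", {
  cfg <- cohort_config(counts = tiny_counts(1L, 1L))
  coh <- generate_cohort(cfg, seed = 6)
  maps <- list(seg_a = lapply(seq_along(coh$lesions), function(i)
    fit_roi(coh$signals[[i]], coh$lesions[[i]]$scheme, "seg_a")))
  ft <- feature_table(coh, maps)
  expect_setequal(unique(ft$metric), reported_metrics())
  expect_identical(nrow(ft), 6L * 16L)
  expect_identical(anyDuplicated(ft[, c("patient_id", "method", "metric")]), 0L)
  expect_false("f_p_min" %in% ft$metric)
})
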