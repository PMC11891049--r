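test_that("lesion centers reproduce the published distributions", {
  streams <- rng_streams(101, 500)
  centers <- t(vapply(streams, function(st)
    sample_lesion("C", "malignant", stream = st)$center, numeric(3)))
  # published Site C malignant D_t: 0.93 +/- 0.29 (1e-3 mm^2/s)
  sem <- 0.29e-3 / sqrt(500)
  expect_lt(abs(mean(centers[, "D_t"]) - 0.93e-3), 3 * sem)
  # physical ordering enforced for every draw
  expect_true(all(centers[, "D_p"] >= centers[, "D_t"]))
})

test_that("voxel counts match the published ROI sizes", {
  streams <- rng_streams(202, 500)
  nv <- vapply(streams, function(st)
    sample_lesion("A", "benign", stream = st)$n_voxels, integer(1))
  sem <- 143 / sqrt(500)
  expect_lt(abs(mean(nv) - 201), 3 * sem)
  expect_true(all(nv >= 3))
})

test_that("zero variability collapses voxels onto the center", {
  cfg <- cohort_config(variability = 0)
  les <- sample_lesion("B", "benign", stream = rng_streams(3, 1)[[1]],
                       config = cfg)
  expect_true(all(les$truth$f_p == les$center["f_p"]))
  expect_true(all(les$truth$D_p == les$center["D_p"]))
  expect_true(all(les$truth$D_t == les$center["D_t"]))
})

test_that("unknown site/label combinations error", {
  expect_error(sample_lesion("Z", "benign"), "no reference entry")
})

test_that("tiny cohorts satisfy all structural invariants", {
  coh <- generate_cohort(cohort_config(counts = tiny_counts(1L, 1L)), seed = 5)
  expect_identical(nrow(coh$patients), 6L)
  expect_identical(length(coh$lesions), 6L)
  for (i in seq_along(coh$lesions)) {
    les <- coh$lesions[[i]]
    sig <- coh$signals[[i]]
    expect_gte(les$n_voxels, 3L)
    expect_identical(dim(sig), c(les$n_voxels,
                                 length(les$scheme$b_values)))
    expect_true(all(sig > 0))
    expect_true(all(les$truth$f_p >= 0 & les$truth$f_p <= 1))
    expect_true(all(les$truth$D_p >= les$truth$D_t))
  }
  # one lesion per patient, prevalence exactly as configured
  expect_identical(anyDuplicated(coh$patients$patient_id), 0L)
  tab <- table(coh$patients$site, coh$patients$label)
  expect_true(all(tab == 1L))
})

test_that("cohorts are a pure function of (config, seed)", {
  cfg <- cohort_config(counts = tiny_counts())
  a <- generate_cohort(cfg, seed = 9)
  b <- generate_cohort(cfg, seed = 9)
  expect_identical(a$signals, b$signals)
  expect_identical(a$patients, b$patients)
  c <- generate_cohort(cfg, seed = 10)
  expect_false(identical(a$signals, c$signals))
})

test_that("signals decay in expectation and classes separate as published", {
  cfg <- cohort_config(counts = data.frame(
    site = "C", label = c("benign", "malignant"), n_patients = c(100L, 100L)))
  coh <- generate_cohort(cfg, seed = 21)
  # mean signal at the highest b below mean signal at b = 0, per lesion
  for (i in seq_len(6)) {
    sig <- coh$signals[[i]]
    expect_lt(mean(sig[, ncol(sig)]), mean(sig[, 1]))
  }
  dt_centers <- vapply(coh$lesions, function(l) l$center[["D_t"]], numeric(1))
  lab <- coh$patients$label
  expect_gt(mean(dt_centers[lab == "benign"]),
            mean(dt_centers[lab == "malignant"]))
  expect_lt(t.test(dt_centers[lab == "benign"],
                   dt_centers[lab == "malignant"])$p.value, 0.01)
})

test_that("Site A sub-schemes are apportioned by their usage counts", {
  v <- apportion_variants(58)
  expect_identical(tabulate(v, 5), c(9L, 24L, 10L, 14L, 1L))
  expect_identical(length(apportion_variants(10)), 10L)
  coh <- generate_cohort(cohort_config(counts = data.frame(
    site = "A", label = "malignant", n_patients = 12L)), seed = 2)
  expect_true(all(coh$patients$variant %in% 1:5))
  for (i in seq_len(nrow(coh$patients))) {
    expect_identical(coh$lesions[[i]]$scheme$variant, coh$patients$variant[i])
  }
})
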