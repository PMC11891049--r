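test_that("logistic fit flags complete separation but keeps perfect ranks", {
  x <- c(1:10, 21:30)
  y <- rep(c(0, 1), each = 10)
  site <- rep("A", 20)
  fit <- fit_site_adjusted_logistic(x, site, y)
  expect_true(fit$separation_flag)
  p <- predict_prob(fit, x, site)
  expect_equal(auc_delong(p, y)$auc, 1)
  expect_true(all(is.finite(fit$coefficients)))
})

test_that("null slope estimates stay within 3 Wald SEs of zero", {
  withr::with_seed(16, {
    x <- rnorm(2000)
    y <- rbinom(2000, 1, 0.5) # independent of x
  })
  site <- rep("A", 2000)
  fit <- fit_site_adjusted_logistic(x, site, y)
  # independent oracle: glm's Wald SE on the same design
  ref <- glm(y ~ x, family = binomial())
  se <- summary(ref)$coefficients["x", "Std. Error"]
  slope <- fit$coefficients["siteA:x"]
  expect_lt(abs(slope), 3 * se * sd(x) + 1e-9)
  expect_equal(unname(slope), unname(coef(ref)["x"] * sd(x)), tolerance = 1e-4)
})

test_that("site-specific slopes recover opposite generating signs", {
  withr::with_seed(17, {
    n <- 1000
    x1 <- rnorm(n); y1 <- rbinom(n, 1, plogis(2 * x1))
    x2 <- rnorm(n); y2 <- rbinom(n, 1, plogis(-2 * x2))
  })
  fit <- fit_site_adjusted_logistic(c(x1, x2), rep(c("A", "B"), each = n),
                                    c(y1, y2))
  expect_gt(fit$coefficients["siteA:x"], 0)
  expect_lt(fit$coefficients["siteB:x"], 0)
})

test_that("predicted probabilities follow the inverse logit", {
  fit <- structure(list(coefficients = c(siteA = 0, `siteA:x` = 1),
                        sites = "A", shared_slope = FALSE, center = 0,
                        scale = 1, converged = TRUE, separation_flag = FALSE),
                   class = "ivim_logit")
  expect_equal(predict_prob(fit, 0, "A"), 0.5)
  expect_equal(predict_prob(fit, log(3), "A"), 0.75)
  # monotone within site for positive slope
  xs <- sort(rnorm(20))
  expect_true(all(diff(predict_prob(fit, xs, rep("A", 20))) > 0))
  expect_error(predict_prob(fit, 1, "B"), "unseen site")
})

test_that("DeLong AUC and SE match hand-computed examples", {
  # benign 0.3/0.5, malignant 0.2/0.4: 1 of 4 pairs concordant
  r <- auc_delong(c(0.3, 0.5, 0.2, 0.4), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.25)
  # benign 1/3, malignant 2/4: placements give S10 = S01 = 0.125
  r2 <- auc_delong(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(r2$auc, 0.75)
  expect_equal(r2$se, sqrt(0.125 / 2 + 0.125 / 2))
  # perfect separation: SE = 0
  r3 <- auc_delong(c(1, 2, 10, 20), c(0, 0, 1, 1))
  expect_equal(r3$auc, 1)
  expect_equal(r3$se, 0)
  expect_error(auc_delong(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals brute-force pair counting, with ties and antisymmetry", {
  withr::with_seed(18, {
    for (i in 1:30) {
      n <- sample(6:30, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # ties likely
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      m <- sum(labels == 1); nn <- sum(labels == 0)
      expect_identical(round(2 * m * nn * auc_delong(scores, labels)$auc),
                       round(2 * m * nn * auc_brute(scores, labels)))
      cont <- rnorm(n) # tie-free
      expect_equal(auc_delong(cont, labels)$auc +
                     auc_delong(-cont, labels)$auc, 1)
    }
  })
})

test_that("DeLong machinery agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  withr::with_seed(19, {
    labels <- rbinom(80, 1, 0.5)
    s1 <- rnorm(80) + labels
    s2 <- rnorm(80) + 0.8 * labels
  })
  mine <- auc_delong(s1, labels)
  ref <- pROC::roc(labels, s1, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
  expect_equal(mine$se, sqrt(pROC::var(ref, method = "delong")))
  ref2 <- pROC::roc(labels, s2, quiet = TRUE, direction = "<")
  mine_test <- delong_paired_test(s1, s2, labels)
  ref_test <- pROC::roc.test(ref, ref2, method = "delong", paired = TRUE)
  expect_equal(mine_test$p, ref_test$p.value, tolerance = 1e-10)
})

test_that("paired test is degenerate for rank-identical classifiers", {
  withr::with_seed(20, {
    labels <- rbinom(40, 1, 0.5)
    s <- rnorm(40)
  })
  expect_equal(delong_paired_test(s, s, labels)$p, 1)
  r <- delong_paired_test(s, 2 * s + 7, labels)
  expect_equal(r$p, 1)
  expect_true(r$degenerate)
})

test_that("leave-one-patient-out AUC behaves for strong and null effects", {
  withr::with_seed(21, {
    n <- 60
    y <- rep(c(0, 1), each = n / 2)
    site <- rep("A", n)
    x_strong <- rnorm(n) + 3 * y
    lou_s <- lou_cv_auc(x_strong, site, y)
    fit <- fit_site_adjusted_logistic(x_strong, site, y)
    ap <- auc_delong(predict_prob(fit, x_strong, site), y)
    expect_lt(abs(lou_s$auc - ap$auc), 0.05)
    # permuted labels: LOU AUC near chance
    n2 <- 300
    y2 <- sample(rep(c(0, 1), each = n2 / 2))
    site2 <- rep(c("A", "B", "C"), each = n2 / 3)
    x2 <- rnorm(n2)
    lou_null <- lou_cv_auc(x2, site2, y2)
    expect_gt(lou_null$auc, 0.4)
    expect_lt(lou_null$auc, 0.6)
  })
})

test_that("diagnostic_study summarizes identical methods degenerately", {
  withr::with_seed(22, {
    base <- rnorm(36, 0, 1)
    labels <- rep(c("benign", "malignant"), 18)
    base <- base + 1.5 * (labels == "malignant")
    ft <- make_feature_table(list(a = base, b = base, c = base),
                             labels = labels)
  })
  ds <- diagnostic_study(ft, lou = FALSE)
  expect_equal(ds$summary$cv_auc_pct, 0)
  expect_true(all(ds$delong$p == 1))
  expect_identical(nrow(ds$auc), 3L)
})

test_that("diagnostic_study ranks a more separable metric higher", {
  withr::with_seed(23, {
    n <- 60
    labels <- rep(c("benign", "malignant"), n / 2)
    strong <- lapply(1:3, function(i) rnorm(n) + 2.5 * (labels == "malignant"))
    weak <- lapply(1:3, function(i) rnorm(n) + 0.3 * (labels == "malignant"))
    names(strong) <- names(weak) <- c("a", "b", "c")
    ft <- rbind(make_feature_table(strong, metric = "D_t_mean", labels = labels),
                make_feature_table(weak, metric = "D_p_mean", labels = labels))
    class(ft) <- c("feature_table", class(ft))
  })
  ds <- diagnostic_study(ft)
  s <- ds$summary
  expect_lt(s$rank_apparent[s$metric == "D_t_mean"],
            s$rank_apparent[s$metric == "D_p_mean"])
  expect_true(all(ds$auc$lou_auc <= ds$auc$auc + 0.1))
})
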