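test_that("confusion counts match a naive loop and the boundary rule", {
  cc <- confusion(c(0.9, 0.4), c(1, 0))
  expect_equal(unlist(cc), c(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  expect_equal(confusion(0.5, 0)$fp, 1)   # boundary counts positive
  expect_error(confusion(numeric(0), numeric(0)), "empty")
  expect_error(confusion(c(0.1, 0.2), 1), "mismatch")
  withr::with_seed(12, {
    for (r in 1:50) {
      s <- runif(40)
      l <- rbinom(40, 1, 0.3)
      th <- runif(1)
      expect_equal(unlist(confusion(s, l, th)), oracle_confusion(s, l, th))
    }
  })
})

test_that("MCC hits its bounds and the worked arithmetic", {
  expect_equal(mcc(tibble::tibble(tp = 5, tn = 5, fp = 0, fn = 0)), 1)
  expect_equal(mcc(tibble::tibble(tp = 0, tn = 0, fp = 5, fn = 5)), -1)
  expect_equal(mcc(tibble::tibble(tp = 3, fp = 1, fn = 2, tn = 4)),
               10 / sqrt(600))
  expect_true(is.na(mcc(tibble::tibble(tp = 0, fp = 0, tn = 5, fn = 5))))
})

test_that("MCC is invariant under simultaneous label and call swap", {
  withr::with_seed(22, {
    for (r in 1:20) {
      s <- runif(60)
      l <- rbinom(60, 1, 0.4)
      m1 <- mcc(confusion(s, l, 0.5))
      # swap: negate scores around the threshold and flip labels
      m2 <- mcc(confusion(1 - s + 1e-9, 1 - l, 0.5))
      expect_equal(m1, m2, tolerance = 1e-12)
    }
  })
})

test_that("percent metrics match their formulas and flag zero denominators", {
  cc <- tibble::tibble(tp = 3, tn = 4, fp = 1, fn = 2)
  expect_equal(q_total(cc), 70)
  expect_equal(ppv(tibble::tibble(tp = 3, fp = 0, tn = 1, fn = 1)), 100)
  expect_equal(sensitivity(cc), 100 * 3 / 5)
  expect_equal(specificity(cc), 100 * 4 / 5)
  none <- tibble::tibble(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_true(is.na(ppv(none)))
  expect_true(is.na(sensitivity(tibble::tibble(tp = 0, fp = 1, tn = 1,
                                               fn = 0))))
  withr::with_seed(32, {
    for (r in 1:50) {
      cc <- tibble::tibble(tp = sample(1:40, 1), fp = sample(1:40, 1),
                           tn = sample(1:40, 1), fn = sample(1:40, 1))
      n <- cc$tp + cc$fp + cc$tn + cc$fn
      expect_equal(q_total(cc), 100 * (cc$tp + cc$tn) / n,
                   tolerance = 1e-12)
      expect_equal(ppv(cc), 100 * cc$tp / (cc$tp + cc$fp),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC equals the normalized rank statistic and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
  withr::with_seed(42, {
    for (r in 1:200) {
      s <- round(runif(50), 2)       # rounding forces ties
      l <- rbinom(50, 1, 0.4)
      if (length(unique(l)) < 2) next
      expect_equal(roc_auc(s, l)$auc, oracle_auc(s, l), tolerance = 1e-10)
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(52, {
    s <- runif(80)
    l <- rbinom(80, 1, 0.3)
    a0 <- roc_auc(s, l)$auc
    expect_equal(roc_auc(plogis(5 * s - 2), l)$auc, a0, tolerance = 1e-12)
    expect_equal(roc_auc(s^3, l)$auc, a0, tolerance = 1e-12)
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(62, {
    s <- runif(120)
    l <- rbinom(120, 1, 0.35)
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(s, l)$auc, ref, tolerance = 1e-10)
  })
})

test_that("threshold sweep exposes the accuracy/MCC trade-off", {
  sw0 <- threshold_sweep(c(0.2, 0.7), c(0, 1), step = 0.5)
  expect_equal(sw0$curve$threshold, c(0, 0.5, 1))
  withr::with_seed(72, {
    # unbalanced scores: ~25% positives, overlapping score distributions
    n <- 4000
    l <- rbinom(n, 1, 0.25)
    s <- plogis(rnorm(n, ifelse(l == 1, 0.8, -0.8), 1.2))
    sw <- threshold_sweep(s, l)
    expect_gt(sw$best_q_total_threshold, sw$best_mcc_threshold)
    at <- function(th, col) sw$curve[[col]][sw$curve$threshold == th]
    expect_gte(at(sw$best_q_total_threshold, "q_total"), at(0.5, "q_total"))
    expect_gte(at(0.5, "mcc"), at(sw$best_q_total_threshold, "mcc"))
  })
})

test_that("metric_set bundles counts, rates and AUC coherently", {
  withr::with_seed(82, {
    s <- runif(100)
    l <- rbinom(100, 1, 0.3)
    ms <- metric_set(s, l, threshold = 0.4)
    expect_equal(ms$tp + ms$fp + ms$tn + ms$fn, 100)
    expect_equal(ms$auc, roc_auc(s, l)$auc)
    expect_equal(ms$threshold, 0.4)
  })
})

test_that("AUC difference test: null, power and symmetry", {
  withr::with_seed(92, {
    l <- rbinom(400, 1, 0.3)
    s <- runif(400)
    same <- auc_difference_test(s, s, l)
    expect_equal(same$z, 0)
    expect_equal(same$p_value, 1)

    # perfect vs random scores at n = 1000: overwhelming evidence
    l2 <- rep(c(1, 0), 500)
    perfect <- ifelse(l2 == 1, runif(1000, 0.6, 1), runif(1000, 0, 0.4))
    noise <- runif(1000)
    big <- auc_difference_test(perfect, noise, l2)
    expect_lt(big$p_value, 0.001)

    ab <- auc_difference_test(perfect, noise, l2)
    ba <- auc_difference_test(noise, perfect, l2)
    expect_equal(ab$p_value, ba$p_value)
    expect_equal(ab$z, -ba$z)
  })
})

test_that("roc and sweep autoplots build without error", {
  withr::with_seed(102, {
    s <- runif(60)
    l <- rbinom(60, 1, 0.4)
    expect_s3_class(ggplot2::autoplot(roc_auc(s, l)), "ggplot")
    expect_s3_class(ggplot2::autoplot(threshold_sweep(s, l, step = 0.1)),
                    "ggplot")
  })
})
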