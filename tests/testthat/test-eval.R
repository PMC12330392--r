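pred_df <- function(label, prob) {
  data.frame(patient_id = sprintf("P%03d", seq_along(label)), label = label,
             probability = prob)
}

test_that("metrics on a six-patient hand table match the exhaustive oracle", {
  label <- c(1, 1, 1, 0, 0, 0)
  prob <- c(0.9, 0.6, 0.4, 0.7, 0.3, 0.1)
  # by hand at threshold 0.5: TP=2 (0.9, 0.6), FN=1 (0.4), FP=1 (0.7), TN=2
  rep <- compute_metrics(pred_df(label, prob), threshold = 0.5, n_boot = 50)
  est <- setNames(rep$estimate, rep$metric)
  expect_equal(est[["accuracy"]], 4 / 6)
  expect_equal(est[["precision"]], 2 / 3)
  expect_equal(est[["recall"]], 2 / 3)
  expect_equal(est[["f1"]], 2 / 3)
  o <- oracle_confusion(label, prob, 0.5)
  expect_equal(est[["accuracy"]], o$accuracy)
  expect_equal(est[["precision"]], o$precision)
  expect_equal(est[["recall"]], o$recall)
  expect_equal(est[["f1"]], o$f1)
  expect_equal(est[["auc"]], oracle_pairwise_auc(label, prob))
  expect_true(all(rep$lower <= rep$estimate & rep$estimate <= rep$upper))
})

test_that("perfect and constant classifiers give their textbook values", {
  label <- c(1, 1, 0, 0)
  perfect <- compute_metrics(pred_df(label, label), n_boot = 20)
  expect_true(all(perfect$estimate == 1))

  const <- compute_metrics(pred_df(label, rep(0.5, 4)), n_boot = 20)
  est <- setNames(const$estimate, const$metric)
  expect_equal(est[["recall"]], 1)      # ties at the cutoff are positive
  expect_equal(est[["accuracy"]], 0.5)
  expect_equal(est[["auc"]], 0.5)
})

test_that("zero predicted positives reports precision 0 with a warning", {
  expect_warning(
    rep <- compute_metrics(pred_df(c(1, 1, 0, 0), c(0.4, 0.3, 0.2, 0.1)),
                           n_boot = 10),
    "precision")
  expect_equal(rep$estimate[rep$metric == "precision"], 0)
  expect_true(attr(rep, "zero_positive_warning"))
})

test_that("single-class truth is rejected for AUC", {
  expect_error(compute_metrics(pred_df(c(1, 1), c(0.2, 0.9))), "single-class")
  expect_error(auc_score(c(0, 0), c(0.1, 0.2)), "both classes")
})

test_that("the ROC staircase runs from (0,0) to (1,1) monotonically and its
           trapezoid area equals the pairwise count", {
  set.seed(2)
  for (r in 1:20) {
    n <- sample(5:50, 1)
    label <- c(0, 1, rbinom(n - 2, 1, 0.5))
    prob <- round(runif(n), 2)  # coarse grid forces ties
    roc <- roc_curve(pred_df(label, prob))
    expect_equal(roc$points$fpr[1], 0)
    expect_equal(roc$points$tpr[1], 0)
    expect_equal(tail(roc$points$fpr, 1), 1)
    expect_equal(tail(roc$points$tpr, 1), 1)
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(diff(roc$points$tpr) >= 0))
    expect_equal(roc$auc, oracle_pairwise_auc(label, prob), tolerance = 1e-12)
    expect_equal(auc_score(label, prob), roc$auc, tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  label <- rbinom(60, 1, 0.5)
  label[1:2] <- c(0, 1)
  prob <- runif(60)
  ours <- auc_score(label, prob)
  ref <- as.numeric(pROC::auc(pROC::roc(label, prob, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("extreme orderings hit the AUC bounds", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.8, 0.9, 0.1, 0.2)), 0)
})

test_that("F1 lies between precision and recall whenever defined", {
  set.seed(9)
  for (r in 1:50) {
    n <- sample(4:30, 1)
    label <- c(0, 1, rbinom(n - 2, 1, 0.5))
    prob <- runif(n)
    rep <- suppressWarnings(
      compute_metrics(pred_df(label, prob), n_boot = 2))
    est <- setNames(rep$estimate, rep$metric)
    if (est[["precision"]] + est[["recall"]] > 0) {
      expect_gte(est[["f1"]], min(est[["precision"]], est[["recall"]]) - 1e-12)
      expect_lte(est[["f1"]], max(est[["precision"]], est[["recall"]]) + 1e-12)
    }
  }
})

test_that("bootstrap intervals are deterministic given the seed and bracket
           the point estimate", {
  set.seed(3)
  label <- rbinom(80, 1, 0.5)
  label[1:2] <- c(0, 1)
  prob <- plogis(rnorm(80) + label)
  r1 <- compute_metrics(pred_df(label, prob), n_boot = 200, seed = 7)
  r2 <- compute_metrics(pred_df(label, prob), n_boot = 200, seed = 7)
  expect_identical(r1$lower, r2$lower)
  expect_true(all(r1$lower <= r1$estimate & r1$estimate <= r1$upper))
})

test_that("the paired t-test and Cohen's d match closed-form arithmetic", {
  a <- c(1, 2, 3, 4, 5)
  b <- a  # identical samples
  res <- paired_comparison(a, b)
  expect_true(res$degenerate)
  expect_equal(res$cohens_d, 0)
  expect_equal(res$effect_band, "negligible")
  expect_true(is.na(res$p_value))

  set.seed(11)
  n <- 30
  noise <- rnorm(n)
  a <- noise + 0.7
  b <- noise * 0  # diff = noise + 0.7, sd = sd(noise)
  res <- paired_comparison(a + b, b)
  d <- mean(a) / sd(a)
  tstat <- d * sqrt(n)
  expect_equal(res$cohens_d, d, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), n - 1), tolerance = 1e-12)
})

test_that("effect-size bands honor the 0.2 / 0.5 / 0.8 cutoffs exactly", {
  expect_equal(effect_band(0.19), "negligible")
  expect_equal(effect_band(0.2), "small")
  expect_equal(effect_band(-0.3), "small")
  expect_equal(effect_band(0.5), "medium")
  expect_equal(effect_band(0.79), "medium")
  expect_equal(effect_band(0.8), "large")
  expect_equal(effect_band(-2), "large")
})

test_that("a planted medium effect is recovered from paired samples", {
  for (s in 1:3) {
    set.seed(s)
    n <- 1000
    b <- rnorm(n)
    sd_d <- 0.1
    a <- b + rnorm(n, mean = 0.5 * sd_d, sd = sd_d)
    res <- paired_comparison(a, b)
    expect_gt(res$cohens_d, 0.4)
    expect_lt(res$cohens_d, 0.6)
    expect_equal(res$effect_band, effect_band(res$cohens_d))
  }
})
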