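#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, ties counted one half. Identical to the
#' trapezoid area under the empirical ROC curve.
#'
#' @param label Binary 0/1 truth.
#' @param score Numeric scores, larger = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(label, score) {
  pos <- label == 1L
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("auc_score: both classes must be present", call. = FALSE)
  }
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Sweeps the decision threshold over all observed scores and returns the
#' (FPR, TPR) staircase from (0, 0) to (1, 1) together with the trapezoid
#' AUC.
#'
#' @param preds data.frame with columns `label` (0/1) and `probability`.
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(preds) {
  label <- preds$label
  score <- preds$probability
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("roc_curve: both classes must be present", call. = FALSE)
  }
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  y <- label[ord]
  grp <- cumsum(!duplicated(s))        # tie groups share one operating point
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.frame(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / n0),
    tpr = c(0, tp[last] / n1)
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

confusion_metrics <- function(label, prob, threshold) {
  pred <- as.integer(prob >= threshold)  # ties at the cutoff are positive
  tp <- sum(pred == 1L & label == 1L)
  fp <- sum(pred == 1L & label == 0L)
  fn <- sum(pred == 0L & label == 1L)
  tn <- sum(pred == 0L & label == 0L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = (tp + tn) / length(label), precision = precision,
    recall = recall, f1 = f1)
}

#' Classification metrics with bootstrap confidence intervals
#'
#' Computes accuracy, precision, recall, F1 and AUC of patient-level
#' predictions (positive class = high-risk, label 1; probabilities at the
#' threshold count as positive), plus percentile confidence intervals from
#' a stratified patient bootstrap (resampling within each class, default
#' 1000 resamples).
#'
#' @param preds data.frame with columns `patient_id`, `label`,
#'   `probability` — one row per patient.
#' @param threshold Decision cutoff on the probability (default 0.5).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `metrics_report`: a data.frame with one row per
#'   metric (`estimate`, `lower`, `upper`), plus attributes `threshold` and
#'   `zero_positive_warning`.
#' @export
compute_metrics <- function(preds, threshold = 0.5, n_boot = 1000L,
                            conf_level = 0.95, seed = 1L) {
  label <- as.integer(preds$label)
  prob <- preds$probability
  stopifnot(all(label %in% c(0L, 1L)), all(prob >= 0 & prob <= 1))
  if (length(unique(label)) < 2L) {
    stop("compute_metrics: AUC undefined with single-class truth",
         call. = FALSE)
  }
  zero_pos <- sum(prob >= threshold) == 0L
  if (zero_pos) {
    warning("compute_metrics: no predicted positives; precision reported as 0")
  }
  point <- c(confusion_metrics(label, prob, threshold),
             auc = auc_score(label, prob))
  idx_pos <- which(label == 1L)
  idx_neg <- which(label == 0L)
  boot <- matrix(NA_real_, n_boot, length(point),
                 dimnames = list(NULL, names(point)))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- c(idx_pos[sample.int(length(idx_pos), replace = TRUE)],
             idx_neg[sample.int(length(idx_neg), replace = TRUE)])
    boot[b, ] <- c(confusion_metrics(label[idx], prob[idx], threshold),
                   auc = auc_score(label[idx], prob[idx]))
  }
  alpha <- (1 - conf_level) / 2
  ci <- apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  rep <- data.frame(
    metric = names(point), estimate = unname(point),
    lower = pmin(ci[1, ], point), upper = pmax(ci[2, ], point),
    stringsAsFactors = FALSE
  )
  structure(rep, class = c("metrics_report", "data.frame"),
            threshold = threshold, zero_positive_warning = zero_pos,
            boot = boot)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics (threshold %.2f, 95%% bootstrap CI):\n",
              attr(x, "threshold")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-9s %.4f  [%.4f, %.4f]\n", x$metric[i], x$estimate[i],
                x$lower[i], x$upper[i]))
  }
  invisible(x)
}

#' Paired model comparison: t-test and Cohen's d
#'
#' Two-sided paired t-test on equal-length metric samples from two models,
#' with the paired-data Cohen's d (mean of differences over their standard
#' deviation). Effect-size bands follow the conventional 0.2 / 0.5 / 0.8
#' cutoffs on |d|: below 0.2 negligible, then small, medium, large.
#'
#' @param a,b Equal-length numeric vectors of paired metric samples
#'   (e.g. per-bootstrap-resample metrics of two models evaluated on shared
#'   resample indices).
#' @return Object of class `comparison_result`: `p_value`, `cohens_d`,
#'   `effect_band`, `mean_diff`, `n`, `degenerate` (TRUE when the
#'   differences have zero variance, in which case `p_value` is NA).
#' @export
paired_comparison <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    res <- list(p_value = NA_real_, cohens_d = 0, effect_band = "negligible",
                mean_diff = mean(d), n = length(d), degenerate = TRUE)
    return(structure(res, class = "comparison_result"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  cd <- mean(d) / sdd
  structure(
    list(p_value = tt$p.value, cohens_d = cd,
         effect_band = effect_band(cd), mean_diff = mean(d),
         n = length(d), degenerate = FALSE),
    class = "comparison_result"
  )
}

#' Effect-size band for a Cohen's d value
#'
#' @param d Cohen's d (sign ignored).
#' @return `"negligible"`, `"small"`, `"medium"` or `"large"` per the
#'   0.2 / 0.5 / 0.8 cutoffs.
#' @export
effect_band <- function(d) {
  ad <- abs(d)
  if (ad < 0.2) "negligible"
  else if (ad < 0.5) "small"
  else if (ad < 0.8) "medium"
  else "large"
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("paired comparison: mean diff %.4f, Cohen's d %.3f (%s), p %s\n",
              x$mean_diff, x$cohens_d, x$effect_band,
              ifelse(is.na(x$p_value), "NA (degenerate)",
                     format.pval(x$p_value, digits = 3))))
  invisible(x)
}

#' Pooling ablation harness
#'
#' Trains one model per aggregation operator (attention, mean, max) under an
#' identical protocol — same data, same seed, same encoder initialization —
#' differing only in the pooling field, then evaluates each on the test bags
#' and runs paired comparisons of attention against each baseline. Pairing
#' unit: per-bootstrap-resample AUC on a shared resample index, so both
#' models are measured on identical resamples.
#'
#' @param train_bags,test_bags Preprocessed bags.
#' @param poolings Character vector of aggregation operators to compare.
#' @param encoder_spec Shared [encoder_spec()].
#' @param config Shared [train_config()].
#' @param model_seed Seed for weight initialization (shared across arms).
#' @param n_boot Bootstrap resamples for metrics and pairing.
#' @return Object of class `ablation_result`: `metrics` (named list of
#'   `metrics_report`), `auc` (named vector), `comparisons` (attention vs
#'   each baseline, when attention is among the arms), `fits`.
#' @export
ablation_run <- function(train_bags, test_bags,
                         poolings = c("attention", "mean", "max"),
                         encoder_spec = sonomil::encoder_spec(),
                         config = train_config(), model_seed = 1L,
                         n_boot = 1000L) {
  poolings <- match.arg(poolings, c("attention", "mean", "max"),
                        several.ok = TRUE)
  fits <- list()
  reports <- list()
  preds <- list()
  for (pl in poolings) {
    m <- mil_model(encoder_spec = encoder_spec, pooling = pl,
                   seed = model_seed)
    fit <- train_mil(train_bags, m, config)
    pr <- predict_bags(fit$model, test_bags)
    fits[[pl]] <- fit
    preds[[pl]] <- pr
    reports[[pl]] <- compute_metrics(pr, n_boot = n_boot, seed = model_seed)
  }
  aucs <- vapply(reports, function(r) r$estimate[r$metric == "auc"],
                 numeric(1))
  comparisons <- list()
  if ("attention" %in% poolings && length(poolings) > 1L) {
    # shared stratified resample indices across arms
    label <- preds[[1]]$label
    idx_pos <- which(label == 1L)
    idx_neg <- which(label == 0L)
    set.seed(model_seed + 977L)
    idx_list <- lapply(seq_len(n_boot), function(i) {
      c(idx_pos[sample.int(length(idx_pos), replace = TRUE)],
        idx_neg[sample.int(length(idx_neg), replace = TRUE)])
    })
    boot_auc <- function(pr) {
      vapply(idx_list, function(idx) auc_score(pr$label[idx],
                                               pr$probability[idx]),
             numeric(1))
    }
    attn_auc <- boot_auc(preds[["attention"]])
    for (pl in setdiff(poolings, "attention")) {
      comparisons[[pl]] <- paired_comparison(attn_auc, boot_auc(preds[[pl]]))
    }
  }
  structure(
    list(metrics = reports, auc = aucs, comparisons = comparisons,
         fits = fits, predictions = preds),
    class = "ablation_result"
  )
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("pooling ablation (test AUC):\n")
  for (nm in names(x$auc)) cat(sprintf("  %-9s %.4f\n", nm, x$auc[nm]))
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    cat(sprintf("  attention vs %s: d = %.3f (%s), p = %s\n", nm,
                cmp$cohens_d, cmp$effect_band,
                ifelse(is.na(cmp$p_value), "NA",
                       format.pval(cmp$p_value, digits = 3))))
  }
  invisible(x)
}
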