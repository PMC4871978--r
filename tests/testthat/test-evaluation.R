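test_that("confusion counts tally the declared positive class", {
  cc <- confusion_counts(c("P", "P", "N", "N"), c("P", "N", "N", "P"), "P")
  expect_identical(cc[c("TP", "FN", "TN", "FP")],
                   list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  truth <- c("P", "N", "P", "N", "P")
  perfect <- confusion_counts(truth, truth, "P")
  expect_identical(perfect$FP + perfect$FN, 0L)
  # swapping the positive class swaps TP<->TN and FP<->FN
  pred <- c("P", "P", "N", "N", "P")
  a <- confusion_counts(truth, pred, "P")
  b <- confusion_counts(truth, pred, "N")
  expect_identical(list(a$TP, a$FN, a$FP), list(b$TN, b$FP, b$FN))
  expect_error(confusion_counts(truth, c(pred[-5], "X"), "P"), "unseen")
})

test_that("sensitivity, specificity and overall accuracy follow their defining ratios", {
  for (tp in 0:3) for (fn in 0:3) for (tn in 0:3) for (fp in 0:3) {
    cc <- structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
                    class = "confusion_counts")
    if (tp + fn > 0) expect_identical(sensitivity(cc), tp / (tp + fn))
    else expect_error(sensitivity(cc), "undefined")
    if (tn + fp > 0) expect_identical(specificity(cc), tn / (tn + fp))
    else expect_error(specificity(cc), "undefined")
    if (tp + fn + tn + fp > 0) {
      expect_identical(overall_accuracy(cc),
                       (tp + tn) / (tp + tn + fp + fn))
    }
  }
  cc <- structure(list(TP = 9L, TN = 0L, FP = 0L, FN = 1L),
                  class = "confusion_counts")
  expect_identical(sensitivity(cc), 0.9)
})

test_that("roc_curve matches a brute-force threshold enumeration", {
  truth <- c("P", "P", "N", "P", "N", "N")
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.5)
  roc <- roc_curve(truth, scores, "P")
  # brute force: every distinct score as threshold, predict pos if >= t
  brute <- unique(do.call(rbind, lapply(c(Inf, sort(unique(scores),
                                                    decreasing = TRUE), -Inf),
    function(t) {
      pred <- scores >= t
      c(fpr = sum(pred & truth == "N") / 3, tpr = sum(pred & truth == "P") / 3)
    })))
  expect_equal(as.matrix(roc[, c("fpr", "tpr")]), brute,
               ignore_attr = TRUE)
  expect_identical(roc$fpr[1], 0); expect_identical(roc$tpr[1], 0)
  expect_identical(roc$fpr[nrow(roc)], 1)
  expect_identical(roc$tpr[nrow(roc)], 1)
})

test_that("roc_curve handles perfect separation and all-tied scores", {
  truth <- c(1, 1, 0, 0)
  perfect <- roc_curve(truth, c(5, 4, 1, 0), 1)
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  expect_identical(roc_auc(perfect), 1)
  tied <- roc_curve(truth, rep(2, 4), 1)
  expect_identical(nrow(tied), 2L)
  expect_identical(roc_auc(tied), 0.5)
  expect_error(roc_curve(c(1, 1), c(0.2, 0.4), 1), "both classes")
})

test_that("trapezoidal AUC equals the pair-counting rank statistic", {
  withr::with_seed(77, {
    for (i in 1:50) {
      n <- sample(10:60, 1)
      truth <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      scores <- round(rnorm(n), sample(0:2, 1))  # induce ties sometimes
      roc <- roc_curve(truth, scores, 1)
      a_trap <- roc_auc(roc)
      pos <- scores[truth == 1]; neg <- scores[truth == 0]
      pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
      expect_lt(abs(a_trap - mean(pairs)), 1e-12)
      expect_true(all(roc$fpr >= 0 & roc$fpr <= 1 &
                        roc$tpr >= 0 & roc$tpr <= 1))
      expect_false(is.unsorted(roc$fpr) || is.unsorted(roc$tpr))
    }
  })
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(78, {
    truth <- sample(0:1, 40, replace = TRUE)
    truth[1:2] <- 0:1
    scores <- rnorm(40) + truth
    ours <- roc_auc(roc_curve(truth, scores, 1))
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("sensitivity and specificity are invariant to monotone score transforms", {
  withr::with_seed(79, {
    truth <- c(rep(1, 15), rep(0, 15))
    scores <- rnorm(30) + truth
    pred <- function(s) ifelse(s >= 0, 1, 0)
    cc1 <- confusion_counts(truth, pred(scores), 1)
    # a strictly monotone transform preserving the 0 threshold
    cc2 <- confusion_counts(truth, pred(tanh(scores)), 1)
    expect_identical(sensitivity(cc1), sensitivity(cc2))
    expect_identical(specificity(cc1), specificity(cc2))
    # and AUC is invariant to any strictly monotone transform
    expect_equal(roc_auc(roc_curve(truth, scores, 1)),
                 roc_auc(roc_curve(truth, exp(scores), 1)),
                 tolerance = 1e-12)
  })
})

test_that("repeated holdout splits have the stated sizes and are disjoint", {
  d <- simulate_parkinsons(n_samples = 192, effect_size = 1, seed = 91)
  plan <- split_plan("repeated_holdout", train_fraction = 2 / 3,
                     repeats = 3, seed = 91)
  splits <- wkelm:::build_splits(plan, d$status)
  expect_length(splits, 3)
  for (sp in splits) {
    expect_identical(length(sp$test), 192L - length(sp$train))
    expect_identical(length(sp$train), 128L)  # round(2/3 * 144) + round(2/3 * 48)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_true(length(unique(d$status[sp$train])) == 2)
  }
})

test_that("3-fold cross-validation tests every case exactly once", {
  d <- simulate_parkinsons(n_samples = 192, effect_size = 1, seed = 92)
  plan <- split_plan("k_fold", k = 3, repeats = 1, seed = 92)
  splits <- wkelm:::build_splits(plan, d$status)
  expect_length(splits, 3)
  expect_identical(sort(unlist(lapply(splits, `[[`, "test"))), 1:192)
  expect_identical(unique(vapply(splits, function(s) length(s$test), 0L)),
                   64L)
})

test_that("group-aware splitting keeps all recordings of a subject together", {
  d <- simulate_parkinsons(n_samples = 60, effect_size = 1, seed = 93)
  d$subject <- rep(sprintf("S%02d", 1:20), each = 3)
  plan <- split_plan("repeated_holdout", repeats = 2, group = "subject",
                     seed = 93)
  splits <- wkelm:::build_splits(plan, d$status, d$subject)
  for (sp in splits) {
    expect_length(intersect(d$subject[sp$train], d$subject[sp$test]), 0)
  }
})

test_that("run_protocol aggregates per-split statistics by arithmetic mean", {
  d <- simulate_parkinsons(n_samples = 90, effect_size = 2, seed = 94)
  ev <- run_protocol(d, split_plan(repeats = 3, seed = 94))
  expect_s3_class(tidy(ev), "tbl_df")
  expect_identical(nrow(tidy(ev)), 3L)
  expect_equal(glance(ev)$overall, mean(tidy(ev)$overall))
  expect_equal(glance(ev)$auc, mean(tidy(ev)$auc))
  expect_equal(glance(ev)$sensitivity, mean(tidy(ev)$sensitivity))
  # deterministic under the same plan seed
  ev2 <- run_protocol(d, split_plan(repeats = 3, seed = 94))
  expect_identical(tidy(ev), tidy(ev2))
})

test_that("the training pipeline never sees held-out rows", {
  d <- simulate_parkinsons(n_samples = 60, effect_size = 2, seed = 95)
  plan <- split_plan(repeats = 1, seed = 95)
  sp <- wkelm:::build_splits(plan, d$status)[[1]]
  # perturb only test rows: the fitted model must be bit-identical
  d_pert <- d
  d_pert[sp$test, "HNR"] <- d_pert[sp$test, "HNR"] * 10
  m1 <- wkelm(d[sp$train, ])
  m2 <- wkelm(d_pert[sp$train, ])
  expect_identical(m1$output_weights, m2$output_weights)
  expect_identical(m1$standardizer, m2$standardizer)
  # and the standardizer comes from the training rows alone
  expect_equal(unname(m1$standardizer$mean),
               unname(colMeans(as.matrix(d[sp$train, m1$feature_names]))))
})

test_that("a training split collapsing to one class is reported with its repeat", {
  d <- make_null_data(n = 12, prevalence = 1 / 12, seed = 96)
  seen_error <- FALSE
  for (s in 1:30) {
    plan <- split_plan(repeats = 1, train_fraction = 0.5,
                       stratified = FALSE, seed = s)
    res <- tryCatch(run_protocol(d, plan), error = function(e) e)
    if (inherits(res, "error") &&
        grepl("single class", conditionMessage(res))) {
      seen_error <- TRUE
      expect_match(conditionMessage(res), "repeat 1")
      break
    }
  }
  expect_true(seen_error)
})
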