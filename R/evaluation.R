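#' Two-by-two confusion counts
#'
#' @param truth Vector of true binary labels.
#' @param predicted Vector of predicted labels, same length and classes.
#' @param positive The label value counted as positive (diseased).
#' @return A `confusion_counts` list with integers `TP`, `TN`, `FP`,
#'   `FN`.
#' @examples
#' confusion_counts(c("P", "P", "N", "N"), c("P", "N", "N", "P"), "P")
#' @export
confusion_counts <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted have different lengths", call. = FALSE)
  }
  classes <- unique(truth)
  if (length(classes) > 2) stop("more than two classes in truth", call. = FALSE)
  if (!positive %in% classes) {
    stop("positive class '", positive, "' not present in truth", call. = FALSE)
  }
  if (any(!predicted %in% classes)) {
    stop("predicted contains labels unseen in truth", call. = FALSE)
  }
  tpos <- truth == positive
  ppos <- predicted == positive
  structure(
    list(TP = sum(tpos & ppos), TN = sum(!tpos & !ppos),
         FP = sum(!tpos & ppos), FN = sum(tpos & !ppos)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FN %d  FP %d  TN %d\n",
              x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Diagnostic-test statistics from confusion counts
#'
#' Sensitivity is the fraction of diseased cases classified diseased,
#' `TP / (TP + FN)`; specificity the fraction of healthy cases
#' classified healthy, `TN / (TN + FP)`; overall accuracy the fraction
#' of all cases classified correctly, `(TP + TN) / total`.  A zero
#' denominator is an error, never a silent 0.
#'
#' @param counts A [confusion_counts()] object.
#' @return A fraction in \[0, 1\].
#' @export
sensitivity <- function(counts) {
  denom <- counts$TP + counts$FN
  if (denom == 0) stop("sensitivity undefined: no positive cases", call. = FALSE)
  counts$TP / denom
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  denom <- counts$TN + counts$FP
  if (denom == 0) stop("specificity undefined: no negative cases", call. = FALSE)
  counts$TN / denom
}

#' @rdname sensitivity
#' @export
overall_accuracy <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("overall accuracy undefined: no cases", call. = FALSE)
  (counts$TP + counts$TN) / total
}

#' ROC curve from decision scores
#'
#' Sweeps the decision threshold over the distinct score values from
#' +Inf downward, predicting positive when `score >= threshold`, and
#' records (false-positive rate, true-positive rate) at each threshold.
#' Tied scores collapse to a single point; the endpoints (0, 0) and
#' (1, 1) are always present.
#'
#' @param truth True binary labels (both classes must occur).
#' @param scores Numeric decision scores, higher = more positive.
#' @param positive The positive class label.
#' @return A tibble of class `wkelm_roc` with columns `threshold`,
#'   `fpr`, `tpr`, ordered by increasing `fpr`.
#' @export
roc_curve <- function(truth, scores, positive) {
  if (length(truth) != length(scores)) {
    stop("truth and scores have different lengths", call. = FALSE)
  }
  is_pos <- truth == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs both classes in truth", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(is_pos & scores >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(!is_pos & scores >= t) / n_neg, 0)
  pts <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr),
                        tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- dplyr::bind_rows(pts, tibble::tibble(threshold = -Inf,
                                                fpr = 1, tpr = 1))
  }
  pts <- dplyr::distinct(pts, .data$fpr, .data$tpr, .keep_all = TRUE)
  class(pts) <- c("wkelm_roc", class(pts))
  pts
}

#' Area under a ROC curve
#'
#' Trapezoidal integration of the (fpr, tpr) polyline.  Mathematically
#' this equals the rank statistic `P(score_pos > score_neg) +
#' P(score_pos = score_neg) / 2` computed from the same scores.
#'
#' @param roc A [roc_curve()] tibble (or any data frame with ordered
#'   `fpr`, `tpr` columns and at least two rows).
#' @return The AUC in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  if (nrow(roc) < 2) stop("need at least 2 ROC points", call. = FALSE)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Resampling plan for classifier evaluation
#'
#' @param scheme `"repeated_holdout"` (stratified random train/test
#'   splits) or `"k_fold"` (cross-validation).
#' @param train_fraction Training fraction in (0, 1) (holdout only).
#' @param k Number of folds (k_fold only), >= 2.
#' @param repeats Number of repeats (holdout: independent splits;
#'   k_fold: independent fold assignments).
#' @param stratified Stratify splits by class (default TRUE; small
#'   unstratified test sets can lose a class entirely).
#' @param group Optional name of a grouping column (e.g. subject id);
#'   when given, all rows of a group travel together.
#' @param seed Integer seed for all split randomness.
#' @return A `split_plan` list.
#' @export
split_plan <- function(scheme = c("repeated_holdout", "k_fold"),
                       train_fraction = 2 / 3, k = 3, repeats = 3,
                       stratified = TRUE, group = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "repeated_holdout" &&
      (train_fraction <= 0 || train_fraction >= 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  if (scheme == "k_fold" && k < 2) stop("k must be >= 2", call. = FALSE)
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  structure(
    list(scheme = scheme, train_fraction = train_fraction, k = as.integer(k),
         repeats = as.integer(repeats), stratified = isTRUE(stratified),
         group = group, seed = as.integer(seed)),
    class = "split_plan"
  )
}

# Build the list of train/test index pairs for a plan.  Grouped rows are
# assigned at the group level; stratification uses each row's (or
# group's majority) class.
build_splits <- function(plan, labels, groups = NULL) {
  n <- length(labels)
  units <- if (is.null(groups)) seq_len(n) else unique(groups)
  unit_rows <- if (is.null(groups)) {
    as.list(seq_len(n))
  } else {
    lapply(units, function(g) which(groups == g))
  }
  unit_class <- vapply(unit_rows, function(rows) {
    tab <- table(labels[rows])
    names(tab)[which.max(tab)]
  }, "")
  strata <- if (plan$stratified) unit_class else rep("all", length(units))
  withr::with_seed(plan$seed, {
    out <- list()
    for (r in seq_len(plan$repeats)) {
      if (plan$scheme == "repeated_holdout") {
        train_units <- integer(0)
        for (s in unique(strata)) {
          idx <- which(strata == s)
          n_train <- round(plan$train_fraction * length(idx))
          n_train <- max(1, min(length(idx) - 1, n_train))
          train_units <- c(train_units, sample(idx, n_train))
        }
        train <- sort(unlist(unit_rows[train_units]))
        out[[length(out) + 1]] <- list(
          repeat_id = r, fold = NA_integer_,
          train = train, test = setdiff(seq_len(n), train))
      } else {
        fold_of <- integer(length(units))
        for (s in unique(strata)) {
          idx <- which(strata == s)
          fold_of[idx] <- sample(rep_len(seq_len(plan$k), length(idx)))
        }
        for (f in seq_len(plan$k)) {
          test_units <- which(fold_of == f)
          test <- sort(unlist(unit_rows[test_units]))
          out[[length(out) + 1]] <- list(
            repeat_id = r, fold = f,
            train = setdiff(seq_len(n), test), test = test)
        }
      }
    }
    out
  })
}

#' Run a train/evaluate resampling protocol
#'
#' For every split of the plan, calls `fit_fun` on the training rows
#' only (so any standardisation or hyperparameter search inside it sees
#' no test data), scores the held-out rows, and computes the full
#' diagnostic report: confusion counts, sensitivity, specificity,
#' overall accuracy, ROC curve and AUC.  The aggregate is the
#' arithmetic mean of the per-split statistics at full precision.
#'
#' @param data A data frame with an outcome column.
#' @param plan A [split_plan()].
#' @param fit_fun A function `training data frame -> fitted model`; the
#'   model must work with [decision_scores()] (any [wkelm()] fit does).
#'   Default: a full-kernel wavelet ELM with package defaults.
#' @param outcome Label column name.
#' @param positive Positive (diseased) class label; default as in
#'   [wkelm()].
#' @return An object of class `wkelm_eval`: `reports` (list of
#'   per-split reports with counts, statistics and the ROC tibble),
#'   `summary` (per-split tibble) and `aggregate` (one-row tibble of
#'   means).
#' @examples
#' d <- simulate_parkinsons(n_samples = 90, effect_size = 2, seed = 7)
#' ev <- run_protocol(d, split_plan(repeats = 2, seed = 7))
#' glance(ev)
#' @export
run_protocol <- function(data, plan = split_plan(),
                         fit_fun = NULL, outcome = "status",
                         positive = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  labels <- data[[outcome]]
  if (is.null(labels)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  if (is.null(positive)) positive <- attr(data, "positive_class")
  if (is.null(positive)) {
    cl <- sort(unique(labels))
    positive <- cl[length(cl)]
  }
  if (is.null(fit_fun)) {
    fit_fun <- function(train) wkelm(train, outcome = outcome,
                                     positive = positive)
  }
  groups <- if (!is.null(plan$group)) data[[plan$group]] else NULL
  splits <- build_splits(plan, labels, groups)
  reports <- lapply(splits, function(sp) {
    train <- data[sp$train, , drop = FALSE]
    test <- data[sp$test, , drop = FALSE]
    if (length(unique(train[[outcome]])) < 2) {
      stop("repeat ", sp$repeat_id,
           if (!is.na(sp$fold)) paste0(" fold ", sp$fold) else "",
           ": training split contains a single class", call. = FALSE)
    }
    model <- fit_fun(train)
    scores <- decision_scores(model, test)
    predicted <- ifelse(scores >= 0, positive,
                        setdiff(unique(labels), positive))
    counts <- confusion_counts(test[[outcome]], predicted, positive)
    roc <- roc_curve(test[[outcome]], scores, positive)
    list(repeat_id = sp$repeat_id, fold = sp$fold, counts = counts,
         sensitivity = sensitivity(counts),
         specificity = specificity(counts),
         overall = overall_accuracy(counts),
         roc = roc, auc = roc_auc(roc),
         n_test = nrow(test))
  })
  summary <- purrr::map_dfr(reports, function(r) {
    tibble::tibble(repeat_id = r$repeat_id, fold = r$fold,
                   n_test = r$n_test,
                   TP = r$counts$TP, TN = r$counts$TN,
                   FP = r$counts$FP, FN = r$counts$FN,
                   sensitivity = r$sensitivity,
                   specificity = r$specificity,
                   overall = r$overall, auc = r$auc)
  })
  aggregate <- dplyr::summarise(
    summary,
    sensitivity = mean(.data$sensitivity),
    specificity = mean(.data$specificity),
    overall = mean(.data$overall),
    auc = mean(.data$auc),
    n_splits = dplyr::n()
  )
  structure(list(reports = reports, summary = summary,
                 aggregate = aggregate, plan = plan, positive = positive),
            class = "wkelm_eval")
}

#' @export
print.wkelm_eval <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "<wkelm_eval> %d splits (%s): SEA %.4f  SPA %.4f  OC %.4f  AUC %.4f\n",
    a$n_splits, x$plan$scheme, a$sensitivity, a$specificity, a$overall,
    a$auc))
  invisible(x)
}

#' Per-split evaluation statistics
#'
#' @param x A [run_protocol()] result.
#' @param ... Unused.
#' @return A tibble with one row per split: confusion counts,
#'   sensitivity, specificity, overall accuracy and AUC.
#' @method tidy wkelm_eval
#' @export
tidy.wkelm_eval <- function(x, ...) x$summary

#' Aggregate evaluation statistics
#'
#' @param x A [run_protocol()] result.
#' @param ... Unused.
#' @return A one-row tibble of mean sensitivity, specificity, overall
#'   accuracy and AUC across splits.
#' @method glance wkelm_eval
#' @export
glance.wkelm_eval <- function(x, ...) x$aggregate
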