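## Split designs, Random Forest training/evaluation, CV threshold
## optimization, repeated splits, disagreement and importance analyses.

#' Area under the ROC curve
#'
#' Trapezoidal rule over the ROC curve traced at every distinct score
#' threshold; equivalent to the Mann-Whitney U formulation (with 1/2 credit
#' for ties).
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical or "toxic"/"nontoxic" vector; `TRUE`/"toxic" is
#'   the positive class.
#' @return AUC in `[0, 1]`; `NA` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_positive(labels)
  if (length(unique(y)) < 2) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  # collapse tied scores into single ROC vertices
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(!y))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Average precision
#'
#' Step-sum of precision times the increment in recall over the ranked
#' predictions (ties processed as single blocks).
#'
#' @inheritParams roc_auc
#' @return average precision in `[0, 1]`; `NA` when no positives.
#' @export
average_precision <- function(scores, labels) {
  y <- as_positive(labels)
  if (!any(y)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  n_seen <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)
  prec <- tp[last] / n_seen[last]
  rec <- tp[last] / sum(y)
  sum(diff(c(0, rec)) * prec)
}

as_positive <- function(labels) {
  if (is.logical(labels)) labels else labels == "toxic"
}

# sensitivity / specificity / CCR at a threshold (toxic iff p >= threshold)
threshold_metrics <- function(prob, labels, threshold) {
  y <- as_positive(labels)
  pred <- prob >= threshold
  sens <- if (any(y)) mean(pred[y]) else NA_real_
  spec <- if (any(!y)) mean(!pred[!y]) else NA_real_
  list(sensitivity = sens, specificity = spec, ccr = (sens + spec) / 2)
}

#' Class-stratified random split
#'
#' Samples the stated fraction of each class (rounded half-up per class)
#' into the test set, without replacement.
#'
#' @param labels "toxic"/"nontoxic" vector named by compound key.
#' @param fraction test fraction per class.
#' @param seed RNG seed.
#' @return list of class `"split_spec"`: `name`, `seed`, `test_keys`,
#'   `train_keys`.
#' @export
random_split <- function(labels, fraction = 0.2, seed = 1) {
  assert_that(!is.null(names(labels)), "labels must be named by compound key")
  assert_that(all(table(labels) >= 5),
              "each class needs >= 5 members to stratify at 20%")
  set.seed(seed)
  test <- unlist(lapply(unique(labels), function(cl) {
    keys <- names(labels)[labels == cl]
    sample(keys, round_half_up(length(keys) * fraction))
  }))
  structure(list(name = "random", seed = seed, test_keys = sort(test),
                 train_keys = sort(setdiff(names(labels), test))),
            class = "split_spec")
}

#' Rare-scaffolds split
#'
#' Test set = all compounds whose Murcko scaffold occurs no more than twice
#' in the modelling set. Acyclic compounds share the empty scaffold string
#' and are therefore usually in the training set. Deterministic (no seed).
#'
#' @param smiles named character vector of standardized SMILES (modelling
#'   set).
#' @param max_count scaffold frequency bound for the test set.
#' @return a `"split_spec"` (plus `scaffolds`, the per-compound scaffold).
#' @export
rare_scaffold_split <- function(smiles, max_count = 2) {
  assert_that(!is.null(names(smiles)), "smiles must be named by compound key")
  scaff <- murcko_scaffold(smiles)
  scaff[is.na(scaff)] <- ""
  counts <- table(scaff)
  rare <- names(smiles)[counts[scaff] <= max_count]
  structure(list(name = "rare_scaffolds", seed = NA_integer_,
                 test_keys = sort(rare),
                 train_keys = sort(setdiff(names(smiles), rare)),
                 scaffolds = stats::setNames(scaff, names(smiles))),
            class = "split_spec")
}

#' Single-source split
#'
#' Class-stratified 20% test set drawn exclusively from compounds present
#' in exactly one authoritative GHS source. Errors when the single-source
#' pool cannot fill a class quota.
#'
#' @param labels "toxic"/"nontoxic" vector named by compound key.
#' @param source_counts named integer vector: number of authoritative
#'   sources covering each compound.
#' @param fraction test fraction (of the whole modelling set, per class).
#' @param seed RNG seed.
#' @return a `"split_spec"`.
#' @export
single_source_split <- function(labels, source_counts, fraction = 0.2,
                                seed = 1) {
  assert_that(!is.null(names(labels)), "labels must be named by compound key")
  set.seed(seed)
  pool <- names(source_counts)[source_counts == 1]
  test <- unlist(lapply(unique(labels), function(cl) {
    keys <- names(labels)[labels == cl]
    quota <- round_half_up(length(keys) * fraction)
    cand <- intersect(keys, pool)
    if (length(cand) < quota)
      stop(sprintf(
        "single-source pool cannot fill the %s quota: need %d, have %d",
        cl, quota, length(cand)), call. = FALSE)
    sample(cand, quota)
  }))
  structure(list(name = "single_source", seed = seed,
                 test_keys = sort(test),
                 train_keys = sort(setdiff(names(labels), test))),
            class = "split_spec")
}

#' CV-optimal decision threshold
#'
#' Pools out-of-fold Random Forest probabilities over stratified k-fold
#' cross-validation within the training set, then scans candidate
#' thresholds (midpoints of sorted unique pooled probabilities, plus 0 and
#' 1) for the one maximizing CCR under the rule toxic iff p >= threshold.
#' Ties are broken by the smallest threshold (favouring sensitivity).
#'
#' @param x training feature matrix (rows named by compound key).
#' @param labels training labels ("toxic"/"nontoxic").
#' @param k folds.
#' @param seed RNG seed.
#' @param ntree trees per fold model.
#' @return list with `threshold`, `ccr` (pooled CCR at the optimum),
#'   `pooled` (data.frame of out-of-fold probabilities and labels).
#' @export
cv_optimal_threshold <- function(x, labels, k = 5, seed = 1, ntree = 200) {
  assert_that(length(unique(labels)) == 2,
              "training set must contain both classes")
  y <- factor(labels, levels = c("nontoxic", "toxic"))
  folds <- stratified_folds(y, k, stage_seed(seed, "folds"))
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2)
      stop("degenerate single-class training fold", call. = FALSE)
    set.seed(stage_seed(seed, paste0("cvfit", f)))
    rf <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                     ntree = ntree)
    oof[!tr] <- stats::predict(rf, x[!tr, , drop = FALSE],
                               type = "prob")[, "toxic"]
  }
  sel <- best_ccr_threshold(oof, labels)
  list(threshold = sel$threshold, ccr = sel$ccr,
       pooled = data.frame(prob = oof, label = labels,
                           stringsAsFactors = FALSE))
}

# exhaustive CCR scan over candidate thresholds
best_ccr_threshold <- function(prob, labels) {
  u <- sort(unique(prob))
  cand <- sort(unique(c(0, if (length(u) > 1)
    (utils::head(u, -1) + utils::tail(u, -1)) / 2, 1)))
  ccrs <- vapply(cand, function(th)
    threshold_metrics(prob, labels, th)$ccr, numeric(1))
  best <- max(ccrs)
  list(threshold = cand[which(ccrs == best)[1]], ccr = best)
}

#' Train a Random Forest and evaluate it on a test set
#'
#' 200 gini trees, sqrt(p) features per split, unlimited depth; the
#' predicted probability is the fraction of trees voting toxic. Reports ROC
#' AUC (trapezoidal), average precision (step-sum), and the sensitivity,
#' specificity and CCR at the supplied threshold.
#'
#' @param x_train,x_test feature matrices (rows named by compound key).
#' @param y_train,y_test labels ("toxic"/"nontoxic").
#' @param threshold decision threshold (toxic iff p >= threshold).
#' @param descriptor_combo label recorded in the report.
#' @param split_name label recorded in the report.
#' @param ntree number of trees.
#' @param seed RNG seed for training.
#' @return object of class `"ghs_model_report"`: a list with `report`
#'   (one-row data.frame), `prob` (test-set probabilities), `model`
#'   (the randomForest fit), `threshold`.
#' @export
train_and_evaluate <- function(x_train, y_train, x_test, y_test,
                               threshold = 0.5,
                               descriptor_combo = "molecular",
                               split_name = "random",
                               ntree = 200, seed = 1) {
  set.seed(stage_seed(seed, "final_fit"))
  yf <- factor(y_train, levels = c("nontoxic", "toxic"))
  rf <- randomForest::randomForest(x_train, yf, ntree = ntree)
  prob <- stats::predict(rf, x_test, type = "prob")[, "toxic"]
  auc <- roc_auc(prob, y_test)
  ap <- average_precision(prob, y_test)
  tm <- threshold_metrics(prob, y_test, threshold)
  report <- data.frame(split_name = split_name,
                       descriptor_combo = descriptor_combo,
                       threshold = threshold, roc_auc = auc,
                       avg_precision = ap,
                       sensitivity = tm$sensitivity,
                       specificity = tm$specificity, ccr = tm$ccr,
                       auc_defined = length(unique(y_test)) == 2,
                       stringsAsFactors = FALSE)
  structure(list(report = report, prob = prob, model = rf,
                 threshold = threshold),
            class = "ghs_model_report")
}

#' @export
print.ghs_model_report <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<ghs_model_report> %s / %s\n  threshold %.3f | ROC AUC %.3f | AP %.3f | sens %.3f | spec %.3f | CCR %.3f\n",
    r$split_name, r$descriptor_combo, r$threshold, r$roc_auc,
    r$avg_precision, r$sensitivity, r$specificity, r$ccr))
  invisible(x)
}

#' Full modelling cycle for one split
#'
#' Runs CV threshold selection on the training side, trains the final
#' model, and evaluates on the test side.
#'
#' @param x feature matrix for the whole modelling set (rows named).
#' @param labels named label vector.
#' @param split a `"split_spec"`.
#' @param descriptor_combo,ntree,k,seed see [train_and_evaluate()] and
#'   [cv_optimal_threshold()].
#' @return a `"ghs_model_report"` (with `cv` attached).
#' @export
run_split_model <- function(x, labels, split,
                            descriptor_combo = "molecular",
                            ntree = 200, k = 5, seed = 1) {
  tr <- intersect(split$train_keys, rownames(x))
  te <- intersect(split$test_keys, rownames(x))
  cv <- cv_optimal_threshold(x[tr, , drop = FALSE], labels[tr], k = k,
                             seed = stage_seed(seed, "cv"), ntree = ntree)
  fit <- train_and_evaluate(x[tr, , drop = FALSE], labels[tr],
                            x[te, , drop = FALSE], labels[te],
                            threshold = cv$threshold,
                            descriptor_combo = descriptor_combo,
                            split_name = split$name, ntree = ntree,
                            seed = seed)
  fit$cv <- cv
  fit
}

#' Repeat randomized splits
#'
#' Repeats the full split/threshold/train/evaluate cycle with independent
#' seeds and reports the mean and Bessel-corrected sample SD of each
#' metric. Only split methods with randomness can be repeated (the
#' rare-scaffolds split is deterministic and is refused).
#'
#' @param x feature matrix; `labels` named label vector.
#' @param method `"random"` or `"single_source"`.
#' @param n number of repeats.
#' @param base_seed seeds are `base_seed + 1:n`.
#' @param source_counts required for `method = "single_source"`.
#' @param fraction,ntree,k passed through.
#' @param descriptor_combo report label.
#' @return list with `summary` (data.frame metric, mean, sd) and `reports`
#'   (per-repeat rows).
#' @export
repeat_splits <- function(x, labels, method = c("random", "single_source"),
                          n = 20, base_seed = 100, source_counts = NULL,
                          fraction = 0.2, ntree = 200, k = 5,
                          descriptor_combo = "molecular") {
  method <- match.arg(method)
  rows <- lapply(seq_len(n), function(i) {
    seed <- base_seed + i
    split <- if (method == "random") {
      random_split(labels, fraction, seed)
    } else {
      single_source_split(labels, source_counts, fraction, seed)
    }
    run_split_model(x, labels, split, descriptor_combo, ntree, k,
                    seed = seed)$report
  })
  reports <- do.call(rbind, rows)
  metrics <- c("roc_auc", "avg_precision", "sensitivity", "specificity",
               "ccr")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(reports[[m]]), numeric(1)),
    sd = vapply(metrics, function(m)
      if (n > 1) stats::sd(reports[[m]]) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary, reports = reports)
}

#' Disagreement analysis between two thresholded models
#'
#' Restricts to compounds classified differently by the two models and
#' reports, per true class, the fraction on which model A is correct
#' (model B's fraction is the complement).
#'
#' @param pred_a,pred_b logical vectors (TRUE = predicted toxic) over the
#'   same compounds.
#' @param labels true labels ("toxic"/"nontoxic").
#' @return data.frame with `true_class`, `n_disagreements`,
#'   `frac_a_correct`, `frac_b_correct`; zero rows when the models agree
#'   everywhere.
#' @export
disagreement_analysis <- function(pred_a, pred_b, labels) {
  assert_that(length(pred_a) == length(pred_b) &&
                length(pred_a) == length(labels),
              "predictions and labels must align")
  dis <- pred_a != pred_b
  if (!any(dis))
    return(data.frame(true_class = character(0),
                      n_disagreements = integer(0),
                      frac_a_correct = numeric(0),
                      frac_b_correct = numeric(0)))
  out <- lapply(unique(labels[dis]), function(cl) {
    idx <- dis & labels == cl
    truth <- cl == "toxic"
    fa <- mean(pred_a[idx] == truth)
    data.frame(true_class = cl, n_disagreements = sum(idx),
               frac_a_correct = fa, frac_b_correct = 1 - fa,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ranked feature importances
#'
#' Impurity-based (mean decrease in Gini) importances, normalized to sum
#' to 1, in descending order with ties broken by feature name.
#'
#' @param model a fitted randomForest (e.g. from a `"ghs_model_report"`).
#' @return data.frame with `feature`, `importance`.
#' @export
feature_importances <- function(model) {
  if (inherits(model, "ghs_model_report")) model <- model$model
  imp <- randomForest::importance(model)[, "MeanDecreaseGini"]
  total <- sum(imp)
  imp <- if (total > 0) imp / total else imp
  res <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$importance, res$feature), ]
  rownames(res) <- NULL
  res
}
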