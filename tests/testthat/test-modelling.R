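# Split designs, metrics, threshold optimization, RF evaluation.

test_that("random split stratifies per class and is seed-deterministic", {
  labels <- stats::setNames(rep(c("toxic", "nontoxic"), c(100, 100)),
                            sprintf("m%03d", 1:200))
  sp <- random_split(labels, 0.2, seed = 3)
  expect_equal(length(sp$test_keys), 40)
  expect_equal(sum(labels[sp$test_keys] == "toxic"), 20)
  expect_equal(sort(c(sp$test_keys, sp$train_keys)), sort(names(labels)))
  expect_identical(sp, random_split(labels, 0.2, seed = 3))
  # uneven classes stay within one compound of the fraction
  lab2 <- stats::setNames(rep(c("toxic", "nontoxic"), c(33, 67)),
                          sprintf("u%03d", 1:100))
  sp2 <- random_split(lab2, 0.2, seed = 4)
  expect_lte(abs(sum(lab2[sp2$test_keys] == "toxic") - 33 * 0.2), 1)
  expect_error(random_split(stats::setNames(rep(c("toxic", "nontoxic"),
                                                c(3, 50)),
                                            sprintf("v%03d", 1:53))),
               "stratify")
})

test_that("rare-scaffold split follows the frequency rule exactly", {
  smis <- c(b1 = "Cc1ccccc1", b2 = "CCc1ccccc1", b3 = "CCCc1ccccc1",
            b4 = "OCc1ccccc1", b5 = "NCc1ccccc1",
            p1 = "Cc1ccncc1",
            t1 = "Cc1cccs1", t2 = "CCc1cccs1",
            f1 = "Cc1ccco1", f2 = "CCc1ccco1", f3 = "OCc1ccco1")
  sp <- rare_scaffold_split(smis)
  # pyridine occurs once, thiophene twice: all three in test
  expect_true(all(c("p1", "t1", "t2") %in% sp$test_keys))
  # benzene (5x) and furan (3x) compounds train
  expect_true(all(c(paste0("b", 1:5), paste0("f", 1:3)) %in% sp$train_keys))
  # scaffold frequencies of test compounds never exceed the bound
  counts <- table(sp$scaffolds)
  expect_true(all(counts[sp$scaffolds[sp$test_keys]] <= 2))
  # acyclic molecules share the empty scaffold
  smis2 <- c(smis, a1 = "CCCCO", a2 = "CCCCCO", a3 = "CCCCCC")
  sp2 <- rare_scaffold_split(smis2)
  expect_equal(unname(sp2$scaffolds[c("a1", "a2", "a3")]), rep("", 3))
  expect_true(all(c("a1", "a2", "a3") %in% sp2$train_keys))
})

test_that("single-source split draws only from the single-source pool", {
  labels <- stats::setNames(rep(c("toxic", "nontoxic"), each = 50),
                            sprintf("s%03d", 1:100))
  counts <- stats::setNames(rep(c(1L, 2L), 50), names(labels))
  sp <- single_source_split(labels, counts, 0.2, seed = 5)
  expect_true(all(counts[sp$test_keys] == 1))
  expect_equal(length(sp$test_keys), 20)
  expect_identical(sp, single_source_split(labels, counts, 0.2, seed = 5))
  # quota exceeding the pool fails loudly
  few <- counts; few[] <- 2L; few[1:3] <- 1L
  expect_error(single_source_split(labels, few, 0.2, seed = 5), "quota")
})

test_that("roc auc and average precision match reference implementations", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (i in 1:5) {
    scores <- stats::runif(80)
    labels <- ifelse(stats::rbinom(80, 1, stats::plogis(scores * 3 - 1.5)),
                     "toxic", "nontoxic")
    if (length(unique(labels)) < 2) next
    auc <- roc_auc(scores, labels)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                          levels = c("nontoxic", "toxic"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(auc, ref, tolerance = 1e-9)
    # Mann-Whitney formulation
    pos <- scores[labels == "toxic"]; neg <- scores[labels != "toxic"]
    u <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(auc, u, tolerance = 1e-9)
  }
  # perfect separation
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("toxic", "toxic", "nontoxic", "nontoxic")), 1)
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1),
                                 c("toxic", "toxic", "nontoxic",
                                   "nontoxic")), 1)
  # single-class test set: AUC undefined
  expect_true(is.na(roc_auc(c(0.2, 0.8), c("toxic", "toxic"))))
})

test_that("threshold optimization matches the exhaustive oracle", {
  # worked example: any threshold in (0.4, 0.6] is optimal; midpoint 0.5
  sel <- ghstox:::best_ccr_threshold(c(0.1, 0.4, 0.6, 0.9),
                                     c("nontoxic", "nontoxic", "toxic",
                                       "toxic"))
  expect_equal(sel$threshold, 0.5)
  expect_equal(sel$ccr, 1.0)

  # anti-correlated probabilities: extreme threshold, CCR 0.5
  sel2 <- ghstox:::best_ccr_threshold(c(0.9, 0.6, 0.4, 0.1),
                                      c("nontoxic", "nontoxic", "toxic",
                                        "toxic"))
  expect_equal(sel2$ccr, 0.5)

  # all probabilities equal: smallest candidate wins the tie
  sel3 <- ghstox:::best_ccr_threshold(rep(0.4, 6),
                                      rep(c("toxic", "nontoxic"), 3))
  expect_equal(sel3$threshold, 0)
  expect_equal(sel3$ccr, 0.5)

  # 100 random fixtures against an independent exhaustive scan
  set.seed(37)
  ccr_at <- function(prob, labels, th) {
    y <- labels == "toxic"
    (mean(prob[y] >= th) + mean(prob[!y] < th)) / 2
  }
  for (i in 1:100) {
    n <- sample(10:40, 1)
    prob <- round(stats::runif(n), 2)
    labels <- sample(rep(c("toxic", "nontoxic"), length.out = n))
    sel <- ghstox:::best_ccr_threshold(prob, labels)
    oracle_max <- max(vapply(c(0, sort(unique(prob)), 1),
                             function(th) ccr_at(prob, labels, th),
                             numeric(1)))
    expect_equal(sel$ccr, oracle_max, tolerance = 1e-12)
    expect_equal(ccr_at(prob, labels, sel$threshold), sel$ccr,
                 tolerance = 1e-12)
  }
})

test_that("cv threshold selection runs on stratified folds", {
  set.seed(51)
  x <- matrix(stats::rnorm(200 * 10), 200, 10,
              dimnames = list(sprintf("c%03d", 1:200),
                              sprintf("f%02d", 1:10)))
  labels <- ifelse(x[, 1] + stats::rnorm(200, 0, 0.5) > 0, "toxic",
                   "nontoxic")
  cv <- cv_optimal_threshold(x, labels, k = 5, seed = 2, ntree = 100)
  expect_true(cv$threshold >= 0 && cv$threshold <= 1)
  expect_false(anyNA(cv$pooled$prob))
  expect_error(cv_optimal_threshold(x, rep("toxic", 200)), "both classes")
})

test_that("rf evaluation reports internally consistent metrics", {
  set.seed(53)
  x <- matrix(stats::rnorm(300 * 8), 300, 8,
              dimnames = list(sprintf("c%03d", 1:300),
                              sprintf("f%02d", 1:8)))
  labels <- stats::setNames(
    ifelse(x[, 1] > 0, "toxic", "nontoxic"), rownames(x))
  sp <- random_split(labels, 0.2, seed = 6)
  fit <- run_split_model(x, labels, sp, "molecular", ntree = 100, seed = 6)
  r <- fit$report
  expect_equal(r$ccr, (r$sensitivity + r$specificity) / 2)
  expect_gt(r$roc_auc, 0.9)  # perfectly separable construction
  expect_true(all(unlist(r[c("roc_auc", "avg_precision", "sensitivity",
                             "specificity", "ccr")]) >= 0))
  # determinism of the full cycle
  fit2 <- run_split_model(x, labels, sp, "molecular", ntree = 100, seed = 6)
  expect_equal(fit$report, fit2$report)
})

test_that("labels independent of features give chance-level auc", {
  set.seed(57)
  x <- matrix(stats::rnorm(600 * 10), 600, 10,
              dimnames = list(sprintf("c%03d", 1:600),
                              sprintf("f%02d", 1:10)))
  labels <- stats::setNames(sample(rep(c("toxic", "nontoxic"), 300)),
                            rownames(x))
  sp <- random_split(labels, 0.2, seed = 7)
  fit <- run_split_model(x, labels, sp, "molecular", ntree = 100, seed = 7)
  expect_gt(fit$report$roc_auc, 0.35)
  expect_lt(fit$report$roc_auc, 0.65)
})

test_that("repeated splits report means and sample SDs", {
  set.seed(61)
  x <- matrix(stats::rnorm(150 * 6), 150, 6,
              dimnames = list(sprintf("c%03d", 1:150),
                              sprintf("f%02d", 1:6)))
  labels <- stats::setNames(ifelse(x[, 1] > 0, "toxic", "nontoxic"),
                            rownames(x))
  rs <- repeat_splits(x, labels, "random", n = 3, base_seed = 9,
                      ntree = 50)
  expect_equal(nrow(rs$reports), 3)
  expect_true(all(rs$reports$roc_auc >= 0 & rs$reports$roc_auc <= 1))
  expect_true(all(is.finite(rs$summary$sd)))
  rs1 <- repeat_splits(x, labels, "random", n = 1, base_seed = 9,
                       ntree = 50)
  expect_true(is.na(rs1$summary$sd[1]))
})

test_that("disagreement analysis matches hand counts", {
  labels <- c("toxic", "toxic", "toxic", "nontoxic", "nontoxic", "nontoxic")
  a <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  b <- c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE)
  # disagreements: 1 (A right), 3 (B right), 4 (A right), 5 (B right)
  res <- disagreement_analysis(a, b, labels)
  expect_equal(res$n_disagreements[res$true_class == "toxic"], 2)
  expect_equal(res$frac_a_correct[res$true_class == "toxic"], 0.5)
  expect_equal(res$frac_a_correct[res$true_class == "nontoxic"], 0.5)
  expect_equal(res$frac_b_correct, 1 - res$frac_a_correct)
  # identical predictions: empty report
  expect_equal(nrow(disagreement_analysis(a, a, labels)), 0)
  # one-sided case
  res2 <- disagreement_analysis(c(TRUE, TRUE), c(FALSE, FALSE),
                                c("toxic", "toxic"))
  expect_equal(res2$frac_a_correct, 1)
})

test_that("feature importances rank a determining feature first", {
  set.seed(67)
  x <- cbind(signal = rep(c(1, 0), each = 100),
             matrix(stats::rnorm(200 * 9), 200, 9,
                    dimnames = list(NULL, paste0("noise", 1:9))))
  rownames(x) <- sprintf("c%03d", 1:200)
  y <- stats::setNames(ifelse(x[, "signal"] == 1, "toxic", "nontoxic"),
                       rownames(x))
  fit <- train_and_evaluate(x[1:160, ], y[1:160], x[161:200, ], y[161:200],
                            ntree = 100, seed = 8)
  imp <- feature_importances(fit)
  expect_equal(imp$feature[1], "signal")
  expect_gt(imp$importance[1], 0.5)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance[-1] < imp$importance[1]))
})
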