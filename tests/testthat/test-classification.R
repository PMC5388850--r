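test_that("feature ranking orders by p and picks the right test", {
  coh <- one_informative_cohort(seed = 3, delta = 3, p = 5)
  rk <- rank_features(coh$features, coh$labels)
  expect_s3_class(rk, "feature_ranking")
  expect_equal(rk$feature[1], "f1")
  expect_lt(rk$p_value[1], 0.001)
  expect_false(is.unsorted(rk$p_value))
  # heavily skewed feature -> Mann-Whitney chosen
  set.seed(8)
  X <- data.frame(skew = exp(rnorm(56, sd = 2)))
  lab <- factor(rep(c("good", "poor"), c(42, 14)))
  expect_equal(rank_features(X, lab)$test, "mann-whitney")
  # constant feature dropped with a warning; single class errors
  Xc <- data.frame(f = rnorm(56), k = rep(1, 56))
  expect_warning(rk2 <- rank_features(Xc, lab), "constant")
  expect_equal(rk2$feature, "f")
  expect_error(rank_features(Xc, factor(rep("good", 56))),
               class = "qus_invalid_parameter")
})

test_that("k-NN posteriors implement the weighted-neighbour ratio", {
  # worked example: distances (1,1,2), classes (good,good,poor), W = 1/d
  train <- matrix(c(1, 1, 2), ncol = 1)
  lab <- factor(c("good", "good", "poor"))
  post <- knn_posterior(0, train, lab, k = 3)
  expect_equal(unname(post["good"]), 2 / 2.5, tolerance = 1e-6)
  expect_equal(sum(post), 1)
  # unanimity
  post1 <- knn_posterior(0, matrix(1:3, ncol = 1),
                         factor(c("good", "good", "good"),
                                levels = c("good", "poor")), k = 3)
  expect_equal(unname(post1["good"]), 1)
  # posteriors always sum to one
  set.seed(11)
  for (i in 1:200) {
    X <- matrix(rnorm(20), 10, 2)
    y <- factor(sample(c("a", "b"), 10, replace = TRUE))
    p <- knn_posterior(rnorm(2), X, y, k = 5)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_error(knn_posterior(0, train, lab, k = 4),
               class = "qus_invalid_parameter")
})

test_that("classification metrics reproduce the confusion arithmetic", {
  pred <- c(rep("good", 38), rep("poor", 4), rep("poor", 11), rep("good", 3))
  lab <- c(rep("good", 42), rep("poor", 14))
  m <- compute_metrics(pred, lab, "good")
  expect_equal(m$sensitivity, 100 * 38 / 42, tolerance = 1e-9)  # 90.5
  expect_equal(m$specificity, 100 * 11 / 14, tolerance = 1e-9)  # 78.6
  expect_equal(m$accuracy, 100 * 49 / 56, tolerance = 1e-9)     # 87.5
  perfect <- compute_metrics(lab, lab, "good")
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$accuracy),
               c(100, 100, 100))
  allpos <- compute_metrics(rep("good", 56), lab, "good")
  expect_equal(allpos$specificity, 0)
  nopos <- compute_metrics(rep("poor", 4), rep("poor", 4), "good")
  expect_true(is.na(nopos$sensitivity))
})

test_that("rank AUC equals the pair-counting oracle", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    lab <- factor(sample(c("good", "poor"), n, replace = TRUE))
    if (nlevels(droplevels(lab)) < 2) next
    sc <- round(rnorm(n), 1)        # rounding forces ties
    expect_equal(auc_rank(sc, lab, "good"), auc_pair_oracle(sc, lab, "good"))
  }
})

test_that("bootstrap AUC has sane endpoints and a degenerate-free CI", {
  lab <- factor(rep(c("good", "poor"), c(12, 8)))
  sep <- c(rnorm(12, 10), rnorm(8, -10))
  bs <- bootstrap_auc(sep, lab, "good", B = 500, seed = 2)
  expect_equal(bs$auc, 1)
  expect_equal(bs$ci, c(1, 1))
  set.seed(3)
  null_auc <- bootstrap_auc(rnorm(200), factor(rep(c("good", "poor"), 100)),
                            "good", B = 200, seed = 4)
  expect_lt(abs(null_auc$auc - 0.5), 0.1)
  expect_error(bootstrap_auc(1:5, rep("good", 5), "good"),
               class = "qus_invalid_parameter")
})

test_that("posterior separation test distinguishes separated groups", {
  lab <- factor(rep(c("good", "poor"), c(42, 14)))
  clean <- c(rep(1, 42), rep(0, 14))
  expect_lt(posterior_separation_test(clean, lab), 0.001)
  expect_true(is.na(posterior_separation_test(rep(0.5, 56), lab)))
  set.seed(6)
  p_null <- posterior_separation_test(runif(56), lab)
  expect_gt(p_null, 0.001)
})

test_that("LOOCV separates a 3-sigma cohort and is deterministic", {
  coh <- separated_cohort(seed = 4)
  r1 <- loocv_evaluate(coh$features, coh$labels, "knn", positive = "good",
                       B = 200, seed = 9)
  expect_gte(r1$metrics$accuracy, 95)
  expect_gte(r1$auc, 0.98)
  expect_true(all(r1$posterior >= 0 & r1$posterior <= 1))
  expect_true(r1$auc_ci[1] <= r1$auc && r1$auc <= r1$auc_ci[2])
  r2 <- loocv_evaluate(coh$features, coh$labels, "knn", positive = "good",
                       B = 200, seed = 9)
  expect_identical(r1$predicted, r2$predicted)
  expect_identical(r1$auc_ci, r2$auc_ci)
})

test_that("FLD and SVM run under LOOCV on a separable cohort", {
  coh <- separated_cohort(seed = 5, p = 3)
  fld <- loocv_evaluate(coh$features, coh$labels, "fld", positive = "good",
                        B = 50, seed = 1)
  expect_gte(fld$metrics$accuracy, 90)
  svm <- loocv_evaluate(coh$features, coh$labels, "svm", positive = "good",
                        B = 50, seed = 1,
                        config = list(svm_cost_grid = c(1, 10),
                                      svm_gamma_grid = c(0.1, 1)))
  expect_gte(svm$metrics$accuracy, 90)
  expect_s3_class(fld, "qus_loocv")
})

test_that("label permutation keeps classifiers at the null level", {
  coh <- separated_cohort(seed = 6)
  set.seed(31)
  aucs <- replicate(8, {
    perm <- sample(coh$labels)
    r <- loocv_evaluate(coh$features, perm, "knn", positive = "good",
                        B = 1, seed = 1)
    c(r$auc, r$metrics$accuracy)
  })
  expect_lt(abs(mean(aucs[1, ]) - 0.5), 0.1)
  # accuracy stays inside the binomial null band around the majority rate
  band <- qbinom(c(0.001, 0.999), 56, 0.75) / 56 * 100
  expect_gt(mean(aucs[2, ]), band[1] - 10)
  expect_lt(mean(aucs[2, ]), band[2])
})

test_that("forward selection finds the informative feature and stops", {
  coh <- one_informative_cohort(seed = 7, delta = 3, p = 5)
  sel <- sequential_forward_select(coh$features, coh$labels, "knn")
  expect_equal(sel$features[1], "f1")
  expect_lte(length(sel$features), 2)
  # a duplicated informative feature brings no improvement
  dup <- coh$features
  dup$f1_copy <- dup$f1
  sel2 <- sequential_forward_select(dup, coh$labels, "knn")
  expect_false(all(c("f1", "f1_copy") %in% sel2$features))
  # single feature available -> returned as-is
  one <- coh$features[, c("patient_id", "f1")]
  sel3 <- sequential_forward_select(one, coh$labels, "knn")
  expect_equal(sel3$features, "f1")
  # the selected model performs near the single-feature Bayes limit
  expect_gte(sel$accuracy, 85)
  # exhaustive-subset oracle at this scale: the greedy model is within two
  # misclassified patients of the best subset of all 31
  subsets <- unlist(lapply(1:5, function(k)
    utils::combn(paste0("f", 1:5), k, simplify = FALSE)), recursive = FALSE)
  accs <- vapply(subsets, function(fs)
    loocv_evaluate(coh$features, coh$labels, "knn", positive = "good",
                   feature_set = fs, B = 1, seed = 1)$metrics$accuracy,
    numeric(1))
  expect_gte(sel$accuracy, max(accs) - 2 / 56 * 100)
})
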