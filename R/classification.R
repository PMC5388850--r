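# Feature ranking, sequential forward selection, FLD / weighted k-NN /
# RBF-SVM under leave-one-patient-out cross-validation, and classification
# metrics with bootstrap AUC confidence intervals.

# numeric feature matrix from a feature table (patient_id column dropped)
feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    ids <- if ("patient_id" %in% names(features)) features$patient_id
           else rownames(features)
    num <- vapply(features, is.numeric, logical(1))
    num["patient_id"] <- FALSE
    m <- as.matrix(features[, num, drop = FALSE])
    rownames(m) <- ids
    m
  } else as.matrix(features)
}

# Shapiro-Wilk normality gate at alpha = 0.05 per class; degenerate or
# out-of-range samples fail the gate (rank-based test is then used).
class_normal <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000 || stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value > 0.05
}

#' Rank features by univariate class separation
#'
#' Each feature is tested for a class difference with an unpaired t-test when
#' both classes pass a Shapiro-Wilk normality check (alpha = 0.05), otherwise
#' a Mann-Whitney test; one-tailed in the direction of the observed
#' class-mean difference. Features are sorted from lowest to highest p-value.
#' Features constant in both classes are dropped with a warning.
#'
#' @param features feature table (data.frame with `patient_id` + numeric
#'   columns, or numeric matrix).
#' @param labels two-level factor (or character) of class labels.
#' @return data.frame of class `feature_ranking`: `feature`, `p_value`,
#'   `test` ("t" or "mann-whitney"), sorted ascending by p.
#' @export
rank_features <- function(features, labels) {
  X <- feature_matrix(features)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop_invalid("labels must contain two classes")
  l1 <- levels(labels)[1]
  rows <- lapply(colnames(X), function(fn) {
    x <- X[labels == l1, fn]; y <- X[labels != l1, fn]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    if (stats::sd(c(x, y)) == 0) return(NULL)
    alt <- if (mean(x) >= mean(y)) "greater" else "less"
    if (class_normal(x) && class_normal(y)) {
      p <- stats::t.test(x, y, alternative = alt)$p.value
      test <- "t"
    } else {
      p <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt,
                                               exact = FALSE)$p.value)
      test <- "mann-whitney"
    }
    data.frame(feature = fn, p_value = p, test = test,
               stringsAsFactors = FALSE)
  })
  dropped <- colnames(X)[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("dropped constant/degenerate feature(s): ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) stop_invalid("no testable features")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Weighted k-NN class posteriors
#'
#' The posterior for class j is the ratio of the summed weights of the k
#' nearest neighbours belonging to j to the summed weights of all k
#' neighbours, with inverse-distance weights `W_i = 1 / (d_i + eps)`.
#' Distances are Euclidean; callers standardize features beforehand.
#'
#' @param x numeric query vector.
#' @param train_x numeric matrix of training samples (rows).
#' @param train_labels factor of training labels.
#' @param k neighbour count, `1 <= k <= nrow(train_x)`.
#' @param eps small constant guarding zero distances.
#' @return named posterior vector over the label levels (sums to 1).
#' @export
knn_posterior <- function(x, train_x, train_labels, k, eps = 1e-8) {
  train_labels <- as.factor(train_labels)
  n <- nrow(train_x)
  if (k < 1 || k > n) stop_invalid("k must be between 1 and nrow(train_x)")
  d <- sqrt(colSums((t(train_x) - x)^2))
  nb <- order(d)[seq_len(k)]
  w <- 1 / (d[nb] + eps)
  post <- vapply(levels(train_labels),
                 function(l) sum(w[train_labels[nb] == l]) / sum(w),
                 numeric(1))
  post
}

# ---- classifier backends ------------------------------------------------

default_config <- function() {
  list(eps = 1e-8,
       k_grid = NULL,                              # odd 1..min(15, m-1)
       svm_cost_grid = 2^seq(-5, 15, by = 2),
       svm_gamma_grid = 2^seq(-15, 3, by = 2))
}

merge_config <- function(config) {
  out <- default_config()
  out[names(config)] <- config
  out
}

# inner-LOOCV accuracy of k-NN on a training fold, per candidate k
knn_pick_k <- function(X, y, k_grid, eps) {
  m <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  acc <- vapply(k_grid, function(k) {
    ok <- vapply(seq_len(m), function(i) {
      nb <- order(D[i, ])[seq_len(k)]
      w <- 1 / (D[i, nb] + eps)
      sums <- tapply(w, y[nb], sum, default = 0)
      names(which.max(sums)) == as.character(y[i])
    }, logical(1))
    mean(ok)
  }, numeric(1))
  k_grid[which.max(acc)]          # ties -> smallest k (which.max is first)
}

svm_pick_grid <- function(X, y, cost_grid, gamma_grid) {
  m <- nrow(X)
  best <- c(acc = -1, cost = cost_grid[1], gamma = gamma_grid[1])
  for (g in gamma_grid) for (co in cost_grid) {
    ok <- vapply(seq_len(m), function(i) {
      fit <- e1071::svm(X[-i, , drop = FALSE], y[-i], kernel = "radial",
                        cost = co, gamma = g, scale = FALSE)
      as.character(stats::predict(fit, X[i, , drop = FALSE])) ==
        as.character(y[i])
    }, logical(1))
    a <- mean(ok)
    if (a > best["acc"]) best <- c(acc = a, cost = co, gamma = g)
  }
  best
}

# Train on standardized X; returns a model closure-free list.
train_classifier <- function(X, y, classifier, config) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    return(list(type = "majority", majority = names(which.max(table(y))),
                levels = levels(y)))
  switch(classifier,
    fld = list(type = "fld", fit = MASS::lda(X, grouping = y),
               levels = levels(y)),
    knn = {
      kg <- config$k_grid
      if (is.null(kg)) kg <- seq(1L, max(1L, min(15L, nrow(X) - 1L)), by = 2L)
      kg <- kg[kg <= nrow(X)]
      k <- if (length(kg) > 1) knn_pick_k(X, y, kg, config$eps) else kg[1]
      list(type = "knn", X = X, y = y, k = k, eps = config$eps,
           levels = levels(y))
    },
    svm = {
      sel <- if (length(config$svm_cost_grid) * length(config$svm_gamma_grid) > 1)
        svm_pick_grid(X, y, config$svm_cost_grid, config$svm_gamma_grid)
      else c(cost = config$svm_cost_grid[1], gamma = config$svm_gamma_grid[1])
      fit <- e1071::svm(X, y, kernel = "radial", cost = sel[["cost"]],
                        gamma = sel[["gamma"]], scale = FALSE)
      list(type = "svm", fit = fit, cost = sel[["cost"]],
           gamma = sel[["gamma"]], levels = levels(y))
    },
    stop_invalid("unknown classifier: ", classifier))
}

# posterior matrix (rows = samples, cols = label levels)
predict_posterior <- function(model, newX) {
  lv <- model$levels
  n <- nrow(newX)
  switch(model$type,
    majority = {
      post <- matrix(0, n, length(lv), dimnames = list(NULL, lv))
      post[, model$majority] <- 1
      post
    },
    fld = {
      p <- stats::predict(model$fit, newX)$posterior
      p[, lv, drop = FALSE]
    },
    knn = t(apply(newX, 1L, knn_posterior, train_x = model$X,
                  train_labels = model$y, k = model$k, eps = model$eps)),
    svm = {
      pr <- stats::predict(model$fit, newX, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision value is oriented to the class named first in the colname
      first <- strsplit(colnames(dv)[1], "/")[[1]][1]
      p_first <- stats::plogis(dv[, 1])
      post <- cbind(p_first, 1 - p_first)
      colnames(post) <- c(first, setdiff(lv, first))
      post[, lv, drop = FALSE]
    })
}

standardize_train <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

apply_standardize <- function(X, st) {
  sweep(sweep(X, 2L, st$mu, "-"), 2L, st$sd, "/")
}

#' Classification metrics
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy = (TP+TN)/n,
#' all in percent, with the positive class configurable (good responders, or
#' complete responders under the alternative grouping).
#'
#' @param predictions predicted labels.
#' @param labels true labels.
#' @param positive positive class label.
#' @return list: `sensitivity`, `specificity`, `accuracy` (percent), and the
#'   confusion counts `tp`, `fn`, `tn`, `fp`.
#' @export
compute_metrics <- function(predictions, labels, positive) {
  pred <- as.character(predictions); lab <- as.character(labels)
  tp <- sum(pred == positive & lab == positive)
  fn <- sum(pred != positive & lab == positive)
  tn <- sum(pred != positive & lab != positive)
  fp <- sum(pred == positive & lab != positive)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec,
       accuracy = 100 * (tp + tn) / length(lab),
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Rank-form AUC
#'
#' Area under the ROC curve via the normalized Mann-Whitney U statistic
#' (ties counted half).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels true labels.
#' @param positive positive class label.
#' @export
auc_rank <- function(scores, labels, positive) {
  lab <- as.character(labels) == positive
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap AUC with percentile confidence interval
#'
#' The point AUC is the rank-form Mann-Whitney AUC; the CI comes from the
#' 2.5/97.5 percentiles of AUCs over patient-resampled bootstrap replicates
#' (single-class resamples are redrawn).
#'
#' @inheritParams auc_rank
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param max_retry retry cap for degenerate resamples.
#' @return list: `auc`, `ci` (length 2), `B`.
#' @export
bootstrap_auc <- function(scores, labels, positive, B = 1000L, seed = 1L,
                          max_retry = 10000L) {
  lab <- as.character(labels)
  if (length(unique(lab)) < 2) stop_invalid("both classes must be present")
  if (B < 1) stop_invalid("B must be >= 1")
  point <- auc_rank(scores, labels, positive)
  n <- length(scores)
  reps <- with_seed(seed, {
    out <- numeric(B)
    retries <- 0L
    b <- 1L
    while (b <= B) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(lab[idx])) < 2) {
        retries <- retries + 1L
        if (retries > max_retry)
          stop_invalid("too many degenerate bootstrap resamples")
        next
      }
      out[b] <- auc_rank(scores[idx], lab[idx], positive)
      b <- b + 1L
    }
    out
  })
  list(auc = point,
       ci = unname(stats::quantile(reps, c(0.025, 0.975), type = 7)),
       B = as.integer(B))
}

#' Normality-gated two-sample test on posterior probabilities
#'
#' Tests whether the positive-class posteriors separate the two true groups:
#' a t-test when both groups pass the Shapiro-Wilk check, a Mann-Whitney
#' test otherwise (the same rule used for feature ranking).
#'
#' @param posteriors positive-class posterior per patient.
#' @param labels true labels.
#' @return p-value (NA when the posteriors are constant).
#' @export
posterior_separation_test <- function(posteriors, labels) {
  labels <- as.factor(labels)
  x <- posteriors[labels == levels(labels)[1]]
  y <- posteriors[labels != levels(labels)[1]]
  if (stats::sd(posteriors) == 0 || length(x) < 2 || length(y) < 2)
    return(NA_real_)
  if (class_normal(x) && class_normal(y))
    stats::t.test(x, y)$p.value
  else
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
}

#' Leave-one-patient-out evaluation of a classifier
#'
#' One fold per patient. Standardization, k-NN neighbour count and SVM
#' (C, gamma) grid searches are computed within each training fold; the
#' left-out patient is scored on the trained model. Optionally
#' (`select = TRUE`) the feature ranking and sequential forward selection are
#' also recomputed inside every training fold for fully honest
#' cross-validation; by default the caller supplies the feature set
#' (whole-dataset selection, as in classical wrapper pipelines).
#'
#' @param features feature table (`patient_id` + numeric columns).
#' @param labels two-level factor of true labels.
#' @param classifier `"fld"`, `"knn"` or `"svm"`.
#' @param positive positive class label (defaults to the first level).
#' @param feature_set character vector of feature columns to use (default:
#'   all).
#' @param select recompute ranking + forward selection inside every fold.
#' @param config list overriding the classifier defaults (`k_grid`,
#'   `svm_cost_grid`, `svm_gamma_grid`, `eps`).
#' @param B bootstrap replicates for the AUC CI.
#' @param seed RNG seed (bootstrap).
#' @return object of class `qus_loocv`: per-patient `predicted` and
#'   `posterior` (positive class), `metrics`, `auc`, `auc_ci`,
#'   `separation_p`, `feature_set`, `classifier`, `positive`.
#' @export
loocv_evaluate <- function(features, labels, classifier = c("knn", "fld", "svm"),
                           positive = NULL, feature_set = NULL,
                           select = FALSE, config = list(), B = 1000L,
                           seed = 1L) {
  classifier <- match.arg(classifier)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop_invalid("both classes required")
  if (is.null(positive)) positive <- levels(labels)[1]
  X_all <- feature_matrix(features)
  n <- nrow(X_all)
  if (n < 3) stop_invalid("need at least 3 patients")
  if (is.null(feature_set)) feature_set <- colnames(X_all)
  config <- merge_config(config)
  pred <- character(n); post <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- droplevels(labels[tr])
    fs <- feature_set
    if (select) {
      rk <- rank_features(X_all[tr, , drop = FALSE], labels[tr])
      fs <- sequential_forward_select(X_all[tr, , drop = FALSE], labels[tr],
                                      classifier = classifier,
                                      ranking = rk, config = config)$features
    }
    if (nlevels(ytr) < 2) {
      flagged[i] <- TRUE
      warning("fold ", i, " has a single training class; majority fallback")
    }
    Xtr <- X_all[tr, fs, drop = FALSE]
    st <- standardize_train(Xtr)
    model <- train_classifier(apply_standardize(Xtr, st), ytr, classifier,
                              config)
    p <- predict_posterior(model, apply_standardize(
      X_all[i, fs, drop = FALSE], st))
    lv <- colnames(p)
    pred[i] <- lv[which.max(p[1, ])]
    post[i] <- if (positive %in% lv) p[1, positive] else 0
  }
  metrics <- compute_metrics(pred, labels, positive)
  bs <- bootstrap_auc(post, labels, positive, B = B, seed = seed)
  structure(list(predicted = stats::setNames(pred, rownames(X_all)),
                 posterior = stats::setNames(post, rownames(X_all)),
                 labels = labels, metrics = metrics,
                 auc = bs$auc, auc_ci = bs$ci,
                 separation_p = posterior_separation_test(post, labels),
                 feature_set = feature_set, classifier = classifier,
                 positive = positive, flagged_folds = which(flagged)),
            class = "qus_loocv")
}

#' @export
print.qus_loocv <- function(x, ...) {
  cat(sprintf("LOOCV %s classifier (%d patients, positive = '%s')\n",
              x$classifier, length(x$predicted), x$positive))
  cat(sprintf("  Se %.1f%%  Sp %.1f%%  Ac %.1f%%  AUC %.2f (%.2f, %.2f)\n",
              x$metrics$sensitivity, x$metrics$specificity,
              x$metrics$accuracy, x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' @export
summary.qus_loocv <- function(object, ...) {
  cat(sprintf("Leave-one-patient-out cross-validation, %s classifier\n",
              object$classifier))
  cat(sprintf("Patients: %d  (positive class: %s)\n",
              length(object$predicted), object$positive))
  m <- object$metrics
  cat(sprintf("Confusion: TP %d  FN %d  TN %d  FP %d\n", m$tp, m$fn, m$tn, m$fp))
  cat(sprintf("Sensitivity %.1f%%  Specificity %.1f%%  Accuracy %.1f%%\n",
              m$sensitivity, m$specificity, m$accuracy))
  cat(sprintf("AUC %.3f, 95%% CI (%.3f, %.3f)\n", object$auc,
              object$auc_ci[1], object$auc_ci[2]))
  cat(sprintf("Posterior group-separation p = %.4g\n", object$separation_p))
  cat("Features:", paste(object$feature_set, collapse = ", "), "\n")
  invisible(object)
}

#' @export
plot.qus_loocv <- function(x, ...) {
  lab <- as.character(x$labels) == x$positive
  th <- sort(unique(c(-Inf, x$posterior, Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(x$posterior[lab] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(x$posterior[!lab] >= t), numeric(1))
  graphics::plot(fpr, tpr, type = "s", xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("ROC (%s), AUC = %.2f", x$classifier, x$auc),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Sequential forward feature selection
#'
#' Starting from the lowest-p ranked feature, candidates are added in rank
#' order and kept only when the leave-one-out classification accuracy
#' strictly improves (ties keep the smaller model). The scan terminates after
#' the full ranked list has been examined.
#'
#' @param features feature table or matrix.
#' @param labels two-level factor.
#' @param classifier `"fld"`, `"knn"` or `"svm"`.
#' @param ranking a [rank_features()] result (computed if omitted).
#' @param config classifier configuration (see [loocv_evaluate()]).
#' @param positive positive class label.
#' @return list: `features` (selected set, in inclusion order), `accuracy`
#'   (LOOCV accuracy of the final model, percent), `trace` (data.frame of
#'   candidate decisions).
#' @export
sequential_forward_select <- function(features, labels, classifier = "knn",
                                      ranking = NULL, config = list(),
                                      positive = NULL) {
  labels <- as.factor(labels)
  X <- feature_matrix(features)
  if (is.null(ranking)) ranking <- rank_features(X, labels)
  if (is.null(positive)) positive <- levels(labels)[1]
  config <- merge_config(config)
  cand <- ranking$feature
  acc_of <- function(fs) {
    res <- loocv_evaluate(X, labels, classifier = classifier,
                          positive = positive, feature_set = fs,
                          config = config, B = 1L, seed = 1L)
    res$metrics$accuracy
  }
  current <- cand[1]
  best_acc <- acc_of(current)
  trace <- data.frame(feature = cand[1], accuracy = best_acc, kept = TRUE,
                      stringsAsFactors = FALSE)
  for (f in cand[-1]) {
    a <- acc_of(c(current, f))
    keep <- a > best_acc
    if (keep) { current <- c(current, f); best_acc <- a }
    trace <- rbind(trace, data.frame(feature = f, accuracy = a, kept = keep,
                                     stringsAsFactors = FALSE))
  }
  list(features = current, accuracy = best_acc, trace = trace)
}
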