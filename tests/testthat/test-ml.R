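# toy cohort construction used across the ML tests
toy_cohort <- function(n = 60, p_noise = 10, planted = 0, shift = 1.2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  data <- as.data.frame(matrix(rnorm(n * p_noise), n,
                               dimnames = list(NULL, sprintf("noise%02d", 1:p_noise))))
  if (planted > 0) {
    for (k in seq_len(planted))
      data[[sprintf("signal%d", k)]] <- rnorm(n) + shift * y
  }
  meta <- data.frame(name = names(data), kind = "continuous",
                     provenance = ifelse(grepl("signal", names(data)),
                                         "sim_biv", "clinical"),
                     preop_safe = TRUE)
  outcomes <- data.frame(delta_ef = ifelse(y == 1, 17, 3) + rnorm(n, 0, 0.1),
                         delta_esv = ifelse(y == 1, -47, -9))
  cohort_table(data, meta, outcomes)
}

test_that("response labels follow the EF and ESV criteria", {
  oc <- data.frame(delta_ef = c(17, 3, 10.5, 6, NA),
                   delta_esv = c(-47, -10, -20, -16, -50))
  expect_equal(label_response(oc, "EF10"), c(1L, 0L, 1L, 0L, NA))
  expect_equal(label_response(oc, "EF5"), c(1L, 0L, 1L, 1L, NA))
  expect_equal(label_response(oc, "EF15"), c(1L, 0L, 0L, 0L, NA))
  expect_equal(label_response(oc, "ESV15"), c(1L, 0L, 1L, 1L, 1L))
  expect_equal(label_response(oc, "EF10_ESV15"), c(1L, 0L, 1L, 0L, NA))
})

test_that("preprocessing drops missing, constant, and collinear columns", {
  ct <- toy_cohort(n = 50)
  ct$data$withNA <- c(NA, rnorm(49))
  ct$data$constant <- 1
  ct$data$dup <- ct$data$noise01                       # r = 1
  set.seed(4)
  ct$data$corr80 <- 0.8 * scale(ct$data$noise02) + sqrt(1 - 0.64) * rnorm(50)
  ct$data$postop <- rnorm(50)
  ct$meta <- rbind(ct$meta,
                   data.frame(name = c("withNA", "constant", "dup", "corr80", "postop"),
                              kind = "continuous", provenance = "clinical",
                              preop_safe = c(TRUE, TRUE, TRUE, TRUE, FALSE)))
  expect_warning(pp <- preprocess_cohort(ct), "zero-variance")
  expect_false("withNA" %in% names(pp$data))
  expect_false("constant" %in% names(pp$data))
  expect_false("postop" %in% names(pp$data))            # leakage guard on columns
  expect_true(xor("dup" %in% names(pp$data), "noise01" %in% names(pp$data)))
  r_emp <- abs(cor(ct$data$corr80, ct$data$noise02))
  expect_lt(r_emp, 0.85)
  expect_true(all(c("corr80", "noise02") %in% names(pp$data)))  # r = 0.80 pair kept
  cm <- abs(cor(as.matrix(pp$data)))
  diag(cm) <- 0
  expect_lte(max(cm), 0.85)                             # full pairwise oracle
  # z-scoring of continuous columns
  expect_lt(max(abs(colMeans(as.matrix(pp$data)))), 1e-12)
})

test_that("every selector ranks a perfect separator first", {
  ct <- toy_cohort(n = 80, planted = 0, seed = 2)
  y <- label_response(ct$outcomes, "EF10")
  x <- ct$data
  x$separator <- y * 2 + rnorm(80, 0, 0.01)
  meta <- rbind(ct$meta, data.frame(name = "separator", kind = "continuous",
                                    provenance = "sim_biv", preop_safe = TRUE))
  for (sel in c("UST", "MDA", "L1")) {
    got <- select_features(x, y, meta, sel, k = 3, seed = 7)
    expect_equal(got[1], "separator", info = sel)
  }
})

test_that("UST tests categorical columns by chi-squared and continuous by t-test", {
  ct <- toy_cohort(n = 80, seed = 3)
  y <- label_response(ct$outcomes, "EF10")
  x <- ct$data
  set.seed(5)
  x$cat <- rbinom(80, 1, 0.4)
  meta <- rbind(ct$meta, data.frame(name = "cat", kind = "categorical",
                                    provenance = "clinical", preop_safe = TRUE))
  got <- select_features(x, y, meta, "UST", k = 5)
  audit <- attr(got, "audit")
  expect_equal(audit$method[audit$name == "cat"], "chisq")
  expect_true(all(audit$method[audit$name != "cat"] == "ttest"))
})

test_that("k larger than the feature count returns everything with a warning", {
  ct <- toy_cohort(n = 40, p_noise = 4)
  y <- label_response(ct$outcomes, "EF10")
  expect_warning(got <- select_features(ct$data, y, ct$meta, "UST", k = 8),
                 "exceeds")
  expect_length(got, 4)
})

test_that("planted features are recovered inside the top-8 across CV folds", {
  ct <- toy_cohort(n = 200, p_noise = 17, planted = 3, shift = 1.2, seed = 6)
  r <- evaluate_classifier(ct, classifier = "LR", selector = "UST", cv = "kfold",
                           n_repeats = 2, seed = 6)
  freq <- r$selection_freq[sprintf("signal%d", 1:3)]
  expect_true(all(freq >= 0.9))
})

test_that("perfectly separable cohorts give pooled AUC 1 for linear classifiers", {
  ct <- toy_cohort(n = 30, p_noise = 3, planted = 1, shift = 30, seed = 8)
  for (clf in c("LR", "SVM")) {
    r <- evaluate_classifier(ct, classifier = clf, selector = "UST", cv = "loo",
                             k = 2, seed = 8)
    expect_equal(r$auc, 1, info = clf)
    expect_equal(r$accuracy, 1, info = clf)
  }
})

test_that("the pooled AUC equals the concordant-pair oracle", {
  ct <- toy_cohort(n = 40, p_noise = 6, planted = 2, seed = 9)
  r <- evaluate_classifier(ct, classifier = "LDA", selector = "UST", cv = "loo",
                           k = 4, seed = 9)
  expect_equal(r$auc_pooled,
               auc_oracle(r$scores$label, r$scores$score), tolerance = 1e-9)
  # and on a fixed toy score set with ties
  lab <- c(1, 1, 1, 0, 0, 0, 1, 0, 1, 0)
  sc <- c(0.9, 0.8, 0.5, 0.5, 0.2, 0.1, 0.7, 0.3, 0.3, 0.3)
  r2 <- pROC::roc(lab, sc, levels = c(0, 1), direction = "<", quiet = TRUE)
  expect_equal(as.numeric(pROC::auc(r2)), auc_oracle(lab, sc), tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transformations", {
  set.seed(10)
  lab <- rbinom(50, 1, 0.4)
  sc <- rnorm(50) + lab
  expect_equal(auc_oracle(lab, exp(sc)), auc_oracle(lab, sc))
  r1 <- pROC::roc(lab, sc, levels = c(0, 1), direction = "<", quiet = TRUE)
  r2 <- pROC::roc(lab, exp(sc), levels = c(0, 1), direction = "<", quiet = TRUE)
  expect_equal(as.numeric(pROC::auc(r1)), as.numeric(pROC::auc(r2)))
})

test_that("stochastic pipelines are reproducible under a fixed seed", {
  ct <- toy_cohort(n = 50, p_noise = 8, planted = 2, seed = 11)
  a <- evaluate_classifier(ct, classifier = "RF", selector = "MDA", cv = "kfold",
                           n_repeats = 2, seed = 5)
  b <- evaluate_classifier(ct, classifier = "RF", selector = "MDA", cv = "kfold",
                           n_repeats = 2, seed = 5)
  expect_identical(a$scores, b$scores)
  expect_identical(a$auc, b$auc)
  c2 <- evaluate_classifier(ct, classifier = "RF", selector = "MDA", cv = "kfold",
                            n_repeats = 2, seed = 6)
  expect_false(identical(a$scores$score, c2$scores$score))
})

test_that("no test-fold row ever reaches a scaler, selector, or classifier fit", {
  ct <- toy_cohort(n = 40, p_noise = 6, planted = 1, seed = 12)
  for (cv in c("loo", "kfold")) {
    r <- evaluate_classifier(ct, classifier = "LR", selector = "UST", cv = cv,
                             k = 5, n_repeats = 2, seed = 12)
    for (fold in r$audit) {
      expect_length(intersect(fold$test_rows, fold$scaler_rows), 0)
      expect_length(intersect(fold$test_rows, fold$selector_rows), 0)
      expect_length(intersect(fold$test_rows, fold$fit_rows), 0)
      expect_setequal(c(fold$test_rows, fold$fit_rows), seq_len(r$n))
    }
  }
})

test_that("binary metrics at the Youden cutoff match the confusion matrix", {
  ct <- toy_cohort(n = 60, p_noise = 5, planted = 2, seed = 13)
  r <- evaluate_classifier(ct, classifier = "LR", selector = "UST", cv = "loo",
                           k = 4, seed = 13)
  cm <- r$confusion
  expect_equal(sum(cm), r$n)
  expect_equal(r$accuracy, (cm[1, 1] + cm[2, 2]) / sum(cm))
  expect_equal(r$sensitivity, cm[1, 1] / sum(cm[, 1]))
  expect_equal(r$specificity, cm[2, 2] / sum(cm[, 2]))
})

test_that("PCA at full rank reproduces the plain logistic fit (rotation invariance)", {
  ct <- toy_cohort(n = 40, p_noise = 4, planted = 1, shift = 1.5, seed = 14)
  pl <- suppressWarnings(pca_lr(ct, n_components = c(2, 5), seed = 14))
  full <- evaluate_classifier(ct, classifier = "LR", selector = "UST", cv = "loo",
                              k = 5, seed = 14)
  expect_equal(pl$auc[pl$ncomp == 5], full$auc, tolerance = 1e-9)
  expect_true(all(diff(pl$explained_variance) >= 0))
  expect_warning(pca_lr(ct, n_components = c(2, 30), seed = 1), "capped")
  # component scores are orthogonal on the fitted data
  pp <- preprocess_cohort(cohort_table(ct$data, ct$meta, ct$outcomes))
  pc <- prcomp(as.matrix(pp$data), center = TRUE, scale. = TRUE)
  gram <- crossprod(pc$x[, 1:3])
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
})

test_that("k-means on the first two PCs recovers separated groups", {
  set.seed(15)
  n <- 40
  grp <- rep(c(0, 1), each = n / 2)
  data <- data.frame(f1 = rnorm(n, 10 * grp), f2 = rnorm(n, -6 * grp),
                     f3 = rnorm(n))
  meta <- data.frame(name = names(data), kind = "continuous",
                     provenance = "clinical", preop_safe = TRUE)
  oc <- data.frame(delta_ef = ifelse(grp == 1, 15, 2), delta_esv = rnorm(n))
  ct <- cohort_table(data, meta, oc)
  km <- kmeans_clusters(ct, seed = 15)
  agree <- max(mean((km$cluster - 1) == grp), mean((km$cluster - 1) != grp))
  expect_equal(agree, 1)
  expect_equal(nrow(km$outcome_summary), 2)
  # duplicated rows land in the same cluster
  dup <- cohort_table(rbind(data, data[1, ]), meta,
                      rbind(oc, oc[1, ]))
  kmd <- kmeans_clusters(dup, seed = 15)
  expect_equal(unname(kmd$cluster[1]), unname(kmd$cluster[n + 1]))
  # within-cluster sum of squares is minimal over all assignments at tiny n
  small <- cohort_table(data[1:8, ], meta, oc[1:8, ])
  kms <- kmeans_clusters(small, seed = 15)
  z <- prcomp(as.matrix(preprocess_cohort(small)$data), center = TRUE,
              scale. = TRUE)$x[, 1:2]
  wss <- function(assign) {
    sum(vapply(unique(assign), function(cl) {
      zz <- z[assign == cl, , drop = FALSE]
      sum(sweep(zz, 2, colMeans(zz))^2)
    }, 0))
  }
  all_assign <- expand.grid(rep(list(1:2), 8))
  valid <- apply(all_assign, 1, function(a) length(unique(a)) == 2)
  best <- min(apply(all_assign[valid, ], 1, wss))
  expect_lte(wss(kms$cluster), best + 1e-9)
})
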