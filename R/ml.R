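# Supervised classification pipeline for CRT response.
#
# A cohort table couples a feature matrix with per-column metadata (kind,
# provenance, preop-safety) and post-operative outcomes.  Response labels
# are derived from the outcomes per criterion; preprocessing drops
# missing-value and collinear columns; feature selection (top 8) runs
# INSIDE the cross-validation loop together with scaling and classifier
# fitting, so no test-fold row ever reaches a fit; out-of-fold scores are
# pooled into one ROC curve.

.PROVENANCE_ORDER <- c("clinical", "ctmri_model", "sim_lbbb", "sim_biv", "sim_delta")

#' Construct a cohort table
#'
#' @param data data frame of per-patient feature columns (numeric; binary
#'   categorical features coded 0/1)
#' @param meta data frame with one row per feature column: `name`,
#'   `kind` (`"continuous"`/`"categorical"`), `provenance` (one of
#'   clinical, ctmri_model, sim_lbbb, sim_biv, sim_delta), `preop_safe`
#' @param outcomes data frame with `delta_ef` (absolute percentage-point EF
#'   change after CRT) and `delta_esv` (% ESV change), one row per patient
#' @return a `cohort_table`
#' @export
cohort_table <- function(data, meta, outcomes) {
  stopifnot(is.data.frame(data), is.data.frame(meta), is.data.frame(outcomes))
  if (!all(c("name", "kind", "provenance", "preop_safe") %in% names(meta)))
    stop("meta needs name, kind, provenance, preop_safe")
  if (!identical(sort(names(data)), sort(meta$name)))
    stop("meta rows must match data columns")
  if (!all(meta$provenance %in% .PROVENANCE_ORDER))
    stop("unknown provenance")
  if (!all(meta$kind %in% c("continuous", "categorical")))
    stop("kind must be continuous or categorical")
  if (nrow(outcomes) != nrow(data)) stop("outcomes must have one row per patient")
  structure(list(data = data, meta = meta[match(names(data), meta$name), ],
                 outcomes = outcomes),
            class = "cohort_table")
}

#' Binary response labels from post-operative outcomes
#'
#' EF criteria use the absolute percentage-point EF increase
#' (`delta_ef > cutoff`); ESV15 uses a relative end-systolic volume
#' reduction of more than 15% (`delta_esv < -15`); `EF10_ESV15` is the
#' conjunction.
#'
#' @param outcomes outcomes data frame (`delta_ef`, `delta_esv`)
#' @param criterion one of `"EF5"`, `"EF10"`, `"EF15"`, `"ESV15"`,
#'   `"EF10_ESV15"`
#' @return integer 0/1 vector (NA where the needed outcome is missing)
#' @export
label_response <- function(outcomes, criterion = "EF10") {
  criterion <- match.arg(criterion, c("EF5", "EF10", "EF15", "ESV15", "EF10_ESV15"))
  ef <- function(cut) as.integer(outcomes$delta_ef > cut)
  switch(criterion,
         EF5 = ef(5), EF10 = ef(10), EF15 = ef(15),
         ESV15 = as.integer(outcomes$delta_esv < -15),
         EF10_ESV15 = as.integer(outcomes$delta_ef > 10 & outcomes$delta_esv < -15))
}

# priority order for collinearity drops: clinical first, then model-derived,
# alphabetical within provenance (the earlier column of a correlated pair
# is kept)
.column_priority <- function(meta) {
  order(match(meta$provenance, .PROVENANCE_ORDER), meta$name)
}

#' Preprocess a cohort table
#'
#' Restricts to pre-operative-safe columns, drops any column containing a
#' missing value (column-wise exclusion, no imputation), drops zero-variance
#' columns, z-scores continuous columns, and removes collinear features:
#' walking the columns in priority order (clinical before model-derived,
#' alphabetical within), a column is dropped when it correlates above the
#' threshold with any already-kept column, so no surviving pair exceeds the
#' threshold.
#'
#' @param ct a [cohort_table()]
#' @param collinearity_threshold absolute Pearson correlation above which the
#'   lower-priority column of a pair is dropped (default 0.85)
#' @param scale z-score continuous columns (default TRUE)
#' @return the preprocessed `cohort_table`; dropped column names are in
#'   `attr(, "dropped")`
#' @export
preprocess_cohort <- function(ct, collinearity_threshold = 0.85, scale = TRUE) {
  data <- ct$data; meta <- ct$meta
  dropped <- list()
  unsafe <- meta$name[!meta$preop_safe]
  keep <- setdiff(names(data), unsafe)
  miss <- keep[vapply(data[keep], function(x) any(is.na(x)), TRUE)]
  dropped$missing <- miss
  keep <- setdiff(keep, miss)
  novar <- keep[vapply(data[keep], function(x) var(x) < 1e-12, TRUE)]
  if (length(novar)) warning("zero-variance column(s) dropped: ",
                             paste(novar, collapse = ", "))
  dropped$zero_variance <- novar
  keep <- setdiff(keep, novar)
  if (length(keep) < 2) stop("fewer than two usable features")
  meta <- meta[match(keep, meta$name), ]
  data <- data[keep]
  ord <- .column_priority(meta)
  cm <- abs(cor(as.matrix(data)))
  kept_idx <- integer(0)
  drop_col <- character(0)
  for (j in ord) {
    if (length(kept_idx) && any(cm[j, kept_idx] > collinearity_threshold)) {
      drop_col <- c(drop_col, meta$name[j])
    } else kept_idx <- c(kept_idx, j)
  }
  dropped$collinear <- drop_col
  keep <- meta$name[sort(kept_idx)]
  meta <- meta[match(keep, meta$name), ]
  data <- data[keep]
  if (scale) {
    for (nm in keep[meta$kind == "continuous"])
      data[[nm]] <- as.numeric(base::scale(data[[nm]]))
  }
  out <- cohort_table(data, meta, ct$outcomes)
  attr(out, "dropped") <- dropped
  out
}

#' Rank features on training data and return the top k
#'
#' Three selectors: `"MDA"` -- permutation importance (mean decrease in
#' accuracy) of a random forest; `"UST"` -- univariate statistical testing,
#' two-sample t-test for continuous and chi-squared for categorical columns,
#' ranked by ascending p-value; `"L1"` -- descending absolute coefficients
#' of an L1-penalized logistic fit (penalty relaxed on a small internal grid
#' if everything is shrunk to zero).
#'
#' @param x training feature data frame
#' @param y training 0/1 labels
#' @param meta feature metadata (for the column kinds)
#' @param selector `"UST"`, `"MDA"` or `"L1"`
#' @param k number of features to return (default 8)
#' @param seed integer seed for the stochastic selectors
#' @return character vector of selected names; the full ranking audit (name,
#'   score, method per feature) is in `attr(, "audit")`
#' @export
select_features <- function(x, y, meta, selector = c("UST", "MDA", "L1"),
                            k = 8, seed = 1L) {
  selector <- match.arg(selector)
  nm <- names(x)
  meta <- meta[match(nm, meta$name), ]
  if (k > length(nm)) {
    warning("k exceeds available features; returning all")
    k <- length(nm)
  }
  yf <- factor(y, levels = c(0, 1))
  if (selector == "UST") {
    p <- numeric(length(nm)); method <- character(length(nm))
    for (j in seq_along(nm)) {
      xx <- x[[j]]
      if (meta$kind[j] == "categorical") {
        method[j] <- "chisq"
        tb <- table(factor(xx), yf)
        p[j] <- if (min(dim(tb)) < 2) 1 else
          suppressWarnings(chisq.test(tb, correct = FALSE)$p.value)
      } else {
        method[j] <- "ttest"
        p[j] <- if (var(xx[y == 0]) + var(xx[y == 1]) < 1e-24) 1 else
          suppressWarnings(t.test(xx[y == 0], xx[y == 1])$p.value)
      }
      if (!is.finite(p[j])) p[j] <- 1
    }
    ordx <- order(p, nm)
    audit <- data.frame(name = nm, score = p, method = method)
  } else if (selector == "MDA") {
    set.seed(seed)
    rf <- randomForest::randomForest(x, yf, ntree = 300, importance = TRUE)
    imp <- randomForest::importance(rf, type = 1)[, 1]
    ordx <- order(-imp, nm)
    audit <- data.frame(name = nm, score = imp, method = "rf_mda")
  } else {
    lambdas <- c(0.05, 0.02, 0.01, 0.005, 0.001)
    co <- NULL
    for (lam in lambdas) {
      fit <- glmnet::glmnet(as.matrix(x), yf, family = "binomial",
                            alpha = 1, lambda = lam)
      co <- abs(as.numeric(coef(fit))[-1])
      if (any(co > 0)) break
    }
    ordx <- order(-co, nm)
    audit <- data.frame(name = nm, score = co, method = "l1_logistic")
  }
  out <- nm[ordx][seq_len(k)]
  attr(out, "audit") <- audit[ordx, ]
  out
}

# ---- classifiers ----------------------------------------------------------

.fit_classifier <- function(x, y, classifier, seed = 1L) {
  yf <- factor(y, levels = c(0, 1))
  if (classifier == "LR") {
    df <- cbind(x, .y = y)
    fit <- suppressWarnings(glm(.y ~ ., family = binomial(), data = df))
    list(kind = "LR", fit = fit)
  } else if (classifier == "LDA") {
    fit <- MASS::lda(as.matrix(x), grouping = yf)
    list(kind = "LDA", fit = fit)
  } else if (classifier == "SVM") {
    set.seed(seed)
    fit <- e1071::svm(as.matrix(x), yf, kernel = "linear", scale = FALSE)
    dv <- attr(predict(fit, as.matrix(x), decision.values = TRUE),
               "decision.values")[, 1]
    flip <- if (mean(dv[y == 1]) < mean(dv[y == 0])) -1 else 1
    list(kind = "SVM", fit = fit, flip = flip)
  } else if (classifier == "RF") {
    set.seed(seed)
    fit <- randomForest::randomForest(x, yf, ntree = 500)
    list(kind = "RF", fit = fit)
  } else stop("unknown classifier: ", classifier)
}

.score_classifier <- function(model, x) {
  switch(model$kind,
         LR = suppressWarnings(as.numeric(predict(model$fit, newdata = x,
                                                  type = "response"))),
         LDA = as.numeric(predict(model$fit, as.matrix(x))$posterior[, "1"]),
         SVM = {
           dv <- attr(predict(model$fit, as.matrix(x), decision.values = TRUE),
                      "decision.values")[, 1]
           # squash oriented decision values into (0, 1) score units
           1 / (1 + exp(-model$flip * dv))
         },
         RF = as.numeric(predict(model$fit, x, type = "prob")[, "1"]))
}

# stratified k-fold assignment
.stratified_folds <- function(y, nfolds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

#' Cross-validated evaluation of a response classifier
#'
#' Runs the full pipeline -- per-fold scaling, in-loop feature selection,
#' classifier fit, out-of-fold scoring -- under either Leave-One-Out CV
#' (scores pooled into a single ROC/AUC) or repeated stratified 5-fold CV
#' (AUC per fold, mean +/- SD over folds x repeats).  Binary metrics are
#' reported at the Youden-J-optimal cutoff of the pooled scores.
#'
#' @param ct a [cohort_table()]
#' @param criterion response criterion, see [label_response()]
#' @param classifier `"LR"`, `"LDA"`, `"SVM"` or `"RF"`
#' @param selector `"UST"`, `"MDA"` or `"L1"`
#' @param cv `"loo"` or `"kfold"`
#' @param k number of selected features (default 8)
#' @param nfolds folds for `"kfold"` (default 5)
#' @param n_repeats repeats for `"kfold"` (default 1000)
#' @param collinearity_threshold forwarded to [preprocess_cohort()]
#' @param seed master seed for all stochastic stages
#' @return a `cv_result`: pooled `scores`, `auc` (and `auc_sd`,
#'   `auc_per_fold` for kfold), `cutoff`, `confusion`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, per-feature
#'   `selection_freq`, and an `audit` list recording exactly which rows each
#'   scaler/selector/classifier fit saw
#' @export
evaluate_classifier <- function(ct, criterion = "EF10", classifier = "SVM",
                                selector = "UST", cv = c("loo", "kfold"),
                                k = 8, nfolds = 5, n_repeats = 1000,
                                collinearity_threshold = 0.85, seed = 1L) {
  cv <- match.arg(cv)
  classifier <- match.arg(classifier, c("LR", "LDA", "SVM", "RF"))
  y_all <- label_response(ct$outcomes, criterion)
  use <- which(!is.na(y_all))
  if (length(use) < nrow(ct$data))
    message(sprintf("%d patient(s) dropped for missing outcome", nrow(ct$data) - length(use)))
  ct_use <- cohort_table(ct$data[use, , drop = FALSE], ct$meta,
                         ct$outcomes[use, , drop = FALSE])
  pp <- preprocess_cohort(ct_use, collinearity_threshold, scale = FALSE)
  x <- pp$data; meta <- pp$meta
  y <- y_all[use]
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- length(y)
  cont <- meta$name[meta$kind == "continuous"]

  set.seed(seed)
  fold_sets <- list()
  if (cv == "loo") {
    fold_sets <- lapply(seq_len(n), function(i) list(test = i, repeat_id = 1L))
  } else {
    for (r in seq_len(n_repeats)) {
      fold <- .stratified_folds(y, nfolds)
      for (f in seq_len(nfolds))
        fold_sets[[length(fold_sets) + 1L]] <- list(test = which(fold == f),
                                                    repeat_id = r)
    }
  }

  pooled_row <- integer(0); pooled_score <- numeric(0); pooled_rep <- integer(0)
  auc_per_fold <- numeric(0)
  sel_tally <- setNames(numeric(ncol(x)), names(x))
  audit <- vector("list", length(fold_sets))
  for (fi in seq_along(fold_sets)) {
    test <- fold_sets[[fi]]$test
    train <- setdiff(seq_len(n), test)
    fseed <- seed + 7907L * fi
    xtr <- x[train, , drop = FALSE]
    xte <- x[test, , drop = FALSE]
    for (nmc in cont) {                   # scaler fit on training rows only
      mu <- mean(xtr[[nmc]]); sdv <- sd(xtr[[nmc]])
      if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
      xtr[[nmc]] <- (xtr[[nmc]] - mu) / sdv
      xte[[nmc]] <- (xte[[nmc]] - mu) / sdv
    }
    sel <- select_features(xtr, y[train], meta, selector, k = k, seed = fseed)
    sel_tally[sel] <- sel_tally[sel] + 1
    model <- .fit_classifier(xtr[sel], y[train], classifier, seed = fseed)
    sc <- .score_classifier(model, xte[sel])
    pooled_row <- c(pooled_row, test)
    pooled_score <- c(pooled_score, sc)
    pooled_rep <- c(pooled_rep, rep(fold_sets[[fi]]$repeat_id, length(test)))
    audit[[fi]] <- list(test_rows = test, scaler_rows = train,
                        selector_rows = train, fit_rows = train)
    if (cv == "kfold" && length(unique(y[test])) == 2) {
      r <- pROC::roc(y[test], sc, levels = c(0, 1), direction = "<", quiet = TRUE)
      auc_per_fold <- c(auc_per_fold, as.numeric(pROC::auc(r)))
    }
  }

  roc_all <- pROC::roc(y[pooled_row], pooled_score, levels = c(0, 1),
                       direction = "<", quiet = TRUE)
  auc_pooled <- as.numeric(pROC::auc(roc_all))
  cutoff <- pROC::coords(roc_all, "best", best.method = "youden",
                         ret = "threshold", transpose = FALSE)$threshold[1]
  if (!is.finite(cutoff)) cutoff <- 0.5
  pred <- as.integer(pooled_score >= cutoff)
  truth <- y[pooled_row]
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  structure(list(
    scores = data.frame(row = pooled_row, repeat_id = pooled_rep,
                        label = truth, score = pooled_score),
    auc = if (cv == "loo") auc_pooled else mean(auc_per_fold),
    auc_pooled = auc_pooled,
    auc_sd = if (cv == "loo") NA_real_ else sd(auc_per_fold),
    auc_per_fold = if (cv == "loo") NULL else auc_per_fold,
    cutoff = cutoff,
    confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                       dimnames = list(c("pred_resp", "pred_nonresp"),
                                       c("responder", "nonresponder"))),
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = tp / max(tp + fn, 1), specificity = tn / max(tn + fp, 1),
    ppv = tp / max(tp + fp, 1), npv = tn / max(tn + fn, 1),
    selection_freq = sel_tally / length(fold_sets),
    n = n, labels = y, audit = audit,
    config = list(criterion = criterion, classifier = classifier,
                  selector = selector, cv = cv, k = k, nfolds = nfolds,
                  n_repeats = n_repeats, seed = seed)
  ), class = "cv_result")
}

#' PCA + logistic regression over a range of component counts
#'
#' PCA is fitted inside the CV loop on the training rows only; a logistic
#' classifier runs on the component scores.
#'
#' @inheritParams evaluate_classifier
#' @param n_components vector of component counts to evaluate (capped at the
#'   feature rank with a warning)
#' @return data frame with `ncomp`, `auc` (pooled LOO), and mean cumulative
#'   `explained_variance` of the training-fold PCAs
#' @export
pca_lr <- function(ct, criterion = "EF10", n_components = 2:10, seed = 1L,
                   collinearity_threshold = 0.85) {
  y_all <- label_response(ct$outcomes, criterion)
  use <- which(!is.na(y_all))
  ct_use <- cohort_table(ct$data[use, , drop = FALSE], ct$meta,
                         ct$outcomes[use, , drop = FALSE])
  pp <- preprocess_cohort(ct_use, collinearity_threshold, scale = FALSE)
  x <- as.matrix(pp$data); y <- y_all[use]
  n <- nrow(x)
  maxrank <- min(n - 2L, ncol(x))
  if (any(n_components > maxrank)) {
    warning("n_components capped at the feature rank")
    n_components <- unique(pmin(n_components, maxrank))
  }
  out <- data.frame(ncomp = n_components, auc = NA_real_,
                    explained_variance = NA_real_)
  set.seed(seed)
  for (ci in seq_along(n_components)) {
    nc <- n_components[ci]
    scores <- numeric(n); expl <- numeric(n)
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      pc <- prcomp(x[tr, , drop = FALSE], center = TRUE, scale. = TRUE)
      ztr <- pc$x[, seq_len(nc), drop = FALSE]
      zte <- predict(pc, x[i, , drop = FALSE])[, seq_len(nc), drop = FALSE]
      df <- data.frame(ztr, .y = y[tr])
      fit <- suppressWarnings(glm(.y ~ ., family = binomial(), data = df))
      scores[i] <- suppressWarnings(predict(fit, newdata = data.frame(zte),
                                            type = "response"))
      expl[i] <- sum(pc$sdev[seq_len(nc)]^2) / sum(pc$sdev^2)
    }
    r <- pROC::roc(y, scores, levels = c(0, 1), direction = "<", quiet = TRUE)
    out$auc[ci] <- as.numeric(pROC::auc(r))
    out$explained_variance[ci] <- mean(expl)
  }
  out
}

#' K-means clustering on the first two principal components
#'
#' Unsupervised stratification: k-means (best of 10 restarts) on the first
#' two PC scores of the preprocessed feature matrix, with per-cluster mean
#' outcomes and label composition.
#'
#' @inheritParams evaluate_classifier
#' @param n_clusters number of clusters (default 2)
#' @return list with `cluster` assignments, `centers`, `outcome_summary`
#'   (per-cluster mean delta EF / delta ESV and responder counts under the
#'   criterion), and the `pca` explained-variance fractions
#' @export
kmeans_clusters <- function(ct, criterion = "EF10", n_clusters = 2, seed = 1L,
                            collinearity_threshold = 0.85) {
  y_all <- label_response(ct$outcomes, criterion)
  use <- which(!is.na(y_all))
  ct_use <- cohort_table(ct$data[use, , drop = FALSE], ct$meta,
                         ct$outcomes[use, , drop = FALSE])
  pp <- preprocess_cohort(ct_use, collinearity_threshold, scale = FALSE)
  x <- as.matrix(pp$data)
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  z <- pc$x[, 1:2, drop = FALSE]
  set.seed(seed)
  km <- kmeans(z, centers = n_clusters, nstart = 10)
  oc <- ct_use$outcomes
  summ <- do.call(rbind, lapply(seq_len(n_clusters), function(cl) {
    sel <- km$cluster == cl
    data.frame(cluster = cl, n = sum(sel),
               mean_delta_ef = mean(oc$delta_ef[sel], na.rm = TRUE),
               mean_delta_esv = mean(oc$delta_esv[sel], na.rm = TRUE),
               responders = sum(y_all[use][sel] == 1))
  }))
  list(cluster = km$cluster, centers = km$centers, outcome_summary = summ,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s/%s/%s, %s]: AUC %.3f%s, acc %.2f, sens %.2f, spec %.2f (cutoff %.2f)\n",
              x$config$criterion, x$config$classifier, x$config$selector,
              x$config$cv, x$auc,
              if (is.na(x$auc_sd)) "" else sprintf(" +/- %.3f", x$auc_sd),
              x$accuracy, x$sensitivity, x$specificity, x$cutoff))
  invisible(x)
}
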