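# Multivariate prediction of severe TR from the seven valve measurements:
# stratified train/test split, LASSO-penalized logistic regression with a
# best-n-predictor budget, ROC/AUC and Eq.-style confusion metrics at the
# balanced (Youden) threshold, precision-recall curves, and per-feature
# Student's t comparisons.

#' The seven valve-geometry feature names
#'
#' Column names of the predictors used throughout the prediction module.
#' @return Character vector of length 7.
#' @export
tv_feature_names <- function() {
  c("d_ap", "d_sl", "phi_bend", "h_sept", "h_ant", "h_post", "delta_area")
}

#' Area under the ROC curve
#'
#' Trapezoid-rule AUC of scores against binary labels (the c statistic).
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels 0/1 outcomes.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  sw <- roc_sweep(scores, labels)
  sum(diff(sw$fpr) * (utils::head(sw$tpr, -1) + sw$tpr[-1]) / 2)
}

#' Stratified train/test split of a cohort table
#'
#' @param table Cohort data frame containing a 0/1 severity column.
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed RNG seed; the split is reproducible.
#' @param label_col Name of the 0/1 severity column.
#' @return List with `train`, `test` (data frames) and `assignment`
#'   (character vector "train"/"test" aligned with `table` rows).
#' @export
split_cohort <- function(table, train_fraction = 0.7, seed = 1L,
                         label_col = "tr_severe") {
  if (!label_col %in% names(table))
    stop("cohort table is missing the severity column '", label_col, "'")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  y <- table[[label_col]]
  if (length(unique(y)) < 2)
    stop("both severity classes must be present to split the cohort")
  assignment <- rep("test", nrow(table))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_tr <- round(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      assignment[sample(idx, n_tr)] <- "train"
    }
  })
  list(train = table[assignment == "train", , drop = FALSE],
       test = table[assignment == "test", , drop = FALSE],
       assignment = assignment)
}

#' Fit a LASSO logistic model under a best-n-predictor budget
#'
#' Features are standardized to zero mean and unit variance on the
#' training rows; the L1 penalty path is walked from the strongest
#' penalty, and the model at the smallest penalty whose nonzero
#' coefficient count stays within `max_nonzero` is returned. Penalized
#' coefficients are reported as-is (no post-selection refit), in both
#' standardized and raw-scale form.
#'
#' @param train Training data frame.
#' @param features Predictor column names (default the seven valve
#'   parameters).
#' @param label_col Name of the 0/1 severity column.
#' @param penalty_path Decreasing vector of penalty values; `NULL` lets
#'   the underlying path solver lay out 100 log-spaced values.
#' @param max_nonzero Predictor budget n (nonzero coefficients allowed).
#' @return An object of class `tv_predictor` with standardized and
#'   raw-scale coefficients, the selected penalty, and the training
#'   standardization statistics.
#' @export
fit_lasso_logistic <- function(train, features = tv_feature_names(),
                               label_col = "tr_severe",
                               penalty_path = NULL, max_nonzero = 7L) {
  missing <- setdiff(c(features, label_col), names(train))
  if (length(missing))
    stop("training table is missing columns: ", paste(missing, collapse = ", "))
  X <- as.matrix(train[, features, drop = FALSE])
  y <- train[[label_col]]
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl < 1e-12))
    stop("feature(s) constant on the training set: ",
         paste(features[scl < 1e-12], collapse = ", "))
  Z <- scale(X, center = ctr, scale = scl)
  fit <- if (is.null(penalty_path)) {
    glmnet::glmnet(Z, y, family = "binomial", alpha = 1,
                   standardize = FALSE, nlambda = 100,
                   thresh = 1e-10)
  } else {
    if (is.unsorted(rev(penalty_path)))
      stop("penalty_path must be decreasing")
    glmnet::glmnet(Z, y, family = "binomial", alpha = 1,
                   standardize = FALSE, lambda = penalty_path,
                   thresh = 1e-10)
  }
  df <- fit$df
  ok <- which(df <= max_nonzero)
  if (!length(ok)) {
    warning("no penalty on the path satisfies the budget; ",
            "returning the sparsest model found")
    ok <- which.min(df)
  }
  sel <- ok[which.min(fit$lambda[ok])]
  beta_std <- as.vector(fit$beta[, sel])
  names(beta_std) <- features
  b0_std <- fit$a0[sel]
  beta_raw <- beta_std / scl
  b0_raw <- b0_std - sum(beta_std * ctr / scl)
  structure(list(intercept = unname(b0_std), coef = beta_std,
                 intercept_raw = unname(b0_raw), coef_raw = beta_raw,
                 penalty = fit$lambda[sel], df = df[sel],
                 max_nonzero = as.integer(max_nonzero),
                 features = features, label_col = label_col,
                 center = ctr, scale = scl),
            class = "tv_predictor")
}

#' @export
print.tv_predictor <- function(x, ...) {
  cat(sprintf("LASSO logistic TR predictor (budget %d, penalty %.4g, %d nonzero)\n",
              x$max_nonzero, x$penalty, x$df))
  co <- rbind(standardized = c(`(intercept)` = x$intercept, x$coef),
              raw = c(`(intercept)` = x$intercept_raw, x$coef_raw))
  print(round(t(co), 4))
  invisible(x)
}

#' Predicted probability of severe TR
#'
#' @param object A [fit_lasso_logistic()] model.
#' @param newdata Data frame with the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.tv_predictor <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  stats::plogis(object$intercept_raw + drop(X %*% object$coef_raw))
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)` and
#' precision `PREC = TP/(TP+FP)`.
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return Named numeric vector `c(sn, sp, prec)`.
#' @export
#' @examples
#' performance_metrics(3, 1, 1, 5)
performance_metrics <- function(tp, fp, fn, tn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn); tn <- unname(tn)
  if (any(c(tp, fp, fn, tn) < 0)) stop("confusion counts must be >= 0")
  c(sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    prec = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

# ROC / precision-recall sweep over all score thresholds (descending).
# Positive prediction: score >= threshold.
roc_sweep <- function(scores, y) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  P <- sum(y == 1); N <- sum(y == 0)
  tp <- cumsum(yy == 1); fp <- cumsum(yy == 0)
  # collapse ties: keep last index of each distinct score
  keep <- c(diff(s) != 0, TRUE)
  thr <- s[keep]; tp <- tp[keep]; fp <- fp[keep]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  prec <- c(1, ifelse(tp + fp > 0, tp / (tp + fp), 1))
  data.frame(threshold = c(Inf, thr), tpr = tpr, fpr = fpr,
             precision = prec)
}

#' Evaluate a TR predictor on a test set
#'
#' Builds the ROC curve from the predicted probabilities, computes the c
#' statistic (area under the ROC curve, trapezoid rule), picks the
#' threshold balancing the true- and false-positive rates (maximizing
#' Youden's J = TPR - FPR, ties broken toward the higher threshold),
#' reports sensitivity/specificity/precision at that threshold, and the
#' precision-recall curve over the same thresholds.
#'
#' @param model A [fit_lasso_logistic()] model.
#' @param test Test data frame with feature and severity columns.
#' @return An object of class `model_eval`: `auc`, `sn`, `sp`, `prec`,
#'   `threshold`, `counts` (TP/FP/FN/TN), `roc` and `pr` data frames.
#' @export
evaluate_model <- function(model, test) {
  y <- test[[model$label_col]]
  if (length(y) == 0) stop("test set is empty")
  if (length(unique(y)) < 2)
    stop("test set must contain both severity classes")
  scores <- predict(model, test)
  sw <- roc_sweep(scores, y)
  auc <- roc_auc(scores, y)
  j <- sw$tpr - sw$fpr
  best <- which.max(j)  # first maximum in descending-threshold order
  thr <- sw$threshold[best]
  pred <- as.integer(scores >= thr)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  pm <- performance_metrics(tp, fp, fn, tn)
  structure(list(auc = auc, sn = unname(pm["sn"]), sp = unname(pm["sp"]),
                 prec = unname(pm["prec"]), threshold = thr,
                 counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 roc = sw[, c("threshold", "fpr", "tpr")],
                 pr = data.frame(threshold = sw$threshold,
                                 recall = sw$tpr, precision = sw$precision)),
            class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf(paste0("Model evaluation: AUC %.3f; at threshold %.3g: ",
                     "SN %.3f, SP %.3f, PREC %.3f\n",
                     "  confusion: TP %d, FP %d, FN %d, TN %d\n"),
              x$auc, x$threshold, x$sn, x$sp, x$prec,
              x$counts["tp"], x$counts["fp"], x$counts["fn"], x$counts["tn"]))
  invisible(x)
}

#' Per-feature Student's t comparison between severity groups
#'
#' Two-sample pooled-variance (Student's) t-test of each measurement
#' between the severe and non-severe groups, with two-sided p-values.
#' No multiple-testing adjustment is applied by default.
#'
#' @param table Cohort data frame with feature and severity columns.
#' @param features Feature column names.
#' @param label_col Name of the 0/1 severity column.
#' @param adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"holm"`); `"none"` leaves raw p-values.
#' @return Data frame with one row per feature: `t`, `df`, `p`,
#'   `mean_severe`, `mean_nonsevere`.
#' @export
compare_features <- function(table, features = tv_feature_names(),
                             label_col = "tr_severe", adjust = "none") {
  y <- table[[label_col]]
  g1 <- table[y == 1, , drop = FALSE]
  g0 <- table[y == 0, , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g0) < 2)
    stop("both severity groups need at least 2 members")
  res <- lapply(features, function(f) {
    a <- g1[[f]]; b <- g0[[f]]
    pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    if (pooled_var < 1e-24) {
      # zero within-group variance: degenerate limit of the t statistic
      d <- mean(a) - mean(b)
      tt <- if (abs(d) < 1e-24) 0 else sign(d) * Inf
      p <- if (abs(d) < 1e-24) 1 else 0
      data.frame(feature = f, t = tt, df = length(a) + length(b) - 2, p = p,
                 mean_severe = mean(a), mean_nonsevere = mean(b))
    } else {
      ht <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(feature = f, t = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 mean_severe = mean(a), mean_nonsevere = mean(b))
    }
  })
  out <- do.call(rbind, res)
  out$p <- stats::p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}
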