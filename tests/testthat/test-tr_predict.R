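# LASSO predictor selection, ROC/confusion evaluation and t comparisons.

make_table <- function(n = 100, n_severe = 20, seed = 5) {
  set.seed(seed)
  df <- as.data.frame(matrix(rnorm(n * 7), n,
                             dimnames = list(NULL, tv_feature_names())))
  df$tr_severe <- c(rep(1L, n_severe), rep(0L, n - n_severe))
  df
}

test_that("the 70/30 split is stratified and reproducible", {
  tab <- make_table(100, 20)
  sp <- split_cohort(tab, 0.7, seed = 3)
  expect_equal(sum(sp$train$tr_severe == 1), 14)
  expect_equal(sum(sp$train$tr_severe == 0), 56)
  expect_equal(nrow(sp$test), 30)
  sp2 <- split_cohort(tab, 0.7, seed = 3)
  expect_identical(sp$assignment, sp2$assignment)
  tab$tr_severe <- 1L
  expect_error(split_cohort(tab, 0.7, seed = 3), "both severity classes")
  expect_error(split_cohort(make_table(), 1.2), "train_fraction")
})

test_that("full shrinkage leaves only the train log-odds intercept", {
  tab <- make_table(200, 60)
  model <- fit_lasso_logistic(tab, max_nonzero = 0)
  expect_equal(unname(model$df), 0)
  expect_true(all(model$coef == 0))
  expect_equal(model$intercept, qlogis(0.3), tolerance = 1e-6)
})

test_that("the unpenalized limit matches the maximum-likelihood oracle", {
  set.seed(11)
  df <- logistic_cohort(300, beta = c(1, -0.5, 0.25))
  feats <- tv_feature_names()[1:3]
  model <- fit_lasso_logistic(df, features = feats,
                              penalty_path = c(0.5, 0.1, 0.01, 0),
                              max_nonzero = 3)
  oracle <- glm(reformulate(feats, "tr_severe"), binomial, df)
  expect_equal(model$intercept_raw, unname(coef(oracle)[1]), tolerance = 1e-4)
  expect_equal(unname(model$coef_raw),
               unname(coef(oracle)[-1]), tolerance = 1e-4)
})

test_that("active predictors are recovered with correct signs", {
  for (rep in 1:20) {
    df <- logistic_cohort(2000, beta = c(1.5, -1.5, 0, 0, 0, 0, 0),
                          seed = 100 + rep)
    model <- fit_lasso_logistic(df, max_nonzero = 3)
    expect_gt(model$coef["d_ap"], 0)
    expect_lt(model$coef["d_sl"], 0)
    expect_lte(sum(model$coef != 0), 3)
  }
})

test_that("the nonzero-coefficient budget is respected along the path", {
  tab <- make_table(200, 60)
  for (b in c(1, 3, 5, 7)) {
    model <- fit_lasso_logistic(tab, max_nonzero = b)
    expect_lte(sum(model$coef != 0), b)
  }
})

test_that("confusion metrics follow their definitions exactly", {
  pm <- performance_metrics(3, 1, 1, 5)
  expect_equal(unname(pm["sn"]), 0.75)
  expect_equal(unname(pm["sp"]), 5 / 6)
  expect_equal(unname(pm["prec"]), 0.75)
  expect_error(performance_metrics(-1, 0, 0, 0), ">= 0")
})

test_that("separable scores give perfect discrimination", {
  tab <- make_table(40, 10, seed = 9)
  tab$d_ap <- ifelse(tab$tr_severe == 1, 5 + rnorm(40, sd = 0.1),
                     -5 + rnorm(40, sd = 0.1))
  model <- fit_lasso_logistic(tab, max_nonzero = 7,
                              penalty_path = c(0.5, 0.05, 0.005))
  ev <- evaluate_model(model, tab)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$sn, 1.0)
  expect_equal(ev$sp, 1.0)
  expect_equal(ev$prec, 1.0)
  expect_equal(sum(ev$counts), nrow(tab))
})

test_that("reversing scores mirrors the AUC", {
  set.seed(21)
  y <- rbinom(60, 1, 0.4)
  s <- rnorm(60) + y
  expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1, tolerance = 1e-12)
})

test_that("trapezoid AUC equals the normalized Mann-Whitney statistic", {
  set.seed(33)
  for (case in 1:100) {
    n1 <- sample(3:20, 1); n0 <- sample(3:20, 1)
    y <- c(rep(1, n1), rep(0, n0))
    s <- c(rnorm(n1, mean = runif(1, 0, 2)), rnorm(n0))
    if (sample(c(TRUE, FALSE), 1)) s <- round(s, 1)  # force ties
    u <- wilcox.test(s[y == 1], s[y == 0], exact = FALSE)$statistic
    expect_equal(roc_auc(s, y), unname(u) / (n1 * n0), tolerance = 1e-10,
                 info = paste("case", case))
  }
})

test_that("evaluation metrics are recomputable from the confusion counts", {
  set.seed(4)
  df <- logistic_cohort(150, beta = c(1, -1, 0.5))
  model <- fit_lasso_logistic(df, features = tv_feature_names()[1:3],
                              max_nonzero = 3)
  ev <- evaluate_model(model, df)
  pm <- performance_metrics(ev$counts["tp"], ev$counts["fp"],
                            ev$counts["fn"], ev$counts["tn"])
  expect_equal(ev$sn, unname(pm["sn"]))
  expect_equal(ev$sp, unname(pm["sp"]))
  expect_equal(ev$prec, unname(pm["prec"]))
  # Youden threshold maximizes TPR - FPR over the ROC sweep
  j <- ev$roc$tpr - ev$roc$fpr
  expect_equal(max(j), ev$sn - (1 - ev$sp), tolerance = 1e-12)
})

test_that("Student's t comparisons match the closed form", {
  tab <- data.frame(d_ap = c(1, 2, 3, 2, 3, 4),
                    tr_severe = c(1, 1, 1, 0, 0, 0))
  res <- compare_features(tab, features = "d_ap")
  expect_equal(res$t, -sqrt(3 / 2), tolerance = 1e-4)
  expect_equal(res$df, 4)

  # identical groups: no effect
  tab2 <- data.frame(d_ap = rep(c(1, 2, 3), 2),
                     tr_severe = rep(c(1, 0), each = 3))
  res2 <- compare_features(tab2, features = "d_ap")
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)

  # zero within-group variance with distinct means: divide-safe limit
  tab3 <- data.frame(d_ap = rep(c(1, 2), each = 3),
                     tr_severe = rep(c(1, 0), each = 3))
  res3 <- compare_features(tab3, features = "d_ap")
  expect_equal(res3$p, 0)
  expect_true(is.infinite(res3$t) && res3$t < 0)

  expect_error(compare_features(data.frame(d_ap = 1:3,
                                           tr_severe = c(1, 0, 0)),
                                features = "d_ap"), "at least 2")
})
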