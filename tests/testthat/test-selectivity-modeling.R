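test_that("catalyst-out splits hold out whole catalysts, pins included", {
  records <- make_trial_dataset(n_catalysts = 50, n_reactions = 4, seed = 1)
  split <- make_catalyst_split(records, n_random = 9, pinned = "pep007",
                               seed = 3)
  test_l <- split$catalyst_label[split$role == "test"]
  train_l <- split$catalyst_label[split$role == "train"]
  expect_equal(length(test_l), 10)
  expect_equal(length(train_l), 40)
  expect_true("pep007" %in% test_l)
  expect_length(intersect(test_l, train_l), 0)
  # determinism, degenerate split, bad pin
  split2 <- make_catalyst_split(records, 9, "pep007", seed = 3)
  expect_identical(split, split2)
  all_train <- make_catalyst_split(records, 0, character(0), seed = 1)
  expect_true(all(all_train$role == "train"))
  expect_error(make_catalyst_split(records, 9, "nope"), "nope")
  expect_error(make_catalyst_split(records, 60), "exceeds")
})

test_that("model data carries free-energy targets and reaction indicators", {
  records <- make_trial_dataset(n_catalysts = 8, n_reactions = 4, seed = 2)
  x <- simulate_feature_space(sprintf("pep%03d", 1:8), 5, seed = 1)
  d_ee <- prepare_model_data(records, x, target = "ee")
  expect_equal(d_ee$ddg, ee_to_ddg(records$ee, records$temperature))
  d_dr <- prepare_model_data(records, x, target = "dr")
  expect_equal(d_dr$ddg,
               dr_to_ddg(records$dr_syn, records$dr_anti, records$temperature))
  fc <- attr(d_ee, "feature_cols")
  expect_length(fc, 5 + 3) # 5 components + 3 reaction indicators
  expect_true(all(c("rxn_rxn2", "rxn_rxn3", "rxn_rxn4") %in% fc))
  expect_error(prepare_model_data(records, x[1:3, ], "ee"), "pep004")
})

test_that("PLS recovers noiseless linear maps and the univariate least-squares fit", {
  withr::with_seed(4, {
    x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  })
  y <- 2.5 * x[, 3]
  # noiseless linear map in a single feature: 1 component suffices
  fit1 <- pls_nipals(x[, 3, drop = FALSE], y, ncomp = 1)
  expect_lt(mean(abs(predict(fit1, x[, 3, drop = FALSE]) - y)), 1e-8)
  # with correlated extra columns, the full component ladder recovers it
  fit <- pls_nipals(x, y, ncomp = 6)
  expect_lt(mean(abs(predict(fit, x) - y)), 1e-8)
  # single-feature PLS equals ordinary least squares
  x1 <- x[, 3, drop = FALSE]
  y2 <- 1.3 * x1[, 1] + withr::with_seed(5, rnorm(40, sd = 0.2))
  p_pls <- predict(pls_nipals(x1, y2, 1), x1)
  p_lm <- unname(predict(lm(y2 ~ x1)))
  expect_lt(max(abs(p_pls - p_lm)), 1e-8)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  withr::with_seed(11, {
    x <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("f", 1:8)))
    y <- x %*% rnorm(8) + rnorm(60, sd = 0.3)
  })
  ours <- predict(pls_nipals(x, as.numeric(y), 3), x)
  ref <- suppressMessages({
    fit <- mixOmics::pls(x, as.numeric(y), ncomp = 3, mode = "regression")
    as.numeric(predict(fit, x)$predict[, 1, 3])
  })
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("the fitted model recovers generating weights within the noise floor", {
  bench <- benchmark_pls_recovery(n_seeds = 5, n = 120, n_components = 10,
                                  noise_frac = 0.10, seed = 7)
  expect_true(all(bench$test_mae >= 0.5 * bench$noise_sd))
  expect_true(all(bench$test_mae <= 1.5 * bench$noise_sd))
  expect_true(all(bench$cosine > 0.9))
})

test_that("evaluation reports exact MAEs and refuses leakage", {
  records <- make_trial_dataset(n_catalysts = 20, n_reactions = 2, seed = 6)
  x <- simulate_feature_space(sprintf("pep%03d", 1:20), 6, seed = 2)
  data <- prepare_model_data(records, x, "ee")
  split <- make_catalyst_split(records, n_random = 4, seed = 8)
  train <- data[data$catalyst_label %in%
                  split$catalyst_label[split$role == "train"], ]
  attr(train, "feature_cols") <- attr(data, "feature_cols")
  fit <- fit_pls(train, ncomp = 3)
  report <- evaluate_model(fit, data, split)
  expect_s3_class(report, "model_report")
  m <- glance(report)
  expect_gte(m$mae_test, 0)
  # degenerate 0-component-like predictor: a model predicting the constant
  # training mean must report MAE equal to the direct mean-absolute-deviation
  # formula; and predictions equal to observations give MAE 0
  rep2 <- report
  rep2$predictions$predicted <- mean(train$ddg)
  mae_const <- mean(abs(mean(train$ddg) - data$ddg))
  expect_equal(mean(abs(rep2$predictions$predicted - rep2$predictions$observed)),
               mae_const)
  rep3 <- report
  rep3$predictions$predicted <- rep3$predictions$observed
  expect_equal(mean(abs(rep3$predictions$predicted - rep3$predictions$observed)), 0)
  # leakage: fitting on everything then claiming the same split errors
  full_fit <- fit_pls(data, ncomp = 3)
  expect_error(evaluate_model(full_fit, data, split), "leakage")
})

test_that("shuffled targets destroy out-of-sample accuracy", {
  withr::with_seed(13, {
    x <- simulate_feature_space(60, 8, seed = 31)
    w <- rnorm(8)
  })
  spec <- landscape_spec(w, noise_sd = 0.05, seed = 14)
  rec <- simulate_selectivity(x, spec)
  rec$reaction_id <- "rxn1"
  data <- prepare_model_data(rec, x, "ee")
  split <- make_catalyst_split(rec, n_random = 12, seed = 15)
  tr <- data$catalyst_label %in% split$catalyst_label[split$role == "train"]
  train <- data[tr, ]; attr(train, "feature_cols") <- attr(data, "feature_cols")
  fit_true <- fit_pls(train, ncomp = 5)
  mae_true <- mean(abs(predict(fit_true, data[!tr, ]) - data$ddg[!tr]))
  shuf <- train
  shuf$ddg <- withr::with_seed(16, sample(shuf$ddg))
  fit_shuf <- fit_pls(shuf, ncomp = 5)
  mae_shuf <- mean(abs(predict(fit_shuf, data[!tr, ]) - data$ddg[!tr]))
  expect_gt(mae_shuf, 3 * mae_true)
})

test_that("cross-validated component selection stays within the cap", {
  rec <- make_trial_dataset(n_catalysts = 15, n_reactions = 2, seed = 9)
  x <- simulate_feature_space(sprintf("pep%03d", 1:15), 6, seed = 3)
  data <- prepare_model_data(rec, x, "ee")
  fit <- fit_pls(data, ncomp = NULL, max_ncomp = 4)
  expect_lte(fit$model$ncomp, 4)
  expect_s3_class(fit$cv, "tbl_df")
  expect_equal(fit$cv$ncomp, 1:4)
})
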