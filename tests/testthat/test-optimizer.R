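linear_zoo_data <- function(n = 60, d = 4, noise = 0, seed = 1) {
  x <- simulate_feature_space(n, d, seed = seed)
  w <- withr::with_seed(seed + 1, rnorm(d))
  y <- as.numeric(x %*% w) +
    withr::with_seed(seed + 2, rnorm(n, sd = noise))
  list(x = x, y = y, w = w)
}

test_that("every interpolating family nails an easy noiseless linear target", {
  d <- linear_zoo_data(n = 80, d = 3, noise = 0, seed = 2)
  zoo <- fit_model_zoo(d$x, d$y, families = c("pls", "kernel", "nnet"),
                       seed = 5)
  expect_true(all(zoo$cv_scores$cv_mae < 0.05))
  # tree ensembles cannot interpolate a continuous linear map exactly but
  # must still track it closely relative to the response scale
  zoo_f <- fit_model_zoo(d$x, d$y, families = "forest", seed = 5)
  expect_lt(zoo_f$cv_scores$cv_mae, 0.5 * sd(d$y))
})

test_that("zoo fits are deterministic under a fixed seed", {
  d <- linear_zoo_data(n = 40, d = 3, noise = 0.1, seed = 3)
  z1 <- fit_model_zoo(d$x, d$y, families = c("pls", "forest", "nnet"), seed = 7)
  z2 <- fit_model_zoo(d$x, d$y, families = c("pls", "forest", "nnet"), seed = 7)
  expect_identical(z1$cv_scores, z2$cv_scores)
  expect_error(fit_model_zoo(d$x[1:10, ], d$y[1:10]), "20")
  expect_error(fit_model_zoo(d$x, d$y, families = "quantum"), "quantum")
})

test_that("CV family ranking agrees with an independent held-out evaluation", {
  # nonlinear landscape: the interaction term separates family skill
  x <- simulate_feature_space(150, 3, seed = 9)
  y <- as.numeric(0.3 * x[, 1] + x[, 2] * x[, 3]) +
    withr::with_seed(10, rnorm(150, sd = 0.05))
  tr <- 1:100
  zoo <- fit_model_zoo(x[tr, ], y[tr], families = c("pls", "forest"), seed = 4)
  cv_best <- zoo$cv_scores$family[which.min(zoo$cv_scores$cv_mae)]
  # oracle: refit each family independently and score on the held-out rows
  hold_mae <- sapply(c("pls", "forest"), function(fam) {
    z <- fit_model_zoo(x[tr, ], y[tr], families = fam, seed = 4)
    preds <- pepcatml:::zoo_member_predictions(z, x[-tr, ])
    mean(abs(rowMeans(preds) - y[-tr]))
  })
  expect_equal(cv_best, names(which.min(hold_mae)))
})

test_that("prediction certainty is the population SD of member predictions", {
  fake_zoo <- structure(list(
    members = list(a = function(x) rep(1.0, nrow(x)),
                   b = function(x) rep(1.5, nrow(x))),
    feature_names = c("f1", "f2")
  ), class = "model_zoo")
  x <- matrix(0, 3, 2, dimnames = list(NULL, c("f1", "f2")))
  # two members predicting x and x + d: certainty d/2
  expect_equal(prediction_certainty(fake_zoo, x), rep(0.25, 3))
  unanimous <- fake_zoo
  unanimous$members$b <- unanimous$members$a
  expect_equal(prediction_certainty(unanimous, x), rep(0, 3))
  single <- fake_zoo
  single$members <- single$members[1]
  expect_error(prediction_certainty(single, x), "greedy")
})

test_that("far-from-training candidates carry higher certainty scores", {
  d <- linear_zoo_data(n = 60, d = 4, noise = 0.05, seed = 6)
  y_nl <- d$y + 0.5 * d$x[, 1] * d$x[, 2]
  zoo <- fit_model_zoo(d$x, y_nl, families = c("pls", "forest"), seed = 8)
  near <- simulate_feature_space(40, 4, seed = 20)
  far <- simulate_feature_space(40, 4, seed = 21) + 3
  expect_gt(median(prediction_certainty(zoo, far)),
            median(prediction_certainty(zoo, near)))
})

test_that("ranking is a filter-then-sort over unmeasured candidates", {
  d <- linear_zoo_data(n = 100, d = 3, noise = 0.02, seed = 12)
  zoo <- fit_model_zoo(d$x, d$y, families = c("pls", "kernel"), seed = 2)
  measured <- rownames(d$x)[1:10]
  ranked <- rank_candidates(zoo, d$x, measured = measured, mode = "greedy")
  expect_length(intersect(ranked$label, measured), 0)
  expect_true(all(diff(abs(ranked$predicted_ddg)) <= 1e-12))
  expect_true(all(abs(ranked$predicted_ee) < 1))
  # greedy top pick on a near-exact model is the true landscape argmax
  truth <- abs(as.numeric(d$x %*% d$w))
  names(truth) <- rownames(d$x)
  truth[measured] <- -Inf
  expect_equal(ranked$label[1], names(which.max(truth)))
  # certainty mode equals the brute-force filter-then-sort oracle
  rc <- rank_candidates(zoo, d$x, measured = measured, mode = "certainty",
                        certainty_quantile = 0.5)
  all_scores <- rank_candidates(zoo, d$x, measured = measured, mode = "greedy")
  cutoff <- quantile(all_scores$certainty, 0.5)
  oracle <- all_scores[all_scores$certainty < cutoff, ]
  oracle <- oracle[order(-abs(oracle$predicted_ddg), oracle$label), ]
  expect_equal(utils::head(rc$label, 10), utils::head(oracle$label, 10))
  # degenerate quantile filters everything out
  expect_error(rank_candidates(zoo, d$x, measured = measured,
                               mode = "certainty", certainty_quantile = 0),
               "quantile")
})

test_that("campaigns never repeat picks, keep a monotone best trace, and replay identically", {
  d <- linear_zoo_data(n = 80, d = 4, noise = 0, seed = 30)
  measure <- function(labels) {
    tibble::tibble(catalyst_label = labels,
                   ddg = d$y[match(labels, rownames(d$x))])
  }
  initial <- measure(rownames(d$x)[1:25])
  plans <- lapply(1:3, function(r) list(families = c("pls", "forest"),
                                        mode = "certainty",
                                        certainty_quantile = 0.8))
  s1 <- run_campaign(d$x, initial, measure, rounds = 3, batch_size = 4,
                     round_plans = plans, seed = 11)
  expect_equal(nrow(s1$records), 25 + 12)
  expect_false(anyDuplicated(s1$records$catalyst_label) > 0)
  expect_true(all(diff(s1$best_trace$best_abs_ddg) >= 0))
  expect_true(all(diff(s1$best_trace$best_abs_ee) >= 0))
  s2 <- run_campaign(d$x, initial, measure, rounds = 3, batch_size = 4,
                     round_plans = plans, seed = 11)
  expect_identical(s1$records, s2$records)
  # batch size 0 leaves the state unchanged round after round
  s0 <- run_campaign(d$x, initial, measure, rounds = 3, batch_size = 0,
                     round_plans = plans, seed = 11)
  expect_equal(nrow(s0$records), 25)
  # a measurement table missing a selected label is an error
  short_tbl <- initial
  expect_error(run_campaign(d$x, initial, short_tbl, rounds = 1,
                            batch_size = 2, round_plans = plans, seed = 1),
               "missing")
})
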