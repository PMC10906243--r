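# Simulation benchmarks shared by the test suite, the acceptance script and
# the vignette: PLS parameter recovery on the synthetic landscape, planted-
# optimum recovery by the iterative campaign, and the greedy-versus-certainty
# selection comparison on an extrapolation benchmark.

#' PLS parameter-recovery benchmark
#'
#' For each seed: simulate a UTS-sized library (`n` catalysts, `n_components`
#' reduced dimensions) with a latent-linear DDG landscape and Gaussian noise
#' whose SD is `noise_frac` of the noiseless signal SD, fit PLS on a random
#' 80% of catalysts, and record the held-out MAE, the noise SD, and the
#' cosine between the fitted coefficient vector and the generating weights.
#'
#' @param n_seeds Number of replicate seeds (default 20).
#' @param n Library size per replicate (default 169, a 13-exemplar UTS).
#' @param n_components Reduced-space dimensionality (default 20).
#' @param noise_frac Noise SD as a fraction of signal SD (default 0.10).
#' @param seed Base seed.
#' @return A tibble with one row per replicate: `test_mae`, `noise_sd`,
#'   `cosine`.
#' @export
benchmark_pls_recovery <- function(n_seeds = 20, n = 169, n_components = 20,
                                   noise_frac = 0.10, seed = 1) {
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    si <- seed + i
    # weights scaled so the noiseless DDG SD is ~1 kcal/mol (a realistic
    # screening spread, |ee| mostly below 0.99)
    w <- withr::with_seed(si * 7919,
                          stats::rnorm(n_components) / sqrt(n_components))
    x <- simulate_feature_space(n, n_components, seed = si)
    signal_sd <- stats::sd(as.numeric(x %*% w))
    spec <- landscape_spec(w, noise_sd = noise_frac * signal_sd, seed = si + 1)
    rec <- simulate_selectivity(x, spec)
    rec$reaction_id <- "rxn1"
    rec$temperature <- spec$temperature
    data <- prepare_model_data(rec, x, target = "ee")
    test_idx <- withr::with_seed(si + 2, sample(n, round(0.2 * n)))
    fit <- fit_pls(data[-test_idx, ], ncomp = min(10, n_components))
    pred <- predict(fit, data[test_idx, ])
    coef_full <- fit$model$coefficients_raw[seq_len(n_components)]
    tibble::tibble(
      replicate = i,
      test_mae = mean(abs(pred - data$ddg[test_idx])),
      noise_sd = spec$noise_sd,
      cosine = abs(sum(coef_full * w)) /
        (sqrt(sum(coef_full^2)) * sqrt(sum(w^2)))
    )
  })
}

#' Planted-optimum campaign recovery benchmark
#'
#' For each replicate: simulate a library with a latent-linear landscape
#' whose noiseless argmax is boosted to a planted maximum, measure a random
#' starting subset, then run the default three-round campaign (greedy
#' flexible model first, certainty-filtered simpler models after) with noisy
#' acquisitions whose SD is `noise_frac` of the noiseless signal range.
#' Records whether (and when) the planted optimum was measured.
#'
#' @param n_reps Number of replicates (default 25).
#' @param n_library Library size (default 150).
#' @param n_components Feature dimensionality (default 8).
#' @param n_initial Starting measurements per replicate (default 30).
#' @param rounds,batch_size Campaign shape (defaults 3 and 5).
#' @param noise_frac Acquisition noise SD as a fraction of the signal range
#'   (default 0.05).
#' @param seed Base seed.
#' @return A tibble with one row per replicate: `found`, `round_found`,
#'   `best_abs_ddg`.
#' @export
benchmark_campaign_recovery <- function(n_reps = 25, n_library = 150,
                                        n_components = 8, n_initial = 30,
                                        rounds = 3, batch_size = 5,
                                        noise_frac = 0.05, seed = 1) {
  purrr::map_dfr(seq_len(n_reps), function(i) {
    si <- seed + 131 * i
    w <- withr::with_seed(si, stats::rnorm(n_components) / sqrt(n_components))
    x <- simulate_feature_space(n_library, n_components, seed = si + 1)
    ddg_true <- as.numeric(x %*% w)
    planted <- rownames(x)[which.max(abs(ddg_true))]
    target <- sign(ddg_true[which.max(abs(ddg_true))]) * max(abs(ddg_true)) * 1.2
    ddg_true[which.max(abs(ddg_true))] <- target
    noise_sd <- noise_frac * diff(range(ddg_true))
    measure <- function(labels) {
      idx <- match(labels, rownames(x))
      tibble::tibble(
        catalyst_label = labels,
        ddg = ddg_true[idx] + stats::rnorm(length(idx), sd = noise_sd)
      )
    }
    start <- withr::with_seed(si + 2,
                              sample(setdiff(rownames(x), planted), n_initial))
    state <- withr::with_seed(si + 3, run_campaign(
      x,
      initial_records = measure(start),
      measure = measure,
      rounds = rounds, batch_size = batch_size, seed = si + 4
    ))
    hit <- state$records[state$records$catalyst_label == planted, ]
    tibble::tibble(
      replicate = i,
      found = nrow(hit) > 0,
      round_found = if (nrow(hit) > 0) min(hit$round) else NA_integer_,
      best_abs_ddg = max(abs(state$records$ddg))
    )
  })
}

#' Greedy-versus-certainty selection benchmark
#'
#' An extrapolation experiment: the measured starting set lives in the bulk
#' of descriptor space, while part of the candidate library is shifted
#' outside it; the landscape carries an interaction term the linear latent
#' model cannot extrapolate. One selection round is run in greedy mode and
#' one in certainty-filtered mode from identical starting records, and the
#' absolute prediction error of the realized picks is recorded.
#'
#' @param n_reps Number of replicates (default 25).
#' @param n_bulk In-distribution library members (default 120).
#' @param n_shift Shifted (extrapolated) members (default 60).
#' @param n_components Feature dimensionality (default 8).
#' @param n_initial Starting measurements (default 40).
#' @param batch_size Picks per round (default 5).
#' @param shift Mean feature shift of the extrapolated block (default 2.5).
#' @param seed Base seed.
#' @return A tibble with one row per replicate and mode: `mode`,
#'   `median_abs_error` of the round's picks.
#' @export
benchmark_selection_modes <- function(n_reps = 25, n_bulk = 120, n_shift = 60,
                                      n_components = 8, n_initial = 40,
                                      batch_size = 5, shift = 2.5, seed = 1) {
  purrr::map_dfr(seq_len(n_reps), function(i) {
    si <- seed + 977 * i
    w <- withr::with_seed(si, stats::rnorm(n_components) / sqrt(n_components))
    x_bulk <- simulate_feature_space(n_bulk, n_components, seed = si + 1)
    x_shift <- simulate_feature_space(n_shift, n_components, seed = si + 2) + shift
    rownames(x_shift) <- sprintf("far%04d", seq_len(n_shift))
    x <- rbind(x_bulk, x_shift)
    ddg_true <- as.numeric(x %*% w) + 0.5 * x[, 1] * x[, 2]
    noise_sd <- 0.05 * stats::sd(ddg_true)
    measure <- function(labels) {
      idx <- match(labels, rownames(x))
      tibble::tibble(
        catalyst_label = labels,
        ddg = ddg_true[idx] + stats::rnorm(length(idx), sd = noise_sd)
      )
    }
    start <- withr::with_seed(si + 3, sample(rownames(x_bulk), n_initial))
    initial <- withr::with_seed(si + 4, measure(start))
    one_round <- function(mode, quantile) {
      plan <- list(list(families = c("pls", "kernel", "forest"), mode = mode,
                        certainty_quantile = quantile))
      state <- withr::with_seed(si + 5, run_campaign(
        x, initial_records = initial, measure = measure, rounds = 1,
        batch_size = batch_size, round_plans = plan, seed = si + 6
      ))
      stats::median(abs(state$round_scores$predicted_ddg -
                          state$round_scores$realized_ddg))
    }
    tibble::tibble(
      replicate = i,
      mode = c("greedy", "certainty"),
      median_abs_error = c(one_round("greedy", 1), one_round("certainty", 0.5))
    )
  })
}
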