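# Iterative optimization campaign: fit a configurable model zoo on the
# accumulated records, score the full in-silico library, select the next
# batch greedily or under a prediction-certainty criterion, acquire outcomes
# (simulator or measurement table), and iterate.
#
# Certainty metric: the population SD of predictions across all zoo members
# (model family x CV fold). Smaller = more certain; 0 for unanimous members.
# The metric sits behind prediction_certainty() so alternative realisations
# can be swapped in.

zoo_family_fitters <- function(n_features, seed) {
  list(
    pls = function(x, y) {
      fit <- pls_nipals(x, y, ncomp = min(5, ncol(x), nrow(x) - 1))
      function(newx) predict(fit, newx)
    },
    kernel = function(x, y) {
      # broad RBF scaled to the feature dimension (standardized inputs):
      # kernlab's k(x,x') = exp(-sigma |x-x'|^2), E|x-x'|^2 ~ 2p
      sigma <- 0.3 / (2 * ncol(x))
      fit <- withr::with_seed(seed, kernlab::gausspr(
        x, y, var = 0.001, kpar = list(sigma = sigma)))
      function(newx) as.numeric(kernlab::predict(fit, newx))
    },
    forest = function(x, y) {
      df <- as.data.frame(x); df$.y <- y
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = 300, seed = seed)
      function(newx) {
        stats::predict(fit, data = as.data.frame(newx))$predictions
      }
    },
    nnet = function(x, y) {
      size <- min(64, 2 * ncol(x))
      sc <- max(stats::sd(y), 1e-8)
      fit <- withr::with_seed(seed, nnet::nnet(
        x, (y - mean(y)) / sc, size = size, linout = TRUE, decay = 1e-3,
        maxit = 500, trace = FALSE, MaxNWts = 10000
      ))
      mu <- mean(y)
      function(newx) as.numeric(stats::predict(fit, newx)) * sc + mu
    }
  )
}

#' Fit the model zoo with cross-validation
#'
#' Fits each configured family under K-fold cross-validation (recording the
#' CV MAE and keeping every fold model as an ensemble member) plus one fit on
#' all records. A family whose fit fails is recorded and excluded, not fatal.
#'
#' @param x Feature matrix of the measured records.
#' @param y DDG responses (kcal/mol).
#' @param families Character subset of `c("pls", "kernel", "forest", "nnet")`.
#' @param n_folds CV folds (default 5).
#' @param seed RNG seed (fold draw and stochastic learners).
#' @return A `model_zoo`: ensemble member predictors, per-family CV scores,
#'   and any failures.
#' @export
fit_model_zoo <- function(x, y, families = c("pls", "kernel", "forest"),
                          n_folds = 5, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 20) stop("at least 20 training records are required", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  fitters <- zoo_family_fitters(ncol(x), seed)
  unknown <- setdiff(families, names(fitters))
  if (length(unknown) > 0) {
    stop("unknown model famil(ies): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), nrow(x))))
  members <- list()
  cv_rows <- list()
  failures <- character(0)
  for (fam in families) {
    res <- try({
      fold_preds <- rep(NA_real_, nrow(x))
      fam_members <- list()
      for (k in seq_len(n_folds)) {
        tr <- folds != k
        pred_fn <- fitters[[fam]](x[tr, , drop = FALSE], y[tr])
        fold_preds[!tr] <- pred_fn(x[!tr, , drop = FALSE])
        fam_members[[k]] <- pred_fn
      }
      full_fn <- fitters[[fam]](x, y)
      list(members = fam_members, full = full_fn,
           cv_mae = mean(abs(fold_preds - y)))
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failures <- c(failures, fam)
    } else {
      names(res$members) <- paste0(fam, "_fold", seq_len(n_folds))
      members <- c(members, res$members,
                   stats::setNames(list(res$full), paste0(fam, "_full")))
      cv_rows[[fam]] <- tibble::tibble(family = fam, cv_mae = res$cv_mae)
    }
  }
  if (length(members) == 0) stop("every model family failed to fit", call. = FALSE)
  structure(list(
    members = members,
    cv_scores = dplyr::bind_rows(cv_rows),
    families = setdiff(families, failures),
    failures = failures,
    n_folds = n_folds, seed = seed,
    feature_names = colnames(x)
  ), class = "model_zoo")
}

#' @export
print.model_zoo <- function(x, ...) {
  cat(sprintf("<model_zoo> %d member predictors (%s), %d-fold CV\n",
              length(x$members), paste(x$families, collapse = ", "), x$n_folds))
  print(x$cv_scores)
  invisible(x)
}

zoo_member_predictions <- function(zoo, x) {
  x <- as.matrix(x)
  colnames(x) <- zoo$feature_names
  sapply(zoo$members, function(fn) fn(x))
}

#' Prediction certainty of zoo candidates
#'
#' The population standard deviation of the member predictions (across model
#' families and CV folds) per candidate, in kcal/mol. Zero means a unanimous
#' ensemble; larger values flag extrapolation into sparsely learned regions.
#'
#' @param zoo A `model_zoo`.
#' @param x Candidate feature matrix.
#' @return Numeric vector of certainty scores (>= 0), one per candidate.
#' @export
prediction_certainty <- function(zoo, x) {
  preds <- zoo_member_predictions(zoo, x)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  if (ncol(preds) < 2) {
    stop("certainty needs an ensemble with >= 2 member predictions; ",
         "use greedy selection for single models", call. = FALSE)
  }
  m <- rowMeans(preds)
  sqrt(rowMeans((preds - m)^2))
}

#' Score and rank library candidates
#'
#' Predicts DDG for every unmeasured library member (ensemble-mean
#' prediction), attaches the certainty score, and ranks. Greedy mode sorts by
#' `|predicted DDG|` descending; certainty-filtered mode first discards
#' candidates whose certainty exceeds the given quantile of the candidate
#' certainty distribution, then sorts.
#'
#' @param zoo A `model_zoo`.
#' @param features Library feature matrix, rownames = peptide labels.
#' @param measured Labels already measured (excluded from ranking).
#' @param mode `"greedy"` or `"certainty"`.
#' @param certainty_quantile Quantile cutoff for certainty filtering
#'   (default 0.5).
#' @param temperature Temperature for the equivalent-ee column.
#' @return A ranked tibble of candidate scores (`label`, `predicted_ddg`,
#'   `predicted_ee`, `certainty`).
#' @export
rank_candidates <- function(zoo, features, measured = character(),
                            mode = c("greedy", "certainty"),
                            certainty_quantile = 0.5, temperature = 293.15) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  if (is.null(rownames(features))) {
    stop("library features need rownames (peptide labels)", call. = FALSE)
  }
  cand <- setdiff(rownames(features), measured)
  if (length(cand) == 0) stop("library is exhausted", call. = FALSE)
  fx <- features[cand, , drop = FALSE]
  preds <- zoo_member_predictions(zoo, fx)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  scores <- tibble::tibble(
    label = cand,
    predicted_ddg = rowMeans(preds),
    predicted_ee = ddg_to_ee(rowMeans(preds), temperature),
    certainty = prediction_certainty(zoo, fx)
  )
  if (mode == "certainty") {
    cutoff <- stats::quantile(scores$certainty, certainty_quantile)
    scores <- dplyr::filter(scores, .data$certainty < cutoff |
                              (.data$certainty == 0 & cutoff == 0))
    if (nrow(scores) == 0) {
      stop("all candidates filtered out; loosen certainty_quantile",
           call. = FALSE)
    }
  }
  dplyr::arrange(scores, dplyr::desc(abs(.data$predicted_ddg)), .data$label)
}

default_round_plans <- function(rounds) {
  # round 1: flexible model, greedy; later rounds: simpler families with
  # certainty filtering at the median
  plans <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    plans[[r]] <- if (r == 1) {
      list(families = c("nnet", "pls", "forest"), mode = "greedy",
           certainty_quantile = 1)
    } else {
      list(families = c("pls", "kernel", "forest"), mode = "certainty",
           certainty_quantile = 0.5)
    }
  }
  plans
}

#' Run an iterative optimization campaign
#'
#' Per round: fit the zoo on all accumulated records, rank the unmeasured
#' library, select the top `batch_size` candidates, acquire their outcomes
#' from `measure` (a simulator function, or a measurement tibble in real
#' campaigns), and append. No catalyst is ever selected twice.
#'
#' @param features Library feature matrix, rownames = peptide labels.
#' @param initial_records Tibble of starting measurements (`catalyst_label`,
#'   `ddg`), e.g. the UTS screen.
#' @param measure Either a function `function(labels) -> tibble(catalyst_label,
#'   ddg)` or a tibble covering all library members.
#' @param rounds Number of rounds (default 3).
#' @param batch_size Candidates per round (default 5).
#' @param round_plans Optional list (length `rounds`) of per-round settings
#'   (`families`, `mode`, `certainty_quantile`); defaults to a greedy
#'   flexible-model first round and certainty-filtered simpler models after.
#' @param temperature Temperature in K for ee equivalents.
#' @param seed RNG seed.
#' @return A `campaign_state`: accumulated `records` (with `round`), per-round
#'   `plans` and pick tables, and the best-so-far `|ddg|`/`|ee|` trace.
#' @export
run_campaign <- function(features, initial_records, measure, rounds = 3,
                         batch_size = 5, round_plans = NULL,
                         temperature = 293.15, seed = 1) {
  stopifnot(nrow(initial_records) >= 1)
  features <- as.matrix(features)
  round_plans <- round_plans %||% default_round_plans(rounds)
  stopifnot(length(round_plans) >= rounds)
  measure_fn <- if (is.function(measure)) {
    measure
  } else {
    lookup <- measure
    function(labels) {
      miss <- setdiff(labels, lookup$catalyst_label)
      if (length(miss) > 0) {
        stop("measurement table is missing selected label(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      lookup[match(labels, lookup$catalyst_label), ]
    }
  }
  records <- dplyr::mutate(tibble::as_tibble(initial_records), round = 0L)
  plans <- list()
  round_tables <- list()
  for (r in seq_len(rounds)) {
    plan <- round_plans[[r]]
    if (batch_size == 0) {
      plans[[r]] <- c(plan, list(round = r, picks = character(0)))
      next
    }
    zoo <- fit_model_zoo(features[records$catalyst_label, , drop = FALSE],
                         records$ddg, families = plan$families,
                         seed = seed + r)
    ranked <- rank_candidates(zoo, features, measured = records$catalyst_label,
                              mode = plan$mode,
                              certainty_quantile = plan$certainty_quantile %||% 0.5,
                              temperature = temperature)
    picks <- utils::head(ranked, batch_size)
    outcome <- measure_fn(picks$label)
    realized <- tibble::tibble(
      catalyst_label = picks$label,
      ddg = outcome$ddg[match(picks$label, outcome$catalyst_label)],
      round = r
    )
    round_tables[[r]] <- dplyr::mutate(
      dplyr::left_join(picks,
                       dplyr::select(realized, "catalyst_label", realized_ddg = "ddg"),
                       by = c(label = "catalyst_label")),
      round = r
    )
    records <- dplyr::bind_rows(records, realized)
    plans[[r]] <- c(plan, list(round = r, picks = picks$label))
  }
  best_trace <- records |>
    dplyr::group_by(.data$round) |>
    dplyr::summarise(round_best = max(abs(.data$ddg)), .groups = "drop") |>
    dplyr::arrange(.data$round) |>
    dplyr::mutate(best_abs_ddg = cummax(.data$round_best),
                  best_abs_ee = abs(ddg_to_ee(.data$best_abs_ddg, temperature)))
  structure(list(
    records = records,
    plans = plans,
    round_scores = dplyr::bind_rows(round_tables),
    best_trace = best_trace,
    temperature = temperature, seed = seed
  ), class = "campaign_state")
}

#' @export
print.campaign_state <- function(x, ...) {
  n_rounds <- max(x$records$round)
  cat(sprintf("<campaign_state> %d rounds, %d records, best |ee| so far %.1f%%\n",
              n_rounds, nrow(x$records),
              100 * utils::tail(x$best_trace$best_abs_ee, 1)))
  invisible(x)
}
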