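# broom-style tidiers: tidy() returns the per-observation table of an object,
# glance() its one-row summary.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a cluster scan into its elbow curve
#'
#' @param x A `cluster_scan`.
#' @param ... Unused.
#' @return A tibble with one row per scanned k (`k`, `distortion`).
#' @export
tidy.cluster_scan <- function(x, ...) x$scan

#' @export
glance.cluster_scan <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$x), k_min = min(x$scan$k),
                 k_max = max(x$scan$k), n_restarts = x$n_restarts,
                 seed = x$seed)
}

#' Per-component summary of a reduced descriptor space
#'
#' @param x A `reduced_space`.
#' @param ... Unused.
#' @return A tibble with one row per retained principal component.
#' @export
tidy.reduced_space <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    variance_ratio = x$explained_variance_ratio,
    cumulative_variance = cumsum(x$explained_variance_ratio)
  )
}

#' @export
glance.reduced_space <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    n_retained_features = length(x$kept),
    explained_variance = sum(x$explained_variance_ratio)
  )
}

#' Per-feature coefficients of a fitted PLS model
#'
#' @param x A `pls_fit`.
#' @param ... Unused.
#' @return A tibble of standardized-scale coefficients per feature.
#' @export
tidy.pls_fit <- function(x, ...) {
  tibble::tibble(term = x$feature_cols,
                 estimate = x$model$coefficients)
}

#' @export
glance.pls_fit <- function(x, ...) {
  tibble::tibble(ncomp = x$model$ncomp,
                 n_features = length(x$feature_cols),
                 n_train = x$n_train,
                 n_catalysts = length(x$train_labels),
                 cv_mae = if (is.null(x$cv)) NA_real_ else min(x$cv$cv_mae))
}

#' Per-record predictions of a model report
#'
#' @param x A `model_report`.
#' @param ... Unused.
#' @return The predicted/observed tibble, one row per record.
#' @export
tidy.model_report <- function(x, ...) x$predictions

#' One-row metric summary of a model report
#'
#' @param x A `model_report`.
#' @param ... Unused.
#' @return A tibble with `mae_train`, `mae_test` (kcal/mol) and counts.
#' @export
glance.model_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$metrics, names_from = "partition",
                             values_from = c("n", "mae", "rmse"))
  out <- tibble::tibble(
    mae_train = wide$mae_train %||% NA_real_,
    mae_test = if ("mae_test" %in% names(wide)) wide$mae_test else NA_real_,
    rmse_train = wide$rmse_train %||% NA_real_,
    rmse_test = if ("rmse_test" %in% names(wide)) wide$rmse_test else NA_real_,
    n_train = wide$n_train %||% 0L,
    n_test = if ("n_test" %in% names(wide)) wide$n_test else 0L
  )
  out
}

#' @export
tidy.model_zoo <- function(x, ...) x$cv_scores

#' Accumulated measurements of a campaign
#'
#' @param x A `campaign_state`.
#' @param ... Unused.
#' @return Tibble of all measured records with their acquisition round.
#' @export
tidy.campaign_state <- function(x, ...) x$records

#' @export
glance.campaign_state <- function(x, ...) {
  tibble::tibble(
    rounds = max(x$records$round),
    n_measured = nrow(x$records),
    best_abs_ddg = utils::tail(x$best_trace$best_abs_ddg, 1),
    best_abs_ee = utils::tail(x$best_trace$best_abs_ee, 1)
  )
}
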