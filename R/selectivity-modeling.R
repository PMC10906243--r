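# Selectivity modeling: catalyst-out splits, NIPALS PLS regression of
# free-energy targets on descriptor components, and train/test evaluation.
# Enantio- and diastereoselectivity are modeled separately; reaction identity
# enters as indicator columns so one model spans several trial reactions.

#' Plan a catalyst-out train/test split
#'
#' Hold out whole catalysts: every reaction record of a held-out catalyst
#' moves to the test set, so test catalysts are truly out-of-sample. Pinned
#' labels (e.g. the top performer) are always held out; the rest are drawn
#' uniformly without replacement.
#'
#' @param records Tibble with a `catalyst_label` column.
#' @param n_random Number of randomly drawn held-out catalysts (default 9).
#' @param pinned Character vector of labels always held out (default none).
#' @param seed RNG seed for the draw.
#' @return A `split_plan` tibble (`catalyst_label`, `role` in train/test).
#' @export
make_catalyst_split <- function(records, n_random = 9, pinned = character(),
                                seed = 1) {
  labels <- sort(unique(records$catalyst_label))
  missing <- setdiff(pinned, labels)
  if (length(missing) > 0) {
    stop("pinned label(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  candidates <- setdiff(labels, pinned)
  if (n_random > length(candidates)) {
    stop("n_random + pinned exceeds the number of distinct catalysts",
         call. = FALSE)
  }
  drawn <- withr::with_seed(seed, sample(candidates, n_random))
  held <- union(pinned, drawn)
  plan <- tibble::tibble(
    catalyst_label = labels,
    role = ifelse(labels %in% held, "test", "train")
  )
  structure(plan, pinned = pinned, seed = seed,
            class = c("split_plan", class(plan)))
}

split_labels <- function(split, role) split$catalyst_label[split$role == role]

#' Attach free-energy targets and model features to selectivity records
#'
#' Converts the chosen selectivity to DDG at each record's temperature
#' ([ee_to_ddg()] or [dr_to_ddg()]), joins the catalyst feature rows, and --
#' when several reactions are present -- appends 0/1 reaction indicator
#' columns.
#'
#' @param records Selectivity tibble with `catalyst_label`, `reaction_id`,
#'   `temperature` and either `ee` or `dr_syn`/`dr_anti`.
#' @param features Numeric matrix of catalyst features (reduced-space
#'   scores), rownames = catalyst labels.
#' @param target `"ee"` or `"dr"`.
#' @return A tibble with `ddg` and feature columns; the feature column names
#'   are recorded in the `"feature_cols"` attribute.
#' @export
prepare_model_data <- function(records, features, target = c("ee", "dr")) {
  target <- match.arg(target)
  features <- as.matrix(features)
  missing <- setdiff(unique(records$catalyst_label), rownames(features))
  if (length(missing) > 0) {
    stop("no feature row for catalyst(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  temperature <- records$temperature %||% 293.15
  ddg <- if (target == "ee") {
    ee_to_ddg(records$ee, temperature)
  } else {
    dr_to_ddg(records$dr_syn, records$dr_anti, temperature)
  }
  fx <- features[records$catalyst_label, , drop = FALSE]
  if (is.null(colnames(fx))) colnames(fx) <- paste0("pc", seq_len(ncol(fx)))
  out <- dplyr::bind_cols(
    tibble::tibble(catalyst_label = records$catalyst_label,
                   reaction_id = records$reaction_id %||% "rxn1",
                   ddg = ddg),
    tibble::as_tibble(fx)
  )
  feature_cols <- colnames(fx)
  rxns <- sort(unique(out$reaction_id))
  if (length(rxns) > 1) {
    for (r in rxns[-1]) out[[paste0("rxn_", r)]] <- as.numeric(out$reaction_id == r)
    feature_cols <- c(feature_cols, paste0("rxn_", rxns[-1]))
  }
  attr(out, "feature_cols") <- feature_cols
  out
}

# NIPALS PLS1: X standardized per column, y centered. Returns scores/loadings
# and the regression coefficients on the original feature scale.
pls_nipals <- function(x, y, ncomp) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= ncomp + 1)
  xc <- colMeans(x)
  xs <- apply(x, 2, stats::sd)
  xs[xs < .Machine$double.eps] <- 1
  e <- sweep(sweep(x, 2, xc), 2, xs, `/`)
  ym <- mean(y)
  f <- y - ym
  p <- ncol(x)
  W <- P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(e, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { # residual signal exhausted; truncate
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Q <- Q[seq_len(a - 1)]
      ncomp <- a - 1L
      break
    }
    w <- w / nw
    t <- as.numeric(e %*% w)
    tt <- sum(t^2)
    pv <- crossprod(e, t) / tt
    q <- sum(f * t) / tt
    e <- e - tcrossprod(t, pv)
    f <- f - q * t
    W[, a] <- w; P[, a] <- pv; Q[a] <- q
  }
  if (ncomp == 0) stop("response has no variance to model", call. = FALSE)
  beta_std <- W %*% solve(crossprod(P, W), Q)
  structure(list(
    x_center = xc, x_scale = xs, y_mean = ym,
    weights = W, loadings = P, q = Q,
    coefficients = as.numeric(beta_std),
    coefficients_raw = as.numeric(beta_std / xs),
    feature_names = colnames(x),
    ncomp = as.integer(ncomp)
  ), class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    x <- x[, object$feature_names, drop = FALSE]
  }
  e <- sweep(sweep(x, 2, object$x_center), 2, object$x_scale, `/`)
  as.numeric(e %*% object$coefficients) + object$y_mean
}

#' Fit a PLS selectivity model
#'
#' Fits the DDG response on the feature columns of a prepared data tibble
#' (see [prepare_model_data()]) with NIPALS PLS. When `ncomp` is `NULL`, the
#' component count is chosen by leave-catalyst-out cross-validation (all
#' records of one catalyst held out per fold), capped at `max_ncomp`.
#'
#' @param data Prepared tibble (typically the training rows only).
#' @param ncomp Number of latent components, or `NULL` for CV selection.
#' @param max_ncomp Cap for CV selection (default 10).
#' @param feature_cols Feature column names (default: the `"feature_cols"`
#'   attribute of `data`).
#' @return A `pls_fit` object: the fitted `pls_model`, the training labels,
#'   and the CV table when CV was run.
#' @export
fit_pls <- function(data, ncomp = NULL, max_ncomp = 10, feature_cols = NULL) {
  feature_cols <- feature_cols %||% attr(data, "feature_cols")
  stopifnot(!is.null(feature_cols))
  x <- as.matrix(data[feature_cols])
  y <- data$ddg
  cv_table <- NULL
  if (is.null(ncomp)) {
    cats <- unique(data$catalyst_label)
    cap <- min(max_ncomp, ncol(x), nrow(x) - max(table(data$catalyst_label)) - 1)
    cv_mae <- vapply(seq_len(cap), function(a) {
      errs <- purrr::map_dbl(cats, function(cl) {
        tr <- data$catalyst_label != cl
        fit <- pls_nipals(x[tr, , drop = FALSE], y[tr], a)
        mean(abs(predict(fit, x[!tr, , drop = FALSE]) - y[!tr]))
      })
      mean(errs)
    }, numeric(1))
    ncomp <- which.min(cv_mae)
    cv_table <- tibble::tibble(ncomp = seq_len(cap), cv_mae = cv_mae)
  }
  model <- pls_nipals(x, y, ncomp)
  structure(list(model = model, feature_cols = feature_cols,
                 train_labels = unique(data$catalyst_label),
                 n_train = nrow(data), cv = cv_table),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d latent components, %d features, %d training records (%d catalysts)\n",
              x$model$ncomp, length(x$feature_cols), x$n_train,
              length(x$train_labels)))
  invisible(x)
}

#' @export
predict.pls_fit <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata[object$feature_cols])
  predict(object$model, newdata)
}

#' Evaluate a fitted model under a catalyst-out split
#'
#' Computes train and test MAE (kcal/mol) and per-record predicted/observed
#' pairs. Errors if any held-out catalyst contributed a training row
#' (leakage) -- the model must have been fitted on exactly the split's train
#' rows.
#'
#' @param fit A `pls_fit` (or any object with a `predict` method and
#'   `train_labels`).
#' @param data The full prepared data tibble (train + test rows).
#' @param split A `split_plan`.
#' @return A `model_report`: `metrics` (one row per partition) and
#'   `predictions` (per record).
#' @export
evaluate_model <- function(fit, data, split) {
  test_labels <- split_labels(split, "test")
  leaked <- intersect(fit$train_labels, test_labels)
  if (length(leaked) > 0) {
    stop("leakage: held-out catalyst(s) in the training set: ",
         paste(leaked, collapse = ", "), call. = FALSE)
  }
  preds <- tibble::tibble(
    catalyst_label = data$catalyst_label,
    reaction_id = data$reaction_id,
    partition = ifelse(data$catalyst_label %in% test_labels, "test", "train"),
    observed = data$ddg,
    predicted = predict(fit, data)
  )
  metrics <- preds |>
    dplyr::group_by(.data$partition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mae = mean(abs(.data$predicted - .data$observed)),
      rmse = sqrt(mean((.data$predicted - .data$observed)^2)),
      .groups = "drop"
    )
  structure(list(metrics = metrics, predictions = preds, fit = fit),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report>\n")
  print(x$metrics)
  invisible(x)
}
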