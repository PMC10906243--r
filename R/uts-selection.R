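# Universal Training Set design: k-means scan over descriptor space with an
# elbow (distortion) curve, centroid-exemplar selection, manual augmentation,
# combinatorial UTS construction, and selectivity-distribution diagnostics.

# k-means++ initial centers (D^2 sampling); stats::kmeans does not provide
# this initialisation, so it is drawn here and passed via `centers=`.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- rep(Inf, n)
    for (i in idx) {
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[i, ], `-`)^2))
    }
    if (sum(d2) <= 0) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
    } else {
      idx <- c(idx, sample.int(n, 1, prob = d2))
    }
  }
  x[idx, , drop = FALSE]
}

kmeans_once <- function(x, centers) {
  res <- try(suppressWarnings(
    stats::kmeans(x, centers = centers, iter.max = 200, algorithm = "Lloyd")
  ), silent = TRUE)
  if (inherits(res, "try-error")) NULL else res
}

#' Scan k-means clusterings over a range of k
#'
#' For each k, keeps the best of `n_restarts` k-means++-initialised runs plus
#' a warm start from the previous k's solution (its centers augmented with
#' the point farthest from its assigned centroid), which guarantees the
#' distortion sequence is non-increasing in k. Distortion is the mean squared
#' Euclidean distance of points to their assigned centroid (the elbow-method
#' convention).
#'
#' @param x Matrix (or data frame) of reduced-space coordinates, one row per
#'   item; row names are the item ids.
#' @param k_range Integer vector of cluster counts to scan (default 1:50,
#'   truncated to the number of rows).
#' @param n_restarts Restarts per k (default 25).
#' @param seed RNG seed for the whole scan.
#' @return A `cluster_scan` object: tibble of (k, distortion) in `$scan`,
#'   per-k assignments and centers, and ids.
#' @export
kmeans_scan <- function(x, k_range = 1:50, n_restarts = 25, seed = 1) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("item", seq_len(nrow(x)))
  if (max(k_range) > nrow(x)) {
    stop("k_max (", max(k_range), ") exceeds the number of points (",
         nrow(x), ")", call. = FALSE)
  }
  k_range <- sort(unique(as.integer(k_range)))
  fits <- vector("list", length(k_range))
  withr::with_seed(seed, {
    prev <- NULL
    for (kk in seq_along(k_range)) {
      k <- k_range[kk]
      best <- NULL
      for (r in seq_len(n_restarts)) {
        fit <- kmeans_once(x, kmeanspp_centers(x, k))
        if (!is.null(fit) &&
            (is.null(best) || fit$tot.withinss < best$tot.withinss)) best <- fit
      }
      if (!is.null(prev) && k == prev$k + 1) {
        d2 <- rowSums((x - prev$fit$centers[prev$fit$cluster, , drop = FALSE])^2)
        warm <- rbind(prev$fit$centers, x[which.max(d2), ])
        fit <- kmeans_once(x, warm)
        if (!is.null(fit) && fit$tot.withinss < best$tot.withinss) best <- fit
      }
      if (is.null(best)) stop("k-means failed for k = ", k, call. = FALSE)
      fits[[kk]] <- best
      prev <- list(k = k, fit = best)
    }
  })
  structure(list(
    scan = tibble::tibble(
      k = k_range,
      distortion = vapply(fits, function(f) f$tot.withinss / nrow(x), numeric(1))
    ),
    assignments = lapply(fits, `[[`, "cluster"),
    centers = lapply(fits, `[[`, "centers"),
    ids = rownames(x), x = x,
    n_restarts = n_restarts, seed = seed
  ), class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  cat(sprintf("<cluster_scan> %d points, k = %d..%d (%d restarts, seed %d)\n",
              nrow(x$x), min(x$scan$k), max(x$scan$k), x$n_restarts, x$seed))
  invisible(x)
}

#' Select cluster exemplars
#'
#' For each cluster of the k-cluster solution, picks the member nearest its
#' centroid (Euclidean distance; ties broken by lowest id).
#'
#' @param scan A `cluster_scan`.
#' @param k Cluster count; must be in the scanned range.
#' @return An `exemplar_set` tibble with columns `id`, `cluster`,
#'   `centroid_distance`, `manual`.
#' @export
select_exemplars <- function(scan, k) {
  kk <- match(k, scan$scan$k)
  if (is.na(kk)) stop("k = ", k, " was not scanned", call. = FALSE)
  assign <- scan$assignments[[kk]]
  centers <- scan$centers[[kk]]
  picks <- purrr::map_dfr(sort(unique(assign)), function(cl) {
    members <- which(assign == cl)
    d <- sqrt(rowSums(sweep(scan$x[members, , drop = FALSE], 2,
                            centers[cl, ], `-`)^2))
    ids <- scan$ids[members]
    ord <- order(d, ids)
    tibble::tibble(id = ids[ord[1]], cluster = cl,
                   centroid_distance = unname(d[ord[1]]), manual = FALSE)
  })
  structure(picks, class = c("exemplar_set", class(picks)))
}

#' Add manually chosen building blocks to an exemplar set
#'
#' Expert-picked residues (e.g. glutamic-acid-type relatives of an
#' algorithmically selected glutamine) are appended with a `manual` flag;
#' they must exist in the building-block universe and must not duplicate an
#' algorithmic exemplar.
#'
#' @param exemplars An `exemplar_set`.
#' @param additions Character vector of building-block ids (may be empty).
#' @param universe Character vector of all known building-block ids.
#' @return The augmented `exemplar_set`.
#' @export
augment_manual <- function(exemplars, additions, universe) {
  if (length(additions) == 0) return(exemplars)
  unknown <- setdiff(additions, universe)
  if (length(unknown) > 0) {
    stop("unknown building-block id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dup <- intersect(additions, exemplars$id)
  if (length(dup) > 0) {
    stop("manual addition(s) duplicate algorithmic exemplar(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::bind_rows(
    exemplars,
    tibble::tibble(id = additions, cluster = NA_integer_,
                   centroid_distance = NA_real_, manual = TRUE)
  )
  structure(out, class = c("exemplar_set", setdiff(class(out), "exemplar_set")))
}

#' Build the Universal Training Set
#'
#' Enumerates the combinatorial tripeptide set with the fixed first residue
#' and the exemplar pool (algorithmic + manual) at positions 2 and 3:
#' `|exemplars|^2` peptides.
#'
#' @param exemplars An `exemplar_set`.
#' @param blocks Validated building-block tibble.
#' @param fixed_first Id of the fixed N-terminal residue (default `"dPro"`).
#' @param c_terminus `"amide"` or `"acid"`.
#' @return A `catalyst_library` tibble.
#' @export
build_uts <- function(exemplars, blocks, fixed_first = "dPro",
                      c_terminus = c("amide", "acid")) {
  if (nrow(exemplars) == 0) stop("exemplar set is empty", call. = FALSE)
  enumerate_library(blocks, fixed_first = fixed_first, pool = exemplars$id,
                    c_terminus = match.arg(c_terminus))
}

#' Summarize a selectivity distribution
#'
#' Sample skewness and excess kurtosis (classical moment estimators) plus a
#' Kolmogorov-Smirnov test against a normal with the sample mean and SD.
#'
#' @param values Numeric vector of selectivities (ee or DDG scale), n >= 4.
#' @return A one-row `distribution_summary` tibble: `n`, `mean`, `sd`,
#'   `skewness`, `excess_kurtosis`, `ks_statistic`, `ks_p_value`.
#' @export
summarize_distribution <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4) {
    stop("at least 4 finite values are required", call. = FALSE)
  }
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))
  )
  out <- tibble::tibble(
    n = length(values),
    mean = mean(values),
    sd = stats::sd(values),
    skewness = e1071::skewness(values, type = 1),
    excess_kurtosis = e1071::kurtosis(values, type = 1),
    ks_statistic = unname(ks$statistic),
    ks_p_value = ks$p.value
  )
  structure(out, class = c("distribution_summary", class(out)))
}
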