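# Conformer-averaged grid descriptors: Average Steric Occupancy (ASO) and an
# Average Electronic Indicator Field (AEIF), plus feature-matrix assembly
# (flatten, concatenate, standardise) and variance/correlation pruning with
# PCA reduction.
#
# ASO(g)  = weighted fraction of conformers with at least one atom whose van
#           der Waals sphere covers grid point g; in [0, 1].
# AEIF(g) = weighted mean over conformers of the partial charge of the
#           nearest covering atom (0 where uncovered). This
#           nearest-covering-atom realisation is one admissible electronic
#           indicator; it is isolated behind this interface so alternative
#           indicator fields can be swapped in.

#' Bondi van der Waals radii
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
    Cl = 1.75, Br = 1.85, I = 1.98, Si = 2.10, B = 1.92)
}

#' Define a rectilinear descriptor grid
#'
#' @param origin Numeric length-3, grid corner in Angstrom.
#' @param spacing Grid step in Angstrom (> 0).
#' @param dims Integer length-3, number of points per axis (>= 1).
#' @return A `descriptor_grid` object.
#' @export
descriptor_grid <- function(origin, spacing, dims) {
  stopifnot(length(origin) == 3, length(dims) == 3, spacing > 0, all(dims >= 1))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = as.integer(dims)),
            class = "descriptor_grid")
}

#' @export
print.descriptor_grid <- function(x, ...) {
  cat(sprintf("<descriptor_grid> %d x %d x %d points, spacing %.2f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

n_grid_points <- function(grid) prod(grid$dims)

#' Coordinates of all grid points
#'
#' Flattening order: x varies fastest, then y, then z. Feature columns across
#' the package use this order.
#'
#' @param grid A `descriptor_grid`.
#' @return An N x 3 matrix of coordinates.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(i) grid$origin[i] + grid$spacing * (seq_len(grid$dims[i]) - 1))
  pts <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                     KEEP.OUT.ATTRS = FALSE)
  unname(as.matrix(pts))
}

#' Fit a grid around aligned ensembles
#'
#' Encloses the bounding box of all conformers of all calibration ensembles
#' plus a margin.
#'
#' @param ensembles A list of aligned `conformer_ensemble`s (or one ensemble).
#' @param spacing Grid step in Angstrom (default 1.0).
#' @param margin Padding beyond the bounding box in Angstrom (default 3.0).
#' @return A `descriptor_grid`.
#' @export
fit_grid <- function(ensembles, spacing = 1.0, margin = 3.0) {
  if (inherits(ensembles, "conformer_ensemble")) ensembles <- list(ensembles)
  coords <- do.call(rbind, unlist(lapply(ensembles, `[[`, "conformers"),
                                  recursive = FALSE))
  lo <- apply(coords, 2, min) - margin
  hi <- apply(coords, 2, max) + margin
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  descriptor_grid(origin = lo, spacing = spacing, dims = dims)
}

# Shared occupancy scan. For each conformer returns, per grid point, whether
# it is covered and (optionally) the charge of the nearest covering atom.
scan_occupancy <- function(ensemble, grid, radii, charges = NULL) {
  pts <- grid_points(grid)
  missing_el <- setdiff(unique(ensemble$elements), names(radii))
  if (length(missing_el) > 0) {
    stop("element(s) missing from radius table: ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  r <- radii[ensemble$elements]
  lapply(ensemble$conformers, function(cf) {
    best_d2 <- rep(Inf, nrow(pts))
    q <- numeric(nrow(pts))
    for (a in seq_along(r)) {
      d2 <- (pts[, 1] - cf[a, 1])^2 + (pts[, 2] - cf[a, 2])^2 +
            (pts[, 3] - cf[a, 3])^2
      hit <- d2 <= r[a]^2 & d2 < best_d2
      if (any(hit)) {
        best_d2[hit] <- d2[hit]
        if (!is.null(charges)) q[hit] <- charges[a]
      }
    }
    list(occupied = is.finite(best_d2), charge = q)
  })
}

#' Average steric occupancy field
#'
#' ASO(g) is the (weighted) fraction of conformers in which some atom's van
#' der Waals sphere covers grid point g.
#'
#' @param ensemble An aligned `conformer_ensemble`.
#' @param grid A `descriptor_grid`.
#' @param radii Named radius table in Angstrom (default [bondi_radii()]).
#' @param weights Conformer weights (default uniform; see
#'   [conformer_weights()]).
#' @return A numeric vector of length `prod(grid$dims)` with class
#'   `steric_field`; values in `[0, 1]`.
#' @export
compute_aso <- function(ensemble, grid, radii = bondi_radii(),
                        weights = NULL) {
  w <- weights %||% rep(1 / n_conformers(ensemble), n_conformers(ensemble))
  stopifnot(length(w) == n_conformers(ensemble))
  scans <- scan_occupancy(ensemble, grid, radii)
  vals <- Reduce(`+`, Map(function(s, wi) wi * s$occupied, scans, w))
  structure(as.numeric(vals), grid = grid, class = "steric_field")
}

#' Average electronic indicator field
#'
#' AEIF(g) is the (weighted) mean over conformers of the partial charge of
#' the nearest atom whose van der Waals sphere covers g, taking 0 in
#' conformers where g is uncovered.
#'
#' @inheritParams compute_aso
#' @param charges Per-atom partial charges (default `ensemble$charges`).
#' @return A numeric vector with class `electronic_field`, in units of
#'   elementary charge.
#' @export
compute_aeif <- function(ensemble, grid, radii = bondi_radii(),
                         charges = ensemble$charges, weights = NULL) {
  if (is.null(charges)) stop("no partial charges available", call. = FALSE)
  if (length(charges) != length(ensemble$elements)) {
    stop("charge vector length (", length(charges),
         ") does not match atom count (", length(ensemble$elements), ")",
         call. = FALSE)
  }
  w <- weights %||% rep(1 / n_conformers(ensemble), n_conformers(ensemble))
  stopifnot(length(w) == n_conformers(ensemble))
  scans <- scan_occupancy(ensemble, grid, radii, charges = charges)
  vals <- Reduce(`+`, Map(function(s, wi) wi * s$charge, scans, w))
  structure(as.numeric(vals), grid = grid, class = "electronic_field")
}

#' Compute both descriptor fields for one catalyst
#'
#' @inheritParams compute_aeif
#' @return A list with elements `aso` and `aeif`.
#' @export
compute_fields <- function(ensemble, grid, radii = bondi_radii(),
                           charges = ensemble$charges, weights = NULL) {
  list(aso = compute_aso(ensemble, grid, radii, weights),
       aeif = compute_aeif(ensemble, grid, radii, charges, weights))
}

same_grid <- function(g1, g2) {
  isTRUE(all.equal(g1$origin, g2$origin)) && g1$spacing == g2$spacing &&
    all(g1$dims == g2$dims)
}

#' Assemble the standardized feature matrix
#'
#' Flattens and concatenates each catalyst's ASO and AEIF fields into one row
#' and standardises every column to zero mean / unit variance, recording the
#' scaling parameters so new catalysts can be projected with
#' [apply_feature_scaling()]. Constant columns get scale 1 (they are removed
#' later by [reduce_features()]).
#'
#' @param fields Named list, one element per catalyst, each a list with
#'   `aso` and `aeif` fields on a shared grid (see [compute_fields()]).
#' @return A `feature_matrix` object: list with the scaled matrix `x`,
#'   `center`, `scale`, and a `provenance` tibble (field, grid_index) per
#'   column.
#' @export
assemble_feature_matrix <- function(fields) {
  stopifnot(length(fields) >= 1)
  g0 <- attr(fields[[1]]$aso, "grid")
  for (f in fields) {
    if (!same_grid(attr(f$aso, "grid"), g0) ||
        !same_grid(attr(f$aeif, "grid"), g0)) {
      stop("all catalysts must share one grid", call. = FALSE)
    }
  }
  raw <- do.call(rbind, lapply(fields, function(f) c(as.numeric(f$aso),
                                                     as.numeric(f$aeif))))
  rownames(raw) <- names(fields)
  npt <- n_grid_points(g0)
  provenance <- tibble::tibble(
    field = rep(c("aso", "aeif"), each = npt),
    grid_index = rep(seq_len(npt), 2)
  )
  center <- colMeans(raw)
  scale <- apply(raw, 2, stats::sd)
  scale[scale < .Machine$double.eps] <- 1
  x <- sweep(sweep(raw, 2, center), 2, scale, `/`)
  colnames(x) <- paste0(provenance$field, "_", provenance$grid_index)
  structure(list(x = x, center = center, scale = scale,
                 provenance = provenance, grid = g0),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d catalysts x %d grid features (ASO + AEIF)\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Apply stored feature scaling to new catalysts
#'
#' @param fm A `feature_matrix` (provides center/scale and the grid contract).
#' @param fields Named list of per-catalyst field pairs, as in
#'   [assemble_feature_matrix()].
#' @return A matrix of standardized rows on the training scale.
#' @export
apply_feature_scaling <- function(fm, fields) {
  for (f in fields) {
    if (!same_grid(attr(f$aso, "grid"), fm$grid)) {
      stop("grid mismatch with the training feature matrix", call. = FALSE)
    }
  }
  raw <- do.call(rbind, lapply(fields, function(f) c(as.numeric(f$aso),
                                                     as.numeric(f$aeif))))
  rownames(raw) <- names(fields)
  out <- sweep(sweep(raw, 2, fm$center), 2, fm$scale, `/`)
  colnames(out) <- colnames(fm$x)
  out
}

#' Prune features and reduce to principal components
#'
#' Drops columns with variance at or below `var_tol`, then scans the
#' remaining columns in index order and greedily drops the later member of
#' any pair with `|Pearson r| >= corr_threshold`, and finally projects the
#' retained columns onto the first `n_pc` principal components.
#'
#' @param fm A `feature_matrix`.
#' @param var_tol Variance threshold (default 1e-10; scaled columns have
#'   variance 1, constant columns 0).
#' @param corr_threshold Absolute-correlation threshold (default 0.95).
#' @param n_pc Number of principal components to retain (default 20).
#' @return A `reduced_space` object: `scores` (rows x n_pc), `rotation`,
#'   `explained_variance_ratio`, `kept` column names, and the source
#'   `feature_matrix` scaling for projecting new catalysts.
#' @export
reduce_features <- function(fm, var_tol = 1e-10, corr_threshold = 0.95,
                            n_pc = 20) {
  x <- fm$x
  stopifnot(nrow(x) >= 2)
  v <- apply(x, 2, stats::var)
  keep <- which(v > var_tol)
  if (length(keep) >= 2) {
    xs <- x[, keep, drop = FALSE]
    cmat <- abs(stats::cor(xs))
    drop <- rep(FALSE, ncol(xs))
    for (j in seq_len(ncol(xs))[-1]) {
      earlier <- which(!drop[seq_len(j - 1)])
      if (length(earlier) > 0 && any(cmat[earlier, j] >= corr_threshold)) {
        drop[j] <- TRUE
      }
    }
    keep <- keep[!drop]
  }
  if (n_pc > length(keep)) {
    stop(sprintf("n_pc (%d) exceeds the number of retained columns (%d)",
                 n_pc, length(keep)), call. = FALSE)
  }
  xr <- x[, keep, drop = FALSE]
  pca <- stats::prcomp(xr, center = TRUE, scale. = FALSE)
  evr <- pca$sdev^2 / sum(pca$sdev^2)
  structure(list(
    scores = pca$x[, seq_len(n_pc), drop = FALSE],
    rotation = pca$rotation[, seq_len(n_pc), drop = FALSE],
    pca_center = pca$center,
    explained_variance_ratio = evr[seq_len(n_pc)],
    all_variance_ratio = evr,
    kept = colnames(fm$x)[keep],
    n_components = as.integer(n_pc),
    feature_matrix = fm[c("center", "scale", "grid")]
  ), class = "reduced_space")
}

#' @export
print.reduced_space <- function(x, ...) {
  cat(sprintf("<reduced_space> %d rows x %d components (%.1f%% variance), %d retained grid features\n",
              nrow(x$scores), x$n_components,
              100 * sum(x$explained_variance_ratio), length(x$kept)))
  invisible(x)
}

#' Project new standardized feature rows into a reduced space
#'
#' @param space A `reduced_space`.
#' @param x_new Matrix of standardized feature rows (from
#'   [apply_feature_scaling()]).
#' @return Matrix of principal-component scores.
#' @export
project_features <- function(space, x_new) {
  xr <- x_new[, space$kept, drop = FALSE]
  sweep(xr, 2, space$pca_center) %*% space$rotation
}
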