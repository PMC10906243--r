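test_that("ASO realises the covering-sphere indicator exactly", {
  grid <- descriptor_grid(origin = c(-2, -2, -2), spacing = 1, dims = c(5, 5, 5))
  pts <- grid_points(grid)
  # single conformer, one atom at the origin: 1 inside r_vdW, 0 outside
  ens <- conformer_ensemble("C", list(matrix(0, 1, 3)))
  aso <- compute_aso(ens, grid)
  r <- bondi_radii()["C"]
  inside <- rowSums(pts^2) <= r^2
  expect_equal(as.numeric(aso), as.numeric(inside))
  # two conformers, exactly one covering a point: ASO = 0.5 there
  far <- matrix(c(100, 0, 0), 1, 3)
  ens2 <- conformer_ensemble("C", list(matrix(0, 1, 3), far))
  aso2 <- compute_aso(ens2, grid)
  expect_equal(as.numeric(aso2), 0.5 * as.numeric(inside))
  expect_error(compute_aso(conformer_ensemble("Zz", list(matrix(0, 1, 3))),
                           grid), "Zz")
})

test_that("AEIF is zero without charges and equals the covering charge for one atom", {
  grid <- descriptor_grid(c(-2, -2, -2), 1, c(5, 5, 5))
  ens <- conformer_ensemble(c("C", "N"),
                            list(matrix(c(0, 0, 0, 0.5, 0, 0), 2, 3, byrow = TRUE)))
  expect_equal(as.numeric(compute_aeif(ens, grid, charges = c(0, 0))),
               rep(0, 125))
  one <- conformer_ensemble("C", list(matrix(0, 1, 3)))
  aeif <- compute_aeif(one, grid, charges = 0.37)
  inside <- rowSums(grid_points(grid)^2) <= bondi_radii()["C"]^2
  expect_equal(as.numeric(aeif), 0.37 * as.numeric(inside))
  expect_error(compute_aeif(ens, grid, charges = c(1, 2, 3)), "length")
})

test_that("fields match the brute-force per-point oracle on random toy ensembles", {
  grid <- descriptor_grid(c(-3, -3, -3), 1.2, c(6, 6, 6))
  for (seed in 1:6) {
    ens <- random_toy_ensemble(n_atoms = 5, n_conf = 4, seed = seed)
    charges <- withr::with_seed(seed + 100, runif(5, -0.5, 0.5))
    aso <- compute_aso(ens, grid)
    aeif <- compute_aeif(ens, grid, charges = charges)
    expect_equal(as.numeric(aso), aso_bruteforce(ens, grid), tolerance = 1e-12)
    expect_equal(as.numeric(aeif), aeif_bruteforce(ens, grid, charges),
                 tolerance = 1e-12)
    expect_true(all(aso >= 0 & aso <= 1))
    expect_true(all(abs(aeif) <= max(abs(charges)) + 1e-12))
  }
})

test_that("adding a duplicate conformer leaves the averaged fields unchanged", {
  grid <- descriptor_grid(c(-3, -3, -3), 1.5, c(5, 5, 5))
  ens <- random_toy_ensemble(n_atoms = 4, n_conf = 3, seed = 42)
  dup <- conformer_ensemble(ens$elements,
                            c(ens$conformers, ens$conformers),
                            rep(ens$energies, 2))
  expect_equal(as.numeric(compute_aso(ens, grid)),
               as.numeric(compute_aso(dup, grid)), tolerance = 1e-12)
})

test_that("feature assembly flattens, concatenates, and standardises with a recoverable scaling", {
  grid <- descriptor_grid(c(0, 0, 0), 1, c(2, 2, 2)) # 8 points
  mk <- function(seed) {
    ens <- random_toy_ensemble(n_atoms = 3, n_conf = 2, seed = seed)
    charges <- withr::with_seed(seed, runif(3, -0.3, 0.3))
    compute_fields(ens, grid, charges = charges)
  }
  fields <- list(cat1 = mk(1), cat2 = mk(2), cat3 = mk(3))
  fm <- assemble_feature_matrix(fields)
  expect_equal(dim(fm$x), c(3, 16)) # 8 ASO + 8 AEIF columns
  v <- apply(fm$x, 2, var)
  expect_true(all(abs(colMeans(fm$x)) < 1e-9))
  expect_true(all(abs(v[v > 1e-9] - 1) < 1e-9)) # unit variance where defined
  # round trip: re-applying the stored scaling reproduces the matrix exactly
  expect_identical(unname(apply_feature_scaling(fm, fields)), unname(fm$x))
  # grid mismatch across catalysts errors
  other <- descriptor_grid(c(0, 0, 0), 2, c(2, 2, 2))
  bad <- list(cat1 = mk(1),
              cat2 = lapply(mk(2), function(f) { attr(f, "grid") <- other; f }))
  expect_error(assemble_feature_matrix(bad), "share one grid")
})

test_that("feature reduction prunes variance/correlation and matches an eigendecomposition", {
  withr::with_seed(7, {
    raw <- matrix(rnorm(20 * 30), 20, 30)
  })
  raw[, 5] <- 3 # constant column
  raw[, 12] <- raw[, 4] # duplicated column
  # assemble a feature_matrix-shaped object directly (constant column -> 0)
  sds <- apply(raw, 2, sd)
  fm <- structure(list(
    x = sweep(sweep(raw, 2, colMeans(raw)), 2, ifelse(sds > 0, sds, 1), `/`),
    center = colMeans(raw), scale = ifelse(sds > 0, sds, 1),
    provenance = NULL, grid = descriptor_grid(c(0, 0, 0), 1, c(30, 1, 1))
  ), class = "feature_matrix")
  colnames(fm$x) <- paste0("f", 1:30)
  red <- reduce_features(fm, corr_threshold = 0.999, n_pc = 5)
  expect_false("f5" %in% red$kept)   # zero variance dropped
  expect_true("f4" %in% red$kept)    # earlier duplicate kept
  expect_false("f12" %in% red$kept)  # later duplicate dropped
  # PCA variances equal eigenvalues of the sample covariance (oracle)
  xr <- fm$x[, red$kept]
  ev <- eigen(cov(xr), symmetric = TRUE)$values
  pca_var <- red$all_variance_ratio * sum(ev)
  expect_equal(pca_var[1:5], ev[1:5], tolerance = 1e-8)
  expect_true(all(diff(red$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(red$all_variance_ratio), 1 + 1e-12)
  expect_error(reduce_features(fm, n_pc = 100), "exceeds")
})

test_that("descriptor fields are invariant to pre-alignment rigid motions", {
  grid <- descriptor_grid(c(-3, -3, -3), 1.2, c(6, 6, 6))
  for (seed in 1:5) {
    ens <- random_toy_ensemble(n_atoms = 5, n_conf = 3, seed = seed)
    ens$core_atoms <- 1:3
    aligned <- align_to_core(ens)
    base <- compute_aso(aligned, grid)
    tf <- random_rigid_transform(seed + 50)
    moved <- apply_transform_to_ensemble(ens, tf)
    realigned <- align_to_core(moved, reference = aligned$reference_core)
    expect_lt(max(abs(compute_aso(realigned, grid) - base)), 1e-9)
  }
})

test_that("projection of new rows reproduces training scores", {
  withr::with_seed(21, {
    raw <- matrix(rnorm(15 * 10), 15, 10)
  })
  fm <- structure(list(
    x = scale(raw), center = colMeans(raw), scale = apply(raw, 2, sd),
    provenance = NULL, grid = descriptor_grid(c(0, 0, 0), 1, c(5, 1, 1))
  ), class = "feature_matrix")
  colnames(fm$x) <- paste0("f", 1:10)
  red <- reduce_features(fm, n_pc = 4)
  proj <- project_features(red, fm$x)
  expect_equal(unname(proj), unname(red$scores), tolerance = 1e-10)
})
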