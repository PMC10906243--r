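# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive per-point loops, independent of the vectorised implementation.

# A random toy ensemble: n_atoms light atoms, n_conf conformers in a small box.
random_toy_ensemble <- function(n_atoms = 5, n_conf = 4, seed = 1,
                                elements = c("C", "N", "O", "H", "S")) {
  withr::with_seed(seed, {
    els <- sample(elements, n_atoms, replace = TRUE)
    confs <- lapply(seq_len(n_conf), function(i) {
      matrix(stats::runif(n_atoms * 3, -3, 3), ncol = 3)
    })
    energies <- stats::runif(n_conf, 0, 8)
  })
  conformer_ensemble(els, confs, energies, label = paste0("toy_seed", seed))
}

# Naive per-point ASO: triple loop over points, conformers, atoms.
aso_bruteforce <- function(ensemble, grid, radii = bondi_radii()) {
  pts <- grid_points(grid)
  r <- radii[ensemble$elements]
  vals <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    hits <- 0
    for (cf in ensemble$conformers) {
      covered <- FALSE
      for (a in seq_along(r)) {
        if (sum((pts[p, ] - cf[a, ])^2) <= r[a]^2) { covered <- TRUE; break }
      }
      hits <- hits + covered
    }
    vals[p] <- hits / length(ensemble$conformers)
  }
  vals
}

# Naive per-point AEIF: nearest covering atom's charge per conformer.
aeif_bruteforce <- function(ensemble, grid, charges,
                            radii = bondi_radii()) {
  pts <- grid_points(grid)
  r <- radii[ensemble$elements]
  vals <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    acc <- 0
    for (cf in ensemble$conformers) {
      best_d2 <- Inf; q <- 0
      for (a in seq_along(r)) {
        d2 <- sum((pts[p, ] - cf[a, ])^2)
        if (d2 <= r[a]^2 && d2 < best_d2) { best_d2 <- d2; q <- charges[a] }
      }
      acc <- acc + q
    }
    vals[p] <- acc / length(ensemble$conformers)
  }
  vals
}

# Naive energy-window + pairwise-RMSD filter, keeping lower-energy members
# (heavy-atom RMSD, matching the documented pruning convention).
prune_bruteforce <- function(ensemble, energy_window, rmsd_threshold) {
  heavy <- which(ensemble$elements != "H")
  if (length(heavy) == 0) heavy <- seq_along(ensemble$elements)
  rel <- ensemble$energies - min(ensemble$energies)
  idx <- which(rel <= energy_window)
  idx <- idx[order(rel[idx])]
  kept <- integer(0)
  for (i in idx) {
    ok <- TRUE
    for (j in kept) {
      if (conformer_rmsd(ensemble$conformers[[i]][heavy, , drop = FALSE],
                         ensemble$conformers[[j]][heavy, , drop = FALSE]) <
          rmsd_threshold) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# Exhaustive nearest-member exemplar search for a given assignment/centers.
exemplars_bruteforce <- function(x, assign, centers, ids) {
  out <- character(0)
  for (cl in sort(unique(assign))) {
    members <- which(assign == cl)
    best_id <- NULL; best_d <- Inf
    for (m in members) {
      d <- sqrt(sum((x[m, ] - centers[cl, ])^2))
      if (d < best_d - 1e-12 ||
          (abs(d - best_d) <= 1e-12 && ids[m] < best_id)) {
        best_d <- d; best_id <- ids[m]
      }
    }
    out <- c(out, best_id)
  }
  out
}

# A random rigid-body transform (proper rotation + translation).
random_rigid_transform <- function(seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(9), 3)
    qr_ <- qr(m)
    rot <- qr.Q(qr_)
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    shift <- stats::runif(3, -5, 5)
  })
  list(rotation = rot, shift = shift)
}

apply_transform_to_ensemble <- function(ensemble, tf) {
  ensemble$conformers <- lapply(ensemble$conformers, function(cf) {
    sweep(cf %*% t(tf$rotation), 2, tf$shift, `+`)
  })
  ensemble
}

# Blocks-shaped tibble without chemistry validation, for enumeration tests.
fake_blocks <- function(ids) {
  tibble::tibble(id = ids, name = ids,
                 residue_smiles = "NCC(=O)", stereo_tag = "achiral",
                 manual_addition = FALSE)
}
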