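# Conformer ensembles: generation (systematic rotor scan + force-field
# minimisation through OpenBabel), rigid-body core alignment (Kabsch), and
# energy/RMSD pruning. The aligned ensemble is the averaging domain for the
# grid descriptors.

#' Construct a conformer ensemble
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param conformers List of n_atoms x 3 coordinate matrices (Angstrom).
#' @param energies Numeric vector of relative energies (kcal/mol), one per
#'   conformer; defaults to zeros.
#' @param charges Optional per-atom partial charges (elementary charge).
#' @param core_atoms Integer indices of the alignment-core atoms.
#' @param label Molecule label.
#' @return A `conformer_ensemble` object.
#' @export
conformer_ensemble <- function(elements, conformers, energies = NULL,
                               charges = NULL, core_atoms = NULL,
                               label = "molecule") {
  stopifnot(is.list(conformers), length(conformers) >= 1)
  n_atoms <- length(elements)
  for (cf in conformers) {
    if (!is.matrix(cf) || nrow(cf) != n_atoms || ncol(cf) != 3) {
      stop("each conformer must be an n_atoms x 3 coordinate matrix", call. = FALSE)
    }
  }
  energies <- energies %||% rep(0, length(conformers))
  stopifnot(length(energies) == length(conformers), all(is.finite(energies)))
  if (!is.null(charges) && length(charges) != n_atoms) {
    stop("charge vector length (", length(charges),
         ") does not match atom count (", n_atoms, ")", call. = FALSE)
  }
  if (!is.null(core_atoms)) {
    stopifnot(all(core_atoms >= 1), all(core_atoms <= n_atoms))
  }
  structure(list(
    label = label, elements = elements,
    conformers = lapply(conformers, unname),
    energies = energies - min(energies),
    charges = charges, core_atoms = core_atoms,
    reference_core = NULL
  ), class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %s: %d atoms, %d conformers, span %.2f kcal/mol\n",
              x$label, length(x$elements), length(x$conformers),
              diff(range(x$energies))))
  invisible(x)
}

n_conformers <- function(ensemble) length(ensemble$conformers)

#' Tidy a conformer ensemble into a long tibble
#'
#' @param x A `conformer_ensemble`.
#' @param ... Unused.
#' @return A tibble with one row per atom per conformer.
#' @export
tidy.conformer_ensemble <- function(x, ...) {
  elements <- x$elements
  energies <- x$energies
  purrr::imap_dfr(x$conformers, function(cf, i) {
    tibble::tibble(conformer = i, atom = seq_along(elements),
                   element = elements,
                   x = cf[, 1], y = cf[, 2], z = cf[, 3],
                   energy = energies[i])
  })
}

#' Generate a conformer ensemble for a peptide
#'
#' Embeds `n_embed` conformers by seeded distance-geometry embedding
#' (ETKDG), minimises each with the MMFF94 force field (UFF where MMFF94
#' parameters are missing), records relative energies and Gasteiger partial
#' charges, and prunes with [prune_ensemble()]. The whole pipeline is
#' deterministic for a fixed seed: two calls with the same inputs give
#' bit-identical coordinates.
#'
#' @param mol A `peptide_mol` (from [assemble_peptide()]) or a SMILES string.
#' @param n_embed Number of distance-geometry embeddings (default 200).
#' @param seed Embedding random seed (default 42).
#' @param energy_window Relative-energy window in kcal/mol (default 5).
#' @param rmsd_threshold RMSD dedup threshold in Angstrom (default 0.5).
#' @param minimize_steps Force-field minimisation iteration cap (default 500).
#' @return A `conformer_ensemble` with charges and (for `peptide_mol` input)
#'   the N-terminal-residue core atoms set, ready for [align_to_core()].
#' @export
generate_ensemble <- function(mol, n_embed = 200, seed = 42,
                              energy_window = 5, rmsd_threshold = 0.5,
                              minimize_steps = 500) {
  stopifnot(n_embed >= 1)
  if (is.character(mol)) {
    mol <- list(label = "molecule", smiles = mol, core_atoms = NULL)
  }
  dir <- tempfile("confgen"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  sdf <- run_embedding_backend(mol$smiles, mol$label, n_embed = n_embed,
                               seed = seed, max_iters = minimize_steps,
                               dir = dir)
  parsed <- read_conformer_sdf(sdf)
  ens <- conformer_ensemble(
    elements = parsed$records[[1]]$elements,
    conformers = lapply(parsed$records, `[[`, "coords"),
    energies = parsed$energies,
    charges = parsed$charges,
    core_atoms = mol$core_atoms,
    label = mol$label
  )
  ens$provenance <- list(n_embed = n_embed, seed = seed,
                         energy_window = energy_window,
                         rmsd_threshold = rmsd_threshold,
                         minimize_steps = minimize_steps,
                         forcefield = parsed$forcefield)
  prune_ensemble(ens, energy_window = energy_window,
                 rmsd_threshold = rmsd_threshold)
}

# Optimal rigid superposition (Kabsch): rotation + translation mapping
# `moving` onto `fixed` (both m x 3) in the least-squares sense.
kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  a <- sweep(moving, 2, cm); b <- sweep(fixed, 2, cf)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = rot, center_moving = cm, center_fixed = cf)
}

apply_rigid <- function(coords, tf) {
  sweep(sweep(coords, 2, tf$center_moving) %*% t(tf$rotation), 2,
        tf$center_fixed, `+`)
}

#' Pairwise heavy-coordinate RMSD after optimal superposition
#'
#' @param a,b n x 3 coordinate matrices over the same atoms.
#' @param superpose Rigidly superpose `a` onto `b` first (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
conformer_rmsd <- function(a, b, superpose = TRUE) {
  if (superpose) a <- apply_rigid(a, kabsch(a, b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Align an ensemble onto a common core
#'
#' Rigidly transforms every conformer so that the RMSD of the core atoms to a
#' reference core geometry is minimised; non-core atoms are carried along.
#' The core defaults to the ensemble's own `core_atoms` (the N-terminal
#' residue, as set by the assembler). The reference geometry defaults to the
#' core of the ensemble's first conformer, so aligning a set of catalysts to
#' one persisted reference means passing the same `reference` to each.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param core Integer atom indices of the core (default `ensemble$core_atoms`).
#' @param reference A |core| x 3 matrix of reference core coordinates, or
#'   `NULL` to use the first conformer's core.
#' @param core_smarts Optional SMARTS pattern checked against `smiles` for
#'   presence of the core motif; zero matches is an error, multiple matches
#'   are resolved to the construction-order (N-terminal) match.
#' @param smiles SMILES for the `core_smarts` check.
#' @return The aligned `conformer_ensemble`, with `reference_core` recorded.
#' @export
align_to_core <- function(ensemble, core = ensemble$core_atoms,
                          reference = NULL, core_smarts = NULL, smiles = NULL) {
  if (!is.null(core_smarts)) {
    stopifnot(!is.null(smiles))
    n_match <- count_smarts_matches(smiles, core_smarts)
    if (n_match == 0) {
      stop("molecule '", ensemble$label, "' lacks the core motif '",
           core_smarts, "'", call. = FALSE)
    }
    # multiple matches: the documented tie-break keeps the match containing
    # the N-terminal nitrogen, which is the construction-order core below
  }
  if (is.null(core)) stop("no core atoms defined for alignment", call. = FALSE)
  stopifnot(all(core >= 1), all(core <= length(ensemble$elements)))
  reference <- reference %||% ensemble$conformers[[1]][core, , drop = FALSE]
  stopifnot(nrow(reference) == length(core))
  ensemble$conformers <- lapply(ensemble$conformers, function(cf) {
    tf <- kabsch(cf[core, , drop = FALSE], reference)
    apply_rigid(cf, tf)
  })
  ensemble$core_atoms <- core
  ensemble$reference_core <- reference
  ensemble
}

#' Prune a conformer ensemble by energy window and RMSD
#'
#' Drops conformers above `min(energy) + energy_window`, then greedily
#' deduplicates by pairwise superposed RMSD in order of increasing energy, so
#' the lower-energy member of any near-duplicate pair is kept. The
#' minimum-energy conformer always survives. RMSD is computed over heavy
#' atoms when the ensemble carries explicit hydrogens (the usual convention:
#' methyl-rotor hydrogen permutations do not make a new conformer).
#'
#' @param ensemble A `conformer_ensemble`.
#' @param energy_window Window above the minimum energy, kcal/mol (>= 0).
#' @param rmsd_threshold Dedup threshold in Angstrom (>= 0).
#' @return The pruned `conformer_ensemble`.
#' @export
prune_ensemble <- function(ensemble, energy_window = 5, rmsd_threshold = 0.5) {
  stopifnot(energy_window >= 0, rmsd_threshold >= 0)
  heavy <- which(ensemble$elements != "H")
  if (length(heavy) == 0) heavy <- seq_along(ensemble$elements)
  rel <- ensemble$energies - min(ensemble$energies)
  keep_e <- which(rel <= energy_window)
  ord <- keep_e[order(rel[keep_e])]
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    if (rmsd_threshold > 0) {
      for (j in kept) {
        if (conformer_rmsd(ensemble$conformers[[i]][heavy, , drop = FALSE],
                           ensemble$conformers[[j]][heavy, , drop = FALSE]) <
            rmsd_threshold) {
          dup <- TRUE; break
        }
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  kept <- sort(kept)
  ensemble$conformers <- ensemble$conformers[kept]
  ensemble$energies <- rel[kept]
  ensemble
}

#' Conformer averaging weights
#'
#' Uniform by default (the published convention for average-occupancy
#' descriptors); optionally Boltzmann-weighted by relative energy.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param weighting `"uniform"` or `"boltzmann"`.
#' @param temperature Temperature in K for Boltzmann weighting.
#' @return Numeric weights summing to 1, one per conformer.
#' @export
conformer_weights <- function(ensemble, weighting = c("uniform", "boltzmann"),
                              temperature = 293.15) {
  weighting <- match.arg(weighting)
  n <- n_conformers(ensemble)
  if (weighting == "uniform") return(rep(1 / n, n))
  w <- exp(-ensemble$energies / (R_GAS_KCAL * temperature))
  w / sum(w)
}

#' Write an ensemble to an XYZ-format file
#'
#' One XYZ frame per conformer, energy in the comment line.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_xyz <- function(ensemble, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(n_conformers(ensemble))) {
    cf <- ensemble$conformers[[i]]
    writeLines(c(
      as.character(length(ensemble$elements)),
      sprintf("%s conformer %d energy %.4f kcal/mol", ensemble$label, i,
              ensemble$energies[i]),
      sprintf("%-3s %12.6f %12.6f %12.6f", ensemble$elements,
              cf[, 1], cf[, 2], cf[, 3])
    ), con)
  }
  invisible(path)
}
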