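# Synthetic-data generators: toy amino-acid building blocks, latent-linear
# selectivity landscapes over descriptor space, and trial-reaction datasets
# with the screening-campaign shape (bimodal conversions, wide ee/dr spread).
# These define the study conditions every stage is tested under without any
# external download.

#' Generate toy amino-acid building blocks
#'
#' Constructs `n` structurally distinct, chemically valid residues in the
#' package residue dialect by combining backbone families (glycine-type with
#' L/D alpha stereocentres, proline-type rings) with side chains of varying
#' length, polarity, charge-bearing groups and halogenation. Block 1 is
#' always the minimal glycine residue; the remainder are drawn in a
#' seed-reproducible order.
#'
#' @param n Number of residues (1 to ~190).
#' @param seed RNG seed for the draw order.
#' @return A validated building-block tibble (`toy001`...).
#' @export
make_toy_building_blocks <- function(n, seed = 1) {
  stopifnot(n >= 1)
  terminals <- c("", "O", "N", "F", "Cl", "Br", "OC", "SC", "C(=O)O",
                 "C(=O)N", "#N")
  chains <- purrr::map(1:8, function(len) {
    purrr::map_chr(terminals, function(tm) paste0(strrep("C", len), tm))
  })
  side <- unique(unlist(chains))
  gly_type <- purrr::map(side, function(s) {
    list(
      list(smiles = sprintf("N[C@@H](%s)C(=O)", s), tag = "L",
            name = paste0("L-2-amino(", s, ")acetic")),
      list(smiles = sprintf("N[C@H](%s)C(=O)", s), tag = "D",
            name = paste0("D-2-amino(", s, ")acetic"))
    )
  })
  ring_type <- list(
    list(smiles = "N1CCC[C@H]1C(=O)", tag = "L", name = "L-proline"),
    list(smiles = "N1CCC[C@@H]1C(=O)", tag = "D", name = "D-proline"),
    list(smiles = "N1CCCC[C@H]1C(=O)", tag = "L", name = "L-pipecolic"),
    list(smiles = "N1CCC[C@]1(C)C(=O)", tag = "L", name = "alpha-methyl-L-proline"),
    list(smiles = "N1C[C@H](F)C[C@H]1C(=O)", tag = "L", name = "(4S)-fluoro-L-proline"),
    list(smiles = "N1C[C@@H](F)C[C@H]1C(=O)", tag = "L", name = "(4R)-fluoro-L-proline"),
    list(smiles = "N1C[C@H](O)C[C@H]1C(=O)", tag = "L", name = "(4S)-hydroxy-L-proline"),
    list(smiles = "N1C[C@H](N=[N+]=[N-])C[C@H]1C(=O)", tag = "L",
         name = "(4S)-azido-L-proline")
  )
  candidates <- c(unlist(gly_type, recursive = FALSE), ring_type)
  if (n - 1 > length(candidates)) {
    stop("at most ", length(candidates) + 1, " toy building blocks are available",
         call. = FALSE)
  }
  picked <- withr::with_seed(seed, sample(candidates, n - 1))
  rows <- c(list(list(smiles = "NCC(=O)", tag = "achiral", name = "glycine")),
            picked)
  out <- tibble::tibble(
    id = sprintf("toy%03d", seq_len(n)),
    name = purrr::map_chr(rows, "name"),
    residue_smiles = purrr::map_chr(rows, "smiles"),
    stereo_tag = purrr::map_chr(rows, "tag"),
    manual_addition = FALSE
  )
  validate_building_blocks(out, check_structures = FALSE)
}

#' Generate a synthetic reduced descriptor space
#'
#' Standard-normal principal-component scores for a set of catalysts; the
#' latent space the selectivity landscape is linear in.
#'
#' @param labels Catalyst labels (rownames of the result), or an integer
#'   count.
#' @param n_components Number of components (default 20).
#' @param seed RNG seed.
#' @return Matrix of scores with columns `pc1`...
#' @export
simulate_feature_space <- function(labels, n_components = 20, seed = 1) {
  if (is.numeric(labels) && length(labels) == 1) {
    labels <- sprintf("pep%04d", seq_len(labels))
  }
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(length(labels) * n_components),
                nrow = length(labels),
                dimnames = list(labels, paste0("pc", seq_len(n_components))))
  })
  m
}

#' Define a synthetic selectivity landscape
#'
#' @param weights Latent weight vector over the reduced-space components
#'   (kcal/mol per unit score).
#' @param noise_sd Gaussian noise SD on DDG, kcal/mol (>= 0).
#' @param planted_optimum Offset the member with the largest noiseless
#'   `|DDG|` to `planted_ddg`?
#' @param planted_ddg The planted maximum DDG in kcal/mol.
#' @param temperature Temperature in K for the ee conversion.
#' @param seed RNG seed for the noise draw.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(weights, noise_sd = 0.1, planted_optimum = FALSE,
                           planted_ddg = NULL, temperature = 293.15, seed = 1) {
  stopifnot(all(is.finite(weights)), noise_sd >= 0)
  structure(list(weights = as.numeric(weights), noise_sd = noise_sd,
                 planted_optimum = planted_optimum, planted_ddg = planted_ddg,
                 temperature = temperature, seed = seed),
            class = "landscape_spec")
}

#' Simulate selectivities over a descriptor space
#'
#' `DDG = X w + noise`; optionally one member (the noiseless argmax) is
#' offset to a configured maximum. DDG is converted to ee with the inverse
#' free-energy transform and clamped to +/-0.999 so the log-ratio stays
#' finite.
#'
#' @param features Matrix of reduced-space scores, rownames = labels.
#' @param spec A [landscape_spec()].
#' @return A tibble of records (`catalyst_label`, `ddg_true`, `ddg`, `ee`,
#'   `temperature`).
#' @export
simulate_selectivity <- function(features, spec) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == length(spec$weights))
  if (is.null(rownames(features))) {
    rownames(features) <- sprintf("pep%04d", seq_len(nrow(features)))
  }
  ddg_true <- as.numeric(features %*% spec$weights)
  if (isTRUE(spec$planted_optimum)) {
    target <- spec$planted_ddg %||% (max(abs(ddg_true)) * 1.2)
    ddg_true[which.max(abs(ddg_true))] <- target
  }
  noise <- withr::with_seed(spec$seed,
                            stats::rnorm(length(ddg_true), sd = spec$noise_sd))
  ddg <- ddg_true + noise
  # tanh already keeps |ee| < 1; the cap only guards the inverse transform
  # against floating-point saturation without censoring the landscape
  ee_cap <- 1 - 1e-9
  ee <- pmin(pmax(ddg_to_ee(ddg, spec$temperature), -ee_cap), ee_cap)
  tibble::tibble(
    catalyst_label = rownames(features),
    ddg_true = ddg_true,
    ddg = ddg,
    ee = ee,
    temperature = spec$temperature
  )
}

#' Simulate a trial-reaction screening dataset
#'
#' Full cross of catalysts x reactions with the shape of a primary screen:
#' conversions from a three-component mixture (about a quarter below 10%,
#' half between 10% and 90%, a quarter above 90%), ee uniform on
#' [0.10, 0.98], and dr syn fractions uniform on [0.58, 0.98].
#'
#' @param n_catalysts,n_reactions Positive counts (defaults 50 and 4).
#' @param seed RNG seed.
#' @param temperature Temperature in K.
#' @return A tibble with one row per catalyst x reaction: `catalyst_label`,
#'   `reaction_id`, `conversion`, `ee`, `dr_syn`, `dr_anti`, `temperature`.
#' @export
make_trial_dataset <- function(n_catalysts = 50, n_reactions = 4, seed = 1,
                               temperature = 293.15) {
  stopifnot(n_catalysts >= 1, n_reactions >= 1)
  grid <- tidyr::expand_grid(
    catalyst_label = sprintf("pep%03d", seq_len(n_catalysts)),
    reaction_id = sprintf("rxn%d", seq_len(n_reactions))
  )
  n <- nrow(grid)
  withr::with_seed(seed, {
    comp <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.50, 0.25))
    conversion <- ifelse(comp == 1, stats::runif(n, 0, 10),
                  ifelse(comp == 2, stats::runif(n, 10, 90),
                                    stats::runif(n, 90, 100)))
    ee <- stats::runif(n, 0.10, 0.98)
    dr_syn <- stats::runif(n, 0.58, 0.98)
  })
  dplyr::mutate(grid,
    conversion = conversion,
    ee = ee,
    dr_syn = dr_syn,
    dr_anti = 1 - dr_syn,
    temperature = temperature
  )
}
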