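# Amino-acid building blocks, tripeptide assembly, and combinatorial
# enumeration of the in-silico catalyst library.
#
# Residue dialect: `residue_smiles` is the SMILES fragment of one residue
# written N -> C. Its two attachment points are annotated positionally -- the
# string must BEGIN with the backbone amine nitrogen and END with the backbone
# carbonyl carbon written `C(=O)`. Peptides are then assembled by pure
# concatenation: each residue's trailing carbonyl carbon bonds to the next
# residue's leading nitrogen, forming the amide bond, and the C-terminal cap
# is appended as `N` (primary amide) or `O` (free acid). This positional
# annotation is explicit rather than inferred, so noncanonical backbones
# (Pip, MePro, 4-substituted Pro) need no template matching.

BLOCK_COLUMNS <- c("id", "name", "residue_smiles", "stereo_tag", "manual_addition")
STEREO_TAGS <- c("L", "D", "achiral")

residue_format_ok <- function(smiles) {
  grepl("^(N|\\[N[^]]*\\])", smiles) & grepl("C\\(=O\\)$", smiles)
}

#' Validate a building-block table
#'
#' Checks the five-column contract (`id`, `name`, `residue_smiles`,
#' `stereo_tag`, `manual_addition`), id uniqueness, stereo tags, the
#' residue-dialect attachment annotation, and -- via OpenBabel -- that every
#' residue parses to a valid molecular graph once capped as a free acid.
#'
#' @param blocks A data frame of building blocks.
#' @param check_structures Parse every structure with the chemistry toolkit
#'   (slower; requires OpenBabel). Default `TRUE`.
#' @return The validated blocks as a tibble (invisibly the same data).
#' @export
validate_building_blocks <- function(blocks, check_structures = TRUE) {
  missing <- setdiff(BLOCK_COLUMNS, names(blocks))
  if (length(missing) > 0) {
    stop("building-block table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  blocks <- tibble::as_tibble(blocks)[BLOCK_COLUMNS]
  blocks$manual_addition <- as.logical(blocks$manual_addition)
  dup <- unique(blocks$id[duplicated(blocks$id)])
  if (length(dup) > 0) {
    stop("duplicate building-block id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_tag <- !blocks$stereo_tag %in% STEREO_TAGS
  if (any(bad_tag)) {
    stop("invalid stereo_tag in row(s) ", paste(which(bad_tag), collapse = ", "),
         " (must be one of L, D, achiral)", call. = FALSE)
  }
  bad_fmt <- !residue_format_ok(blocks$residue_smiles)
  if (any(bad_fmt)) {
    stop("residue_smiles must start at the backbone N and end with 'C(=O)'; ",
         "offending row(s): ", paste(which(bad_fmt), collapse = ", "),
         call. = FALSE)
  }
  if (check_structures) {
    ok <- smiles_is_valid(paste0(blocks$residue_smiles, "O"))
    if (any(!ok)) {
      stop("unparsable residue structure(s) in row(s): ",
           paste(which(!ok), collapse = ", "), " (id: ",
           paste(blocks$id[!ok], collapse = ", "), ")", call. = FALSE)
    }
  }
  blocks
}

#' Load amino-acid building blocks from CSV
#'
#' Reads a building-block table (columns `id`, `name`, `residue_smiles`,
#' `stereo_tag`, `manual_addition`) and validates it with
#' [validate_building_blocks()].
#'
#' @param path Path to the CSV file.
#' @param check_structures Parse every structure with OpenBabel.
#' @return A validated tibble of building blocks.
#' @export
load_building_blocks <- function(path, check_structures = TRUE) {
  if (!file.exists(path)) stop("building-block file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_building_blocks(raw, check_structures = check_structures)
}

#' Built-in demonstration building blocks
#'
#' A small set of proline-family and polar residues from the Pro-Pro-Xaa
#' catalyst literature (D-/L-proline, pipecolic acid, alpha-methyl-proline,
#' (4S)-fluoro- and (4S)-azido-proline, glycine, alanine, glutamic acid,
#' glutamine), in the package residue dialect.
#'
#' @return A tibble of building blocks.
#' @export
demo_building_blocks <- function() {
  tibble::tribble(
    ~id,     ~name,                      ~residue_smiles,                           ~stereo_tag, ~manual_addition,
    "dPro",  "D-proline",                "N1CCC[C@@H]1C(=O)",                       "D",  FALSE,
    "Pro",   "L-proline",                "N1CCC[C@H]1C(=O)",                        "L",  FALSE,
    "Pip",   "L-pipecolic acid",         "N1CCCC[C@H]1C(=O)",                       "L",  FALSE,
    "MePro", "alpha-methyl-L-proline",   "N1CCC[C@]1(C)C(=O)",                      "L",  FALSE,
    "Flp",   "(4S)-fluoro-L-proline",    "N1C[C@H](F)C[C@H]1C(=O)",                 "L",  FALSE,
    "Azp",   "(4S)-azido-L-proline",     "N1C[C@H](N=[N+]=[N-])C[C@H]1C(=O)",       "L",  FALSE,
    "Gly",   "glycine",                  "NCC(=O)",                                 "achiral", FALSE,
    "Ala",   "L-alanine",                "N[C@@H](C)C(=O)",                         "L",  FALSE,
    "Glu",   "L-glutamic acid",          "N[C@@H](CCC(=O)O)C(=O)",                  "L",  TRUE,
    "Gln",   "L-glutamine",              "N[C@@H](CCC(=O)N)C(=O)",                  "L",  FALSE
  )
}

peptide_label <- function(res_ids, c_terminus = c("amide", "acid")) {
  c_terminus <- match.arg(c_terminus)
  cap <- if (c_terminus == "amide") "NH2" else "OH"
  paste0("H-", paste(res_ids, collapse = "-"), "-", cap)
}

peptide_smiles <- function(res_smiles, c_terminus = c("amide", "acid")) {
  c_terminus <- match.arg(c_terminus)
  paste0(paste(res_smiles, collapse = ""),
         if (c_terminus == "amide") "N" else "O")
}

#' Enumerate the combinatorial tripeptide library
#'
#' Builds every tripeptide with a fixed first residue and all ordered pairs
#' from `pool` at positions 2 and 3: `|pool|^2` members, ordered
#' lexicographically by (position-2 id, position-3 id) for reproducible
#' indexing.
#'
#' @param blocks Validated building-block tibble containing `fixed_first` and
#'   every pool member.
#' @param fixed_first Id of the fixed N-terminal residue (default `"dPro"`).
#' @param pool Character vector of building-block ids for positions 2-3;
#'   defaults to all ids in `blocks`.
#' @param c_terminus `"amide"` (default, H-Xaa-Xaa-Xaa-NH2) or `"acid"`.
#' @return A `catalyst_library` tibble with columns `label`, `res1`, `res2`,
#'   `res3`, `smiles`, and attributes `pool_size` and `provenance`.
#' @export
enumerate_library <- function(blocks, fixed_first = "dPro",
                              pool = blocks$id, c_terminus = c("amide", "acid")) {
  c_terminus <- match.arg(c_terminus)
  if (length(pool) == 0) stop("building-block pool is empty", call. = FALSE)
  unknown <- setdiff(c(fixed_first, pool), blocks$id)
  if (length(unknown) > 0) {
    stop("unknown building-block id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pool <- sort(unique(pool))
  smi <- stats::setNames(blocks$residue_smiles, blocks$id)
  grid <- tidyr::expand_grid(res2 = pool, res3 = pool) # res2 varies slowest
  lib <- tibble::tibble(
    label = peptide_label_vec(fixed_first, grid$res2, grid$res3, c_terminus),
    res1 = fixed_first, res2 = grid$res2, res3 = grid$res3,
    smiles = paste0(smi[fixed_first], smi[grid$res2], smi[grid$res3],
                    if (c_terminus == "amide") "N" else "O")
  )
  if (anyDuplicated(lib$label)) stop("duplicate peptide labels in library", call. = FALSE)
  structure(lib,
            pool_size = length(pool),
            provenance = list(fixed_first = fixed_first, pool = pool,
                              c_terminus = c_terminus),
            class = c("catalyst_library", class(lib)))
}

peptide_label_vec <- function(r1, r2, r3, c_terminus) {
  cap <- if (c_terminus == "amide") "NH2" else "OH"
  paste0("H-", r1, "-", r2, "-", r3, "-", cap)
}

#' Assemble a tripeptide from residue ids
#'
#' Joins the three residues N to C by amide bonds, leaves the N-terminus a
#' free amine, and caps the C-terminus as a primary amide (default) or free
#' acid. The result records the SMILES, the OpenBabel molecular formula, and
#' the index range of the N-terminal-residue atoms (the alignment core):
#' the assembler defines SMILES atom order, which OpenBabel preserves.
#'
#' @param res_ids Character vector of exactly 3 building-block ids, N to C.
#' @param blocks Validated building-block tibble.
#' @param c_terminus `"amide"` or `"acid"`.
#' @return A `peptide_mol` object (list with `label`, `smiles`, `formula`,
#'   `residues`, `core_atoms`).
#' @export
assemble_peptide <- function(res_ids, blocks, c_terminus = c("amide", "acid")) {
  c_terminus <- match.arg(c_terminus)
  if (length(res_ids) != 3) stop("a tripeptide needs exactly 3 residues", call. = FALSE)
  unknown <- setdiff(res_ids, blocks$id)
  if (length(unknown) > 0) {
    stop("unknown residue id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  smi_map <- stats::setNames(blocks$residue_smiles, blocks$id)
  frags <- unname(smi_map[res_ids])
  smiles <- peptide_smiles(frags, c_terminus)
  if (!smiles_is_valid(smiles)) {
    stop("assembled peptide is not a valid molecule (valence or ring error): ",
         smiles, call. = FALSE)
  }
  structure(list(
    label = peptide_label(res_ids, c_terminus),
    smiles = smiles,
    formula = molecular_formula(smiles),
    residues = res_ids,
    c_terminus = c_terminus,
    core_atoms = seq_len(smiles_heavy_atom_count(frags[1]))
  ), class = "peptide_mol")
}

#' @export
print.peptide_mol <- function(x, ...) {
  cat("<peptide_mol> ", x$label, "\n", sep = "")
  cat("  smiles:  ", x$smiles, "\n", sep = "")
  cat("  formula: ", x$formula, "\n", sep = "")
  cat("  core atoms (N-terminal residue): 1-", max(x$core_atoms), "\n", sep = "")
  invisible(x)
}

#' @export
print.catalyst_library <- function(x, ...) {
  cat(sprintf("<catalyst_library> %d tripeptides (pool of %d at positions 2-3)\n",
              nrow(x), attr(x, "pool_size")))
  NextMethod()
}

#' Write a library manifest CSV
#'
#' @param library A `catalyst_library`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_library_manifest <- function(library, path) {
  utils::write.csv(as.data.frame(library), path, row.names = FALSE)
  invisible(path)
}
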