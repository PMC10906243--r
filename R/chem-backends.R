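# Chemistry backends. SMILES-level operations (validation, canonicalisation,
# molecular formula, SMARTS counts) run in-process through ChemmineOB
# (OpenBabel). Conformer embedding runs through the RDKit helper script
# shipped in inst/python/ (see generate_ensemble()): seeded distance-geometry
# embedding is the one step the OpenBabel toolchain cannot do reproducibly.
# Nothing here reimplements a file format: SDF I/O goes through ChemmineR.

#' Is the conformer-embedding backend available?
#'
#' Conformer generation shells out to the `python` interpreter with RDKit;
#' SMILES-level operations use ChemmineOB in-process and do not need it.
#'
#' @return `TRUE` if a `python` with importable `rdkit` is on the `PATH`.
#' @export
embedding_backend_available <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) return(FALSE)
  code <- suppressWarnings(system2(py, c("-c", shQuote("import rdkit")),
                                   stdout = FALSE, stderr = FALSE))
  identical(code, 0L)
}

#' Validate SMILES strings
#'
#' Each string is parsed by OpenBabel; strings that fail to produce a molecule
#' are reported invalid. Vectorised over `smiles`.
#'
#' @param smiles Character vector of SMILES.
#' @return Logical vector, `TRUE` where the string parses to a valid molecule.
#' @export
smiles_is_valid <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(logical(0))
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s) || grepl("[[:space:]]", s)) return(FALSE)
    ok <- FALSE
    # ChemmineOB prints parse errors to the console; silence them.
    utils::capture.output({
      suppressWarnings(suppressMessages(
        try({
          can <- ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))
          ok <- nzchar(trimws(can))
        }, silent = TRUE)
      ))
    }, type = "output")
    ok
  }, logical(1), USE.NAMES = FALSE)
}

#' Molecular formula of a SMILES string
#'
#' Hill-order molecular formula with implicit hydrogens, computed by OpenBabel.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of formulas (e.g. `"C6H12N4O3"`).
#' @export
molecular_formula <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  vapply(smiles, function(s) {
    props <- ChemmineOB::forEachMol("SMILES", s, ChemmineOB::prop_OB)
    props[[1]]$formula
  }, character(1), USE.NAMES = FALSE)
}

# Count heavy atoms in a SMILES string without a round trip through the
# toolkit: one per bracket atom, one per organic-subset symbol. Sufficient for
# the restricted residue dialect used by the assembler, where it defines the
# core atom index range (both toolkits preserve SMILES atom order, heavy
# atoms first).
smiles_heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) {
    n_bracket <- lengths(regmatches(s, gregexpr("\\[[^]]+\\]", s)))
    bare <- gsub("\\[[^]]+\\]", "", s)
    n_two <- lengths(regmatches(bare, gregexpr("Cl|Br", bare)))
    bare <- gsub("Cl|Br", "", bare)
    n_one <- lengths(regmatches(bare, gregexpr("[BCNOPSFI]|[bcnops]", bare)))
    n_bracket + n_two + n_one
  }, integer(1), USE.NAMES = FALSE)
}

#' Count substructure matches of a SMARTS pattern
#'
#' @param smiles Single SMILES string.
#' @param smarts SMARTS pattern.
#' @param unique Count unique atom sets only (default) or all mappings.
#' @return Integer match count.
#' @export
count_smarts_matches <- function(smiles, smarts, unique = TRUE) {
  stopifnot(length(smiles) == 1, length(smarts) == 1)
  mols <- ChemmineOB::forEachMol("SMILES", smiles, function(m) m)
  as.integer(ChemmineOB::smartsSearch_OB(mols, smarts, uniqueMatches = unique))
}

# Run the RDKit embedding helper for one molecule; returns the SDF path.
run_embedding_backend <- function(smiles, label, n_embed, seed, max_iters,
                                  dir = tempdir()) {
  if (!embedding_backend_available()) {
    stop("no python interpreter with RDKit on the PATH; ",
         "conformer embedding is unavailable", call. = FALSE)
  }
  script <- system.file("python", "embed_conformers.py", package = "pepcatml",
                        mustWork = TRUE)
  out <- file.path(dir, "conformers.sdf")
  log <- suppressWarnings(system2(
    Sys.which("python"),
    c(shQuote(script), "--smiles", shQuote(smiles), "--label", shQuote(label),
      "--n-embed", n_embed, "--seed", seed, "--max-iters", max_iters,
      "--out", shQuote(out)),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(log, "status") %||% 0L
  if (status != 0L || !file.exists(out)) {
    stop(sprintf("conformer embedding failed for '%s': %s", label,
                 paste(log, collapse = " | ")), call. = FALSE)
  }
  out
}

# Read a multi-record conformer SDF: element symbols, one coordinate matrix
# per record, per-record properties (energies, charges, forcefield).
read_conformer_sdf <- function(sdf_path) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(sdf_path))
  blocks <- ChemmineR::atomblock(sdfs)
  props <- ChemmineR::datablock(sdfs)
  records <- lapply(blocks, function(ab) {
    list(elements = gsub("_.*$", "", rownames(ab)),
         coords = unname(ab[, 1:3, drop = FALSE]))
  })
  # ChemmineR suffixes duplicated property names with " (n) "
  prop_get <- function(p, key) {
    unname(p[grep(paste0("^", key), names(p))][1])
  }
  energies <- vapply(props, function(p) as.numeric(prop_get(p, "energy_kcal")),
                     numeric(1))
  charges <- as.numeric(strsplit(prop_get(props[[1]], "gasteiger_charges"),
                                 " ", fixed = TRUE)[[1]])
  list(records = records, energies = energies, charges = charges,
       forcefield = prop_get(props[[1]], "forcefield"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
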