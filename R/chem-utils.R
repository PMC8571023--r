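# Low-level molecule handling on top of ChemmineOB (OpenBabel). Each
# SMILES is parsed once and all per-molecule work happens inside the
# OpenBabel callback, which keeps parse failures isolated per molecule
# (a batch conversion would abort at the first bad entry) and makes
# bond-less single-atom molecules (e.g. methane) first-class citizens,
# which the SDF round trip does not.

# Apply fn(obmolRef) to each SMILES individually; returns a list with one
# element per input, NULL where the SMILES failed to parse to a molecule
# with at least one atom.
.obApply <- function(smiles, fn) {
  lapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    out <- NULL
    ok <- tryCatch({
      ChemmineOB::forEachMol("SMILES", s, function(mol) {
        out <<- fn(mol)
      })
      TRUE
    }, error = function(e) FALSE)
    if (!ok) NULL else out
  })
}

.isParseableSmiles <- function(smiles) {
  res <- .obApply(smiles, function(mol)
    ChemmineOB::smartsSearch_OB(list(mol), "[!#1]") >= 1)
  vapply(res, isTRUE, logical(1))
}

# Heavy (non-hydrogen) atom count; NA for unparseable input.
.heavyAtomCount <- function(smiles) {
  res <- .obApply(smiles, function(mol)
    as.integer(ChemmineOB::smartsSearch_OB(list(mol), "[!#1]")))
  vapply(res, function(x) if (is.null(x)) NA_integer_ else x, integer(1))
}

# Count embeddings of one or more SMARTS patterns (unique atom sets) in
# each molecule: returns a length(smiles) x length(patterns) integer
# matrix. All patterns for a molecule are evaluated on a single parse.
.smartsCountMatrix <- function(smiles, patterns, unique = TRUE) {
  res <- .obApply(smiles, function(mol) {
    vapply(patterns, function(p) {
      n <- tryCatch(
        ChemmineOB::smartsSearch_OB(list(mol), p, uniqueMatches = unique),
        error = function(e) stop("invalid SMARTS pattern: ", p,
                                 call. = FALSE))
      as.integer(n)
    }, integer(1))
  })
  bad <- vapply(res, is.null, logical(1))
  if (any(bad))
    stop("unparseable SMILES at position(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  out <- do.call(rbind, res)
  dimnames(out) <- list(NULL, names(patterns))
  out
}

.smartsCountSmiles <- function(smiles, ids, smarts, unique = TRUE) {
  stats::setNames(as.integer(.smartsCountMatrix(smiles, smarts,
                                                unique = unique)), ids)
}

# OpenBabel descriptor block (MW, logP, TPSA, HBA/HBD variants, canonical
# SMILES) per molecule.
.obProperties <- function(smiles) {
  res <- .obApply(smiles, function(mol) ChemmineOB::prop_OB(list(mol)))
  bad <- vapply(res, is.null, logical(1))
  if (any(bad))
    stop("unparseable SMILES at position(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  do.call(rbind, res)
}

# Path (FP2) fingerprint matrix, one row per molecule.
.obPathFingerprint <- function(smiles) {
  res <- .obApply(smiles, function(mol)
    as.numeric(ChemmineOB::fingerprint_OB(list(mol), "FP2")))
  bad <- vapply(res, is.null, logical(1))
  if (any(bad))
    stop("unparseable SMILES at position(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  do.call(rbind, res)
}

# Aromatic ring count (smallest set of smallest rings). Ring perception
# runs per molecule on the SDF form; molecules the perception cannot
# handle (e.g. bond-less single atoms) count zero rings.
.aromaticRingCount <- function(smiles) {
  vapply(smiles, function(s) {
    tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(c(mol = s)))
      rc <- ChemmineR::rings(sdf[1], type = "count", arom = TRUE,
                             inner = TRUE)
      if (is.null(dim(rc))) as.integer(rc[["AROMATIC"]])
      else as.integer(rc[1, "AROMATIC"])
    }, error = function(e) 0L)
  }, integer(1), USE.NAMES = FALSE)
}
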