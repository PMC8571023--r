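# Post-processing of MM-PBSA/GBSA end-state output: entropy-enthalpy
# compensation identities, hot-residue calls from per-residue or pairwise
# energy decompositions, and buried surface area from accessible-surface
# triples. No solver is run here; these operate on the summary tables the
# molecular-dynamics packages emit.

#' Gibbs energy from entropy-enthalpy compensation
#'
#' dG = dH - TdS, the identity linking the tabulated enthalpy and entropy
#' components of an end-state free-energy calculation (TdS is the
#' pre-multiplied entropy term in kcal/mol).
#'
#' @param dh enthalpy in kcal/mol.
#' @param tds entropy term T*dS in kcal/mol.
#' @return dG in kcal/mol.
#' @examples
#' gibbsFromCompensation(-34.15, -20.4)
#' @export
gibbsFromCompensation <- function(dh, tds) {
  if (any(!is.finite(dh)) || any(!is.finite(tds)))
    stop("dh and tds must be finite", call. = FALSE)
  dh - tds
}

#' Read an MM-PBSA/GBSA summary table
#'
#' CSV mirroring an end-state summary: \code{compound} plus any of
#' \code{dg_pb, dg_gb, dg_pr, gscore, tds, dh_pb, dh_gb, bsa} (kcal/mol;
#' BSA in A^2). Missing columns/cells are tolerated; the compensation
#' audit skips rows it cannot check.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readThermoTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"compound" %in% names(df))
    stop("thermo table requires a 'compound' column", call. = FALSE)
  df
}

#' Audit entropy-enthalpy compensation
#'
#' Checks, for each compound and each solvation model (PB and GB), that
#' the tabulated dG equals dH - TdS within \code{tol}. Rows lacking any of
#' the three quantities are skipped (reported in the \code{skipped}
#' attribute); an empty result means every checkable identity holds.
#'
#' @param thermo data.frame with columns \code{compound, tds} and
#'   per-model pairs \code{dg_pb/dh_pb}, \code{dg_gb/dh_gb}.
#' @param tol tolerance in kcal/mol (default 0.01, i.e. agreement at
#'   2-decimal printing precision).
#' @return data.frame of violations with columns
#'   \code{compound, model, dg_stated, dg_expected, delta}.
#' @examples
#' tab <- data.frame(compound = "TRA", dg_pb = -2.28, dh_pb = -20.19,
#'                   tds = -17.91)
#' checkCompensation(tab)  # zero rows: identity holds
#' @export
checkCompensation <- function(thermo, tol = 0.01) {
  stopifnot(is.data.frame(thermo), "compound" %in% names(thermo))
  out <- data.frame(compound = character(), model = character(),
                    dg_stated = numeric(), dg_expected = numeric(),
                    delta = numeric(), stringsAsFactors = FALSE)
  skipped <- character()
  for (model in c("pb", "gb")) {
    dgCol <- paste0("dg_", model)
    dhCol <- paste0("dh_", model)
    if (!all(c(dgCol, dhCol, "tds") %in% names(thermo))) {
      skipped <- c(skipped, paste0(model, ": columns missing"))
      next
    }
    ok <- stats::complete.cases(thermo[, c(dgCol, dhCol, "tds")])
    if (any(!ok))
      skipped <- c(skipped, sprintf("%s: %d row(s) with missing values",
                                    model, sum(!ok)))
    sub <- thermo[ok, , drop = FALSE]
    expected <- gibbsFromCompensation(sub[[dhCol]], sub$tds)
    bad <- abs(sub[[dgCol]] - expected) > tol
    if (any(bad))
      out <- rbind(out, data.frame(
        compound = as.character(sub$compound[bad]), model = toupper(model),
        dg_stated = sub[[dgCol]][bad], dg_expected = expected[bad],
        delta = sub[[dgCol]][bad] - expected[bad],
        stringsAsFactors = FALSE))
  }
  if (length(skipped)) attr(out, "skipped") <- skipped
  out
}

#' Read a long-format energy decomposition table
#'
#' Normalized long CSV decoupling analysis from the varying decomposition
#' output dialects: columns \code{compound_id, residue, chain, model,
#' energy}, with \code{model} in \code{pb}/\code{gb} and \code{energy} in
#' kcal/mol. An optional logical \code{pairwise} column marks pairwise
#' (ligand-residue) entries.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
readDecomposition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validateDecomposition(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readDecomposition
#' @param df a data.frame to validate in place of a file.
#' @export
validateDecomposition <- function(df) {
  need <- c("compound_id", "residue", "chain", "model", "energy")
  if (!all(need %in% names(df)))
    stop("decomposition table requires columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(df$model %in% c("pb", "gb")))
    stop("model must be 'pb' or 'gb'", call. = FALSE)
  if (!"pairwise" %in% names(df)) df$pairwise <- logical(nrow(df))
  df
}

#' Call hot residues from an energy decomposition
#'
#' A residue is hot when its energetic contribution reaches the threshold
#' or below (\code{<=}, "threshold and below") under either implicit
#' solvation model -- the per-residue decompositions are plotted for both
#' models, so a residue crossing the threshold in one model alone is
#' still reported. Default thresholds: -3.0 kcal/mol per-residue, -6.0
#' kcal/mol for pairwise decompositions.
#'
#' @param entries long decomposition table (see
#'   \code{\link{readDecomposition}}).
#' @param threshold energetic cutoff in kcal/mol; must be negative.
#'   Defaults by \code{pairwise}.
#' @param pairwise analyze the pairwise rows (default: per-residue rows).
#' @return data.frame with one row per hot residue: \code{compound_id,
#'   residue, chain, dg_pb, dg_gb} (NA when a model has no entry).
#' @examples
#' d <- data.frame(compound_id = "m", residue = c("Lys16", "Tyr10"),
#'                 chain = c("A", "B"), model = "pb",
#'                 energy = c(-3.5, -2.0))
#' hotResidues(d)
#' @export
hotResidues <- function(entries, threshold = NULL, pairwise = FALSE) {
  entries <- validateDecomposition(entries)
  if (is.null(threshold)) threshold <- if (pairwise) -6.0 else -3.0
  if (!is.finite(threshold) || threshold >= 0)
    stop("threshold must be negative", call. = FALSE)
  entries <- entries[entries$pairwise == pairwise, , drop = FALSE]
  if (nrow(entries) == 0)
    return(data.frame(compound_id = character(), residue = character(),
                      chain = character(), dg_pb = numeric(),
                      dg_gb = numeric(), stringsAsFactors = FALSE))
  key <- interaction(entries$compound_id, entries$residue, entries$chain,
                     drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  wide <- data.frame(compound_id = entries$compound_id[first],
                     residue = entries$residue[first],
                     chain = entries$chain[first],
                     dg_pb = NA_real_, dg_gb = NA_real_,
                     stringsAsFactors = FALSE)
  rownames(wide) <- as.character(key[first])
  for (m in c("pb", "gb")) {
    sel <- entries$model == m
    wide[as.character(key[sel]), paste0("dg_", m)] <- entries$energy[sel]
  }
  hot <- (wide$dg_pb <= threshold & !is.na(wide$dg_pb)) |
    (wide$dg_gb <= threshold & !is.na(wide$dg_gb))
  out <- wide[hot, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Buried surface area of a complex
#'
#' BSA = (ASA_pep + ASA_lig - ASA_comp) / 2: half the total accessible
#' surface lost on binding (the loss is split across the two interface
#' faces). A physically valid ASA triple satisfies
#' ASA_comp <= ASA_pep + ASA_lig; a negative BSA beyond \code{tol} is an
#' error, and tiny negative values from numerical round-off are clamped
#' to 0.
#'
#' @param asaPep,asaLig,asaComp accessible surface areas (A^2) of the
#'   free peptide, the free ligand and the complex.
#' @param tol numerical tolerance in A^2.
#' @return BSA in A^2.
#' @examples
#' buriedSurfaceArea(100, 50, 120)
#' @export
buriedSurfaceArea <- function(asaPep, asaLig, asaComp, tol = 1e-6) {
  if (any(asaPep < 0) || any(asaLig < 0) || any(asaComp < 0))
    stop("ASA values must be >= 0", call. = FALSE)
  bsa <- (asaPep + asaLig - asaComp) / 2
  if (any(bsa < -tol))
    stop("invalid ASA triple: complex area exceeds the sum of the parts",
         call. = FALSE)
  pmax(bsa, 0)
}
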