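# Docking post-processing: inhibition constants, ligand efficiency, and
# lead selection against a reference compound.

# Gas constant in kcal/(mol K) and room temperature in K, the constants
# under which tabulated docking energies convert to inhibition constants.
.KI_R <- 1.98e-3
.KI_T <- 298.15

#' Inhibition constant from a binding free energy
#'
#' Ki = exp(dG / (R T)) with R = 1.98e-3 kcal/(mol K) and T = 298.15 K,
#' in mol/L. Strictly increasing in dG: stronger (more negative) binding
#' gives a smaller Ki, and dG = 0 gives 1 M exactly.
#'
#' @param dgBind binding free energy in kcal/mol (may be positive).
#' @return Ki in mol/L.
#' @examples
#' kiFromDg(-6.19) * 1e6  # micromolar
#' @export
kiFromDg <- function(dgBind) {
  if (any(!is.finite(dgBind)))
    stop("dgBind must be finite", call. = FALSE)
  exp(dgBind / (.KI_R * .KI_T))
}

#' Format an inhibition constant for display
#'
#' Auto-scales a molar Ki to the unit a results table would print: M at
#' 0.1 M and above, mM from 1e-3 M, and micromolar below that, with the
#' value rounded half-up to 2 decimals.
#'
#' @param kiMolar Ki in mol/L (positive).
#' @return data.frame with columns \code{ki_value} and \code{ki_unit}
#'   (\code{"uM"}, \code{"mM"} or \code{"M"}).
#' @examples
#' formatKi(kiFromDg(c(-6.19, -3.7, 0.66)))
#' @export
formatKi <- function(kiMolar) {
  if (any(!is.finite(kiMolar)) || any(kiMolar <= 0))
    stop("kiMolar must be positive and finite", call. = FALSE)
  unit <- ifelse(kiMolar >= 0.1, "M", ifelse(kiMolar >= 1e-3, "mM", "uM"))
  scale <- c(M = 1, mM = 1e3, uM = 1e6)[unit]
  data.frame(ki_value = .roundHalfUp(kiMolar * scale, 2), ki_unit = unit,
             stringsAsFactors = FALSE)
}

# round() half-way cases go to even; tables conventionally round half away
# from zero.
.roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Ligand efficiency
#'
#' Binding free energy normalized by heavy-atom count, kcal/mol per
#' non-hydrogen atom. Sign follows the binding energy.
#'
#' @param dgBind binding free energy in kcal/mol.
#' @param nAtm heavy (non-hydrogen) atom count, >= 1.
#' @return LE in kcal/mol per heavy atom.
#' @examples
#' ligandEfficiency(-6.19, 11)
#' @export
ligandEfficiency <- function(dgBind, nAtm) {
  if (any(!is.finite(dgBind))) stop("dgBind must be finite", call. = FALSE)
  if (any(nAtm < 1)) stop("nAtm must be >= 1", call. = FALSE)
  dgBind / nAtm
}

#' Read a docking summary table
#'
#' CSV with columns \code{compound_id, dg_bind, n_atm, n_tor} and optional
#' conformational-cluster statistics \code{cl_rms} (RMS between the top
#' two conformations of the lowest-energy cluster) and \code{cl_rms_a}
#' (mean RMS of all conformations against the lowest-energy one). Empty
#' cells are missing values. Extra columns are carried through.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
readDockingTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateDockingTable(df)
}

#' @rdname readDockingTable
#' @param df a data.frame to validate in place of a file.
#' @export
validateDockingTable <- function(df) {
  need <- c("compound_id", "dg_bind", "n_atm", "n_tor")
  if (!all(need %in% names(df)))
    stop("docking table requires columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$compound_id <- as.character(df$compound_id)
  if (anyDuplicated(df$compound_id))
    stop("duplicate compound_id in docking table", call. = FALSE)
  if (any(!is.finite(df$dg_bind)))
    stop("dg_bind must be finite", call. = FALSE)
  if (any(df$n_atm < 1)) stop("n_atm must be >= 1", call. = FALSE)
  if (any(df$n_tor < 0)) stop("n_tor must be >= 0", call. = FALSE)
  for (col in c("cl_rms", "cl_rms_a")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop(col, " must be >= 0 when present", call. = FALSE)
  }
  df
}

#' Derive binding metrics from a docking table
#'
#' Adds the molar inhibition constant, its display form (value + unit) and
#' the ligand efficiency to every row of a docking summary.
#'
#' @param dock docking table (see \code{\link{readDockingTable}}).
#' @return the table with columns \code{ki_molar, ki_value, ki_unit, le}
#'   appended.
#' @examples
#' bindingMetrics(data.frame(compound_id = "tra", dg_bind = -6.19,
#'                           n_atm = 11, n_tor = 5))
#' @export
bindingMetrics <- function(dock) {
  dock <- validateDockingTable(dock)
  dock$ki_molar <- kiFromDg(dock$dg_bind)
  disp <- formatKi(dock$ki_molar)
  dock$ki_value <- disp$ki_value
  dock$ki_unit <- disp$ki_unit
  dock$le <- ligandEfficiency(dock$dg_bind, dock$n_atm)
  dock
}

#' Select lead compounds against a reference
#'
#' Leads are the compounds whose binding energy is strictly lower (more
#' favorable) than the reference compound's, sorted by ascending binding
#' energy; the reference itself is excluded. No statistical test is
#' applied -- with one docking energy per compound the comparison is a
#' strict inequality.
#'
#' @param dock docking table.
#' @param referenceId compound_id of the reference.
#' @return character vector of lead compound ids.
#' @examples
#' dock <- data.frame(compound_id = c("a", "b", "ref"),
#'                    dg_bind = c(-8, -5, -6), n_atm = 10, n_tor = 2)
#' selectLeads(dock, "ref")
#' @export
selectLeads <- function(dock, referenceId) {
  dock <- validateDockingTable(dock)
  ref <- match(as.character(referenceId), dock$compound_id)
  if (is.na(ref))
    stop("reference compound '", referenceId, "' not in docking table",
         call. = FALSE)
  dgRef <- dock$dg_bind[ref]
  leads <- dock[dock$dg_bind < dgRef & dock$compound_id !=
                  dock$compound_id[ref], , drop = FALSE]
  leads$compound_id[order(leads$dg_bind)]
}
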