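# Orchestration: run the full screen over a library plus docking and
# descriptor tables, and regenerate every derived quantity of the packaged
# study tables for validation.

#' Run the full scaffold screen
#'
#' Executes the pipeline stages in order: scaffold filter, similarity of
#' each hit to the scaffold reference, binding metrics (Ki, LE), logBB
#' profile, and lead selection against the reference compound. Any stage
#' failure aborts with the stage name. The report ranks compounds by
#' ascending binding energy (ties: ascending Ki, then id).
#'
#' @param library a \linkS4class{CompoundLibrary}.
#' @param docking docking summary table (see
#'   \code{\link{readDockingTable}}) keyed by \code{compound_id}.
#' @param referenceId id of the reference compound.
#' @param descriptors optional descriptor table with \code{id, alogp,
#'   psa} for the logBB profile; computed from structures when
#'   \code{NULL} and \code{computeMissingDescriptors} is TRUE.
#' @param query a \linkS4class{ScaffoldQuery}.
#' @param similarityReference SMILES used for the Tanimoto column.
#' @param psaMax CNS window upper bound on PSA (A^2).
#' @param computeMissingDescriptors compute descriptors from the hit
#'   structures when no table is supplied.
#' @return a \linkS4class{LeadReport}.
#' @examples
#' lib <- compoundLibrary(c("hit", "ref"),
#'                        c("CC(=O)NCCCS(=O)(=O)O", "NCCCS(=O)(=O)O"))
#' dock <- data.frame(compound_id = c("hit", "ref"),
#'                    dg_bind = c(-7.0, -6.2), n_atm = c(11, 8),
#'                    n_tor = c(5, 4))
#' rep <- runScreen(lib, dock, referenceId = "ref",
#'                  computeMissingDescriptors = FALSE)
#' leadIds(rep)
#' @export
runScreen <- function(library, docking, referenceId, descriptors = NULL,
                      query = defaultScaffoldQuery(),
                      similarityReference = "CCCS(=O)(=O)O",
                      psaMax = 70, computeMissingDescriptors = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("screen stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  hits <- stage("filter", scaffoldFilter(library, query))
  if (length(hits) == 0) {
    warning("no library compound matches the scaffold query")
    return(new("LeadReport",
               table = data.frame(compound_id = character()),
               referenceId = as.character(referenceId),
               leads = character(),
               config = list(query = query@pattern, psaMax = psaMax)))
  }
  docking <- stage("dock-metrics", validateDockingTable(docking))
  keep <- intersect(hits@id, docking$compound_id)
  if (!as.character(referenceId) %in% docking$compound_id)
    stop("screen stage 'select-leads' failed: reference compound '",
         referenceId, "' not in docking table", call. = FALSE)
  simT <- stage("similarity",
                similarityToReference(hits, similarityReference))
  metrics <- stage("dock-metrics",
                   bindingMetrics(docking[docking$compound_id %in%
                                            c(keep, referenceId), ,
                                          drop = FALSE]))
  if (is.null(descriptors) && computeMissingDescriptors)
    descriptors <- stage("descriptors", computeDescriptors(hits))
  tab <- merge(metrics,
               data.frame(compound_id = simT$id, tanimoto = simT$tanimoto,
                          stringsAsFactors = FALSE),
               by = "compound_id", all.x = TRUE)
  if (!is.null(descriptors)) {
    bbb <- stage("bbb", classifyBBB(descriptors, psaMax = psaMax))
    tab <- merge(tab,
                 bbb[, c("id", "alogp", "psa", "logbb_cl", "logbb_ri",
                         "optimal", "psa_cns_ok")],
                 by.x = "compound_id", by.y = "id", all.x = TRUE)
  }
  leads <- stage("select-leads", selectLeads(metrics, referenceId))
  tab$status <- ifelse(tab$compound_id == as.character(referenceId),
                       "reference",
                       ifelse(tab$compound_id %in% leads, "lead", "hit"))
  tab <- tab[order(tab$dg_bind, tab$ki_molar, tab$compound_id), ,
             drop = FALSE]
  rownames(tab) <- NULL
  new("LeadReport", table = tab, referenceId = as.character(referenceId),
      leads = leads,
      config = list(query = query@pattern,
                    similarityReference = similarityReference,
                    psaMax = psaMax))
}

#' @rdname LeadReport-class
#' @export
setMethod("leadIds", "LeadReport", function(object) object@leads)

#' @rdname LeadReport-class
#' @export
setMethod("reportTable", "LeadReport", function(object) object@table)

setMethod("show", "LeadReport", function(object) {
  cat(sprintf("LeadReport: %d compound(s), reference '%s'\n",
              nrow(object@table), object@referenceId))
  cat(sprintf("  leads (dG below reference): %s\n",
              if (length(object@leads)) paste(object@leads,
                                              collapse = ", ")
              else "none"))
  if (nrow(object@table) > 0) {
    cols <- intersect(c("compound_id", "dg_bind", "ki_value", "ki_unit",
                        "le", "tanimoto", "logbb_cl", "logbb_ri",
                        "status"), names(object@table))
    print(utils::head(object@table[, cols], 15))
  }
})

#' Path to a packaged study fixture
#'
#' The package ships the study's printed summary tables as plain CSVs:
#' \describe{
#'   \item{table2_docking.csv}{per-compound docking summary (binding
#'     energy, cluster RMS statistics, heavy-atom and torsion counts) with
#'     the printed Ki/LE/Tanimoto columns for cross-checking.}
#'   \item{table3_descriptors.csv}{descriptors (MW, AlogP, HBA, HBD, PSA,
#'     QED) and printed logBB values for the two lead candidates, the
#'     reference and the CNS-control compound.}
#'   \item{table4_thermo.csv}{MM-PBSA/GBSA energies, entropy, enthalpy
#'     and buried surface areas for leads and reference.}
#'   \item{table1_hits_reconstructed.csv}{SMILES for the 13 hit drugs and
#'     the reference, reconstructed from the compound names (the study
#'     lists structures only as drawings); a stand-in, not a verbatim
#'     export of the original library entries.}
#' }
#'
#' @param file fixture file name; with no argument, lists the available
#'   fixtures.
#' @return a file path (or vector of available names).
#' @examples
#' studyFixture()
#' dock <- readDockingTable(studyFixture("table2_docking.csv"))
#' @export
studyFixture <- function(file = NULL) {
  dir <- system.file("extdata", package = "ScaffoldScreen")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop("no packaged fixture '", file, "'", call. = FALSE)
  path
}

#' Regenerate the study's derived quantities from packaged fixtures
#'
#' Recomputes every derived cell of the packaged summary tables from its
#' printed inputs -- inhibition constants and ligand efficiencies from
#' binding energies, both logBB models from AlogP/PSA, the
#' entropy-enthalpy compensation identities, the two regressions and the
#' lead set -- and compares against the printed values. Printed Ki and LE
#' are accepted within one unit in the last printed digit (the study's
#' own tables were evidently produced from unrounded docking energies);
#' logBB and compensation cells must match exactly after 2-decimal
#' rounding, and regression statistics at their printed precision.
#'
#' @return data.frame with one row per check: \code{table, compound,
#'   quantity, printed, computed, tolerance, pass}.
#' @examples
#' rep <- reproduceStudyTables()
#' all(rep$pass)
#' @export
reproduceStudyTables <- function() {
  rows <- list()
  add <- function(table, compound, quantity, printed, computed,
                  tolerance) {
    rows[[length(rows) + 1]] <<- data.frame(
      table = table, compound = as.character(compound),
      quantity = quantity, printed = printed, computed = computed,
      tolerance = tolerance,
      pass = is.finite(computed) && abs(computed - printed) <=
        tolerance + 1e-12,
      stringsAsFactors = FALSE)
  }

  dock <- readDockingTable(studyFixture("table2_docking.csv"))
  metrics <- bindingMetrics(dock)
  for (k in seq_len(nrow(metrics))) {
    add("docking", metrics$compound_id[k], "ki",
        dock$ki_printed[k],
        metrics$ki_molar[k] * c(uM = 1e6, mM = 1e3, M = 1)[[
          dock$ki_unit_printed[k]]],
        0.01)
    add("docking", metrics$compound_id[k], "ki_unit",
        1, as.numeric(metrics$ki_unit[k] == dock$ki_unit_printed[k]), 0)
    add("docking", metrics$compound_id[k], "le", dock$le_printed[k],
        metrics$le[k], 0.01)
  }

  desc <- utils::read.csv(studyFixture("table3_descriptors.csv"),
                          stringsAsFactors = FALSE)
  bbb <- classifyBBB(desc)
  for (k in seq_len(nrow(bbb))) {
    add("descriptors", bbb$id[k], "logbb_cl", desc$logbb_cl_printed[k],
        .roundHalfUp(bbb$logbb_cl[k], 2), 0)
    add("descriptors", bbb$id[k], "logbb_ri", desc$logbb_ri_printed[k],
        .roundHalfUp(bbb$logbb_ri[k], 2), 0)
  }

  thermo <- readThermoTable(studyFixture("table4_thermo.csv"))
  for (m in c("pb", "gb")) {
    dg <- gibbsFromCompensation(thermo[[paste0("dh_", m)]], thermo$tds)
    for (k in seq_len(nrow(thermo)))
      add("thermo", thermo$compound[k], paste0("dg_", m),
          thermo[[paste0("dg_", m)]][k], .roundHalfUp(dg[k], 2), 0)
  }

  fitRms <- pearsonRegression(dock$n_tor, dock$cl_rms)
  add("regression", "clRMS~Ntor", "r2", 0.78,
      .roundHalfUp(fitRms@r2, 2), 0)
  add("regression", "clRMS~Ntor", "p", 0.02, .roundHalfUp(fitRms@p, 2),
      0)
  fitTle <- pearsonRegression(dock$tanimoto_printed,
                              bindingMetrics(dock)$le)
  add("regression", "LE~T", "p", 0.008, .roundHalfUp(fitTle@p, 3), 0)

  leads <- selectLeads(dock, referenceId = "14")
  add("leads", "set", "n_leads", 2, length(leads), 0)
  add("leads", "set", "identity", 1,
      as.numeric(identical(sort(leads), c("4", "6"))), 0)

  do.call(rbind, rows)
}
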