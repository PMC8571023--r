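#' @import methods
NULL

#' CompoundLibrary: an identified set of small molecules
#'
#' Container for a screening library: parallel vectors of compound
#' identifiers, display names and SMILES strings, plus a provenance tag and
#' a free-form metadata list. All SMILES are checked to parse to a molecular
#' graph with at least one heavy atom at construction time; identifiers must
#' be unique (duplicates signal an upstream problem and are an error, never
#' silently deduplicated).
#'
#' @slot id character vector of unique compound identifiers.
#' @slot name character vector of display names (same length as \code{id}).
#' @slot smiles character vector of SMILES strings.
#' @slot source scalar provenance tag (e.g. the file the library was read
#'   from, or \code{"simulated"}).
#' @slot metadata list of optional annotations (e.g. \code{skipped}, the
#'   number of unparseable records dropped by \code{\link{readLibrary}}, or
#'   \code{planted}, the ground-truth scaffold carriers of a simulated
#'   library).
#'
#' @seealso \code{\link{readLibrary}}, \code{\link{scaffoldFilter}},
#'   \code{\link{simulateLibrary}}
#' @export
setClass("CompoundLibrary",
  representation(
    id = "character",
    name = "character",
    smiles = "character",
    source = "character",
    metadata = "list"
  ),
  prototype(source = NA_character_, metadata = list())
)

setValidity("CompoundLibrary", function(object) {
  msgs <- character()
  n <- length(object@id)
  if (length(object@name) != n || length(object@smiles) != n)
    msgs <- c(msgs, "id, name and smiles must have equal length")
  if (anyDuplicated(object@id))
    msgs <- c(msgs, sprintf("duplicate compound ids: %s",
      paste(unique(object@id[duplicated(object@id)]), collapse = ", ")))
  if (n > 0 && any(!nzchar(object@smiles)))
    msgs <- c(msgs, "empty SMILES string")
  if (length(object@source) != 1)
    msgs <- c(msgs, "source must be a scalar")
  if (length(msgs)) msgs else TRUE
})

#' ScaffoldQuery: a validated substructure query
#'
#' A named SMARTS pattern together with a reference structure the pattern is
#' required to match. The self-match requirement doubles as a compile check:
#' a pattern that does not compile, or that fails to hit its own reference
#' molecule, is rejected at construction time (a configuration error caught
#' before any screening work is done).
#'
#' @slot name query label.
#' @slot pattern SMARTS substructure pattern.
#' @slot reference SMILES of a structure the pattern must match.
#'
#' @seealso \code{\link{scaffoldQuery}}, \code{\link{defaultScaffoldQuery}}
#' @export
setClass("ScaffoldQuery",
  representation(name = "character", pattern = "character",
                 reference = "character"))

setValidity("ScaffoldQuery", function(object) {
  if (length(object@pattern) != 1 || !nzchar(object@pattern))
    return("pattern must be a non-empty scalar")
  if (length(object@reference) != 1 || !nzchar(object@reference))
    return("reference must be a non-empty scalar SMILES")
  TRUE
})

#' FingerprintSet: fixed-length molecular fingerprints
#'
#' A compounds-by-features matrix of non-negative fingerprint values under a
#' single scheme. E-state fingerprints hold per-atom-type counts (or their
#' binarization at > 0); path fingerprints are binary.
#'
#' @slot scheme fingerprint scheme, \code{"estate"} or \code{"path"}.
#' @slot values numeric matrix, one row per compound (rownames are compound
#'   ids), one column per feature.
#' @slot binary whether \code{values} has been binarized at > 0.
#'
#' @seealso \code{\link{eStateFingerprint}}, \code{\link{pathFingerprint}},
#'   \code{\link{tanimoto}}
#' @export
setClass("FingerprintSet",
  representation(scheme = "character", values = "matrix", binary = "logical"))

setValidity("FingerprintSet", function(object) {
  msgs <- character()
  if (!object@scheme %in% c("estate", "path"))
    msgs <- c(msgs, "scheme must be 'estate' or 'path'")
  if (is.null(rownames(object@values)))
    msgs <- c(msgs, "values must have compound ids as rownames")
  if (any(object@values < 0))
    msgs <- c(msgs, "fingerprint values must be non-negative")
  if (object@binary && any(!object@values %in% c(0, 1)))
    msgs <- c(msgs, "binary fingerprints must contain only 0/1")
  if (length(msgs)) msgs else TRUE
})

#' SimilarityMatrix: pairwise Tanimoto similarities
#'
#' Square symmetric matrix of Tanimoto indexes in [0, 1] with unit diagonal.
#'
#' @slot ids ordered compound identifiers.
#' @slot values square numeric matrix of similarities.
#'
#' @seealso \code{\link{tanimotoMatrix}}, \code{\link{hierarchicalCluster}}
#' @export
setClass("SimilarityMatrix",
  representation(ids = "character", values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) != ncol(v) || nrow(v) != length(object@ids))
    msgs <- c(msgs, "values must be square with one row per id")
  else {
    if (any(v < -1e-9 | v > 1 + 1e-9))
      msgs <- c(msgs, "similarities must lie in [0, 1]")
    if (max(abs(v - t(v))) > 1e-9)
      msgs <- c(msgs, "matrix must be symmetric")
    if (nrow(v) > 0 && max(abs(diag(v) - 1)) > 1e-9)
      msgs <- c(msgs, "diagonal must be 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' ClusterTree: an agglomerative clustering of compounds
#'
#' Wraps the merge history of an agglomerative clustering on Tanimoto
#' distance (1 - T) together with the flat assignment obtained by cutting
#' the tree into \code{k} groups.
#'
#' @slot hclust the \code{\link[stats]{hclust}} merge history.
#' @slot k number of groups the tree was cut into.
#' @slot assignments named integer vector mapping each leaf id to its group.
#' @slot linkage agglomeration method used.
#'
#' @seealso \code{\link{hierarchicalCluster}}, \code{\link{treeNewick}}
#' @export
setClass("ClusterTree",
  representation(hclust = "ANY", k = "integer", assignments = "integer",
                 linkage = "character"))

setValidity("ClusterTree", function(object) {
  msgs <- character()
  if (!inherits(object@hclust, "hclust"))
    msgs <- c(msgs, "hclust slot must be an hclust object")
  else if (nrow(object@hclust$merge) != length(object@assignments) - 1L)
    msgs <- c(msgs, "a tree over n leaves must record n - 1 merges")
  if (length(unique(object@assignments)) != object@k)
    msgs <- c(msgs, "cut must yield exactly k non-empty groups")
  if (length(msgs)) msgs else TRUE
})

#' RegressionResult: a simple linear regression with Pearson statistics
#'
#' Ordinary least-squares fit of y on x together with the Pearson
#' correlation r, its square, and the two-tailed p-value from the t-test on
#' r with n - 2 degrees of freedom.
#'
#' @slot n number of complete observation pairs used.
#' @slot slope,intercept OLS coefficients.
#' @slot r Pearson correlation coefficient.
#' @slot r2 coefficient of determination (r squared).
#' @slot p two-tailed p-value.
#'
#' @seealso \code{\link{pearsonRegression}}
#' @export
setClass("RegressionResult",
  representation(n = "integer", slope = "numeric", intercept = "numeric",
                 r = "numeric", r2 = "numeric", p = "numeric"))

setValidity("RegressionResult", function(object) {
  msgs <- character()
  if (object@n < 3) msgs <- c(msgs, "n must be at least 3")
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12)
    msgs <- c(msgs, "r2 must lie in [0, 1]")
  if (abs(object@r^2 - object@r2) > 1e-9)
    msgs <- c(msgs, "r2 must equal r squared")
  if (object@p < 0 || object@p > 1) msgs <- c(msgs, "p must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' LeadReport: the ranked outcome of a screening run
#'
#' Per-compound table of the full screen (binding energy, Ki with display
#' unit, ligand efficiency, Tanimoto similarity to the scaffold, logBB
#' profile and status flags) plus the derived lead set and run metadata.
#' Compounds are ranked by ascending binding energy, ties broken by
#' ascending Ki and then id.
#'
#' @slot table ranked per-compound data.frame.
#' @slot referenceId id of the reference compound leads were called against.
#' @slot leads ids with binding energy strictly below the reference.
#' @slot config list of run settings (query pattern, thresholds, seed).
#'
#' @seealso \code{\link{runScreen}}
#' @export
setClass("LeadReport",
  representation(table = "data.frame", referenceId = "character",
                 leads = "character", config = "list"))

setValidity("LeadReport", function(object) {
  msgs <- character()
  if (!all(object@leads %in% object@table$compound_id))
    msgs <- c(msgs, "leads must be a subset of the reported compounds")
  if (length(object@referenceId) != 1)
    msgs <- c(msgs, "referenceId must be a scalar")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: reproducible settings for the synthetic-data generators
#'
#' Bundles every knob of the synthetic-data module. A fixed seed makes all
#' generator output byte-identical across runs and platforms (Mersenne
#' Twister; each generator draws from its own seed offset so the modules do
#' not perturb one another).
#'
#' @slot seed integer base seed.
#' @slot nMolecules library size for \code{\link{simulateLibrary}}.
#' @slot fracScaffold fraction of the library carrying the planted scaffold.
#' @slot slope,intercept,noiseSd linear model for
#'   \code{\link{simulateRegressionData}} (noise is Normal(0, noiseSd)).
#' @slot nObs number of (x, y) pairs to draw.
#' @slot nResidues,nHot,hotEffect decomposition settings for
#'   \code{\link{simulateDecomposition}}: number of receptor residues,
#'   number planted below the hot-spot threshold, and how far below (in
#'   kcal/mol) their energies are pushed.
#'
#' @seealso \code{\link{simulationConfig}}
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", nMolecules = "integer",
                 fracScaffold = "numeric", slope = "numeric",
                 intercept = "numeric", noiseSd = "numeric", nObs = "integer",
                 nResidues = "integer", nHot = "integer",
                 hotEffect = "numeric"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@fracScaffold < 0 || object@fracScaffold > 1)
    msgs <- c(msgs, "fracScaffold must lie in [0, 1]")
  if (object@nMolecules < 1) msgs <- c(msgs, "nMolecules must be >= 1")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (object@nHot > object@nResidues)
    msgs <- c(msgs, "nHot cannot exceed nResidues")
  if (object@hotEffect < 0) msgs <- c(msgs, "hotEffect must be >= 0")
  if (length(msgs)) msgs else TRUE
})
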