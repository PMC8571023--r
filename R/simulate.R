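# Synthetic inputs with the structure the pipeline assumes: a compound
# library with a known planted fraction of scaffold carriers, regression
# data from a known linear model, and energy decompositions with a known
# hot-residue set. Each generator draws from the Mersenne Twister seeded
# with config seed + a generator-specific offset, so the generators are
# individually reproducible and do not perturb one another (or the
# caller's RNG state, which is saved and restored).

.SEED_OFFSET <- c(library = 101L, regression = 202L, decomposition = 303L)

.withGeneratorSeed <- function(seed, generator, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offset <- .SEED_OFFSET[[generator]]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) + offset, kind = "Mersenne-Twister")
  expr
}

#' @rdname SimulationConfig-class
#' @param seed integer base seed.
#' @param nMolecules,fracScaffold library settings.
#' @param slope,intercept,noiseSd,nObs regression settings.
#' @param nResidues,nHot,hotEffect decomposition settings.
#' @export
simulationConfig <- function(seed = 1L, nMolecules = 20L,
                             fracScaffold = 0.3, slope = 0.1,
                             intercept = 0.2, noiseSd = 0.2, nObs = 50L,
                             nResidues = 42L, nHot = 3L,
                             hotEffect = 1.5) {
  new("SimulationConfig", seed = as.integer(seed),
      nMolecules = as.integer(nMolecules),
      fracScaffold = as.numeric(fracScaffold), slope = as.numeric(slope),
      intercept = as.numeric(intercept), noiseSd = as.numeric(noiseSd),
      nObs = as.integer(nObs), nResidues = as.integer(nResidues),
      nHot = as.integer(nHot), hotEffect = as.numeric(hotEffect))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  seed %d | library n = %d, fracScaffold = %.2f\n",
              object@seed, object@nMolecules, object@fracScaffold))
  cat(sprintf("  regression y = %.3g x + %.3g + N(0, %.3g), n = %d\n",
              object@slope, object@intercept, object@noiseSd,
              object@nObs))
  cat(sprintf("  decomposition %d residues, %d hot (effect %.2f kcal/mol)\n",
              object@nResidues, object@nHot, object@hotEffect))
})

# Organic cores with an open attachment position (written so that a
# substituent SMILES can be appended). All are free of sulfonate groups,
# so a core + decoy-substituent molecule can never match the
# propanesulfonic query, while core + sulfonate tail always does.
.simCores <- c(
  "c1ccc(cc1)", "c1ccc2ccccc2c1", "Cc1ccc(cc1)", "COc1ccc(cc1)",
  "c1ccncc1", "c1ccc(nc1)", "c1cccc(c1)C(=O)N", "CC(C)",
  "CC(C)C", "C1CCCCC1", "C1CCCC1", "C1CCNCC1", "C1CCOC1",
  "c1ccc(cc1)C(=O)O", "Nc1ccc(cc1)", "Clc1ccc(cc1)", "Fc1ccc(cc1)",
  "OCC(O)", "CC(=O)N", "CC(O)", "c1csc(c1)", "c1[nH]ccc1",
  "c1ccc(cc1)O", "CCOC(=O)", "CN(C)", "CC(N)C(=O)O", "OC(=O)CC",
  "c1ccc(cc1)NC(=O)", "CCCCC", "C1=CC(=O)CC1")

.simDecoySubstituents <- c("C", "CC", "O", "N", "CO", "C(=O)N", "CC(C)O",
                           "CCN", "Cl", "C#N")

.scaffoldTail <- "CCCS(=O)(=O)O"

#' Simulate a compound library with planted scaffold carriers
#'
#' Generates \code{n} valid structures of which exactly
#' \code{round(n * fracScaffold)} contain the propane-1-sulfonic acid
#' scaffold (a propanesulfonate tail grafted onto a random organic core);
#' the remaining decoys are built from sulfonate-free cores and
#' substituents and are verified non-matching at generation time. The
#' planted ids are recorded in \code{metadata(...)$planted}.
#'
#' @param config a \linkS4class{SimulationConfig} (or nothing, to use the
#'   defaults); \code{nMolecules}, \code{fracScaffold} and \code{seed} may
#'   also be given directly.
#' @param nMolecules,fracScaffold,seed overrides for the config fields.
#' @return a \linkS4class{CompoundLibrary}.
#' @examples
#' lib <- simulateLibrary(simulationConfig(seed = 1, nMolecules = 10,
#'                                         fracScaffold = 0.5))
#' metadata <- lib@metadata
#' length(metadata$planted)
#' @export
simulateLibrary <- function(config = simulationConfig(),
                            nMolecules = NULL, fracScaffold = NULL,
                            seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  n <- as.integer(nMolecules %||% config@nMolecules)
  frac <- fracScaffold %||% config@fracScaffold
  sd <- as.integer(seed %||% config@seed)
  if (n < 1) stop("nMolecules must be >= 1", call. = FALSE)
  if (frac < 0 || frac > 1)
    stop("fracScaffold must lie in [0, 1]", call. = FALSE)
  nPlant <- as.integer(round(n * frac))
  .withGeneratorSeed(sd, "library", {
    planted <- sort(sample.int(n, nPlant))
    cores <- sample(.simCores, n, replace = TRUE)
    subs <- sample(.simDecoySubstituents, n, replace = TRUE)
    smiles <- ifelse(seq_len(n) %in% planted,
                     paste0(cores, .scaffoldTail), paste0(cores, subs))
    ids <- sprintf("SIM%03d", seq_len(n))
    lib <- compoundLibrary(ids, smiles, source = "simulated",
                           metadata = list(planted = ids[planted],
                                           seed = sd))
    counts <- scaffoldMatchCount(lib)
    decoyIdx <- setdiff(seq_len(n), planted)
    if (any(counts[planted] < 1) || any(counts[decoyIdx] > 0)) {
      bad <- c(ids[planted][counts[planted] < 1],
               ids[decoyIdx][counts[decoyIdx] > 0])
      stop("internal: simulated ground truth violated for ",
           paste(bad, collapse = ", "))
    }
    lib
  })
}

#' Simulate linear regression data
#'
#' y = slope * x + intercept + Normal(0, noiseSd), with x drawn uniformly
#' on [1, 30] (the order of magnitude of a torsion count). With
#' \code{noiseSd = 0} the generating line is recovered exactly by
#' \code{\link{pearsonRegression}}.
#'
#' @inheritParams simulateLibrary
#' @param slope,intercept,noiseSd,nObs,seed overrides for the config
#'   fields.
#' @return list with components \code{x} and \code{y}.
#' @examples
#' xy <- simulateRegressionData(simulationConfig(seed = 7, noiseSd = 0))
#' pearsonRegression(xy$x, xy$y)
#' @export
simulateRegressionData <- function(config = simulationConfig(),
                                   slope = NULL, intercept = NULL,
                                   noiseSd = NULL, nObs = NULL,
                                   seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  b <- slope %||% config@slope
  a <- intercept %||% config@intercept
  s <- noiseSd %||% config@noiseSd
  n <- as.integer(nObs %||% config@nObs)
  sd <- as.integer(seed %||% config@seed)
  if (s < 0) stop("noiseSd must be >= 0", call. = FALSE)
  .withGeneratorSeed(sd, "regression", {
    x <- stats::runif(n, 1, 30)
    y <- b * x + a + stats::rnorm(n, 0, s)
    list(x = x, y = y)
  })
}

# Amyloid-beta 1-42 residue sequence, used to give simulated
# decompositions realistic residue labels.
.abeta42 <- c("Asp1", "Ala2", "Glu3", "Phe4", "Arg5", "His6", "Asp7",
  "Ser8", "Gly9", "Tyr10", "Glu11", "Val12", "His13", "His14", "Gln15",
  "Lys16", "Leu17", "Val18", "Phe19", "Phe20", "Ala21", "Glu22",
  "Asp23", "Val24", "Gly25", "Ser26", "Asn27", "Lys28", "Gly29",
  "Ala30", "Ile31", "Ile32", "Gly33", "Leu34", "Met35", "Val36",
  "Gly37", "Gly38", "Val39", "Val40", "Ile41", "Ala42")

#' Simulate a per-residue energy decomposition
#'
#' Draws per-residue PB and GB contributions for \code{nResidues}
#' receptor residues (labelled with the amyloid-beta 1-42 sequence,
#' recycled beyond 42, across chains A/B/C) such that exactly
#' \code{nHot} planted residues lie at or below the hot-spot threshold --
#' pushed below it by up to \code{hotEffect} kcal/mol in both models,
#' with \code{hotEffect = 0} placing them exactly at the threshold --
#' and all others lie strictly above it in both models.
#' \code{\link{hotResidues}} therefore recovers exactly the planted set.
#'
#' @inheritParams simulateLibrary
#' @param nResidues,nHot,hotEffect,seed overrides for the config fields.
#' @param threshold hot-spot threshold the planted residues are pushed
#'   below (kcal/mol).
#' @return long decomposition data.frame (see
#'   \code{\link{readDecomposition}}) with the planted residue keys in
#'   \code{attr(..., "planted")}.
#' @examples
#' d <- simulateDecomposition(simulationConfig(seed = 2, nHot = 3))
#' nrow(hotResidues(d))
#' @export
simulateDecomposition <- function(config = simulationConfig(),
                                  nResidues = NULL, nHot = NULL,
                                  hotEffect = NULL, seed = NULL,
                                  threshold = -3.0) {
  stopifnot(is(config, "SimulationConfig"))
  nRes <- as.integer(nResidues %||% config@nResidues)
  nH <- as.integer(nHot %||% config@nHot)
  eff <- hotEffect %||% config@hotEffect
  sd <- as.integer(seed %||% config@seed)
  if (nH > nRes) stop("nHot cannot exceed nResidues", call. = FALSE)
  if (eff < 0) stop("hotEffect must be >= 0", call. = FALSE)
  if (threshold >= 0) stop("threshold must be negative", call. = FALSE)
  .withGeneratorSeed(sd, "decomposition", {
    residue <- rep_len(.abeta42, nRes)
    chain <- sample(c("A", "B", "C"), nRes, replace = TRUE)
    hotIdx <- sort(sample.int(nRes, nH))
    coldRange <- c(threshold + 0.05, -0.01)
    pb <- stats::runif(nRes, coldRange[1], coldRange[2])
    gb <- stats::runif(nRes, coldRange[1], coldRange[2])
    pb[hotIdx] <- threshold - eff * stats::runif(nH)
    gb[hotIdx] <- threshold - eff * stats::runif(nH)
    out <- data.frame(
      compound_id = "SIMLIG",
      residue = rep(residue, 2L), chain = rep(chain, 2L),
      model = rep(c("pb", "gb"), each = nRes),
      energy = c(pb, gb), pairwise = FALSE,
      stringsAsFactors = FALSE)
    attr(out, "planted") <- paste0(residue[hotIdx], "(", chain[hotIdx],
                                   ")")
    out
  })
}
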