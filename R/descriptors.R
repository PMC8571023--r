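# Molecular descriptors: MW, AlogP, Lipinski H-bond counts, topological
# PSA, and the quantitative estimate of drug-likeness (QED).
#
# MW, AlogP (atom-contribution logP) and topological PSA come from
# OpenBabel via ChemmineOB. QED is the weighted-desirability composite of
# eight simple descriptors (Bickerton-style asymmetric double sigmoids with
# the published parameterization and mean weights); its structural-alert
# term counts a curated set of common reactive/undesirable motifs (see
# .qedAlertSmarts).

# ADS desirability parameters (a, b, c, d, e, f, dmax) per property.
.qedADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353,
             49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897,
             0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202,
             0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 1e-09,
             0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614,
             12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.01, 272.4121427, 2.55837997, 1.565547684,
             1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.21778897, 957.7374108, 2.274627939, 1e-09,
             1.317690384, 0.375760881, 312.337261),
  ALERTS = c(0.01, 1199.094025, -0.09002883, 1e-09,
             0.185904477, 0.875193782, 417.725314))

.qedWeights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.qedDesirability <- function(x, p) {
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]
  dmax <- p[7]
  val <- a + b / (1 + exp(-(x - cc + d / 2) / e)) *
    (1 - 1 / (1 + exp(-(x - cc - d / 2) / f)))
  pmin(pmax(val / dmax, 1e-12), 1)
}

# Curated structural-alert motifs (reactive or generally undesirable
# groups: Michael acceptors, alkylating agents, redox-active and unstable
# functions). Deliberately a compact set; the alert count enters QED only
# through a saturating desirability term.
.qedAlertSmarts <- c(
  nitro            = "[NX3](=O)=O",
  nitro_charged    = "[NX3+](=O)[O-]",
  aldehyde         = "[CX3H1](=O)[#6]",
  michael_acceptor = "C=CC(=O)[!N]",
  acyl_halide      = "C(=O)[Cl,Br,I]",
  alkyl_halide     = "[CX4][Cl,Br,I]",
  azo              = "[#6]N=N[#6]",
  hydrazine        = "[NX3][NX3]",
  isocyanate       = "N=C=O",
  thiol            = "[#6][SX2H]",
  epoxide          = "C1OC1",
  aziridine        = "C1NC1",
  peroxide         = "OO",
  quinone          = "O=C1C=CC(=O)C=C1",
  n_oxide          = "[#7+][O-]",
  phosphorus       = "[#15]",
  long_chain       = "[CX4H2][CX4H2][CX4H2][CX4H2][CX4H2][CX4H2][CX4H2]",
  imine            = "[#6]C=[NX2][#6]",
  sulfonyl_halide  = "S(=O)(=O)[Cl,Br,I]",
  anhydride        = "C(=O)OC(=O)")

# Rotatable bonds: single acyclic bonds between non-terminal heavy atoms,
# excluding bonds adjacent to triple bonds (simple definition; amide C-N
# bonds are counted).
.rotbSmarts <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

.countAlerts <- function(smiles) {
  hits <- .smartsCountMatrix(smiles, .qedAlertSmarts) > 0
  as.integer(rowSums(hits))
}

#' QED from precomputed property values
#'
#' The weighted-desirability drug-likeness composite: each property is
#' mapped through its published asymmetric-double-sigmoid desirability
#' function and the results are combined as a weighted geometric mean
#' (mean weights).
#'
#' @param mw molecular weight (g/mol).
#' @param alogp atom-contribution logP.
#' @param hba,hbd hydrogen-bond acceptor/donor counts.
#' @param psa topological polar surface area (A^2).
#' @param rotb rotatable-bond count.
#' @param arom aromatic-ring count.
#' @param alerts structural-alert count.
#' @return QED values in [0, 1].
#' @examples
#' qedFromProperties(300, 2.5, 4, 1, 70, 4, 2, 0)
#' @export
qedFromProperties <- function(mw, alogp, hba, hbd, psa, rotb, arom,
                              alerts) {
  props <- list(MW = mw, ALOGP = alogp, HBA = hba, HBD = hbd, PSA = psa,
                ROTB = rotb, AROM = arom, ALERTS = alerts)
  d <- vapply(names(props), function(k)
    log(.qedDesirability(props[[k]], .qedADS[[k]])),
    numeric(length(mw)))
  if (length(mw) == 1)
    d <- matrix(d, nrow = 1, dimnames = list(NULL, names(props)))
  w <- .qedWeights[colnames(d)]
  exp(as.vector(d %*% w) / sum(w))
}

#' Compute molecular descriptors for a library
#'
#' Computes, per compound: molecular weight (standard atomic masses with
#' implicit hydrogens), atom-contribution AlogP, Lipinski-style H-bond
#' acceptor (N + O) and donor (N-H/O-H bearing heteroatom) counts,
#' topological polar surface area, and QED. Salts are stripped to the
#' largest component first, matching how marketed salt forms are profiled.
#'
#' @param library a \linkS4class{CompoundLibrary} (or character vector of
#'   SMILES).
#' @param stripSalts strip to the largest covalent component first.
#' @return data.frame with columns
#'   \code{id, mw, alogp, hba, hbd, psa, qed}.
#' @examples
#' lib <- compoundLibrary("etoh", "CCO")
#' computeDescriptors(lib)
#' @export
computeDescriptors <- function(library, stripSalts = TRUE) {
  if (is.character(library))
    library <- compoundLibrary(sprintf("mol%d", seq_along(library)),
                               library)
  stopifnot(is(library, "CompoundLibrary"))
  if (length(library) == 0)
    return(data.frame(id = character(), mw = numeric(), alogp = numeric(),
                      hba = integer(), hbd = integer(), psa = numeric(),
                      qed = numeric()))
  smi <- if (stripSalts) stripSalts(library@smiles) else library@smiles
  prop <- .obProperties(smi)
  counts <- .smartsCountMatrix(smi, c(hba = "[#7,#8]",
                                      hbd = "[#7!H0,#8!H0]",
                                      rotb = .rotbSmarts))
  hba <- counts[, "hba"]
  hbd <- counts[, "hbd"]
  rotb <- counts[, "rotb"]
  arom <- .aromaticRingCount(smi)
  alerts <- .countAlerts(smi)
  qed <- qedFromProperties(prop$MW, prop$logP, hba, hbd, prop$TPSA, rotb,
                           arom, alerts)
  data.frame(id = library@id, mw = prop$MW, alogp = prop$logP,
             hba = as.integer(hba), hbd = as.integer(hbd),
             psa = prop$TPSA, qed = qed, stringsAsFactors = FALSE)
}

#' Write a descriptor table to CSV
#'
#' @param descriptors data.frame from \code{\link{computeDescriptors}}.
#' @param path output CSV path.
#' @return the input, invisibly.
#' @export
writeDescriptors <- function(descriptors, path) {
  utils::write.csv(descriptors, path, row.names = FALSE)
  invisible(descriptors)
}
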