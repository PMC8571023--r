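---
title: "Scaffold-based screening and docking post-processing with ScaffoldScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold-based screening and docking post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(ScaffoldScreen))
```

## The problem

Repurposing approved drugs is one of the few fast routes to new therapy
in indications with long histories of clinical failure, Alzheimer's
disease chief among them. A scaffold-based repurposing screen starts from
a pharmacologically validated core substructure — here the
propane-1-sulfonic acid moiety of tramiprosate (3-aminopropanesulfonic
acid), an amyloid-beta aggregation inhibitor — and asks which already
approved drugs carry that core, how strongly they are predicted to bind
the target, and whether they can reach it across the blood–brain barrier.

ScaffoldScreen implements the desk-scale half of that workflow. The heavy
simulation engines (docking, molecular dynamics, surface-area solvers)
are deliberately out of scope: this package consumes their summary tables
and makes everything derived from those tables — inhibition constants,
ligand efficiencies, logBB profiles, similarity trees, hot-residue calls,
regressions, lead calls — reproducible, testable R code.

## The screening model, stage by stage

### Scaffold filtering

A library (SMILES, SDF, or CSV) is filtered with a SMARTS substructure
query. The default query,

```
CCCS(=O)(=O)[OX1,OX2]
```

is a three-carbon chain bonded to a sulfonate/sulfonic sulfur whose
terminal oxygen may be protonated (`OX2`) or anionic (`OX1`). The query
must match its own reference structure (tramiprosate) at construction
time, which doubles as a compile check. Structures are salt-stripped
before matching — the largest covalently connected component is kept —
because approved-drug libraries list marketed salt forms (sodium salts,
bisulfite adducts) whose counter-ions would otherwise defeat a
substructure query.

Two caveats are worth knowing. First, commercial scaffold-search tools
often use similarity-based matching rather than strict substructure
semantics, so hit counts need not agree between tools; this package makes
the semantics explicit (at least one embedding of the SMARTS after salt
stripping) and verifiable. Second, a handful of sulfonate-bearing drugs
(O-sulfated sugars, methanesulfonates, aryl-ethanesulfonates) contain
sulfur chemistry that resembles the scaffold without containing the
literal three-carbon sulfonate; under strict semantics they are not hits.

### Descriptors and drug-likeness

`computeDescriptors()` reports molecular weight, atom-contribution AlogP,
Lipinski-style H-bond acceptor (N + O) and donor (N–H/O–H) counts,
topological polar surface area, and QED, all computed on the salt-stripped
structure. Descriptor values of this kind are software-lineage dependent
— different logP parameterizations and PSA conventions differ by tenths
of log units and several Å² — so cross-tool agreement is expected to be
approximate, and the package's tests assert exact values only for
quantities that are exact (counts, masses of small molecules).

QED is implemented as the published weighted-desirability composite: each
of eight properties (MW, ALOGP, HBA, HBD, PSA, rotatable bonds, aromatic
rings, structural alerts) is mapped through its published
asymmetric-double-sigmoid desirability function and combined as a
weighted geometric mean with the published mean weights. The
structural-alert term uses a curated set of twenty common reactive or
undesirable motifs (nitro, Michael acceptors, acyl/alkyl halides,
epoxides, quinones, and the like) rather than a larger published alert
catalogue; since the alert count enters only through a saturating
desirability term, the effect of the difference on QED is small, and QED
values are documented as approximate.

### Fingerprints, similarity, and clustering

Compound similarity uses electrotopological-state (E-state) atom-type
fingerprints: every atom is assigned to one of 79 published atom types,
and the fingerprint is the 79-vector of type counts, binarized at > 0
for Tanimoto comparison. Each type name encodes its environment exactly —
bond pattern (s/d/t/a for single/double/triple/aromatic), element, and
hydrogen count — so the package generates the matching SMARTS for each
type mechanically from its name and counts matches with OpenBabel. Atoms
fitting no type (bare metals, charged oxygens outside the table)
contribute to no feature, as in the published scheme. A hashed path
fingerprint (OpenBabel FP2, 1024 bits) is available as an alternative
scheme; the Tanimoto index is intersection-over-union for binary
fingerprints and the min/max generalization for counts.

Two conventions matter here and are deliberate:

* **Similarity to the scaffold**, the `T` column of a screening report,
  is computed against the *bare scaffold* (propane-1-sulfonic acid), not
  against tramiprosate itself — which is why tramiprosate's own `T` is
  below 1.
* **Clustering operates on the as-listed (salted) structures.** A
  marketed drug's identity includes its counter-ion, and the library
  lists salt forms; fingerprinting the whole entry keeps, e.g., a
  bisulfite adduct and a camphorsulfonate salt close in fingerprint
  space through their shared sulfonate features. Salt stripping remains
  the default for substructure matching and descriptors.

Hierarchical clustering is agglomerative on Tanimoto distance 1 − T with
average linkage by default (the common choice for chemical similarity
trees; complete and single linkage are available), cut into *k* groups.
Merge order is deterministic, with ties resolved by lowest pair index.
Trees export as Newick strings.

### Docking post-processing

Docking summaries arrive as a CSV of binding free energies (ΔG_bind,
kcal/mol), heavy-atom counts (N_atm), torsion counts (N_tor) and optional
conformational-cluster RMS statistics. From these:

* **Inhibition constant**: Ki = exp(ΔG_bind / RT) with
  R = 1.98 × 10⁻³ kcal mol⁻¹ K⁻¹ and T = 298.15 K, in mol/L. Display
  formatting auto-scales to µM below 10⁻³ M, mM in [10⁻³, 0.1) M, and M
  above, rounding half-up to two decimals — the convention under which
  the packaged study table's unit footnotes reproduce. The temperature
  is the room temperature the source tables were computed at (the
  ligand-preparation temperature of 310 K does not reproduce them).
* **Ligand efficiency**: LE = ΔG_bind / N_atm, kcal/mol per heavy atom,
  sign preserved.
* **Lead selection**: leads are compounds with ΔG_bind strictly below
  the reference compound's, sorted by ascending energy. No statistical
  test is applied — each compound has a single docking energy, so the
  comparison is a plain inequality, and the package documents it as
  such rather than dressing it up.

A note on regeneration precision: when a printed table is itself the
input (energies rounded to two decimals), quantities derived from it can
differ from the printed derived values by one unit in the last printed
digit, because the original authors computed from unrounded energies.
The packaged regeneration report (`reproduceStudyTables()`) therefore
accepts Ki and LE within ±0.01 on the displayed scale while requiring
units, logBB and compensation cells to match exactly at printed
precision.

### Blood–brain-barrier models

Two published linear models estimate logBB (the log brain-to-blood
concentration ratio) from AlogP and PSA:

* Clark: logBB = 0.152·AlogP − 0.0148·PSA + 0.139
* Rishton: logBB = 0.155·AlogP − 0.01·PSA + 0.164

Both are monotone increasing in lipophilicity and decreasing in polar
surface area. `classifyBBB()` flags a compound as CNS-`optimal` only when
*both* models give logBB > 0 (strictly) — the models disagree in slope,
and requiring agreement avoids calling a borderline compound favorable on
the strength of one parameterization. A second flag, `psa_cns_ok`, marks
PSA below the CNS permeation window; the literature gives 60–70 Å² as
the usual requirement, and the package fixes the threshold at the
permissive upper bound, 70 Å² (configurable). Experimental logBB values,
where known, are carried as annotations and never computed: a compound
like donepezil owes its measured logBB largely to carrier-mediated
transport that no passive-diffusion model captures.

### MM-PBSA/GBSA post-processing

End-state free-energy tables decompose as ΔG = ΔH − TΔS per solvation
model (Poisson–Boltzmann and generalized Born). `checkCompensation()`
audits that identity at a default tolerance of 0.01 kcal/mol — agreement
at two-decimal printing precision — and reports violations rather than
failing, since an inconsistent row is a data problem the analyst should
see. Per-residue and pairwise energy decompositions are normalized into a
long table (compound, residue, chain, model, energy), and
`hotResidues()` calls a residue hot when its contribution is at or below
the threshold (≤, "threshold and below") under *either* solvation model:
the study plots both models side by side and highlights residues crossing
in one model alone, so "either" is the faithful reading; this is an
interpretation and is flagged as such. Defaults are −3.0 kcal/mol for
per-residue and −6.0 kcal/mol for pairwise decompositions.

Buried surface area uses the standard half-interface convention,
BSA = (ASA_pep + ASA_lig − ASA_comp) / 2: the accessible surface lost on
binding is split across the two faces of the interface. The typeset
source formula is ambiguous about the scope of the /2; the conventional
definition is used, and with ASA inputs unavailable in print the BSA
values themselves are not regeneration targets — only internal
consistency (non-negativity, monotonicity in the complex area, and
concordance of the BSA ordering with the affinity ordering) is tested.

### Regression analysis

`pearsonRegression()` is ordinary least squares plus the Pearson
correlation and its two-tailed t-test on n − 2 degrees of freedom,
with pairwise-complete handling of missing values (docking tables print
"—" for compounds whose conformational statistics are undefined). Two
regressions from the packaged tables reproduce at printed precision:
cluster RMS against torsion count over the six complete rows (r² = 0.78,
p = 0.02), and ligand efficiency against scaffold similarity over all 14
compounds (p = 0.008, with the reference compound included — excluding
it does not reproduce the printed statistic). One printed statistic is
knowingly not recoverable: the clRMSa–N_tor correlation of r² = 0.63,
which the printed table values put at r² ≈ 0.95; the package computes
and reports it but does not assert it.

## The synthetic-data generators

Three generators produce inputs with the exact structure the pipeline
assumes, so every stage can be tested end to end with known ground truth:

* `simulateLibrary()` builds n valid SMILES of which exactly
  round(n · fracScaffold) carry the scaffold — a propanesulfonate tail
  grafted onto one of ~30 organic cores — while decoys are assembled
  from sulfonate-free cores and substituents and verified non-matching
  at generation time. Default n = 20 with fracScaffold = 0.3, a planted
  hit fraction large enough to exercise both classes at test-sized n.
* `simulateRegressionData()` draws y = slope·x + intercept + N(0, sd)
  with x uniform on [1, 30] (the scale of a torsion count). Defaults
  (slope 0.1, sd 0.2, n = 50) give a signal-to-noise ratio where
  recovery succeeds but is not trivial.
* `simulateDecomposition()` plants nHot residues at or below the
  −3.0 kcal/mol threshold (pushed below by up to hotEffect kcal/mol;
  hotEffect = 0 places them exactly at the boundary) among residues
  labelled with the amyloid-beta 1-42 sequence across chains A/B/C, all
  others strictly above it in both solvation models.

Each generator seeds the Mersenne Twister with the config seed plus a
generator-specific offset, draws, and restores the caller's RNG state:
identical configs give byte-identical output, and the generators cannot
perturb one another or the session.

What the generators do *not* emulate is as important: there is no
docking physics (energies in tests are assigned, not sampled from a
force field), no correlation structure between descriptors and binding,
and no attempt at realistic chemistry beyond syntactic validity and the
planted/decoy distinction. Passing tests on synthetic data therefore
demonstrate that the *bookkeeping* — filtering, thresholding, recovery
of planted truth, statistical calibration — is correct; they say nothing
about docking accuracy on real systems, which is out of scope by design.

## Numerical and design choices

* **Rounding for display** is half-up (away from zero) at two decimals;
  R's own `round()` goes to even at half-way cases, which is the wrong
  convention for matching printed tables.
* **Strict inequalities** are used where the source language says
  "lower" or "> 0" (lead selection, logBB optimality); **non-strict**
  where it says "threshold and below" (hot residues).
* **Duplicate compound ids are an error**, never silently deduplicated —
  a duplicate usually means an upstream join went wrong.
* **Unparseable library entries are skipped and counted**, with the
  count reported; a library with zero parseable entries is an error.
* **Degenerate regressions** (zero variance, n < 3 after missing-value
  filtering) are errors, not NaN-propagating fits.
* **Tanimoto of two empty fingerprints** is defined as 0 with a warning
  (no shared features is the natural reading of no features at all).
* **Tiny negative BSA** within numerical tolerance clamps to zero;
  beyond tolerance it is an invalid ASA triple and errors.

## The packaged study tables

The package ships four small CSV fixtures: the docking summary
(14 compounds), the descriptor/logBB table (4 compounds), the
MM-PBSA/GBSA summary (3 complexes) — all printed data — and a SMILES
table for the 14 compounds reconstructed from their drug names, since
the source lists structures only as drawings. The reconstruction is a
stand-in, good enough to exercise filtering, descriptors and clustering,
and is labelled as such; analyses that depend only on printed numeric
tables (Ki, LE, logBB, compensation, regressions, lead calls) do not
touch it.

```{r reproduce}
rep <- reproduceStudyTables()
table(rep$table, rep$pass)
```

A worked screen over the packaged fixtures:

```{r screen}
lib <- readLibrary(studyFixture("table1_hits_reconstructed.csv"),
                   format = "csv")
dock <- readDockingTable(studyFixture("table2_docking.csv"))
report <- runScreen(lib, dock, referenceId = "14",
                    computeMissingDescriptors = FALSE)
leadIds(report)
head(reportTable(report)[, c("compound_id", "dg_bind", "ki_value",
                             "ki_unit", "le", "tanimoto", "status")])
```

And the similarity tree of the 13 hits, cut into four groups:

```{r cluster}
hits13 <- lib[as.character(1:13)]
tree <- hierarchicalCluster(tanimotoMatrix(eStateFingerprint(hits13)),
                            k = 4)
clusterAssignments(tree)
```

The two lead candidates (compounds 4 and 6) fall in the same group —
the behavior the similarity analysis is meant to surface, reproduced
here from reconstructed structures.

## Problem sizes

Everything in the package runs at desk scale: the packaged tables are
14 × 9 and smaller, simulated libraries in the tests span 10–20
molecules, regression simulations use up to 200 observations with 500
replicate seeds for the type-I-error calibration, and the full test
suite completes in well under a minute. Users screening a real
approved-drug library (thousands of molecules) pay one OpenBabel parse
per molecule per analysis; the E-state fingerprint evaluates 79 SMARTS
on a single parse.

## Known limitations

* Substructure semantics are strict; similarity-based scaffold searches
  in commercial tools will produce different (usually larger) hit sets.
* AlogP and PSA follow OpenBabel's parameterizations; logBB values
  computed from them will differ from those computed with other
  descriptor software, although the logBB *equations* are exact.
* The E-state implementation assigns no type to atoms outside the 79
  published types; molecules dominated by exotic atoms fingerprint
  sparsely. OpenBabel normalizes some charge-separated salt forms on
  import, which can toggle single protonation-dependent features.
* QED uses a curated 20-motif alert set, not a full published alert
  catalogue.
* The entropy, enthalpy and surface-area inputs are trusted as given;
  the package audits their internal consistency but cannot detect a
  systematically wrong upstream calculation.
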