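# ScaffoldScreen

Scaffold-based virtual screening and docking post-processing for drug
repurposing, in R.

## What this is for

Drug-repurposing screens for hard indications (Alzheimer's disease being
the motivating case) often start from a validated core substructure — a
*scaffold* — of a known active compound and ask three questions about an
approved-drug library: which drugs carry the scaffold, how strongly does
docking predict they bind the target, and can they reach a CNS target
across the blood–brain barrier? The docking and molecular-dynamics
engines that feed such a screen are heavyweight external software, but
everything *derived* from their outputs is desk-scale arithmetic that
deserves to be reproducible and tested. ScaffoldScreen implements that
derived layer for computational chemists and cheminformaticians:

* substructure filtering of SMILES/SDF/CSV libraries with salt stripping
  (default query: the propane-1-sulfonic acid core of tramiprosate,
  `CCCS(=O)(=O)[OX1,OX2]`);
* molecular descriptors (MW, AlogP, HBA/HBD, PSA, QED), 79-type E-state
  fingerprints, Tanimoto similarity matrices, and hierarchical cluster
  trees with Newick export;
* docking post-processing: inhibition constants
  `Ki = exp(ΔG_bind / RT)` (R = 1.98×10⁻³ kcal mol⁻¹ K⁻¹,
  T = 298.15 K) with µM/mM/M display scaling, ligand efficiency
  `LE = ΔG_bind / N_atm`, and lead selection against a reference
  compound (strict `ΔG < ΔG_ref`);
* blood–brain-barrier scoring with two published linear models,
  `logBB_cl = 0.152·AlogP − 0.0148·PSA + 0.139` and
  `logBB_ri = 0.155·AlogP − 0.01·PSA + 0.164`, plus CNS flags
  (both models > 0; PSA < 70 Å²);
* MM-PBSA/GBSA post-processing: the entropy–enthalpy compensation audit
  `ΔG = ΔH − TΔS`, per-residue/pairwise hot-residue calls at the
  −3.0 / −6.0 kcal/mol thresholds, and buried surface area
  `BSA = (ASA_pep + ASA_lig − ASA_comp) / 2`;
* Pearson regression with the t-test on n − 2 degrees of freedom and
  pairwise-complete missing-value handling;
* seeded synthetic-data generators (planted scaffold carriers, linear
  regression data, planted hot residues) so the whole pipeline is
  testable without any external engine.

The chemistry backend is OpenBabel via ChemmineR/ChemmineOB. The package
ships the study's printed summary tables as plain CSV fixtures
(`studyFixture()`), including a SMILES table for the 14 screen compounds
reconstructed from their drug names (structures are drawings in the
source; the reconstruction is a documented stand-in).

## A worked screen

Screen the packaged 14-compound set against its docking summary, with
compound 14 (tramiprosate) as the reference:

```r
library(ScaffoldScreen)

lib  <- readLibrary(studyFixture("table1_hits_reconstructed.csv"),
                    format = "csv")
dock <- readDockingTable(studyFixture("table2_docking.csv"))
report <- runScreen(lib, dock, referenceId = "14",
                    computeMissingDescriptors = FALSE)

leadIds(report)
#> [1] "4" "6"
head(reportTable(report)[, c("compound_id", "dg_bind", "ki_value",
                             "ki_unit", "le", "status")], 5)
#>   compound_id dg_bind ki_value ki_unit         le    status
#> 1           4   -7.11     5.88      uM -0.3950000      lead
#> 2           6   -6.82     9.61      uM -0.4546667      lead
#> 3          14   -6.19    27.94      uM -0.5627273 reference
#> 4           8   -6.17    28.90      uM -0.1542500       hit
#> 5          13   -5.71    63.00      uM -0.1038182       hit
```

Two compounds — menadione bisulfite (4) and camphotamide (6) — bind
more favorably than the reference and are called leads, with predicted
inhibition constants of 5.88 and 9.61 µM against the reference's
27.94 µM. The `le` column is the binding energy per heavy atom: the
small reference compound is the most ligand-efficient even though the
leads bind more strongly overall.

Conformational spread grows with ligand flexibility; over the compounds
with defined cluster-RMS statistics:

```r
pearsonRegression(dock$n_tor, dock$cl_rms)
#> RegressionResult: n = 6
#>   y = 0.1062 x + 0.09514
#>   r = 0.8810, r2 = 0.7762, p = 0.02039
```

And every derived cell of the packaged study tables regenerates from its
printed inputs:

```r
rep <- reproduceStudyTables()
sum(rep$pass) / nrow(rep)
#> [1] 1
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/scaffold-screen.R` (subcommands `filter-scaffold`,
`descriptors`, `similarity`, `cluster`, `dock-metrics`, `bbb`, `thermo`,
`regress`, `simulate`, `screen`, `reproduce-tables`).

See the vignette (`vignettes/scaffold-screening.Rmd`) for the model
details, parameter choices, and the limits of what the synthetic tests
demonstrate.

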