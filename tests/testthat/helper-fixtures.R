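# Shared fixtures built in code. The packaged study tables are loaded via
# studyFixture(); everything else is constructed here.

table2 <- function() readDockingTable(studyFixture("table2_docking.csv"))

table3 <- function() read.csv(studyFixture("table3_descriptors.csv"),
                              stringsAsFactors = FALSE)

table4 <- function() readThermoTable(studyFixture("table4_thermo.csv"))

hitsLibrary <- function() {
  readLibrary(studyFixture("table1_hits_reconstructed.csv"),
              format = "csv")
}

# A tiny validated library: the scaffold itself, an N-acetyl homolog that
# carries it, and two scaffold-free molecules.
tinyLibrary <- function() {
  compoundLibrary(
    id = c("tra", "acam", "benzene", "ethanol"),
    smiles = c("NCCCS(=O)(=O)O", "CC(=O)NCCCS(=O)(=O)O", "c1ccccc1",
               "CCO"))
}

# Write a .smi file with the given lines, returning its path.
writeSmi <- function(lines) {
  path <- tempfile(fileext = ".smi")
  writeLines(lines, path)
  path
}

roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
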