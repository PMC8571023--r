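test_that("readLibrary parses .smi files, skipping and counting bad rows", {
  # single named entry
  lib <- readLibrary(writeSmi("CCCS(=O)(=O)O scaffold"))
  expect_s4_class(lib, "CompoundLibrary")
  expect_length(lib, 1)
  expect_equal(compoundNames(lib), "scaffold")

  # empty file is a fatal error
  expect_error(readLibrary(writeSmi(character())), "zero parseable")
  # as is a file of only malformed entries
  expect_error(readLibrary(writeSmi(c("xy(z bad1", "Q#! bad2"))),
               "zero parseable")

  # 10 entries, 2 syntactically invalid -> 8 records, skip count 2
  good <- c("CCO e1", "CCN e2", "CCC e3", "c1ccccc1 e4", "CCOC e5",
            "CC(C)C e6", "OCCO e7", "CCS e8")
  bad <- c("C1CC garbage", "notasmiles!! x")
  expect_message(lib10 <- readLibrary(writeSmi(c(good[1:5], bad, good[6:8]))),
                 "skipped 2")
  expect_length(lib10, 8)
  expect_identical(lib10@metadata$skipped, 2L)
})

test_that("readLibrary reads CSV with the fixed dialect and rejects dup ids", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles,name", "a,CCO,ethanol", "b,CCC,propane"), path)
  lib <- readLibrary(path)
  expect_equal(compoundIds(lib), c("a", "b"))
  expect_equal(compoundNames(lib), c("ethanol", "propane"))

  writeLines(c("id,smiles", "a,CCO", "a,CCC"), path)
  expect_error(readLibrary(path), "duplicate")

  writeLines(c("smiles,name", "CCO,x"), path)
  expect_error(readLibrary(path), "requires columns")

  expect_error(readLibrary(tempfile(fileext = ".csv")), "not found")
})

test_that("readLibrary round-trips structures through SDF", {
  lib <- tinyLibrary()
  sdf <- ChemmineR::smiles2sdf(compoundSmiles(lib))
  path <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, path)
  back <- readLibrary(path)
  expect_length(back, 4)
  expect_setequal(compoundIds(back), compoundIds(lib))
  # same hit set after the round trip
  expect_setequal(compoundIds(scaffoldFilter(back)),
                  compoundIds(scaffoldFilter(lib)))
})

test_that("stripSalts keeps the largest covalent component and is idempotent", {
  expect_equal(stripSalts("CCCS(=O)(=O)[O-].[Na+]"), "CCCS(=O)(=O)[O-]")
  expect_equal(stripSalts("CCO"), "CCO")
  # two organic components of 5 and 7 heavy atoms -> the 7-atom one
  expect_equal(stripSalts("CCCCC.CCCCCCC"), "CCCCCCC")
  expect_equal(stripSalts("CCCCCCC.CCCCC"), "CCCCCCC")
  # idempotence over a mix of salts and single components
  for (s in c("CCCS(=O)(=O)[O-].[Na+]", "CCO", "CCCCC.CCCCCCC",
              "C[n+]1cccc(C(N)=O)c1.CC1(C)C2CCC1(CS(=O)(=O)[O-])C(=O)C2"))
    expect_identical(stripSalts(stripSalts(s)), stripSalts(s))
})

test_that("scaffoldQuery validates its pattern against the reference", {
  q <- defaultScaffoldQuery()
  expect_s4_class(q, "ScaffoldQuery")
  # a pattern that cannot match its reference is a configuration error
  expect_error(scaffoldQuery("broken", "c1ccccc1", "CCO"),
               "configuration error")
  expect_error(scaffoldQuery("garbage", "[[[", "CCO"), "")
})

test_that("scaffoldFilter returns exactly the matching subset, in order", {
  # the scaffold structure itself is a hit
  solo <- compoundLibrary("s", "CCCS(=O)(=O)O")
  expect_equal(compoundIds(scaffoldFilter(solo)), "s")
  # no sulfur anywhere -> no hits
  none <- compoundLibrary(c("b", "e"), c("c1ccccc1", "CCO"))
  expect_length(scaffoldFilter(none), 0)

  lib <- tinyLibrary()
  hits <- scaffoldFilter(lib)
  expect_equal(compoundIds(hits), c("tra", "acam"))
  # subset of input, order preserved
  expect_true(all(compoundIds(hits) %in% compoundIds(lib)))
  expect_lte(length(hits), length(lib))
  expect_false(is.unsorted(match(compoundIds(hits), compoundIds(lib))))
})

test_that("filtering is invariant to SMILES atom-order permutation", {
  # the same molecules written with different atom orderings
  forms <- list(
    tra = c("NCCCS(=O)(=O)O", "OS(=O)(=O)CCCN", "C(CN)CS(O)(=O)=O"),
    decoy = c("CC(=O)Nc1ccccc1", "c1ccccc1NC(C)=O"))
  for (molForms in forms) {
    hitCounts <- vapply(molForms, function(s) {
      length(scaffoldFilter(compoundLibrary("m", s)))
    }, integer(1))
    expect_length(unique(hitCounts), 1)
  }
})

test_that("planted scaffold carriers are recovered exactly in a synthetic library", {
  lib <- simulateLibrary(simulationConfig(seed = 1, nMolecules = 20,
                                          fracScaffold = 0.3))
  planted <- lib@metadata$planted
  expect_length(planted, 6)
  hits <- scaffoldFilter(lib)
  expect_setequal(compoundIds(hits), planted)
  # independent check: planted structures end in the grafted sulfonate
  # tail by construction, decoys never contain a sulfonate at all
  tailRe <- "CCCS\\(=O\\)\\(=O\\)O$"
  smi <- compoundSmiles(lib)
  expect_setequal(names(smi)[grepl(tailRe, smi)], planted)
  expect_false(any(grepl("S\\(=O\\)\\(=O\\)", smi[setdiff(names(smi),
                                                          planted)])))
})

test_that("writeHits emits the id,name,smiles,n_matches dialect", {
  path <- tempfile(fileext = ".csv")
  out <- writeHits(tinyLibrary(), path)
  expect_true(file.exists(path))
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(names(back), c("id", "name", "smiles", "n_matches"))
  expect_equal(back$id, c("tra", "acam"))
  expect_true(all(back$n_matches >= 1))
})

test_that("duplicate ids and unparseable SMILES are construction errors", {
  expect_error(compoundLibrary(c("a", "a"), c("CCO", "CCC")), "duplicate")
  expect_error(compoundLibrary("a", "xy(z"), "unparseable")
  # subsetting by unknown id fails loudly
  expect_error(tinyLibrary()["nope"], "unknown compound id")
})
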