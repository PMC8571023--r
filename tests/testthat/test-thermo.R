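test_that("entropy-enthalpy compensation reproduces the fixture dG cells", {
  expect_equal(gibbsFromCompensation(-34.15, -20.4), -13.75)
  expect_equal(gibbsFromCompensation(-28.01, -17.91), -10.10)
  expect_equal(gibbsFromCompensation(5, 0), 5)
  thermoTab <- table4()
  expect_equal(roundHalfUp(gibbsFromCompensation(thermoTab$dh_pb, thermoTab$tds), 2),
               thermoTab$dg_pb)
  expect_equal(roundHalfUp(gibbsFromCompensation(thermoTab$dh_gb, thermoTab$tds), 2),
               thermoTab$dg_gb)
})

test_that("checkCompensation flags only genuine inconsistencies", {
  thermoTab <- table4()
  expect_identical(nrow(checkCompensation(thermoTab, tol = 0.011)), 0L)
  camp <- thermoTab[thermoTab$compound == "Camphotamide", ]
  expect_identical(nrow(checkCompensation(camp, tol = 0.01)), 0L)
  # perturb one stated dG by +1 kcal/mol -> exactly one violation
  bad <- thermoTab
  bad$dg_pb[1] <- bad$dg_pb[1] + 1
  v <- checkCompensation(bad, tol = 0.011)
  expect_identical(nrow(v), 1L)
  expect_identical(v$model, "PB")
  expect_equal(v$delta, 1, tolerance = 1e-9)
  # rows without the needed fields are skipped with a note, not failed
  sparse <- data.frame(compound = "x", dg_pb = NA, dh_pb = NA, tds = NA)
  out <- checkCompensation(sparse)
  expect_identical(nrow(out), 0L)
  expect_true(length(attr(out, "skipped")) > 0)
})

test_that("hotResidues applies <= threshold under either solvation model", {
  d <- data.frame(compound_id = "m",
                  residue = c("Lys16", "Tyr10"), chain = c("A", "B"),
                  model = "pb", energy = c(-3.5, -2.0))
  hot <- hotResidues(d)
  expect_identical(hot$residue, "Lys16")
  # empty input and all-above-threshold input give empty output
  expect_identical(nrow(hotResidues(d[0, ])), 0L)
  cold <- transform(d, energy = c(-1, -2))
  expect_identical(nrow(hotResidues(cold)), 0L)
  # a residue crossing the threshold in only one model is still hot
  mixed <- data.frame(compound_id = "m", residue = "Glu11", chain = "A",
                      model = c("pb", "gb"), energy = c(-1.0, -3.2))
  expect_identical(nrow(hotResidues(mixed)), 1L)
  # boundary: exactly at the threshold is included
  edge <- data.frame(compound_id = "m", residue = "His13", chain = "B",
                     model = "pb", energy = -3.0)
  expect_identical(nrow(hotResidues(edge)), 1L)
  expect_error(hotResidues(d, threshold = 1), "negative")
})

test_that("a milder threshold admits a superset of a stricter one", {
  d <- simulateDecomposition(simulationConfig(seed = 5, nResidues = 30,
                                              nHot = 6, hotEffect = 2))
  key <- function(h) paste(h$residue, h$chain)
  strict <- key(hotResidues(d, threshold = -3))
  mild <- key(hotResidues(d, threshold = -2))
  expect_true(all(strict %in% mild))
})

test_that("pairwise entries use their own default threshold", {
  d <- data.frame(compound_id = "m", residue = c("Tyr10", "Lys16"),
                  chain = "B", model = "gb", energy = c(-6.5, -4.0),
                  pairwise = TRUE)
  hot <- hotResidues(d, pairwise = TRUE)  # default -6.0
  expect_identical(hot$residue, "Tyr10")
})

test_that("buried surface area halves the interface loss and stays valid", {
  expect_equal(buriedSurfaceArea(100, 50, 150), 0)
  expect_equal(buriedSurfaceArea(100, 50, 120), 15)
  expect_equal(buriedSurfaceArea(0, 0, 0), 0)
  expect_error(buriedSurfaceArea(100, 50, 160), "invalid ASA")
  expect_error(buriedSurfaceArea(-1, 50, 40), ">= 0")
  # monotone decreasing in the complex area
  comp <- seq(150, 60, by = -10)
  expect_true(all(diff(buriedSurfaceArea(100, 50, comp)) > 0))
})

test_that("BSA ordering matches the affinity ordering on the thermo fixture", {
  thermoTab <- table4()
  # larger buried interface accompanies stronger GB-model binding
  expect_identical(order(thermoTab$bsa, decreasing = TRUE), order(thermoTab$dg_gb))
})
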