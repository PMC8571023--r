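test_that("E-state typing assigns the hand-derivable atom types", {
  # tramiprosate N-C-C-C-S(=O)(=O)-OH: one primary amine N (sNH2), three
  # sp3 CH2 (ssCH2), a sulfone-type S (ddssS), two =O (dO), one OH (sOH)
  fp <- eStateFingerprint(compoundLibrary("tra", "NCCCS(=O)(=O)O"),
                          binary = FALSE)
  v <- fingerprintValues(fp)[1, ]
  expect_equal(v[["sNH2"]], 1)
  expect_equal(v[["ssCH2"]], 3)
  expect_equal(v[["ddssS"]], 1)
  expect_equal(v[["dO"]], 2)
  expect_equal(v[["sOH"]], 1)
  expect_equal(sum(v), 8)  # every heavy atom typed exactly once

  # benzene: six aromatic CH, nothing else
  vb <- fingerprintValues(eStateFingerprint(
    compoundLibrary("bz", "c1ccccc1"), binary = FALSE))[1, ]
  expect_equal(vb[["aaCH"]], 6)
  expect_equal(sum(vb), 6)
})

test_that("fingerprints have fixed length and are order-invariant", {
  fp <- eStateFingerprint(tinyLibrary())
  expect_identical(dim(fingerprintValues(fp)), c(4L, 79L))
  expect_identical(fingerprintScheme(fp), "estate")
  a <- fingerprintValues(eStateFingerprint(
    compoundLibrary("x", "NCCCS(=O)(=O)O")))
  b <- fingerprintValues(eStateFingerprint(
    compoundLibrary("x", "OS(=O)(=O)CCCN")))
  expect_equal(unname(a), unname(b))
})

test_that("tanimoto matches set arithmetic and handles edge cases", {
  # bits {1,2} vs {1,3}: 1 shared / 3 in the union
  a <- c(1, 1, 0, 0)
  b <- c(1, 0, 1, 0)
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_warning(z <- tanimoto(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length mismatch")
})

test_that("tanimoto is symmetric and bounded on random binary vectors", {
  set.seed(42)
  for (rep in 1:25) {
    a <- rbinom(30, 1, 0.4)
    b <- rbinom(30, 1, 0.4)
    if (sum(pmax(a, b)) == 0) next
    t1 <- tanimoto(a, b)
    expect_identical(t1, tanimoto(b, a))
    expect_gte(t1, 0)
    expect_lte(t1, 1)
  }
})

test_that("scheme mismatch between fingerprint sets is an error", {
  lib <- compoundLibrary("m", "CCO")
  expect_error(tanimoto(eStateFingerprint(lib), pathFingerprint(lib)),
               "scheme mismatch")
})

test_that("one-pass similarity matrix equals pairwise tanimoto calls", {
  fp <- eStateFingerprint(tinyLibrary())
  sm <- tanimotoMatrix(fp)
  v <- fingerprintValues(fp)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(similarityValues(sm)[i, j],
                 suppressWarnings(tanimoto(v[i, ], v[j, ])))
  }
  expect_equal(diag(similarityValues(sm)), setNames(rep(1, 4),
                                                    compoundIds(tinyLibrary())))
})

test_that("similarityToReference scores the reference itself as 1", {
  lib <- compoundLibrary(c("ref", "other"),
                         c("CCCS(=O)(=O)O", "c1ccccc1"))
  tv <- similarityToReference(lib, reference = "CCCS(=O)(=O)O")
  expect_equal(tv$tanimoto[tv$id == "ref"], 1)
  expect_true(all(tv$tanimoto >= 0 & tv$tanimoto <= 1))
  # brute-force oracle over the fingerprint vectors
  v <- fingerprintValues(eStateFingerprint(lib))
  ref <- v["ref", ]
  for (k in seq_len(nrow(v)))
    expect_equal(tv$tanimoto[k],
                 sum(pmin(v[k, ], ref)) / sum(pmax(v[k, ], ref)))
})

test_that("hierarchicalCluster honors forced merges and cut sizes", {
  # n = 2, k = 2: singletons
  sm2 <- new("SimilarityMatrix", ids = c("a", "b"),
             values = matrix(c(1, 0.3, 0.3, 1), 2,
                             dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(sort(unname(clusterAssignments(
    hierarchicalCluster(sm2, 2)))), c(1, 2))

  # n = 3 with T(1,2) = 0.9, rest 0.1: the single merge is forced
  ids <- c("m1", "m2", "m3")
  vals <- matrix(0.1, 3, 3, dimnames = list(ids, ids))
  vals[1, 2] <- vals[2, 1] <- 0.9
  diag(vals) <- 1
  cl <- clusterAssignments(hierarchicalCluster(
    new("SimilarityMatrix", ids = ids, values = vals), 2))
  expect_identical(cl[["m1"]], cl[["m2"]])
  expect_false(cl[["m3"]] == cl[["m1"]])

  # k = 1 pools everything; k = n gives singletons; k > n errors
  fp <- eStateFingerprint(tinyLibrary())
  sm <- tanimotoMatrix(fp)
  expect_length(unique(clusterAssignments(hierarchicalCluster(sm, 1))), 1)
  expect_length(unique(clusterAssignments(hierarchicalCluster(sm, 4))), 4)
  expect_error(hierarchicalCluster(sm, 5), "between 1 and")
})

test_that("the lead compounds co-cluster among the 13 reconstructed hits", {
  hits13 <- hitsLibrary()[as.character(1:13)]
  tree <- hierarchicalCluster(tanimotoMatrix(eStateFingerprint(hits13)),
                              k = 4)
  cl <- clusterAssignments(tree)
  expect_length(unique(cl), 4)
  expect_identical(cl[["4"]], cl[["6"]])
})

test_that("treeNewick emits a parseable tree with the compound ids", {
  tree <- hierarchicalCluster(tanimotoMatrix(eStateFingerprint(
    tinyLibrary())), k = 2)
  nwk <- treeNewick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, compoundIds(tinyLibrary()))
})
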