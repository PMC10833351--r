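test_that("toy PDB round-trips atoms, order, coordinates and B values", {
  m <- toyThreeAtomModel()
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeToyPdb(m, tf)
  m2 <- readStructure(tf)
  expect_s4_class(m2, "StructureModel")
  expect_equal(nAtoms(m2), 3L)
  expect_equal(atomTable(m2)$atomName, atomTable(m)$atomName)
  expect_equal(atomTable(m2)$chainId, atomTable(m)$chainId)
  expect_equal(atomCoords(m2), atomCoords(m), tolerance = 5e-4)
  expect_equal(bValues(m2), c(10, 20, 30), tolerance = 5e-3)
  expect_false(any(isEnvironment(m2)))

  # second round trip preserves everything written the first time
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  writeToyPdb(m2, tf2)
  m3 <- readStructure(tf2)
  expect_equal(atomTable(m3)[, c("atomName", "chainId", "resSeq")],
               atomTable(m2)[, c("atomName", "chainId", "resSeq")])
  expect_equal(atomCoords(m3), atomCoords(m2))
})

test_that("heavy-protein selection drops hydrogens and is idempotent", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 11.00           C",
    "ATOM      3  HA  ALA A   1       1.800   1.000   0.000  1.00  5.00           H",
    "ATOM      4  HB1 ALA A   1       2.000  -1.000   0.000  1.00  5.00           H",
    "ATOM      5  C   ALA A   1       2.000   1.200   0.500  1.00 12.00           C",
    "END")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  m <- readStructure(tf)
  expect_equal(nAtoms(m), 3L)
  expect_equal(atomTable(m)$atomName, c("N", "CA", "C"))

  # idempotence: re-reading what the selection produced changes nothing
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  writeToyPdb(m, tf2)
  expect_equal(nAtoms(readStructure(tf2)), 3L)

  mAll <- readStructure(tf, selection = "all-atoms")
  expect_equal(nAtoms(mAll), 5L)
})

test_that("altloc policy keeps the highest-occupancy conformer, ties to A", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40 11.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.100   0.000  0.60 12.00           C",
    "ATOM      4  C  AALA A   1       2.000   1.200   0.500  0.50 13.00           C",
    "ATOM      5  C  BALA A   1       2.100   1.300   0.500  0.50 14.00           C",
    "END")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  m <- readStructure(tf)
  a <- atomTable(m)
  expect_equal(nAtoms(m), 3L)
  # CA: B conformer wins on occupancy 0.6 > 0.4
  expect_equal(a$altloc[a$atomName == "CA"], "B")
  expect_equal(a$bValue[a$atomName == "CA"], 12)
  # C: occupancy tie 0.5/0.5 -> altloc A
  expect_equal(a$altloc[a$atomName == "C"], "A")
  expect_equal(a$bValue[a$atomName == "C"], 13)
})

test_that("markEnvironment sets flags and validates length", {
  m <- toyThreeAtomModel()
  m2 <- markEnvironment(m, c(FALSE, FALSE, TRUE))
  expect_equal(isEnvironment(m2), c(FALSE, FALSE, TRUE))
  expect_error(markEnvironment(m, c(TRUE, FALSE)), "length")
  # all-false flags leave behavior unchanged
  expect_equal(atomTable(markEnvironment(m, rep(FALSE, 3))),
               atomTable(m))
  # all-true flags: downstream response extraction must refuse
  mAllEnv <- markEnvironment(m, rep(TRUE, 3))
  expect_error(normalizeB(mAllEnv), "empty response")
})

test_that("environment atoms are graph nodes but not regression rows", {
  s <- syntheticStructure(60, seed = 11, noiseSd = 0)
  model <- s$model
  flags <- rep(FALSE, 60)
  flags[51:60] <- TRUE
  model <- markEnvironment(model, flags)
  g <- buildContactGraph(model, 5.0)
  expect_equal(nNodes(g), 60L)
  expect_equal(nrow(orbitCounts(countOrbits(g))), 60L)
  feats <- gdvFeatures(model, cutoff = 5.0)
  expect_equal(nrow(featureValues(feats)), 50L)
})

test_that("writeStructureWithB replaces the B column and omits env atoms", {
  m <- toyThreeAtomModel()
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeStructureWithB(m, c(0, 0, 0), tf)
  expect_equal(bValues(readStructure(tf)), c(0, 0, 0))
  txt <- readLines(tf)
  atomLines <- grep("^ATOM", txt, value = TRUE)
  expect_true(all(substr(atomLines, 61, 66) == "  0.00"))

  # negative normalized values are written as-is
  writeStructureWithB(m, c(-1.23, 0.5, 2.0), tf)
  expect_equal(bValues(readStructure(tf)), c(-1.23, 0.5, 2.0))
  expect_equal(substr(grep("^ATOM", readLines(tf), value = TRUE)[1], 61, 66),
               " -1.23")

  mEnv <- markEnvironment(m, c(FALSE, TRUE, FALSE))
  expect_error(writeStructureWithB(mEnv, c(1, 2, 3), tf),
               "non-environment")
  writeStructureWithB(mEnv, c(1, 2), tf)
  expect_equal(nAtoms(readStructure(tf)), 2L)
})

test_that("unreadable input and empty selections raise errors", {
  expect_error(readStructure(file.path(tempdir(), "nope.pdb")),
               "not found")
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER junk", "END"), tf)
  expect_error(readStructure(tf))
})
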