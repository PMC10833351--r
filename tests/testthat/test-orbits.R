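test_that("worked-example graph reproduces every published orbit degree", {
  g <- fig2Graph()
  expect_equal(nNodes(g), 9L)
  expect_equal(nEdges(g), 10L)
  m <- orbitCounts(countOrbits(g))
  rownames(m) <- LETTERS[1:9]
  expect_identical(m["C", "O0"], 3L)
  expect_identical(m["C", "O1"], 5L)
  expect_identical(m["C", "O5"], 10L)
  expect_identical(m["F", "O0"], 4L)
  expect_identical(m["F", "O1"], 2L)
  expect_equal(sort(rownames(m)[m[, "O3"] > 0]), c("F", "G", "H", "I"))
  # the matrix maximum is the 10 at (C, O5)
  expect_equal(max(m), 10L)
  expect_equal(which(m == 10L, arr.ind = TRUE)[1, ],
               c(row = 3L, col = 6L))
})

test_that("small canonical graphs have the forced orbit signatures", {
  # single edge: both ends on orbit 0 only
  e1 <- contactGraphFromEdges(2, rbind(c(1, 2)))
  m <- orbitCounts(countOrbits(e1))
  expect_equal(unname(m[, 1]), c(1L, 1L))
  expect_true(all(m[, 2:15] == 0L))

  # K3: the induced 3-subgraph is the triangle, never a path
  k3 <- contactGraphFromEdges(3, t(utils::combn(3, 2)))
  m <- orbitCounts(countOrbits(k3))
  expect_equal(unname(m[, "O0"]), rep(2L, 3))
  expect_equal(unname(m[, "O3"]), rep(1L, 3))
  expect_true(all(m[, c("O1", "O2")] == 0L))

  # K4: frozen from the brute-force enumeration of its induced subgraphs
  k4 <- contactGraphFromEdges(4, t(utils::combn(4, 2)))
  m <- orbitCounts(countOrbits(k4))
  expect_equal(unname(m[, "O0"]), rep(3L, 4))
  expect_equal(unname(m[, "O3"]), rep(3L, 4))
  expect_equal(unname(m[, "O14"]), rep(1L, 4))
  expect_true(all(m[, paste0("O", c(1, 2, 4:13))] == 0L))

  # path P4 and star S4 and cycle C4
  p4 <- contactGraphFromEdges(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
  m <- orbitCounts(countOrbits(p4))
  expect_equal(unname(m[, "O4"]), c(1L, 0L, 0L, 1L))
  expect_equal(unname(m[, "O5"]), c(0L, 1L, 1L, 0L))

  s4 <- contactGraphFromEdges(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  m <- orbitCounts(countOrbits(s4))
  expect_equal(unname(m[, "O7"]), c(1L, 0L, 0L, 0L))
  expect_equal(unname(m[, "O6"]), c(0L, 1L, 1L, 1L))

  c4 <- contactGraphFromEdges(4, rbind(c(1, 2), c(2, 3), c(3, 4),
                                       c(1, 4)))
  expect_equal(unname(orbitCounts(countOrbits(c4))[, "O8"]), rep(1L, 4))
})

test_that("efficient counter equals the brute-force oracle on random graphs", {
  for (s in 1:30) {
    n <- 5L + (s %% 18L)
    p <- 0.05 + 0.45 * (s %% 7L) / 6
    g <- randomGraph(n, p, seed = s)
    expect_identical(plainOrbits(countOrbits(g)),
                     plainOrbits(bruteForceOrbits(g)),
                     info = sprintf("seed %d n %d p %.2f", s, n, p))
  }
})

test_that("orbit-sum identities hold against the oracle graphlet tally", {
  info <- orbitGraphletTable()
  for (s in c(3, 14, 27)) {
    g <- randomGraph(15, 0.3, seed = s)
    bf <- bruteForceOrbits(g)
    m <- orbitCounts(bf)
    tally <- attr(m, "graphletCounts")
    expect_equal(sum(m[, "O0"]), 2L * nEdges(g))
    expect_equal(sum(m[, "O1"]), 2L * sum(m[, "O2"]))
    expect_equal(sum(m[, "O3"]), 3L * unname(tally["G2"]))
    expect_equal(sum(m[, "O4"]), sum(m[, "O5"]))
    for (k in 0:14) {
      expect_equal(
        sum(m[, k + 1L]),
        info$multiplicity[k + 1L] * unname(tally[info$graphlet[k + 1L]]),
        info = paste("orbit", k))
    }
  }
})

test_that("orbit counts are isomorphism-invariant under node relabeling", {
  g <- randomGraph(12, 0.35, seed = 8)
  perm <- withr::with_seed(9, sample(12))
  e <- edgeMatrix(g)
  gPerm <- contactGraphFromEdges(12, cbind(perm[e[, 1]], perm[e[, 2]]))
  m <- orbitCounts(countOrbits(g))
  mPerm <- orbitCounts(countOrbits(gPerm))
  expect_equal(unname(mPerm[perm, ]), unname(m[, ]))
})

test_that("disconnected and empty graphs are handled", {
  empty <- contactGraphFromEdges(5, matrix(integer(0), ncol = 2))
  expect_true(all(orbitCounts(countOrbits(empty)) == 0L))
  expect_true(all(orbitCounts(bruteForceOrbits(empty)) == 0L))

  # two disjoint triangles: per-component counting
  twoTri <- contactGraphFromEdges(6, rbind(c(1, 2), c(2, 3), c(1, 3),
                                           c(4, 5), c(5, 6), c(4, 6)))
  m <- orbitCounts(countOrbits(twoTri))
  expect_equal(unname(m[, "O3"]), rep(1L, 6))
  expect_true(all(m[, 5:15] == 0L))
})

test_that("brute force refuses oversized graphs", {
  g <- randomGraph(45, 0.1, seed = 1)
  expect_error(bruteForceOrbits(g), "refusing")
})

test_that("orbit TSV export carries identity columns and 15 orbit columns", {
  s <- syntheticStructure(40, seed = 2, noiseSd = 0)
  g <- buildContactGraph(s$model, 5.0)
  om <- countOrbits(g)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeOrbitTable(om, s$model, tf)
  tab <- read.delim(tf, comment.char = "#")
  expect_equal(nrow(tab), 40L)
  expect_equal(colnames(tab),
               c("chain", "resSeq", "atomName", paste0("O", 0:14)))
  expect_equal(tab$O0, unname(orbitCounts(om)[, 1]))
})
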