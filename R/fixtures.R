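#' The nine-node, ten-edge worked-example graph
#'
#' Canonical regression fixture for the orbit counter.  Nodes A..I map to
#' indices 1..9; edges are A-B, B-C, C-D, D-E, C-F, F-G, F-H, F-I, G-H,
#' H-I.  Eight of the ten edges are pinned directly by the published path
#' enumerations around nodes C and F; the remaining two (G-H and H-I) are
#' reconstructed from the triangle membership statement (exactly F, G, H,
#' I touch the triangle orbit) and validated by requiring the full set of
#' printed orbit degrees simultaneously -- notably that the matrix maximum
#' is 10 at (C, O5) -- which this edge set uniquely satisfies.
#'
#' @return a [ContactGraph] (abstract; cutoff `NA`) whose edge matrix
#'   carries node letters as an attribute `nodeNames`.
#' @export
fig2Graph <- function() {
  nodes <- LETTERS[1:9]
  edges <- rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E"),
                 c("C", "F"), c("F", "G"), c("F", "H"), c("F", "I"),
                 c("G", "H"), c("H", "I"))
  idx <- matrix(match(edges, nodes), ncol = 2L)
  g <- contactGraphFromEdges(9L, idx)
  attr(g@edges, "nodeNames") <- nodes
  g
}

#' Reproducible Erdos-Renyi random graph
#'
#' @param n number of nodes (>= 2).
#' @param p edge probability in [0, 1].
#' @param seed integer seed; global RNG state is restored.
#' @return a [ContactGraph] (abstract).
#' @export
randomGraph <- function(n, p, seed = 1L) {
  stopifnot(n >= 2L, p >= 0, p <= 1)
  pairs <- t(utils::combn(n, 2L))
  keep <- withr::with_seed(seed, stats::runif(nrow(pairs)) < p)
  contactGraphFromEdges(n, pairs[keep, , drop = FALSE])
}

#' Default generating coefficients for synthetic structures
#'
#' A GDV coefficient set used by the synthetic-data generator: all orbit
#' weights negative (denser, more richly wired neighborhoods mean lower
#' mobility), dominated by the path orbits O4, O1 and O5 -- the wiring
#' features that carry most of the signal in real structures.  Defined on
#' z-scored features with intercept 0.
#'
#' @return a [CoefficientSet] (`provenance = "preset"`).
#' @export
syntheticGdvCoefficients <- function() {
  b <- c(O0 = -0.05, O1 = -0.25, O2 = -0.05, O3 = -0.02, O4 = -0.30,
         O5 = -0.20, O6 = -0.05, O7 = -0.02, O8 = -0.01, O9 = -0.08,
         O10 = -0.05, O11 = -0.02, O12 = -0.06, O13 = -0.03,
         O14 = -0.01)
  new("CoefficientSet", intercept = 0, betas = b, modelKind = "gdv",
      cutoff = 5.0, provenance = "preset")
}

#' Generate a synthetic protein-like structure with known B-value model
#'
#' Generates 3D coordinates (helix-like by default: ideal alpha-helical
#' rise of 1.5 A and ~100 degree twist per residue, four jittered atoms
#' per residue, so contact counts resemble real proteins), builds the
#' contact graph at the generating cutoff, computes the GDV features
#' through the standard pipeline (count, optional smooth, z-score), and
#' sets the true normalized B values to
#' `intercept + sum_k beta_k feature_k + N(0, noiseSd)`.  The raw B
#' column written into the model is `bMean + bSd * truth`, floored at
#' 1.0 Angstrom^2.
#'
#' Pure function of its arguments including `seed`.
#'
#' @param nAtoms number of atoms (>= 20).
#' @param seed integer seed.
#' @param geometry `"helix"` (default) or `"cloud"` (uniform points at
#'   protein-like density 0.05 atoms/A^3).
#' @param coefficients generating [CoefficientSet] (default
#'   [syntheticGdvCoefficients()]).
#' @param noiseSd standard deviation of the Gaussian noise on the
#'   normalized scale (default 0.5).
#' @param bMean,bSd mapping from normalized to raw B values (defaults 30
#'   and 10 Angstrom^2).
#' @param smooth,radius feature smoothing switches as in
#'   [gdvFeatures()].
#' @param entryId entry identifier.
#' @return list with components `model` (a [StructureModel] carrying the
#'   raw B column), `truth` (numeric, the true normalized B values),
#'   `features` (the [FeatureMatrix] the truth was generated from) and
#'   `coefficients`.
#' @export
syntheticStructure <- function(nAtoms, seed = 1L,
                               geometry = c("helix", "cloud"),
                               coefficients = syntheticGdvCoefficients(),
                               noiseSd = 0.5, bMean = 30, bSd = 10,
                               smooth = TRUE, radius = 2.0,
                               entryId = sprintf("synth%04d", seed)) {
  geometry <- match.arg(geometry)
  stopifnot(nAtoms >= 20L, noiseSd >= 0)
  xyz <- withr::with_seed(seed, {
    if (geometry == "helix") {
      res <- (seq_len(nAtoms) - 1L) %/% 4L
      ang <- res * 100 * pi / 180
      base <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * res)
      base + matrix(stats::rnorm(3L * nAtoms, sd = 0.4), ncol = 3L)
    } else {
      side <- (nAtoms / 0.05)^(1 / 3)
      matrix(stats::runif(3L * nAtoms, 0, side), ncol = 3L)
    }
  })
  if (max(apply(xyz, 2L, stats::sd)) == 0)
    stop("degenerate geometry: all points coincident")

  atoms <- data.frame(
    serial = seq_len(nAtoms),
    atomName = rep(c("N", "CA", "C", "O"), length.out = nAtoms),
    element = rep(c("N", "C", "C", "O"), length.out = nAtoms),
    altloc = "", resName = "ALA", chainId = "A",
    resSeq = (seq_len(nAtoms) - 1L) %/% 4L + 1L, icode = "",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    occupancy = 1, bValue = 0, isHetero = FALSE, isEnvironment = FALSE,
    stringsAsFactors = FALSE)
  model <- new("StructureModel", entryId = entryId, atoms = atoms,
               resolution = NA_real_,
               metadata = list(generator = geometry, seed = seed))

  feats <- gdvFeatures(model, cutoff = coefficients@cutoff,
                       modelKind = modelKind(coefficients),
                       smooth = smooth, radius = radius, zscore = TRUE)
  signal <- predictB(coefficients, feats)
  noise <- withr::with_seed(seed + 1L,
                            stats::rnorm(nAtoms, sd = noiseSd))
  truth <- signal + noise
  model@atoms$bValue <- pmax(bMean + bSd * truth, 1.0)
  list(model = model, truth = truth, features = feats,
       coefficients = coefficients)
}

#' Generate a batch of synthetic entries for cross-validation studies
#'
#' @param nEntries number of entries.
#' @param nAtoms atoms per entry.
#' @param seed base seed; entry i uses `seed + 1000 * i`.
#' @param ... passed to [syntheticStructure()].
#' @return list of entries, each a list with `features`, `response`
#'   (truth as numeric), `entryId`, `model`.
#' @export
syntheticEntries <- function(nEntries, nAtoms, seed = 1L, ...) {
  lapply(seq_len(nEntries), function(i) {
    s <- syntheticStructure(nAtoms, seed = seed + 1000L * i, ...)
    list(features = s$features, response = s$truth,
         entryId = entryId(s$model), model = s$model)
  })
}

#' Write a minimal toy PDB file
#'
#' Writes all atoms of the model (including environment atoms) as plain
#' ATOM/HETATM records that round-trip through [readStructure()]:
#' coordinates to 3 decimals, B values to 2 decimals.
#'
#' @param model a [StructureModel].
#' @param path output path.
#' @export
writeToyPdb <- function(model, path) {
  stopifnot(is(model, "StructureModel"))
  .writePdbAtoms(atomTable(model), path)
  invisible(NULL)
}

#' Build a small StructureModel from bare coordinates
#'
#' Fixture helper: wraps an N x 3 coordinate matrix as carbon atoms in
#' chain A, one residue per atom.
#'
#' @param xyz N x 3 numeric matrix (Angstrom).
#' @param b numeric B values (recycled; default 0).
#' @param entryId entry identifier.
#' @return a [StructureModel].
#' @export
modelFromCoords <- function(xyz, b = 0, entryId = "toy") {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n), atomName = "CA", element = "C", altloc = "",
    resName = "ALA", chainId = "A", resSeq = seq_len(n), icode = "",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], occupancy = 1,
    bValue = rep_len(as.numeric(b), n), isHetero = FALSE,
    isEnvironment = FALSE, stringsAsFactors = FALSE)
  new("StructureModel", entryId = entryId, atoms = atoms,
      resolution = NA_real_, metadata = list())
}
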