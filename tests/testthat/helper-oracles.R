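# Independent reference implementations used as oracles in the tests.

# All-pairs O(N^2) edge reference for the cell-list neighbor search.
refEdges <- function(xyz, cutoff, strict = TRUE) {
  d <- as.matrix(dist(xyz))
  keep <- if (strict) d < cutoff else d <= cutoff
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  which(keep, arr.ind = TRUE)[, c(1, 2), drop = FALSE]
}

sortEdges <- function(e) {
  e <- matrix(as.integer(e), ncol = 2)
  if (nrow(e) == 0) return(e)
  flip <- e[, 1] > e[, 2]
  e[flip, ] <- e[flip, 2:1]
  unname(e[order(e[, 1], e[, 2]), , drop = FALSE])
}

# Monte-Carlo oracle for the expected per-entry Pearson r between the
# noise-free signal and a noisy realization: r is simulated directly from
# the generating model, never through the fitting path.
mcExpectedR <- function(signalList, noiseSd, nSim = 200, seed = 999) {
  withr::with_seed(seed, {
    mean(vapply(seq_len(nSim), function(i) {
      sig <- signalList[[((i - 1) %% length(signalList)) + 1]]
      cor(sig, sig + rnorm(length(sig), sd = noiseSd))
    }, numeric(1)))
  })
}

# Orbit matrix without class/attribute baggage, for equality checks.
plainOrbits <- function(om) {
  m <- GraphletADP::orbitCounts(om)
  attr(m, "graphletCounts") <- NULL
  unname(m)
}

toyThreeAtomModel <- function() {
  modelFromCoords(matrix(c(0, 0, 0,
                           4, 0, 0,
                           8, 0, 0), ncol = 3, byrow = TRUE),
                  b = c(10, 20, 30), entryId = "toy3")
}
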