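#' Count graphlet orbit degrees (GDVs) for every node
#'
#' Computes, for each node of a simple undirected graph, how many induced
#' connected subgraphs on 2-4 nodes (graphlets G0-G8) contain the node at
#' each of the 15 automorphism orbits O0..O14.  Counts are per occurrence:
#' a node sitting on the same orbit in ten distinct graphlet occurrences
#' scores 10.  Column `O0` equals the plain degree.  Disconnected input
#' graphs are fine; graphlets are induced connected subgraphs, so
#' components are handled automatically.
#'
#' The counter enumerates every connected induced subgraph of size 3 and 4
#' exactly once (ESU enumeration, implemented in C++) and classifies it by
#' its edge count and within-subgraph degree signature.  Its contract is
#' entrywise equality with [bruteForceOrbits()], the definitional oracle.
#'
#' @param graph a [ContactGraph].
#' @return an [OrbitMatrix] (N x 15, integer).
#' @seealso [bruteForceOrbits()], [writeOrbitTable()]
#' @export
countOrbits <- function(graph) {
  stopifnot(is(graph, "ContactGraph"))
  m <- cpp_count_orbits(nNodes(graph), edgeMatrix(graph))
  colnames(m) <- paste0("O", 0:14)
  new("OrbitMatrix", counts = m, cutoff = graphCutoff(graph))
}

# How many nodes of each parent graphlet lie on each orbit; used by the
# sum identities Sum_n O_k(n) = m_k * count(graphlet).
.ORBIT_INFO <- data.frame(
  orbit = 0:14,
  graphlet = c("G0", "G1", "G1", "G2", "G3", "G3", "G4", "G4", "G5",
               "G6", "G6", "G6", "G7", "G7", "G8"),
  multiplicity = c(2L, 2L, 1L, 3L, 2L, 2L, 3L, 1L, 4L, 1L, 2L, 1L, 2L,
                   2L, 4L),
  stringsAsFactors = FALSE)

#' Orbit-to-graphlet lookup table
#'
#' One row per orbit: parent graphlet (G0-G8) and the number of nodes of
#' that graphlet lying on the orbit (the multiplicity in the identity
#' `sum_n O_k(n) = m_k * count(graphlet)`).
#'
#' @return data.frame with columns `orbit`, `graphlet`, `multiplicity`.
#' @export
orbitGraphletTable <- function() .ORBIT_INFO

#' Brute-force orbit counting by exhaustive induced-subgraph enumeration
#'
#' Definitional oracle for [countOrbits()]: enumerates every 2-, 3- and
#' 4-node subset (via `combn`), keeps the connected induced subgraphs,
#' classifies each by its degree signature and accumulates per-node orbit
#' counts.  Independent of the C++ enumeration path.  Quadratic-to-quartic
#' in node count, hence restricted to small graphs.
#'
#' @param graph a [ContactGraph] with at most `maxNodes` nodes.
#' @param maxNodes refusal threshold (default 40).
#' @return an [OrbitMatrix] carrying an attribute `graphletCounts`
#'   (named integer vector, total occurrences of G0..G8 in the graph) on
#'   its `counts` slot.
#' @export
bruteForceOrbits <- function(graph, maxNodes = 40L) {
  stopifnot(is(graph, "ContactGraph"))
  n <- nNodes(graph)
  if (n > maxNodes)
    stop("refusing brute-force enumeration for n = ", n, " > ", maxNodes)
  A <- matrix(FALSE, n, n)
  e <- edgeMatrix(graph)
  if (nrow(e)) {
    A[e] <- TRUE
    A[e[, 2:1, drop = FALSE]] <- TRUE
  }
  orb <- matrix(0L, n, 15L, dimnames = list(NULL, paste0("O", 0:14)))
  tally <- stats::setNames(integer(9L), paste0("G", 0:8))

  deg <- rowSums(A)
  orb[, "O0"] <- as.integer(deg)
  tally["G0"] <- nrow(e)

  # accumulate counts for orbit ids 1..14 (column = orbit + 1)
  addCounts <- function(nodes, orbits) {
    cnt <- tabulate((orbits - 1L) * n + nodes, nbins = 14L * n)
    orb[, 2:15] <<- orb[, 2:15] + matrix(cnt, n, 14L)
  }

  if (n >= 3L) {
    S <- utils::combn(n, 3L)
    e12 <- A[cbind(S[1L, ], S[2L, ])]
    e13 <- A[cbind(S[1L, ], S[3L, ])]
    e23 <- A[cbind(S[2L, ], S[3L, ])]
    ecnt <- e12 + e13 + e23
    conn <- ecnt >= 2L
    if (any(conn)) {
      Sc <- S[, conn, drop = FALSE]
      d <- rbind(e12 + e13, e12 + e23, e13 + e23)[, conn, drop = FALSE]
      ec <- ecnt[conn]
      tally["G1"] <- sum(ec == 2L)
      tally["G2"] <- sum(ec == 3L)
      orbId <- ifelse(rep(ec, each = 3L) == 3L, 3L,
                      ifelse(as.vector(d) == 2L, 2L, 1L))
      addCounts(as.vector(Sc), orbId)
    }
  }

  if (n >= 4L) {
    S <- utils::combn(n, 4L)
    p <- list(A[cbind(S[1L, ], S[2L, ])], A[cbind(S[1L, ], S[3L, ])],
              A[cbind(S[1L, ], S[4L, ])], A[cbind(S[2L, ], S[3L, ])],
              A[cbind(S[2L, ], S[4L, ])], A[cbind(S[3L, ], S[4L, ])])
    ecnt <- Reduce(`+`, p)
    d <- rbind(p[[1L]] + p[[2L]] + p[[3L]],
               p[[1L]] + p[[4L]] + p[[5L]],
               p[[2L]] + p[[4L]] + p[[6L]],
               p[[3L]] + p[[5L]] + p[[6L]])
    # 4 nodes, >= 3 edges, minimum degree >= 1  <=>  connected
    conn <- ecnt >= 3L & apply(d, 2L, min) >= 1L
    if (any(conn)) {
      Sc <- S[, conn, drop = FALSE]
      dc <- d[, conn, drop = FALSE]
      ec <- ecnt[conn]
      maxd <- apply(dc, 2L, max)
      tally["G3"] <- sum(ec == 3L & maxd == 2L)
      tally["G4"] <- sum(ec == 3L & maxd == 3L)
      tally["G5"] <- sum(ec == 4L & maxd == 2L)
      tally["G6"] <- sum(ec == 4L & maxd == 3L)
      tally["G7"] <- sum(ec == 5L)
      tally["G8"] <- sum(ec == 6L)
      eRep <- rep(ec, each = 4L)
      mRep <- rep(maxd, each = 4L)
      dv <- as.vector(dc)
      orbId <- integer(length(dv))
      orbId[eRep == 3L & mRep == 2L] <-
        ifelse(dv[eRep == 3L & mRep == 2L] == 1L, 4L, 5L)
      orbId[eRep == 3L & mRep == 3L] <-
        ifelse(dv[eRep == 3L & mRep == 3L] == 1L, 6L, 7L)
      orbId[eRep == 4L & mRep == 2L] <- 8L
      sel <- eRep == 4L & mRep == 3L
      orbId[sel] <- c(9L, 10L, 11L)[dv[sel]]
      orbId[eRep == 5L] <- ifelse(dv[eRep == 5L] == 2L, 12L, 13L)
      orbId[eRep == 6L] <- 14L
      addCounts(as.vector(Sc), orbId)
    }
  }

  attr(orb, "graphletCounts") <- tally
  new("OrbitMatrix", counts = orb, cutoff = graphCutoff(graph))
}

#' Export an orbit matrix as TSV
#'
#' One row per atom: identity columns (`chain`, `resSeq`, `atomName`)
#' followed by the 15 integer orbit-degree columns `O0`..`O14`.
#'
#' @param orbits an [OrbitMatrix].
#' @param model the [StructureModel] the rows refer to (same order).
#' @param path output path.
#' @param header optional comment lines (prefixed `#`) written first.
#' @export
writeOrbitTable <- function(orbits, model, path, header = character(0)) {
  stopifnot(is(orbits, "OrbitMatrix"), is(model, "StructureModel"))
  m <- orbitCounts(orbits)
  if (nrow(m) != nAtoms(model))
    stop("orbit matrix rows (", nrow(m), ") do not match atom count (",
         nAtoms(model), ")")
  a <- atomTable(model)
  out <- data.frame(chain = a$chainId, resSeq = a$resSeq,
                    atomName = a$atomName, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(out, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(NULL)
}
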