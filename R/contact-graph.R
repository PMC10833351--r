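#' Build the atom contact graph
#'
#' Two atoms are joined by an edge iff their center-to-center Euclidean
#' distance is strictly below `cutoff`.  Environment atoms are included as
#' nodes.  Edges do not distinguish covalent from non-covalent contacts,
#' and no periodic/crystal symmetry handling is performed -- crystal
#' context must come from pre-expanded environment atoms.
#'
#' The neighbor search uses cell lists and is exactly equivalent (bit
#' identical edge membership) to the all-pairs check.
#'
#' @param x a [StructureModel] or an N x 3 numeric coordinate matrix
#'   (Angstrom).
#' @param cutoff positive cutoff distance in Angstrom.  The package
#'   defaults are 5.0 A for the GDV model and 7.0 A for the contact model.
#' @return a [ContactGraph].
#' @export
buildContactGraph <- function(x, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  xyz <- if (is(x, "StructureModel")) atomCoords(x) else as.matrix(x)
  if (ncol(xyz) != 3L) stop("coordinates must be N x 3")
  if (nrow(xyz) < 1L) stop("need at least one atom")
  bad <- which(!apply(is.finite(xyz), 1L, all))
  if (length(bad))
    stop("non-finite coordinates for atom(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  e <- cpp_contact_edges(xyz, cutoff, TRUE)
  new("ContactGraph", nNodes = nrow(xyz), edges = .canonicalEdges(e),
      cutoff = cutoff)
}

.canonicalEdges <- function(e) {
  e <- matrix(as.integer(e), ncol = 2L)
  if (nrow(e)) {
    flip <- e[, 1L] > e[, 2L]
    e[flip, ] <- e[flip, 2:1]
    e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  }
  e
}

#' Construct a ContactGraph from an explicit edge list
#'
#' For abstract (non-geometric) graphs such as worked examples or random
#' graphs.  Edges are canonicalized to i < j and deduplicated checks are
#' enforced by the class validity.
#'
#' @param nNodes number of nodes.
#' @param edges m x 2 matrix (or 2-column data.frame) of 1-based node
#'   pairs.
#' @param cutoff optional cutoff annotation in Angstrom.
#' @return a [ContactGraph].
#' @export
contactGraphFromEdges <- function(nNodes, edges, cutoff = NA_real_) {
  e <- .canonicalEdges(as.matrix(edges))
  new("ContactGraph", nNodes = as.integer(nNodes), edges = e,
      cutoff = as.numeric(cutoff))
}

#' Per-atom neighbor lists within a radius
#'
#' For every atom, the indices of all other atoms at distance less than or
#' equal to `radius` (inclusive, so exact covalent-bond-length pairs are
#' captured; this deliberately differs from the strict `<` used for the
#' contact graph).  Self is excluded.
#'
#' @param x a [StructureModel] or N x 3 coordinate matrix.
#' @param radius positive radius in Angstrom (2.0 A is the smoothing
#'   default).
#' @return list of integer vectors, one per atom, sorted ascending.
#' @export
neighborsWithin <- function(x, radius) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0)
  xyz <- if (is(x, "StructureModel")) atomCoords(x) else as.matrix(x)
  if (ncol(xyz) != 3L) stop("coordinates must be N x 3")
  bad <- which(!apply(is.finite(xyz), 1L, all))
  if (length(bad))
    stop("non-finite coordinates for atom(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  cpp_neighbor_lists(xyz, radius)
}

#' Node degrees of a contact graph
#'
#' @param graph a [ContactGraph].
#' @return integer vector of degrees.
#' @export
graphDegrees <- function(graph) {
  stopifnot(is(graph, "ContactGraph"))
  tabulate(as.vector(edgeMatrix(graph)), nbins = nNodes(graph))
}

#' Export an edge list as text
#'
#' Writes the edge set as a two-column whitespace-separated file with
#' 0-based node indices (debugging aid).
#'
#' @param graph a [ContactGraph].
#' @param path output path.
#' @export
writeEdgeList <- function(graph, path) {
  stopifnot(is(graph, "ContactGraph"))
  e <- edgeMatrix(graph) - 1L
  utils::write.table(e, path, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(NULL)
}
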