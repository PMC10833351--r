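#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib GraphletADP, .registration = TRUE
NULL

# Column layout of the atom table inside a StructureModel.  Atom order is
# load-bearing: it defines the row indices of every downstream matrix.
.ATOM_COLS <- c("serial", "atomName", "element", "altloc", "resName",
                "chainId", "resSeq", "icode", "x", "y", "z",
                "occupancy", "bValue", "isHetero", "isEnvironment")

#' StructureModel: an ordered atom list with coordinates and B values
#'
#' Thin container around a parsed macromolecular model.  The `atoms` slot is
#' a data.frame with one row per atom (columns `serial`, `atomName`,
#' `element`, `altloc`, `resName`, `chainId`, `resSeq`, `icode`, `x`, `y`,
#' `z`, `occupancy`, `bValue`, `isHetero`, `isEnvironment`); row order is
#' stable and defines the node indices of the contact graph and the rows of
#' all feature matrices.  Environment atoms are symmetry-related copies kept
#' only to complete the contact shell of surface atoms; they take part in
#' graph building and smoothing but are excluded from regression responses.
#'
#' @slot entryId single string identifying the entry.
#' @slot atoms data.frame of atom records (see above).
#' @slot resolution numeric, resolution in Angstrom (`NA` if unknown).
#' @slot metadata named list of free-form key/value metadata.
#' @exportClass StructureModel
setClass("StructureModel",
         representation(entryId = "character", atoms = "data.frame",
                        resolution = "numeric", metadata = "list"),
         prototype(entryId = "unknown", resolution = NA_real_,
                   metadata = list()))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  if (!all(.ATOM_COLS %in% names(a)))
    return(paste("atoms is missing columns:",
                 paste(setdiff(.ATOM_COLS, names(a)), collapse = ", ")))
  if (nrow(a) < 1L) return("model must contain at least one atom")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite atom coordinates")
  # no sign constraint on bValue: raw ADPs are nonnegative, but the B
  # column is also used to carry normalized scores, which can be negative
  if (length(object@entryId) != 1L) return("entryId must be length 1")
  TRUE
})

#' ContactGraph: simple undirected graph over atoms
#'
#' Nodes are atom indices in [1, nNodes] in StructureModel order.  An edge
#' (i, j) is present iff the Euclidean distance between atoms i and j is
#' strictly below the cutoff.  The `edges` slot is an m x 2 integer matrix
#' with i < j per row, no duplicates and no self-loops.
#'
#' @slot nNodes integer node count.
#' @slot edges m x 2 integer matrix of 1-based node index pairs.
#' @slot cutoff numeric cutoff distance in Angstrom (`NA` for abstract
#'   graphs that were not built from coordinates).
#' @exportClass ContactGraph
setClass("ContactGraph",
         representation(nNodes = "integer", edges = "matrix",
                        cutoff = "numeric"),
         prototype(cutoff = NA_real_))

setValidity("ContactGraph", function(object) {
  e <- object@edges
  n <- object@nNodes
  if (length(n) != 1L || is.na(n) || n < 1L) return("nNodes must be >= 1")
  if (!is.numeric(e) || ncol(e) != 2L) return("edges must be an m x 2 matrix")
  if (nrow(e)) {
    if (any(e < 1L | e > n)) return("edge index out of [1, nNodes]")
    if (any(e[, 1L] == e[, 2L])) return("self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L])) return("edges must be stored with i < j")
    if (anyDuplicated(paste(e[, 1L], e[, 2L]))) return("duplicate edges")
  }
  TRUE
})

#' OrbitMatrix: per-node graphlet orbit degrees (GDVs)
#'
#' N x 15 matrix of nonnegative integers; column k + 1 holds the degree of
#' orbit k (k = 0..14) in the standard numbering of the connected 2-4-node
#' graphlets G0-G8.  Column `O0` equals the plain graph degree.
#'
#' @slot counts N x 15 integer matrix with colnames `O0`..`O14`.
#' @slot cutoff cutoff distance (Angstrom) of the source graph, `NA` for
#'   abstract graphs.
#' @exportClass OrbitMatrix
setClass("OrbitMatrix",
         representation(counts = "matrix", cutoff = "numeric"),
         prototype(cutoff = NA_real_))

setValidity("OrbitMatrix", function(object) {
  m <- object@counts
  if (ncol(m) != 15L) return("orbit matrix must have 15 columns")
  if (!identical(colnames(m), paste0("O", 0:14)))
    return("columns must be named O0..O14")
  if (any(m < 0) || any(m != round(m)))
    return("orbit degrees must be nonnegative integers")
  TRUE
})

#' FeatureMatrix: transformed explanatory variables for the regression
#'
#' Real-valued N x K matrix derived from an OrbitMatrix (15 columns for the
#' GDV model, the single `O0` column for the contact model), with a record
#' of the transforms applied, in order, from `smoothed` and
#' `column_zscored`.
#'
#' @slot values numeric matrix with orbit colnames.
#' @slot transforms ordered character vector of applied transforms.
#' @slot cutoff source graph cutoff in Angstrom.
#' @slot smoothRadius smoothing radius in Angstrom (`NA` if unsmoothed).
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
         representation(values = "matrix", transforms = "character",
                        cutoff = "numeric", smoothRadius = "numeric"),
         prototype(transforms = character(0), cutoff = NA_real_,
                   smoothRadius = NA_real_))

setValidity("FeatureMatrix", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (is.null(colnames(object@values))) return("columns must be named")
  if (!all(object@transforms %in% c("smoothed", "column_zscored")))
    return("unknown transform label")
  TRUE
})

#' BValueVector: per-atom response values with normalization bookkeeping
#'
#' @slot values numeric per-atom B values (raw Angstrom^2 or normalized).
#' @slot scale either `"raw"` or `"normalized"`.
#' @slot groups character normalization-group label per atom (chain,
#'   domain or TLS-group id; a single repeated label for whole-structure
#'   normalization).
#' @exportClass BValueVector
setClass("BValueVector",
         representation(values = "numeric", scale = "character",
                        groups = "character"))

setValidity("BValueVector", function(object) {
  if (!object@scale %in% c("raw", "normalized"))
    return("scale must be 'raw' or 'normalized'")
  if (length(object@groups) != length(object@values))
    return("groups and values lengths differ")
  TRUE
})

#' CoefficientSet: intercept and orbit coefficients of a fitted or preset model
#'
#' @slot intercept numeric intercept b0.
#' @slot betas named numeric vector of orbit coefficients (`O0` only for the
#'   contact model; `O0`..`O14` for the GDV model).
#' @slot modelKind `"contact"` or `"gdv"`.
#' @slot cutoff graph cutoff distance in Angstrom the model was built for.
#' @slot provenance one of `"fitted"`, `"preset"`, `"user"`.
#' @exportClass CoefficientSet
setClass("CoefficientSet",
         representation(intercept = "numeric", betas = "numeric",
                        modelKind = "character", cutoff = "numeric",
                        provenance = "character"),
         prototype(provenance = "user", cutoff = NA_real_))

setValidity("CoefficientSet", function(object) {
  if (!object@modelKind %in% c("contact", "gdv"))
    return("modelKind must be 'contact' or 'gdv'")
  want <- if (object@modelKind == "contact") "O0" else paste0("O", 0:14)
  if (!identical(names(object@betas), want))
    return(sprintf("betas must be named %s for a %s model",
                   paste(want, collapse = ","), object@modelKind))
  if (!object@provenance %in% c("fitted", "preset", "user"))
    return("provenance must be fitted/preset/user")
  TRUE
})

#' FitReport: OLS fit summary for a contact or GDV model
#'
#' @slot coefficients the fitted [CoefficientSet].
#' @slot tStatistics named numeric t-statistics per coefficient (betas only).
#' @slot importance named numeric |t| rescaled so the maximum is 100.
#' @slot rSquared numeric coefficient of determination.
#' @slot nObs integer number of observations used.
#' @exportClass FitReport
setClass("FitReport",
         representation(coefficients = "CoefficientSet",
                        tStatistics = "numeric", importance = "numeric",
                        rSquared = "numeric", nObs = "integer"))

#' EvaluationReport: per-entry correlation table from cross-validation
#'
#' @slot perEntry data.frame with columns `entryId`, `modelKind`, `fold`,
#'   `pearsonR`.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
         representation(perEntry = "data.frame"))

#' SIGDParams: shifted inverse gamma distribution parameters
#'
#' Models the distribution of raw B values in one structure: density is an
#' inverse gamma in (B - b0) with shape `alpha` and scale `beta`, zero at
#' and below the shift `b0`.
#'
#' @slot alpha shape, > 0.
#' @slot beta scale in Angstrom^2, > 0.
#' @slot b0 shift in Angstrom^2.
#' @exportClass SIGDParams
setClass("SIGDParams",
         representation(alpha = "numeric", beta = "numeric", b0 = "numeric"))

setValidity("SIGDParams", function(object) {
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha <= 0) return("alpha must be a single positive number")
  if (length(object@beta) != 1L || !is.finite(object@beta) ||
      object@beta <= 0) return("beta must be a single positive number")
  if (length(object@b0) != 1L || !is.finite(object@b0))
    return("b0 must be a single finite number")
  TRUE
})

#' QCReport: outcome of the entry-level inclusion filters
#'
#' @slot entryId single string.
#' @slot passed logical; `TRUE` iff no rule failed.
#' @slot failures data.frame with columns `rule`, `observed`, `threshold`.
#' @exportClass QCReport
setClass("QCReport",
         representation(entryId = "character", passed = "logical",
                        failures = "data.frame"))

setValidity("QCReport", function(object) {
  if (!identical(object@passed, nrow(object@failures) == 0L))
    return("passed must be TRUE iff failures is empty")
  TRUE
})
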