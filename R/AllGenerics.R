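#' Accessor generics
#'
#' Small accessor layer over the S4 containers; user code should use these
#' rather than reaching into slots.
#'
#' @param x an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))

#' @rdname accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' @rdname accessors
#' @export
setGeneric("isEnvironment", function(x) standardGeneric("isEnvironment"))

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname accessors
#' @export
setGeneric("graphCutoff", function(x) standardGeneric("graphCutoff"))

#' @rdname accessors
#' @export
setGeneric("orbitCounts", function(x) standardGeneric("orbitCounts"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("transformsApplied", function(x) standardGeneric("transformsApplied"))

#' @rdname accessors
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname accessors
#' @export
setGeneric("bScale", function(x) standardGeneric("bScale"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("modelKind", function(x) standardGeneric("modelKind"))

#' @rdname accessors
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' @rdname accessors
#' @export
setGeneric("betas", function(x) standardGeneric("betas"))

#' @rdname accessors
#' @export
setGeneric("coefficientSet", function(x) standardGeneric("coefficientSet"))

#' @rdname accessors
#' @export
setGeneric("tStatistics", function(x) standardGeneric("tStatistics"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("perEntry", function(x) standardGeneric("perEntry"))

#' @rdname accessors
#' @export
setGeneric("qcPassed", function(x) standardGeneric("qcPassed"))

#' @rdname accessors
#' @export
setGeneric("qcFailures", function(x) standardGeneric("qcFailures"))

# ---- methods -------------------------------------------------------------

#' @rdname accessors
setMethod("atomTable", "StructureModel", function(x) x@atoms)

#' @rdname accessors
setMethod("nAtoms", "StructureModel", function(x) nrow(x@atoms))

#' @rdname accessors
setMethod("entryId", "StructureModel", function(x) x@entryId)

#' @rdname accessors
setMethod("atomCoords", "StructureModel", function(x)
  as.matrix(x@atoms[, c("x", "y", "z")]))

#' @rdname accessors
setMethod("isEnvironment", "StructureModel", function(x) x@atoms$isEnvironment)

#' @rdname accessors
setMethod("bValues", "StructureModel", function(x) x@atoms$bValue)

#' @rdname accessors
setMethod("nNodes", "ContactGraph", function(x) x@nNodes)

#' @rdname accessors
setMethod("edgeMatrix", "ContactGraph", function(x) x@edges)

#' @rdname accessors
setMethod("nEdges", "ContactGraph", function(x) nrow(x@edges))

#' @rdname accessors
setMethod("graphCutoff", "ContactGraph", function(x) x@cutoff)

#' @rdname accessors
setMethod("orbitCounts", "OrbitMatrix", function(x) x@counts)

#' @rdname accessors
setMethod("featureValues", "OrbitMatrix", function(x) {
  m <- x@counts
  storage.mode(m) <- "double"
  m
})

#' @rdname accessors
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname accessors
setMethod("transformsApplied", "FeatureMatrix", function(x) x@transforms)

#' @rdname accessors
setMethod("bValues", "BValueVector", function(x) x@values)

#' @rdname accessors
setMethod("bScale", "BValueVector", function(x) x@scale)

#' @rdname accessors
setMethod("groupLabels", "BValueVector", function(x) x@groups)

#' @rdname accessors
setMethod("modelKind", "CoefficientSet", function(x) x@modelKind)

#' @rdname accessors
setMethod("intercept", "CoefficientSet", function(x) x@intercept)

#' @rdname accessors
setMethod("betas", "CoefficientSet", function(x) x@betas)

#' @rdname accessors
setMethod("coefficientSet", "FitReport", function(x) x@coefficients)

#' @rdname accessors
setMethod("tStatistics", "FitReport", function(x) x@tStatistics)

#' @rdname accessors
setMethod("rSquared", "FitReport", function(x) x@rSquared)

#' @rdname accessors
setMethod("perEntry", "EvaluationReport", function(x) x@perEntry)

#' @rdname accessors
setMethod("qcPassed", "QCReport", function(x) x@passed)

#' @rdname accessors
setMethod("qcFailures", "QCReport", function(x) x@failures)

# ---- show methods --------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel '%s': %d atoms (%d environment), %d chain(s)\n",
              object@entryId, nrow(a), sum(a$isEnvironment),
              length(unique(a$chainId))))
  if (!is.na(object@resolution))
    cat(sprintf("  resolution: %.2f A\n", object@resolution))
})

setMethod("show", "ContactGraph", function(object) {
  cat(sprintf("ContactGraph: %d nodes, %d edges (cutoff %s A)\n",
              object@nNodes, nrow(object@edges),
              ifelse(is.na(object@cutoff), "NA",
                     format(object@cutoff))))
})

setMethod("show", "OrbitMatrix", function(object) {
  cat(sprintf("OrbitMatrix: %d nodes x 15 orbits; max degree %d (orbit O0 sum %d)\n",
              nrow(object@counts), max(object@counts),
              sum(object@counts[, 1L])))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d x %d [%s]\n", nrow(object@values),
              ncol(object@values),
              if (length(object@transforms))
                paste(object@transforms, collapse = " -> ")
              else "raw counts"))
})

setMethod("show", "CoefficientSet", function(object) {
  cat(sprintf("CoefficientSet (%s model, %s): intercept %.4g, %d beta(s)\n",
              object@modelKind, object@provenance, object@intercept,
              length(object@betas)))
})

setMethod("show", "FitReport", function(object) {
  cat(sprintf("FitReport: %s model, n = %d, R^2 = %.4f\n",
              object@coefficients@modelKind, object@nObs, object@rSquared))
})

setMethod("show", "EvaluationReport", function(object) {
  pe <- object@perEntry
  cat(sprintf("EvaluationReport: %d entry evaluations\n", nrow(pe)))
  for (mk in unique(pe$modelKind)) {
    r <- pe$pearsonR[pe$modelKind == mk]
    cat(sprintf("  %s: mean r = %.3f, median = %.3f, range [%.3f, %.3f]\n",
                mk, mean(r), stats::median(r), min(r), max(r)))
  }
})

setMethod("show", "SIGDParams", function(object) {
  cat(sprintf("SIGDParams: alpha = %.4g, beta = %.4g A^2, b0 = %.4g A^2\n",
              object@alpha, object@beta, object@b0))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport '%s': %s\n", object@entryId,
              if (object@passed) "PASS" else
                paste0("FAIL [", paste(object@failures$rule, collapse = ", "),
                       "]")))
})
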