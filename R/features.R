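#' Smooth per-atom features over close spatial neighbors
#'
#' Mimics the refinement restraint that covalently bonded atoms carry
#' similar displacement parameters: each atom's value becomes the sum of
#' its current value and the average value of all neighboring atoms within
#' `radius` (inclusive, default 2.0 A -- slightly above covalent bond
#' lengths).  Atoms with no neighbor inside the radius keep their value
#' unchanged.  The smoothing neighborhood is purely Euclidean and
#' independent of the graph cutoff used to build the GDVs.
#'
#' Smoothing is applied to raw orbit counts, before column z-scoring (the
#' default pipeline order is count -> smooth -> zscore).
#'
#' @param x an [OrbitMatrix] or [FeatureMatrix] whose rows align with
#'   `model`'s atoms.
#' @param model the [StructureModel] supplying coordinates.
#' @param radius smoothing radius in Angstrom (default 2.0).
#' @return a [FeatureMatrix] with `"smoothed"` appended to its transforms.
#' @export
smoothFeatures <- function(x, model, radius = 2.0) {
  stopifnot(is(model, "StructureModel"))
  v <- featureValues(x)
  if (nrow(v) != nAtoms(model))
    stop("feature rows (", nrow(v), ") do not match atom count (",
         nAtoms(model), ")")
  nb <- neighborsWithin(model, radius)
  out <- v
  for (i in seq_len(nrow(v))) {
    if (length(nb[[i]]))
      out[i, ] <- v[i, ] + colMeans(v[nb[[i]], , drop = FALSE])
  }
  prev <- if (is(x, "FeatureMatrix")) transformsApplied(x) else character(0)
  new("FeatureMatrix", values = out, transforms = c(prev, "smoothed"),
      cutoff = x@cutoff, smoothRadius = radius)
}

#' Standardize feature columns to mean 0, sd 1
#'
#' Each column is centered on its mean and divided by its sample (n - 1)
#' standard deviation, so that orbit columns with very different count
#' scales become comparable.  Constant columns cannot be standardized and
#' are mapped to all zeros with a warning.  Idempotent on already
#' standardized input.
#'
#' @param x an [OrbitMatrix] or [FeatureMatrix] with at least 2 rows.
#' @return a [FeatureMatrix] with `"column_zscored"` appended.
#' @export
zscoreColumns <- function(x) {
  v <- featureValues(x)
  if (nrow(v) < 2L) stop("need at least 2 rows to standardize")
  mu <- colMeans(v)
  sd <- apply(v, 2L, stats::sd)
  const <- sd == 0 | !is.finite(sd)
  if (any(const)) {
    warning("constant column(s) mapped to zero: ",
            paste(colnames(v)[const], collapse = ", "))
    sd[const] <- 1
  }
  out <- sweep(sweep(v, 2L, mu, "-"), 2L, sd, "/")
  out[, const] <- 0
  prev <- if (is(x, "FeatureMatrix")) transformsApplied(x) else character(0)
  sr <- if (is(x, "FeatureMatrix")) x@smoothRadius else NA_real_
  new("FeatureMatrix", values = out,
      transforms = c(prev, "column_zscored"), cutoff = x@cutoff,
      smoothRadius = sr)
}

#' Normalize B values to mean 0, sd 1 within groups
#'
#' B values are normalized independently per structure so that entries of
#' different overall mobility become comparable: subtract the group mean,
#' divide by the group sample standard deviation.  By default the whole
#' structure is one group; for entries whose B values are multimodal
#' (chains, domains or TLS groups at clearly different B levels) the
#' normalization should be performed per mode, via `groupBy = "chain"` or
#' an explicit label vector.
#'
#' @param x a [StructureModel] (non-environment atoms are used), a
#'   [BValueVector], or a plain numeric vector.
#' @param groupBy `"structure"` (default), `"chain"` (only for a
#'   StructureModel), or a character vector of per-atom group labels.
#' @return a [BValueVector] with `scale = "normalized"`.
#' @export
normalizeB <- function(x, groupBy = "structure") {
  if (is(x, "StructureModel")) {
    core <- !isEnvironment(x)
    if (!any(core)) stop("no non-environment atoms: empty response")
    vals <- bValues(x)[core]
    if (anyNA(vals)) stop("missing B values")
    groups <- if (identical(groupBy, "chain"))
      atomTable(x)$chainId[core]
    else if (identical(groupBy, "structure"))
      rep("all", length(vals))
    else {
      if (length(groupBy) != length(vals))
        stop("group labels must match the non-environment atom count")
      as.character(groupBy)
    }
  } else {
    vals <- if (is(x, "BValueVector")) bValues(x) else as.numeric(x)
    groups <- if (is(x, "BValueVector") && !identical(groupBy, "structure"))
      groupLabels(x)
    else if (is.character(groupBy) && length(groupBy) == length(vals))
      groupBy
    else rep("all", length(vals))
  }
  out <- vals
  for (g in unique(groups)) {
    idx <- groups == g
    if (sum(idx) < 2L)
      stop("normalization group '", g, "' has fewer than 2 atoms")
    s <- stats::sd(vals[idx])
    if (!is.finite(s) || s == 0)
      stop("normalization group '", g, "' has zero B-value spread")
    out[idx] <- (vals[idx] - mean(vals[idx])) / s
  }
  new("BValueVector", values = out, scale = "normalized", groups = groups)
}

#' Raw (unnormalized) B values as a BValueVector
#'
#' @param model a [StructureModel]; non-environment atoms only.
#' @param groupBy as in [normalizeB()].
#' @return a [BValueVector] with `scale = "raw"`.
#' @export
rawBValues <- function(model, groupBy = "structure") {
  stopifnot(is(model, "StructureModel"))
  core <- !isEnvironment(model)
  if (!any(core)) stop("no non-environment atoms: empty response")
  vals <- bValues(model)[core]
  groups <- if (identical(groupBy, "chain"))
    atomTable(model)$chainId[core]
  else rep("all", length(vals))
  new("BValueVector", values = vals, scale = "raw", groups = groups)
}

#' Full GDV feature pipeline for one structure
#'
#' Convenience wrapper implementing the default pipeline: build the
#' contact graph at `cutoff` over all atoms (environment included), count
#' orbit degrees, optionally smooth the raw counts over the `radius`
#' neighborhood, drop environment-atom rows, and z-score the columns of
#' the resulting regression design.  For the contact model only the `O0`
#' column is retained before z-scoring.
#'
#' @param model a [StructureModel].
#' @param cutoff graph cutoff in Angstrom; defaults to 5.0 for
#'   `modelKind = "gdv"` and 7.0 for `"contact"`.
#' @param modelKind `"gdv"` (default) or `"contact"`.
#' @param smooth logical, apply neighbor smoothing (default TRUE).
#' @param radius smoothing radius in Angstrom (default 2.0).
#' @param zscore logical, z-score columns over the regression rows
#'   (default TRUE).
#' @return a [FeatureMatrix] whose rows are the non-environment atoms, in
#'   model order.
#' @export
gdvFeatures <- function(model, cutoff = NULL,
                        modelKind = c("gdv", "contact"), smooth = TRUE,
                        radius = 2.0, zscore = TRUE) {
  modelKind <- match.arg(modelKind)
  if (is.null(cutoff)) cutoff <- if (modelKind == "gdv") 5.0 else 7.0
  graph <- buildContactGraph(model, cutoff)
  feats <- countOrbits(graph)
  feats <- if (smooth) smoothFeatures(feats, model, radius)
  else new("FeatureMatrix", values = featureValues(feats),
           transforms = character(0), cutoff = cutoff)
  core <- !isEnvironment(model)
  if (!any(core)) stop("no non-environment atoms: empty response")
  v <- featureValues(feats)[core, , drop = FALSE]
  if (modelKind == "contact") v <- v[, "O0", drop = FALSE]
  out <- new("FeatureMatrix", values = v,
             transforms = transformsApplied(feats), cutoff = cutoff,
             smoothRadius = feats@smoothRadius)
  if (zscore) out <- zscoreColumns(out)
  out
}

#' Export a feature matrix as TSV
#'
#' Header comment lines record the transforms applied, the graph cutoff
#' and the smoothing radius.
#'
#' @param features a [FeatureMatrix].
#' @param path output path.
#' @export
writeFeatureTable <- function(features, path) {
  stopifnot(is(features, "FeatureMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# transforms_applied: ",
           paste(transformsApplied(features), collapse = ",")),
    paste0("# cutoff_A: ", features@cutoff),
    paste0("# smooth_radius_A: ", features@smoothRadius)), con)
  utils::write.table(featureValues(features), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
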