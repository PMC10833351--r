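#' Default entry-level inclusion thresholds
#'
#' The printed wording of the screening rules is strict at every boundary:
#' "more than 10 000 atoms", B values "greater than 200", standard
#' deviation "below 0.1" and Z-scores "less than -2" all exclude strictly
#' beyond the threshold, so the boundary value itself passes.  The
#' resolution window, R-value cap and residue-count window are the
#' sequence-culling criteria; they are optional rules evaluated only when
#' the corresponding metadata fields are present.
#'
#' @param maxAtoms maximum atom count (default 10000).
#' @param maxB maximum allowed B value in Angstrom^2 (default 200).
#' @param minBSd minimum B-value standard deviation (default 0.1).
#' @param minRamaZ,minRotamerZ minimum Ramachandran / rotamer Z-scores
#'   (default -2).
#' @param resolutionRange allowed resolution window in Angstrom (default
#'   c(1.6, 2.6)).
#' @param maxR maximum crystallographic R value (default 0.25).
#' @param residueRange allowed protein size in residues (default
#'   c(50, 500)).
#' @return named list of thresholds.
#' @export
qcThresholds <- function(maxAtoms = 10000L, maxB = 200, minBSd = 0.1,
                         minRamaZ = -2, minRotamerZ = -2,
                         resolutionRange = c(1.6, 2.6), maxR = 0.25,
                         residueRange = c(50L, 500L)) {
  list(maxAtoms = maxAtoms, maxB = maxB, minBSd = minBSd,
       minRamaZ = minRamaZ, minRotamerZ = minRotamerZ,
       resolutionRange = resolutionRange, maxR = maxR,
       residueRange = residueRange)
}

#' Entry metadata record for QC
#'
#' @param entryId single string.
#' @param nAtoms atom count.
#' @param bMin,bMax,bSd B-value statistics in Angstrom^2 (`NA` allowed).
#' @param hasMissingB logical, any atom without a B value.
#' @param resolution resolution in Angstrom (optional).
#' @param rValue crystallographic R value (optional).
#' @param ramachandranZ,rotamerZ model-quality Z-scores (optional).
#' @param nResidues residue count (optional).
#' @return named list (an EntryMetadata record).
#' @export
entryMetadata <- function(entryId, nAtoms, bMin = NA_real_,
                          bMax = NA_real_, bSd = NA_real_,
                          hasMissingB = FALSE, resolution = NA_real_,
                          rValue = NA_real_, ramachandranZ = NA_real_,
                          rotamerZ = NA_real_, nResidues = NA_integer_) {
  stopifnot(length(entryId) == 1L, nAtoms >= 0)
  if (!is.na(bMin) && !is.na(bMax) && bMin > bMax)
    stop("bMin > bMax")
  list(entryId = as.character(entryId), nAtoms = as.integer(nAtoms),
       bMin = bMin, bMax = bMax, bSd = bSd,
       hasMissingB = isTRUE(hasMissingB), resolution = resolution,
       rValue = rValue, ramachandranZ = ramachandranZ,
       rotamerZ = rotamerZ, nResidues = as.integer(nResidues))
}

#' Summarize a StructureModel into an EntryMetadata record
#'
#' @param model a [StructureModel].
#' @return an EntryMetadata record (see [entryMetadata()]).
#' @export
modelMetadata <- function(model) {
  stopifnot(is(model, "StructureModel"))
  a <- atomTable(model)[!isEnvironment(model), , drop = FALSE]
  b <- a$bValue
  entryMetadata(entryId = entryId(model), nAtoms = nrow(a),
                bMin = if (all(is.na(b))) NA_real_ else min(b, na.rm = TRUE),
                bMax = if (all(is.na(b))) NA_real_ else max(b, na.rm = TRUE),
                bSd = if (all(is.na(b))) NA_real_ else stats::sd(b[!is.na(b)]),
                hasMissingB = anyNA(b),
                resolution = model@resolution,
                nResidues = length(unique(paste(a$chainId, a$resSeq,
                                                a$icode))))
}

#' Apply the entry-level inclusion filters
#'
#' Evaluates each screening rule independently and lists every violated
#' rule with the observed value; an entry passes iff no rule fails.
#' Optional fields (`resolution`, `rValue`, Z-scores, `nResidues`) that
#' are absent skip their rules with a warning.  The "B values greater
#' than 200" rule is evaluated against the maximum B value of the entry.
#'
#' @param meta an EntryMetadata record ([entryMetadata()]) or a
#'   [StructureModel].
#' @param thresholds rule configuration from [qcThresholds()].
#' @return a [QCReport].
#' @export
applyQCFilters <- function(meta, thresholds = qcThresholds()) {
  if (is(meta, "StructureModel")) meta <- modelMetadata(meta)
  if (is.null(meta$entryId) || is.null(meta$nAtoms))
    stop("metadata must contain entryId and nAtoms")
  th <- thresholds
  fails <- list()
  addFail <- function(rule, observed, threshold)
    fails[[length(fails) + 1L]] <<- data.frame(
      rule = rule, observed = observed, threshold = threshold,
      stringsAsFactors = FALSE)
  skipped <- character(0)

  if (meta$nAtoms > th$maxAtoms)
    addFail("max_atoms", meta$nAtoms, th$maxAtoms)
  if (isTRUE(meta$hasMissingB))
    addFail("missing_b", 1, 0)
  if (!is.na(meta$bMax)) {
    if (meta$bMax > th$maxB) addFail("max_b", meta$bMax, th$maxB)
  } else if (!isTRUE(meta$hasMissingB)) skipped <- c(skipped, "max_b")
  if (!is.na(meta$bSd)) {
    if (meta$bSd < th$minBSd) addFail("min_b_sd", meta$bSd, th$minBSd)
  } else if (!isTRUE(meta$hasMissingB)) skipped <- c(skipped, "min_b_sd")
  if (!is.null(meta$ramachandranZ) && !is.na(meta$ramachandranZ)) {
    if (meta$ramachandranZ < th$minRamaZ)
      addFail("min_rama_z", meta$ramachandranZ, th$minRamaZ)
  } else skipped <- c(skipped, "min_rama_z")
  if (!is.null(meta$rotamerZ) && !is.na(meta$rotamerZ)) {
    if (meta$rotamerZ < th$minRotamerZ)
      addFail("min_rotamer_z", meta$rotamerZ, th$minRotamerZ)
  } else skipped <- c(skipped, "min_rotamer_z")
  if (!is.null(meta$resolution) && !is.na(meta$resolution)) {
    if (meta$resolution < th$resolutionRange[1L] ||
        meta$resolution > th$resolutionRange[2L])
      addFail("resolution_range", meta$resolution,
              mean(th$resolutionRange))
  } else skipped <- c(skipped, "resolution_range")
  if (!is.null(meta$rValue) && !is.na(meta$rValue)) {
    if (meta$rValue > th$maxR) addFail("max_r", meta$rValue, th$maxR)
  } else skipped <- c(skipped, "max_r")
  if (!is.null(meta$nResidues) && !is.na(meta$nResidues)) {
    if (meta$nResidues < th$residueRange[1L] ||
        meta$nResidues > th$residueRange[2L])
      addFail("residue_range", meta$nResidues, mean(th$residueRange))
  } else skipped <- c(skipped, "residue_range")

  if (length(skipped))
    warning("rules skipped for '", meta$entryId,
            "' (missing fields): ", paste(skipped, collapse = ", "))
  failures <- if (length(fails)) do.call(rbind, fails)
  else data.frame(rule = character(0), observed = numeric(0),
                  threshold = numeric(0), stringsAsFactors = FALSE)
  new("QCReport", entryId = meta$entryId,
      passed = nrow(failures) == 0L, failures = failures)
}

#' Batch QC over a metadata table
#'
#' Consumes a data.frame of EntryMetadata rows (columns named as in
#' [entryMetadata()]) and returns one report row per entry.
#'
#' @param metaTable data.frame; one row per entry.
#' @param thresholds rule configuration from [qcThresholds()].
#' @return data.frame with columns `entryId`, `passed`, `failures`
#'   (comma-separated rule ids).
#' @export
qcBatch <- function(metaTable, thresholds = qcThresholds()) {
  rows <- lapply(seq_len(nrow(metaTable)), function(i) {
    rec <- as.list(metaTable[i, , drop = FALSE])
    rep <- suppressWarnings(applyQCFilters(rec, thresholds))
    data.frame(entryId = rep@entryId, passed = rep@passed,
               failures = paste(qcFailures(rep)$rule, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write QC thresholds as key=value text
#'
#' Ranges are serialized as two comma-separated numbers.  The files
#' round-trip losslessly.
#'
#' @param thresholds a list from [qcThresholds()].
#' @param path file path.
#' @return `readQCThresholds` returns the thresholds list.
#' @export
writeQCThresholds <- function(thresholds, path) {
  fmt <- function(v) paste(format(v, scientific = FALSE, trim = TRUE),
                           collapse = ",")
  writeLines(paste0(names(thresholds), "=",
                    vapply(thresholds, fmt, character(1L))), path)
  invisible(NULL)
}

#' @rdname writeQCThresholds
#' @export
readQCThresholds <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- stats::setNames(
    lapply(kv, function(x) as.numeric(strsplit(x[2L], ",")[[1L]])),
    vapply(kv, `[`, character(1L), 1L))
  out$maxAtoms <- as.integer(out$maxAtoms)
  out$residueRange <- as.integer(out$residueRange)
  out[names(qcThresholds())]
}
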