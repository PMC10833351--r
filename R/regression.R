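#' Fit the contact or GDV linear model by ordinary least squares
#'
#' Fits `B_n = b0 + sum_k beta_k O_{n,k} + e_n` with plain OLS (no
#' regularization).  The single-column `O0` design is the contact model;
#' the 15-column design is the GDV model.  t-statistics come from standard
#' OLS inference; variable importance is |t| rescaled so the most
#' important variable scores 100.
#'
#' @param features a [FeatureMatrix] (or numeric matrix with orbit
#'   colnames) whose rows align with the response.
#' @param response a [BValueVector] (normalized) or numeric vector.
#' @return a [FitReport].
#' @export
fitLinear <- function(features, response) {
  X <- if (is.numeric(features)) as.matrix(features)
  else featureValues(features)
  y <- if (is(response, "BValueVector")) bValues(response)
  else as.numeric(response)
  if (nrow(X) != length(y))
    stop("feature rows (", nrow(X), ") do not match response length (",
         length(y), ")")
  if (length(y) == 0L) stop("empty response")
  p <- ncol(X)
  if (nrow(X) <= p + 1L)
    stop("need more than ", p + 1L, " observations to fit ", p,
         " predictors")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1L) {
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)] - 1L]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  df <- data.frame(.b = y, X, check.names = FALSE)
  fit <- stats::lm(.b ~ ., data = df)
  sm <- summary(fit)
  cf <- sm$coefficients
  betaNames <- rownames(cf)[-1L]
  betaNames <- gsub("^`|`$", "", betaNames)
  betas <- stats::setNames(cf[-1L, "Estimate"], betaNames)
  tstat <- stats::setNames(cf[-1L, "t value"], betaNames)
  kind <- if (identical(betaNames, "O0")) "contact" else "gdv"
  imp <- 100 * abs(tstat) / max(abs(tstat))
  cutoff <- if (is(features, "FeatureMatrix")) features@cutoff else NA_real_
  cs <- new("CoefficientSet", intercept = unname(cf[1L, "Estimate"]),
            betas = betas, modelKind = kind, cutoff = cutoff,
            provenance = "fitted")
  new("FitReport", coefficients = cs, tStatistics = tstat,
      importance = imp, rSquared = sm$r.squared, nObs = length(y))
}

#' Predict normalized B values from features and coefficients
#'
#' Computes `b0 + sum_k beta_k O_{n,k}`; no clipping is applied.  The
#' feature columns must match the coefficient set exactly (`O0` only for a
#' contact model, `O0`..`O14` for a GDV model).
#'
#' @param coefficients a [CoefficientSet].
#' @param features a [FeatureMatrix] or numeric matrix with matching
#'   columns.
#' @return numeric vector of predicted normalized B values.
#' @export
predictB <- function(coefficients, features) {
  stopifnot(is(coefficients, "CoefficientSet"))
  X <- if (is.numeric(features)) as.matrix(features)
  else featureValues(features)
  b <- betas(coefficients)
  if (!all(names(b) %in% colnames(X)))
    stop("feature columns do not match the ", modelKind(coefficients),
         " model: need ", paste(names(b), collapse = ","))
  X <- X[, names(b), drop = FALSE]
  drop(intercept(coefficients) + X %*% b)
}

#' Pearson correlation between predicted and reference B values
#'
#' @param predicted,reference equal-length numeric vectors (>= 3 values,
#'   neither constant).
#' @return Pearson product-moment correlation.
#' @export
evaluateCorrelation <- function(predicted, reference) {
  predicted <- as.numeric(predicted)
  reference <- if (is(reference, "BValueVector")) bValues(reference)
  else as.numeric(reference)
  if (length(predicted) != length(reference))
    stop("length mismatch")
  if (length(predicted) < 3L) stop("need at least 3 values")
  if (stats::sd(predicted) == 0 || stats::sd(reference) == 0)
    stop("constant vector: correlation undefined")
  stats::cor(predicted, reference)
}

#' Structure-wise k-fold cross-validation of a linear model
#'
#' Entries (structures), never atoms, are partitioned into `k` folds; for
#' each fold the model is fitted by OLS on the pooled atoms of the
#' training entries and each held-out entry is predicted, recording its
#' Pearson correlation between predicted and reference normalized B
#' values.  Fold assignment is a deterministic function of the entry list
#' order and `seed`.
#'
#' @param entries list; each element a list with components `features` (a
#'   [FeatureMatrix]), `response` (a [BValueVector] or numeric) and
#'   optionally `entryId`.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return an [EvaluationReport].
#' @export
crossValidate <- function(entries, k = 10L, seed = 1L) {
  nEntry <- length(entries)
  if (nEntry < k)
    stop("fewer entries (", nEntry, ") than folds (", k, ")")
  ids <- vapply(seq_along(entries), function(i) {
    id <- entries[[i]]$entryId
    if (is.null(id)) sprintf("entry%03d", i) else as.character(id)
  }, character(1L))
  folds <- withr::with_seed(seed,
    sample(rep(seq_len(k), length.out = nEntry)))
  rows <- vector("list", nEntry)
  getY <- function(e) if (is(e$response, "BValueVector"))
    bValues(e$response) else as.numeric(e$response)
  getX <- function(e) featureValues(e$features)
  for (fold in seq_len(k)) {
    trainIdx <- which(folds != fold)
    testIdx <- which(folds == fold)
    Xtr <- do.call(rbind, lapply(entries[trainIdx], getX))
    ytr <- unlist(lapply(entries[trainIdx], getY), use.names = FALSE)
    fit <- fitLinear(Xtr, ytr)
    cs <- coefficientSet(fit)
    for (i in testIdx) {
      pred <- predictB(cs, getX(entries[[i]]))
      rows[[i]] <- data.frame(entryId = ids[i],
                              modelKind = modelKind(cs),
                              fold = fold,
                              pearsonR = evaluateCorrelation(
                                pred, getY(entries[[i]])),
                              stringsAsFactors = FALSE)
    }
  }
  new("EvaluationReport", perEntry = do.call(rbind, rows))
}

#' Variable importance table from a fitted model
#'
#' Importance is the absolute value of the OLS t-statistic, rescaled so
#' the most important variable scores 100; rows are sorted descending.
#'
#' @param report a [FitReport].
#' @return data.frame with columns `orbit`, `t`, `importance`.
#' @export
variableImportance <- function(report) {
  stopifnot(is(report, "FitReport"))
  t <- tStatistics(report)
  out <- data.frame(orbit = names(t), t = unname(t),
                    importance = unname(report@importance),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Per-entry correlation deltas between two model kinds
#'
#' For entries evaluated under both the GDV and the contact model, the
#' difference `r(gdv) - r(contact)`.
#'
#' @param report an [EvaluationReport] containing both model kinds.
#' @return data.frame with columns `entryId`, `rGdv`, `rContact`, `delta`.
#' @export
correlationDeltas <- function(report) {
  pe <- perEntry(report)
  g <- pe[pe$modelKind == "gdv", c("entryId", "pearsonR")]
  c_ <- pe[pe$modelKind == "contact", c("entryId", "pearsonR")]
  m <- merge(g, c_, by = "entryId", suffixes = c("Gdv", "Contact"))
  data.frame(entryId = m$entryId, rGdv = m$pearsonRGdv,
             rContact = m$pearsonRContact,
             delta = m$pearsonRGdv - m$pearsonRContact,
             stringsAsFactors = FALSE)
}

#' Rescale normalized predictions to raw Angstrom^2 (unreliable)
#'
#' Mapping normalized predictions back to an absolute scale requires the
#' target mean and standard deviation, which are strongly
#' resolution-dependent and vary widely between entries; supplying an
#' incorrect pair gives badly wrong absolute values.  Provided only as an
#' explicit user-driven utility.
#'
#' @param normalized numeric vector of normalized predictions.
#' @param mean,sd target mean and standard deviation in Angstrom^2.
#' @return numeric vector `mean + sd * normalized`.
#' @export
rescaleToRawB <- function(normalized, mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  mean + sd * as.numeric(normalized)
}
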