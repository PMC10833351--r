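#' Built-in coefficient presets
#'
#' The contact model preset is the published final fit over the full
#' training corpus: intercept 0 and slope -0.64 on the z-scored contact
#' count `O0`, at a 7.0 A graph cutoff -- more contacts, lower B value.
#' GDV coefficient sets are supplied as plain-text files (see
#' [readCoefficients()]) or fitted with [fitLinear()]; no numeric GDV
#' preset ships built in.
#'
#' @param name preset name; currently `"contact"`.
#' @return a [CoefficientSet].
#' @export
presetCoefficients <- function(name = "contact") {
  switch(name,
         contact = new("CoefficientSet", intercept = 0,
                       betas = c(O0 = -0.64), modelKind = "contact",
                       cutoff = 7.0, provenance = "preset"),
         stop("unknown preset '", name,
              "'; available presets: contact"))
}

#' Write a coefficient set as key=value text
#'
#' Round-trippable plain-text format: `model_kind`, `cutoff_A`,
#' `intercept` and one `Ok=` line per beta, full double precision.
#'
#' @param coefficients a [CoefficientSet].
#' @param path output path.
#' @export
writeCoefficients <- function(coefficients, path) {
  stopifnot(is(coefficients, "CoefficientSet"))
  b <- betas(coefficients)
  writeLines(c(
    paste0("model_kind=", modelKind(coefficients)),
    paste0("cutoff_A=", format(coefficients@cutoff, digits = 17)),
    paste0("intercept=", format(intercept(coefficients), digits = 17)),
    paste0(names(b), "=", vapply(b, format, character(1L),
                                 digits = 17))), path)
  invisible(NULL)
}

#' Read a coefficient set from key=value text
#'
#' @param path file written by [writeCoefficients()] or transcribed by
#'   hand (keys `model_kind`, optional `cutoff_A`, `intercept`,
#'   `O0`..`O14` or `O0` alone).
#' @return a [CoefficientSet] (`provenance = "user"`).
#' @export
readCoefficients <- function(path) {
  if (!file.exists(path)) stop("coefficient file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1L), 2L),
                          vapply(kv, `[`, character(1L), 1L))
  kind <- if ("model_kind" %in% names(vals)) vals[["model_kind"]]
  else if ("O1" %in% names(vals)) "gdv" else "contact"
  want <- if (kind == "contact") "O0" else paste0("O", 0:14)
  missing <- setdiff(want, names(vals))
  if (length(missing))
    stop("coefficient file lacks: ", paste(missing, collapse = ", "))
  new("CoefficientSet",
      intercept = as.numeric(vals[["intercept"]]),
      betas = stats::setNames(as.numeric(vals[want]), want),
      modelKind = kind,
      cutoff = if ("cutoff_A" %in% names(vals))
        as.numeric(vals[["cutoff_A"]]) else NA_real_,
      provenance = "user")
}
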