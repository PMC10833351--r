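#' Read a macromolecular structure file
#'
#' Parses a PDB or mmCIF file (format chosen by extension, `.cif`/`.mmcif`
#' vs anything else) and returns the atoms, in file order after selection,
#' as a [StructureModel].  Parsing is delegated to \pkg{bio3d}
#' (`read.pdb`/`read.cif`); this function applies the atom selection,
#' resolves alternate locations and populates the record table.
#'
#' The default `"heavy-protein"` selection keeps polymer (`ATOM`) records
#' and drops hydrogens/deuteriums, waters and hetero compounds --
#' crystallographic B-value work is conventionally done on the non-H
#' protein atoms.  `"all-atoms"` keeps every atom in the file.  A custom
#' selection is expressed through `chains`/`residues` filters combined with
#' the `keep*` switches.
#'
#' Alternate locations are resolved to a single conformer per atom: the
#' highest-occupancy altloc wins, ties break lexicographically (so `A`
#' beats `B`).  For multi-model (NMR-style) files only model 1 is used,
#' with a warning.  ANISOU records are ignored.
#'
#' @param path path to a PDB or mmCIF file.
#' @param selection `"heavy-protein"` (default), `"all-atoms"` or
#'   `"custom"`.
#' @param chains optional character vector of chain ids to keep
#'   (`selection = "custom"`).
#' @param residues optional integer vector of residue numbers to keep
#'   (`selection = "custom"`).
#' @param keepHydrogens,keepHetero,keepWaters logicals refining a
#'   `"custom"` selection (all `FALSE` by default, as in
#'   `"heavy-protein"`).
#' @param entryId entry identifier; defaults to the file base name.
#' @return a [StructureModel]; `isEnvironment` is `FALSE` for every atom
#'   (set it separately with [markEnvironment()]).
#' @seealso [markEnvironment()], [writeStructureWithB()]
#' @export
readStructure <- function(path,
                          selection = c("heavy-protein", "all-atoms",
                                        "custom"),
                          chains = NULL, residues = NULL,
                          keepHydrogens = FALSE, keepHetero = FALSE,
                          keepWaters = FALSE,
                          entryId = NULL) {
  selection <- match.arg(selection)
  if (!file.exists(path)) stop("file not found: ", path)
  isCif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  # rm.alt = FALSE: bio3d would otherwise keep altloc A only; the
  # occupancy-based altloc policy below needs all conformers
  pdb <- tryCatch(
    if (isCif) bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("cannot parse structure file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (!is.null(pdb$xyz) && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1L)
    warning("multi-model file: using model 1 only")

  a <- pdb$atom
  elem <- .guessElement(a)
  keep <- rep(TRUE, nrow(a))
  if (selection == "heavy-protein") {
    keep <- a$type == "ATOM" & !(elem %in% c("H", "D"))
  } else if (selection == "custom") {
    if (!keepHydrogens) keep <- keep & !(elem %in% c("H", "D"))
    if (!keepWaters) keep <- keep & !(a$resid %in% c("HOH", "WAT", "DOD"))
    if (!keepHetero) keep <- keep & (a$type == "ATOM" |
                                       a$resid %in% c("HOH", "WAT", "DOD") &
                                       keepWaters)
    if (!is.null(chains)) keep <- keep & a$chain %in% chains
    if (!is.null(residues)) keep <- keep & a$resno %in% residues
  }
  a <- a[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(a) == 0L)
    stop("empty selection: no atoms left after applying '", selection, "'")

  alt <- ifelse(is.na(a$alt), "", a$alt)
  insert <- ifelse(is.na(a$insert), "", a$insert)
  occ <- ifelse(is.na(a$o), 1, a$o)
  # altloc policy: one conformer per atom site, highest occupancy,
  # ties broken lexicographically
  siteKey <- paste(a$chain, a$resno, insert, a$elety, sep = "\r")
  ord <- order(siteKey, -occ, alt)
  firstOfSite <- !duplicated(siteKey[ord])
  keepRows <- sort(seq_len(nrow(a))[ord][firstOfSite])
  a <- a[keepRows, , drop = FALSE]
  elem <- elem[keepRows]
  alt <- alt[keepRows]
  insert <- insert[keepRows]
  occ <- occ[keepRows]

  atoms <- data.frame(
    serial = as.integer(a$eleno),
    atomName = as.character(a$elety),
    element = elem,
    altloc = alt,
    resName = as.character(a$resid),
    chainId = ifelse(is.na(a$chain), "", as.character(a$chain)),
    resSeq = as.integer(a$resno),
    icode = insert,
    x = a$x, y = a$y, z = a$z,
    occupancy = occ,
    bValue = ifelse(is.na(a$b), NA_real_, a$b),
    isHetero = a$type != "ATOM",
    isEnvironment = FALSE,
    stringsAsFactors = FALSE)
  rownames(atoms) <- NULL

  if (is.null(entryId))
    entryId <- sub("\\.[^.]*$", "", basename(path))
  new("StructureModel", entryId = entryId, atoms = atoms,
      resolution = NA_real_, metadata = list(path = path,
                                             selection = selection))
}

.guessElement <- function(atom) {
  e <- atom$elesy
  if (is.null(e)) e <- rep(NA_character_, nrow(atom))
  e <- toupper(trimws(ifelse(is.na(e), "", e)))
  miss <- e == ""
  if (any(miss)) {
    # fall back on the atom name: strip digits/primes, 1st character
    nm <- toupper(gsub("[0-9']", "", atom$elety[miss]))
    e[miss] <- substr(nm, 1L, 1L)
  }
  e
}

#' Flag symmetry-related environment atoms
#'
#' Environment atoms are symmetry copies included only so that surface
#' atoms have a complete contact shell; they take part in graph building
#' and feature smoothing but are excluded from regression responses and
#' evaluation.  Symmetry expansion itself is not performed here -- read a
#' pre-expanded file and flag the added atoms.
#'
#' @param model a [StructureModel].
#' @param flags logical vector, one per atom; `TRUE` marks an environment
#'   atom.
#' @return the model with `isEnvironment` replaced.
#' @export
markEnvironment <- function(model, flags) {
  stopifnot(is(model, "StructureModel"))
  if (!is.logical(flags) || length(flags) != nAtoms(model))
    stop("flags must be a logical vector of length ", nAtoms(model))
  model@atoms$isEnvironment <- flags
  validObject(model)
  model
}

#' Write a model with a replaced B column
#'
#' Writes a PDB file identical in atom content to the input model, except
#' that the B column (columns 61-66, `%6.2f`) holds `values` and
#' environment atoms are omitted.  Negative values are permitted so that
#' normalized scores can be written.
#'
#' @param model a [StructureModel].
#' @param values numeric vector, one value per non-environment atom.
#' @param path output path.
#' @export
writeStructureWithB <- function(model, values, path) {
  stopifnot(is(model, "StructureModel"))
  core <- !isEnvironment(model)
  if (length(values) != sum(core))
    stop("values must have one entry per non-environment atom (",
         sum(core), "), got ", length(values))
  a <- atomTable(model)[core, , drop = FALSE]
  a$bValue <- values
  .writePdbAtoms(a, path)
  invisible(NULL)
}

# Fixed-column ATOM/HETATM writer via bio3d, which formats the B column
# as %6.2f and coordinates as %8.3f.
.writePdbAtoms <- function(a, path) {
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$isHetero, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$atomName,
                   resid = a$resName, chain = ifelse(a$chainId == "", " ",
                                                     a$chainId),
                   resno = a$resSeq,
                   insert = ifelse(a$icode == "", "", a$icode),
                   alt = ifelse(a$altloc == "", "", a$altloc),
                   o = a$occupancy, b = a$bValue,
                   elesy = a$element, end = TRUE)
}
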