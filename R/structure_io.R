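# Reading aligned PDB ensembles and assigning van der Waals radii.
#
# Coordinates are Angstrom throughout.  Input ensembles must be pre-aligned
# and consistently numbered; no superposition is attempted.  Hydrogens are
# kept when present but never added -- protonate upstream if the analysis
# should account for hydrogen atoms.

waterResnames <- c("HOH", "WAT", "TIP", "TIP3", "TIP4", "SOL", "DOD")

#' Default van der Waals radii table
#'
#' Reads a plain-text "element whitespace radius" table.  The shipped default
#' is the Bondi (1964) set (`vdw_bondi.txt`); results depend on the radii
#' set, so its name is recorded in all report headers.
#'
#' @param file path to a radii table; `NULL` for the shipped Bondi set.
#' @return named numeric vector of radii (Angstrom) with attribute `"table"`
#'   carrying the table name.
#' @export
defaultRadii <- function(file = NULL) {
  name <- if (is.null(file)) "bondi64" else basename(file)
  if (is.null(file))
    file <- system.file("extdata", "vdw_bondi.txt", package = "tunnelscape")
  tab <- read.table(file, header = FALSE, comment.char = "#",
                    col.names = c("element", "radius"),
                    stringsAsFactors = FALSE)
  if (any(tab$radius <= 0)) stop("radii table contains non-positive radii")
  r <- tab$radius
  names(r) <- toupper(tab$element)
  attr(r, "table") <- name
  r
}

.elementFromName <- function(name, elesy) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    guess <- toupper(sub("^[0-9']*", "", trimws(name[miss])))
    el[miss] <- substr(guess, 1, 1)
  }
  el
}

.readOnePDB <- function(path, keepWater, keepHetatm, atomFilter) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse PDB file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = .elementFromName(at$elety, at$elesy),
    resname = trimws(at$resid),
    resid = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    record = at$type,
    stringsAsFactors = FALSE
  )
  isWater <- atoms$resname %in% waterResnames
  keep <- ifelse(isWater, keepWater,
                 atoms$record == "ATOM" | keepHetatm)
  if (!is.null(atomFilter)) keep <- keep & atomFilter(atoms)
  if (!any(keep)) stop("no atoms left after filtering in '", path, "'")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(sum(keep), 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)[keep, ,
                                                              drop = FALSE]
  list(atoms = atoms[keep, , drop = FALSE], coords = coords)
}

#' Read a structure or aligned ensemble from PDB files
#'
#' A multi-MODEL file expands to one snapshot per MODEL; several files are
#' concatenated as consecutive snapshots.  Frames must contain identical atom
#' sets with consistent numbering; the first mismatching serial is reported
#' otherwise.  Waters are excluded by default and HETATM records are kept
#' only on request, since tunnels are computed in the macromolecule.
#'
#' @param paths character vector of PDB files.
#' @param keepWater keep water molecules (default `FALSE`).
#' @param keepHetatm keep HETATM records (default `FALSE`).
#' @param atomFilter optional `function(atoms)` returning a logical keep mask
#'   over the atom table.
#' @return a [TunnelEnsemble-class]
#' @export
readEnsemble <- function(paths, keepWater = FALSE, keepHetatm = FALSE,
                         atomFilter = NULL) {
  stopifnot(length(paths) >= 1)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  parts <- lapply(paths, .readOnePDB, keepWater = keepWater,
                  keepHetatm = keepHetatm, atomFilter = atomFilter)
  ref <- parts[[1]]$atoms
  for (i in seq_along(parts)[-1]) {
    a <- parts[[i]]$atoms
    if (nrow(a) != nrow(ref) || !all(a$serial == ref$serial)) {
      bad <- union(setdiff(ref$serial, a$serial), setdiff(a$serial, ref$serial))
      if (!length(bad)) bad <- ref$serial[which(a$serial != ref$serial)[1]]
      stop("inconsistent atom sets across frames: first mismatching serial ",
           bad[1], " (file '", paths[i], "')")
    }
  }
  coords <- array(unlist(lapply(parts, function(p) p$coords)),
                  c(nrow(ref), 3, sum(vapply(parts, function(p)
                    dim(p$coords)[3], integer(1)))))
  new("TunnelEnsemble", atoms = ref, coords = coords,
      radii = rep(NA_real_, nrow(ref)), radiiTable = "unassigned",
      sourcePaths = paths)
}

#' Assign van der Waals radii to an ensemble
#'
#' @param ensemble a [TunnelEnsemble-class]
#' @param radiiTable named radii vector, e.g. from [defaultRadii()].
#' @param default fallback radius for elements missing from the table;
#'   `NA` (the default) makes unknown elements an error.
#' @return the ensemble with radii assigned
#' @export
assignRadii <- function(ensemble, radiiTable = defaultRadii(),
                        default = NA_real_) {
  el <- toupper(ensemble@atoms$element)
  r <- unname(radiiTable[el])
  if (anyNA(r)) {
    if (is.na(default)) {
      bad <- unique(el[is.na(r)])
      stop("no vdw radius for element(s) ", paste(bad, collapse = ", "),
           " and no default radius configured")
    }
    r[is.na(r)] <- default
  }
  ensemble@radii <- r
  tn <- attr(radiiTable, "table")
  ensemble@radiiTable <- if (is.null(tn)) "custom" else tn
  validObject(ensemble)
  ensemble
}

#' Write an ensemble (or selected snapshots) as a PDB file
#'
#' Multi-snapshot ensembles are written as multi-MODEL files with fixed
#' PDB columns, 3-decimal coordinates.
#'
#' @param ensemble a [TunnelEnsemble-class]
#' @param file output path
#' @param snapshots frame indices to write (default: all)
#' @export
writeEnsemblePDB <- function(ensemble, file, snapshots = NULL) {
  if (is.null(snapshots)) snapshots <- seq_len(nSnapshots(ensemble))
  con <- file(file, "w")
  on.exit(close(con))
  multi <- length(snapshots) > 1
  for (f in snapshots) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(formatPDBAtoms(ensemble@atoms, snapshotCoords(ensemble, f)),
               con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
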