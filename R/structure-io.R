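#' Create a domain definition
#'
#' Named domains default to the RECQL5 catalytic-core boundaries (D1 residues
#' 1-219, D2 residues 220-364, Zn subdomain residues 365-437); `custom`
#' requires explicit bounds. Intervals are inclusive and use author numbering.
#'
#' @param name "D1", "D2", "Zn" or "custom".
#' @param start,end inclusive residue bounds; defaults taken from `name` for
#'   the named domains.
#' @return a [DomainDefinition-class] object.
#' @examples
#' domainDefinition("D1")
#' domainDefinition("custom", 220, 437)
#' @export
domainDefinition <- function(name = c("D1", "D2", "Zn", "custom"),
                             start = NULL, end = NULL) {
  name <- match.arg(name)
  defaults <- list(D1 = c(1, 219), D2 = c(220, 364), Zn = c(365, 437))
  if (name == "custom") {
    if (is.null(start) || is.null(end))
      stop("custom domains require explicit start and end")
  } else {
    if (is.null(start)) start <- defaults[[name]][1]
    if (is.null(end)) end <- defaults[[name]][2]
  }
  new("DomainDefinition", name = name, start = as.numeric(start),
      end = as.numeric(end))
}

.waterNames <- c("HOH", "WAT", "DOD", "H2O")
.ionNames <- c("ZN", "MG", "NA", "CL", "K", "CA", "MN", "SO4", "PO4", "EDO",
               "GOL")

# light pre-scan of a PDB file so malformed coordinate records are reported
# with their line number (bio3d would fail less informatively)
.validatePDBLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(idx) == 0)
    stop("empty structure: no ATOM/HETATM records in '", path, "'")
  for (i in idx) {
    coords <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                            substr(lines[i], 39, 46),
                                            substr(lines[i], 47, 54))))
    if (any(is.na(coords)))
      stop("format error: unparseable coordinates at line ", i,
           " of '", path, "'")
  }
  invisible(length(idx))
}

# altloc policy: keep the highest-occupancy conformer of each atom,
# tie-break alphabetically by altloc id
.resolveAltlocs <- function(a) {
  key <- paste(a$chain, a$resno, a$insert, a$elety, a$type, sep = "\r")
  if (!anyDuplicated(key)) return(a)
  ord <- order(key, -a$o, a$alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]
  a[order(a$eleno), , drop = FALSE]
}

#' Read a structure from a PDB (or mmCIF) file
#'
#' Parses all chains of a coordinate file into a [StructureModel-class].
#' Alternate locations are collapsed to the highest-occupancy conformer
#' (alphabetical tie-break); HETATM records (nucleotides, metals, waters) are
#' retained and flagged as `ligand`/`water` so that geometric selections can
#' skip them.
#'
#' @param path path to the coordinate file.
#' @param format "pdb" (required dialect) or "cif".
#' @param structureId identifier; defaults to the file basename without
#'   extension.
#' @param nucleotideState optional tag ("APO", "ADP", ...) stored in the
#'   metadata and propagated onto landscape tables.
#' @return a [StructureModel-class].
#' @examples
#' fam <- makeHingeFamily(angles = 0, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(fam$structures[[1]], f)
#' readStructure(f, nucleotideState = "APO")
#' @export
readStructure <- function(path, format = c("pdb", "cif"), structureId = NULL,
                          nucleotideState = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: '", path, "'")
  if (format == "pdb") {
    .validatePDBLines(path)
    pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                    error = function(e)
                      stop("format error reading '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  } else {
    pdb <- tryCatch(bio3d::read.cif(path, verbose = FALSE),
                    error = function(e)
                      stop("format error reading '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  }
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0)
    stop("empty structure: no atom records in '", path, "'")
  a$insert <- ifelse(is.na(a$insert), "", a$insert)
  a$alt <- ifelse(is.na(a$alt), "", a$alt)
  a$o <- ifelse(is.na(a$o), 1, a$o)
  a$b <- ifelse(is.na(a$b), 0, a$b)
  a$chain <- ifelse(is.na(a$chain), "A", a$chain)
  if (is.null(a$elesy)) a$elesy <- ""
  a$elesy <- ifelse(is.na(a$elesy), "", a$elesy)
  a <- .resolveAltlocs(a)
  a$water <- a$resid %in% .waterNames
  a$ligand <- a$type == "HETATM" & !a$water
  a <- a[, c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
             "insert", "x", "y", "z", "o", "b", "elesy", "ligand", "water")]
  rownames(a) <- NULL
  if (is.null(structureId))
    structureId <- sub("\\.[^.]*$", "", basename(path))
  new("StructureModel", structureId = structureId, atoms = a,
      metadata = list(sourceFile = path, format = format,
                      nucleotideState = nucleotideState))
}

#' Write a structure to a PDB file
#'
#' Writes fixed-column ATOM/HETATM records (coordinates at 0.001 Angstrom
#' precision, the PDB dialect's limit). Round-tripping through
#' [readStructure()] preserves residue content and coordinates to that
#' precision.
#'
#' @param structure a [StructureModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(structure, path) {
  stopifnot(is(structure, "StructureModel"))
  a <- atoms(structure)
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = a$type, resno = a$resno, resid = a$resid,
                   eleno = a$eleno, elety = a$elety, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   alt = ifelse(a$alt == "", NA, a$alt),
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

.selectionResnos <- function(selection) {
  if (is(selection, "DomainDefinition"))
    return(seq(selection@start, selection@end))
  as.numeric(selection)
}

#' Extract Calpha coordinates for a residue selection
#'
#' Returns the Calpha atoms of polymer residues (waters and ligands excluded)
#' in strictly ascending residue order. Residues absent from the model (for
#' instance disordered loops) are silently missing, so callers see numbering
#' gaps.
#'
#' @param structure a [StructureModel-class].
#' @param chain chain identifier; defaults to the first polymer chain.
#' @param selection a [DomainDefinition-class], a numeric vector of residue
#'   numbers, or `NULL` for all residues.
#' @return data frame with columns `resno`, `insert`, `x`, `y`, `z`.
#' @examples
#' fam <- makeHingeFamily(angles = 0, seed = 1)
#' ca <- extractCA(fam$structures[[1]], selection = domainDefinition("D1"))
#' head(ca)
#' @export
extractCA <- function(structure, chain = NULL, selection = NULL) {
  stopifnot(is(structure, "StructureModel"))
  a <- atoms(structure)
  if (is.null(chain)) chain <- chains(structure)[1]
  if (!chain %in% a$chain) stop("chain '", chain, "' not present in ",
                                structureId(structure))
  keep <- a$chain == chain & a$elety == "CA" & a$type == "ATOM" & !a$water
  if (!is.null(selection))
    keep <- keep & a$resno %in% .selectionResnos(selection)
  ca <- a[keep, c("resno", "insert", "x", "y", "z"), drop = FALSE]
  if (nrow(ca) == 0)
    stop("empty-selection: no CA atoms in the requested selection of ",
         structureId(structure), " chain ", chain)
  ca <- ca[order(ca$resno, ca$insert), , drop = FALSE]
  rownames(ca) <- NULL
  ca
}
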