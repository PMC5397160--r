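#' The RECQL5 reference anchor set
#'
#' The four structurally invariant Calpha positions used to place RecQ-family
#' structures on the conformational landscape: Q34 (motif 0) and L79
#' (motif Ia) on the D1 domain, T268 (motif IV) and F420 (Zn-binding
#' subdomain) on the D2/Zn module, in RECQL5 author numbering.
#'
#' @param structureId,chain identifiers recorded on the set.
#' @return an [AnchorSet-class].
#' @examples
#' anchors(referenceAnchors())
#' @export
referenceAnchors <- function(structureId = "RECQL5", chain = "A") {
  new("AnchorSet", structureId = structureId, chain = chain,
      anchors = c(D1_motif0 = 34, D1_motifIa = 79,
                  D2_motifIV = 268, D2_Zn = 420))
}

#' Construct an anchor set
#'
#' @param anchors named numeric of length 4 (names `D1_motif0`, `D1_motifIa`,
#'   `D2_motifIV`, `D2_Zn`) giving author residue numbers.
#' @param structureId,chain identifiers.
#' @return an [AnchorSet-class].
#' @export
anchorSet <- function(anchors, structureId = "", chain = "A") {
  new("AnchorSet", structureId = structureId, chain = chain,
      anchors = anchors[.anchorNames])
}

#' One-letter sequence of a structure chain
#'
#' Extracts the amino-acid sequence of a chain, in residue order, together
#' with the author residue number of every position. Selenomethionine (MSE)
#' is read as M; other non-standard polymer residues map to X. Numbering
#' gaps (disordered loops) are preserved in the residue-number index, not in
#' the string.
#'
#' @param structure a [StructureModel-class].
#' @param chain chain id; defaults to the first polymer chain.
#' @return list with elements `sequence` (character scalar) and `resno`
#'   (integer vector, one entry per sequence position).
#' @export
sequenceFromStructure <- function(structure, chain = NULL) {
  stopifnot(is(structure, "StructureModel"))
  a <- atoms(structure)
  if (is.null(chain)) chain <- chains(structure)[1]
  poly <- a[a$chain %in% chain & !a$water &
              (a$type == "ATOM" | a$resid == "MSE"), , drop = FALSE]
  res <- unique(poly[, c("resno", "insert", "resid")])
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  if (nrow(res) == 0)
    stop("empty-sequence: chain ", chain, " of ", structureId(structure),
         " has no polymer residues")
  letters1 <- suppressWarnings(bio3d::aa321(res$resid))
  std <- letters1 %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!any(std))
    stop("empty-sequence: chain ", chain, " of ", structureId(structure),
         " has no standard amino-acid residues")
  letters1[!std] <- "X"
  list(sequence = paste(letters1, collapse = ""),
       resno = as.integer(res$resno))
}

.substitutionMatrix <- function(name) {
  if (is.matrix(name)) return(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global (Needleman-Wunsch) alignment with affine gaps
#'
#' Optimal global alignment of two sequences under a substitution matrix and
#' affine gap penalties (a gap of length L costs
#' `gapOpen + L * gapExtend`), with a deterministic traceback. Returns the
#' residue correspondence over aligned, non-gap columns.
#'
#' @param ref,target sequences: either character scalars or the lists
#'   returned by [sequenceFromStructure()] (whose residue numbers are then
#'   carried into the mapping).
#' @param substitutionMatrix matrix or the name of a Biostrings matrix
#'   (default "BLOSUM62").
#' @param gapOpen,gapExtend affine gap penalties (positive costs; defaults
#'   10 and 0.5, classical protein-alignment values).
#' @return a [ResidueMapping-class].
#' @examples
#' m <- globalAlign("ACDEFG", "ACEFG")
#' mappingTable(m)
#' @export
globalAlign <- function(ref, target, substitutionMatrix = "BLOSUM62",
                        gapOpen = 10, gapExtend = 0.5) {
  refIdx <- NULL; targetIdx <- NULL
  if (is.list(ref)) { refIdx <- ref$resno; ref <- ref$sequence }
  if (is.list(target)) { targetIdx <- target$resno; target <- target$sequence }
  if (!nzchar(ref) || !nzchar(target))
    stop("empty-sequence: both sequences must be non-empty")
  sm <- .substitutionMatrix(substitutionMatrix)
  aln <- Biostrings::pairwiseAlignment(
    pattern = ref, subject = target, type = "global",
    substitutionMatrix = sm, gapOpening = gapOpen, gapExtension = gapExtend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ri <- cumsum(p != "-")
  ti <- cumsum(s != "-")
  both <- p != "-" & s != "-"
  pairs <- data.frame(refPos = ri[both], targetPos = ti[both])
  pairs$refResno <- if (is.null(refIdx)) pairs$refPos else
    refIdx[pairs$refPos]
  pairs$targetResno <- if (is.null(targetIdx)) pairs$targetPos else
    targetIdx[pairs$targetPos]
  new("ResidueMapping", pairs = pairs, score = Biostrings::score(aln),
      percentIdentity = Biostrings::pid(aln))
}

#' Transfer reference anchors onto a target structure
#'
#' Maps each of the four reference anchor residues through an alignment-based
#' residue correspondence and checks that the target residue carries a
#' Calpha atom.
#'
#' @param referenceAnchors an [AnchorSet-class] in reference numbering.
#' @param mapping a [ResidueMapping-class] whose reference side uses the
#'   anchor numbering (`refResno`) and whose target side uses the target
#'   structure's numbering (`targetResno`).
#' @param target the target [StructureModel-class].
#' @param chain target chain; defaults to the first polymer chain.
#' @return an [AnchorSet-class] in target numbering.
#' @export
mapAnchors <- function(referenceAnchors, mapping, target, chain = NULL) {
  stopifnot(is(referenceAnchors, "AnchorSet"), is(mapping, "ResidueMapping"),
            is(target, "StructureModel"))
  if (is.null(chain)) chain <- chains(target)[1]
  p <- mappingTable(mapping)
  ca <- extractCA(target, chain)
  refA <- anchors(referenceAnchors)
  out <- vapply(.anchorNames, function(nm) {
    i <- match(refA[[nm]], p$refResno)
    if (is.na(i))
      stop("unmappable-anchor: ", nm, " (reference residue ", refA[[nm]],
           ") falls in a gap column of the alignment")
    tr <- p$targetResno[i]
    if (!tr %in% ca$resno)
      stop("unmappable-anchor: ", nm, " maps to target residue ", tr,
           " which has no CA atom")
    tr
  }, numeric(1))
  new("AnchorSet", structureId = structureId(target), chain = chain,
      anchors = out)
}
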