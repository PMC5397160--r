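#' @import methods
NULL

#' StructureModel: atomic coordinates organised by chain and residue
#'
#' Container for a parsed macromolecular structure. Atom records are stored in
#' a single data frame (one row per atom) using author residue numbering;
#' waters and other heteroatoms are retained but flagged so that geometric
#' selections can exclude them.
#'
#' @slot structureId single character identifier (typically the PDB id or file
#'   basename).
#' @slot atoms data frame with columns `type` ("ATOM"/"HETATM"), `eleno`,
#'   `elety` (atom name, e.g. "CA"), `alt`, `resid` (3-letter residue name),
#'   `chain`, `resno` (author numbering), `insert` (insertion code, `""` when
#'   absent), `x`, `y`, `z` (Angstrom), `o` (occupancy), `b`, `elesy`
#'   (element), `ligand` (logical), `water` (logical).
#' @slot metadata free-form list; the reader records `sourceFile`, `format`
#'   and `nucleotideState`.
#'
#' @seealso [readStructure()], [extractCA()]
#' @export
setClass("StructureModel",
  representation(structureId = "character", atoms = "data.frame",
                 metadata = "list"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  needed <- c("type", "elety", "resid", "chain", "resno", "insert",
              "x", "y", "z", "o", "ligand", "water")
  if (!all(needed %in% names(a)))
    return(paste("atoms must contain columns:",
                 paste(setdiff(needed, names(a)), collapse = ", ")))
  if (nrow(a) == 0) return("empty structure: no atom records")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (any(a$o < 0 | a$o > 1, na.rm = TRUE))
    return("occupancy outside [0, 1]")
  if (length(object@structureId) != 1) return("structureId must be length 1")
  TRUE
})

#' DomainDefinition: an inclusive residue interval in reference numbering
#'
#' Named domains default to the RECQL5 catalytic-core boundaries: the two
#' RecA-like domains D1 (residues 1-219) and D2 (residues 220-364) and the
#' Zn-binding subdomain (residues 365-437).
#'
#' @slot name one of "D1", "D2", "Zn" or "custom".
#' @slot start,end inclusive 1-based residue bounds (author numbering).
#' @export
setClass("DomainDefinition",
  representation(name = "character", start = "numeric", end = "numeric"))

setValidity("DomainDefinition", function(object) {
  if (!object@name %in% c("D1", "D2", "Zn", "custom"))
    return("name must be one of D1, D2, Zn, custom")
  if (object@start > object@end) return("interval start must be <= end")
  TRUE
})

#' SuperpositionResult: an optimal rigid-body transform
#'
#' Result of a Kabsch least-squares superposition. Applying
#' `rotation %*% x + translation` to mobile coordinates `x` minimises the RMSD
#' to the reference over all proper rigid transforms.
#'
#' @slot rotation 3x3 proper rotation matrix (orthonormal, determinant +1).
#' @slot translation length-3 numeric (Angstrom).
#' @slot rmsd root-mean-square deviation over the fitted atoms (Angstrom).
#' @slot nAtoms number of matched atom pairs used.
#' @slot frame the selection (e.g. a [DomainDefinition-class]) the fit used,
#'   or `NULL`.
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nAtoms = "integer", frame = "ANY"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation is not orthonormal")
  if (abs(det(R) - 1) > 1e-8) return("rotation determinant must be +1")
  if (length(object@translation) != 3) return("translation must be length 3")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  if (object@nAtoms < 3) return("superposition requires >= 3 atom pairs")
  TRUE
})

#' DisplacementProfile: per-residue displacement between two structures
#'
#' Per-residue Calpha displacements after superposing one structure onto
#' another using only the residues of a chosen frame domain. Displacements are
#' reported for every residue common to both structures, inside and outside
#' the frame.
#'
#' @slot profile data frame with columns `resno` and `displacement`
#'   (Angstrom), ordered by residue number.
#' @slot frame the frame selection used for the superposition.
#' @slot maxDisplacement maximum of the displacement column.
#' @slot superposition the [SuperpositionResult-class] of the frame fit.
#' @export
setClass("DisplacementProfile",
  representation(profile = "data.frame", frame = "ANY",
                 maxDisplacement = "numeric",
                 superposition = "SuperpositionResult"))

setValidity("DisplacementProfile", function(object) {
  p <- object@profile
  if (!all(c("resno", "displacement") %in% names(p)))
    return("profile must have columns resno, displacement")
  if (nrow(p) > 0) {
    if (any(p$displacement < 0)) return("displacements must be >= 0")
    if (abs(object@maxDisplacement - max(p$displacement)) > 1e-9)
      return("maxDisplacement must equal max(profile$displacement)")
  }
  TRUE
})

#' AnchorSet: the four invariant anchor residues of a structure
#'
#' The four structurally invariant Calpha positions that place a RecQ-family
#' structure on the 2D conformational landscape: two on the D1 domain
#' (motif 0 and motif Ia) and two on the D2/Zn module (motif IV and the
#' Zn-binding subdomain). In RECQL5 numbering these are Q34, L79, T268 and
#' F420; [referenceAnchors()] returns that set, and [mapAnchors()] transfers
#' it onto homologous structures.
#'
#' @slot structureId structure the anchors refer to.
#' @slot chain chain identifier within that structure.
#' @slot anchors named numeric of length 4 with names `D1_motif0`,
#'   `D1_motifIa`, `D2_motifIV`, `D2_Zn`; values are author residue numbers
#'   in the target structure.
#' @export
setClass("AnchorSet",
  representation(structureId = "character", chain = "character",
                 anchors = "numeric"))

.anchorNames <- c("D1_motif0", "D1_motifIa", "D2_motifIV", "D2_Zn")

setValidity("AnchorSet", function(object) {
  if (length(object@anchors) != 4 ||
      !identical(sort(names(object@anchors)), sort(.anchorNames)))
    return(paste("anchors must be a named numeric of length 4 with names:",
                 paste(.anchorNames, collapse = ", ")))
  TRUE
})

#' ResidueMapping: residue correspondence from a pairwise global alignment
#'
#' Ordered residue-number correspondence between a reference and a target
#' sequence over the aligned, non-gap columns of a Needleman-Wunsch global
#' alignment. The mapping is strictly monotonic in both numberings.
#'
#' @slot pairs data frame with columns `refPos`, `targetPos` (1-based
#'   positions in the ungapped sequences) and `refResno`, `targetResno`
#'   (author residue numbers when the sequences came from structures).
#' @slot score alignment score under the scoring scheme used.
#' @slot percentIdentity percent identity over aligned columns.
#' @export
setClass("ResidueMapping",
  representation(pairs = "data.frame", score = "numeric",
                 percentIdentity = "numeric"))

setValidity("ResidueMapping", function(object) {
  p <- object@pairs
  if (!all(c("refPos", "targetPos") %in% names(p)))
    return("pairs must have columns refPos, targetPos")
  if (nrow(p) > 1) {
    if (any(diff(p$refPos) <= 0) || any(diff(p$targetPos) <= 0))
      return("mapping must be strictly monotonic in both numberings")
  }
  TRUE
})

#' MMFit: a Michaelis-Menten fit of a rate-versus-substrate curve
#'
#' Nonlinear least-squares fit of v = kcat * S / (Km + S). Units follow the
#' input data: with rates as turnover (min^-1) and substrate in molar, `kcat`
#' is min^-1 and `km` molar.
#'
#' @slot kcat,km fitted parameters.
#' @slot se named numeric of standard errors ("kcat", "km").
#' @slot rss residual sum of squares.
#' @slot nPoints number of data points fitted.
#' @slot converged logical convergence flag.
#' @slot notes character vector of fit warnings (empty when clean).
#' @export
setClass("MMFit",
  representation(kcat = "numeric", km = "numeric", se = "numeric",
                 rss = "numeric", nPoints = "integer",
                 converged = "logical", notes = "character"))

setValidity("MMFit", function(object) {
  if (object@converged && (object@kcat <= 0 || object@km <= 0))
    return("kcat and km must be positive at convergence")
  TRUE
})

#' BindingFit: a four-parameter-logistic binding fit
#'
#' Fit of the four-parameter logistic model
#' FP(x) = bottom + (top - bottom) / (1 + (Kd / x)^hill) to a
#' fluorescence-polarization titration. When fitted jointly with a shared
#' maximal signal, `sharedTopGroup` identifies the group.
#'
#' @slot kd equilibrium dissociation constant (same units as concentration).
#' @slot top,bottom upper and lower asymptotes (mP).
#' @slot hill Hill coefficient (dimensionless).
#' @slot se named numeric of standard errors ("kd", "top", "bottom", "hill").
#' @slot rss residual sum of squares.
#' @slot nPoints number of data points.
#' @slot sharedTopGroup group label when `top` was shared, else `NA`.
#' @slot notes character vector of fit warnings (e.g. Kd extrapolation).
#' @export
setClass("BindingFit",
  representation(kd = "numeric", top = "numeric", bottom = "numeric",
                 hill = "numeric", se = "numeric", rss = "numeric",
                 nPoints = "integer", sharedTopGroup = "character",
                 notes = "character"))

setValidity("BindingFit", function(object) {
  if (object@kd <= 0) return("kd must be positive")
  if (object@hill <= 0) return("hill must be positive")
  if (object@top <= object@bottom) return("top must exceed bottom")
  TRUE
})
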