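#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `thetaDeg`
#' degrees about `axis` (normalised internally).
#'
#' @param axis length-3 numeric axis direction.
#' @param thetaDeg rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotationMatrix <- function(axis, thetaDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- thetaDeg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix or a data frame with `x`, `y`, `z` columns.
#' @param superposition a [SuperpositionResult-class], or a 3x3 rotation
#'   matrix (then supply `translation`).
#' @param translation length-3 numeric, used when `superposition` is a bare
#'   rotation matrix.
#' @return transformed coordinates, same shape as the input matrix.
#' @export
transformCoordinates <- function(coords, superposition,
                                 translation = c(0, 0, 0)) {
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("x", "y", "z")])
  if (is(superposition, "SuperpositionResult")) {
    R <- rotation(superposition)
    tr <- translation(superposition)
  } else {
    R <- superposition
    tr <- translation
  }
  sweep(coords %*% t(R), 2, -tr)
}

.caMatrix <- function(ca) {
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

.checkNonDegenerate <- function(m, what) {
  d <- svd(scale(m, scale = FALSE))$d
  if (d[2] <= 1e-8 * max(d[1], 1))
    stop("degenerate-superposition: ", what, " points are (near-)collinear")
}

#' Optimal rigid-body (Kabsch) superposition
#'
#' Least-squares optimal superposition of paired Calpha coordinates by the
#' SVD form of the Kabsch algorithm, with reflection correction (the sign of
#' the smallest singular vector is flipped when the determinant would be
#' negative), so the result is always a proper rotation. The returned
#' transform maps mobile coordinates onto the reference frame.
#'
#' @param mobile,reference Calpha tables as returned by [extractCA()] (data
#'   frames with `resno`, `x`, `y`, `z`), or bare n x 3 matrices.
#' @param pairing optional two-column matrix/data frame of matched residue
#'   numbers `(mobile, reference)`. Defaults to matching equal residue
#'   numbers when both inputs carry `resno`, or row order for bare matrices.
#' @param frame optional [DomainDefinition-class] recorded in the result.
#' @return a [SuperpositionResult-class].
#' @examples
#' fam <- makeHingeFamily(angles = c(0, 30), seed = 1)
#' d1 <- domainDefinition("D1")
#' a <- extractCA(fam$structures[[1]], selection = d1)
#' b <- extractCA(fam$structures[[2]], selection = d1)
#' rmsd(kabschSuperpose(b, a))
#' @export
kabschSuperpose <- function(mobile, reference, pairing = NULL, frame = NULL) {
  if (is.data.frame(mobile) && is.data.frame(reference) &&
      !is.null(mobile$resno) && !is.null(reference$resno)) {
    if (is.null(pairing)) {
      common <- intersect(mobile$resno, reference$resno)
      pairing <- cbind(common, common)
    }
    pairing <- as.matrix(pairing)
    im <- match(pairing[, 1], mobile$resno)
    ir <- match(pairing[, 2], reference$resno)
    if (any(is.na(im)) || any(is.na(ir)))
      stop("pairing refers to residues absent from the inputs")
    P <- .caMatrix(mobile)[im, , drop = FALSE]
    Q <- .caMatrix(reference)[ir, , drop = FALSE]
  } else {
    P <- if (is.data.frame(mobile)) .caMatrix(mobile) else as.matrix(mobile)
    Q <- if (is.data.frame(reference)) .caMatrix(reference)
         else as.matrix(reference)
    if (nrow(P) != nrow(Q))
      stop("mobile and reference must contain the same number of points")
  }
  n <- nrow(P)
  if (n < 3)
    stop("degenerate-superposition: need >= 3 matched pairs, got ", n)
  .checkNonDegenerate(P, "mobile")
  .checkNonDegenerate(Q, "reference")
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  s <- svd(crossprod(Pc, Qc))         # covariance C = t(Pc) %*% Qc
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(qc - R %*% pc)
  fitted <- sweep(Pc %*% t(R), 2, qc, "+")
  rmsdVal <- sqrt(mean(rowSums((fitted - Q)^2)))
  new("SuperpositionResult", rotation = R, translation = tr,
      rmsd = rmsdVal, nAtoms = as.integer(n), frame = frame)
}

.matchedCA <- function(caA, caB, mapping = NULL) {
  if (is.null(mapping)) {
    common <- intersect(caA$resno, caB$resno)
    data.frame(resnoA = common, resnoB = common)
  } else {
    p <- mappingTable(mapping)
    keep <- p$refResno %in% caA$resno & p$targetResno %in% caB$resno
    data.frame(resnoA = p$refResno[keep], resnoB = p$targetResno[keep])
  }
}

#' Per-residue displacement profile between two structures
#'
#' Superposes structure `b` onto structure `a` using only the Calpha atoms of
#' the frame domain, then reports the displacement of every Calpha common to
#' both structures (inside and outside the frame). The default frame is D1,
#' the nucleotide-binding domain; the profile then reads out the swing of the
#' D2/Zn module across open and closed states. Residues present in only one
#' structure are dropped, not imputed.
#'
#' @param a,b [StructureModel-class] objects; `b` is superposed onto `a`.
#' @param frame a [DomainDefinition-class] giving the superposition frame
#'   (default D1), in the numbering of `a`.
#' @param mapping optional [ResidueMapping-class] from `a` (reference) to `b`
#'   (target); defaults to identity residue numbering.
#' @param chainA,chainB chain identifiers (default: first chain of each).
#' @return a [DisplacementProfile-class].
#' @export
displacementProfile <- function(a, b, frame = domainDefinition("D1"),
                                mapping = NULL, chainA = NULL,
                                chainB = NULL) {
  caA <- extractCA(a, chainA)
  caB <- extractCA(b, chainB)
  matched <- .matchedCA(caA, caB, mapping)
  if (nrow(matched) == 0)
    stop("no residues common to both structures")
  inFrame <- matched$resnoA >= frame@start & matched$resnoA <= frame@end
  if (sum(inFrame) < 3)
    stop("degenerate-superposition: < 3 frame residues common to both ",
         "structures")
  sup <- kabschSuperpose(
    mobile = caB[match(matched$resnoB[inFrame], caB$resno), ],
    reference = caA[match(matched$resnoA[inFrame], caA$resno), ],
    pairing = cbind(matched$resnoB[inFrame], matched$resnoA[inFrame]),
    frame = frame)
  xb <- transformCoordinates(caB[match(matched$resnoB, caB$resno), ], sup)
  xa <- .caMatrix(caA[match(matched$resnoA, caA$resno), ])
  disp <- sqrt(rowSums((xb - xa)^2))
  prof <- data.frame(resno = matched$resnoA, displacement = disp)
  prof <- prof[order(prof$resno), , drop = FALSE]
  rownames(prof) <- NULL
  new("DisplacementProfile", profile = prof, frame = frame,
      maxDisplacement = max(disp), superposition = sup)
}

#' Pairwise RMSD matrix over a structure set
#'
#' Symmetric matrix of Calpha RMSDs after Kabsch superposition restricted to
#' the frame domain; entry (i, j) is the frame RMSD between structures i
#' and j.
#'
#' @param structures list of [StructureModel-class] objects.
#' @param frame a [DomainDefinition-class] (default D1).
#' @param mappings optional list of [ResidueMapping-class] objects, one per
#'   structure, translating each structure's numbering to a common reference
#'   numbering; identity numbering when `NULL`.
#' @param chains optional character vector of chain ids, one per structure.
#' @return symmetric numeric matrix (Angstrom) with zero diagonal, named by
#'   structure id.
#' @export
pairwiseRMSDMatrix <- function(structures, frame = domainDefinition("D1"),
                               mappings = NULL, chains = NULL) {
  n <- length(structures)
  if (n == 0) stop("no structures supplied")
  refCA <- lapply(seq_len(n), function(i) {
    ca <- extractCA(structures[[i]], chain = chains[i])
    if (!is.null(mappings) && !is.null(mappings[[i]])) {
      p <- mappingTable(mappings[[i]])
      idx <- match(ca$resno, p$targetResno)
      ca <- ca[!is.na(idx), , drop = FALSE]
      ca$resno <- p$refResno[idx[!is.na(idx)]]
    }
    ca[ca$resno >= frame@start & ca$resno <= frame@end, , drop = FALSE]
  })
  ids <- vapply(structures, structureId, character(1))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      common <- intersect(refCA[[i]]$resno, refCA[[j]]$resno)
      if (length(common) < 3)
        stop("structures ", ids[i], " and ", ids[j],
             " share < 3 frame residues")
      sup <- kabschSuperpose(refCA[[j]], refCA[[i]],
                             pairing = cbind(common, common), frame = frame)
      m[i, j] <- m[j, i] <- rmsd(sup)
    }
  }
  m
}

#' Export a displacement profile as TSV
#'
#' Writes two tab-separated columns, `residue_number` and `displacement_A`.
#'
#' @param profile a [DisplacementProfile-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportProfile <- function(profile, path) {
  p <- profileTable(profile)
  utils::write.table(
    data.frame(residue_number = p$resno, displacement_A = p$displacement),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a rigid transform as JSON
#'
#' Serialises the rotation (row-major) and translation of a superposition
#' together with its RMSD and atom count.
#'
#' @param superposition a [SuperpositionResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportTransform <- function(superposition, path) {
  jsonlite::write_json(
    list(rotation = as.vector(t(rotation(superposition))),
         translation = translation(superposition),
         rmsd = rmsd(superposition), n_atoms = nAtoms(superposition)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Apply a global rigid motion to a whole structure
#'
#' Rotates and translates every atom of a structure; useful for testing
#' frame invariance of downstream quantities.
#'
#' @param structure a [StructureModel-class].
#' @param R 3x3 rotation matrix.
#' @param tr length-3 translation (Angstrom).
#' @return the transformed [StructureModel-class].
#' @export
transformStructure <- function(structure, R, tr = c(0, 0, 0)) {
  stopifnot(is(structure, "StructureModel"))
  a <- atoms(structure)
  xyz <- transformCoordinates(as.matrix(a[, c("x", "y", "z")]), R, tr)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new("StructureModel", structureId = structureId(structure), atoms = a,
      metadata = structure@metadata)
}
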