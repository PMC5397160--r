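#' Log-spaced design points
#'
#' @param from,to positive endpoints (inclusive).
#' @param n number of points.
#' @return numeric vector of `n` logarithmically spaced values.
#' @export
logSpaced <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

# Calpha trace of an ideal alpha-helix walking along `axis`:
# 1.5 A rise and 100 degrees of turn per residue on a 2.3 A radius
.caHelix <- function(n, origin, axis, radius = 2.3, rise = 1.5,
                     turnDeg = 100) {
  u <- axis / sqrt(sum(axis^2))
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  i <- seq_len(n) - 1
  ph <- i * turnDeg * pi / 180
  t(vapply(seq_len(n), function(j)
    origin + i[j] * rise * u + radius * (cos(ph[j]) * e1 + sin(ph[j]) * e2),
    numeric(3)))
}

.aaAlphabet <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

.structureFromCA <- function(id, resno, resid, xyz, metadata = list()) {
  n <- length(resno)
  atomsDF <- data.frame(
    type = "ATOM", eleno = seq_len(n), elety = "CA", alt = "",
    resid = resid, chain = "A", resno = resno, insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0, elesy = "C",
    ligand = FALSE, water = FALSE, stringsAsFactors = FALSE)
  new("StructureModel", structureId = id, atoms = atomsDF,
      metadata = metadata)
}

#' Generate a family of synthetic two-domain hinge structures
#'
#' Builds a Calpha-only model of two pseudo-globular domains (ideal helical
#' walks; geometry, not chemistry, is what these fixtures exercise) joined at
#' a hinge: D1 (residues 1 to `nD1`) is held fixed while the D2/Zn module
#' (residues `nD1 + 1` onward) is rigid-rotated about the hinge axis by each
#' requested angle. Gaussian coordinate noise, applied to the mobile domain
#' after rotation, and missing-residue intervals (mimicking disordered
#' loops) are optional. The four RECQL5 anchor residues (34, 79, 268, 420)
#' carry their reference identities (GLN, LEU, THR, PHE) so sequence-based
#' anchor mapping works on the output; remaining residue identities are drawn
#' once per family from a seeded RNG, so every member shares one sequence.
#'
#' Because rotation about the hinge axis moves each mobile atom along a
#' chord, the displacement of an atom at distance r from the axis is exactly
#' 2 r sin(theta / 2), which gives the family an analytic ground truth for
#' displacement profiles.
#'
#' @param angles numeric vector of hinge opening angles in degrees, each in
#'   \[0, 180\]; one structure is generated per entry.
#' @param nD1 residues in the fixed D1 domain (default 219).
#' @param nD2 residues in the mobile D2/Zn module (default 218, so the
#'   default family spans residues 1-437 and contains all four anchors).
#' @param hingeAxis hinge axis direction through the origin (default z).
#' @param noiseSd isotropic Gaussian coordinate noise (Angstrom) added to
#'   the mobile domain of each structure (default 0).
#' @param missing list of length-2 vectors of residue intervals to delete,
#'   e.g. `list(c(250, 260))`.
#' @param seed RNG seed; the full output is deterministic given the seed.
#' @param idPrefix structure ids are `<idPrefix>_<index>`.
#' @param nucleotideStates optional character vector (recycled) stored as
#'   each structure's nucleotide-state tag.
#' @return list with elements:
#'   \describe{
#'     \item{structures}{list of [StructureModel-class], one per angle.}
#'     \item{truth}{data frame per structure: `structure_id`, `angle`,
#'       noise-free anchor coordinates (`<anchor>_x/y/z`), noise-free axis
#'       distances under both cross pairings (`axis1_cross1`, ...), `r_max`
#'       (largest distance of a mobile atom from the hinge axis) and
#'       `max_displacement_from_base` = 2 r_max sin(angle / 2) relative to
#'       the 0-degree base geometry.}
#'     \item{anchors}{the reference [AnchorSet-class] valid for every
#'       member.}
#'     \item{seed}{the seed used.}
#'   }
#' @examples
#' fam <- makeHingeFamily(angles = c(0, 30), seed = 7)
#' fam$truth[, c("structure_id", "angle", "axis1_cross1")]
#' @export
makeHingeFamily <- function(angles, nD1 = 219, nD2 = 218,
                            hingeAxis = c(0, 0, 1), noiseSd = 0,
                            missing = list(), seed = 1,
                            idPrefix = "hinge",
                            nucleotideStates = NA_character_) {
  stopifnot(length(angles) >= 1, all(angles >= 0), all(angles <= 180),
            noiseSd >= 0, nD1 >= 3, nD2 >= 3)
  set.seed(seed)
  nTot <- nD1 + nD2
  resid <- sample(.aaAlphabet, nTot, replace = TRUE)
  for (a in list(c(34, "GLN"), c(79, "LEU"), c(268, "THR"), c(420, "PHE"))) {
    i <- as.numeric(a[1])
    if (i <= nTot) resid[i] <- a[2]
  }
  # D1 extends into +x with negative y offset, D2 with positive y offset;
  # this geometry keeps the cross-domain anchor distances monotonic in the
  # hinge angle over [0, 180] degrees
  d1 <- .caHelix(nD1, origin = c(3, -6, 0),
                 axis = c(1, -0.15, 0.08))
  d2base <- .caHelix(nD2, origin = c(3, 6, 0),
                     axis = c(1, 0.15, -0.08))
  u <- hingeAxis / sqrt(sum(hingeAxis^2))
  axisDist <- function(m) {
    proj <- m %*% u
    sqrt(rowSums((m - proj %*% t(u))^2))
  }
  rMax <- max(axisDist(d2base))
  nucleotideStates <- rep(nucleotideStates, length.out = length(angles))

  anchorsRef <- referenceAnchors(structureId = idPrefix)
  anchorIdx <- anchors(anchorsRef)
  structures <- vector("list", length(angles))
  truthRows <- vector("list", length(angles))
  for (k in seq_along(angles)) {
    R <- rotationMatrix(u, angles[k])
    d2 <- d2base %*% t(R)
    xyzClean <- rbind(d1, d2)
    d2noisy <- d2
    if (noiseSd > 0)
      d2noisy <- d2 + matrix(stats::rnorm(length(d2), sd = noiseSd),
                             nrow(d2), 3)
    xyz <- rbind(d1, d2noisy)
    resno <- seq_len(nTot)
    keep <- rep(TRUE, nTot)
    for (iv in missing) keep[resno >= iv[1] & resno <= iv[2]] <- FALSE
    id <- sprintf("%s_%02d", idPrefix, k)
    structures[[k]] <- .structureFromCA(
      id, resno[keep], resid[keep], xyz[keep, , drop = FALSE],
      metadata = list(angle = angles[k], seed = seed, noiseSd = noiseSd,
                      nucleotideState = nucleotideStates[k],
                      generator = "makeHingeFamily"))
    anchorXYZ <- xyzClean[anchorIdx, , drop = FALSE]
    rownames(anchorXYZ) <- names(anchorIdx)
    dOf <- function(a1, a2) sqrt(sum((anchorXYZ[a1, ] - anchorXYZ[a2, ])^2))
    row <- data.frame(structure_id = id, angle = angles[k],
                      axis1_cross1 = dOf("D1_motif0", "D2_Zn"),
                      axis2_cross1 = dOf("D1_motifIa", "D2_motifIV"),
                      axis1_cross2 = dOf("D1_motif0", "D2_motifIV"),
                      axis2_cross2 = dOf("D1_motifIa", "D2_Zn"),
                      r_max = rMax,
                      max_displacement_from_base =
                        2 * rMax * sin(angles[k] * pi / 360),
                      stringsAsFactors = FALSE)
    for (nm in names(anchorIdx)) {
      row[[paste0(nm, "_x")]] <- anchorXYZ[nm, 1]
      row[[paste0(nm, "_y")]] <- anchorXYZ[nm, 2]
      row[[paste0(nm, "_z")]] <- anchorXYZ[nm, 3]
    }
    truthRows[[k]] <- row
  }
  list(structures = structures, truth = do.call(rbind, truthRows),
       anchors = anchorsRef, seed = seed)
}

#' Derive a homolog sequence with a known residue correspondence
#'
#' Applies a set of edits (substitutions, insertions, deletions) to a
#' reference sequence and returns the edited sequence together with the
#' exact reference-to-target residue correspondence, for use as ground truth
#' when testing alignment-based anchor transfer.
#'
#' @param reference character scalar (1-letter amino-acid sequence).
#' @param edits list of edits, each a list with `type` ("sub", "ins",
#'   "del"), `pos` (1-based reference position; insertions insert *before*
#'   `pos`), and either `seq` (replacement/inserted letters, for
#'   "sub"/"ins") or `length` (number of residues deleted, for "del").
#'   Edits must not overlap.
#' @param substitutionRate optionally, instead of explicit substitution
#'   edits, randomly substitute this fraction of positions (seeded).
#' @param seed RNG seed for random substitutions.
#' @return list with `sequence` (edited sequence) and `mapping` (data frame
#'   `refPos`, `targetPos` over conserved and substituted positions).
#' @examples
#' makeHomologSequence("ACDEFG", list(list(type = "del", pos = 3,
#'                                         length = 1)))
#' @export
makeHomologSequence <- function(reference, edits = list(),
                                substitutionRate = 0, seed = 1) {
  stopifnot(nzchar(reference))
  chars <- strsplit(reference, "")[[1]]
  n <- length(chars)
  if (substitutionRate > 0) {
    set.seed(seed)
    nSub <- round(substitutionRate * n)
    pos <- sample(n, nSub)
    aa1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (p in pos) {
      edits <- c(edits, list(list(type = "sub", pos = p,
                                  seq = sample(setdiff(aa1, chars[p]), 1))))
    }
  }
  span <- function(e) switch(e$type,
    sub = c(e$pos, e$pos + nchar(e$seq) - 1),
    del = c(e$pos, e$pos + e$length - 1),
    ins = c(e$pos, e$pos - 1))   # zero-width
  if (length(edits) > 1) {
    spans <- t(vapply(edits, span, numeric(2)))
    ord <- order(spans[, 1])
    sp <- spans[ord, , drop = FALSE]
    for (i in seq_len(nrow(sp) - 1))
      if (sp[i + 1, 1] <= sp[i, 2])
        stop("overlapping edits at reference position ", sp[i + 1, 1])
  }
  # per-reference-position state: keep / substitute / delete, plus
  # insertions keyed by the position they precede
  keepChar <- chars
  deleted <- rep(FALSE, n)
  insBefore <- vector("list", n + 1)
  for (e in edits) {
    if (e$type == "sub") {
      idx <- e$pos + seq_len(nchar(e$seq)) - 1
      if (max(idx) > n) stop("substitution runs past the sequence end")
      keepChar[idx] <- strsplit(e$seq, "")[[1]]
    } else if (e$type == "del") {
      idx <- e$pos + seq_len(e$length) - 1
      if (max(idx) > n) stop("deletion runs past the sequence end")
      deleted[idx] <- TRUE
    } else if (e$type == "ins") {
      if (e$pos < 1 || e$pos > n + 1) stop("insertion position out of range")
      insBefore[[e$pos]] <- c(insBefore[[e$pos]], e$seq)
    } else stop("unknown edit type: ", e$type)
  }
  out <- character(0)
  refPos <- integer(0); targetPos <- integer(0)
  for (i in seq_len(n + 1)) {
    for (s in insBefore[[i]]) out <- c(out, strsplit(s, "")[[1]])
    if (i <= n && !deleted[i]) {
      out <- c(out, keepChar[i])
      refPos <- c(refPos, i)
      targetPos <- c(targetPos, length(out))
    }
  }
  list(sequence = paste(out, collapse = ""),
       mapping = data.frame(refPos = refPos, targetPos = targetPos))
}
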