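#' Anchor pairing schemes for the 2D landscape
#'
#' The two landscape axes are distances between one D1 anchor and one D2/Zn
#' anchor; intra-domain distances are rigid and carry no conformational
#' signal. Named schemes:
#' \describe{
#'   \item{cross1 (default)}{axis1 = D1_motif0 to D2_Zn (Q34-F420);
#'     axis2 = D1_motifIa to D2_motifIV (L79-T268).}
#'   \item{cross2}{axis1 = D1_motif0 to D2_motifIV (Q34-T268);
#'     axis2 = D1_motifIa to D2_Zn (L79-F420).}
#' }
#' A custom scheme may be supplied as a list of two character vectors of
#' anchor names, e.g. `list(axis1 = c("D1_motif0", "D2_Zn"), axis2 = ...)`.
#'
#' @param pairing scheme name or custom list.
#' @return list with elements `axis1`, `axis2` (anchor-name pairs) and
#'   `label`.
#' @export
pairingScheme <- function(pairing = "cross1") {
  if (is.list(pairing)) {
    stopifnot(length(pairing$axis1) == 2, length(pairing$axis2) == 2,
              all(c(pairing$axis1, pairing$axis2) %in% .anchorNames))
    return(list(axis1 = pairing$axis1, axis2 = pairing$axis2,
                label = "custom"))
  }
  switch(pairing,
    cross1 = list(axis1 = c("D1_motif0", "D2_Zn"),
                  axis2 = c("D1_motifIa", "D2_motifIV"), label = "cross1"),
    cross2 = list(axis1 = c("D1_motif0", "D2_motifIV"),
                  axis2 = c("D1_motifIa", "D2_Zn"), label = "cross2"),
    stop("unknown pairing scheme: ", pairing))
}

.anchorCoords <- function(structure, anchorsObj, chain = NULL) {
  if (is.null(chain)) chain <- anchorsObj@chain
  ca <- extractCA(structure, chain)
  av <- anchors(anchorsObj)
  coords <- lapply(.anchorNames, function(nm) {
    i <- match(av[[nm]], ca$resno)
    if (is.na(i))
      stop("unmappable-anchor: ", nm, " (residue ", av[[nm]],
           ") has no CA atom in ", structureId(structure), " chain ", chain)
    as.numeric(ca[i, c("x", "y", "z")])
  })
  names(coords) <- .anchorNames
  coords
}

#' Conformational coordinates of one structure chain
#'
#' Computes the two inter-anchor distances that place a structure on the 2D
#' conformational landscape. Distances are frame-free: no superposition is
#' needed, and the coordinates are invariant under any global rigid motion of
#' the structure.
#'
#' @param structure a [StructureModel-class].
#' @param anchors an [AnchorSet-class] in the structure's numbering.
#' @param pairing pairing scheme (see [pairingScheme()]).
#' @param chain chain id; defaults to the anchor set's chain.
#' @return one-row data frame with columns `structure_id`, `chain_id`,
#'   `axis1`, `axis2` (Angstrom), `nucleotide_state`, `pairing`.
#' @export
conformationalCoordinates <- function(structure, anchors, pairing = "cross1",
                                      chain = NULL) {
  scheme <- pairingScheme(pairing)
  if (is.null(chain)) chain <- anchors@chain
  xyz <- .anchorCoords(structure, anchors, chain)
  dist1 <- sqrt(sum((xyz[[scheme$axis1[1]]] - xyz[[scheme$axis1[2]]])^2))
  dist2 <- sqrt(sum((xyz[[scheme$axis2[1]]] - xyz[[scheme$axis2[2]]])^2))
  ns <- structureMetadata(structure)$nucleotideState
  if (is.null(ns)) ns <- NA_character_
  data.frame(structure_id = structureId(structure), chain_id = chain,
             axis1 = dist1, axis2 = dist2, nucleotide_state = ns,
             pairing = scheme$label, stringsAsFactors = FALSE)
}

#' Build the conformational landscape table
#'
#' Computes conformational coordinates for every polymer chain of every
#' structure (chains of the same entry are treated separately). Chains whose
#' anchors cannot be resolved are skipped with a warning and reported in the
#' `skipped` attribute.
#'
#' @param structures list of [StructureModel-class] objects.
#' @param anchorsList optional list, parallel to `structures`, each element
#'   an [AnchorSet-class] (applied to every chain) or a list of anchor sets
#'   keyed by chain id. Defaults to the RECQL5 reference numbering
#'   ([referenceAnchors()]) applied directly.
#' @param pairing pairing scheme (see [pairingScheme()]).
#' @return data frame (one row per chain) ordered by `structure_id` then
#'   `chain_id`, with attribute `skipped`: a data frame of skipped chains and
#'   reasons (zero rows when none).
#' @examples
#' fam <- makeHingeFamily(angles = c(10, 60), seed = 1)
#' buildLandscape(fam$structures)
#' @export
buildLandscape <- function(structures, anchorsList = NULL,
                           pairing = "cross1") {
  if (length(structures) == 0) stop("no structures supplied")
  rows <- list(); skipped <- list()
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    for (ch in chains(s)) {
      anch <- if (is.null(anchorsList)) {
        anchorSet(anchors(referenceAnchors()), structureId(s), ch)
      } else {
        el <- anchorsList[[i]]
        if (is(el, "AnchorSet")) anchorSet(anchors(el), structureId(s), ch)
        else el[[ch]]
      }
      row <- tryCatch(
        conformationalCoordinates(s, anch, pairing, chain = ch),
        error = function(e) e)
      if (inherits(row, "error")) {
        warning("skipping ", structureId(s), " chain ", ch, ": ",
                conditionMessage(row), call. = FALSE)
        skipped[[length(skipped) + 1]] <- data.frame(
          structure_id = structureId(s), chain_id = ch,
          reason = conditionMessage(row), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  if (length(rows) == 0)
    stop("all chains were unmappable; see warnings for per-chain reasons")
  out <- do.call(rbind, rows)
  out <- out[order(out$structure_id, out$chain_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(structure_id = character(), chain_id = character(),
               reason = character())
  out
}

#' Classify landscape points into open/closed (and intermediate) states
#'
#' Clusters the 2D conformational coordinates and labels the clusters by
#' their mean axis1 distance: the cluster with the largest mean inter-domain
#' distance is "open", the smallest "closed" (with k = 3 the middle cluster
#' is "intermediate"). With `method = "kmeans"` a fixed seed makes the
#' assignment deterministic. An optional margin flags points near the cluster
#' boundary as "intermediate".
#'
#' @param coordinates landscape table from [buildLandscape()].
#' @param method "kmeans" or "threshold".
#' @param k number of clusters for k-means (default 2).
#' @param seed RNG seed for k-means (default 0).
#' @param margin half-width of the intermediate band: points whose distances
#'   to the two nearest cluster centres (k-means), or whose axis1 distance to
#'   the cutoff (threshold), differ by less than `margin` Angstrom are
#'   labelled "intermediate". Default 0 (off).
#' @param cutoff axis1 threshold (Angstrom) for `method = "threshold"`;
#'   points above it are "open".
#' @return data frame with columns `structure_id`, `chain_id`, `label`, plus
#'   attributes `method` and `params`.
#' @export
classifyStates <- function(coordinates, method = c("kmeans", "threshold"),
                           k = 2, seed = 0, margin = 0, cutoff = NULL) {
  method <- match.arg(method)
  X <- as.matrix(coordinates[, c("axis1", "axis2")])
  n <- nrow(X)
  if (method == "kmeans") {
    if (k < 1 || k > nrow(unique(X)))
      stop("parameter error: k = ", k, " exceeds the number of distinct ",
           "points (", nrow(unique(X)), ")")
    ux <- unique(X)
    if (k < nrow(ux)) {
      set.seed(seed)
      kmFit <- stats::kmeans(X, centers = k, nstart = 25)
    } else {
      # as many clusters as distinct points: each point is its own centre
      # (stats::kmeans requires k strictly below the number of points)
      kmFit <- list(centers = ux,
                    cluster = match(do.call(paste, as.data.frame(X)),
                                    do.call(paste, as.data.frame(ux))))
    }
    ord <- order(kmFit$centers[, "axis1"], decreasing = TRUE)
    lab <- if (k == 1) "closed" else if (k == 2) c("open", "closed") else
      if (k == 3) c("open", "intermediate", "closed") else
        paste0("state", seq_len(k))
    labels <- lab[match(kmFit$cluster, ord)]
    if (margin > 0 && k >= 2) {
      dc <- as.matrix(stats::dist(rbind(X, kmFit$centers)))
      dc <- dc[seq_len(n), n + seq_len(k), drop = FALSE]
      near <- t(apply(dc, 1, sort))[, 1:2, drop = FALSE]
      labels[near[, 2] - near[, 1] < margin] <- "intermediate"
    }
    params <- list(k = k, seed = seed, margin = margin)
  } else {
    if (is.null(cutoff)) stop("parameter error: threshold method needs a cutoff")
    labels <- ifelse(X[, "axis1"] > cutoff, "open", "closed")
    if (margin > 0)
      labels[abs(X[, "axis1"] - cutoff) < margin] <- "intermediate"
    params <- list(cutoff = cutoff, margin = margin)
  }
  out <- data.frame(structure_id = coordinates$structure_id,
                    chain_id = coordinates$chain_id, label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "params") <- params
  out
}

#' Scatter plot of the conformational landscape
#'
#' @param coordinates landscape table from [buildLandscape()].
#' @param assignments optional state table from [classifyStates()]; labels
#'   are then mapped to point shape.
#' @return a ggplot object.
#' @export
plotLandscape <- function(coordinates, assignments = NULL) {
  d <- coordinates
  if (!is.null(assignments))
    d <- merge(d, assignments, by = c("structure_id", "chain_id"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = axis1, y = axis2,
                                       colour = nucleotide_state))
  if (!is.null(assignments))
    p <- p + ggplot2::aes(shape = label)
  p + ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "axis 1 anchor distance (Å)",
                  y = "axis 2 anchor distance (Å)",
                  colour = "nucleotide state", shape = "state") +
    ggplot2::theme_bw()
}

utils::globalVariables(c("axis1", "axis2", "nucleotide_state", "label"))
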