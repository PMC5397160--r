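# Accessor generics and show methods. Slots are reached through these
# accessors rather than `@`.

#' @rdname StructureModel-class
#' @param object,x an object of the documented class
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))
#' @rdname StructureModel-class
#' @export
setMethod("structureId", "StructureModel", function(x) x@structureId)

#' @rdname StructureModel-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname StructureModel-class
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname StructureModel-class
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))
#' @rdname StructureModel-class
#' @export
setMethod("chains", "StructureModel",
          function(x) unique(x@atoms$chain[x@atoms$type == "ATOM"]))

#' @rdname StructureModel-class
#' @export
setGeneric("structureMetadata", function(x) standardGeneric("structureMetadata"))
#' @rdname StructureModel-class
#' @export
setMethod("structureMetadata", "StructureModel", function(x) x@metadata)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  poly <- a[a$type == "ATOM" & !a$water, , drop = FALSE]
  nres <- nrow(unique(poly[, c("chain", "resno", "insert")]))
  cat("StructureModel:", object@structureId, "\n",
      " chains: ", paste(chains(object), collapse = ", "),
      " | residues: ", nres, " | atoms: ", nrow(a), "\n", sep = "")
  ns <- object@metadata$nucleotideState
  if (!is.null(ns) && !is.na(ns)) cat("  nucleotide state:", ns, "\n")
})

#' @rdname SuperpositionResult-class
#' @param x an object of the documented class
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @rdname SuperpositionResult-class
#' @export
setMethod("rotation", "SuperpositionResult", function(x) x@rotation)

#' @rdname SuperpositionResult-class
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))
#' @rdname SuperpositionResult-class
#' @export
setMethod("translation", "SuperpositionResult", function(x) x@translation)

#' @rdname SuperpositionResult-class
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))
#' @rdname SuperpositionResult-class
#' @export
setMethod("rmsd", "SuperpositionResult", function(x) x@rmsd)

#' @rdname SuperpositionResult-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname SuperpositionResult-class
#' @export
setMethod("nAtoms", "SuperpositionResult", function(x) x@nAtoms)

setMethod("show", "SuperpositionResult", function(object) {
  cat("SuperpositionResult: rmsd =", format(object@rmsd, digits = 4),
      "A over", object@nAtoms, "atom pairs\n")
})

#' @rdname DisplacementProfile-class
#' @param x an object of the documented class
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))
#' @rdname DisplacementProfile-class
#' @export
setMethod("profileTable", "DisplacementProfile", function(x) x@profile)

#' @rdname DisplacementProfile-class
#' @export
setGeneric("maxDisplacement", function(x) standardGeneric("maxDisplacement"))
#' @rdname DisplacementProfile-class
#' @export
setMethod("maxDisplacement", "DisplacementProfile",
          function(x) x@maxDisplacement)

setMethod("show", "DisplacementProfile", function(object) {
  cat("DisplacementProfile over", nrow(object@profile), "residues; max =",
      format(object@maxDisplacement, digits = 4), "A\n")
})

#' @rdname AnchorSet-class
#' @param x an object of the documented class
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))
#' @rdname AnchorSet-class
#' @export
setMethod("anchors", "AnchorSet", function(x) x@anchors)

#' @rdname AnchorSet-class
#' @export
setMethod("structureId", "AnchorSet", function(x) x@structureId)

setMethod("show", "AnchorSet", function(object) {
  cat("AnchorSet for", object@structureId, "chain", object@chain, "\n")
  print(object@anchors)
})

#' @rdname ResidueMapping-class
#' @param x an object of the documented class
#' @export
setGeneric("mappingTable", function(x) standardGeneric("mappingTable"))
#' @rdname ResidueMapping-class
#' @export
setMethod("mappingTable", "ResidueMapping", function(x) x@pairs)

#' @rdname ResidueMapping-class
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname ResidueMapping-class
#' @export
setMethod("alignmentScore", "ResidueMapping", function(x) x@score)

#' @rdname ResidueMapping-class
#' @export
setGeneric("percentIdentity", function(x) standardGeneric("percentIdentity"))
#' @rdname ResidueMapping-class
#' @export
setMethod("percentIdentity", "ResidueMapping", function(x) x@percentIdentity)

setMethod("show", "ResidueMapping", function(object) {
  cat("ResidueMapping:", nrow(object@pairs), "aligned pairs; score =",
      format(object@score, digits = 5), "; identity =",
      format(object@percentIdentity, digits = 4), "%\n")
})

#' @rdname MMFit-class
#' @param x an object of the documented class
#' @export
setGeneric("kcat", function(x) standardGeneric("kcat"))
#' @rdname MMFit-class
#' @export
setMethod("kcat", "MMFit", function(x) x@kcat)

#' @rdname MMFit-class
#' @export
setGeneric("km", function(x) standardGeneric("km"))
#' @rdname MMFit-class
#' @export
setMethod("km", "MMFit", function(x) x@km)

#' @rdname MMFit-class
#' @export
setGeneric("fitSE", function(x) standardGeneric("fitSE"))
#' @rdname MMFit-class
#' @export
setMethod("fitSE", "MMFit", function(x) x@se)

#' @rdname MMFit-class
#' @export
setGeneric("fitRSS", function(x) standardGeneric("fitRSS"))
#' @rdname MMFit-class
#' @export
setMethod("fitRSS", "MMFit", function(x) x@rss)

#' @rdname MMFit-class
#' @export
setGeneric("fitNotes", function(x) standardGeneric("fitNotes"))
#' @rdname MMFit-class
#' @export
setMethod("fitNotes", "MMFit", function(x) x@notes)

setMethod("show", "MMFit", function(object) {
  cat("MMFit: kcat =", format(object@kcat, digits = 5),
      "+/-", format(object@se["kcat"], digits = 3),
      "| Km =", format(object@km, digits = 5),
      "+/-", format(object@se["km"], digits = 3),
      "| n =", object@nPoints, "\n")
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' @rdname BindingFit-class
#' @param x an object of the documented class
#' @export
setGeneric("kd", function(x) standardGeneric("kd"))
#' @rdname BindingFit-class
#' @export
setMethod("kd", "BindingFit", function(x) x@kd)

#' @rdname BindingFit-class
#' @export
setGeneric("hillCoefficient", function(x) standardGeneric("hillCoefficient"))
#' @rdname BindingFit-class
#' @export
setMethod("hillCoefficient", "BindingFit", function(x) x@hill)

#' @rdname BindingFit-class
#' @export
setGeneric("topSignal", function(x) standardGeneric("topSignal"))
#' @rdname BindingFit-class
#' @export
setMethod("topSignal", "BindingFit", function(x) x@top)

#' @rdname BindingFit-class
#' @export
setGeneric("bottomSignal", function(x) standardGeneric("bottomSignal"))
#' @rdname BindingFit-class
#' @export
setMethod("bottomSignal", "BindingFit", function(x) x@bottom)

#' @rdname BindingFit-class
#' @export
setMethod("fitSE", "BindingFit", function(x) x@se)
#' @rdname BindingFit-class
#' @export
setMethod("fitRSS", "BindingFit", function(x) x@rss)
#' @rdname BindingFit-class
#' @export
setMethod("fitNotes", "BindingFit", function(x) x@notes)

setMethod("show", "BindingFit", function(object) {
  cat("BindingFit: Kd =", format(object@kd, digits = 5),
      "| top =", format(object@top, digits = 5),
      "| bottom =", format(object@bottom, digits = 5),
      "| hill =", format(object@hill, digits = 4), "\n")
  if (!is.na(object@sharedTopGroup))
    cat("  shared top group:", object@sharedTopGroup, "\n")
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})
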