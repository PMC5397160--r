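.writeRunConfig <- function(outDir, config) {
  config$version <- as.character(utils::packageVersion("RecQLandscape"))
  jsonlite::write_json(config, file.path(outDir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

.writeTSV <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the conformational-landscape stage end to end
#'
#' Reads (or accepts) a set of structures, resolves the four anchor residues
#' on every chain, builds the 2D landscape table, classifies the points into
#' open/closed states and optionally writes all outputs (landscape and
#' assignment TSVs, a config snapshot with seed and package version, and a
#' scatter plot) into a directory. Outputs are deterministic given the
#' inputs and seed.
#'
#' Anchor resolution, per chain: an explicit entry in `anchorOverrides`
#' wins; otherwise, when `referenceStructure` is given, anchors are
#' transferred by global sequence alignment ([globalAlign()] +
#' [mapAnchors()]); otherwise the RECQL5 reference numbering is applied
#' directly.
#'
#' @param structures list of [StructureModel-class] objects, or a character
#'   vector of PDB file paths (validated before any computation).
#' @param nucleotideStates optional character vector of state tags, one per
#'   structure (used when reading from paths, or to override metadata).
#' @param pairing anchor pairing scheme (see [pairingScheme()]).
#' @param k number of k-means clusters (default 2). Classification is
#'   skipped, with a message, when there are fewer points than `k`.
#' @param seed RNG seed for classification.
#' @param margin intermediate-band margin (Angstrom); see
#'   [classifyStates()].
#' @param anchorOverrides optional named list `structureId -> AnchorSet` (or
#'   `structureId -> list(chain -> AnchorSet)`) of manually curated anchors.
#' @param referenceStructure optional [StructureModel-class] carrying the
#'   reference numbering for alignment-based anchor transfer.
#' @param outDir optional output directory (created if needed).
#' @return list with `landscape` (coordinate table, `skipped` attribute for
#'   unmappable chains), `assignments` (state table or `NULL`), and
#'   `outputs` (paths written, or `NULL`).
#' @export
runLandscape <- function(structures, nucleotideStates = NULL,
                         pairing = "cross1", k = 2, seed = 0, margin = 0,
                         anchorOverrides = NULL, referenceStructure = NULL,
                         outDir = NULL) {
  if (is.character(structures)) {
    missingFiles <- structures[!file.exists(structures)]
    if (length(missingFiles))
      stop("validation error: missing structure file(s): ",
           paste(missingFiles, collapse = ", "))
    tags <- if (is.null(nucleotideStates)) rep(NA_character_,
                                               length(structures))
            else rep(nucleotideStates, length.out = length(structures))
    structures <- mapply(function(p, tag)
      readStructure(p, nucleotideState = tag),
      structures, tags, SIMPLIFY = FALSE)
  } else if (!is.null(nucleotideStates)) {
    tags <- rep(nucleotideStates, length.out = length(structures))
    structures <- mapply(function(s, tag) {
      s@metadata$nucleotideState <- tag
      s
    }, structures, tags, SIMPLIFY = FALSE)
  }
  if (length(structures) == 0) stop("validation error: no structures")

  refSeq <- if (!is.null(referenceStructure))
    sequenceFromStructure(referenceStructure) else NULL
  anchorsList <- lapply(structures, function(s) {
    sid <- structureId(s)
    perChain <- lapply(chains(s), function(ch) {
      ov <- anchorOverrides[[sid]]
      if (!is.null(ov)) {
        if (is(ov, "AnchorSet")) return(anchorSet(anchors(ov), sid, ch))
        if (!is.null(ov[[ch]])) return(ov[[ch]])
      }
      if (!is.null(refSeq)) {
        res <- tryCatch({
          mp <- globalAlign(refSeq, sequenceFromStructure(s, ch))
          mapAnchors(referenceAnchors(), mp, s, ch)
        }, error = function(e) e)
        return(res)
      }
      anchorSet(anchors(referenceAnchors()), sid, ch)
    })
    names(perChain) <- chains(s)
    # alignment failures surface later as skipped chains
    perChain <- lapply(perChain, function(a)
      if (inherits(a, "error"))
        anchorSet(c(D1_motif0 = -1, D1_motifIa = -1, D2_motifIV = -1,
                    D2_Zn = -1), sid, "?")
      else a)
    perChain
  })

  landscape <- buildLandscape(structures, anchorsList, pairing)
  assignments <- NULL
  if (nrow(landscape) >= max(k, 2)) {
    assignments <- classifyStates(landscape, method = "kmeans", k = k,
                                  seed = seed, margin = margin)
  } else {
    message("classification skipped: ", nrow(landscape),
            " point(s) is fewer than k = ", k)
  }

  outputs <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    lsPath <- file.path(outDir, "landscape.tsv")
    .writeTSV(landscape, lsPath)
    outputs <- lsPath
    if (!is.null(assignments)) {
      asPath <- file.path(outDir, "assignments.tsv")
      .writeTSV(assignments, asPath)
      outputs <- c(outputs, asPath)
    }
    .writeRunConfig(outDir, list(stage = "landscape", seed = seed,
                                 pairing = pairing, k = k, margin = margin,
                                 n_structures = length(structures)))
    outputs <- c(outputs, file.path(outDir, "run_config.json"))
    plotPath <- file.path(outDir, "landscape.png")
    ok <- tryCatch({
      grDevices::png(plotPath, width = 900, height = 700, res = 120)
      print(plotLandscape(landscape, assignments))
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      warning("plot device unavailable: ", conditionMessage(e),
              call. = FALSE)
      FALSE
    })
    if (ok) outputs <- c(outputs, plotPath)
  }
  list(landscape = landscape, assignments = assignments, outputs = outputs)
}

#' Run the kinetics-report stage end to end
#'
#' Fits every assay dataset in a manifest and assembles a construct-by-
#' activity parameter report (estimate and standard error per parameter),
#' mirroring the usual layout of a kinetic-constants table. Fit failures are
#' reported per row and do not abort the run.
#'
#' @param datasets list of entries, each a list with elements:
#'   \describe{
#'     \item{construct}{construct label (e.g. "11-609").}
#'     \item{activity}{activity label (e.g. "DNA binding (SD)").}
#'     \item{type}{"fourpl", "mm" or "trace".}
#'     \item{data}{a data frame (`conc`/`signal`, `substrate`/`rate`, or
#'       `time`/`a340`).}
#'     \item{args}{optional list of extra fitting arguments (for traces:
#'       `enzymeConc`, and optionally `extinction`, `pathlength`,
#'       `window`).}
#'   }
#' @param outDir optional output directory; the report is written as TSV
#'   and JSON alongside a config snapshot.
#' @param seed seed recorded in the config snapshot (the fits themselves
#'   are deterministic).
#' @return data frame with columns `construct`, `activity`, `parameter`,
#'   `estimate`, `se`, `status` (and `message` for failed rows).
#' @export
runKineticsReport <- function(datasets, outDir = NULL, seed = 0) {
  if (length(datasets) == 0) stop("validation error: no assay datasets")
  rows <- list()
  addRow <- function(construct, activity, parameter, estimate, se,
                     status = "ok", msg = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      construct = construct, activity = activity, parameter = parameter,
      estimate = estimate, se = se, status = status, message = msg,
      stringsAsFactors = FALSE)
  }
  for (d in datasets) {
    stopifnot(!is.null(d$construct), !is.null(d$activity), !is.null(d$type))
    res <- tryCatch({
      if (d$type == "mm") {
        fit <- fitMichaelisMenten(d$data)
        addRow(d$construct, d$activity, "kcat_per_min", kcat(fit),
               fitSE(fit)[["kcat"]])
        addRow(d$construct, d$activity, "Km_M", km(fit), fitSE(fit)[["km"]])
      } else if (d$type == "fourpl") {
        fit <- fitBinding4PL(d$data,
                             shareTop = isTRUE(d$args$shareTop))[[1]]
        addRow(d$construct, d$activity, "Kd_M", kd(fit), fitSE(fit)[["kd"]])
        addRow(d$construct, d$activity, "top_mP", topSignal(fit),
               fitSE(fit)[["top"]])
      } else if (d$type == "trace") {
        args <- c(list(trace = d$data), d$args)
        args$shareTop <- NULL
        rate <- do.call(traceToRate, args)
        addRow(d$construct, d$activity, "turnover_per_min",
               as.numeric(rate), NA_real_)
      } else stop("unknown dataset type: ", d$type)
      TRUE
    }, error = function(e) e)
    if (inherits(res, "error"))
      addRow(d$construct, d$activity, NA_character_, NA_real_, NA_real_,
             status = "failed", msg = conditionMessage(res))
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .writeTSV(report, file.path(outDir, "kinetics_report.tsv"))
    jsonlite::write_json(report, file.path(outDir, "kinetics_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
    .writeRunConfig(outDir, list(stage = "kinetics", seed = seed,
                                 n_datasets = length(datasets)))
  }
  report
}
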