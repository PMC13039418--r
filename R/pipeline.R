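# End-to-end orchestration: registration -> segmentation -> features ->
# islets -> expression landscape, with every stage's outputs written to an
# output directory and a parameter log.

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

# merge aligned rounds into one multichannel image; duplicate channel names
# from later rounds get a round suffix, extra nuclei channels are dropped
mergeRounds <- function(reference, alignedList) {
  chans <- reference@channels
  for (rid in names(alignedList)) {
    al <- alignedList[[rid]]
    for (ch in channelNames(al)) {
      if (identical(ch, nucleiChannel(al))) next
      nm <- if (ch %in% names(chans)) paste0(ch, ".", rid) else ch
      chans[[nm]] <- getChannel(al, ch)
    }
  }
  MultiplexImage(chans, pixelSizeUm = reference@pixelSizeUm,
                 nucleiChannel = nucleiChannel(reference),
                 roundId = "merged")
}

#' Run the full quantification pipeline
#'
#' Orchestrates all stages on one or more imaging rounds: cross-round
#' registration to the first round (skipped for a single round), nucleus
#' detection and cell tessellation, background-corrected feature
#' extraction, islet segmentation and islet-level features (when the
#' configured insulin/glucagon channels are present), and the expression
#' landscape (ROIs, z-score/PCA/k-means clustering, positivity calls).
#' All outputs are written under `outdir`; the run is deterministic given
#' `config@randomSeed`. A failure in any stage aborts with an error naming
#' the stage.
#'
#' @param config a [PipelineConfig-class].
#' @param images list of [MultiplexImage-class] objects or TIFF paths
#'   (readable by [readMultiplexImage()]); the first is the reference round.
#' @param outdir output directory (created if missing).
#' @param markers markers used for the expression landscape; default: every
#'   non-nuclei channel of the merged image.
#' @return invisibly, a list with the main in-memory results (`merged`,
#'   `nuclei`, `cells`, `features`, `islets`, `isletTable`, `clustering`,
#'   `positivity`, `paths`).
#' @export
runPipeline <- function(config, images, outdir, markers = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  if (length(images) < 1) stop("at least one imaging round is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config@randomSeed)
  logLines <- c(sprintf("mplexquant pipeline run, seed %d", config@randomSeed))
  logIt <- function(...) {
    line <- sprintf(...)
    message(line)
    logLines <<- c(logLines, line)
  }

  images <- withStage("input", lapply(images, function(im) {
    if (is.character(im)) readMultiplexImage(im) else im
  }))
  reference <- images[[1]]

  # registration
  transforms <- list()
  if (length(images) > 1) {
    reg <- withStage("registration", registerRounds(
      reference, images[-1], stepPx = config@deformGridStepPx))
    aligned <- reg$aligned
    transforms <- reg$transforms
    logIt("registered %d round(s) to '%s' (grid step %g px)",
          length(aligned), reference@roundId, config@deformGridStepPx)
  } else {
    aligned <- list()
    logIt("single round: registration skipped")
  }
  merged <- withStage("registration", mergeRounds(reference, aligned))

  # segmentation
  nuclei <- withStage("segmentation", detectNuclei(
    getChannel(merged, nucleiChannel(merged))))
  cells <- withStage("segmentation", expandCells(nuclei, expansionPx(config)))
  logIt("segmented %d nuclei; expansion %d px", max(nuclei), expansionPx(config))

  # features
  features <- withStage("features", extractFeatures(
    nuclei, cells, merged,
    correctBackground = TRUE,
    backgroundWindowPx = config@backgroundWindowPx,
    backgroundDownsize = config@backgroundDownsize))

  # islet analysis (when endocrine channels are present)
  isletLabels <- NULL
  isletTable <- NULL
  haveIslets <- all(c(config@insulinChannel, config@glucagonChannel) %in%
                      channelNames(merged))
  # expression landscape
  if (is.null(markers))
    markers <- setdiff(channelNames(merged), nucleiChannel(merged))
  landscape <- withStage("landscape", {
    rois <- selectROIs(dim(merged), config@nRois, config@roiSizePx,
                       seed = config@randomSeed)
    sce <- buildExpressionMatrix(features, markers,
                                 localization = config@markerLocalization,
                                 rois = rois)
    k <- min(config@kmeansK, ncol(sce))
    if (k < config@kmeansK)
      logIt("k reduced to %d (only %d cells in ROIs)", k, ncol(sce))
    cl <- clusterCells(sce, k = k, varFrac = config@pcaVarFrac,
                       seed = config@randomSeed)
    pos <- callPositivity(cl$sce, thresholds = config@positivityThresholds,
                          endocrineMarkers = c(config@insulinChannel,
                                               config@glucagonChannel, "SST"))
    list(rois = rois, clustering = cl, positivity = pos)
  })
  logIt("landscape: %d cells in %d ROIs, %d components, k = %d",
        ncol(landscape$clustering$sce), nrow(landscape$rois),
        landscape$clustering$model@nComponents,
        landscape$clustering$model@k)

  if (haveIslets) {
    isletLabels <- withStage("islets", segmentIslets(
      getChannel(merged, config@insulinChannel),
      getChannel(merged, config@glucagonChannel),
      thresholds = config@isletThresholds,
      minAreaUm2 = config@isletMinAreaUm2,
      pixelSizeUm = config@pixelSizeUm,
      structRadiusPx = config@structRadiusPx))
    isletTable <- withStage("islets", isletFeatures(
      isletLabels, merged, cells = features,
      positivity = landscape$positivity$calls))
    logIt("islets: %d retained (>= %g um2)", max(isletLabels),
          config@isletMinAreaUm2)
  } else {
    logIt("islet channels (%s, %s) not present: islet stage skipped",
          config@insulinChannel, config@glucagonChannel)
  }

  # outputs
  paths <- withStage("output", {
    p <- list(
      alignedImage = file.path(outdir, "aligned.ome.tif"),
      nucleusLabels = file.path(outdir, "nucleus_labels.tif"),
      cellLabels = file.path(outdir, "cell_labels.tif"),
      cellTable = file.path(outdir, "cell_features.csv"),
      clusterProfiles = file.path(outdir, "cluster_profiles.csv"),
      config = file.path(outdir, "config_used.yaml"),
      log = file.path(outdir, "pipeline_log.txt")
    )
    writeMultiplexImage(merged, p$alignedImage)
    writeLabelMap(nuclei, p$nucleusLabels)
    writeLabelMap(cells, p$cellLabels)
    # cell table augmented with ROI, cluster and positivity calls
    aug <- features
    cl <- landscape$clustering
    sceIds <- SummarizedExperiment::colData(cl$sce)$cell_id
    aug$roi <- NA_integer_
    aug$roi[match(sceIds, aug$cell_id)] <-
      SummarizedExperiment::colData(cl$sce)$roi
    aug$cluster <- NA_integer_
    aug$cluster[match(sceIds, aug$cell_id)] <- cl$assignments
    calls <- landscape$positivity$calls
    for (col in setdiff(names(calls), "cell_id")) {
      aug[[paste0("call_", col)]] <- NA
      aug[[paste0("call_", col)]][match(calls$cell_id, aug$cell_id)] <-
        calls[[col]]
    }
    writeCellTable(aug, p$cellTable)
    prof <- as.data.frame(cl$profiles)
    prof <- cbind(cluster = seq_len(nrow(prof)),
                  occurrence = cl$occurrence, prof)
    writeTableFull(prof, p$clusterProfiles)
    if (!is.null(isletLabels)) {
      p$isletLabels <- file.path(outdir, "islet_labels.tif")
      p$isletTable <- file.path(outdir, "islet_features.csv")
      writeLabelMap(isletLabels, p$isletLabels)
      writeIsletTable(isletTable, p$isletTable)
    }
    if (length(transforms)) {
      p$transforms <- file.path(outdir, "transforms.yaml")
      writeTransforms(transforms, p$transforms)
    }
    writePipelineConfig(config, p$config)
    writeLines(logLines, p$log)
    p
  })

  invisible(list(
    merged = merged, nuclei = nuclei, cells = cells, features = features,
    islets = isletLabels, isletTable = isletTable,
    clustering = landscape$clustering, positivity = landscape$positivity,
    rois = landscape$rois, transforms = transforms, paths = paths
  ))
}
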