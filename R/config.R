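#' PipelineConfig: scalar parameters of the quantification workflow
#'
#' Houses every tunable scalar of the pipeline, pre-filled with the standard
#' whole-slide defaults: 0.65 µm pixels, 4.5 µm cell expansion, 7x7 median
#' background window on 10x down-sized images, 400 µm² minimum islet area,
#' 500 px deformation-grid step, 2000 px ROIs, k = 20 expression subtypes at
#' 95% retained PCA variance. An empty override therefore reproduces the
#' reference processing parameters.
#'
#' @slot pixelSizeUm physical pixel size (µm).
#' @slot expansionUm cell-boundary expansion from the nucleus boundary (µm).
#' @slot backgroundWindowPx median-filter window (pixels, odd).
#' @slot backgroundDownsize down-sizing factor before median filtering.
#' @slot isletMinAreaUm2 minimum retained islet area (µm²).
#' @slot deformGridStepPx deformable-registration grid step (px).
#' @slot roiSizePx side length of square analysis ROIs (px).
#' @slot nRois number of ROIs sampled for the expression landscape.
#' @slot kmeansK number of k-means expression subtypes.
#' @slot pcaVarFrac fraction of variance retained by PCA, in (0, 1].
#' @slot markerLocalization named character vector, per-marker `"nuclear"` or
#'   `"cytosolic"` (cytosolic markers are quantified over the whole cell
#'   region, as done for P16).
#' @slot positivityThresholds named list of per-marker positivity threshold
#'   specs: `list(mode = "manual", value =)`, `list(mode = "quantile", q =)`
#'   or `list(mode = "otsu")`.
#' @slot insulinChannel,glucagonChannel channel names used for islet
#'   segmentation.
#' @slot isletThresholds numeric length-2: manual insulin / glucagon
#'   thresholds; `NA` means automatic (Otsu).
#' @slot structRadiusPx disk radius for islet morphological refinement (px).
#' @slot randomSeed integer seed for every stochastic stage.
#' @seealso [pipelineConfig()], [readPipelineConfig()]
#' @export
setClass("PipelineConfig",
  representation(
    pixelSizeUm = "numeric",
    expansionUm = "numeric",
    backgroundWindowPx = "integer",
    backgroundDownsize = "integer",
    isletMinAreaUm2 = "numeric",
    deformGridStepPx = "numeric",
    roiSizePx = "integer",
    nRois = "integer",
    kmeansK = "integer",
    pcaVarFrac = "numeric",
    markerLocalization = "character",
    positivityThresholds = "list",
    insulinChannel = "character",
    glucagonChannel = "character",
    isletThresholds = "numeric",
    structRadiusPx = "integer",
    randomSeed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  pos <- c(
    pixelSizeUm = object@pixelSizeUm, expansionUm = object@expansionUm,
    backgroundWindowPx = object@backgroundWindowPx,
    backgroundDownsize = object@backgroundDownsize,
    isletMinAreaUm2 = object@isletMinAreaUm2,
    deformGridStepPx = object@deformGridStepPx,
    roiSizePx = object@roiSizePx, nRois = object@nRois,
    kmeansK = object@kmeansK, structRadiusPx = object@structRadiusPx
  )
  if (any(!is.finite(pos)) || any(pos <= 0))
    return(paste("all numeric parameters must be positive; offending:",
                 paste(names(pos)[!is.finite(pos) | pos <= 0], collapse = ", ")))
  if (object@backgroundWindowPx %% 2L != 1L)
    return("backgroundWindowPx must be odd")
  if (object@pcaVarFrac <= 0 || object@pcaVarFrac > 1)
    return("pcaVarFrac must be in (0, 1]")
  if (length(object@markerLocalization) &&
      !all(object@markerLocalization %in% c("nuclear", "cytosolic")))
    return("markerLocalization values must be 'nuclear' or 'cytosolic'")
  TRUE
})

#' Construct a pipeline configuration
#'
#' All arguments default to the standard whole-slide processing parameters
#' (see [PipelineConfig-class]); pass only what you want to override.
#'
#' @param pixelSizeUm,expansionUm,backgroundWindowPx,backgroundDownsize
#'   geometry and background parameters.
#' @param isletMinAreaUm2,deformGridStepPx,roiSizePx,nRois,kmeansK,pcaVarFrac
#'   islet, registration and clustering parameters.
#' @param markerLocalization named per-marker localization flags.
#' @param positivityThresholds named per-marker threshold specs.
#' @param insulinChannel,glucagonChannel,isletThresholds,structRadiusPx
#'   islet-segmentation inputs.
#' @param randomSeed seed used by every stochastic stage.
#' @return A validated [PipelineConfig-class].
#' @examples
#' cfg <- pipelineConfig()                    # reference defaults
#' cfg2 <- pipelineConfig(kmeansK = 9)        # one override
#' expansionPx(cfg)                           # 4.5 um / 0.65 um -> 7 px
#' @export
pipelineConfig <- function(pixelSizeUm = 0.65,
                           expansionUm = 4.5,
                           backgroundWindowPx = 7L,
                           backgroundDownsize = 10L,
                           isletMinAreaUm2 = 400,
                           deformGridStepPx = 500,
                           roiSizePx = 2000L,
                           nRois = 11L,
                           kmeansK = 20L,
                           pcaVarFrac = 0.95,
                           markerLocalization = character(0),
                           positivityThresholds = list(),
                           insulinChannel = "INS",
                           glucagonChannel = "GCG",
                           isletThresholds = c(NA_real_, NA_real_),
                           structRadiusPx = 3L,
                           randomSeed = 1L) {
  obj <- new("PipelineConfig",
    pixelSizeUm = as.numeric(pixelSizeUm),
    expansionUm = as.numeric(expansionUm),
    backgroundWindowPx = as.integer(backgroundWindowPx),
    backgroundDownsize = as.integer(backgroundDownsize),
    isletMinAreaUm2 = as.numeric(isletMinAreaUm2),
    deformGridStepPx = as.numeric(deformGridStepPx),
    roiSizePx = as.integer(roiSizePx),
    nRois = as.integer(nRois),
    kmeansK = as.integer(kmeansK),
    pcaVarFrac = as.numeric(pcaVarFrac),
    markerLocalization = markerLocalization,
    positivityThresholds = positivityThresholds,
    insulinChannel = insulinChannel,
    glucagonChannel = glucagonChannel,
    isletThresholds = as.numeric(isletThresholds),
    structRadiusPx = as.integer(structRadiusPx),
    randomSeed = as.integer(randomSeed)
  )
  validObject(obj)
  obj
}

#' Cell expansion in whole pixels
#'
#' Rounds `expansionUm / pixelSizeUm` half-up; with the defaults,
#' 4.5 / 0.65 = 6.92 gives 7 pixels.
#'
#' @param config a [PipelineConfig-class].
#' @return integer number of pixels.
#' @export
expansionPx <- function(config) {
  as.integer(floor(config@expansionUm / config@pixelSizeUm + 0.5))
}

#' Minimum islet area in pixels
#'
#' `ceiling(isletMinAreaUm2 / pixelSizeUm^2)`; with the defaults,
#' 400 / 0.65² gives 947 pixels.
#'
#' @param config a [PipelineConfig-class].
#' @return integer pixel-area threshold.
#' @export
isletMinAreaPx <- function(config) {
  as.integer(ceiling(config@isletMinAreaUm2 / config@pixelSizeUm^2))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  cat(sprintf("  pixel size        %g um/px\n", object@pixelSizeUm))
  cat(sprintf("  cell expansion    %g um (%d px)\n", object@expansionUm,
              expansionPx(object)))
  cat(sprintf("  background        median %dx%d on %dx down-sized\n",
              object@backgroundWindowPx, object@backgroundWindowPx,
              object@backgroundDownsize))
  cat(sprintf("  islet min area    %g um2 (%d px)\n", object@isletMinAreaUm2,
              isletMinAreaPx(object)))
  cat(sprintf("  deform grid step  %g px\n", object@deformGridStepPx))
  cat(sprintf("  ROIs              %d x %d px\n", object@nRois, object@roiSizePx))
  cat(sprintf("  clustering        k = %d, PCA var frac = %g\n",
              object@kmeansK, object@pcaVarFrac))
  cat(sprintf("  seed              %d\n", object@randomSeed))
})

#' Read / write a pipeline configuration as YAML
#'
#' The file holds only overrides; missing keys keep their reference
#' defaults, so an empty file reproduces the standard parameters.
#'
#' @param path YAML file path.
#' @return `readPipelineConfig` returns a [PipelineConfig-class];
#'   `writePipelineConfig` returns `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$markerLocalization))
    vals$markerLocalization <- unlist(vals$markerLocalization)
  do.call(pipelineConfig, vals)
}

#' @rdname readPipelineConfig
#' @param config a [PipelineConfig-class] to serialise.
#' @export
writePipelineConfig <- function(config, path) {
  vals <- list(
    pixelSizeUm = config@pixelSizeUm,
    expansionUm = config@expansionUm,
    backgroundWindowPx = config@backgroundWindowPx,
    backgroundDownsize = config@backgroundDownsize,
    isletMinAreaUm2 = config@isletMinAreaUm2,
    deformGridStepPx = config@deformGridStepPx,
    roiSizePx = config@roiSizePx,
    nRois = config@nRois,
    kmeansK = config@kmeansK,
    pcaVarFrac = config@pcaVarFrac,
    markerLocalization = as.list(config@markerLocalization),
    positivityThresholds = config@positivityThresholds,
    insulinChannel = config@insulinChannel,
    glucagonChannel = config@glucagonChannel,
    isletThresholds = config@isletThresholds,
    structRadiusPx = config@structRadiusPx,
    randomSeed = config@randomSeed
  )
  yaml::write_yaml(vals, path)
  invisible(path)
}
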