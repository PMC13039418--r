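# TIFF input/output for multichannel images and label maps.
#
# Channels are stored one per TIFF page. Integer-valued channels up to 65535
# are stored as 16-bit (bit-exact round trip); anything else is stored as
# 32-bit float scaled into [0, 1] with the scale factor recorded in the
# metadata. Minimal OME-style XML (channel names, physical pixel size,
# nuclei-channel designation, storage mode and scale) travels in a companion
# file `<image>.ome.xml` next to the TIFF, in the spirit of OME companion
# metadata files.

omeDescription <- function(img, mode, scale) {
  d <- dim(img)
  ch <- paste(sprintf('      <Channel Name="%s"/>', channelNames(img)),
              collapse = "\n")
  sprintf(paste0(
    '<OME>\n  <Image ID="%s" Name="%s">\n',
    '    <Pixels PhysicalSizeX="%.10g" PhysicalSizeXUnit="µm" ',
    'PhysicalSizeY="%.10g" PhysicalSizeYUnit="µm" ',
    'SizeX="%d" SizeY="%d" SizeC="%d" Type="%s">\n%s\n    </Pixels>\n',
    '  </Image>\n  <StructuredAnnotations>\n',
    '    <XMLAnnotation ID="mplexquant"><Value>',
    '<mplexquant nucleiChannel="%s" scale="%.17g" mode="%s"/>',
    '</Value></XMLAnnotation>\n  </StructuredAnnotations>\n</OME>'),
    img@roundId, img@roundId, img@pixelSizeUm, img@pixelSizeUm,
    d[2], d[1], length(img@channels), mode, ch,
    img@nucleiChannel, scale, mode)
}

parseOmeDescription <- function(txt) {
  doc <- tryCatch(xml2::read_xml(txt), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  chn <- xml2::xml_find_all(doc, ".//Channel")
  ann <- xml2::xml_find_first(doc, ".//mplexquant")
  px <- xml2::xml_find_first(doc, ".//Pixels")
  list(
    channels = if (length(chn)) xml2::xml_attr(chn, "Name") else NULL,
    pixelSizeUm = if (!inherits(px, "xml_missing"))
      as.numeric(xml2::xml_attr(px, "PhysicalSizeX")) else NULL,
    roundId = {
      im <- xml2::xml_find_first(doc, ".//Image")
      if (!inherits(im, "xml_missing")) xml2::xml_attr(im, "ID") else NULL
    },
    nucleiChannel = if (!inherits(ann, "xml_missing"))
      xml2::xml_attr(ann, "nucleiChannel") else NULL,
    scale = if (!inherits(ann, "xml_missing"))
      as.numeric(xml2::xml_attr(ann, "scale")) else NULL,
    mode = if (!inherits(ann, "xml_missing"))
      xml2::xml_attr(ann, "mode") else NULL
  )
}

#' Write a MultiplexImage as a multi-page TIFF
#'
#' One page per channel, in channel order. Integer-valued images are stored
#' as 16-bit for a bit-exact round trip; other images as 32-bit float with a
#' recorded scale factor. Channel names, pixel size and the nuclei-channel
#' designation are written as minimal OME-style XML to a companion file
#' `<path>.ome.xml`, which [readMultiplexImage()] picks up automatically.
#'
#' @param img a [MultiplexImage-class].
#' @param path output file path (.tif / .ome.tif).
#' @return `path`, invisibly.
#' @seealso [readMultiplexImage()]
#' @export
writeMultiplexImage <- function(img, path) {
  stopifnot(is(img, "MultiplexImage"))
  validObject(img)
  vals <- unlist(lapply(img@channels, range))
  if (any(vals < 0)) stop("channel intensities must be non-negative")
  integerLike <- all(vapply(img@channels, function(m)
    all(m == floor(m)), logical(1))) && max(vals) <= 65535
  if (integerLike) {
    mode <- "uint16"
    scale <- 65535
    pages <- lapply(img@channels, function(m) m / 65535)
    bps <- 16L
  } else {
    mode <- "float32"
    scale <- max(vals, 1)
    pages <- lapply(img@channels, function(m) m / scale)
    bps <- 32L
  }
  tiff::writeTIFF(unname(pages), path, bits.per.sample = bps)
  writeLines(omeDescription(img, mode, scale), paste0(path, ".ome.xml"))
  invisible(path)
}

#' Read a multi-page TIFF as a MultiplexImage
#'
#' Metadata are taken from the embedded description written by
#' [writeMultiplexImage()] when present; explicit arguments override it.
#' For plain TIFFs (no embedded metadata) `channels` and `pixelSizeUm` must
#' be supplied.
#'
#' @param path TIFF file with one page per channel.
#' @param channels character vector of channel names, one per page.
#' @param pixelSizeUm physical pixel size in micrometres.
#' @param nucleiChannel nuclei channel name (default: first channel).
#' @param roundId round identifier.
#' @return A [MultiplexImage-class].
#' @export
readMultiplexImage <- function(path, channels = NULL, pixelSizeUm = NULL,
                               nucleiChannel = NULL, roundId = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  meta <- NULL
  sidecar <- paste0(path, ".ome.xml")
  if (file.exists(sidecar))
    meta <- parseOmeDescription(paste(readLines(sidecar), collapse = "\n"))
  if (is.null(channels)) channels <- meta$channels
  if (is.null(pixelSizeUm)) pixelSizeUm <- meta$pixelSizeUm
  if (is.null(nucleiChannel)) nucleiChannel <- meta$nucleiChannel
  if (is.null(roundId)) roundId <- if (!is.null(meta$roundId)) meta$roundId else "round1"
  if (is.null(channels))
    stop("channel names not found in file metadata; supply `channels`")
  if (is.null(pixelSizeUm))
    stop("pixel size not found in file metadata; supply `pixelSizeUm`")
  asIs <- is.null(meta$mode) || identical(meta$mode, "uint16")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = asIs)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channels))
    stop(sprintf("page/name count mismatch: %d pages, %d channel names",
                 length(pages), length(channels)))
  scale <- if (!asIs && !is.null(meta$scale)) meta$scale else 1
  mats <- lapply(pages, function(p) {
    m <- if (length(dim(p)) == 3) p[, , 1] else p
    m <- matrix(as.numeric(m), nrow(m), ncol(m))
    if (!asIs) m * scale else m
  })
  names(mats) <- channels
  if (is.null(nucleiChannel) || !nucleiChannel %in% channels)
    nucleiChannel <- channels[1]
  MultiplexImage(mats, pixelSizeUm = pixelSizeUm,
                 nucleiChannel = nucleiChannel, roundId = roundId)
}

#' Write an integer label map as a 16-bit TIFF (label 0 = background)
#'
#' @param labels integer matrix of non-negative labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLabelMap <- function(labels, path) {
  if (any(labels < 0) || any(labels != floor(labels)))
    stop("labels must be non-negative integers")
  if (max(labels) > 65535) stop("label values exceed 16-bit range")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an integer label map written by [writeLabelMap()]
#' @param path TIFF path.
#' @return integer matrix.
#' @export
readLabelMap <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}
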