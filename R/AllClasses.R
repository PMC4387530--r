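# S4 containers for the pipeline's central data objects.

#' WoundGeometry: the scratch-wound edge
#'
#' Represents the wound edge as a polyline in pixel coordinates together with
#' the side of the field that was denuded and the time of wounding.
#'
#' @slot edge numeric matrix with columns `x`, `y` (pixel coordinates, at
#'   least two vertices) tracing the wound edge.
#' @slot removedSide `"left"` or `"right"`: the side of the edge from which
#'   cells were removed.
#' @slot woundTime numeric, time of wounding in seconds from the start of the
#'   recording.
#' @export
setClass("WoundGeometry",
  representation(edge = "matrix", removedSide = "character",
                 woundTime = "numeric"))

setValidity("WoundGeometry", function(object) {
  msg <- character()
  e <- object@edge
  if (!is.numeric(e) || ncol(e) != 2L || nrow(e) < 2L || !all(is.finite(e)))
    msg <- c(msg, "edge must be a finite numeric matrix with >= 2 rows and columns (x, y)")
  if (length(object@removedSide) != 1L ||
      !object@removedSide %in% c("left", "right"))
    msg <- c(msg, "removedSide must be \"left\" or \"right\"")
  if (length(object@woundTime) != 1L || !is.finite(object@woundTime) ||
      object@woundTime < 0)
    msg <- c(msg, "woundTime must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' Construct a WoundGeometry
#'
#' @param edge two-column numeric matrix of `(x, y)` polyline vertices in
#'   pixels.
#' @param removedSide `"left"` or `"right"`.
#' @param woundTime time of wounding in seconds.
#' @return A [WoundGeometry-class] object.
#' @examples
#' woundGeometry(cbind(x = c(64, 64), y = c(0, 512)), "left", 60)
#' @export
woundGeometry <- function(edge, removedSide = c("left", "right"),
                          woundTime = 0) {
  removedSide <- match.arg(removedSide)
  edge <- as.matrix(edge)
  colnames(edge) <- c("x", "y")
  new("WoundGeometry", edge = edge, removedSide = removedSide,
      woundTime = as.numeric(woundTime))
}

#' CellLayout: ground-truth cell positions and transient parameters
#'
#' A synthetic monolayer: cell centroids, radii, per-cell transient
#' parameters and true class labels, plus optional wound geometry. This is
#' the ground truth against which segmentation and classification are scored.
#'
#' @slot fieldSize integer vector `(height, width)` in pixels.
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot cells data.frame with one row per cell: `id`, `x_px`, `y_px`,
#'   `radius_px`, `brightness`, `secondary_class`, `primary_class`,
#'   `region` (`"proximal"`, `"distal"` or `NA`), `distance_um`, and a
#'   list-column `params` of [transientParams()] objects.
#' @slot wound a [WoundGeometry-class] or `NULL`.
#' @slot protocol `"ATP"` or `"wound"`.
#' @export
setClass("CellLayout",
  representation(fieldSize = "integer", pixelSize = "numeric",
                 cells = "data.frame", wound = "ANY", protocol = "character"))

setValidity("CellLayout", function(object) {
  msg <- character()
  fs <- object@fieldSize
  if (length(fs) != 2L || any(fs < 1L)) {
    msg <- c(msg, "fieldSize must be two positive integers (height, width)")
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  cells <- object@cells
  need <- c("id", "x_px", "y_px", "radius_px")
  if (!all(need %in% names(cells)))
    msg <- c(msg, "cells must have columns id, x_px, y_px, radius_px")
  if (nrow(cells) < 1L) msg <- c(msg, "layout must contain at least one cell")
  if (all(need %in% names(cells)) && nrow(cells) >= 1L && length(fs) == 2L) {
    if (any(cells$radius_px <= 0)) msg <- c(msg, "cell radii must be positive")
    if (any(cells$x_px < 1 | cells$x_px > fs[2L] |
            cells$y_px < 1 | cells$y_px > fs[1L]))
      msg <- c(msg, "cell centroids must lie inside the field")
  }
  if (!is.null(object@wound) && !is(object@wound, "WoundGeometry"))
    msg <- c(msg, "wound must be NULL or a WoundGeometry")
  if (!object@protocol %in% c("ATP", "wound"))
    msg <- c(msg, "protocol must be \"ATP\" or \"wound\"")
  if (length(msg)) msg else TRUE
})

#' ImageSequence: a two-channel ratiometric time-lapse stack
#'
#' Holds the red (calcium-decreasing dye) and green (calcium-increasing dye)
#' fluorescence stacks with acquisition metadata. Arrays are indexed
#' `[row, column, frame]` in arbitrary intensity units.
#'
#' @slot red,green numeric arrays `[H x W x T]`, nonnegative, same shape.
#' @slot frameInterval numeric, seconds between frames (> 0).
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot stimulusTime numeric, stimulus (agonist arrival or wounding) time in
#'   seconds from the start of the recording.
#' @slot metadata list; synthetic renders store the generating
#'   [CellLayout-class] under `$layout`.
#' @export
setClass("ImageSequence",
  representation(red = "array", green = "array", frameInterval = "numeric",
                 pixelSize = "numeric", stimulusTime = "numeric",
                 metadata = "list"))

setValidity("ImageSequence", function(object) {
  msg <- character()
  if (!identical(dim(object@red), dim(object@green)))
    msg <- c(msg, "red and green stacks must have identical dimensions")
  if (length(dim(object@red)) != 3L)
    msg <- c(msg, "stacks must be 3-d arrays [H x W x T]")
  if (min(object@red, 0) < 0 || min(object@green, 0) < 0)
    msg <- c(msg, "intensities must be nonnegative")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(object@stimulusTime) != 1L || object@stimulusTime < 0)
    msg <- c(msg, "stimulusTime must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' ROIMap: a labelled segmentation mask
#'
#' Output of [extractROIs()]: an integer label image (0 = background) plus a
#' table of per-ROI seed coordinates, pixel counts and centroids, with ids in
#' discovery order.
#'
#' @slot labels integer matrix `[H x W]`; 0 is background, positive values
#'   are ROI ids.
#' @slot rois data.frame with columns `id`, `seed_x`, `seed_y`,
#'   `seed_intensity`, `area_px`, `centroid_x`, `centroid_y`.
#' @slot rejected data.frame of size-rejected candidate regions (`seed_x`,
#'   `seed_y`, `area_px`, `reason`).
#' @slot params the [segmentationParams()] list used for extraction.
#' @export
setClass("ROIMap",
  representation(labels = "matrix", rois = "data.frame",
                 rejected = "data.frame", params = "list"))

setValidity("ROIMap", function(object) {
  msg <- character()
  lab <- object@labels
  if (!is.numeric(lab) || any(lab < 0))
    msg <- c(msg, "labels must be a nonnegative integer matrix")
  ids <- object@rois$id
  if (length(ids) && anyDuplicated(ids))
    msg <- c(msg, "ROI ids must be unique")
  present <- unique(as.integer(lab[lab > 0]))
  if (length(setdiff(present, ids)))
    msg <- c(msg, "label image contains ids missing from the ROI table")
  if (length(msg)) msg else TRUE
})

## ---- accessors -------------------------------------------------------------

#' @describeIn ImageSequence-class red-channel stack `[H x W x T]`.
#' @param x an object.
#' @export
setGeneric("redChannel", function(x) standardGeneric("redChannel"))
#' @describeIn ImageSequence-class green-channel stack.
#' @export
setGeneric("greenChannel", function(x) standardGeneric("greenChannel"))
#' @describeIn ImageSequence-class frame interval in seconds.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @describeIn ImageSequence-class pixel size in micrometres.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @describeIn ImageSequence-class stimulus time in seconds.
#' @export
setGeneric("stimulusTime", function(x) standardGeneric("stimulusTime"))
#' @describeIn ROIMap-class integer label image.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @describeIn ROIMap-class per-ROI table.
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))
#' @describeIn ROIMap-class number of accepted ROIs.
#' @export
setGeneric("nROIs", function(x) standardGeneric("nROIs"))
#' @describeIn CellLayout-class per-cell ground-truth table.
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))
#' @describeIn CellLayout-class wound geometry (or `NULL`).
#' @export
setGeneric("woundGeom", function(x) standardGeneric("woundGeom"))

setMethod("redChannel", "ImageSequence", function(x) x@red)
setMethod("greenChannel", "ImageSequence", function(x) x@green)
setMethod("frameInterval", "ImageSequence", function(x) x@frameInterval)
setMethod("pixelSize", "ImageSequence", function(x) x@pixelSize)
setMethod("pixelSize", "CellLayout", function(x) x@pixelSize)
setMethod("stimulusTime", "ImageSequence", function(x) x@stimulusTime)
setMethod("labelMatrix", "ROIMap", function(x) x@labels)
setMethod("roiTable", "ROIMap", function(x) x@rois)
setMethod("nROIs", "ROIMap", function(x) nrow(x@rois))
setMethod("cellTable", "CellLayout", function(x) x@cells)
setMethod("woundGeom", "CellLayout", function(x) x@wound)

setMethod("show", "ImageSequence", function(object) {
  d <- dim(object@red)
  cat(sprintf(
    "ImageSequence: %d x %d px, %d frames @ %.3g s, %.3g um/px, stimulus %.3g s\n",
    d[1], d[2], d[3], object@frameInterval, object@pixelSize,
    object@stimulusTime))
  if (!is.null(object@metadata$layout))
    cat("  synthetic render with embedded ground-truth layout\n")
  invisible(NULL)
})

setMethod("show", "ROIMap", function(object) {
  cat(sprintf("ROIMap: %d ROIs on a %d x %d field (%d size-rejected)\n",
              nrow(object@rois), nrow(object@labels), ncol(object@labels),
              nrow(object@rejected)))
  invisible(NULL)
})

setMethod("show", "CellLayout", function(object) {
  cat(sprintf("CellLayout: %d cells, %d x %d px @ %.3g um/px, protocol %s%s\n",
              nrow(object@cells), object@fieldSize[1], object@fieldSize[2],
              object@pixelSize, object@protocol,
              if (!is.null(object@wound)) ", wounded" else ""))
  invisible(NULL)
})

setMethod("show", "WoundGeometry", function(object) {
  cat(sprintf("WoundGeometry: %d-vertex edge, removed side %s, t = %.3g s\n",
              nrow(object@edge), object@removedSide, object@woundTime))
  invisible(NULL)
})
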