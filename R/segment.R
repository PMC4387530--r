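# Cell segmentation: pre-processing, iterative seeded ROI extraction with
# halo stripping, programmatic review, and scoring against ground truth.

#' Segmentation parameters
#'
#' @param blur_sigma_px Gaussian blur s.d. (px).
#' @param mask_threshold global mask level as a fraction of the normalized
#'   [0, 1] range; pixels below it are zeroed, and ROI extraction stops when
#'   the residual maximum falls below it.
#' @param localmean_window_px side of the square neighbourhood (px, odd) used
#'   for the local-mean suppression that sharpens cell borders.
#' @param localmean_fraction pixels dimmer than this fraction of their local
#'   mean are zeroed.
#' @param roi_threshold_fraction adaptive region-growing level: ROI pixels
#'   must be at least this fraction of their seed's intensity.
#' @param halo_threshold_fraction lower level defining the halo that is
#'   stripped around each ROI (must be below `roi_threshold_fraction`).
#' @param max_radius_px every ROI pixel must lie within this Euclidean radius
#'   of its seed.
#' @param min_size_px,max_size_px accepted ROI area bounds (px).
#' @param max_roi_count stop after this many accepted ROIs.
#' @return list of class `"SegmentationParams"`.
#' @examples
#' segmentationParams(max_radius_px = 20)
#' @export
segmentationParams <- function(blur_sigma_px = 2, mask_threshold = 0.05,
                               localmean_window_px = 25,
                               localmean_fraction = 0.7,
                               roi_threshold_fraction = 0.5,
                               halo_threshold_fraction = 0.3,
                               max_radius_px = 30, min_size_px = 50,
                               max_size_px = 2000, max_roi_count = 1000L) {
  if (!(halo_threshold_fraction > 0 &&
        halo_threshold_fraction < roi_threshold_fraction &&
        roi_threshold_fraction <= 1))
    stop("need 0 < halo_threshold_fraction < roi_threshold_fraction <= 1")
  if (!(min_size_px < max_size_px)) stop("min_size_px must be < max_size_px")
  if (max_radius_px <= 0) stop("max_radius_px must be positive")
  p <- list(blur_sigma_px = blur_sigma_px, mask_threshold = mask_threshold,
            localmean_window_px = as.integer(localmean_window_px),
            localmean_fraction = localmean_fraction,
            roi_threshold_fraction = roi_threshold_fraction,
            halo_threshold_fraction = halo_threshold_fraction,
            max_radius_px = max_radius_px, min_size_px = min_size_px,
            max_size_px = max_size_px, max_roi_count = as.integer(max_roi_count))
  class(p) <- "SegmentationParams"
  p
}

#' Combine red and green frames into one normalized image
#'
#' Sums the supplied frames of both channels and min-max normalizes the
#' result to [0, 1]. A constant sum (no dynamic range) maps to all zeros.
#' Typically called with the first and last frames of each channel so that
#' both early- and late-responding cells are bright.
#'
#' @param red_frames,green_frames a matrix, a list of matrices, or an
#'   `[H x W x k]` array of selected frames per channel.
#' @return numeric matrix in [0, 1].
#' @examples
#' combineChannels(matrix(0:3, 2), matrix(0, 2, 2))
#' @export
combineChannels <- function(red_frames, green_frames) {
  toList <- function(x) {
    if (is.list(x)) x
    else if (is.matrix(x)) list(x)
    else if (length(dim(x)) == 3L)
      lapply(seq_len(dim(x)[3L]), function(k) x[, , k])
    else stop("frames must be a matrix, list of matrices, or 3-d array")
  }
  frames <- c(toList(red_frames), toList(green_frames))
  if (length(frames) == 0L) stop("empty frame selection")
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("all frames must have identical dimensions")
  s <- Reduce(`+`, frames)
  rng <- range(s)
  if (rng[2L] - rng[1L] <= 0) return(matrix(0, d[1L], d[2L]))
  (s - rng[1L]) / (rng[2L] - rng[1L])
}

# Gaussian blur with a kernel clipped to the image size (small test images).
.blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  size <- 2L * ceiling(3 * sigma) + 1L
  size <- min(size, 2L * (min(dim(img)) %/% 2L) - 1L)
  if (size < 3L) return(img)
  EBImage::filter2(img, EBImage::makeBrush(size, shape = "Gaussian",
                                           sigma = sigma))
}

#' Pre-process a combined image for ROI extraction
#'
#' Gaussian blur, then global masking (pixels below `mask_threshold` zeroed),
#' then local-mean suppression: pixels dimmer than `localmean_fraction`
#' times the mean of their `localmean_window_px` square neighbourhood are
#' zeroed, carving dark borders between adjacent cells.
#'
#' @param img numeric matrix in [0, 1] (from [combineChannels()]).
#' @param params a [segmentationParams()] list.
#' @return numeric matrix in [0, 1].
#' @export
preprocessImage <- function(img, params = segmentationParams()) {
  stopifnot(is.matrix(img))
  if (params$localmean_window_px > min(dim(img)))
    stop("localmean window is larger than the image")
  out <- .blur(img, params$blur_sigma_px)
  out[out < params$mask_threshold] <- 0
  w <- params$localmean_window_px
  if (w %% 2L == 0L) w <- w + 1L
  localmean <- EBImage::filter2(out, matrix(1 / w^2, w, w))
  out[out < params$localmean_fraction * localmean] <- 0
  .clip(out, 0, 1)
}

# 8-connected region of pixels >= level, grown from the seed, restricted to
# a Euclidean radius around it. Operates on a window around the seed for
# speed; returns linear indices into the full image.
.growRegion <- function(img, seed_r, seed_c, level, max_radius) {
  H <- nrow(img); W <- ncol(img)
  r0 <- max(1L, seed_r - ceiling(max_radius))
  r1 <- min(H, seed_r + ceiling(max_radius))
  c0 <- max(1L, seed_c - ceiling(max_radius))
  c1 <- min(W, seed_c + ceiling(max_radius))
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  sub <- img[r0:r1, c0:c1, drop = FALSE]
  rr <- (r0:r1) - seed_r; cc <- (c0:c1) - seed_c
  within <- outer(rr^2, cc^2, "+") <= max_radius^2
  eligible <- sub >= level & within
  seen <- matrix(FALSE, nr, nc)
  sr <- seed_r - r0 + 1L; sc <- seed_c - c0 + 1L
  queue <- integer(nr * nc)
  queue[1L] <- (sc - 1L) * nr + sr
  seen[queue[1L]] <- TRUE
  qhead <- 1L; qtail <- 1L
  while (qhead <= qtail) {
    cur <- queue[qhead]; qhead <- qhead + 1L
    cr <- ((cur - 1L) %% nr) + 1L
    ccol <- ((cur - 1L) %/% nr) + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nr2 <- cr + dr; nc2 <- ccol + dc
      if (nr2 < 1L || nr2 > nr || nc2 < 1L || nc2 > nc) next
      ni <- (nc2 - 1L) * nr + nr2
      if (!seen[ni] && eligible[ni]) {
        seen[ni] <- TRUE
        qtail <- qtail + 1L
        queue[qtail] <- ni
      }
    }
  }
  got <- queue[seq_len(qtail)]
  gr <- ((got - 1L) %% nr) + r0
  gc <- ((got - 1L) %/% nr) + c0
  (gc - 1L) * H + gr
}

#' Extract ROIs by iterative seeded region growing with halo stripping
#'
#' Repeatedly: (1) take the brightest remaining pixel as a seed (ties broken
#' by lowest row, then column); (2) grow the 8-connected region at or above
#' `roi_threshold_fraction` of the seed intensity, within `max_radius_px` of
#' the seed — the candidate ROI; (3) grow the same region at the lower
#' `halo_threshold_fraction` — its surplus over the ROI is the halo;
#' (4) zero ROI and halo in the working image; (5) accept the ROI if its
#' area lies in `[min_size_px, max_size_px]`, else record a rejection.
#' Stops when `max_roi_count` ROIs are accepted or the residual maximum
#' falls below `mask_threshold`.
#'
#' @param img prepared image from [preprocessImage()] (nonnegative matrix).
#' @param params a [segmentationParams()] list.
#' @return An [ROIMap-class]; ids are assigned in discovery order.
#' @export
extractROIs <- function(img, params = segmentationParams()) {
  stopifnot(is.matrix(img), min(img) >= 0)
  H <- nrow(img); W <- ncol(img)
  work <- img
  labels <- matrix(0L, H, W)
  rois <- list()
  rejected <- list()
  nid <- 0L
  repeat {
    if (nid >= params$max_roi_count) break
    mx <- max(work)
    if (mx < params$mask_threshold || mx <= 0) break
    cand <- which(work == mx)
    if (length(cand) > 1L) {
      # deterministic tie-break: lowest row, then lowest column
      cr <- ((cand - 1L) %% H) + 1L
      cc <- ((cand - 1L) %/% H) + 1L
      cand <- cand[order(cr, cc)][1L]
    }
    seed_r <- ((cand - 1L) %% H) + 1L
    seed_c <- ((cand - 1L) %/% H) + 1L
    roi <- .growRegion(work, seed_r, seed_c,
                       params$roi_threshold_fraction * mx,
                       params$max_radius_px)
    halo <- .growRegion(work, seed_r, seed_c,
                        params$halo_threshold_fraction * mx,
                        params$max_radius_px)
    work[halo] <- 0
    work[roi] <- 0
    area <- length(roi)
    if (area >= params$min_size_px && area <= params$max_size_px) {
      nid <- nid + 1L
      labels[roi] <- nid
      rr <- ((roi - 1L) %% H) + 1L
      rc <- ((roi - 1L) %/% H) + 1L
      rois[[nid]] <- data.frame(id = nid, seed_x = seed_c, seed_y = seed_r,
                                seed_intensity = mx, area_px = area,
                                centroid_x = mean(rc), centroid_y = mean(rr))
    } else {
      rejected[[length(rejected) + 1L]] <-
        data.frame(seed_x = seed_c, seed_y = seed_r, area_px = area,
                   reason = if (area < params$min_size_px) "too_small"
                            else "too_large")
    }
  }
  emptyRoi <- data.frame(id = integer(), seed_x = integer(),
                         seed_y = integer(), seed_intensity = numeric(),
                         area_px = integer(), centroid_x = numeric(),
                         centroid_y = numeric())
  emptyRej <- data.frame(seed_x = integer(), seed_y = integer(),
                         area_px = integer(), reason = character())
  new("ROIMap", labels = labels,
      rois = if (length(rois)) do.call(rbind, rois) else emptyRoi,
      rejected = if (length(rejected)) do.call(rbind, rejected) else emptyRej,
      params = unclass(params))
}

#' Remove ROIs from a map (programmatic review)
#'
#' Stand-in for interactive ROI checking: deletes the listed ROI ids; the
#' remaining ROIs keep their ids and label values. An empty rejection list
#' returns the map unchanged.
#'
#' @param roimap an [ROIMap-class].
#' @param rejections integer vector of ROI ids to delete.
#' @return The pruned [ROIMap-class].
#' @export
reviewROIs <- function(roimap, rejections = integer()) {
  stopifnot(is(roimap, "ROIMap"))
  if (length(rejections) == 0L) return(roimap)
  rejections <- as.integer(rejections)
  unknown <- setdiff(rejections, roimap@rois$id)
  if (length(unknown))
    stop("unknown ROI id(s): ", paste(unknown, collapse = ", "))
  lab <- roimap@labels
  lab[lab %in% rejections] <- 0L
  new("ROIMap", labels = lab,
      rois = roimap@rois[!roimap@rois$id %in% rejections, , drop = FALSE],
      rejected = roimap@rejected, params = roimap@params)
}

#' Score a segmentation against the ground-truth layout
#'
#' Greedy one-to-one matching of ROI centroids to true cell centroids:
#' candidate pairs within `match_radius_px` are matched in order of
#' increasing distance, each centroid used at most once.
#'
#' @param roimap an [ROIMap-class].
#' @param layout the generating [CellLayout-class].
#' @param match_radius_px maximum centroid distance for a match (px).
#' @return list with `recall` (matched / true cells), `precision`
#'   (matched / detected), `rmse_px` (centroid RMSE over matches), and
#'   `n_matched`.
#' @export
scoreSegmentation <- function(roimap, layout, match_radius_px = 5) {
  stopifnot(is(roimap, "ROIMap"), is(layout, "CellLayout"))
  det <- roimap@rois
  tru <- layout@cells
  nDet <- nrow(det); nTrue <- nrow(tru)
  if (nDet == 0L || nTrue == 0L)
    return(list(recall = 0, precision = if (nDet == 0L) NA_real_ else 0,
                rmse_px = NA_real_, n_matched = 0L))
  dmat <- sqrt(outer(det$centroid_x, tru$x_px, "-")^2 +
               outer(det$centroid_y, tru$y_px, "-")^2)
  pairs <- which(dmat <= match_radius_px, arr.ind = TRUE)
  ord <- order(dmat[pairs])
  usedDet <- logical(nDet); usedTrue <- logical(nTrue)
  dists <- numeric()
  for (k in ord) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (!usedDet[i] && !usedTrue[j]) {
      usedDet[i] <- TRUE; usedTrue[j] <- TRUE
      dists <- c(dists, dmat[i, j])
    }
  }
  m <- length(dists)
  list(recall = m / nTrue, precision = m / nDet,
       rmse_px = if (m) sqrt(mean(dists^2)) else NA_real_,
       n_matched = m)
}
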