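# Rendering a layout into a two-channel image sequence.

#' Imaging model parameters for the synthetic renderer
#'
#' @param background background intensity (a.u.) added to both channels.
#' @param intensity nominal per-cell dye intensity scale (a.u.).
#' @param noise_floor additive Gaussian read-noise s.d. (a.u.).
#' @param shot_coef shot-noise coefficient: the per-pixel noise s.d. is
#'   `noise_floor + shot_coef * sqrt(signal)`.
#' @param dye_polarity `"green-up"` (default: the green dye brightens and the
#'   red dye dims with calcium; the reported ratio is green/red) or
#'   `"red-up"` for the opposite labelling. Either way the ratio of the
#'   increasing over the decreasing channel is monotone in calcium.
#' @param max_overlap_frac warn if a larger fraction of cell footprint pixels
#'   is shared between cells.
#' @return list of class `"ImagingParams"`.
#' @examples
#' imagingParams(noise_floor = 0)
#' @export
imagingParams <- function(background = 0.08, intensity = 1,
                          noise_floor = 0.02, shot_coef = 0.01,
                          dye_polarity = c("green-up", "red-up"),
                          max_overlap_frac = 0.25) {
  dye_polarity <- match.arg(dye_polarity)
  p <- list(background = background, intensity = intensity,
            noise_floor = noise_floor, shot_coef = shot_coef,
            dye_polarity = dye_polarity, max_overlap_frac = max_overlap_frac)
  class(p) <- "ImagingParams"
  p
}

# Soft-edged disc profile: flat core to 70% of the radius, cosine rolloff to
# zero at the radius. Returns footprint pixel indices and weights.
.discFootprint <- function(x, y, r, H, W) {
  x0 <- max(1L, floor(x - r)); x1 <- min(W, ceiling(x + r))
  y0 <- max(1L, floor(y - r)); y1 <- min(H, ceiling(y + r))
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - y)^2, (xs - x)^2, "+"))
  wgt <- matrix(0, nrow = length(ys), ncol = length(xs))
  core <- d <= 0.7 * r
  edge <- d > 0.7 * r & d <= r
  wgt[core] <- 1
  wgt[edge] <- 0.5 * (1 + cos(pi * (d[edge] - 0.7 * r) / (0.3 * r)))
  keep <- wgt > 0
  idx <- outer(ys, (xs - 1L) * H, "+")      # linear indices into H x W frame
  list(idx = as.integer(idx[keep]), w = wgt[keep])
}

#' Render a cell layout into a two-channel time-lapse stack
#'
#' Each cell is drawn as a soft-edged disc whose two dye channels respond
#' reciprocally to its calcium transient: with calcium elevation `c(t)`
#' (trace value above baseline), the increasing channel scales with
#' `sqrt(1 + c)` and the decreasing channel with `1 / sqrt(1 + c)`, so their
#' ratio equals `1 + c` exactly and per-cell brightness cancels. Background
#' and read/shot noise are then added.
#'
#' @param layout a [CellLayout-class].
#' @param frameInterval_s seconds per frame.
#' @param duration_s recording length in seconds (>= 2 frames).
#' @param imaging an [imagingParams()] list.
#' @param stimulusTime stimulus time (s); defaults to the layout's wound time
#'   or 60 s.
#' @param seed integer seed (cell trace noise and pixel noise).
#' @return An [ImageSequence-class]; the generating layout is kept in
#'   `@metadata$layout`.
#' @examples
#' lay <- makeMonolayerLayout(c(96, 96), nCells = 4, seed = 1)
#' seq <- renderSequence(lay, frameInterval_s = 5, duration_s = 20, seed = 1)
#' dim(redChannel(seq))
#' @export
renderSequence <- function(layout, frameInterval_s = 1, duration_s = 2160,
                           imaging = imagingParams(), stimulusTime = NULL,
                           seed = NULL) {
  stopifnot(is(layout, "CellLayout"))
  if (duration_s < 2 * frameInterval_s)
    stop("duration_s must cover at least two frames")
  if (is.null(stimulusTime))
    stimulusTime <- if (!is.null(layout@wound)) layout@wound@woundTime else 60
  H <- layout@fieldSize[1L]; W <- layout@fieldSize[2L]
  times <- seq(0, duration_s, by = frameInterval_s)
  Tn <- length(times)
  cells <- layout@cells

  .withSeed(seed, {
    green <- array(0, dim = c(H, W, Tn))
    red <- array(0, dim = c(H, W, Tn))
    HW <- H * W
    overlapHits <- 0; footPx <- 0
    covered <- matrix(FALSE, H, W)
    for (i in seq_len(nrow(cells))) {
      fp <- .discFootprint(cells$x_px[i], cells$y_px[i], cells$radius_px[i],
                           H, W)
      overlapHits <- overlapHits + sum(covered[fp$idx])
      covered[fp$idx] <- TRUE
      footPx <- footPx + length(fp$idx)
      tr <- makeTransient(cells$params[[i]], times,
                          stimulusTime = stimulusTime)
      ca <- pmax(0, tr$value - cells$params[[i]]$baseline)
      amp <- imaging$intensity * cells$brightness[i]
      up <- amp * sqrt(1 + ca)       # increasing dye
      dn <- amp / sqrt(1 + ca)       # decreasing dye
      flat <- rep(fp$idx, Tn) + rep((seq_len(Tn) - 1L) * HW,
                                    each = length(fp$idx))
      green[flat] <- green[flat] + fp$w %o% up
      red[flat] <- red[flat] + fp$w %o% dn
    }
    if (footPx > 0 && overlapHits / footPx > imaging$max_overlap_frac)
      warning(sprintf("overlapping-cell fraction %.2f exceeds limit %.2f",
                      overlapHits / footPx, imaging$max_overlap_frac))
    if (imaging$dye_polarity == "red-up") {
      tmp <- green; green <- red; red <- tmp
    }
    for (ch in c("green", "red")) {
      a <- get(ch) + imaging$background
      if (imaging$noise_floor > 0 || imaging$shot_coef > 0)
        a <- a + rnorm(length(a),
                       sd = imaging$noise_floor +
                         imaging$shot_coef * sqrt(pmax(a, 0)))
      assign(ch, pmax(a, 0))
    }
    new("ImageSequence", red = red, green = green,
        frameInterval = frameInterval_s, pixelSize = layout@pixelSize,
        stimulusTime = stimulusTime,
        metadata = list(layout = layout, imaging = imaging))
  })
}
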