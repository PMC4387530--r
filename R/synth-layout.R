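# Ground-truth monolayer layouts.

# Jittered hexagonal-ish packing: grid spacing from the target density, with
# uniform centre jitter and lognormal radius variation. Confluent epithelial
# monolayers are near-packed, so cells sit on a perturbed lattice rather
# than a Poisson point process.
.packCells <- function(fieldSize, spacing_px, jitter_frac = 0.12,
                       radius_frac = c(0.34, 0.42)) {
  H <- fieldSize[1L]; W <- fieldSize[2L]
  nx <- max(1L, round(W / spacing_px))
  ny <- max(1L, round(H / spacing_px))
  sx <- W / nx; sy <- H / ny
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  x <- (g$ix - 0.5) * sx + runif(nrow(g), -jitter_frac, jitter_frac) * sx
  y <- (g$iy - 0.5) * sy + runif(nrow(g), -jitter_frac, jitter_frac) * sy
  r <- runif(nrow(g), radius_frac[1L], radius_frac[2L]) * min(sx, sy)
  data.frame(x_px = .clip(x, 1, W), y_px = .clip(y, 1, H), radius_px = r)
}

#' Synthetic confluent monolayer for the agonist protocol
#'
#' Lays out approximately `nCells` cells on a jittered lattice spanning the
#' field, draws each cell's secondary class from `mixture` and its transient
#' parameters from the built-in priors, and assigns a lognormal per-cell
#' brightness (uneven dye loading; the ratiometric readout cancels it).
#'
#' @param fieldSize integer `(height, width)` in pixels.
#' @param pixelSize um per pixel.
#' @param nCells target cell count (the lattice rounds it slightly).
#' @param mixture named class mixture; defaults to the pooled agonist-protocol
#'   mixture [atpClassMixture()].
#' @param noise_sd trace noise passed to the priors.
#' @param brightness_sd s.d. of the lognormal per-cell brightness (mean 1).
#' @param seed integer seed.
#' @return A [CellLayout-class].
#' @examples
#' makeMonolayerLayout(c(128, 128), nCells = 9, seed = 1)
#' @export
makeMonolayerLayout <- function(fieldSize = c(512L, 512L), pixelSize = 0.65,
                                nCells = 120, mixture = atpClassMixture(),
                                noise_sd = 0.05, brightness_sd = 0.25,
                                seed = NULL) {
  fieldSize <- as.integer(fieldSize)
  if (nCells < 1) stop("nCells must be >= 1")
  .withSeed(seed, {
    spacing <- sqrt(prod(fieldSize) / nCells)
    cells <- .packCells(fieldSize, spacing)
    n <- nrow(cells)
    cls <- sample(names(mixture), n, replace = TRUE, prob = mixture)
    params <- lapply(cls, sampleClassParams, protocol = "ATP",
                     noise_sd = noise_sd)
    cells$id <- seq_len(n)
    cells$brightness <- .rlnormM(n, 1, brightness_sd)
    cells$secondary_class <- cls
    cells$primary_class <- primaryClass(cls, "ATP")
    cells$region <- NA_character_
    cells$distance_um <- NA_real_
    cells$params <- params
    new("CellLayout", fieldSize = fieldSize, pixelSize = pixelSize,
        cells = cells, wound = NULL, protocol = "ATP")
  })
}

#' Synthetic wounded monolayer
#'
#' Packs cells over the whole field, removes those inside the scratch strip,
#' and assigns each survivor transient parameters from the distance-dependent
#' response model: cells closer than `model$threshold_um` to the wound edge
#' draw from the proximal class mixture and amplitude moments, the rest from
#' the distal ones.
#'
#' @param fieldSize integer `(height, width)` in pixels.
#' @param pixelSize um per pixel.
#' @param density cells per mm^2 before wounding.
#' @param woundStripWidth_px width of the removed strip (left edge of the
#'   field), in pixels; must be positive and narrower than the field.
#' @param model a [woundResponseModel()].
#' @param woundTime wounding time (s from recording start).
#' @param noise_sd,brightness_sd,seed as in [makeMonolayerLayout()].
#' @return A [CellLayout-class] with a [WoundGeometry-class] attached;
#'   `cellTable()` carries per-cell `distance_um` and `region`.
#' @examples
#' makeWoundLayout(c(256, 256), woundStripWidth_px = 32, seed = 1)
#' @export
makeWoundLayout <- function(fieldSize = c(512L, 512L), pixelSize = 0.65,
                            density = 2600, woundStripWidth_px = 64,
                            model = woundResponseModel(), woundTime = 60,
                            noise_sd = 0.05, brightness_sd = 0.25,
                            seed = NULL) {
  fieldSize <- as.integer(fieldSize)
  if (woundStripWidth_px <= 0)
    stop("woundStripWidth_px must be positive (a zero-width wound is degenerate)")
  if (woundStripWidth_px >= fieldSize[2L])
    stop("wound strip must lie inside the field")
  .withSeed(seed, {
    px_per_mm <- 1000 / pixelSize
    area_px_per_cell <- px_per_mm^2 / density
    cells <- .packCells(fieldSize, sqrt(area_px_per_cell))
    keep <- cells$x_px > woundStripWidth_px
    if (!any(keep)) stop("density and strip width leave no surviving cells")
    cells <- cells[keep, , drop = FALSE]
    n <- nrow(cells)
    wound <- woundGeometry(
      cbind(x = c(woundStripWidth_px, woundStripWidth_px),
            y = c(0, fieldSize[1L])),
      removedSide = "left", woundTime = woundTime)
    dist_um <- (cells$x_px - woundStripWidth_px) * pixelSize
    region <- ifelse(dist_um < model$threshold_um, "proximal", "distal")
    cls <- character(n)
    params <- vector("list", n)
    for (i in seq_len(n)) {
      mx <- model[[region[i]]]$mixture
      cls[i] <- sample(names(mx), 1L, prob = mx)
      params[[i]] <- sampleClassParams(cls[i], "wound", region = region[i],
                                       model = model, noise_sd = noise_sd)
    }
    cells$id <- seq_len(n)
    cells$brightness <- .rlnormM(n, 1, brightness_sd)
    cells$secondary_class <- cls
    cells$primary_class <- primaryClass(cls, "wound")
    cells$region <- region
    cells$distance_um <- dist_um
    cells$params <- params
    new("CellLayout", fieldSize = fieldSize, pixelSize = pixelSize,
        cells = cells, wound = wound, protocol = "wound")
  })
}

#' Trace-level wound population with known proximal/distal sizes
#'
#' Convenience generator for statistical validation: draws exactly
#' `nProximal` and `nDistal` cells with distances uniform inside each band
#' and parameters from the distance-dependent model, without rendering
#' images.
#'
#' @param nProximal,nDistal group sizes.
#' @param model a [woundResponseModel()].
#' @param maxDistance_um largest distal distance generated (um).
#' @param duration_s,dt_s,stimulusTime,noise_sd,seed as in
#'   [makePopulation()].
#' @return list as [makePopulation()] plus `distance_um` and `region`
#'   columns in `$truth`.
#' @examples
#' pop <- makeWoundPopulation(5, 10, seed = 1, dt_s = 2)
#' table(pop$truth$region)
#' @export
makeWoundPopulation <- function(nProximal = 76, nDistal = 178,
                                model = woundResponseModel(),
                                maxDistance_um = 400, duration_s = 2760,
                                dt_s = 1, stimulusTime = 60, noise_sd = 0.05,
                                seed = NULL) {
  .withSeed(seed, {
    thr <- model$threshold_um
    region <- c(rep("proximal", nProximal), rep("distal", nDistal))
    dist_um <- c(runif(nProximal, 5, thr - 5),
                 runif(nDistal, thr + 5, maxDistance_um))
    n <- length(region)
    times <- seq(0, duration_s, by = dt_s)
    cls <- character(n)
    params <- vector("list", n)
    traces <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      mx <- model[[region[i]]]$mixture
      cls[i] <- sample(names(mx), 1L, prob = mx)
      params[[i]] <- sampleClassParams(cls[i], "wound", region = region[i],
                                       model = model, noise_sd = noise_sd)
      traces[[i]] <- makeTransient(params[[i]], times,
                                   stimulusTime = stimulusTime)
      truth[[i]] <- .truthMetrics(params[[i]], times, stimulusTime)
    }
    truth <- do.call(rbind, truth)
    truth <- cbind(data.frame(id = seq_len(n), secondary = cls,
                              primary = primaryClass(cls, "wound"),
                              region = region, distance_um = dist_um,
                              stringsAsFactors = FALSE),
                   truth)
    truth$params <- params
    list(traces = traces, truth = truth, times = times,
         stimulusTime = stimulusTime, protocol = "wound")
  })
}
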