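# TIFF stack input/output and result export.

#' Write an image sequence as two multi-page TIFF stacks
#'
#' One single-channel multi-page float TIFF per dye channel, plus a YAML
#' sidecar with the acquisition metadata.
#'
#' @param seq an [ImageSequence-class].
#' @param red_path,green_path output TIFF paths.
#' @param bits 32 (float, default) or 16. TIFF storage covers [0, 1], so each
#'   channel is scaled by its maximum; the scale factors go into the YAML
#'   sidecar and [readSequence()] undoes them.
#' @return invisibly, the two paths.
#' @export
writeSequence <- function(seq, red_path, green_path, bits = 32) {
  stopifnot(is(seq, "ImageSequence"), bits %in% c(16, 32))
  toFrames <- function(a) lapply(seq_len(dim(a)[3L]), function(k) a[, , k])
  writeOne <- function(a, path) {
    mx <- max(a, 1e-12)
    tiff::writeTIFF(toFrames(a / mx), path,
                    bits.per.sample = as.integer(bits))
    mx
  }
  redScale <- writeOne(seq@red, red_path)
  greenScale <- writeOne(seq@green, green_path)
  meta <- list(frame_interval_s = seq@frameInterval,
               pixel_size_um = seq@pixelSize,
               stimulus_time_s = seq@stimulusTime,
               bits = bits, red_scale = redScale, green_scale = greenScale)
  yaml::write_yaml(meta, paste0(red_path, ".meta.yaml"))
  invisible(c(red_path, green_path))
}

#' Read a two-channel image sequence from TIFF stacks
#'
#' Accepts float or integer TIFFs (integer data are read as normalized
#' floats). The two stacks must have equal frame counts and shapes.
#'
#' @param red_path,green_path multi-page TIFF paths.
#' @param frameInterval_s,pixelSize_um,stimulusTime_s acquisition metadata;
#'   when `NULL`, read from the YAML sidecar written by [writeSequence()]
#'   (falling back to 1 s, 0.65 um, 60 s).
#' @return An [ImageSequence-class].
#' @export
readSequence <- function(red_path, green_path, frameInterval_s = NULL,
                         pixelSize_um = NULL, stimulusTime_s = NULL) {
  readStack <- function(path) {
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    frames <- lapply(frames, function(f) {
      if (length(dim(f)) == 3L) f <- f[, , 1L]   # drop spurious channels
      f
    })
    array(unlist(frames), dim = c(dim(frames[[1L]]), length(frames)))
  }
  red <- readStack(red_path)
  green <- readStack(green_path)
  metaPath0 <- paste0(red_path, ".meta.yaml")
  meta0 <- if (file.exists(metaPath0)) yaml::read_yaml(metaPath0) else list()
  if (!is.null(meta0$red_scale)) red <- red * meta0$red_scale
  if (!is.null(meta0$green_scale)) green <- green * meta0$green_scale
  if (!identical(dim(red), dim(green)))
    stop(sprintf("channel shape mismatch: red has %s frames of %dx%d, green %s of %dx%d",
                 dim(red)[3L], dim(red)[1L], dim(red)[2L],
                 dim(green)[3L], dim(green)[1L], dim(green)[2L]))
  metaPath <- paste0(red_path, ".meta.yaml")
  meta <- if (file.exists(metaPath)) yaml::read_yaml(metaPath) else list()
  if (is.null(frameInterval_s))
    frameInterval_s <- meta$frame_interval_s %||% 1
  if (is.null(pixelSize_um)) pixelSize_um <- meta$pixel_size_um %||% 0.65
  if (is.null(stimulusTime_s))
    stimulusTime_s <- meta$stimulus_time_s %||% 60
  new("ImageSequence", red = red, green = green,
      frameInterval = frameInterval_s, pixelSize = pixelSize_um,
      stimulusTime = stimulusTime_s, metadata = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a data.frame with a provenance sidecar (config hash, seed, version).
.writeCSV <- function(df, path, provenance) {
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(provenance, paste0(path, ".prov.json"),
                       auto_unbox = TRUE, digits = NA)
  path
}
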