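# Segmentation: channel combination, pre-processing, iterative seeded ROI
# extraction with halo stripping, review, and scoring.

test_that("channel combination normalizes to [0, 1] with degenerate cases", {
  expect_equal(combineChannels(matrix(0.2, 4, 4), matrix(0.3, 4, 4)),
               matrix(0, 4, 4))
  red <- matrix(0, 5, 5)
  red[3, 3] <- 10
  out <- combineChannels(red, matrix(0, 5, 5))
  expect_equal(out[3, 3], 1)
  expect_equal(sum(out), 1)
  expect_error(combineChannels(list(), list()), "empty")
  expect_error(combineChannels(matrix(0, 4, 4), matrix(0, 5, 5)),
               "identical dimensions")
})

test_that("combined first+last frames light up every cell footprint", {
  fx <- smallRender(nCells = 4, side = 96, seed = 15)
  Tn <- dim(redChannel(fx$seq))[3]
  comb <- combineChannels(list(redChannel(fx$seq)[, , 1],
                               redChannel(fx$seq)[, , Tn]),
                          list(greenChannel(fx$seq)[, , 1],
                               greenChannel(fx$seq)[, , Tn]))
  cells <- cellTable(fx$layout)
  inCell <- matrix(FALSE, 96, 96)
  for (k in seq_len(nrow(cells))) {
    d2 <- outer((seq_len(96) - cells$y_px[k])^2,
                (seq_len(96) - cells$x_px[k])^2, "+")
    inCell <- inCell | d2 <= (0.7 * cells$radius_px[k])^2
    expect_gt(mean(comb[d2 <= (0.7 * cells$radius_px[k])^2]),
              mean(comb[!inCell]))
  }
})

test_that("pre-processing applies mask and local-mean suppression", {
  sp <- segmentationParams(blur_sigma_px = 0, mask_threshold = 0.05,
                           localmean_window_px = 7,
                           localmean_fraction = 0.9)
  # a pixel equal to its local mean is retained
  expect_equal(preprocessImage(matrix(0.5, 20, 20), sp),
               matrix(0.5, 20, 20))
  # everything below the global mask goes to zero
  expect_equal(preprocessImage(matrix(0.01, 20, 20), sp),
               matrix(0, 20, 20))
  expect_error(preprocessImage(matrix(0.5, 4, 4),
                               segmentationParams(localmean_window_px = 25)),
               "larger than the image")
})

test_that("local-mean suppression carves the ridge between two blobs", {
  # two bright blobs joined by a ridge at 40% of their height, with the
  # local-mean window spanning both
  img <- matrix(0, 25, 61)
  img[, 4:28] <- 1
  img[, 34:58] <- 1
  img[11:15, 29:33] <- 0.4
  sp <- segmentationParams(blur_sigma_px = 0, mask_threshold = 0.05,
                           localmean_window_px = 25,
                           localmean_fraction = 0.8)
  out <- preprocessImage(img, sp)
  # independent evaluation of the stated rule
  w <- 25
  lm <- EBImage::filter2(img, matrix(1 / w^2, w, w))
  manual <- img
  manual[img < 0.05] <- 0
  manual[manual < 0.8 * lm] <- 0
  expect_equal(out, pmin(pmax(manual, 0), 1))
  expect_true(all(out[11:15, 29:33] == 0))          # ridge zeroed
  expect_true(all(out[, c(10:22, 40:52)] > 0))      # blob cores retained
})

test_that("a single blob yields one ROI containing its peak", {
  img <- bumpImage(64, 64, cbind(32, 32), sigma = 6)
  # mask above the halo level so the sub-halo skirt of the smooth blob does
  # not seed remnant fragments
  sp <- segmentationParams(blur_sigma_px = 0, mask_threshold = 0.32,
                           min_size_px = 10, max_size_px = 2000,
                           max_radius_px = 20)
  rmap <- extractROIs(img, sp)
  expect_equal(nROIs(rmap), 1L)
  expect_equal(labelMatrix(rmap)[32, 32], 1L)
})

test_that("a 5x5 blob grid is recovered with per-blob seeds and centroids", {
  centres <- gridCentres(5, 44, offset = 24)
  img <- bumpImage(240, 240, centres, sigma = 6)
  sp <- segmentationParams(blur_sigma_px = 0, mask_threshold = 0.32,
                           min_size_px = 10, max_size_px = 2000,
                           max_radius_px = 15)
  rmap <- extractROIs(img, sp)
  expect_equal(nROIs(rmap), 25L)
  rois <- roiTable(rmap)
  d <- sqrt(outer(rois$centroid_x, centres[, 1], "-")^2 +
            outer(rois$centroid_y, centres[, 2], "-")^2)
  expect_true(all(apply(d, 2, min) <= 2))   # centroids within 2 px of truth
  # one seed per blob
  seedAssign <- apply(sqrt(outer(rois$seed_x, centres[, 1], "-")^2 +
                           outer(rois$seed_y, centres[, 2], "-")^2),
                      1, which.min)
  expect_equal(sort(seedAssign), 1:25)
  # watershed containment invariants (blobs are untouched when discovered)
  for (k in rois$id) {
    px <- which(labelMatrix(rmap) == k)
    rr <- (px - 1) %% 240 + 1
    cc <- (px - 1) %/% 240 + 1
    expect_true(all(img[px] >= sp$roi_threshold_fraction *
                      rois$seed_intensity[rois$id == k] - 1e-9))
    expect_true(all((rr - rois$seed_y[rois$id == k])^2 +
                    (cc - rois$seed_x[rois$id == k])^2 <=
                    sp$max_radius_px^2 + 1e-9))
    expect_equal(length(px), rois$area_px[rois$id == k])
  }
  # determinism
  expect_identical(labelMatrix(extractROIs(img, sp)), labelMatrix(rmap))
})

test_that("ROI review removes exactly the requested ROIs", {
  centres <- gridCentres(3, 40, offset = 20)
  img <- bumpImage(120, 120, centres, sigma = 5)
  sp <- segmentationParams(blur_sigma_px = 0, mask_threshold = 0.32,
                           min_size_px = 5, max_radius_px = 12)
  rmap <- extractROIs(img, sp)
  expect_equal(nROIs(rmap), 9L)
  expect_identical(reviewROIs(rmap, integer()), rmap)
  pruned <- reviewROIs(rmap, 4L)
  expect_equal(nROIs(pruned), 8L)
  expect_false(4L %in% roiTable(pruned)$id)
  keep <- labelMatrix(rmap) != 4L
  expect_identical(labelMatrix(pruned)[keep], labelMatrix(rmap)[keep])
  empty <- reviewROIs(rmap, roiTable(rmap)$id)
  expect_equal(nROIs(empty), 0L)
  expect_true(all(labelMatrix(empty) == 0L))
  expect_error(reviewROIs(rmap, 99L), "unknown ROI id")
})

test_that("segmentation scoring matches a brute-force optimal assignment", {
  mkMap <- function(xy) {
    new("ROIMap", labels = matrix(0L, 100, 100),
        rois = data.frame(id = seq_len(nrow(xy)), seed_x = xy[, 1],
                          seed_y = xy[, 2], seed_intensity = 1,
                          area_px = 10, centroid_x = xy[, 1],
                          centroid_y = xy[, 2]),
        rejected = data.frame(), params = list())
  }
  mkLay <- function(xy) {
    cells <- data.frame(id = seq_len(nrow(xy)), x_px = xy[, 1],
                        y_px = xy[, 2], radius_px = 5)
    new("CellLayout", fieldSize = c(100L, 100L), pixelSize = 1,
        cells = cells, wound = NULL, protocol = "ATP")
  }
  truth <- cbind(c(10, 30, 50, 70, 90, 20), c(10, 30, 50, 70, 90, 80))
  sc <- scoreSegmentation(mkMap(truth), mkLay(truth), 5)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  sc <- scoreSegmentation(mkMap(truth[1:5, , drop = FALSE]), mkLay(truth), 5)
  expect_equal(sc$recall, 5 / 6)
  # brute-force oracle: with spacing > 2 x match radius the greedy matching
  # equals the optimal assignment, for jittered detections
  set.seed(42)
  for (rep in 1:5) {
    det <- truth + matrix(runif(12, -2, 2), ncol = 2)
    sc <- scoreSegmentation(mkMap(det), mkLay(truth), 4)
    dmat <- sqrt(outer(det[, 1], truth[, 1], "-")^2 +
                 outer(det[, 2], truth[, 2], "-")^2)
    best <- max(apply(allPerms(6), 1, function(p)
      sum(dmat[cbind(seq_len(6), p)] <= 4)))
    expect_equal(sc$n_matched, best)
  }
})
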