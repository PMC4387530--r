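# Synthetic transients, populations and layouts.

test_that("zero-amplitude transient is the constant baseline", {
  p <- transientParams("1a", baseline = 0.7, noise_sd = 0)
  tr <- makeTransient(p, atpGrid())
  expect_equal(tr$value, rep(0.7, length(atpGrid())))
})

test_that("generation is deterministic under a fixed seed", {
  p <- transientParams("2a", peak_amplitude = 1, plateau_level = 0.6,
                       noise_sd = 0.05)
  expect_identical(makeTransient(p, atpGrid(), seed = 3),
                   makeTransient(p, atpGrid(), seed = 3))
  pop1 <- makePopulation(atpClassMixture(), 20, "ATP", seed = 4, dt_s = 10)
  pop2 <- makePopulation(atpClassMixture(), 20, "ATP", seed = 4, dt_s = 10)
  expect_identical(pop1$truth$secondary, pop2$truth$secondary)
  expect_identical(pop1$traces, pop2$traces)
})

test_that("transient construction rejects invalid inputs", {
  expect_error(transientParams("9z"), "unknown class_label")
  expect_error(transientParams("W1"), "wound protocol")
  expect_error(transientParams("3b", protocol = "ATP",
                               spike_interval_s = 0), "spike_interval_s")
  p <- transientParams("1a")
  expect_error(makeTransient(p, 5), "at least 2 samples")
  expect_error(makeTransient(p, c(0, 2, 1)), "strictly increasing")
})

test_that("class-2a waveform round-trips through the metric extractor", {
  p <- transientParams("2a", baseline = 0.1, peak_amplitude = 1,
                       plateau_level = 0.79, noise_sd = 0)
  m <- computeMetrics(makeTransient(p, atpGrid()), stimulusTime = 60)
  expect_lt(abs(m$peak_height - 1) / 1, 0.02)
  expect_lt(abs(m$plateau_height - 0.79) / 0.79, 0.02)
})

test_that("spike interval of 500 s reads out as a 2e-3 per-second rate", {
  p <- transientParams("3b", peak_amplitude = 1, spike_interval_s = 500,
                       spike_amplitude = 0.5, noise_sd = 0)
  m <- computeMetrics(makeTransient(p, atpGrid()), stimulusTime = 60)
  expect_lt(abs(m$spike_rate_per_s - 2e-3) / 2e-3, 0.05)
})

test_that("noiseless waveforms of every class round-trip their parameters", {
  for (protocol in c("ATP", "wound")) {
    for (cl in transientClasses(protocol)$secondary) {
      for (seed in 1:3) {
        region <- if (cl %in% c("2a", "2b", "W2", "W3")) "proximal"
                  else c("proximal", "distal")[1 + seed %% 2]
        fx <- noiselessTrace(cl, protocol, region, seed = 100 * seed)
        p <- fx$params
        m <- computeMetrics(fx$trace, stimulusTime = 60)
        info <- paste(protocol, cl, seed)
        if (p$peak_amplitude >= 0.25) {
          expect_lt(abs(m$peak_height - p$peak_amplitude) /
                      p$peak_amplitude, 0.02, label = paste("peak", info))
          expect_lte(abs(m$peak_time_min * 60 - p$peak_time_s), 1,
                     label = paste("peak time", info))
        }
        truth <- makePopulation(setNames(1, cl), 1, protocol,
                                priors = setNames(list(function() p), cl),
                                seed = 1)$truth
        if (truth$true_plateau > 0.05) {
          # dual-plateau responses report the first level as the headline
          # plateau; the terminal level matches the final-third truth
          ext <- if (m$dual_plateau) m$plateau2_height else m$plateau_height
          expect_lt(abs(ext - truth$true_plateau) / truth$true_plateau,
                    0.02, label = paste("plateau", info))
          if (m$dual_plateau)
            expect_lt(abs(m$plateau_height - p$plateau_level) /
                        p$plateau_level, 0.05,
                      label = paste("first plateau", info))
        }
        if (truth$true_spike_rate > 0) {
          expect_lt(abs(m$spike_rate_per_s - truth$true_spike_rate) /
                      truth$true_spike_rate, 0.05,
                    label = paste("rate", info))
        }
      }
    }
  }
})

test_that("population mixtures are validated and reproduced", {
  expect_error(makePopulation(numeric(), 5), "empty")
  expect_error(makePopulation(c("1a" = -0.5, "2a" = 1.5), 5), "nonnegative")
  expect_error(makePopulation(c("1a" = 0.4, "2a" = 0.4), 5), "sum to 1")

  pop <- makePopulation(c("1a" = 1), 10, "ATP", seed = 2, dt_s = 5,
                        noise_sd = 0)
  expect_true(all(pop$truth$secondary == "1a"))
  for (tr in pop$traces) expect_lt(diff(range(tr$value)), 1e-12)

  # replicate-1 counts as a mixture: class counts inside the multinomial
  # 95% envelope of their expectations
  counts1 <- atpClassMixture(pooled = FALSE)[, 1]
  mixr1 <- counts1 / sum(counts1)
  pop <- makePopulation(mixr1, 114, "ATP", seed = 5, dt_s = 60)
  obs <- table(factor(pop$truth$secondary, levels = names(mixr1)))
  lo <- qbinom(0.025, 114, mixr1)
  hi <- qbinom(0.975, 114, mixr1)
  expect_true(all(obs >= lo & obs <= hi))
})

test_that("primary-class proportions are recovered at population scale", {
  mix <- c("1a" = 0.21, "2a" = 0.33, "3b" = 0.47) / 1.01
  pop <- makePopulation(mix, 1000, "ATP", seed = 6, dt_s = 120)
  frac3 <- mean(pop$truth$primary == "3")
  expect_lt(abs(frac3 - 0.47), 0.05)
  # mixture recovery: all class frequencies within 3 s.e. at n >= 500
  p3 <- mix[["3b"]] / sum(mix)
  expect_lt(abs(frac3 - p3), 3 * sqrt(p3 * (1 - p3) / 1000))
})

test_that("wound layouts exclude the scratch strip and grade responses", {
  expect_error(makeWoundLayout(c(256, 256), woundStripWidth_px = 0),
               "degenerate")
  lay <- makeWoundLayout(c(512, 512), woundStripWidth_px = 64, seed = 8)
  cells <- cellTable(lay)
  expect_gt(nrow(cells), 0)
  expect_true(all(cells$x_px > 64))
  expect_true(all(cells$distance_um >= 0))
  # distance-dependent response: proximal cells draw larger initial peaks
  peakOf <- function(rows) mean(vapply(cells$params[rows],
                                       function(p) p$peak_amplitude, 0))
  expect_gt(peakOf(cells$region == "proximal"),
            peakOf(cells$region == "distal"))
})

test_that("a flat cell renders as a time-constant footprint", {
  lay <- makeMonolayerLayout(c(64, 64), nCells = 1,
                             mixture = c("1a" = 1), noise_sd = 0, seed = 9)
  seqn <- renderSequence(lay, frameInterval_s = 5, duration_s = 30,
                         imaging = imagingParams(background = 0,
                                                 noise_floor = 0,
                                                 shot_coef = 0),
                         seed = 10)
  for (ch in list(redChannel(seqn), greenChannel(seqn))) {
    flat <- apply(ch, c(1, 2), function(v) diff(range(v)))
    expect_lt(max(flat), 1e-12)
  }
})

test_that("a noiseless render round-trips the transient through the ratio", {
  lay <- makeMonolayerLayout(c(96, 96), nCells = 1, mixture = c("2a" = 1),
                             noise_sd = 0, seed = 11)
  seqn <- renderSequence(lay, frameInterval_s = 2, duration_s = 2160,
                         imaging = imagingParams(background = 0,
                                                 noise_floor = 0,
                                                 shot_coef = 0),
                         seed = 12)
  cell <- cellTable(lay)[1, ]
  # true footprint: pixels inside 70% of the radius
  H <- 96
  inside <- which(outer((seq_len(H) - cell$y_px)^2,
                        (seq_len(H) - cell$x_px)^2, "+") <=
                  (0.7 * cell$radius_px)^2)
  lab <- matrix(0L, H, H)
  lab[inside] <- 1L
  rmap <- new("ROIMap", labels = lab,
              rois = data.frame(id = 1L, seed_x = cell$x_px,
                                seed_y = cell$y_px, seed_intensity = 1,
                                area_px = length(inside),
                                centroid_x = cell$x_px,
                                centroid_y = cell$y_px),
              rejected = data.frame(), params = list())
  tr <- extractTrace(seqn, rmap, 1)
  truth <- makeTransient(cell$params[[1]], tr$time_s, stimulusTime = 60)
  expect_gte(cor(tr$value, truth$value), 0.99)
})

test_that("the rendered dye ratio is monotone in calcium", {
  # monotone rising transient, noiseless render: the centre-pixel ratio of
  # increasing over decreasing channel must never decrease
  lay <- makeMonolayerLayout(c(64, 64), nCells = 1, mixture = c("1b" = 1),
                             noise_sd = 0, seed = 13)
  lay@cells$params[[1]]$decay_tau_s <- Inf   # strictly nondecreasing input
  seqn <- renderSequence(lay, frameInterval_s = 10, duration_s = 2000,
                         imaging = imagingParams(background = 0,
                                                 noise_floor = 0,
                                                 shot_coef = 0),
                         seed = 14)
  cell <- cellTable(lay)[1, ]
  r <- round(cell$y_px); c <- round(cell$x_px)
  ratio <- greenChannel(seqn)[r, c, ] / redChannel(seqn)[r, c, ]
  expect_true(all(diff(ratio) >= -1e-9))
})
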