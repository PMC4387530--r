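# Rule-based transient classification and population tabulation.

test_that("canonical shapes are assigned their classes", {
  # non-responder
  m <- computeMetrics(data.frame(time_s = 0:2160, value = 1),
                      stimulusTime = 60)
  expect_equal(classifyTransient(m, protocol = "ATP")$secondary, "1a")

  # rapid peak with a sustained 0.79 plateau
  p <- transientParams("2a", peak_amplitude = 1, peak_time_s = 30,
                       rise_tau_s = 10, plateau_level = 0.79, noise_sd = 0)
  m <- computeMetrics(makeTransient(p, atpGrid()), stimulusTime = 60)
  out <- classifyTransient(m, protocol = "ATP")
  expect_equal(out$secondary, "2a")
  expect_equal(out$primary, "2")

  # rapid peak, return to baseline, 5 spikes
  p <- transientParams("3b", peak_amplitude = 1, decay_tau_s = 150,
                       spike_interval_s = 350, spike_amplitude = 0.5,
                       noise_sd = 0)
  m <- computeMetrics(makeTransient(p, atpGrid()), stimulusTime = 60)
  expect_gte(m$n_spikes, 5)
  expect_equal(classifyTransient(m, protocol = "ATP")$secondary, "3b")

  # wound: peak, 0.6 plateau for ~8 min, step down to a stable 0.2
  p <- transientParams("W3", protocol = "wound", peak_amplitude = 1.4,
                       peak_time_s = 40, decay_tau_s = 120,
                       plateau_level = 0.6, plateau2_level = 0.2,
                       plateau_end_s = 550, noise_sd = 0)
  m <- computeMetrics(makeTransient(p, woundGrid()), stimulusTime = 60)
  expect_true(m$dual_plateau)
  expect_equal(classifyTransient(m, protocol = "wound")$secondary, "W3")
})

test_that("every metrics vector maps to exactly one class of its protocol", {
  set.seed(19)
  for (rep in 1:200) {
    m <- data.frame(
      baseline = runif(1, 0.5, 1.5),
      peak_height = runif(1, 0, 3),
      peak_time_min = runif(1, 0, 30),
      onset_latency_s = sample(c(runif(1, 0, 600), Inf), 1),
      fwhm_min = runif(1, 0, 30),
      plateau_height = runif(1, -0.2, 2),
      plateau2_height = runif(1, 0, 1),
      spike_rate_per_s = runif(1, 0, 5e-3),
      n_spikes = sample(0:6, 1),
      has_peak = sample(c(TRUE, FALSE), 1),
      has_plateau = sample(c(TRUE, FALSE), 1),
      is_spiking = NA,
      dipped_to_baseline = sample(c(TRUE, FALSE), 1),
      mid_plateau = sample(c(TRUE, FALSE), 1),
      terminal_plateau = sample(c(TRUE, FALSE), 1),
      dual_plateau = sample(c(TRUE, FALSE), 1))
    m$is_spiking <- m$n_spikes >= 2
    for (protocol in c("ATP", "wound")) {
      out <- suppressWarnings(classifyTransient(m, protocol = protocol))
      expect_length(out$secondary, 1)
      expect_true(out$secondary %in% transientClasses(protocol)$secondary ||
                  (protocol == "wound" &&
                   out$secondary %in% c("1c", "2c", "3a", "3b", "3c")))
      if (protocol == "ATP") expect_false(startsWith(out$secondary, "W"))
      expect_identical(out$primary,
                       primaryClass(out$secondary, protocol))
    }
  }
})

test_that("the secondary-to-primary grouping matches the taxonomy", {
  atp <- transientClasses("ATP")
  expect_equal(atp$primary, substr(atp$secondary, 1, 1))
  wnd <- transientClasses("wound")
  expect_equal(wnd$primary[wnd$secondary %in% c("1a", "1b", "W1")],
               rep("slow/absent", 3))
  expect_equal(wnd$primary[wnd$secondary %in% c("2a", "2b", "W2", "W3")],
               rep("peak-plateau", 4))
  expect_equal(wnd$primary[wnd$secondary %in% c("W4", "W5")],
               rep("peak-baseline", 2))
  expect_error(primaryClass("W1", "ATP"), "wound protocol")
})

test_that("classification recovers generating classes on noisy populations", {
  pop <- makePopulation(atpClassMixture(), 150, "ATP", seed = 20)
  cls <- classifyPopulation(pop$traces, protocol = "ATP")
  expect_gte(mean(cls$secondary == pop$truth$secondary), 0.9)
  wp <- makeWoundPopulation(40, 80, seed = 21)
  clw <- classifyPopulation(wp$traces, protocol = "wound")
  expect_gte(mean(clw$secondary == wp$truth$secondary), 0.9)
})

test_that("population tables reproduce the replicate arithmetic", {
  # one replicate, all non-responding
  tab <- tabulateClasses(data.frame(replicate = 1, secondary = rep("1a", 10)),
                         "ATP")
  expect_equal(tab$summary$mean_pct, c(100, 0, 0))
  expect_equal(tab$summary$sem_pct, c(0, 0, 0))
  expect_true(tab$single_replicate)

  # replicate-1 counts: primary percentages from the printed counts
  counts <- atpClassMixture(pooled = FALSE)
  labels <- do.call(rbind, lapply(1:3, function(r)
    data.frame(replicate = r,
               secondary = rep(rownames(counts), counts[, r]))))
  tab <- tabulateClasses(labels, "ATP")
  expect_equal(unname(tab$percentages[, 1]),
               100 * c(24, 39, 51) / 114, tolerance = 1e-10)
  # across the three replicates the slow/absent group is 21 +- 3%
  s <- tab$summary
  expect_lt(abs(s$mean_pct[s$primary == "1"] - 21), 1)
  expect_lt(abs(s$sem_pct[s$primary == "1"] - 3), 0.6)
  expect_lt(abs(s$mean_pct[s$primary == "2"] - 33), 1)
  expect_lt(abs(s$mean_pct[s$primary == "3"] - 47), 1)
  # per-replicate percentages sum to 100
  expect_equal(unname(colSums(tab$percentages)), rep(100, 3))
})

test_that("feature scatter tables carry groups and separate the clusters", {
  expect_equal(nrow(featureScatter(data.frame(
    peak_height = numeric(), plateau_height = numeric(),
    fwhm_min = numeric(), spike_rate_per_s = numeric(),
    is_spiking = logical())[0, ], "spiking")), 0)
  pop <- makePopulation(c("2a" = 0.5, "3b" = 0.5), 60, "ATP", seed = 22)
  cls <- classifyPopulation(pop$traces, protocol = "ATP")
  sc <- featureScatter(cls, "spiking")
  panel <- sc[sc$panel == "peak_height_vs_plateau_height", ]
  spike <- panel$y[panel$group == "spiking"]
  quiet <- panel$y[panel$group == "non-spiking"]
  pooledSD <- sqrt((var(spike) + var(quiet)) / 2)
  expect_gt(abs(mean(quiet) - mean(spike)), 2 * pooledSD)
})
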