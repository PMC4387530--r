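# Wound distances, proximal/distal statistics and rank tests.

test_that("wound distance is the scaled minimum distance to the polyline", {
  w <- woundGeometry(cbind(x = c(0, 0), y = c(0, 100)), "left", 0)
  expect_equal(distanceToWound(c(0, 50), w, 0.65), 0)
  expect_equal(distanceToWound(c(50, 50), w, 0.65), 32.5)
  expect_warning(d <- distanceToWound(c(-3, 50), w, 0.65), "removed side")
  expect_equal(d, 0)

  # dense-sampling oracle on a jagged polyline
  set.seed(23)
  edge <- cbind(x = 40 + cumsum(runif(5, -8, 8)), y = seq(0, 120, by = 30))
  w <- woundGeometry(edge, "left", 0)
  densePts <- do.call(rbind, lapply(seq_len(nrow(edge) - 1), function(k) {
    f <- seq(0, 1, length.out = 2000)
    cbind(edge[k, 1] + f * (edge[k + 1, 1] - edge[k, 1]),
          edge[k, 2] + f * (edge[k + 1, 2] - edge[k, 2]))
  }))
  for (rep in 1:20) {
    pt <- c(runif(1, max(edge[, 1]) + 1, 120), runif(1, 0, 120))
    oracle <- min(sqrt((densePts[, 1] - pt[1])^2 +
                       (densePts[, 2] - pt[2])^2))
    expect_equal(distanceToWound(pt, w, 1), oracle, tolerance = 0.01)
  }
})

test_that("the proximal/distal split is strict at the threshold", {
  rec <- data.frame(distance_um = c(50, 150))
  sp <- splitProximalDistal(rec)
  expect_equal(sp$proximal$distance_um, 50)
  expect_equal(sp$distal$distance_um, 150)
  sp <- splitProximalDistal(data.frame(distance_um = c(100, 40)))
  expect_equal(sp$distal$distance_um, 100)   # boundary cell is distal
  expect_warning(sp <- splitProximalDistal(data.frame(distance_um = 200)),
                 "empty proximal")
  expect_equal(attr(sp, "empty_side"), "proximal")
})

test_that("Mann-Whitney U matches enumeration and handles degenerate input", {
  out <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(out$U, 0)
  expect_equal(out$p, 2 / 6)
  expect_equal(out$method, "exact")

  # identical multisets: tie-corrected normal path, p = 1
  out <- mannWhitneyU(c(2, 2, 5), c(2, 5, 2))
  expect_equal(out$p, 1)

  # symmetry in the arguments
  set.seed(24)
  x <- rnorm(7); y <- rnorm(5) + 1
  a <- mannWhitneyU(x, y); b <- mannWhitneyU(y, x)
  expect_equal(a$p, b$p)
  expect_equal(a$U + b$U, length(x) * length(y))

  # exact tail equals full enumeration for all tested partitions
  for (sizes in list(c(2, 2), c(3, 3), c(2, 5), c(4, 4), c(5, 5), c(3, 7))) {
    for (rep in 1:3) {
      x <- sample(seq(0, 1, length.out = 50), sizes[1])
      y <- sample(setdiff(seq(0, 1, length.out = 101), x), sizes[2])
      got <- mannWhitneyU(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$p, enumMannWhitneyP(x, y), tolerance = 1e-12)
      # cross-check against the reference implementation
      expect_equal(got$p, wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }

  # normal approximation stays within 0.05 of the exact answer
  for (rep in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    exact <- mannWhitneyU(x, y)$p
    approx <- mannWhitneyU(x, y, exact_max = 0)$p
    expect_lt(abs(exact - approx), 0.05)
  }
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(25)
  x <- rlnorm(30); y <- rlnorm(40) * 1.5
  g3 <- rlnorm(20)
  for (f in list(function(v) exp(v), function(v) log(v),
                 function(v) v^3 + 2)) {
    a <- mannWhitneyU(x, y); b <- mannWhitneyU(f(x), f(y))
    expect_equal(a$U, b$U)
    expect_equal(a$p, b$p)
    k1 <- kruskalWallisDunn(list(a = x, b = y, c = g3))
    k2 <- kruskalWallisDunn(list(a = f(x), b = f(y), c = f(g3)))
    expect_equal(k1$H, k2$H)
    expect_equal(k1$dunn$z, k2$dunn$z)
  }
})

test_that("Kruskal-Wallis with Dunn reproduces hand-computed oracles", {
  # ranks 1..6 in three groups: H = 12/42 * sum(Rj^2/nj) - 21 = 4.5714
  out <- kruskalWallisDunn(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  expect_equal(out$H, 12 / (6 * 7) * (9 / 2 + 49 / 2 + 121 / 2) - 3 * 7,
               tolerance = 1e-10)
  expect_equal(out$H, 4.5714, tolerance = 1e-3)
  expect_equal(out$df, 2)

  # two groups of two: Dunn z = (1.5 - 3.5)/sqrt(20/12) = -1.5492
  out <- kruskalWallisDunn(list(a = c(1, 2), b = c(3, 4)))
  expect_equal(out$dunn$z, -2 / sqrt(20 / 12), tolerance = 1e-10)

  # identical data: H = 0, all Dunn p = 1
  out <- kruskalWallisDunn(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(out$H, 0)
  expect_equal(out$p, 1)
  expect_true(all(out$dunn$p_adj == 1))
})

test_that("primary-class peak heights separate as in the class summaries", {
  mix <- atpClassMixture()
  pks <- lapply(c("1", "2", "3"), function(pc) {
    sub <- mix[startsWith(names(mix), pc)]
    pop <- makePopulation(sub / sum(sub), 50, "ATP",
                          seed = 26 + as.integer(pc), dt_s = 2)
    ms <- classifyPopulation(pop$traces, protocol = "ATP")
    ms$peak_height
  })
  names(pks) <- c("c1", "c2", "c3")
  out <- kruskalWallisDunn(pks)
  d <- out$dunn
  expect_lt(d$p_adj[d$group1 == "c1" & d$group2 == "c2"], 0.001)
  expect_lt(d$p_adj[d$group1 == "c1" & d$group2 == "c3"], 0.001)
})

test_that("threshold sweeps localize a proximal-only elevation", {
  # constant feature: ties everywhere, p = 1 at every defined threshold
  rec <- data.frame(distance_um = seq(5, 395, by = 5), flat = 1)
  sw <- thresholdSweep(rec, "flat")
  expect_true(all(sw$p[!is.na(sw$p)] == 1))

  # all cells beyond the sweep range: every threshold undefined
  far <- data.frame(distance_um = seq(420, 500, by = 10), flat = 1)
  expect_true(all(is.na(thresholdSweep(far, "flat")$p)))

  # plateau elevated only below 100 um: the p-minimum falls near the change
  set.seed(27)
  n <- 240
  d <- runif(n, 5, 395)
  plat <- ifelse(d < 100, 0.45, 0.16) + rnorm(n, 0, 0.08)
  sw <- thresholdSweep(data.frame(distance_um = d, plateau = plat),
                       "plateau")
  best <- sw$threshold_um[which.min(sw$p)]
  expect_gte(best, 40)
  expect_lte(best, 110)
})

test_that("group summaries report mean, s.d. and s.e.m. with n-1 scaling", {
  out <- summarizeGroups(c(1, 2, 3))
  expect_equal(out$mean, 2)
  expect_equal(out$sd, 1)
  expect_equal(out$sem, 1 / sqrt(3), tolerance = 1e-10)
  out <- summarizeGroups(5)
  expect_equal(out$mean, 5)
  expect_true(is.na(out$sd) && is.na(out$sem))
  # distal plateau recovery at the generating moments
  wp <- makeWoundPopulation(20, 178, seed = 28)
  cls <- classifyPopulation(wp$traces, protocol = "wound")
  dist <- wp$truth$region == "distal"
  s <- summarizeGroups(cls$plateau_height[dist])
  expect_lt(abs(s$mean - mean(wp$truth$true_plateau[dist])), 3 * s$sem)
})
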