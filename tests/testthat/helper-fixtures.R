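# Shared fixtures, all generated in code.

# Default time grids for the two protocols (1 Hz).
atpGrid <- function(dt = 1) seq(0, 2160, by = dt)
woundGrid <- function(dt = 1) seq(0, 2760, by = dt)

# One noiseless trace of a given class with class-typical parameters.
noiselessTrace <- function(class_label, protocol = "ATP",
                           region = "proximal", seed = 1) {
  p <- withr::with_seed(seed,
    sampleClassParams(class_label, protocol, region = region, noise_sd = 0))
  grid <- if (protocol == "ATP") atpGrid() else woundGrid()
  list(params = p, trace = makeTransient(p, grid, stimulusTime = 60))
}

# An image with Gaussian bumps at given centres (rows x, y), all of height
# `peak`, sd `sigma`; deterministic stand-in for a prepared cell image.
bumpImage <- function(H, W, centres, sigma = 6, peak = 1) {
  img <- matrix(0, H, W)
  ys <- matrix(seq_len(H), H, W)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (k in seq_len(nrow(centres))) {
    img <- img + peak * exp(-((xs - centres[k, 1])^2 +
                              (ys - centres[k, 2])^2) / (2 * sigma^2))
  }
  img
}

# Grid of blob centres with given spacing.
gridCentres <- function(n_side, spacing, offset = spacing / 2) {
  g <- expand.grid(ix = seq_len(n_side), iy = seq_len(n_side))
  cbind(x = offset + (g$ix - 1) * spacing, y = offset + (g$iy - 1) * spacing)
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# assignments of the pooled sample into groups of the observed sizes.
# Independent of the package implementation.
enumMannWhitneyP <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  uFor <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  uObs <- uFor(seq_len(nx))
  us <- apply(utils::combn(length(pooled), nx), 2, uFor)
  pLo <- mean(us <= uObs)
  pHi <- mean(us >= uObs)
  min(1, 2 * min(pLo, pHi))
}

# Small rendered two-channel field, reused by segmentation/pipeline tests.
smallRender <- function(nCells = 9, side = 160, seed = 7, frames = 12,
                        noise = TRUE) {
  lay <- makeMonolayerLayout(c(side, side), nCells = nCells, seed = seed)
  img <- if (noise) imagingParams() else
    imagingParams(background = 0, noise_floor = 0, shot_coef = 0)
  seqn <- renderSequence(lay, frameInterval_s = 5,
                         duration_s = 5 * (frames - 1), imaging = img,
                         seed = seed + 1)
  list(layout = lay, seq = seqn)
}

# All permutations of 1..n as rows (exhaustive assignment oracle).
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}
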