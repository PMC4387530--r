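# Spatial statistics: wound distances, proximal/distal split, Mann-Whitney
# threshold sweep, Kruskal-Wallis with Dunn post test, group summaries.

# Minimum distance (px) from a point to a segment.
.pointSegDist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx^2 + dy^2
  tt <- if (L2 == 0) 0 else .clip(((px - x1) * dx + (py - y1) * dy) / L2, 0, 1)
  sqrt((px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2)
}

#' Distance from a cell centroid to the wound edge
#'
#' Minimum Euclidean distance from the centroid to the edge polyline,
#' converted to micrometres. Centroids on the removed (denuded) side are
#' reported as distance 0 with a warning. The removed-side test assumes the
#' edge is y-monotone (true for the vertical scratch strip of the synthetic
#' layouts).
#'
#' @param centroid_px numeric `(x, y)` in pixels.
#' @param wound a [WoundGeometry-class].
#' @param pixelSize_um um per pixel.
#' @return distance in micrometres (scalar).
#' @examples
#' w <- woundGeometry(cbind(c(0, 0), c(0, 100)), "left", 0)
#' distanceToWound(c(50, 50), w, 0.65)
#' @export
distanceToWound <- function(centroid_px, wound, pixelSize_um) {
  stopifnot(is(wound, "WoundGeometry"), length(centroid_px) == 2L)
  e <- wound@edge
  px <- centroid_px[1L]; py <- centroid_px[2L]
  # interpolate the edge x at the centroid's y to decide the side
  ys <- e[, 2L]; xs <- e[, 1L]
  o <- order(ys)
  yq <- .clip(py, min(ys), max(ys))
  xEdge <- stats::approx(ys[o], xs[o], xout = yq, ties = "ordered")$y
  onRemoved <- (wound@removedSide == "left" && px < xEdge) ||
               (wound@removedSide == "right" && px > xEdge)
  if (onRemoved) {
    warning("centroid lies on the removed side of the wound; distance 0")
    return(0)
  }
  d <- Inf
  for (k in seq_len(nrow(e) - 1L))
    d <- min(d, .pointSegDist(px, py, e[k, 1L], e[k, 2L],
                              e[k + 1L, 1L], e[k + 1L, 2L]))
  d * pixelSize_um
}

#' Split records into proximal and distal groups
#'
#' Strict partition at the threshold: proximal means distance strictly below
#' it, so a cell at exactly the threshold is distal.
#'
#' @param records data.frame with a `distance_um` column.
#' @param threshold_um boundary (default 100 um).
#' @return list with `proximal` and `distal` data.frames; an empty side is
#'   flagged with attribute `empty_side`.
#' @export
splitProximalDistal <- function(records, threshold_um = 100) {
  stopifnot("distance_um" %in% names(records))
  prox <- records[records$distance_um < threshold_um, , drop = FALSE]
  dist <- records[records$distance_um >= threshold_um, , drop = FALSE]
  out <- list(proximal = prox, distal = dist)
  if (nrow(prox) == 0L || nrow(dist) == 0L) {
    attr(out, "empty_side") <- if (nrow(prox) == 0L) "proximal" else "distal"
    warning("empty ", attr(out, "empty_side"), " group at ", threshold_um,
            " um")
  }
  out
}

#' Two-tailed Mann-Whitney U test
#'
#' U from rank sums with midranks for ties. The two-tailed p-value is exact
#' (Wilcoxon rank-sum distribution) when the pooled sample size is at most
#' 12 and there are no ties, and otherwise uses the normal approximation
#' with tie and continuity corrections. Symmetric in its arguments.
#'
#' @param x,y numeric samples (each nonempty).
#' @param exact_max largest pooled size for the exact tail.
#' @return list with `U` (statistic for `x`), `p` (two-tailed), and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))
#' @export
mannWhitneyU <- function(x, y, exact_max = 12) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both samples must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  hasTies <- any(ties > 1)
  if (!hasTies && nx + ny <= exact_max) {
    # exact tail of the rank-sum distribution
    pLo <- pwilcox(U, nx, ny)
    pHi <- 1 - pwilcox(U - 1, nx, ny)
    p <- min(1, 2 * min(pLo, pHi))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- nx * ny / 2
  N <- nx + ny
  tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tieCorr)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Mann-Whitney threshold sweep over wound distance
#'
#' For each threshold `x`, compares the chosen feature between cells at
#' distance `<= x` and `> x` with the two-tailed Mann-Whitney U test,
#' producing the p-value curve whose minimum locates the distance at which
#' the feature's spatial dependence is sharpest. Thresholds leaving fewer
#' than `min_group_size` cells on either side give `NA`.
#'
#' @param records data.frame with `distance_um` and the feature columns.
#' @param features character vector of feature column names.
#' @param thresholds_um numeric vector of split distances (default 10-400 um
#'   in 10 um steps).
#' @param min_group_size minimum cells per side (default 3).
#' @return data.frame of class `"SweepResult"`: `feature`, `threshold_um`,
#'   `n_below`, `n_above`, `p`, `log10_p`.
#' @export
thresholdSweep <- function(records, features,
                           thresholds_um = seq(10, 400, by = 10),
                           min_group_size = 3) {
  stopifnot("distance_um" %in% names(records),
            all(features %in% names(records)))
  rows <- list()
  for (f in features) {
    vals <- records[[f]]
    for (x in thresholds_um) {
      below <- vals[records$distance_um <= x]
      above <- vals[records$distance_um > x]
      p <- NA_real_
      if (length(below) >= min_group_size && length(above) >= min_group_size)
        p <- mannWhitneyU(below, above)$p
      rows[[length(rows) + 1L]] <-
        data.frame(feature = f, threshold_um = x, n_below = length(below),
                   n_above = length(above), p = p,
                   log10_p = log10(p), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("SweepResult", class(out))
  out
}

#' Kruskal-Wallis test with Dunn's multiple-comparison post test
#'
#' H with tie correction and chi-square p-value (via [stats::kruskal.test]),
#' followed by Dunn z-statistics on mean ranks for every group pair, with
#' Bonferroni-adjusted two-sided p-values.
#'
#' @param groups named list of numeric samples (>= 2 groups, total n >= 3).
#' @return list with `H`, `p`, `df`, and `dunn` (data.frame: `group1`,
#'   `group2`, `z`, `p_unadj`, `p_adj`).
#' @examples
#' kruskalWallisDunn(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))$H
#' @export
kruskalWallisDunn <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group needs at least one observation")
  vals <- unlist(groups, use.names = FALSE)
  N <- length(vals)
  if (N < 3L) stop("need a total of at least 3 observations")
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  if (length(unique(vals)) == 1L) {
    k <- length(groups)
    dunn <- .dunnPairs(names(groups))
    dunn$z <- 0; dunn$p_unadj <- 1; dunn$p_adj <- 1
    return(list(H = 0, p = 1, df = k - 1L, dunn = dunn))
  }
  kw <- kruskal.test(vals, g)
  r <- rank(vals)
  meanRanks <- tapply(r, g, mean)
  ties <- table(r)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  dunn <- .dunnPairs(names(groups))
  z <- p <- numeric(nrow(dunn))
  for (i in seq_len(nrow(dunn))) {
    a <- dunn$group1[i]; b <- dunn$group2[i]
    se <- sqrt((N * (N + 1) / 12 - tieTerm) *
               (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[i] <- (meanRanks[[a]] - meanRanks[[b]]) / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  dunn$z <- z
  dunn$p_unadj <- p
  dunn$p_adj <- p.adjust(p, method = "bonferroni")
  list(H = unname(kw$statistic), p = kw$p.value,
       df = unname(kw$parameter), dunn = dunn)
}

.dunnPairs <- function(nms) {
  idx <- utils::combn(nms, 2L)
  data.frame(group1 = idx[1L, ], group2 = idx[2L, ],
             stringsAsFactors = FALSE)
}

#' Group summary: mean, s.d., s.e.m.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length (optional; one group if
#'   omitted).
#' @return data.frame `group`, `n`, `mean`, `sd`, `sem` (dispersion `NA`
#'   when n = 1).
#' @examples
#' summarizeGroups(c(1, 2, 3))
#' @export
summarizeGroups <- function(values, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(values))
  stopifnot(length(values) == length(groups))
  out <- do.call(rbind, lapply(split(values, groups), function(v) {
    n <- sum(is.finite(v))
    v <- v[is.finite(v)]
    data.frame(n = n, mean = if (n) mean(v) else NA_real_,
               sd = if (n > 1L) sd(v) else NA_real_,
               sem = if (n > 1L) sd(v) / sqrt(n) else NA_real_)
  }))
  out <- cbind(data.frame(group = rownames(out), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}
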