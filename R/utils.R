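# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# stream; seed = NULL uses the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Lognormal draws parameterised by arithmetic mean and standard deviation
# (method of moments); used for nonnegative amplitudes and time constants.
.rlnormM <- function(n, mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Normal draws clipped to [lo, hi].
.rnormT <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

.assertScalarNum <- function(x, name, lo = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lo else x >= lo)
  if (!ok) {
    stop(sprintf("'%s' must be a single finite number %s %s", name,
                 if (strict) ">" else ">=", format(lo)), call. = FALSE)
  }
  invisible(x)
}

# Odd window length (in samples) nearest to `span_s` seconds at step `dt`.
.oddWindow <- function(span_s, dt, minimum = 3L) {
  w <- max(minimum, round(span_s / dt))
  if (w %% 2L == 0L) w <- w + 1L
  as.integer(w)
}

# Centered rolling mean with shrinking windows at the edges.
.rollMean <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Canonical JSON for provenance hashing: stable key order, no whitespace.
.configHash <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}
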