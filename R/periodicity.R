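#' Detect peaks of a distance histogram
#'
#' Smooths the histogram with a centered moving average and returns local
#' maxima whose topographic prominence exceeds a fraction of the local
#' baseline. Two smoothing scales are useful in practice: a narrow window
#' (default 3 bp) resolves the ~10-bp sub-peak lattice of rotationally
#' related positions; a wide window (~21 bp) isolates the main peaks on the
#' nucleosome-repeat (~160 bp) lattice.
#'
#' The self-distance bin d = 0 of a DAC histogram is always excluded.
#'
#' @param h a `distance_histogram`.
#' @param smoothing_window moving-average width in bp (odd; default 3).
#' @param min_prominence minimum peak prominence as a fraction of the local
#'   baseline (default 0.05).
#' @param from,to restrict the search to this distance range.
#' @param refine `"none"` (default) reports the local-maximum bin;
#'   `"centroid"` refines each position to the baseline-subtracted
#'   intensity centroid within one smoothing window — useful for broad
#'   main peaks whose maximum bin is set by residual fine structure.
#' @return object of class `peak_list`: data.frame with columns `position`,
#'   `height` (smoothed value) and `prominence`.
#' @export
find_peaks <- function(h, smoothing_window = 3L, min_prominence = 0.05,
                       from = 1L, to = h$max_distance,
                       refine = c("none", "centroid")) {
  refine <- match.arg(refine)
  stopifnot(inherits(h, "distance_histogram"))
  if (length(h$values) <= smoothing_window)
    stop("histogram shorter than smoothing window")
  from <- max(from, 1L)
  v <- h$values
  v[1L] <- 0  # self-distance bin never participates
  s <- moving_average(v, smoothing_window)
  d <- h$distance
  idx <- which(d >= from & d <= to)
  pk <- integer()
  n <- length(s)
  eps <- max(abs(s), 1) * 1e-9
  for (i in idx) {
    if (i == 1L || i >= n) next
    if (s[i] > s[i - 1L] + eps && s[i] >= s[i + 1L] - eps) {
      # plateau: the run of (numerically) equal values must end in a
      # decrease; the plateau center is reported as the peak position
      j <- i
      while (j < n && abs(s[j + 1L] - s[i]) <= eps) j <- j + 1L
      if (j < n && s[j + 1L] < s[i] - eps) pk <- c(pk, (i + j) %/% 2L)
    }
  }
  pk <- unique(pk)
  pos <- integer(); height <- numeric(); prom <- numeric()
  for (i in pk) {
    lo <- local_min(s, i, -1L, min(idx)); hi <- local_min(s, i, 1L, max(idx))
    baseline <- (lo + hi) / 2
    p <- s[i] - baseline
    keep <- if (baseline > 0) p >= min_prominence * baseline else s[i] > 0
    if (keep) {
      position <- d[i]
      if (refine == "centroid") {
        r <- smoothing_window
        win <- max(1L, i - r):min(length(s), i + r)
        wts <- s[win] - min(s[win])
        if (sum(wts) > 0) position <- sum(d[win] * wts) / sum(wts)
      }
      pos <- c(pos, position); height <- c(height, s[i]); prom <- c(prom, p)
    }
  }
  structure(data.frame(position = pos, height = height, prominence = prom),
            class = c("peak_list", "data.frame"),
            smoothing_window = smoothing_window,
            min_prominence = min_prominence)
}

moving_average <- function(v, w) {
  w <- as.integer(w)
  if (w <= 1L) return(v)
  k <- rep(1 / w, w)
  s <- stats::filter(v, k, sides = 2)
  s <- as.numeric(s)
  # truncated partial windows at the edges
  half <- (w - 1L) %/% 2L
  n <- length(v)
  for (i in which(is.na(s))) {
    a <- max(1L, i - half); b <- min(n, i + half)
    s[i] <- mean(v[a:b])
  }
  s
}

local_min <- function(s, i, step, bound) {
  # walk from a peak until the series turns upward; return the minimum found
  j <- i
  while (j + step >= min(bound, j) && j + step <= max(bound, j) &&
         j + step >= 1L && j + step <= length(s)) {
    if (s[j + step] > s[j]) break
    j <- j + step
  }
  s[j]
}

#' Assign harmonic indices to peak positions
#'
#' Maps each peak position to the nearest multiple of an approximate period:
#' `index = round(position / approximate_period)`. Repeated indices are
#' allowed — the members of a split first peak (e.g. sub-peaks at 151, 162
#' and 171 bp around one nucleosome repeat) all map to index 1. An index of
#' zero signals that the period guess is too large for the data and is an
#' error.
#'
#' @param positions peak positions in bp.
#' @param approximate_period rough period in bp (> 0).
#' @return integer vector of harmonic indices.
#' @export
assign_indices <- function(positions, approximate_period) {
  stopifnot(approximate_period > 0)
  idx <- as.integer(round(positions / approximate_period))
  if (any(idx < 1L))
    stop("peak position(s) map to harmonic index 0; ",
         "use a smaller approximate_period or drop leading peaks")
  idx
}

#' Estimate a period by linear regression of peak positions
#'
#' Ordinary least squares of peak position on harmonic index. The slope is
#' the period estimate: applied to the main peaks of a DAC histogram it
#' estimates the nucleosome repeat length (~162 bp in yeast); applied to the
#' ~10-bp sub-peak lattice it estimates the DNA helical period (~10.25 bp).
#'
#' @param positions peak positions in bp (>= 2 values).
#' @param indices positive integer harmonic indices, same length; repeats
#'   allowed.
#' @return object of class `period_fit` with fields `slope` (bp per index),
#'   `intercept` (bp), `r` (Pearson correlation), `n`, and the inputs.
#' @export
fit_period <- function(positions, indices) {
  if (length(positions) != length(indices))
    stop("positions and indices must have equal length")
  if (length(positions) < 2L) stop("need at least 2 points")
  if (any(indices < 1)) stop("indices must be positive")
  if (length(unique(indices)) < 2L)
    stop("degenerate fit: all harmonic indices identical")
  fit <- stats::lm(positions ~ indices)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r = stats::cor(positions, indices),
         n = length(positions),
         positions = positions, indices = indices),
    class = "period_fit")
}

#' @export
print.period_fit <- function(x, digits = 2, ...) {
  cat(sprintf("period fit: slope = %s bp/index (raw %.6g), intercept = %.3g bp, r = %.4f, n = %d\n",
              format(round(x$slope, digits)), x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' @export
coef.period_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
plot.period_fit <- function(x, ...) {
  graphics::plot(x$indices, x$positions, xlab = "harmonic index",
                 ylab = "peak position (bp)", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Score an envelope discontinuity in a distance histogram
#'
#' The envelope of a DAC profile is the sequence of histogram values at its
#' sub-peaks. When all cells carry nucleosome arrays with a single spacing,
#' the envelope is a smooth curve; when cell subpopulations carry arrays
#' with different spacings, the envelope jumps where the long-spacing
#' population's first-neighbour distances begin (around 80-90 bp for a
#' 160 bp vs 180-250 bp mixture). The score is the largest positive jump
#' between consecutive envelope values inside `probe_range`, normalized by
#' the median absolute consecutive change outside it; a smooth envelope
#' scores near 1, a genuine break scores far above the threshold.
#'
#' @param h a `distance_histogram`.
#' @param subpeaks a `peak_list` of sub-peaks spanning `probe_range`
#'   (at least 5).
#' @param probe_range numeric length-2: distance window (bp) in which a
#'   discontinuity is sought (e.g. `c(70, 100)`).
#' @param threshold score above which a discontinuity is called (default 3).
#' @return object of class `envelope_report`: list with
#'   `subpeak_positions`, `envelope_values`, `discontinuity_score` and
#'   `discontinuity_location` (NA when the score is at or below threshold).
#' @export
envelope_discontinuity <- function(h, subpeaks, probe_range, threshold = 3) {
  stopifnot(inherits(h, "distance_histogram"),
            length(probe_range) == 2L, probe_range[1L] < probe_range[2L])
  pos <- subpeaks$position
  if (length(pos) < 5L || min(pos) > probe_range[1L] ||
      max(pos) < probe_range[2L])
    stop("need at least 5 sub-peaks spanning probe_range")
  env <- h$values[match(pos, h$distance)]
  jumps <- diff(env)
  land <- pos[-1L]
  inside <- land >= probe_range[1L] & land <= probe_range[2L]
  outside <- !inside
  norm <- stats::median(abs(jumps[outside]))
  best <- which(inside & jumps > 0)
  if (!length(best) || max(jumps[best]) <= 0) {
    score <- 0
    loc <- NA_integer_
  } else {
    top <- best[which.max(jumps[best])]
    score <- if (norm > 0) jumps[top] / norm else Inf
    loc <- land[top]
  }
  if (score <= threshold) loc <- NA_integer_
  structure(list(subpeak_positions = pos, envelope_values = env,
                 discontinuity_score = score,
                 discontinuity_location = loc,
                 probe_range = probe_range, threshold = threshold),
            class = "envelope_report")
}

#' @export
print.envelope_report <- function(x, ...) {
  cat(sprintf("envelope over %d sub-peaks; discontinuity score %.2f",
              length(x$subpeak_positions), x$discontinuity_score))
  if (is.na(x$discontinuity_location)) {
    cat(" (continuous)\n")
  } else {
    cat(sprintf(" at %d bp\n", x$discontinuity_location))
  }
  invisible(x)
}
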