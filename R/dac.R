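#' Tabulate fragment anchor positions
#'
#' Collapses a [FragmentSet] into per-position occurrence counts, the input
#' of the distance correlation functions. Fragments are strandless
#' intervals, so each fragment contributes two anchors: one defined from its
#' left (5' top-strand) end and one from its right end. The distance
#' correlations sum the histograms over both anchor sides ("both strands").
#'
#' With `anchor = "start"` the anchors are the outermost bases of the
#' fragment (left: `start`; right: last base). With `anchor = "center"` both
#' anchors are the fragment midpoint; for even lengths the left-side anchor
#' uses the round-up rule (see [fragment_dyads()]) and the right-side anchor
#' its mirror image (round-down), so the two sides stay symmetric.
#'
#' @param fs a non-empty [FragmentSet].
#' @param anchor `"start"` or `"center"`.
#' @return object of class `position_counts`: per-chromosome count tables
#'   for the left and right anchor sides.
#' @export
position_counts <- function(fs, anchor = c("start", "center")) {
  stopifnot(inherits(fs, "FragmentSet"))
  anchor <- match.arg(anchor)
  if (length(fs) == 0L) stop("empty FragmentSet")
  fr <- fs$fragments
  len <- fr$end - fr$start
  if (anchor == "start") {
    left <- fr$start
    right <- fr$end - 1L
  } else {
    left <- fr$start + len %/% 2L
    right <- fr$start + (len - 1L) %/% 2L
  }
  structure(
    list(left = count_positions(fr$chrom, left),
         right = count_positions(fr$chrom, right),
         anchor = anchor,
         n_fragments = nrow(fr)),
    class = "position_counts")
}

count_positions <- function(chrom, pos) {
  lapply(split(pos, chrom), function(p) {
    t <- table(p)
    list(pos = as.integer(names(t)), count = as.integer(t))
  })
}

#' Build a position-count table directly from counts
#'
#' Convenience constructor for worked examples and small designed inputs:
#' specify anchor coordinates and their occurrence counts per chromosome.
#' Both anchor sides are set to the same table.
#'
#' @param chrom chromosome names.
#' @param pos anchor coordinates (bp).
#' @param count positive integer occurrence counts.
#' @param anchor anchor mode label.
#' @return a `position_counts` object.
#' @export
position_count_table <- function(chrom, pos, count,
                                 anchor = c("start", "center")) {
  anchor <- match.arg(anchor)
  chrom <- rep_len(as.character(chrom), length(pos))
  stopifnot(length(pos) == length(count), all(count >= 1))
  side <- lapply(split(seq_along(pos), as.character(chrom)), function(i) {
    o <- order(pos[i])
    if (anyDuplicated(pos[i])) stop("duplicate positions within a chromosome")
    list(pos = as.integer(pos[i][o]), count = as.integer(count[i][o]))
  })
  structure(list(left = side, right = side, anchor = anchor,
                 n_fragments = sum(count)),
            class = "position_counts")
}

#' @export
print.position_counts <- function(x, ...) {
  cat("position_counts:", x$n_fragments, "fragments,",
      length(x$left), "chromosome(s), anchor =", x$anchor, "\n")
  invisible(x)
}

# Autocorrelation of a sparse integer count vector up to lag D, exact pair
# counts. FFT over the dense span; zero padding >= D+1 prevents circular
# wrap at the lags we keep.
count_autocorr <- function(pos, count, max_distance) {
  vals <- numeric(max_distance)
  if (length(pos) < 2L) return(vals)
  off <- pos - min(pos)
  span <- max(off) + 1L
  n <- stats::nextn(span + max_distance + 1L)
  x <- numeric(n)
  x[off + 1L] <- count
  f <- stats::fft(x)
  r <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / n
  d <- seq_len(min(max_distance, span - 1L))
  vals[d] <- r[d + 1L]
  round(vals)
}

count_crosscorr <- function(pos_a, count_a, pos_b, count_b, max_distance) {
  # returns c(value at lag 0, values at |lag| 1..max_distance)
  vals <- numeric(max_distance + 1L)
  if (!length(pos_a) || !length(pos_b)) return(vals)
  o <- min(min(pos_a), min(pos_b))
  offa <- pos_a - o
  offb <- pos_b - o
  span <- max(max(offa), max(offb)) + 1L
  n <- stats::nextn(span + max_distance + 1L)
  xa <- numeric(n); xa[offa + 1L] <- count_a
  xb <- numeric(n); xb[offb + 1L] <- count_b
  cc <- Re(stats::fft(Conj(stats::fft(xa)) * stats::fft(xb),
                      inverse = TRUE)) / n
  vals[1L] <- cc[1L]
  d <- seq_len(min(max_distance, span - 1L))
  vals[d + 1L] <- cc[d + 1L] + cc[n - d + 1L]
  if (max_distance >= span) {
    # lags beyond the span are zero; nothing to add
  }
  round(vals)
}

new_distance_histogram <- function(left, right, max_distance, mode,
                                   weighting, anchor) {
  structure(
    list(distance = 0:max_distance,
         values = left + right,
         left = left, right = right,
         max_distance = max_distance,
         mode = mode, weighting = weighting, anchor = anchor,
         self_flagged = identical(mode, "DAC")),
    class = "distance_histogram")
}

#' Distance auto-correlation (DAC) of nucleosome positions
#'
#' For every unordered pair of distinct anchor positions on the same
#' chromosome separated by `d` bp, the pair contributes the product of the
#' two occurrence counts to `DAC[d]` (multiplicity weighting): two positions
#' occupied 5 and 10 times contribute 5 x 10 = 50. With
#' `weighting = "coincidence"` every occupied position counts once
#' (counts clamped to 1), the convention of start-to-start coincidence
#' numbers. The histogram is computed once on left anchors and once on
#' right anchors and the two are summed ("both strands").
#'
#' `DAC[0]` is the within-position pair count `sum(c * (c - 1) / 2)` per
#' anchor side; it is a self-distance term, flagged and excluded from
#' plots and peak detection by default.
#'
#' @param pc a `position_counts` object (see [position_counts()]).
#' @param max_distance largest distance (bp) to tabulate.
#' @param weighting `"multiplicative"` (default) or `"coincidence"`.
#' @return object of class `distance_histogram` with fields `distance`
#'   (0..max_distance), `values` (left + right anchor sums) and the
#'   per-side components `left`, `right`.
#' @export
compute_dac <- function(pc, max_distance,
                        weighting = c("multiplicative", "coincidence")) {
  stopifnot(inherits(pc, "position_counts"))
  weighting <- match.arg(weighting)
  if (max_distance < 1L) stop("max_distance must be >= 1")
  side_sum <- function(side) {
    vals <- numeric(max_distance + 1L)
    for (tab in side) {
      cnt <- if (weighting == "coincidence") rep(1L, length(tab$count))
             else tab$count
      vals[1L] <- vals[1L] + sum(cnt * (cnt - 1) / 2)
      vals[-1L] <- vals[-1L] + count_autocorr(tab$pos, cnt, max_distance)
    }
    vals
  }
  new_distance_histogram(side_sum(pc$left), side_sum(pc$right),
                         max_distance, "DAC", weighting, pc$anchor)
}

#' Distance cross-correlation (DCC) between two datasets
#'
#' For every ordered pair of anchor positions, one from each dataset, on the
#' same chromosome with `|x - y| = d`, the pair contributes the product of
#' the occurrence counts to `DCC[d]`. Left-anchor and right-anchor sums are
#' added as in [compute_dac()]. `DCC[0]` (co-located positions) is included.
#'
#' @param a,b `position_counts` for the two datasets (same genome).
#' @param max_distance largest distance (bp) to tabulate.
#' @return a `distance_histogram` with `mode = "DCC"`.
#' @export
compute_dcc <- function(a, b, max_distance) {
  stopifnot(inherits(a, "position_counts"), inherits(b, "position_counts"))
  if (max_distance < 1L) stop("max_distance must be >= 1")
  ca <- names(a$left); cb <- names(b$left)
  common <- intersect(ca, cb)
  if (!setequal(ca, cb))
    warning("chromosome universes differ; restricting to ",
            length(common), " shared chromosome(s)")
  side_sum <- function(sa, sb) {
    vals <- numeric(max_distance + 1L)
    for (ch in common) {
      ta <- sa[[ch]]; tb <- sb[[ch]]
      vals <- vals + count_crosscorr(ta$pos, ta$count, tb$pos, tb$count,
                                     max_distance)
    }
    vals
  }
  h <- new_distance_histogram(side_sum(a$left, b$left),
                              side_sum(a$right, b$right),
                              max_distance, "DCC", "multiplicative", a$anchor)
  h$self_flagged <- FALSE
  h
}

#' Restrict fragments to gene neighbourhoods
#'
#' Keeps fragments whose midpoint (dyad, round-up rule) lies within the
#' gene body of any listed gene extended by `pad` bp on both sides. A
#' fragment overlapping several genes is kept once; multiplicity of
#' identical fragments is preserved. Used to compute locus- or
#' gene-set-restricted distance correlations.
#'
#' @param fs a [FragmentSet].
#' @param genes gene table (see [read_genes()]).
#' @param pad extension in bp on each side of the gene body (default 200).
#' @return the restricted [FragmentSet].
#' @export
restrict_to_regions <- function(fs, genes, pad = 200L) {
  stopifnot(inherits(fs, "FragmentSet"), pad >= 0)
  if (is.null(genes) || nrow(genes) == 0L) stop("empty gene list")
  reg <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(1L, genes$body_start - as.integer(pad)),
                     end = genes$body_end + as.integer(pad)))
  mid <- GenomicRanges::GRanges(
    fs$fragments$chrom,
    IRanges::IRanges(start = fragment_dyads(fs, one_based = TRUE),
                     width = 1L))
  keep <- GenomicRanges::countOverlaps(mid, reg) > 0L
  subset_fragments(fs, keep, sprintf("gene regions +/-%d bp", as.integer(pad)))
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("%s histogram (weighting: %s, anchor: %s), distances 0-%d bp\n",
              x$mode, x$weighting, x$anchor, x$max_distance))
  nz <- sum(x$values[-1L] > 0)
  cat("  non-zero bins (d >= 1):", nz,
      if (x$self_flagged) "; d = 0 is a flagged self-distance term" else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.distance_histogram <- function(x, ...) {
  data.frame(distance_bp = x$distance, value = x$values,
             mode = x$mode, weighting = x$weighting, anchor_mode = x$anchor,
             stringsAsFactors = FALSE)
}

#' @export
plot.distance_histogram <- function(x, from = 1L, to = x$max_distance, ...) {
  d <- x$distance
  keep <- d >= max(from, if (x$self_flagged) 1L else 0L) & d <= to
  graphics::plot(d[keep], x$values[keep], type = "l",
                 xlab = "distance (bp)",
                 ylab = sprintf("%s value", x$mode), ...)
  invisible(x)
}

#' Write a distance histogram as TSV
#' @param h a `distance_histogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(h, path) {
  utils::write.table(as.data.frame(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a distance histogram written by [write_histogram()]
#' @param path TSV path.
#' @return a `distance_histogram`.
#' @export
read_histogram <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("distance_bp", "value") %in% names(tab)))
  md <- max(tab$distance_bp)
  vals <- numeric(md + 1L)
  vals[tab$distance_bp + 1L] <- tab$value  # tolerate histograms starting at d = 1
  h <- new_distance_histogram(vals / 2, vals / 2, md,
                              if ("mode" %in% names(tab)) tab$mode[1L] else "DAC",
                              if ("weighting" %in% names(tab)) tab$weighting[1L]
                              else "multiplicative",
                              if ("anchor_mode" %in% names(tab))
                                tab$anchor_mode[1L] else "start")
  h$values <- vals
  h
}
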