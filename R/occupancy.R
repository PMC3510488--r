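#' Normalized nucleosome occupancy track
#'
#' The raw occupancy of a nucleotide is the number of fragments covering it.
#' Values are normalized by the average raw coverage per base pair across
#' the whole genome, so the genome-wide mean of the normalized track is
#' exactly 1 and tracks from libraries of different depth are comparable.
#'
#' @param fs a non-empty [FragmentSet].
#' @param genome_lengths named integer vector of chromosome lengths (bp).
#' @return object of class `occupancy_track`: list with `tracks` (named list
#'   of per-chromosome numeric vectors) and `norm_constant` (mean raw
#'   coverage per bp).
#' @export
occupancy_track <- function(fs, genome_lengths) {
  stopifnot(inherits(fs, "FragmentSet"))
  if (length(fs) == 0L) stop("empty FragmentSet")
  if (is.null(names(genome_lengths)))
    stop("genome_lengths must be named by chromosome")
  fr <- fs$fragments
  unknown <- setdiff(unique(fr$chrom), names(genome_lengths))
  if (length(unknown))
    stop("fragment chromosome not in genome_lengths: ", unknown[1L])
  tracks <- list()
  for (ch in names(genome_lengths)) {
    L <- as.integer(genome_lengths[[ch]])
    sel <- fr$chrom == ch
    if (any(fr$end[sel] > L))
      stop("fragment beyond end of ", ch)
    delta <- numeric(L + 1L)
    if (any(sel)) {
      add <- tabulate(fr$start[sel] + 1L, nbins = L + 1L)
      sub <- tabulate(fr$end[sel] + 1L, nbins = L + 1L)
      delta <- add - sub
    }
    tracks[[ch]] <- cumsum(delta)[seq_len(L)]
  }
  total_cov <- sum(vapply(tracks, sum, numeric(1)))
  norm <- total_cov / sum(as.numeric(genome_lengths))
  structure(list(tracks = lapply(tracks, function(t) t / norm),
                 norm_constant = norm),
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat("occupancy_track:", length(x$tracks), "chromosome(s);",
      "normalization constant", format(x$norm_constant, digits = 4), "\n")
  invisible(x)
}

#' Composite TSS-aligned occupancy profile
#'
#' Averages the normalized occupancy track across genes in a window around
#' the transcription start site, in transcription coordinates: minus-strand
#' genes are coordinate-flipped so positive offsets always run with
#' transcription. Each usable gene contributes equally; genes whose window
#' exceeds the chromosome bounds are dropped with a warning.
#'
#' @param track an [occupancy_track()] result.
#' @param genes gene table (see [read_genes()]).
#' @param window length-2 numeric `c(upstream, downstream)` in bp
#'   (default 500 upstream, 2000 downstream).
#' @return object of class `composite_profile`: data.frame with columns
#'   `offset` (bp relative to TSS, negative upstream) and `mean`; attribute
#'   `n_genes`.
#' @export
composite_tss_profile <- function(track, genes, window = c(500L, 2000L)) {
  stopifnot(inherits(track, "occupancy_track"), length(window) == 2L)
  up <- as.integer(window[1L]); down <- as.integer(window[2L])
  width <- up + down + 1L
  acc <- numeric(width)
  used <- 0L; dropped <- 0L
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    tr <- track$tracks[[ch]]
    if (is.null(tr)) { dropped <- dropped + 1L; next }
    tss <- genes$tss[i]
    if (genes$strand[i] == "+") {
      a <- tss - up; b <- tss + down
      if (a < 1L || b > length(tr)) { dropped <- dropped + 1L; next }
      acc <- acc + tr[a:b]
    } else {
      a <- tss - down; b <- tss + up
      if (a < 1L || b > length(tr)) { dropped <- dropped + 1L; next }
      acc <- acc + rev(tr[a:b])
    }
    used <- used + 1L
  }
  if (used == 0L) stop("no usable genes within chromosome bounds")
  if (dropped > 0L)
    warning(dropped, " gene(s) dropped: window exceeds chromosome bounds")
  structure(data.frame(offset = seq(-up, down), mean = acc / used),
            class = c("composite_profile", "data.frame"),
            n_genes = used, window = c(up, down))
}

#' @export
plot.composite_profile <- function(x, ...) {
  graphics::plot(x$offset, x$mean, type = "l",
                 xlab = "position relative to TSS (bp)",
                 ylab = "mean normalized occupancy", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Dyad-position histogram for a region
#'
#' Counts fragment midpoints (dyads, round-up rule for even lengths) at each
#' base pair of a region — the per-locus view in which mutually exclusive
#' overlapping nucleosome positions appear as clusters of occupied dyads.
#'
#' @param fs a [FragmentSet].
#' @param region either a string `"chrom:start-end"` (1-based inclusive) or
#'   a list/data.frame with `chrom`, `start`, `end`.
#' @return object of class `dyad_histogram`: data.frame with columns `pos`
#'   (1-based) and `count`; attribute `region`.
#' @export
dyad_histogram <- function(fs, region) {
  stopifnot(inherits(fs, "FragmentSet"))
  reg <- parse_region(region)
  dy <- fragment_dyads(fs, one_based = TRUE)
  sel <- fs$fragments$chrom == reg$chrom & dy >= reg$start & dy <= reg$end
  counts <- tabulate(dy[sel] - reg$start + 1L,
                     nbins = reg$end - reg$start + 1L)
  structure(data.frame(pos = seq(reg$start, reg$end), count = counts),
            class = c("dyad_histogram", "data.frame"), region = reg)
}

parse_region <- function(region) {
  if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
    if (length(m) != 4L) stop("cannot parse region: ", region)
    reg <- list(chrom = m[2L], start = as.integer(m[3L]),
                end = as.integer(m[4L]))
  } else {
    reg <- list(chrom = as.character(region$chrom),
                start = as.integer(region$start),
                end = as.integer(region$end))
  }
  if (reg$start > reg$end) stop("region start must be <= end")
  reg
}

#' @export
plot.dyad_histogram <- function(x, ...) {
  graphics::plot(x$pos, x$count, type = "h", xlab = "dyad position (bp)",
                 ylab = "sequences per dyad", ...)
  invisible(x)
}

#' Write an occupancy track as bedGraph
#' @param track an `occupancy_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "occupancy_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$tracks)) {
    v <- track$tracks[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based bedGraph starts
    keep <- r$values != 0
    if (any(keep))
      utils::write.table(
        data.frame(ch, starts[keep], ends[keep],
                   signif(r$values[keep], 6)),
        con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
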