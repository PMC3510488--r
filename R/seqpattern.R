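#' Extract dyad-centered, oriented fragment sequences
#'
#' Pulls the genomic sequence of each fragment in a fixed dyad-centered
#' frame: `73 + extension` bp on each side of the dyad (round-up rule), so
#' all rows share the 147-bp core frame with the dyad between base-pair
#' steps 73 and 74 of the core (step 73.5) regardless of the underlying
#' fragment length (147-152 bp cores are center-aligned on their dyads).
#' Fragments assigned to minus-strand genes are reverse-complemented so all
#' rows read in the direction of transcription.
#'
#' @param fs a [FragmentSet]. If its fragment table carries a `strand`
#'   column (e.g. from [select_positional_nucleosomes()]), that orientation
#'   is used directly.
#' @param genome a [Biostrings::DNAStringSet] (see [read_genome()]).
#' @param extension linker extension in bp on each side (default 20).
#' @param orient_by optional gene table; each fragment whose dyad falls in a
#'   minus-strand gene body is reverse-complemented.
#' @return object of class `aligned_seq_matrix`: list with `seqs`
#'   (equal-length character vector), `width`, `extension`, `dyad_column`.
#' @export
extract_aligned <- function(fs, genome, extension = 20L, orient_by = NULL) {
  stopifnot(inherits(fs, "FragmentSet"))
  if (is.null(genome)) stop("a genome is required")
  if (length(fs) == 0L) stop("empty FragmentSet")
  hw <- 73L + as.integer(extension)
  dy <- fragment_dyads(fs)                       # 0-based
  chrom <- fs$fragments$chrom
  strand <- fragment_strands(fs, orient_by)
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  start1 <- dy - hw + 1L       # 1-based window start: 0-based dy - hw
  end1 <- dy + hw + 1L         # 1-based window end:   0-based dy + hw
  ok <- chrom %in% names(clen) & start1 >= 1L & end1 <= clen[chrom]
  if (any(!ok))
    warning(sum(!ok), " fragment(s) dropped: window exceeds chromosome bounds")
  seqs <- character(sum(ok))
  idx <- which(ok)
  for (ch in unique(chrom[idx])) {
    sel <- idx[chrom[idx] == ch]
    v <- Biostrings::Views(genome[[ch]], start = start1[sel], end = end1[sel])
    seqs[match(sel, idx)] <- as.character(v)
  }
  minus <- strand[idx] == "-"
  if (any(minus))
    seqs[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus])))
  structure(list(seqs = seqs, width = 2L * hw + 1L,
                 extension = as.integer(extension),
                 dyad_column = hw + 1L),
            class = "aligned_seq_matrix")
}

fragment_strands <- function(fs, orient_by) {
  n <- length(fs)
  if (!is.null(fs$fragments$strand)) return(fs$fragments$strand)
  strand <- rep("+", n)
  if (!is.null(orient_by) && nrow(orient_by)) {
    body <- GenomicRanges::GRanges(
      orient_by$chrom,
      IRanges::IRanges(start = orient_by$body_start,
                       end = orient_by$body_end))
    mid <- GenomicRanges::GRanges(
      fs$fragments$chrom,
      IRanges::IRanges(start = fragment_dyads(fs, one_based = TRUE),
                       width = 1L))
    hits <- GenomicRanges::findOverlaps(mid, body, select = "first")
    assigned <- !is.na(hits)
    strand[assigned] <- orient_by$strand[hits[assigned]]
  }
  strand
}

#' @export
print.aligned_seq_matrix <- function(x, ...) {
  cat("aligned_seq_matrix:", length(x$seqs), "sequences x", x$width,
      "nt (extension", x$extension, "bp; dyad at column",
      paste0(x$dyad_column, ")"), "\n")
  invisible(x)
}

#' Dinucleotide class profile of aligned sequences
#'
#' At every base-pair step of the alignment, computes the fraction of
#' sequences whose dimer belongs to each class: WW (AA, AT, TA, TT),
#' SS (GG, GC, CG, CC), WS and SW, where W = A/T and S = G/C. Steps
#' containing N in a sequence are excluded from that step's denominator, so
#' the four fractions always sum to 1 where defined. The ~10-bp
#' counter-phase oscillation of WW and SS along the nucleosome core encodes
#' rotational positioning.
#'
#' Optional dyad symmetrization averages each profile with its mirror image
#' about the central step (the dyad; step 73.5 in 147-bp core coordinates).
#' Smoothing is a centered running mean applied after class fractions (and
#' after symmetrization), edges truncated.
#'
#' @param m an [extract_aligned()] result.
#' @param smoothing_window running-mean width in steps (default 3).
#' @param symmetrize average with the dyad-mirrored profile (default FALSE).
#' @return object of class `dinuc_profile`: data.frame with columns `step`,
#'   raw fractions `WW`, `SS`, `WS`, `SW` and their `_smooth` versions.
#' @export
dinuc_profile <- function(m, smoothing_window = 3L, symmetrize = FALSE) {
  stopifnot(inherits(m, "aligned_seq_matrix"))
  n <- length(m$seqs)
  if (n == 0L) stop("no sequences")
  W <- m$width
  code <- vapply(seq_len(W), function(i) {
    b <- substr(m$seqs, i, i)
    ifelse(b %in% c("A", "T"), 1L, ifelse(b %in% c("G", "C"), 2L, 0L))
  }, integer(n))
  if (n == 1L) code <- matrix(code, nrow = 1L)
  steps <- seq_len(W - 1L)
  frac <- matrix(NA_real_, nrow = length(steps), ncol = 4L,
                 dimnames = list(NULL, c("WW", "SS", "WS", "SW")))
  any_valid <- FALSE
  for (i in steps) {
    a <- code[, i]; b <- code[, i + 1L]
    valid <- a > 0L & b > 0L
    nv <- sum(valid)
    if (nv == 0L) next
    any_valid <- TRUE
    frac[i, ] <- c(sum(a == 1L & b == 1L), sum(a == 2L & b == 2L),
                   sum(a == 1L & b == 2L), sum(a == 2L & b == 1L)) / nv
  }
  if (!any_valid) stop("all steps contain N only")
  if (symmetrize) frac <- (frac + frac[rev(steps), , drop = FALSE]) / 2
  sm <- apply(frac, 2L, moving_average, w = smoothing_window)
  colnames(sm) <- paste0(colnames(frac), "_smooth")
  structure(cbind(data.frame(step = steps), as.data.frame(frac),
                  as.data.frame(sm)),
            class = c("dinuc_profile", "data.frame"),
            smoothing_window = as.integer(smoothing_window),
            symmetrized = isTRUE(symmetrize),
            dyad_step = W / 2, n_seqs = n, extension = m$extension)
}

#' @export
plot.dinuc_profile <- function(x, ...) {
  graphics::plot(x$step, x$WW_smooth, type = "l", col = "blue",
                 xlab = "base-pair step", ylab = "dimer frequency",
                 ylim = range(c(x$WW_smooth, x$SS_smooth), na.rm = TRUE), ...)
  graphics::lines(x$step, x$SS_smooth, col = "red")
  graphics::abline(v = attr(x, "dyad_step"), lty = 2)
  graphics::legend("topright", legend = c("WW", "SS"), lty = 1,
                   col = c("blue", "red"), bty = "n")
  invisible(x)
}

#' Write a dinucleotide profile as TSV
#' @param p a `dinuc_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dinuc_profile <- function(p, path) {
  meta <- sprintf("# smoothing_window=%d symmetrized=%s n_seqs=%d dyad_step=%s",
                  attr(p, "smoothing_window"), attr(p, "symmetrized"),
                  attr(p, "n_seqs"), format(attr(p, "dyad_step")))
  writeLines(meta, path)
  suppressWarnings(utils::write.table(p, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

# cut-site windows: label 0 = last genomic base 5' of the fragment,
# +1 = first fragment base; the 3' end is reverse-complemented into the
# same frame. Returns per-end strings of length 2*flank in label order
# -(flank-1)..0,+1..+flank, plus the index of the kept fragments.
end_contexts <- function(fs, genome, flank) {
  fr <- fs$fragments
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  ok <- fr$chrom %in% names(clen) &
    fr$start - flank >= 0L & fr$end + flank <= clen[fr$chrom]
  if (any(!ok))
    warning(sum(!ok), " fragment(s) dropped: no ", flank,
            "-bp flank at a chromosome edge")
  idx <- which(ok)
  left <- character(length(idx)); right <- character(length(idx))
  for (ch in unique(fr$chrom[idx])) {
    sel <- idx[fr$chrom[idx] == ch]
    pos <- match(sel, idx)
    lv <- Biostrings::Views(genome[[ch]],
                            start = fr$start[sel] - flank + 1L,
                            end = fr$start[sel] + flank)
    left[pos] <- as.character(lv)
    rv <- Biostrings::Views(genome[[ch]],
                            start = fr$end[sel] - flank + 1L,
                            end = fr$end[sel] + flank)
    right[pos] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(as.character(rv))))
  }
  list(left = left, right = right, idx = idx)
}

#' MNase cleavage-site consensus
#'
#' Tabulates base frequencies around both cleavage sites of every fragment.
#' Position 0 is the last genomic base 5' of the fragment and +1 the first
#' fragment base; the 3'-end context is reverse-complemented so both ends
#' share the same cut geometry. `ww_cut_fraction` is the fraction of ends
#' whose (0, +1) dimer is WW — the W|W cut preference of micrococcal
#' nuclease.
#'
#' @param fs a [FragmentSet].
#' @param genome a [Biostrings::DNAStringSet].
#' @param flank bases tabulated on each side of the cut (>= 2, default 3):
#'   labels run from `-(flank-1)` to `+flank`.
#' @return object of class `end_consensus`: list with `position_labels`,
#'   `base_freqs` (positions x A/C/G/T matrix), `ww_cut_fraction`,
#'   `n_ends` and a display `consensus` string.
#' @export
end_consensus <- function(fs, genome, flank = 3L) {
  stopifnot(inherits(fs, "FragmentSet"), flank >= 2L)
  flank <- as.integer(flank)
  ctx <- end_contexts(fs, genome, flank)
  ends <- c(ctx$left, ctx$right)
  if (!length(ends)) stop("no fragments with sufficient flank")
  labels <- seq(-(flank - 1L), flank)
  freqs <- matrix(0, nrow = length(labels), ncol = 4L,
                  dimnames = list(labels, c("A", "C", "G", "T")))
  for (i in seq_along(labels)) {
    b <- substr(ends, i, i)
    t <- table(factor(b, levels = c("A", "C", "G", "T")))
    freqs[i, ] <- as.numeric(t) / sum(t)
  }
  z <- substr(ends, flank, flank)       # label 0
  p1 <- substr(ends, flank + 1L, flank + 1L)  # label +1
  ww <- mean(z %in% c("A", "T") & p1 %in% c("A", "T"))
  structure(list(position_labels = labels, base_freqs = freqs,
                 ww_cut_fraction = ww, n_ends = length(ends),
                 consensus = consensus_string(freqs, labels)),
            class = "end_consensus")
}

consensus_string <- function(freqs, labels) {
  # plurality base when it dominates, else the W/S class, else N
  sym <- apply(freqs, 1L, function(f) {
    if (max(f) > 0.5) return(names(f)[which.max(f)])
    if (f["A"] + f["T"] >= 0.75) return("W")
    if (f["G"] + f["C"] >= 0.75) return("S")
    "N"
  })
  cut <- which(labels == 0L)
  paste0(paste(sym[seq_len(cut)], collapse = ""), "|",
         paste(sym[-seq_len(cut)], collapse = ""))
}

#' @export
print.end_consensus <- function(x, ...) {
  cat(sprintf("MNase end consensus over %d ends: %s  (W|W cuts: %.1f%%)\n",
              x$n_ends, x$consensus, 100 * x$ww_cut_fraction))
  invisible(x)
}

#' Select fragments without MNase-preferred cut contexts
#'
#' Retains fragments whose cleavage contexts are not the W|W dimer the
#' enzyme prefers. With the default `rule = "no_ww"`, a fragment is kept
#' when the (0, +1) cut dimer is **not** WW (not both bases A/T) at both
#' ends — with ~80% of cuts being W|W this keeps a few percent of
#' fragments, the non-preferred-cut subset. `rule = "no_w"` is the stricter
#' variant requiring both cut bases to be G/C. Comparing the dinucleotide
#' profile of the subset with the full set tests whether the observed WW/SS
#' periodicity is an artifact of the cutting preference. Fragments at a
#' chromosome edge where the context cannot be read are dropped.
#'
#' @param fs a [FragmentSet].
#' @param genome a [Biostrings::DNAStringSet].
#' @param rule `"no_ww"` (cut dimer must not be WW; default) or `"no_w"`
#'   (no A or T at either cut position).
#' @param both_ends require the rule at both ends (default `TRUE`); when
#'   `FALSE` only the 5' (left) end is constrained.
#' @return the filtered [FragmentSet].
#' @export
filter_end_subset <- function(fs, genome, rule = c("no_ww", "no_w"),
                              both_ends = TRUE) {
  stopifnot(inherits(fs, "FragmentSet"))
  rule <- match.arg(rule)
  ctx <- end_contexts(fs, genome, 2L)
  ok_end <- function(s) {
    # with flank = 2 the labels are -1, 0, +1, +2; positions 0/+1 are 2:3
    b0 <- substr(s, 2L, 2L) %in% c("A", "T")
    b1 <- substr(s, 3L, 3L) %in% c("A", "T")
    if (rule == "no_ww") !(b0 & b1) else !b0 & !b1
  }
  pass <- ok_end(ctx$left)
  if (both_ends) pass <- pass & ok_end(ctx$right)
  keep <- logical(length(fs))
  keep[ctx$idx] <- pass
  subset_fragments(fs, keep,
                   sprintf("cut context filter (%s)", rule))
}

#' Select fragments forming the +1 / -1 / +2 nucleosome of genes
#'
#' A fragment belongs to a gene's +1 nucleosome when its dyad (round-up
#' rule) falls between gene coordinate +1 (the TSS) and +140, measured in
#' the direction of transcription. The -1 and +2 windows default to
#' [-180, -41] and [+141, +300] gene coordinates and are configurable. The
#' returned set carries the assigned gene and strand so that downstream
#' sequence extraction is oriented by transcription; a fragment matching
#' several genes appears once per gene.
#'
#' @param fs a [FragmentSet].
#' @param genes gene table (see [read_genes()]).
#' @param which `"+1"`, `"-1"` or `"+2"`.
#' @param window optional length-2 numeric overriding the gene-coordinate
#'   window.
#' @return a [FragmentSet] with extra columns `gene_id` and `strand`.
#' @export
select_positional_nucleosomes <- function(fs, genes,
                                          which = c("+1", "-1", "+2"),
                                          window = NULL) {
  stopifnot(inherits(fs, "FragmentSet"))
  if (is.null(genes) || nrow(genes) == 0L) stop("empty gene list")
  which <- match.arg(which)
  if (is.null(window))
    window <- switch(which, "+1" = c(1L, 140L), "-1" = c(-180L, -41L),
                     "+2" = c(141L, 300L))
  stopifnot(length(window) == 2L, window[1L] <= window[2L])
  lo <- as.integer(window[1L]); hi <- as.integer(window[2L])
  plus <- genes$strand == "+"
  # gene coordinate t of a dyad d (1-based): t = (d - tss) + 1 on plus,
  # t = (tss - d) + 1 on minus; keep t in [lo, hi]
  win_start <- ifelse(plus, genes$tss + lo - 1L, genes$tss - hi + 1L)
  win_end <- ifelse(plus, genes$tss + hi - 1L, genes$tss - lo + 1L)
  reg <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = win_start, end = win_end))
  mid <- GenomicRanges::GRanges(
    fs$fragments$chrom,
    IRanges::IRanges(start = fragment_dyads(fs, one_based = TRUE),
                     width = 1L))
  hits <- GenomicRanges::findOverlaps(mid, reg)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  n0 <- length(fs)
  out <- FragmentSet(fs$fragments$chrom[qi], fs$fragments$start[qi],
                     fs$fragments$end[qi], genome_id = fs$genome_id,
                     extra = data.frame(gene_id = genes$gene_id[si],
                                        strand = genes$strand[si],
                                        stringsAsFactors = FALSE))
  out$provenance <- fs$provenance
  record_filter(out, sprintf("%s nucleosome window [%d, %d]", which, lo, hi),
                n0, length(out))
}

#' Expected WW spacing on an i.i.d. genome
#'
#' On a genome with i.i.d. bases and A+T content `at_content`, a WW dimer
#' starts at a given position with probability `at_content^2`, so the mean
#' spacing between WW starts is its reciprocal: about 3 bp at 60% AT — WW
#' cut sites are effectively everywhere, which is why the MNase W|W
#' preference barely constrains where nucleosomal fragments can end.
#'
#' @param at_content fraction of A+T (default 0.6).
#' @return expected spacing in bp.
#' @export
expected_ww_spacing <- function(at_content = 0.6) {
  stopifnot(at_content > 0, at_content <= 1)
  1 / at_content^2
}
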