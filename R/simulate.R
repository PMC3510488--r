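#' Configuration for the cell-ensemble nucleosome array simulator
#'
#' Describes a population of cells carrying nucleosome arrays over a set of
#' independent loci (one locus per simulated chromosome; cells are divided
#' evenly among loci). Arrays differ in three ways that the distance
#' auto-correlation is designed to read out:
#'
#' * **spacing mixture** — each cell draws its array model: either the
#'   regular short component, whose anchor positions are *frozen per locus*
#'   (all regular cells at a locus share translational positions, forming
#'   position clusters), or a long "irregular" component whose repeat
#'   length is drawn per cell, uniform on 180-250 bp. Both models start at
#'   the locus anchor, as arrays phased at a gene do. A mixed population
#'   produces a discontinuous DAC envelope, a pure population a smooth one.
#' * **rotational position clusters** — each nucleosome's dyad is offset by
#'   `k` helical turns, realized on the integer lattice by stochastic
#'   rounding of `k * 10.25` bp so the expected offset is exact, with `k`
#'   drawn from `jitter_probs`; this builds the ~10-bp sub-peak lattice of
#'   the DAC fine structure. The default cluster half-width of 7 turns with
#'   geometrically decaying weights produces a sub-peak series extending to
#'   ~14 turns (within-cluster differences up to ~144 bp).
#' * **repeat-length heterogeneity** — the regular component's repeat
#'   length varies between loci (`spacing + N(0, locus_spacing_sd)`),
#'   emulating the 160-170 bp spread of peak separations across genes.
#'   Pooled over loci this leaves main DAC peaks centered on multiples of
#'   `spacing` while decohering them from the within-cluster ~10-bp
#'   lattice, as in genome-wide data.
#'
#' @param n_cells number of cells (arrays), divided evenly among loci.
#' @param region_length locus size in bp.
#' @param spacing mean repeat length of the regular component in bp
#'   (default 160).
#' @param long_spacing_range length-2 range of the long component
#'   (default `c(180, 250)`).
#' @param long_fraction probability that a cell uses the long component
#'   (0 = pure regular spacing; default 0).
#' @param n_loci number of independent loci / chromosomes (default 24).
#' @param locus_spacing_sd between-locus standard deviation of the regular
#'   repeat length, bp (default 5).
#' @param jitter_probs named numeric vector: probability of each rotational
#'   offset index `k` (names are integers; must sum to 1). Default:
#'   geometric decay `0.6^|k|` over `k = -7..7`, normalized.
#' @param rotational_period helical period in bp (default 10.25; realized
#'   as stochastically rounded integer offsets).
#' @param fragment_lengths candidate fragment lengths, sampled uniformly
#'   (default `147:152`).
#' @param first_dyad_offset dyad of the first nucleosome, bp from the locus
#'   start (default 200).
#' @param chrom_prefix chromosome names are `paste0(chrom_prefix, 1:n_loci)`.
#' @param seed mandatory integer seed.
#' @return object of class `array_sim_config`.
#' @export
array_sim_config <- function(n_cells = 2000L, region_length = 4000L,
                             spacing = 160L,
                             long_spacing_range = c(180L, 250L),
                             long_fraction = 0,
                             n_loci = 24L, locus_spacing_sd = 5,
                             jitter_probs = default_jitter_probs(),
                             rotational_period = 10.25,
                             fragment_lengths = 147:152,
                             first_dyad_offset = 200L,
                             chrom_prefix = "simL", seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_cells >= 1, region_length > 300,
            spacing >= 147, all(long_spacing_range >= 147),
            long_fraction >= 0, long_fraction <= 1,
            n_loci >= 1, n_cells >= n_loci, locus_spacing_sd >= 0,
            abs(sum(jitter_probs) - 1) < 1e-8,
            !is.null(names(jitter_probs)),
            rotational_period > 0,
            all(fragment_lengths >= 1),
            first_dyad_offset > max(fragment_lengths))
  structure(list(n_cells = as.integer(n_cells),
                 region_length = as.integer(region_length),
                 spacing = as.integer(spacing),
                 long_spacing_range = as.integer(long_spacing_range),
                 long_fraction = long_fraction,
                 n_loci = as.integer(n_loci),
                 locus_spacing_sd = locus_spacing_sd,
                 jitter_probs = jitter_probs,
                 rotational_period = rotational_period,
                 fragment_lengths = as.integer(fragment_lengths),
                 first_dyad_offset = as.integer(first_dyad_offset),
                 chrom_prefix = chrom_prefix, seed = as.integer(seed)),
            class = "array_sim_config")
}

#' Simulate a cell ensemble of nucleosome arrays
#'
#' Cells are divided evenly among `n_loci` loci. Each locus freezes a
#' regular anchor lattice: an arithmetic progression from
#' `first_dyad_offset` with the locus's own repeat length
#' (`spacing + N(0, locus_spacing_sd)`, rounded per anchor). For each cell:
#' draw the array model (regular/long per `long_fraction`; the long
#' component draws one repeat length per cell, uniform over its range, and
#' starts at the same locus anchor), offset each dyad by a rotational
#' cluster draw, and emit one fragment per nucleosome, its sampled length
#' centered on the dyad so that the round-up midpoint rule recovers the
#' true dyad exactly. Nucleosomes whose fragment would leave the locus are
#' truncated from the array and counted in the truth table's attributes.
#'
#' @param cfg an [array_sim_config()].
#' @return list with `fragments` (a [FragmentSet]) and `truth` (data.frame
#'   with one row per emitted nucleosome: cell, chromosome/locus, array
#'   model, repeat length, base dyad, jitter index, realized dyad, fragment
#'   length).
#' @export
simulate_arrays <- function(cfg) {
  stopifnot(inherits(cfg, "array_sim_config"))
  set.seed(cfg$seed)
  ks <- as.integer(names(cfg$jitter_probs))
  max_dyad <- cfg$region_length - max(cfg$fragment_lengths)
  if (cfg$first_dyad_offset > max_dyad)
    stop("region_length too small for first_dyad_offset")
  locus_of_cell <- rep_len(seq_len(cfg$n_loci), cfg$n_cells)
  # frozen per-locus regular anchor lattices; all regular arrays carry the
  # same number of nucleosomes so no repeat length is overweighted at any
  # harmonic of the distance histogram
  locus_spacing <- cfg$spacing +
    round(stats::rnorm(cfg$n_loci, 0, cfg$locus_spacing_sd))
  locus_spacing <- pmax(locus_spacing, min(cfg$fragment_lengths))
  n_nucs <- max(2L, 1L + (max_dyad - cfg$first_dyad_offset) %/%
                  as.integer(ceiling(cfg$spacing + 4 * cfg$locus_spacing_sd)))
  anchors <- lapply(locus_spacing, function(sp)
    cfg$first_dyad_offset + sp * (seq_len(n_nucs) - 1L))
  rows <- vector("list", cfg$n_cells)
  n_truncated <- 0L
  for (cell in seq_len(cfg$n_cells)) {
    loc <- locus_of_cell[cell]
    long <- stats::runif(1) < cfg$long_fraction
    if (long) {
      sp <- as.integer(round(stats::runif(1, cfg$long_spacing_range[1L],
                                          cfg$long_spacing_range[2L])))
      base <- seq(cfg$first_dyad_offset, max_dyad, by = sp)
    } else {
      sp <- locus_spacing[loc]
      base <- anchors[[loc]]
    }
    k <- sample(ks, length(base), replace = TRUE, prob = cfg$jitter_probs)
    dyad <- base + rotational_offset(k, cfg$rotational_period)
    len <- sample(cfg$fragment_lengths, length(base), replace = TRUE)
    start <- dyad - len %/% 2L
    end <- start + len
    ok <- start >= 0L & end <= cfg$region_length
    n_truncated <- n_truncated + sum(!ok)
    rows[[cell]] <- data.frame(cell = cell,
                               chrom = paste0(cfg$chrom_prefix, loc),
                               model = if (long) "long" else "regular",
                               spacing = sp, base_dyad = base[ok],
                               jitter_k = k[ok], dyad = dyad[ok],
                               frag_len = len[ok])
  }
  truth <- do.call(rbind, rows)
  attr(truth, "n_truncated") <- n_truncated
  attr(truth, "seed") <- cfg$seed
  fs <- FragmentSet(truth$chrom,
                    truth$dyad - truth$frag_len %/% 2L,
                    truth$dyad - truth$frag_len %/% 2L + truth$frag_len,
                    genome_id = "simulated")
  list(fragments = fs, truth = truth)
}

#' Default rotational cluster distribution
#'
#' Probabilities of the rotational offset index `k` (helical turns away
#' from the cluster's dominant position): geometric decay `decay^|k|` over
#' `k = -half_width..half_width`, normalized. The default half-width of 7
#' turns lets within-cluster position pairs differ by up to ~14 turns,
#' matching a DAC sub-peak series that extends to ~144 bp.
#'
#' @param half_width largest offset magnitude in turns (default 7).
#' @param decay geometric decay per turn (default 0.6).
#' @return named probability vector suitable for [array_sim_config()].
#' @export
default_jitter_probs <- function(half_width = 7L, decay = 0.6) {
  ks <- seq(-half_width, half_width)
  p <- decay^abs(ks)
  stats::setNames(p / sum(p), ks)
}

# k helical turns on the integer lattice, stochastically rounded so the
# expected offset is exactly k * period and the pairwise difference lattice
# stays centered on multiples of the period
rotational_offset <- function(k, period) {
  x <- abs(k) * period
  off <- floor(x) + (stats::runif(length(k)) < x - floor(x))
  as.integer(sign(k) * off)
}

#' Configuration for the genome/cut-site simulator
#'
#' @param genome_length genome (region) length in bp.
#' @param at_content genome-wide A+T fraction (default 0.60, the yeast
#'   value).
#' @param planted_ww_amplitude amplitude of the cosine modulation of the
#'   per-base W probability around each true dyad (0 = no planted signal;
#'   must keep probabilities inside \[0, 1\]).
#' @param planted_period period of the planted modulation in bp
#'   (default 10.25).
#' @param cut_bias_strength odds multiplier favouring cut positions whose
#'   (0, +1) dimer is WW (1 = unbiased; ~12 yields roughly the 80% W|W cut
#'   fraction seen for micrococcal nuclease).
#' @param cut_jitter maximum shift (bp) of each fragment end from its
#'   nominal position when resampling cut sites (default 2).
#' @param chrom chromosome name.
#' @param seed mandatory integer seed.
#' @return object of class `seq_sim_config`.
#' @export
seq_sim_config <- function(genome_length, at_content = 0.6,
                           planted_ww_amplitude = 0,
                           planted_period = 10.25,
                           cut_bias_strength = 1, cut_jitter = 2L,
                           chrom = "simI", seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(genome_length >= 1, at_content >= 0, at_content <= 1,
            planted_ww_amplitude >= 0,
            at_content + planted_ww_amplitude <= 1,
            at_content - planted_ww_amplitude >= 0,
            planted_period > 0, cut_bias_strength > 0, cut_jitter >= 0)
  structure(list(genome_length = as.integer(genome_length),
                 at_content = at_content,
                 planted_ww_amplitude = planted_ww_amplitude,
                 planted_period = planted_period,
                 cut_bias_strength = cut_bias_strength,
                 cut_jitter = as.integer(cut_jitter),
                 chrom = chrom, seed = as.integer(seed)),
            class = "seq_sim_config")
}

#' Simulate a genome with planted nucleosomal sequence signal and cut bias
#'
#' Draws an i.i.d. genome at the configured AT content, modulating the
#' per-base W probability around every true dyad with a cosine of the
#' planted period (within +/- 73 bp of the dyad) — this plants the ~10-bp
#' WW/SS rotational signal. Fragment ends are then re-sampled within
#' `cut_jitter` bp of their nominal boundaries with each candidate weighted
#' by `cut_bias_strength` when its (0, +1) cut dimer is WW, emulating the
#' MNase cleavage preference.
#'
#' @param cfg a [seq_sim_config()].
#' @param truth truth table from [simulate_arrays()] (columns `chrom`,
#'   `dyad`, `frag_len`), or an integer vector of dyad positions (0-based;
#'   fragment lengths then default to 147 on a single chromosome).
#' @return list with `genome` (a [Biostrings::DNAStringSet], one sequence of
#'   `genome_length` bp per chromosome in `truth`) and `fragments` (a
#'   [FragmentSet] with the re-sampled cut sites).
#' @export
simulate_genome_and_cuts <- function(cfg, truth) {
  stopifnot(inherits(cfg, "seq_sim_config"))
  if (is.numeric(truth))
    truth <- data.frame(chrom = cfg$chrom, dyad = as.integer(truth),
                        frag_len = 147L)
  stopifnot(all(c("chrom", "dyad", "frag_len") %in% names(truth)))
  set.seed(cfg$seed + 1L)
  L <- cfg$genome_length
  chroms <- unique(truth$chrom)
  seqs <- character(length(chroms))
  starts <- integer(nrow(truth)); ends <- integer(nrow(truth))
  jit <- cfg$cut_jitter
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    rows <- which(truth$chrom == ch)
    p_w <- rep(cfg$at_content, L)
    if (cfg$planted_ww_amplitude > 0) {
      for (d in unique(truth$dyad[rows])) {
        i <- max(0L, d - 73L):min(L - 1L, d + 73L)
        p_w[i + 1L] <- cfg$at_content + cfg$planted_ww_amplitude *
          cos(2 * pi * (i - d) / cfg$planted_period)
      }
    }
    is_w <- stats::runif(L) < p_w
    base <- character(L)
    base[is_w] <- sample(c("A", "T"), sum(is_w), replace = TRUE)
    base[!is_w] <- sample(c("G", "C"), sum(!is_w), replace = TRUE)
    seqs[ci] <- paste(base, collapse = "")
    w <- is_w
    pick <- function(nominal, ww_at) {
      # ww_at(pos): TRUE when the (0, +1) dimer of a cut at pos is WW
      vapply(nominal, function(p) {
        cand <- (p - jit):(p + jit)
        cand <- cand[cand >= 1L & cand <= L - 1L]
        wt <- ifelse(ww_at(cand), cfg$cut_bias_strength, 1)
        if (length(cand) == 1L) cand else sample(cand, 1L, prob = wt)
      }, integer(1))
    }
    nominal_start <- truth$dyad[rows] - truth$frag_len[rows] %/% 2L
    nominal_end <- nominal_start + truth$frag_len[rows]
    # left cut at start s: positions 0/+1 are bases s-1 and s (0-based)
    starts[rows] <- pick(nominal_start, function(p) w[p] & w[p + 1L])
    # right cut at end e: positions 0/+1 are bases e and e-1 (0-based)
    ends[rows] <- pick(nominal_end, function(p) w[p + 1L] & w[p])
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  ok <- ends > starts
  fs <- FragmentSet(truth$chrom[ok], starts[ok], ends[ok],
                    genome_id = "simulated")
  list(genome = genome, fragments = fs)
}

#' Write a simulation truth table as TSV
#' @param truth truth data.frame from [simulate_arrays()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  writeLines(sprintf("# seed=%s n_truncated=%s",
                     format(attr(truth, "seed")),
                     format(attr(truth, "n_truncated"))), path)
  suppressWarnings(utils::write.table(truth, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}
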