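test_that("aligned extraction is dyad-centered with linker extension", {
  g <- genome_from_strings(list(chrI = random_genome_string(600)))
  fs <- FragmentSet("chrI", 200L, 347L)  # 147 bp
  m <- extract_aligned(fs, g, extension = 20L)
  expect_equal(nchar(m$seqs), 187L)
  expect_equal(m$width, 187L)
  # the matrix center column is the dyad base
  dy <- fragment_dyads(fs)
  expect_equal(substr(m$seqs, m$dyad_column, m$dyad_column),
               substr(as.character(g$chrI), dy + 1L, dy + 1L))
})

test_that("dyads of 147- and 149-bp cores coincide at the matrix center", {
  base <- strsplit(random_genome_string(600), "")[[1]]
  base[301L] <- "A"  # 0-based 300 is the planted dyad, flanked by G
  base[c(300L, 302L)] <- "G"
  g <- genome_from_strings(list(chrI = paste(base, collapse = "")))
  fs <- fs_from_dyads(c(300L, 300L), len = c(147L, 149L), chrom = "chrI")
  m <- extract_aligned(fs, g, extension = 20L)
  expect_equal(unique(nchar(m$seqs)), 187L)
  expect_equal(unique(substr(m$seqs, 94L, 94L)), "A")
})

test_that("fragments of minus-strand genes are reverse-complemented", {
  g <- genome_from_strings(list(chrI = paste(
    c(rep("G", 250), rep("A", 200), rep("G", 150)), collapse = "")))
  fs <- fs_from_dyads(300L, chrom = "chrI")  # inside the A block
  gene_m <- gene_table("gm", "chrI", 150L, 500L, "-")
  m_plus <- extract_aligned(fs, g, 20L)
  m_minus <- extract_aligned(fs, g, 20L, orient_by = gene_m)
  expect_equal(m_minus$seqs,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAStringSet(m_plus$seqs))))
  expect_true(grepl("T", m_minus$seqs))
})

test_that("out-of-bounds windows are dropped with a warning", {
  g <- genome_from_strings(list(chrI = random_genome_string(400)))
  fs <- fs_from_dyads(c(50L, 200L), chrom = "chrI")
  expect_warning(m <- extract_aligned(fs, g, 20L), "dropped")
  expect_equal(length(m$seqs), 1L)
})

test_that("dimer classes partition every N-free step", {
  set.seed(21)
  seqs <- replicate(30, random_genome_string(60, at = 0.5))
  m <- structure(list(seqs = seqs, width = 60L, extension = 0L,
                      dyad_column = 30L), class = "aligned_seq_matrix")
  p <- dinuc_profile(m)
  expect_equal(p$WW + p$SS + p$WS + p$SW, rep(1, 59))
  # poly-A input is all WW
  mA <- structure(list(seqs = rep(strrep("A", 40), 5), width = 40L,
                       extension = 0L, dyad_column = 20L),
                  class = "aligned_seq_matrix")
  pA <- dinuc_profile(mA)
  expect_equal(pA$WW, rep(1, 39))
  expect_equal(pA$SS, rep(0, 39))
  mN <- structure(list(seqs = rep(strrep("N", 40), 5), width = 40L,
                       extension = 0L, dyad_column = 20L),
                  class = "aligned_seq_matrix")
  expect_error(dinuc_profile(mN), "N")
})

test_that("symmetrization is idempotent and mirror-symmetric", {
  set.seed(22)
  seqs <- replicate(40, random_genome_string(61))
  m <- structure(list(seqs = seqs, width = 61L, extension = 0L,
                      dyad_column = 31L), class = "aligned_seq_matrix")
  p1 <- dinuc_profile(m, symmetrize = TRUE)
  expect_equal(p1$WW, rev(p1$WW))
  expect_equal(p1$SS, rev(p1$SS))
  # symmetrizing a symmetric profile changes nothing: average the raw
  # profile with its mirror twice by hand
  p0 <- dinuc_profile(m, symmetrize = FALSE)
  once <- (p0$WW + rev(p0$WW)) / 2
  twice <- (once + rev(once)) / 2
  expect_equal(p1$WW, once)
  expect_equal(twice, once)
})

test_that("WW and SS profiles are reverse-complement invariant after mirroring", {
  set.seed(23)
  seqs <- replicate(40, random_genome_string(60))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  m <- structure(list(seqs = seqs, width = 60L, extension = 0L,
                      dyad_column = 30L), class = "aligned_seq_matrix")
  mrc <- structure(list(seqs = rc, width = 60L, extension = 0L,
                        dyad_column = 30L), class = "aligned_seq_matrix")
  p <- dinuc_profile(m)
  prc <- dinuc_profile(mrc)
  expect_equal(prc$WW, rev(p$WW))
  expect_equal(prc$SS, rev(p$SS))
})

make_cut_genome <- function(n_frags = 40L, frag_len = 147L, gap = 20L) {
  # engineered cut contexts: W W T | T G G ... C C A A | W W
  # (left and right read the same after reverse-complementing the 3' end)
  unit <- frag_len + gap
  base <- rep("G", 60L + n_frags * unit)
  starts <- integer(n_frags)
  for (i in seq_len(n_frags)) {
    s <- 30L + (i - 1L) * unit          # 0-based fragment start
    e <- s + frag_len
    starts[i] <- s
    w1 <- if (i %% 2L) "A" else "T"
    w2 <- if (i %% 2L) "T" else "A"
    base[(s - 3L):(s + 2L) + 1L] <- c(w1, w2, "T", "T", "G", "G")
    base[(e - 3L):(e + 2L) + 1L] <- c("C", "C", "A", "A", w2, w1)
  }
  list(genome = genome_from_strings(
         list(chrI = paste(base, collapse = ""))),
       fs = FragmentSet(rep("chrI", n_frags), starts, starts + frag_len))
}

test_that("engineered cut contexts give the WWT|TG consensus and full W|W fraction", {
  fx <- make_cut_genome()
  cons <- end_consensus(fx$fs, fx$genome, flank = 3L)
  expect_true(startsWith(cons$consensus, "WWT|TG"))
  expect_equal(cons$ww_cut_fraction, 1)
  expect_equal(cons$n_ends, 2L * length(fx$fs))
  expect_equal(unname(rowSums(cons$base_freqs)), rep(1, 6))
  # a single fragment yields 0/1 indicator frequencies
  one <- FragmentSet("chrI", fx$fs$fragments$start[1L],
                     fx$fs$fragments$end[1L])
  c1 <- end_consensus(one, fx$genome, flank = 2L)
  expect_true(all(c1$base_freqs %in% c(0, 0.5, 1)))
})

test_that("uniform random cuts on a 60% AT genome give ~36% W|W ends", {
  set.seed(24)
  g <- genome_from_strings(list(chrI = random_genome_string(60000, at = 0.6)))
  start <- sample(3000:50000, 3000L, replace = TRUE)
  fs <- FragmentSet(rep("chrI", 3000L), start, start + 147L)
  cons <- end_consensus(fs, g, flank = 2L)
  # binomial check: 6000 ends, p = 0.36 -> 4 sigma ~ 0.025
  expect_lt(abs(cons$ww_cut_fraction - 0.36), 0.03)
  expect_true(cons$ww_cut_fraction >= 0 && cons$ww_cut_fraction <= 1)
  # and the analytic spacing of WW dimers is 1/0.36 ~ 3 bp
  expect_equal(round(expected_ww_spacing(0.6)), 3)
})

test_that("the end-filtered subset excludes preferred cut contexts", {
  # fragment 1: S|S contexts at both ends -> kept under either rule;
  # fragment 2: A|A (WW) dimer at its left cut -> always removed
  base <- rep("G", 400L)
  base[200:201] <- "A"  # 0-based 199/200 = positions 0/+1 of fragment 2
  g <- genome_from_strings(list(chrI = paste(base, collapse = "")))
  fs <- FragmentSet(c("chrI", "chrI"), c(50L, 200L), c(197L, 347L))
  for (r in c("no_ww", "no_w")) {
    out <- filter_end_subset(fs, g, rule = r)
    expect_equal(length(out), 1L)
    expect_equal(out$fragments$start, 50L)
  }
  # a mixed A|G context is not a WW dimer: kept by default, removed by
  # the strict all-S rule
  gmix <- genome_from_strings(
    list(chrI = paste(replace(rep("G", 400L), 200L, "A"), collapse = "")))
  fs2 <- FragmentSet("chrI", 200L, 347L)
  expect_equal(length(filter_end_subset(fs2, gmix)), 1L)
  expect_equal(length(filter_end_subset(fs2, gmix, rule = "no_w")), 0L)
  # single-end mode only constrains the 5' end
  base2 <- rep("G", 400L)
  base2[347:348] <- "A"  # WW dimer at the right cut of [200,347)
  g2 <- genome_from_strings(list(chrI = paste(base2, collapse = "")))
  fs1 <- FragmentSet("chrI", 200L, 347L)
  expect_equal(length(filter_end_subset(fs1, g2)), 0L)
  expect_equal(length(filter_end_subset(fs1, g2, both_ends = FALSE)), 1L)
})

test_that("+1 nucleosome selection follows gene coordinates and strand", {
  genes <- gene_table(c("gp", "gm"), "chrI", c(1001L, 3001L),
                      c(2000L, 4000L), c("+", "-"))
  # plus gene TSS 1001; minus gene TSS 4000
  dyads1 <- c(1070L, 1140L, 1141L, 1000L)   # t = 70, 140, 141, 0
  fs <- fs_from_dyads(dyads1 - 1L, chrom = "chrI")  # to 0-based
  sel <- select_positional_nucleosomes(fs, genes, "+1")
  expect_equal(sort(fragment_dyads(sel, one_based = TRUE)), c(1070L, 1140L))
  expect_true(all(sel$fragments$strand == "+"))
  expect_true(all(sel$fragments$gene_id == "gp"))
  # minus-strand gene: dyad 70 bp 5' of the TSS in transcription direction
  fsm <- fs_from_dyads(c(3930L, 4070L) - 1L, chrom = "chrI")
  selm <- select_positional_nucleosomes(fsm, genes, "+1")
  expect_equal(fragment_dyads(selm, one_based = TRUE), 3930L)
  expect_equal(selm$fragments$strand, "-")
  # the +2 window [141, 300] picks up exactly the t = 141 dyad
  sel2 <- select_positional_nucleosomes(fs, genes, "+2")
  expect_equal(fragment_dyads(sel2, one_based = TRUE), 1141L)
  selw <- select_positional_nucleosomes(fs, genes, "+1",
                                        window = c(1L, 80L))
  expect_equal(length(selw), 1L)
  expect_error(select_positional_nucleosomes(fs, genes[0, ], "+1"), "empty")
})
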