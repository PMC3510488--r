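test_that("multiplicity weighting contributes the product of counts", {
  # two positions occupied 5 and 10 times -> 50 at their distance
  t <- position_count_table("chrI", c(1000L, 1500L), c(5L, 10L))
  h <- compute_dac(t, 600L)
  expect_equal(h$left[501L], 50)          # single-anchor sum
  expect_equal(h$values[501L], 100)       # both anchor sides
  # HIS3-style increment: counts 19 and 5 at 109 bp -> 95
  t2 <- position_count_table("chrXV", c(721500L, 721609L), c(19L, 5L))
  h2 <- compute_dac(t2, 200L)
  expect_equal(h2$left[110L], 95)
  # coincidence weighting counts each occupied position once
  hc <- compute_dac(t2, 200L, weighting = "coincidence")
  expect_equal(hc$left[110L], 1)
})

test_that("a single occupied position gives no positive-distance signal", {
  t <- position_count_table("chrI", 500L, 7L)
  h <- compute_dac(t, 100L)
  expect_equal(sum(h$values[-1L]), 0)
  expect_equal(h$left[1L], choose(7, 2))  # flagged self-distance term
  expect_true(h$self_flagged)
})

test_that("DAC equals exhaustive pair enumeration on random instances", {
  set.seed(101)
  for (rep in 1:8) {
    inst <- random_count_instance()
    t <- position_count_table(inst$chrom, inst$pos, inst$count)
    for (w in c("multiplicative", "coincidence")) {
      h <- compute_dac(t, 200L, weighting = w)
      oracle <- brute_dac(inst$chrom, inst$pos, inst$count, 200L,
                          clamp = (w == "coincidence"))
      expect_equal(h$left, oracle)
      expect_equal(h$values, 2 * oracle)
    }
  }
})

test_that("DCC equals the brute-force double loop and detects translations", {
  set.seed(202)
  for (rep in 1:8) {
    a <- random_count_instance(n_max = 20L)
    b <- random_count_instance(n_max = 20L)
    ta <- position_count_table(a$chrom, a$pos, a$count)
    tb <- position_count_table(b$chrom, b$pos, b$count)
    h <- compute_dcc(ta, tb, 200L)
    oracle <- brute_dcc(a$chrom, a$pos, a$count, b$chrom, b$pos, b$count,
                        200L)
    expect_equal(h$left, oracle)
  }
  # identical single position: 3 x 3 ordered pairs at distance 0, both sides
  t1 <- position_count_table("chrI", 100L, 3L)
  expect_equal(compute_dcc(t1, t1, 10L)$values[1L], 18)
  # a translated copy peaks at the shift
  pos <- c(100L, 260L, 420L, 580L)
  ta <- position_count_table("chrI", pos, c(2L, 5L, 3L, 4L))
  tb <- position_count_table("chrI", pos + 37L, c(2L, 5L, 3L, 4L))
  h <- compute_dcc(ta, tb, 300L)
  expect_equal(which.max(h$values[-1L]), 37L)
})

test_that("DCC of a set with itself decomposes into twice the DAC plus diagonal", {
  set.seed(303)
  inst <- random_count_instance()
  t <- position_count_table(inst$chrom, inst$pos, inst$count)
  dac <- compute_dac(t, 150L)
  dcc <- compute_dcc(t, t, 150L)
  expect_equal(dcc$values[-1L], 2 * dac$values[-1L])
  expect_equal(dcc$values[1L], sum(inst$count^2) * 2)
})

test_that("scaling counts by k scales multiplicative DAC by k^2", {
  set.seed(404)
  inst <- random_count_instance()
  t1 <- position_count_table(inst$chrom, inst$pos, inst$count)
  t3 <- position_count_table(inst$chrom, inst$pos, inst$count * 3L)
  h1 <- compute_dac(t1, 150L)
  h3 <- compute_dac(t3, 150L)
  expect_equal(h3$values[-1L], 9 * h1$values[-1L])
})

test_that("DAC is invariant under coordinate reversal within chromosomes", {
  set.seed(505)
  inst <- random_count_instance()
  t <- position_count_table(inst$chrom, inst$pos, inst$count)
  tr <- position_count_table(inst$chrom, 1000L - inst$pos, inst$count)
  expect_equal(compute_dac(t, 150L)$values, compute_dac(tr, 150L)$values)
})

test_that("DAC mass is conserved against direct pair summation", {
  set.seed(606)
  inst <- random_count_instance(span = 150L)
  t <- position_count_table(inst$chrom, inst$pos, inst$count)
  D <- 200L  # covers every within-chromosome pair
  h <- compute_dac(t, D)
  direct <- 0
  for (ch in unique(inst$chrom)) {
    sel <- inst$chrom == ch
    cnt <- inst$count[sel]
    direct <- direct + (sum(cnt)^2 - sum(cnt^2)) / 2
  }
  expect_equal(sum(h$left[-1L]), direct)
})

test_that("anchor tables count every fragment and apply the round-up center", {
  fs <- FragmentSet(rep("chrI", 3L), rep(100L, 3L), rep(247L, 3L))
  pc <- position_counts(fs, "start")
  expect_equal(pc$left$chrI$count, 3L)
  expect_equal(pc$left$chrI$pos, 100L)
  expect_equal(pc$right$chrI$pos, 246L)
  # 148-bp fragment starting at 1-based s = 101: center 174.5 -> dyad 175
  fs148 <- FragmentSet("chrI", 100L, 248L)
  pc148 <- position_counts(fs148, "center")
  expect_equal(pc148$left$chrI$pos + 1L, 175L)
  expect_error(position_counts(FragmentSet(character(), integer(),
                                           integer())),
               "empty")
})

test_that("center anchors of a fixed-147 set are start anchors shifted by 73", {
  set.seed(707)
  start <- sample.int(5000L, 50L, replace = TRUE)
  fs <- FragmentSet(rep("chrI", 50L), start, start + 147L)
  st <- position_counts(fs, "start")
  ce <- position_counts(fs, "center")
  expect_equal(ce$left$chrI$pos, st$left$chrI$pos + 73L)
  expect_equal(ce$left$chrI$count, st$left$chrI$count)
  # and the DAC is identical because all anchors shift together
  expect_equal(compute_dac(ce, 300L)$values, compute_dac(st, 300L)$values)
})

test_that("gene-region restriction keeps fragments by padded midpoint", {
  genes <- gene_table("gA", "chrI", body_start = 2001L, body_end = 4000L,
                      strand = "+")
  # dyads 200, 201 and 150 bp upstream of the body, plus one inside
  fs <- fs_from_dyads(c(1800L, 1799L, 1850L, 3000L), chrom = "chrI")
  out <- restrict_to_regions(fs, genes, pad = 200L)
  expect_equal(sort(fragment_dyads(out, one_based = TRUE)),
               c(1801L, 1851L, 3001L))
  expect_error(restrict_to_regions(fs, genes[0, ], 200L), "empty")
  # overlapping genes keep a fragment once
  g2 <- gene_table(c("gA", "gB"), "chrI", c(2001L, 2501L), c(4000L, 4500L),
                   c("+", "+"))
  expect_equal(length(restrict_to_regions(fs_from_dyads(3000L, chrom = "chrI"),
                                          g2, 200L)), 1L)
})

test_that("histograms round-trip through their TSV representation", {
  t <- position_count_table("chrI", c(10L, 100L, 200L), c(2L, 3L, 4L))
  h <- compute_dac(t, 250L)
  path <- tempfile(fileext = ".tsv")
  write_histogram(h, path)
  back <- read_histogram(path)
  expect_equal(back$values, h$values)
  expect_equal(back$mode, "DAC")
})
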