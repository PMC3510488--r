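# Independent brute-force references for the distance correlation functions,
# written directly from the pairwise definitions. Kept deliberately O(n^2):
# they exist to check the production FFT path, never to share code with it.

brute_dac <- function(chrom, pos, count, max_distance, clamp = FALSE) {
  if (clamp) count <- rep(1L, length(count))
  vals <- numeric(max_distance + 1L)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p <- pos[sel]; cnt <- count[sel]
    n <- length(p)
    vals[1L] <- vals[1L] + sum(cnt * (cnt - 1) / 2)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        d <- abs(p[j] - p[i])
        if (d >= 1L && d <= max_distance)
          vals[d + 1L] <- vals[d + 1L] + cnt[i] * cnt[j]
      }
    }
  }
  vals
}

brute_dcc <- function(chrom_a, pos_a, count_a, chrom_b, pos_b, count_b,
                      max_distance) {
  vals <- numeric(max_distance + 1L)
  for (i in seq_along(pos_a)) for (j in seq_along(pos_b)) {
    if (chrom_a[i] != chrom_b[j]) next
    d <- abs(pos_a[i] - pos_b[j])
    if (d <= max_distance)
      vals[d + 1L] <- vals[d + 1L] + count_a[i] * count_b[j]
  }
  vals
}

# random sparse position/count instance on a couple of chromosomes
random_count_instance <- function(n_max = 30L, count_max = 10L,
                                  span = 500L) {
  n <- sample(2:n_max, 1L)
  chrom <- sample(c("chrA", "chrB"), n, replace = TRUE)
  pos <- integer(n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos[sel] <- sample.int(span, sum(sel))
  }
  list(chrom = chrom, pos = pos,
       count = sample.int(count_max, n, replace = TRUE))
}
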