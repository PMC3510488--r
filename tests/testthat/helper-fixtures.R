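# small in-code fixture builders shared across test files

make_fs <- function(chrom, start, end, ...) {
  FragmentSet(chrom, start, end, ...)
}

# fragments of given lengths with dyads at stated 0-based positions
fs_from_dyads <- function(dyad, len = 147L, chrom = "chrI") {
  len <- rep_len(len, length(dyad))
  start <- dyad - len %/% 2L
  FragmentSet(rep_len(chrom, length(dyad)), start, start + len)
}

write_bed <- function(df, path = tempfile(fileext = ".bed")) {
  writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), path)
  path
}

write_gene_tsv <- function(genes, path = tempfile(fileext = ".tsv")) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  close(con)
  path
}

genome_from_strings <- function(seqs) {
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}

random_genome_string <- function(len, at = 0.6) {
  paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}
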