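#' Read a gene annotation table
#'
#' Reads a tab-separated table with columns `gene_id`, `chrom`, `start`,
#' `end`, `strand` and optionally `fold` (induction fold-change).
#' Coordinates are 1-based inclusive gene-body bounds. The transcription
#' start site is derived from the strand: the left end (`start`) for plus
#' strand genes, the right end (`end`) for minus strand genes.
#'
#' @param path TSV file with a header row.
#' @return data.frame with columns `gene_id`, `chrom`, `body_start`,
#'   `body_end`, `strand`, `tss` and (if present) `induction_fold`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  req <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  gene_table(gene_id = tab$gene_id, chrom = tab$chrom,
             body_start = tab$start, body_end = tab$end,
             strand = tab$strand,
             induction_fold = if ("fold" %in% names(tab)) tab$fold else NULL)
}

#' Construct a gene table in memory
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param body_start,body_end 1-based inclusive gene-body bounds.
#' @param strand `"+"` or `"-"`.
#' @param induction_fold optional positive fold-changes.
#' @return validated data.frame as in [read_genes()].
#' @export
gene_table <- function(gene_id, chrom, body_start, body_end, strand,
                       induction_fold = NULL) {
  g <- data.frame(gene_id = as.character(gene_id),
                  chrom = as.character(chrom),
                  body_start = as.integer(body_start),
                  body_end = as.integer(body_end),
                  strand = as.character(strand),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id: ", g$gene_id[duplicated(g$gene_id)][1L])
  if (!all(g$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(g$body_start >= g$body_end))
    stop("gene body_start must be < body_end")
  g$tss <- ifelse(g$strand == "+", g$body_start, g$body_end)
  if (!is.null(induction_fold)) {
    fold <- as.numeric(induction_fold)
    if (any(is.na(fold)) || any(fold <= 0))
      stop("induction fold-change must be positive")
    g$induction_fold <- fold
  }
  g
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] with uppercased sequences; names are
#'   the first whitespace-delimited token of each header.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gs <- Biostrings::readDNAStringSet(path)
  if (length(gs) == 0L) stop("empty FASTA: ", path)
  names(gs) <- sub("\\s.*$", "", names(gs))
  if (anyDuplicated(names(gs)))
    stop("duplicate chromosome name in FASTA: ",
         names(gs)[duplicated(names(gs))][1L])
  # normalize case; DNAStringSet keeps lowercase masking otherwise
  Biostrings::DNAStringSet(toupper(as.character(gs)))
}

#' Group genes by induction fold-change
#'
#' Sorts genes by decreasing fold-change (ties broken by `gene_id`, so the
#' split is deterministic) and returns the top and bottom groups. Group
#' sizes default to the ceiling of `fraction * n`; pass `n_top` / `n_bottom`
#' to fix them explicitly.
#'
#' @param genes gene table carrying `induction_fold` (see [read_genes()]).
#' @param top_fraction,bottom_fraction fractions in (0, 0.5].
#' @param n_top,n_bottom optional explicit group sizes overriding the
#'   fractions.
#' @return list with elements `top` and `bottom`, each a gene table.
#' @export
group_by_induction <- function(genes, top_fraction = 0.2,
                               bottom_fraction = top_fraction,
                               n_top = NULL, n_bottom = NULL) {
  if (is.null(genes$induction_fold) || any(is.na(genes$induction_fold)))
    stop("all genes must carry induction_fold")
  n <- nrow(genes)
  k_top <- if (is.null(n_top)) ceiling(top_fraction * n) else as.integer(n_top)
  k_bot <- if (is.null(n_bottom)) ceiling(bottom_fraction * n)
           else as.integer(n_bottom)
  if (k_top + k_bot > n)
    stop("top and bottom groups would overlap (", k_top, " + ", k_bot,
         " > ", n, " genes)")
  ord <- order(-genes$induction_fold, genes$gene_id)
  sorted <- genes[ord, , drop = FALSE]
  list(top = utils::head(sorted, k_top),
       bottom = utils::tail(sorted, k_bot))
}
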