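# Readers/writers for the standard interchange formats at the package
# boundary: FASTA (Biostrings), GFF3 (rtracklayer), TSV/JSON elsewhere.

#' Write a genome to FASTA
#'
#' @param genome DNAStringSet or named character vector.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA path.
#' @return DNAStringSet.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write gene models to GFF3
#'
#' Emits one \code{gene} record per gene and \code{exon} records with
#' \code{Parent} attributes, 1-based inclusive per the GFF3 convention.
#'
#' @param models list with \code{genes} and \code{exons} data.frames.
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  validate_gene_models(models)
  g <- models$genes
  e <- models$exons
  gr_g <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(g$start, g$end),
                                 strand = g$strand,
                                 type = "gene", ID = g$gene_id)
  if (nrow(e)) {
    strand_e <- g$strand[match(e$gene_id, g$gene_id)]
    gr_e <- GenomicRanges::GRanges(e$chrom,
                                   IRanges::IRanges(e$start, e$end),
                                   strand = strand_e,
                                   type = "exon",
                                   ID = paste0(e$gene_id, ".e", seq_len(nrow(e))))
    S4Vectors::mcols(gr_e)$Parent <- e$gene_id
    S4Vectors::mcols(gr_g)$Parent <- NA_character_
    gr <- c(gr_g, gr_e)
  } else gr <- gr_g
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 path.
#' @return list with \code{genes} and \code{exons} data.frames as used
#'   throughout the package.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  parent <- if (nrow(exons)) vapply(exons$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "") else character()
  list(genes = data.frame(gene_id = genes$ID, chrom = as.character(genes$seqnames),
                          start = genes$start, end = genes$end,
                          strand = as.character(genes$strand)),
       exons = data.frame(gene_id = parent, chrom = as.character(exons$seqnames),
                          start = exons$start, end = exons$end))
}

#' Write tag records as SAM
#'
#' Minimal single-end SAM with \code{@SQ} headers, mainly to exercise
#' the SAM ingestion path on simulated data. Reads are emitted with the
#' reference CCGG at their 5' end; minus-strand reads are stored
#' reverse-complemented as SAM requires.
#'
#' @param tags data.frame with \code{sample_id}, \code{chrom},
#'   \code{pos}, \code{strand} (site coordinates, as in the tag TSV).
#' @param genome reference (DNAStringSet or named character).
#' @param path output path.
#' @param read_len read length (bp).
#' @export
write_tags_sam <- function(tags, genome, path, read_len = 30L) {
  genome <- as_genome(genome)
  chrlen <- stats::setNames(BiocGenerics::width(genome), names(genome))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome), chrlen)), con)
  if (nrow(tags)) {
    # alignment span: forward reads start at the site; reverse reads end
    # at site+3 (so the read itself starts with CCGG)
    start <- ifelse(tags$strand == "+", tags$pos,
                    pmax(1L, tags$pos + 4L - read_len))
    end <- pmin(chrlen[tags$chrom], start + read_len - 1L)
    end <- ifelse(tags$strand == "+", end, tags$pos + 3L)
    seqs <- as.character(Biostrings::subseq(genome[tags$chrom],
                                            start = start, end = end))
    flag <- ifelse(tags$strand == "+", 0L, 16L)
    writeLines(sprintf("%s:%d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       tags$sample_id, seq_len(nrow(tags)), flag,
                       tags$chrom, start, nchar(seqs), seqs), con)
  }
  invisible(path)
}
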