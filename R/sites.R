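#' Catalogue all CCGG (MspI) sites in a reference
#'
#' Scans the forward strand of every chromosome for the palindromic MspI
#' recognition sequence CCGG. Because the motif is its own reverse
#' complement, the forward-strand scan covers both strands: a site is
#' reported once, at the 1-based position of its first C.
#'
#' @param reference named character vector of chromosome sequences, or a
#'   \link[Biostrings]{DNAStringSet}.
#' @return data.frame with columns \code{chrom} and \code{pos} (1-based
#'   position of the first C), in coordinate order.
#' @examples
#' catalog_ccgg(c(chr1 = "AACCGGTT"))
#' @export
catalog_ccgg <- function(reference) {
  genome <- as_genome(reference)
  hits <- Biostrings::vmatchPattern("CCGG", genome)
  out <- lapply(seq_along(genome), function(i) {
    s <- BiocGenerics::start(hits[[i]])
    if (length(s) == 0L) return(NULL)
    data.frame(chrom = names(genome)[i], pos = sort(s))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(), pos = integer())
  rownames(out) <- NULL
  out
}

#' Extract CCGG site coordinates from aligned tags
#'
#' RRHP sequencing tags begin with CCGG at hydroxymethylated MspI sites.
#' A tag is accepted when its leading four read bases are exactly CCGG
#' (ambiguity codes are rejected, not corrected) and the implied site
#' checks out against the reference sequence. In the default
#' \code{"collapsed"} mode both strands map onto the forward-strand
#' coordinate of the palindromic motif: plus-strand tags anchor at their
#' alignment start and minus-strand tags at alignment end minus 3. In
#' \code{"stranded"} mode the tag strand is kept as part of the site key.
#'
#' @param tags data.frame of tag records with columns \code{sample_id},
#'   \code{chrom}, \code{start}, \code{end} (1-based inclusive),
#'   \code{strand} (\code{"+"}/\code{"-"}) and \code{lead4} (first four
#'   bases of the read, in read orientation).
#' @param reference reference genome (named character or DNAStringSet).
#' @param strand_mode \code{"collapsed"} (default) or \code{"stranded"}.
#' @return data.frame of accepted observations with columns
#'   \code{sample_id}, \code{chrom}, \code{pos} and (stranded mode only)
#'   \code{strand}; the number of rejected tags is in attribute
#'   \code{n_rejected}.
#' @seealso \code{\link{build_count_matrix}}
#' @export
extract_sites <- function(tags, reference, strand_mode = c("collapsed", "stranded")) {
  strand_mode <- match.arg(strand_mode)
  genome <- as_genome(reference)
  req <- c("sample_id", "chrom", "start", "end", "strand", "lead4")
  if (!all(req %in% names(tags)))
    stop("tags must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(tags) == 0L) {
    out <- data.frame(sample_id = character(), chrom = character(), pos = integer())
    if (strand_mode == "stranded") out$strand <- character()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  if (!all(tags$chrom %in% names(genome)))
    stop("tag aligned to a chromosome absent from the reference", call. = FALSE)
  if (!all(tags$strand %in% c("+", "-")))
    stop("tag strand must be '+' or '-'", call. = FALSE)
  if (any(tags$end < tags$start))
    stop("tag end precedes start", call. = FALSE)
  chrlen <- BiocGenerics::width(genome)[match(tags$chrom, names(genome))]
  if (any(tags$start < 1L | tags$end > chrlen))
    stop("tag alignment outside chromosome bounds", call. = FALSE)

  keep <- toupper(tags$lead4) == "CCGG"
  pos <- ifelse(tags$strand == "+", tags$start, tags$end - 3L)
  # verify the reference carries CCGG at the claimed site
  ok <- rep(FALSE, nrow(tags))
  if (any(keep)) {
    idx <- which(keep & pos >= 1L & pos + 3L <= chrlen)
    if (length(idx)) {
      ref4 <- as.character(Biostrings::subseq(genome[tags$chrom[idx]],
                                              start = pos[idx], width = 4L))
      ok[idx] <- ref4 == "CCGG"
    }
  }
  out <- data.frame(sample_id = as.character(tags$sample_id[ok]),
                    chrom = as.character(tags$chrom[ok]),
                    pos = as.integer(pos[ok]))
  if (strand_mode == "stranded") out$strand <- as.character(tags$strand[ok])
  attr(out, "n_rejected") <- sum(!ok)
  rownames(out) <- NULL
  out
}

#' Extract the site key of a single tag
#'
#' Scalar convenience around \code{\link{extract_sites}}: returns the
#' CCGG site implied by one tag record, or \code{NULL} when the tag does
#' not start with CCGG or fails reference verification.
#'
#' @inheritParams extract_sites
#' @param tag one-row data.frame (or list) with the tag record fields.
#' @return list with \code{chrom}, \code{pos} (and \code{strand} in
#'   stranded mode), or \code{NULL}.
#' @export
extract_site <- function(tag, reference, strand_mode = c("collapsed", "stranded")) {
  tag <- as.data.frame(tag, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tag)) tag$sample_id <- "s"
  res <- extract_sites(tag, reference, strand_mode)
  if (nrow(res) == 0L) return(NULL)
  as.list(res[1L, setdiff(names(res), "sample_id"), drop = FALSE])
}

#' Read tag records from a SAM file
#'
#' Converts the SAM to BAM with Rsamtools and pulls out the fields a tag
#' record needs. SAM stores minus-strand reads reverse-complemented, so
#' the read's leading four bases are recovered from the end of the stored
#' sequence for minus-strand alignments.
#'
#' @param sam_file path to a SAM file with \code{@SQ} header lines.
#' @param sample_from how to obtain the sample id: \code{"RG"} uses the
#'   read-group tag, \code{"qname_prefix"} takes the read-name prefix
#'   before the first colon.
#' @return tag data.frame as consumed by \code{\link{extract_sites}}.
#' @export
read_tags_sam <- function(sam_file, sample_from = c("qname_prefix", "RG")) {
  sample_from <- match.arg(sample_from)
  bam <- Rsamtools::asBam(sam_file, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  what <- c("qname", "rname", "pos", "strand", "seq", "qwidth")
  p <- Rsamtools::ScanBamParam(what = what,
                               tag = if (sample_from == "RG") "RG" else character())
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(rec$pos)
  strand <- as.character(rec$strand)[keep]
  seqs <- rec$seq[keep]
  lead4 <- ifelse(strand == "+",
                  substr(as.character(Biostrings::subseq(seqs, 1L, 4L)), 1L, 4L),
                  as.character(Biostrings::reverseComplement(
                    Biostrings::subseq(seqs, Biostrings::width(seqs) - 3L))))
  sample_id <- if (sample_from == "RG") {
    as.character(rec$tag$RG[keep])
  } else {
    sub(":.*$", "", rec$qname[keep])
  }
  data.frame(sample_id = sample_id,
             chrom = as.character(rec$rname)[keep],
             start = rec$pos[keep],
             end = rec$pos[keep] + rec$qwidth[keep] - 1L,
             strand = strand,
             lead4 = lead4)
}

#' Read or write tag records as TSV
#'
#' The simulator's plain-text tag interchange format: one accepted tag
#' per row, columns \code{sample_id}, \code{chrom}, \code{pos} (1-based
#' site position), \code{strand}. Reading expands each row back into a
#' tag record anchored at the CCGG so the same extraction path applies.
#'
#' @param path TSV file path.
#' @param tags data.frame with columns sample_id, chrom, pos, strand.
#' @return \code{read_tags_tsv}: a tag data.frame; \code{write_tags_tsv}:
#'   the path, invisibly.
#' @name tags_tsv
#' @export
read_tags_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "chrom", "pos", "strand")
  if (!all(req %in% names(x)))
    stop("tags TSV must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  # a 4 bp record anchors the site identically on either strand
  data.frame(sample_id = as.character(x$sample_id),
             chrom = as.character(x$chrom),
             start = as.integer(x$pos),
             end = as.integer(x$pos) + 3L,
             strand = as.character(x$strand),
             lead4 = "CCGG")
}

#' @rdname tags_tsv
#' @export
write_tags_tsv <- function(tags, path) {
  utils::write.table(tags[, c("sample_id", "chrom", "pos", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
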