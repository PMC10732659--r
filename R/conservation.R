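# Conserved-window detection on pairwise alignments and IUPAC motif
# scanning, for placing DhmCs in their regulatory context (conserved
# non-coding elements, transcription factor binding sites).

#' Detect conserved windows in a pairwise alignment
#'
#' Consumes a gapped pairwise alignment (two equal-length strings) and
#' reports runs of high identity on the reference coordinate system:
#' per reference base the partner base either matches or not (a gap is
#' a mismatch); identity is averaged over sliding windows, windows at
#' or above \code{min_identity} are merged into maximal intervals, and
#' intervals of at least \code{min_len} reference bp are reported with
#' their mean per-base identity.
#'
#' @param ref_aln,partner_aln aligned sequences (equal-length character
#'   strings, gaps as \code{"-"}).
#' @param window sliding-window width in reference bp.
#' @param min_identity window identity threshold (proportion).
#' @param min_len minimum reported interval length (reference bp).
#' @param chrom chromosome label for the output.
#' @param offset 1-based reference coordinate of the first reference
#'   base in the alignment (default 1).
#' @param partner partner species/sequence id.
#' @return data.frame: \code{chrom}, \code{start}, \code{end} (1-based
#'   inclusive reference coordinates), \code{identity}, \code{partner}.
#' @export
conserved_windows <- function(ref_aln, partner_aln, window = 50,
                              min_identity = 0.7, min_len = 100,
                              chrom = "ref", offset = 1L, partner = "partner") {
  r <- strsplit(toupper(ref_aln), "")[[1]]
  p <- strsplit(toupper(partner_aln), "")[[1]]
  if (length(r) != length(p))
    stop("aligned sequences must have equal length", call. = FALSE)
  refbase <- r != "-"
  match_ref <- (r == p)[refbase]  # per reference position; partner gap counts as mismatch
  n <- length(match_ref)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      identity = numeric(), partner = character())
  if (n < window) return(empty)
  cs <- cumsum(c(0L, match_ref))
  ident <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  pass <- ident >= min_identity  # window starting at reference position i
  if (!any(pass)) return(empty)
  covered <- rep(FALSE, n)
  for (off in 0:(window - 1)) {
    idx <- which(pass) + off
    covered[idx[idx <= n]] <- TRUE
  }
  rl <- rle(covered)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  iv <- which(rl$values & rl$lengths >= min_len)
  if (length(iv) == 0L) return(empty)
  data.frame(chrom = chrom,
             start = starts[iv] + offset - 1L,
             end = ends[iv] + offset - 1L,
             identity = vapply(iv, function(i)
               mean(match_ref[starts[i]:ends[i]]), 0),
             partner = partner)
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

#' Scan a sequence for an IUPAC motif on both strands
#'
#' Exact IUPAC matching (no position-weight scores): a position matches
#' when every base falls in the corresponding ambiguity set. Reverse-
#' strand hits are found by scanning with the reverse complement of the
#' motif and are reported on forward-strand coordinates (start = first
#' matched base on the forward strand).
#'
#' @param sequence character string or DNAString (plain ACGT).
#' @param motif IUPAC motif string, e.g. \code{"CAGCTG"}.
#' @param motif_id label echoed in the output.
#' @return data.frame: \code{start} (1-based), \code{strand},
#'   \code{motif_id}, \code{match} (forward-strand sequence at the hit).
#' @export
motif_scan <- function(sequence, motif, motif_id = motif) {
  seq <- Biostrings::DNAString(toupper(as.character(sequence)))
  motif <- toupper(motif)
  if (!all(strsplit(motif, "")[[1]] %in% names(IUPAC_SETS)))
    stop("motif contains a non-IUPAC character", call. = FALSE)
  scan_one <- function(pat, strand) {
    m <- Biostrings::matchPattern(pat, seq, fixed = FALSE)
    if (length(m) == 0L) return(NULL)
    data.frame(start = BiocGenerics::start(m), strand = strand,
               motif_id = motif_id,
               match = as.character(m))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  fwd <- scan_one(motif, "+")
  rev <- if (rc == motif) {
    # palindromic motif: every forward hit is also a reverse-strand hit
    if (!is.null(fwd)) transform(fwd, strand = "-")
  } else scan_one(rc, "-")
  out <- rbind(fwd, rev)
  if (is.null(out))
    return(data.frame(start = integer(), strand = character(),
                      motif_id = character(), match = character()))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place a DhmC in its conserved/motif context
#'
#' Reports whether the site falls inside a conserved interval and the
#' signed distance to the nearest motif hit (hit start minus site
#' position). Positive distances are downstream: on the gene's coding
#' strand when a gene strand is supplied, otherwise on the forward
#' strand.
#'
#' @param site_pos 1-based site position.
#' @param intervals data.frame from \code{\link{conserved_windows}}
#'   (may be empty).
#' @param hits data.frame from \code{\link{motif_scan}} (may be empty).
#' @param gene_strand \code{"+"} (default) or \code{"-"}; flips the
#'   downstream direction.
#' @param radius hits farther than this are ignored (default 10000 bp).
#' @return list: \code{conserved} (logical), \code{nearest_hit}
#'   (row index into \code{hits} or NA), \code{distance} (signed bp,
#'   positive downstream, NA when no hit within radius).
#' @export
dhmc_context <- function(site_pos, intervals, hits, gene_strand = "+",
                         radius = 10000) {
  conserved <- nrow(intervals) > 0 &&
    any(site_pos >= intervals$start & site_pos <= intervals$end)
  nearest <- NA_integer_
  distance <- NA_real_
  if (nrow(hits) > 0) {
    d <- hits$start - site_pos
    ok <- abs(d) <= radius
    if (any(ok)) {
      nearest <- which(ok)[which.min(abs(d[ok]))]
      distance <- d[nearest]
      if (gene_strand == "-") distance <- -distance
    }
  }
  list(conserved = conserved, nearest_hit = nearest, distance = distance)
}

#' Write conserved intervals as BED
#'
#' BED is 0-based half-open; the 1-based inclusive intervals are
#' converted at this boundary.
#'
#' @param intervals data.frame from \code{\link{conserved_windows}}.
#' @param path output path.
#' @export
write_conserved_bed <- function(intervals, path) {
  bed <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1L,
                    end = intervals$end,
                    name = paste0("conserved_", seq_len(nrow(intervals))),
                    score = round(1000 * intervals$identity))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
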