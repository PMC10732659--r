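# Shared fixture builders; everything is generated in code.

# counts object with explicit counts and groups (equal split by default)
make_counts <- function(m, groups = NULL, lib_size = NULL) {
  m <- as.matrix(m)
  if (is.null(groups))
    groups <- rep(c("fast", "slow"), each = ncol(m) / 2)
  if (is.null(rownames(m)))
    rownames(m) <- paste0("chr1:", seq_len(nrow(m)) * 10)
  samples <- data.frame(sample_id = paste0("s", seq_len(ncol(m))),
                        group = groups)
  x <- rrhp_counts(m, samples)
  if (!is.null(lib_size)) x$lib_size <- stats::setNames(lib_size, samples$sample_id)
  x
}

# naive overlapping-match CCGG scan (independent of Biostrings)
naive_ccgg <- function(s) {
  out <- integer()
  for (i in seq_len(max(0L, nchar(s) - 3L)))
    if (substr(s, i, i + 3L) == "CCGG") out <- c(out, i)
  out
}

# tiny gene model set used across annotation tests:
# gene A: chr1 +, 10000..12000, exons 10000-10400 and 11600-12000
# gene B: chr1 -, 30000..33000, exons 30000-30500 and 32500-33000
# gene C: chr2 +, 5000..6000, single exon covering the gene
toy_models <- function() {
  genes <- data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000L, 30000L, 5000L),
    end = c(12000L, 33000L, 6000L),
    strand = c("+", "-", "+"))
  exons <- data.frame(
    gene_id = c("geneA", "geneA", "geneB", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(10000L, 11600L, 30000L, 32500L, 5000L),
    end = c(10400L, 12000L, 30500L, 33000L, 6000L))
  list(genes = genes, exons = exons)
}

# brute-force nearest-TSS oracle with the lexicographic tie rule
brute_nearest_tss <- function(sites, models) {
  g <- models$genes
  tss <- ifelse(g$strand == "+", g$start, g$end)
  out <- data.frame(gene_id = rep(NA_character_, nrow(sites)),
                    d_tss = rep(NA_real_, nrow(sites)))
  for (i in seq_len(nrow(sites))) {
    cand <- which(g$chrom == sites$chrom[i])
    if (length(cand) == 0L) next
    d <- abs(sites$pos[i] - tss[cand])
    best <- cand[order(d, g$gene_id[cand])][1]
    dist <- sites$pos[i] - tss[best]
    up <- if (g$strand[best] == "+") dist < 0 else dist > 0
    out$gene_id[i] <- g$gene_id[best]
    out$d_tss[i] <- if (up) -abs(dist) else abs(dist)
  }
  out
}

# positionwise IUPAC scan oracle (no pattern matching library)
brute_motif_scan <- function(seq, motif) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  ss <- strsplit(toupper(seq), "")[[1]]
  scan <- function(pat) {
    pp <- strsplit(pat, "")[[1]]
    k <- length(pp)
    hits <- integer()
    for (i in seq_len(length(ss) - k + 1L))
      if (all(mapply(function(b, p) b %in% iupac[[p]], ss[i:(i + k - 1L)], pp)))
        hits <- c(hits, i)
    hits
  }
  rc <- paste(rev(comp[strsplit(toupper(motif), "")[[1]]]), collapse = "")
  list(fwd = scan(toupper(motif)), rev = scan(rc))
}
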