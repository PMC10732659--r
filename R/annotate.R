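# Genomic feature annotation of CCGG sites against gene models,
# feature-composition comparison across site sets, nearest-TSS
# assignment, and GMT-based hypergeometric over-representation.

FEATURE_LEVELS <- c("promoter", "TTS", "exon", "intron", "intergenic")

validate_gene_models <- function(models) {
  g <- models$genes
  e <- models$exons
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(g)))
    stop("gene table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(g)) {
    if (!all(g$strand %in% c("+", "-"))) stop("gene strand must be +/-", call. = FALSE)
    if (any(g$end < g$start)) stop("gene end precedes start", call. = FALSE)
  }
  if (nrow(e)) {
    m <- match(e$gene_id, g$gene_id)
    if (anyNA(m)) stop("exon with unknown gene_id", call. = FALSE)
    if (any(e$start < g$start[m] | e$end > g$end[m]))
      stop("exon outside its gene span", call. = FALSE)
  }
  invisible(models)
}

# TSS/TES are strand-aware anchors
tss_of <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end)
tes_of <- function(genes) ifelse(genes$strand == "+", genes$end, genes$start)

# strand-aware window around an anchor: offsets are in coding-strand bp
anchor_window <- function(anchor, strand, up, down) {
  s1 <- ifelse(strand == "+", anchor + up, anchor - down)
  s2 <- ifelse(strand == "+", anchor + down, anchor - up)
  cbind(pmin(s1, s2), pmax(s1, s2))
}

#' Nearest transcription start site
#'
#' For each site, the gene whose TSS is closest by absolute genomic
#' distance (same chromosome). The signed distance is negative when the
#' site lies upstream of the gene on its coding strand. Exact ties in
#' absolute distance go to the lexicographically smaller gene id.
#'
#' @param sites data.frame with \code{chrom}, \code{pos}.
#' @param models gene models (list with \code{genes} and \code{exons}
#'   data.frames, as from \code{\link{sim_genome}} or
#'   \code{\link{read_gene_models_gff3}}).
#' @return data.frame with \code{gene_id} (NA when the chromosome has no
#'   gene) and signed \code{d_tss}.
#' @export
nearest_tss <- function(sites, models) {
  validate_gene_models(models)
  g <- models$genes
  out <- data.frame(gene_id = rep(NA_character_, nrow(sites)),
                    d_tss = rep(NA_real_, nrow(sites)))
  if (nrow(g) == 0L || nrow(sites) == 0L) return(out)
  tss <- tss_of(g)
  for (ch in unique(sites$chrom)) {
    gi <- which(g$chrom == ch)
    si <- which(sites$chrom == ch)
    if (length(gi) == 0L || length(si) == 0L) next
    # order candidate genes by (TSS, gene_id) so that findInterval
    # neighbours plus the id tie-break are deterministic
    o <- gi[order(tss[gi], g$gene_id[gi])]
    ts <- tss[o]
    pos <- sites$pos[si]
    iv <- findInterval(pos, ts)
    first_of_run <- match(ts, ts)  # genes sharing a TSS: first has smallest id
    lo <- first_of_run[pmax(iv, 1L)]
    hi <- first_of_run[pmin(iv + 1L, length(ts))]
    dlo <- abs(pos - ts[lo])
    dhi <- abs(pos - ts[hi])
    pick <- ifelse(dhi < dlo, hi, lo)
    # tie between the two flanking TSSs: smaller gene id wins
    tie <- which(dhi == dlo & hi != lo)
    if (length(tie)) {
      a <- g$gene_id[o[lo[tie]]]; b <- g$gene_id[o[hi[tie]]]
      pick[tie] <- ifelse(b < a, hi[tie], lo[tie])
    }
    # equal-TSS genes are adjacent in o and ordered by id already
    gsel <- o[pick]
    dist <- pos - tss[gsel]
    upstream <- ifelse(g$strand[gsel] == "+", dist < 0, dist > 0)
    out$gene_id[si] <- g$gene_id[gsel]
    out$d_tss[si] <- ifelse(upstream, -abs(dist), abs(dist))
  }
  out
}

#' Classify sites into genomic feature classes
#'
#' Each site receives exactly one class by the priority order promoter >
#' TTS > exon > intron > intergenic, the behaviour of standard peak
#' annotators. Promoter and TTS windows are strand-aware offsets around
#' the TSS and transcription end (defaults -1000..+100 and -100..+1000
#' coding-strand bp). When a site hits the same-priority feature of two
#' genes, the gene with the smaller absolute TSS distance wins. The
#' reported gene and signed TSS distance refer to the assigned gene for
#' genic classes and to the nearest TSS genome-wide for intergenic
#' sites.
#'
#' @param sites data.frame with \code{chrom}, \code{pos}.
#' @param models gene models list (\code{genes}, \code{exons}).
#' @param promoter_window,tts_window length-2 integer vectors of
#'   coding-strand offsets around TSS and transcription end.
#' @return data.frame: \code{chrom}, \code{pos}, \code{class} (factor),
#'   \code{gene_id}, \code{d_tss}.
#' @export
classify_features <- function(sites, models,
                              promoter_window = c(-1000L, 100L),
                              tts_window = c(-100L, 1000L)) {
  validate_gene_models(models)
  if (promoter_window[1] >= promoter_window[2] || tts_window[1] >= tts_window[2])
    stop("degenerate annotation window", call. = FALSE)
  g <- models$genes
  e <- models$exons
  n <- nrow(sites)
  cls <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  nt <- nearest_tss(sites, models)

  if (nrow(g) && n) {
    prom <- anchor_window(tss_of(g), g$strand, promoter_window[1], promoter_window[2])
    tts <- anchor_window(tes_of(g), g$strand, tts_window[1], tts_window[2])
    feats <- rbind(
      data.frame(chrom = g$chrom, start = prom[, 1], end = prom[, 2],
                 gene_id = g$gene_id, class = "promoter", priority = 1L),
      data.frame(chrom = g$chrom, start = tts[, 1], end = tts[, 2],
                 gene_id = g$gene_id, class = "TTS", priority = 2L),
      if (nrow(e)) data.frame(chrom = e$chrom, start = e$start, end = e$end,
                              gene_id = e$gene_id, class = "exon", priority = 3L),
      data.frame(chrom = g$chrom, start = g$start, end = g$end,
                 gene_id = g$gene_id, class = "intron", priority = 4L))
    for (ch in unique(sites$chrom)) {
      fi <- which(feats$chrom == ch)
      si <- which(sites$chrom == ch)
      if (length(fi) == 0L || length(si) == 0L) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(start = sites$pos[si], width = 1L),
        IRanges::IRanges(start = feats$start[fi], end = feats$end[fi]))
      if (length(ov) == 0L) next
      qh <- si[S4Vectors::queryHits(ov)]
      sh <- fi[S4Vectors::subjectHits(ov)]
      tssd <- abs(sites$pos[qh] - tss_of(g)[match(feats$gene_id[sh], g$gene_id)])
      o <- order(qh, feats$priority[sh], tssd, feats$gene_id[sh])
      first <- o[!duplicated(qh[o])]
      cls[qh[first]] <- feats$class[sh[first]]
      gene[qh[first]] <- feats$gene_id[sh[first]]
    }
  }
  # genic sites report their assigned gene's TSS distance; intergenic
  # sites carry no gene (nearest-TSS assignment is a separate step)
  d_tss <- rep(NA_real_, n)
  genic <- !is.na(gene)
  if (any(genic)) {
    gi <- match(gene[genic], g$gene_id)
    dist <- sites$pos[genic] - tss_of(g)[gi]
    up <- ifelse(g$strand[gi] == "+", dist < 0, dist > 0)
    d_tss[genic] <- ifelse(up, -abs(dist), abs(dist))
  }
  data.frame(chrom = sites$chrom, pos = sites$pos,
             class = factor(cls, levels = FEATURE_LEVELS),
             gene_id = gene, d_tss = d_tss)
}

#' Feature-class composition across site sets
#'
#' Fraction of sites per feature class for each set (e.g. the
#' whole-genome CCGG background, all observed sites, the filtered
#' matrix, and the DhmC calls), plus percentage-point differences
#' against the background and the aggregate gene-body share (all
#' non-intergenic classes).
#'
#' @param site_sets named list of site data.frames (\code{chrom},
#'   \code{pos}); the first set (or one named \code{"background"}) is
#'   the reference.
#' @param models gene models list.
#' @param ... passed to \code{\link{classify_features}}.
#' @return list with \code{fractions} (class x set), \code{delta_pp}
#'   (percentage points vs background), and \code{gene_body_share} per
#'   set.
#' @export
feature_enrichment <- function(site_sets, models, ...) {
  stopifnot(is.list(site_sets), length(site_sets) >= 1L)
  if (is.null(names(site_sets)))
    names(site_sets) <- paste0("set", seq_along(site_sets))
  ref <- if ("background" %in% names(site_sets)) "background" else names(site_sets)[1]
  frac <- sapply(site_sets, function(s) {
    cl <- classify_features(s, models, ...)$class
    tab <- table(cl)
    as.numeric(tab) / max(1L, sum(tab))
  })
  rownames(frac) <- FEATURE_LEVELS
  delta <- 100 * (frac - frac[, ref])
  list(fractions = frac, delta_pp = delta,
       gene_body_share = colSums(frac[setdiff(FEATURE_LEVELS, "intergenic"), ,
                                      drop = FALSE]))
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated name, description, then
#' member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  out
}

#' Hypergeometric over-representation of gene sets
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the actual overlap between the query genes and
#' the set, both intersected with the background universe; BH-adjusted
#' across tested sets.
#'
#' @param query character vector of genes of interest (must be a subset
#'   of the background).
#' @param background character vector, the gene universe.
#' @param gene_sets named list of character vectors (see
#'   \code{\link{read_gmt}}).
#' @param alpha significance threshold on the adjusted p (default 0.01).
#' @return data.frame with per-set overlap counts, \code{p}, \code{q}
#'   and \code{significant}; ordered by p.
#' @export
hypergeom_ora <- function(query, background, gene_sets, alpha = 0.01) {
  background <- unique(background)
  query <- unique(query)
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  if (!all(query %in% background))
    stop("query genes must be contained in the background", call. = FALSE)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, query_size = n,
               background_size = N, p = min(1, p))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  out[order(out$p), , drop = FALSE]
}
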