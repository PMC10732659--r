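# Allelic and haplotype association of biallelic loci with the growth
# group, under locus-wise missingness filtering and BH-FDR correction.
# In a full-sib design with random group assignment this is a null
# model: no locus should survive FDR.

#' Filter genotype loci for association testing
#'
#' Keeps loci with zero missing genotype calls (missingness is
#' confounded with group-specific 5hmC enrichment in RRHP data, so any
#' missing call drops the locus) and exactly two observed alleles:
#' monomorphic and multi-allelic loci are excluded.
#'
#' @param geno loci x samples matrix of alt-allele counts (0/1/2,
#'   \code{NA} missing).
#' @param loci optional data.frame with an \code{n_alleles} column for
#'   loci whose raw calls had more than two alleles.
#' @return list with \code{keep} (logical per locus) and \code{report}
#'   (counts of input, missing-dropped, non-biallelic-dropped, kept).
#' @export
filter_loci <- function(geno, loci = NULL) {
  n_in <- nrow(geno)
  has_missing <- apply(geno, 1L, anyNA)
  multi <- if (!is.null(loci) && !is.null(loci$n_alleles)) loci$n_alleles != 2L
           else rep(FALSE, n_in)
  # observed alleles: ref present unless all calls are 2; alt unless all 0
  nonmiss <- !has_missing
  mono <- rep(FALSE, n_in)
  rs <- rowSums(geno, na.rm = TRUE)
  nm <- rowSums(!is.na(geno))
  mono <- rs == 0L | rs == 2L * nm
  keep <- !has_missing & !multi & !mono
  list(keep = keep,
       report = list(n_input = n_in,
                     n_missing = sum(has_missing),
                     n_not_biallelic = sum((multi | mono) & !has_missing),
                     n_kept = sum(keep)))
}

#' Classify per-locus polymorphism by group
#'
#' A locus is polymorphic within a group when that group's samples carry
#' at least two alleles (any heterozygote, or both homozygote classes).
#'
#' @param geno genotype matrix (0/1/2/NA).
#' @param groups character vector of group labels per column.
#' @return factor per locus: \code{fast_only}, \code{slow_only},
#'   \code{both}, or \code{none}.
#' @export
classify_polymorphism <- function(geno, groups) {
  poly_in <- function(cols) {
    g <- geno[, cols, drop = FALSE]
    has_ref <- rowSums(g < 2L, na.rm = TRUE) > 0L
    has_alt <- rowSums(g > 0L, na.rm = TRUE) > 0L
    has_ref & has_alt
  }
  pf <- poly_in(groups == "fast")
  ps <- poly_in(groups == "slow")
  out <- rep("none", nrow(geno))
  out[pf & ps] <- "both"
  out[pf & !ps] <- "fast_only"
  out[!pf & ps] <- "slow_only"
  factor(out, levels = c("fast_only", "slow_only", "both", "none"))
}

allele_table <- function(g, groups) {
  # 2 x 2 allele-count table: rows groups (fast, slow), cols (alt, ref)
  cnt <- function(cols) {
    gg <- g[cols]
    gg <- gg[!is.na(gg)]
    c(alt = sum(gg), ref = 2L * length(gg) - sum(gg))
  }
  rbind(fast = cnt(groups == "fast"), slow = cnt(groups == "slow"))
}

#' Allelic association test of one locus with group
#'
#' Builds the 2x2 allele-count table (each non-missing sample
#' contributes two alleles) and tests group-by-allele independence: a
#' 1-df chi-square without continuity correction when all expected cell
#' counts exceed 5, otherwise the two-sided Fisher exact test
#' (summing tables with probability not exceeding the observed one) —
#' the basic allelic association test of standard GWAS tooling.
#'
#' @param g genotype vector for the locus (0/1/2/NA per sample).
#' @param groups group labels per sample.
#' @return list with \code{table}, \code{statistic} (chi-square, NA for
#'   Fisher), \code{p}, \code{test} (\code{"chi-square"} or
#'   \code{"fisher"}).
#' @export
allelic_test <- function(g, groups) {
  if (all(is.na(g[groups == "fast"])) || all(is.na(g[groups == "slow"])))
    stop("a group has no non-missing genotypes", call. = FALSE)
  tab <- allele_table(g, groups)
  test_counts_2xk(tab)
}

# shared 2 x k (groups x categories) independence test with the
# expected-count rule for choosing asymptotic vs exact
test_counts_2xk <- function(tab, max_exact_k = 4L) {
  tab <- as.matrix(tab)
  keep <- colSums(tab) > 0L
  tab2 <- tab[, keep, drop = FALSE]
  k <- ncol(tab2)
  if (k < 2L || any(rowSums(tab) == 0L))
    return(list(table = tab, statistic = NA_real_, p = 1, test = "degenerate"))
  expected <- outer(rowSums(tab2), colSums(tab2)) / sum(tab2)
  if (all(expected > 5)) {
    ct <- stats::chisq.test(tab2, correct = FALSE)
    list(table = tab, statistic = unname(ct$statistic), p = ct$p.value,
         test = "chi-square")
  } else if (k <= max_exact_k) {
    ft <- stats::fisher.test(tab2, workspace = 2e6)
    list(table = tab, statistic = NA_real_, p = ft$p.value, test = "fisher")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab2, correct = FALSE,
                                             simulate.p.value = TRUE, B = 2000))
    list(table = tab, statistic = unname(ct$statistic), p = ct$p.value,
         test = "chi-square-mc")
  }
}

#' Haplotype association test
#'
#' Tests a k x 2 table of read-phased haplotype counts by group:
#' chi-square with k - 1 df when all expected cells are at least 5,
#' exact enumeration (Fisher) when any expected cell is smaller and k
#' is at most 4. With k = 2 this reduces exactly to the allelic test.
#'
#' @param counts k x 2 matrix (haplotypes x groups) or 2 x k; the group
#'   dimension is detected from dimnames or taken as columns.
#' @return list as in \code{\link{allelic_test}}.
#' @export
haplotype_test <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L && nrow(counts) == 2L) counts <- t(counts)
  if (ncol(counts) != 2L) stop("need a k x 2 haplotype-by-group table", call. = FALSE)
  test_counts_2xk(t(counts))
}

#' Genome-wide association scan and FDR summary
#'
#' Runs \code{\link{allelic_test}} at every kept locus, BH-adjusts the p
#' values across loci, and reports how many loci fall below the
#' highlight p threshold and below the FDR threshold.
#'
#' @param geno genotype matrix (0/1/2/NA).
#' @param groups group labels per column.
#' @param loci optional locus table (used by the missing/biallelic
#'   filter and echoed in the results).
#' @param p_highlight nominal p threshold reported alongside FDR
#'   (default 0.01).
#' @param q_threshold BH threshold (default 0.05).
#' @return list of class \code{assoc_scan}: \code{results} data.frame
#'   (locus, allele counts, statistic, p, q, test), \code{filter}
#'   report, \code{n_p_below}, \code{n_q_below}.
#' @export
assoc_scan <- function(geno, groups, loci = NULL, p_highlight = 0.01,
                       q_threshold = 0.05) {
  fl <- filter_loci(geno, loci)
  idx <- which(fl$keep)
  rows <- lapply(idx, function(i) {
    r <- allelic_test(geno[i, ], groups)
    data.frame(locus = rownames(geno)[i] %||% as.character(i),
               fast_alt = r$table["fast", "alt"], fast_ref = r$table["fast", "ref"],
               slow_alt = r$table["slow", "alt"], slow_ref = r$table["slow", "ref"],
               statistic = r$statistic, p = r$p, test = r$test)
  })
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus = character(), fast_alt = integer(), fast_ref = integer(),
               slow_alt = integer(), slow_ref = integer(),
               statistic = numeric(), p = numeric(), test = character())
  res$q <- bh_adjust(res$p)
  structure(list(results = res, filter = fl$report,
                 n_tested = nrow(res),
                 n_p_below = sum(res$p < p_highlight),
                 n_q_below = sum(res$q < q_threshold),
                 p_highlight = p_highlight, q_threshold = q_threshold),
            class = "assoc_scan")
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("Allelic association scan: %d loci tested (of %d input)\n",
              x$n_tested, x$filter$n_input))
  cat(sprintf("  %d loci at p < %g; %d at q < %g after BH correction\n",
              x$n_p_below, x$p_highlight, x$n_q_below, x$q_threshold))
  invisible(x)
}

#' Read and write genotype matrices as TSV
#'
#' Rows are loci, first columns \code{locus_id}, \code{chrom},
#' \code{pos}, \code{n_alleles}, then one 0/1/2/NA column per sample.
#'
#' @param sim list as returned by \code{\link{sim_fullsib_genotypes}}.
#' @param path file path.
#' @name genotypes_tsv
#' @export
write_genotypes_tsv <- function(sim, path) {
  df <- cbind(sim$loci, as.data.frame(sim$geno))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genotypes_tsv
#' @param samples sample table (\code{sample_id}, \code{group}).
#' @export
read_genotypes_tsv <- function(path, samples) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("locus_id", "chrom", "pos", "n_alleles")
  geno <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(geno) <- df$locus_id
  list(geno = geno[, samples$sample_id, drop = FALSE],
       loci = df[, intersect(meta, names(df)), drop = FALSE],
       samples = samples)
}
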