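# Synthetic genomes, tag counts and full-sib genotypes with known ground
# truth, emulating the design of a two-group (fast vs slow growth) RRHP
# liver study: 5 samples per group, strongly unbalanced library sizes
# (fast ~3x slow), a minority of CCGG sites carrying group-specific
# log2 effects, negative-binomial count noise, and full siblings with no
# true genetic differentiation between groups.

#' Simulate a genome with CCGG sites and gene models
#'
#' Generates random chromosome sequences with MspI (CCGG) sites at
#' approximately the requested mean spacing (extra motifs arising by
#' chance in the random background are accounted for), plus
#' non-overlapping gene models with exon/intron structure fully inside
#' their chromosome. The returned CCGG catalogue is the exhaustive scan
#' of the emitted sequences, so it is exact by construction.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param ccgg_spacing_mean target mean spacing between CCGG sites (bp,
#'   must be >= 8 so adjacent planted motifs cannot overlap).
#' @param n_genes total number of genes across chromosomes.
#' @param exons_per_gene exons per gene.
#' @param gene_length gene span in bp.
#' @param seed RNG seed; all randomness flows from it.
#' @return list with \code{genome} (DNAStringSet), \code{genes} (list of
#'   data.frames \code{genes} and \code{exons}), \code{ccgg} (catalogue
#'   data.frame from \code{\link{catalog_ccgg}}).
#' @export
sim_genome <- function(n_chroms = 1, chrom_length = 100000,
                       ccgg_spacing_mean = 100, n_genes = 20,
                       exons_per_gene = 3, gene_length = 2000, seed = 1) {
  stop_if_not_scalar_count(chrom_length, "chrom_length", 1)
  if (ccgg_spacing_mean < 8)
    stop("ccgg_spacing_mean must be >= 8 to honor non-overlap", call. = FALSE)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_chroms), function(i) {
      s <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)
      # plant CCGG at a density that, combined with chance occurrences in
      # random sequence (1/256 per bp), hits the requested mean spacing
      plant_density <- max(1 / ccgg_spacing_mean - 1 / 256, 0)
      if (plant_density > 0) {
        gaps <- pmax(8, round(stats::rexp(ceiling(chrom_length * plant_density * 2),
                                          rate = plant_density)))
        pos <- cumsum(gaps)
        pos <- pos[pos + 3 <= chrom_length]
        for (p in pos) s[p:(p + 3)] <- c("C", "C", "G", "G")
      }
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(n_chroms))
    genome <- Biostrings::DNAStringSet(seqs)

    genes <- exons <- NULL
    if (n_genes > 0) {
      chrom_of <- sort(rep_len(seq_len(n_chroms), n_genes))
      per_chrom <- table(factor(chrom_of, levels = seq_len(n_chroms)))
      glist <- list(); elist <- list(); gid <- 0L
      for (ci in seq_len(n_chroms)) {
        k <- as.integer(per_chrom[ci])
        if (k == 0L) next
        slot <- chrom_length %/% k
        if (slot < gene_length + 200)
          stop("chromosome too short for the requested non-overlapping genes",
               call. = FALSE)
        for (j in seq_len(k)) {
          gid <- gid + 1L
          margin <- slot - gene_length
          start <- (j - 1L) * slot + sample.int(margin - 100L, 1L) + 50L
          end <- start + gene_length - 1L
          strand <- sample(c("+", "-"), 1L)
          id <- sprintf("gene%03d", gid)
          glist[[gid]] <- data.frame(gene_id = id, chrom = names(seqs)[ci],
                                     start = start, end = end, strand = strand)
          # evenly spaced exons inside the span
          exon_len <- max(50L, gene_length %/% (2L * exons_per_gene))
          step <- (gene_length - exon_len) %/% max(1L, exons_per_gene - 1L)
          es <- start + step * (seq_len(exons_per_gene) - 1L)
          elist[[gid]] <- data.frame(gene_id = id, chrom = names(seqs)[ci],
                                     start = es, end = pmin(es + exon_len - 1L, end))
        }
      }
      genes <- do.call(rbind, glist)
      exons <- do.call(rbind, elist)
      rownames(genes) <- rownames(exons) <- NULL
    } else {
      genes <- data.frame(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(), strand = character())
      exons <- data.frame(gene_id = character(), chrom = character(),
                          start = integer(), end = integer())
    }
    list(genome = genome,
         genes = list(genes = genes, exons = exons),
         ccgg = catalog_ccgg(genome))
  })
}

#' Simulate per-site 5hmC ground truth
#'
#' Assigns each catalogued CCGG site a base rate (expected tags per unit
#' library size, log-normal across sites) and plants group-specific log2
#' effects at an exact fraction of sites. Effect signs follow the study
#' pattern that most differential sites are hyperhydroxymethylated in
#' the fast-growing group (default share 0.84, the observed 2237:440
#' ratio).
#'
#' @param catalog CCGG catalogue data.frame (\code{chrom}, \code{pos}).
#' @param frac_differential fraction of sites carrying a true effect;
#'   exactly \code{round(frac_differential * nrow(catalog))} sites are
#'   flagged.
#' @param effect_log2 absolute log2 fold change at differential sites.
#' @param hyper_share share of differential sites hyper in the fast
#'   group; the hyper count is \code{round(hyper_share * n_differential)}.
#' @param rate_sdlog log-scale SD of the base-rate distribution.
#' @param seed RNG seed.
#' @return data.frame: \code{chrom}, \code{pos}, \code{base_rate},
#'   \code{group_log2_effect}, \code{is_differential}. Mean base rate is
#'   calibrated to 1/n sites so an unbiased library spreads evenly.
#' @export
sim_hmc_truth <- function(catalog, frac_differential = 0.1, effect_log2 = 2,
                          hyper_share = 0.84, rate_sdlog = 1, seed = 1) {
  n <- nrow(catalog)
  if (n == 0L) stop("empty catalog", call. = FALSE)
  if (frac_differential < 0 || frac_differential > 1)
    stop("frac_differential must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    base_rate <- stats::rlnorm(n, meanlog = log(1 / n) - rate_sdlog^2 / 2,
                               sdlog = rate_sdlog)
    effect <- numeric(n)
    n_diff <- round(frac_differential * n)
    if (n_diff > 0 && effect_log2 != 0) {
      idx <- sample.int(n, n_diff)
      n_hyper <- round(hyper_share * n_diff)
      sign <- rep(-1, n_diff)
      if (n_hyper > 0) sign[seq_len(n_hyper)] <- 1
      effect[idx] <- sign * effect_log2
    }
    data.frame(chrom = catalog$chrom, pos = catalog$pos,
               base_rate = base_rate,
               group_log2_effect = effect,
               is_differential = effect != 0)
  })
}

#' Simulate RRHP tag counts
#'
#' Draws the count of site i in sample j from a negative binomial with
#' mean \code{lib_size[j] * base_rate[i] * 2^(effect[i] * I(j in fast))}
#' and variance \code{mu + dispersion * mu^2}; dispersion 0 gives
#' Poisson noise. Default library sizes mirror the study's imbalance:
#' fast-group libraries about three times the slow-group ones, because
#' more hydroxymethylation yields more RRHP fragments.
#'
#' @param truth data.frame from \code{\link{sim_hmc_truth}}.
#' @param n_per_group samples per group (default 5, the study design).
#' @param lib_sizes expected accepted tags per sample, fast group first;
#'   default \code{c(rep(60000, n), rep(20000, n))}.
#' @param nb_dispersion negative-binomial dispersion (>= 0).
#' @param seed RNG seed.
#' @return \code{\link{rrhp_counts}} object; the truth table is attached
#'   as attribute \code{"truth"}.
#' @export
sim_tag_counts <- function(truth, n_per_group = 5, lib_sizes = NULL,
                           nb_dispersion = 0.2, seed = 1) {
  if (nrow(truth) == 0L) stop("truth must be non-empty", call. = FALSE)
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  n_s <- 2L * n_per_group
  if (is.null(lib_sizes))
    lib_sizes <- c(rep(60000, n_per_group), rep(20000, n_per_group))
  if (length(lib_sizes) == 2L)
    lib_sizes <- rep(lib_sizes, each = n_per_group)
  if (length(lib_sizes) != n_s) stop("lib_sizes length mismatch", call. = FALSE)
  if (any(lib_sizes <= 0)) stop("lib_sizes must be positive", call. = FALSE)
  samples <- data.frame(
    sample_id = c(sprintf("fast%d", seq_len(n_per_group)),
                  sprintf("slow%d", seq_len(n_per_group))),
    group = rep(c("fast", "slow"), each = n_per_group))
  with_seed(seed, {
    fast <- samples$group == "fast"
    mu <- outer(truth$base_rate, lib_sizes) *
      2^(truth$group_log2_effect %o% as.numeric(fast))
    cnt <- if (nb_dispersion == 0) {
      stats::rpois(length(mu), lambda = mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
    }
    m <- matrix(as.integer(cnt), nrow = nrow(truth),
                dimnames = list(paste(truth$chrom, truth$pos, sep = ":"),
                                samples$sample_id))
    out <- rrhp_counts(m, samples,
                       sites = data.frame(chrom = truth$chrom, pos = truth$pos))
    attr(out, "truth") <- truth
    out
  })
}

#' Replay a count matrix as a tag stream
#'
#' Expands each count into that many tag observations (one row per tag),
#' the inverse of \code{\link{build_count_matrix}} up to row order.
#'
#' @param x \code{\link{rrhp_counts}} object.
#' @return data.frame with columns \code{sample_id}, \code{chrom},
#'   \code{pos}, \code{strand} (all \code{"+"}).
#' @export
counts_to_tags <- function(x) {
  stopifnot(inherits(x, "rrhp_counts"))
  idx <- which(x$counts > 0, arr.ind = TRUE)
  n <- x$counts[idx]
  data.frame(
    sample_id = rep(x$samples$sample_id[idx[, 2]], n),
    chrom = rep(x$sites$chrom[idx[, 1]], n),
    pos = rep(x$sites$pos[idx[, 1]], n),
    strand = "+")
}

#' Simulate full-sib biallelic genotypes
#'
#' Two parents are drawn from a founder pool with the given minor-allele
#' frequency; offspring genotypes follow Mendelian segregation (each
#' offspring inherits one uniformly chosen allele from each parent), and
#' offspring are assigned to the fast/slow groups independently of
#' genotype. This is the null model of the study design: full siblings
#' with no systematic allele-frequency differentiation between growth
#' groups. Genotype calls are masked at random to emulate missingness.
#'
#' @param n_loci number of loci.
#' @param n_offspring_per_group offspring per group (default 5).
#' @param parent_maf founder minor-allele frequency (0..0.5).
#' @param missing_rate probability a genotype call is missing.
#' @param parents optional 2 x n_loci matrix of parental genotypes
#'   (0/1/2) overriding the founder draw, e.g. to fix an Aa x Aa cross.
#' @param seed RNG seed.
#' @return list with \code{geno} (loci x samples matrix of alt-allele
#'   counts 0/1/2, \code{NA} for missing), \code{loci} data.frame
#'   (\code{locus_id}, \code{chrom}, \code{pos}, \code{n_alleles}),
#'   \code{samples} data.frame, \code{parents} (2-row matrix of parental
#'   genotypes).
#' @export
sim_fullsib_genotypes <- function(n_loci = 2000, n_offspring_per_group = 5,
                                  parent_maf = 0.3, missing_rate = 0,
                                  parents = NULL, seed = 1) {
  if (parent_maf < 0 || parent_maf > 0.5)
    stop("parent_maf must be in [0, 0.5]", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  n_off <- 2L * n_offspring_per_group
  with_seed(seed, {
    if (is.null(parents))
      parents <- matrix(stats::rbinom(2L * n_loci, 2L, parent_maf), nrow = 2L)
    stopifnot(nrow(parents) == 2L, ncol(parents) == n_loci)
    # transmitted allele from parent p: Bernoulli(genotype / 2)
    transmit <- function(pg) {
      matrix(stats::rbinom(n_loci * n_off, 1L,
                           rep(pg / 2, times = n_off)), nrow = n_loci)
    }
    geno <- transmit(parents[1L, ]) + transmit(parents[2L, ])
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(geno)) < missing_rate, nrow = n_loci)
      geno[mask] <- NA_integer_
    }
    samples <- data.frame(
      sample_id = c(sprintf("fast%d", seq_len(n_offspring_per_group)),
                    sprintf("slow%d", seq_len(n_offspring_per_group))),
      group = rep(c("fast", "slow"), each = n_offspring_per_group))
    colnames(geno) <- samples$sample_id
    loci <- data.frame(locus_id = sprintf("locus%05d", seq_len(n_loci)),
                       chrom = "chr1", pos = seq_len(n_loci) * 100L,
                       n_alleles = 2L)
    rownames(geno) <- loci$locus_id
    list(geno = geno, loci = loci, samples = samples, parents = parents)
  })
}
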