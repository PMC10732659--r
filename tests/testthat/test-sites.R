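ref <- c(chr1 = paste0(strrep("A", 100), "CCGG", strrep("T", 168),
                       "CCGG", strrep("A", 24)))
# CCGG at 101 and at 273 (so a minus-strand tag ending at 276 anchors at 273)

test_that("site extraction follows the palindromic coordinate convention", {
  plus <- data.frame(sample_id = "a", chrom = "chr1", start = 101L, end = 130L,
                     strand = "+", lead4 = "CCGG")
  expect_equal(extract_site(plus, ref)$pos, 101L)
  minus <- data.frame(sample_id = "a", chrom = "chr1", start = 200L, end = 276L,
                      strand = "-", lead4 = "CCGG")
  expect_equal(extract_site(minus, ref)$pos, 273L)  # end - 3
  bad <- data.frame(sample_id = "a", chrom = "chr1", start = 101L, end = 130L,
                    strand = "+", lead4 = "ACGG")
  expect_null(extract_site(bad, ref))
  ambig <- transform(plus, lead4 = "CCGN")
  expect_null(extract_site(ambig, ref))
  # stranded mode keeps the tag strand in the key
  expect_equal(extract_site(minus, ref, strand_mode = "stranded")$strand, "-")
  # out-of-bounds coordinates are an input error
  oob <- transform(plus, end = 500L)
  expect_error(extract_sites(oob, ref), "bounds")
  # a tag claiming CCGG where the reference disagrees is rejected
  lie <- data.frame(sample_id = "a", chrom = "chr1", start = 10L, end = 40L,
                    strand = "+", lead4 = "CCGG")
  expect_null(extract_site(lie, ref))
})

test_that("every accepted site carries CCGG in the reference and tags are conserved", {
  g <- sim_genome(n_chroms = 2, chrom_length = 20000, n_genes = 0, seed = 31)
  tr <- sim_hmc_truth(g$ccgg, frac_differential = 0, seed = 32)
  cnt <- sim_tag_counts(tr, n_per_group = 2, lib_sizes = c(2000, 2000), seed = 33)
  tags <- counts_to_tags(cnt)
  tagrec <- data.frame(sample_id = tags$sample_id, chrom = tags$chrom,
                       start = tags$pos, end = tags$pos + 3L,
                       strand = tags$strand, lead4 = "CCGG")
  obs <- extract_sites(tagrec, g$genome)
  seqs <- as.character(g$genome)
  expect_true(all(substr(seqs[obs$chrom], obs$pos, obs$pos + 3) == "CCGG"))
  m <- build_count_matrix(obs, cnt$samples)
  expect_identical(sum(m$counts), nrow(obs) - attr(obs, "n_rejected"))
})

test_that("CCGG catalogue matches a brute-force scan, including adjacency", {
  expect_equal(catalog_ccgg(c(chr1 = "AACCGGTT"))$pos, 3L)
  expect_equal(catalog_ccgg(c(chr1 = "CCGGCCGG"))$pos, c(1L, 5L))
  set.seed(41)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  expect_equal(catalog_ccgg(c(chrX = s))$pos, naive_ccgg(s))
  expect_identical(nrow(catalog_ccgg(c(chr1 = "AAAA"))), 0L)
})

test_that("count matrix construction tallies tags per sample and site", {
  samples <- data.frame(sample_id = c("A", "B"), group = c("fast", "slow"))
  obs <- data.frame(sample_id = rep("A", 3), chrom = "chr1", pos = 101L)
  m <- build_count_matrix(obs, samples)
  expect_equal(unname(m$counts["chr1:101", ]), c(3L, 0L))
  # empty stream
  m0 <- build_count_matrix(obs[0, ], samples)
  expect_identical(dim(m0$counts), c(0L, 2L))
  expect_true(all(m0$lib_size == 0))
  # 10-tag fixture tallied by hand: sites 101 (A:2, B:1), 250 (A:1, B:3), 400 (B:3)
  obs10 <- data.frame(
    sample_id = c("A", "A", "B", "A", "B", "B", "B", "B", "B", "B"),
    chrom = "chr1",
    pos = c(101L, 101L, 101L, 250L, 250L, 250L, 250L, 400L, 400L, 400L))
  m10 <- build_count_matrix(obs10, samples)
  expect_equal(unname(m10$counts),
               matrix(c(2L, 1L, 0L, 1L, 3L, 3L), ncol = 2))
  expect_equal(unname(m10$lib_size), c(3L, 7L))
  expect_error(build_count_matrix(transform(obs, sample_id = "Z"), samples),
               "unknown sample")
})

test_that("presence summary partitions the universe and ignores labels and order", {
  m <- make_counts(rbind(c(1, 0, 0, 0),   # fast only
                         c(0, 2, 1, 0),   # common
                         c(0, 0, 0, 3),   # slow only
                         c(0, 0, 0, 0)))  # not in universe
  v <- presence_venn(m)
  expect_equal(v$n_universe, 3)
  expect_equal(c(v$n_common, v$n_fast_only, v$n_slow_only), c(1, 1, 1))
  expect_equal(v$pct_common + v$pct_fast_only + v$pct_slow_only, 100)
  # fast [1,0] slow [0,0] -> fast only; fast [1,0] slow [2,0] -> common
  expect_equal(presence_venn(make_counts(rbind(c(1, 0, 0, 0))))$n_fast_only, 1)
  expect_equal(presence_venn(make_counts(rbind(c(1, 0, 2, 0))))$n_common, 1)
  # permuting samples within groups leaves the summary unchanged
  m2 <- make_counts(m$counts[, c(2, 1, 4, 3)])
  expect_equal(presence_venn(m2), v)
  # swapping the group labels swaps the unique categories
  m3 <- make_counts(m$counts, groups = c("slow", "slow", "fast", "fast"))
  v3 <- presence_venn(m3)
  expect_equal(v3$n_fast_only, v$n_slow_only)
  expect_equal(v3$n_slow_only, v$n_fast_only)
})

test_that("phenotype correlation equals the closed-form Pearson computation", {
  x <- make_counts(matrix(1L, nrow = 2, ncol = 10))
  weight <- c(5, 7, 9, 4, 8, 3, 2, 6, 1, 5)
  x$lib_size <- stats::setNames(2 * weight, x$samples$sample_id)
  expect_equal(phenotype_correlation(x, weight)$r, 1)
  # load orthogonal to the phenotype by construction: r = 0
  x$lib_size <- stats::setNames(c(11, 9, 11, 9, 11, 9, 11, 9, 11, 9),
                                x$samples$sample_id)
  w0 <- c(1, 1, 3, 3, 1, 1, 3, 3, 1, 1)  # zero dot product after centring
  expect_lt(abs(phenotype_correlation(x, w0)$r), 1e-12)
  # closed-form oracle on an arbitrary fixture
  set.seed(5)
  load <- rpois(10, 50); ph <- rnorm(10, 20, 3)
  x$lib_size <- stats::setNames(load, x$samples$sample_id)
  r_oracle <- sum((load - mean(load)) * (ph - mean(ph))) /
    sqrt(sum((load - mean(load))^2) * sum((ph - mean(ph))^2))
  res <- phenotype_correlation(x, ph)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  t_or <- r_oracle * sqrt(8 / (1 - r_oracle^2))
  expect_equal(res$p, 2 * pt(-abs(t_or), df = 8), tolerance = 1e-12)
  expect_error(phenotype_correlation(x, rep(1, 10)), "undefined")
})

test_that("SAM round trip recovers the same observations as the tag TSV", {
  g <- sim_genome(n_chroms = 1, chrom_length = 8000, n_genes = 0, seed = 51)
  tr <- sim_hmc_truth(g$ccgg, frac_differential = 0, seed = 52)
  cnt <- sim_tag_counts(tr, n_per_group = 2, lib_sizes = c(800, 800), seed = 53)
  tags <- counts_to_tags(cnt)
  # mix of strands
  tags$strand <- rep(c("+", "-"), length.out = nrow(tags))
  sam <- tempfile(fileext = ".sam")
  write_tags_sam(tags, g$genome, sam)
  rec_sam <- read_tags_sam(sam)
  obs_sam <- extract_sites(rec_sam, g$genome)
  tsv <- tempfile(fileext = ".tsv")
  write_tags_tsv(tags, tsv)
  obs_tsv <- extract_sites(read_tags_tsv(tsv), g$genome)
  key <- function(o) sort(paste(o$sample_id, o$chrom, o$pos))
  expect_identical(key(obs_sam), key(obs_tsv))
  expect_identical(attr(obs_sam, "n_rejected"), 0L)
})
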