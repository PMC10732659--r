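grp10 <- rep(c("fast", "slow"), each = 5)

test_that("locus filtering excludes missing, monomorphic and multi-allelic loci", {
  geno <- rbind(ok = c(0, 1, 2, 1, 0, 1, 0, 1, 2, 0),
                miss = c(0, 1, NA, 1, 0, 1, 0, 1, 2, 0),
                mono = rep(0, 10),
                mono2 = rep(2, 10),
                tri = c(0, 1, 2, 1, 0, 1, 0, 1, 2, 0))
  loci <- data.frame(locus_id = rownames(geno), n_alleles = c(2, 2, 2, 2, 3))
  fl <- filter_loci(geno, loci)
  expect_equal(unname(fl$keep), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(fl$report$n_kept, 1)
  expect_equal(fl$report$n_input, 5)
})

test_that("group polymorphism classification matches per-group allele sets", {
  geno <- rbind(f_only = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
                s_only = c(2, 2, 2, 2, 2, 2, 1, 2, 2, 2),
                both = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 0),
                none = rep(1, 10) * 0)
  cl <- classify_polymorphism(geno, grp10)
  expect_equal(as.character(cl), c("fast_only", "slow_only", "both", "none"))
  # random full-sib fixture against a direct allele-set oracle
  gt <- sim_fullsib_genotypes(n_loci = 20, parent_maf = 0.4, seed = 81)
  cl2 <- classify_polymorphism(gt$geno, gt$samples$group)
  oracle <- apply(gt$geno, 1, function(g) {
    sets <- lapply(split(g, gt$samples$group), function(v) {
      v <- v[!is.na(v)]
      u <- character()
      if (any(v < 2)) u <- c(u, "ref")
      if (any(v > 0)) u <- c(u, "alt")
      u
    })
    pf <- length(sets$fast) > 1; ps <- length(sets$slow) > 1
    if (pf && ps) "both" else if (pf) "fast_only"
    else if (ps) "slow_only" else "none"
  })
  expect_equal(as.character(cl2), unname(oracle))
})

test_that("allelic test reproduces closed-form chi-square and exact Fisher values", {
  grp20 <- rep(c("fast", "slow"), each = 10)
  # fast 15 alt / 5 ref, slow 5 alt / 15 ref: chi-square = 10, p ~ 0.00157
  g1 <- c(rep(2, 5), rep(1, 5), rep(0, 5), rep(1, 5))
  r1 <- allelic_test(g1, grp20)
  expect_equal(r1$test, "chi-square")
  expect_equal(unname(r1$statistic),
               40 * (15 * 15 - 5 * 5)^2 / (20 * 20 * 20 * 20))
  expect_equal(unname(r1$statistic), 10)
  expect_equal(r1$p, pchisq(10, df = 1, lower.tail = FALSE), tolerance = 1e-10)
  # complete separation at n = 5+5: Fisher exact p = 2 / C(20, 10)
  g2 <- c(rep(2, 5), rep(0, 5))
  r2 <- allelic_test(g2, grp10)
  expect_equal(r2$test, "fisher")
  expect_equal(r2$p, 2 / choose(20, 10), tolerance = 1e-12)
  # identical allele counts: p = 1
  g3 <- c(1, 1, 0, 2, 1, 1, 1, 0, 2, 1)
  r3 <- allelic_test(g3, grp10)
  expect_equal(r3$p, 1)
  # table margins conserve two alleles per non-missing sample
  g4 <- c(0, 1, NA, 2, 1, NA, 1, 0, 1, 2)
  r4 <- allelic_test(g4, grp10)
  expect_equal(unname(rowSums(r4$table)), c(8, 8))
  expect_error(allelic_test(c(NA, NA, NA, NA, NA, 0, 1, 2, 0, 1), grp10),
               "non-missing")
})

test_that("the test is invariant under group swap and allele relabel", {
  set.seed(82)
  for (i in 1:10) {
    g <- sample(0:2, 10, replace = TRUE)
    if (length(unique(g)) == 1) next
    p1 <- allelic_test(g, grp10)$p
    p2 <- allelic_test(g, rev(grp10))$p      # swap groups
    p3 <- allelic_test(2 - g, grp10)$p       # relabel alleles
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_equal(p1, p3, tolerance = 1e-12)
  }
})

test_that("chi-square and Fisher agree asymptotically on well-filled tables", {
  set.seed(83)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 20000) + 10000, 2)
    pc <- stats::chisq.test(tab, correct = FALSE)$p.value
    pf <- stats::fisher.test(tab)$p.value
    expect_lt(abs(pc - pf), 0.01)
  }
})

test_that("haplotype test reduces to the allelic test at k = 2 and matches enumeration at k = 3", {
  # k = 2 haplotype table == allele-count table
  tab2 <- rbind(h1 = c(15, 5), h2 = c(5, 15))
  colnames(tab2) <- c("fast", "slow")
  hp <- haplotype_test(tab2)
  g1 <- c(rep(2, 5), rep(1, 5), rep(0, 5), rep(1, 5))
  expect_equal(hp$p, allelic_test(g1, rep(c("fast", "slow"), each = 10))$p,
               tolerance = 1e-12)
  # uniform distribution: p = 1
  expect_equal(haplotype_test(rbind(c(7, 7), c(7, 7), c(7, 7)))$p, 1)
  # sparse k = 3 table equals full exact enumeration at fixed margins
  tab3 <- rbind(c(4, 0), c(1, 3), c(2, 2))
  hp3 <- haplotype_test(tab3)
  expect_equal(hp3$test, "fisher")
  rowm <- colSums(tab3)  # per-group totals
  colm <- rowSums(tab3)  # per-haplotype totals
  # enumerate all tables with these margins; two-sided p sums probabilities
  # (multivariate hypergeometric) not exceeding the observed table's
  prob <- function(a, b, c1) {
    d <- colm - c(a, b, c1)
    if (any(d < 0)) return(0)
    exp(sum(lchoose(colm, c(a, b, c1))) - lchoose(sum(colm), rowm[1]))
  }
  pobs <- prob(tab3[1, 1], tab3[2, 1], tab3[3, 1])
  ptot <- 0
  for (a in 0:colm[1]) for (b in 0:colm[2]) {
    c1 <- rowm[1] - a - b
    if (c1 < 0 || c1 > colm[3]) next
    pr <- prob(a, b, c1)
    if (pr <= pobs + 1e-12) ptot <- ptot + pr
  }
  expect_equal(hp3$p, ptot, tolerance = 1e-7)
})

test_that("association scan reports highlight and FDR bins with conserved margins", {
  gt <- sim_fullsib_genotypes(n_loci = 200, missing_rate = 0.02, seed = 84)
  sc <- assoc_scan(gt$geno, gt$samples$group, gt$loci)
  expect_equal(sc$n_tested, sc$filter$n_kept)
  expect_equal(nrow(sc$results), sc$n_tested)
  expect_true(all(rowSums(as.matrix(
    sc$results[, c("fast_alt", "fast_ref")])) == 10))
  expect_equal(sc$n_p_below, sum(sc$results$p < 0.01))
  expect_equal(sc$n_q_below, sum(sc$results$q < 0.05))
  expect_output(print(sc), "loci tested")
  # all-flat scan: nothing anywhere
  geno1 <- matrix(rep(c(0, 1, 0, 1, 0), 2), nrow = 3, ncol = 10, byrow = TRUE)
  rownames(geno1) <- paste0("l", 1:3)
  sc1 <- assoc_scan(geno1, grp10)
  expect_true(all(sc1$results$p == 1))
  expect_equal(sc1$n_p_below + sc1$n_q_below, 0)
})

test_that("genotype TSV round trip preserves the matrix", {
  gt <- sim_fullsib_genotypes(n_loci = 30, missing_rate = 0.1, seed = 85)
  f <- tempfile(fileext = ".tsv")
  write_genotypes_tsv(gt, f)
  back <- read_genotypes_tsv(f, gt$samples)
  expect_equal(unname(back$geno), unname(gt$geno))
})
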