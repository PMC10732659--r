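test_that("zero filter drops sites that are zero in a majority of samples", {
  rows <- rbind(c(rep(0, 6), rep(5, 4)),   # six zeros of 10 -> dropped
                c(rep(0, 5), rep(5, 5)),   # five zeros -> retained
                rep(7, 10))                # all positive -> retained
  x <- make_counts(rows)
  f <- zero_filter(x)  # default k = floor(10/2)+1 = 6
  expect_equal(f$n_removed, 1)
  expect_identical(rownames(f$matrix$counts), rownames(x$counts)[2:3])
  expect_error(zero_filter(x, k_zero = 11), "k_zero")
  # filtering preserves the original library sizes
  expect_identical(f$matrix$lib_size, x$lib_size)
})

test_that("median filter uses the global median with strict 'below' and surviving ties", {
  # hand-computed: entries {10,12,8,9, 1,2,30,40} -> M = 9.5; each site has
  # two entries below M with k = 3, so both survive
  x <- make_counts(rbind(B = c(10, 12, 8, 9), C = c(1, 2, 30, 40)))
  f <- median_filter(x, k_below = 3)
  expect_equal(f$median, 9.5)
  expect_equal(f$n_removed, 0)
  # a site below the median in k samples is dropped
  y <- make_counts(rbind(B = c(10, 12, 8, 9), C = c(1, 2, 30, 40),
                         D = c(0, 0, 0, 41)))
  fy <- median_filter(y, k_below = 3)
  expect_equal(fy$n_removed, 1)
  expect_false("chr1:30" %in% rownames(fy$matrix$counts))
  # all entries identical: nothing strictly below, nothing dropped
  z <- make_counts(matrix(4, nrow = 3, ncol = 4))
  fz <- median_filter(z, k_below = 3)
  expect_equal(fz$median, 4)
  expect_equal(fz$n_removed, 0)
})

test_that("filter report arithmetic always balances", {
  fr <- filter_report(1096820, 691128, 267692, median = 19)
  expect_equal(fr$n_retained, 138000)
  x <- make_counts(matrix(rpois(400, 3), nrow = 40))
  fl <- filter_low_signal(x)
  expect_equal(fl$report$n_retained,
               fl$report$n_input - fl$report$n_removed_stage1 -
                 fl$report$n_removed_stage2)
  expect_equal(nrow(fl$matrix$counts), fl$report$n_retained)
})

test_that("log2-CPM transform and precision weights match an independent implementation", {
  # closed form: count 0 with library such that L + 1 = 1e6 gives log2(0.5)
  x <- make_counts(rbind(c(0, 0, 0, 0), c(10, 10, 10, 10)))
  x$lib_size <- stats::setNames(rep(999999, 4), x$samples$sample_id)
  v <- voom_transform(x)
  expect_equal(unname(v$y[1, ]), rep(-1, 4))
  # identical counts and libraries: zero group effect
  f <- wls_fit(v$y, v$w, v$groups)
  expect_equal(unname(f$beta[2]), 0)
  # 120-site fixture against limma's voom (same span, same library sizes)
  set.seed(61)
  n <- 120
  m <- matrix(rnbinom(n * 10, mu = rep(exp(runif(n, 1, 5)), 10), size = 5),
              nrow = n)
  xx <- make_counts(m)
  vv <- voom_transform(xx)
  design <- cbind(1, as.numeric(xx$samples$group == "fast"))
  lv <- limma::voom(xx$counts, design, lib.size = xx$lib_size, span = 0.5)
  expect_equal(vv$y, lv$E, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(vv$w, lv$weights, ignore_attr = TRUE, tolerance = 1e-8)
  expect_error(voom_transform(make_counts(matrix(1, 2, 3),
                                          groups = c("fast", "slow", "slow"))),
               "at least 2 samples")
})

test_that("weighted least squares matches the per-site lm oracle", {
  # unit weights: coefficient is the difference of group means
  y <- matrix(c(5, 5, 5, 5, 2, 2, 2, 2), nrow = 1)
  w <- matrix(1, 1, 8)
  gr <- rep(c("fast", "slow"), each = 4)
  f <- wls_fit(rbind(y, y), rbind(w, w), gr)
  expect_equal(unname(f$beta[1]), 3)
  # rescaling all weights leaves the estimate unchanged
  f10 <- wls_fit(rbind(y, y), 10 * rbind(w, w), gr)
  expect_equal(f10$beta, f$beta)
  # random sites against lm(y ~ group, weights = w)
  set.seed(62)
  Y <- matrix(rnorm(40), nrow = 5)
  W <- matrix(rexp(40) + 0.1, nrow = 5)
  fw <- wls_fit(Y, W, gr)
  for (i in 1:5) {
    lmfit <- lm(Y[i, ] ~ I(gr == "fast"), weights = W[i, ])
    sm <- summary(lmfit)
    expect_equal(unname(fw$beta[i]), unname(coef(lmfit)[2]), tolerance = 1e-10)
    expect_equal(fw$s2[i], sm$sigma^2, tolerance = 1e-10)
    # unscaled SE = SE / sigma
    expect_equal(unname(fw$u[i]),
                 unname(sm$coefficients[2, 2] / sm$sigma), tolerance = 1e-10)
  }
})

test_that("variance moderation has the documented limits and recovers a planted prior", {
  set.seed(63)
  n <- 150; d <- 8
  fit <- list(s2 = rchisq(n, d) / d, df = d, beta = rnorm(n), u = rep(0.5, n))
  # d0 = 0: ordinary t
  m0 <- ebayes_moderate(fit, prior_df = 0)
  expect_equal(m0$t, fit$beta / (fit$u * sqrt(fit$s2)))
  expect_equal(m0$p, 2 * pt(-abs(m0$t), df = d))
  # equal variances: infinite prior, posterior = prior = the common value
  fe <- list(s2 = rep(2, 10), df = d, beta = rnorm(10), u = rep(1, 10))
  me <- ebayes_moderate(fe)
  expect_identical(me$d0, Inf)
  expect_equal(me$s02, 2)
  expect_equal(me$s2_post, rep(2, 10))
  expect_equal(me$p, 2 * pnorm(-abs(me$t)))
  # full pipeline agrees with limma's eBayes on a realistic fixture
  set.seed(64)
  mm <- matrix(rnbinom(2000, mu = rep(exp(runif(200, 2, 5)), 10), size = 4),
               nrow = 200)
  xx <- make_counts(mm)
  v <- voom_transform(xx)
  f <- wls_fit(v$y, v$w, v$groups)
  mod <- ebayes_moderate(f)
  design <- cbind(1, as.numeric(xx$samples$group == "fast"))
  lf <- limma::lmFit(v$y, design, weights = v$w)
  le <- limma::eBayes(lf)
  expect_equal(mod$d0, le$df.prior, tolerance = 1e-8)
  expect_equal(mod$s02, le$s2.prior, tolerance = 1e-8)
  expect_equal(unname(mod$t), unname(le$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(mod$p), unname(le$p.value[, 2]), tolerance = 1e-8)
  # moment matching recovers a planted prior df of 4 within [2, 8]
  for (s in 1:5) {
    set.seed(400 + s)
    sigma2 <- 0.5 * 4 / rchisq(200, 4)
    s2 <- sigma2 * rchisq(200, d) / d
    mr <- ebayes_moderate(list(s2 = s2, df = d, beta = rnorm(200),
                               u = rep(0.6, 200)))
    expect_gte(mr$d0, 2)
    expect_lte(mr$d0, 8)
  }
})

test_that("BH adjustment equals the hand step-up and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(65)
  for (i in 1:5) {
    p <- runif(50)^2
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, method = "BH"))
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("DhmC classification applies both thresholds", {
  cls <- call_dhmcs(c(1.5, 1.5, -2, 0.5), c(0.01, 0.2, 0.001, 0.001))
  expect_equal(as.character(cls), c("hyper", "ns", "hypo", "ns"))
})

test_that("swapping group labels negates effects and preserves significance", {
  set.seed(66)
  m <- matrix(rnbinom(1200, mu = 30, size = 3), nrow = 120)
  x1 <- make_counts(m)
  x2 <- make_counts(m, groups = rep(c("slow", "fast"), each = 5))
  f1 <- dhmc_fit(x1); f2 <- dhmc_fit(x2)
  expect_equal(f1$table$logFC, -f2$table$logFC)
  expect_equal(abs(f1$table$t), abs(f2$table$t), tolerance = 1e-12)
  expect_equal(f1$table$P.Value, f2$table$P.Value, tolerance = 1e-12)
  expect_equal(f1$table$adj.P.Val, f2$table$adj.P.Val, tolerance = 1e-12)
})

test_that("the fitted model object supports the standard accessors", {
  set.seed(67)
  m <- matrix(rnbinom(600, mu = 25, size = 4), nrow = 60)
  fit <- dhmc_fit(make_counts(m))
  expect_s3_class(fit, "dhmc_fit")
  expect_named(coef(fit))
  expect_equal(length(coef(fit)), nrow(fit$counts$counts))
  r <- residuals(fit)
  expect_equal(dim(r), dim(fit$voom$y))
  expect_equal(r + fitted(fit), fit$voom$y, ignore_attr = TRUE)
  s <- summary(fit)
  expect_equal(s$n_hyper + s$n_hypo + s$n_ns, fit$filter$n_retained)
  expect_output(print(fit), "DhmCs")
  expect_output(print(s), "moderation")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit, type = "trend"))
  expect_invisible(plot(fit, type = "volcano"))
})
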