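# Differential hydroxymethylation: two-stage low-signal filter, log2-CPM
# transform with observation-level precision weights, per-site weighted
# least squares, empirical-Bayes variance moderation, BH adjustment and
# DhmC classification.

subset_sites <- function(x, keep) {
  # library sizes are fixed at construction (total accepted tags); a
  # low-signal filter does not change how deep a sample was sequenced
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out$sites <- x$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out
}

default_k <- function(n) as.integer(floor(n / 2) + 1L)

#' Stage-1 filter: drop sites that are zero in a majority of samples
#'
#' A site is removed when \code{k_zero} or more samples have a zero
#' count; the default \code{k_zero = floor(n/2) + 1} is the
#' majority-of-samples rule (6 of 10 in the study design), ensuring
#' dropped sites have very low counts in both phenotypes.
#'
#' @param x \code{\link{rrhp_counts}} object.
#' @param k_zero minimum number of zero-count samples that drops a site.
#' @return list with \code{matrix} (filtered \code{rrhp_counts}) and
#'   \code{n_removed}.
#' @export
zero_filter <- function(x, k_zero = NULL) {
  stopifnot(inherits(x, "rrhp_counts"))
  n <- ncol(x$counts)
  k_zero <- k_zero %||% default_k(n)
  if (k_zero < 1L || k_zero > n) stop("k_zero must be in 1..n_samples", call. = FALSE)
  nz <- rowSums(x$counts == 0L)
  keep <- nz < k_zero
  list(matrix = subset_sites(x, keep), n_removed = sum(!keep))
}

#' Stage-2 filter: drop sites mostly below the global count median
#'
#' The median \code{M} is computed over all entries of the stage-1
#' retained matrix (one scalar, as the study reports a single value); a
#' site is removed when \code{k_below} or more samples have counts
#' strictly below \code{M}. Ties at the median survive.
#'
#' @param x \code{\link{rrhp_counts}} object (stage-1 output).
#' @param k_below minimum number of below-median samples that drops a
#'   site; default \code{floor(n/2) + 1}.
#' @return list with \code{matrix}, \code{median}, \code{n_removed}.
#' @export
median_filter <- function(x, k_below = NULL) {
  stopifnot(inherits(x, "rrhp_counts"))
  if (nrow(x$counts) == 0L) stop("empty matrix", call. = FALSE)
  n <- ncol(x$counts)
  k_below <- k_below %||% default_k(n)
  if (k_below < 1L || k_below > n) stop("k_below must be in 1..n_samples", call. = FALSE)
  M <- stats::median(x$counts)
  nb <- rowSums(x$counts < M)
  keep <- nb < k_below
  list(matrix = subset_sites(x, keep), median = M, n_removed = sum(!keep))
}

#' Filter cascade report
#'
#' Bookkeeping for the two-stage filter; retained count is always input
#' minus the two removals.
#'
#' @param n_input sites entering the cascade.
#' @param n_removed_stage1,n_removed_stage2 removals per stage.
#' @param median the stage-2 global median threshold.
#' @return list of class \code{filter_report} with \code{n_retained}
#'   computed.
#' @export
filter_report <- function(n_input, n_removed_stage1, n_removed_stage2,
                          median = NA_real_) {
  structure(list(n_input = n_input,
                 n_removed_stage1 = n_removed_stage1,
                 n_removed_stage2 = n_removed_stage2,
                 median = median,
                 n_retained = n_input - n_removed_stage1 - n_removed_stage2),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Low-signal filter: %s sites in\n", format(x$n_input, big.mark = ",")))
  cat(sprintf("  stage 1 (majority zeros)        removed %s\n",
              format(x$n_removed_stage1, big.mark = ",")))
  cat(sprintf("  stage 2 (below global median %s) removed %s\n",
              format(x$median), format(x$n_removed_stage2, big.mark = ",")))
  cat(sprintf("  retained %s\n", format(x$n_retained, big.mark = ",")))
  invisible(x)
}

#' Apply the two-stage low-signal filter
#'
#' @inheritParams zero_filter
#' @param k_below stage-2 threshold, see \code{\link{median_filter}}.
#' @return list with \code{matrix} (filtered counts) and \code{report}
#'   (\code{\link{filter_report}}).
#' @export
filter_low_signal <- function(x, k_zero = NULL, k_below = NULL) {
  s1 <- zero_filter(x, k_zero)
  s2 <- median_filter(s1$matrix, k_below)
  list(matrix = s2$matrix,
       report = filter_report(nrow(x$counts), s1$n_removed, s2$n_removed,
                              s2$median))
}

#' Log2-CPM transform with observation-level precision weights
#'
#' Counts are transformed to \code{y = log2((c + 0.5) / (L + 1) * 1e6)}
#' with \code{L} the library size (total accepted CCGG tags). An
#' unweighted two-group model is fitted per site; the square root of
#' each site's residual standard deviation is regressed on its mean
#' log2-count by LOWESS (span 0.5, 3 robustifying iterations), and the
#' trend evaluated at each observation's fitted log2-count gives the
#' precision weight \code{w = trend^-4}. Sites with lower expected
#' counts are noisier on the log scale and are down-weighted
#' accordingly.
#'
#' @param x \code{\link{rrhp_counts}} object (filtered).
#' @param span LOWESS span for the mean-variance trend.
#' @return list of class \code{voom_fit}: \code{y}, \code{w} (matrices),
#'   \code{amean} (average log2-CPM per site), \code{trend} (LOWESS
#'   curve, \code{x} = mean log2-count, \code{y} = sqrt residual SD),
#'   \code{groups}, \code{lib_size}.
#' @export
voom_transform <- function(x, span = 0.5) {
  stopifnot(inherits(x, "rrhp_counts"))
  gr <- x$samples$group
  if (sum(gr == "fast") < 2L || sum(gr == "slow") < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  if (nrow(x$counts) < 2L) stop("need at least 2 sites", call. = FALSE)
  L1 <- x$lib_size + 1
  y <- t(log2(t(x$counts + 0.5) / L1 * 1e6))
  fast <- gr == "fast"
  mu_f <- rowMeans(y[, fast, drop = FALSE])
  mu_s <- rowMeans(y[, !fast, drop = FALSE])
  fitted <- cbind(mu_f, mu_s)[, ifelse(fast, 1L, 2L), drop = FALSE]
  d <- ncol(y) - 2L
  sigma <- sqrt(rowSums((y - fitted)^2) / d)
  amean <- rowMeans(y)
  sx <- amean + mean(log2(L1)) - log2(1e6)
  sy <- sqrt(sigma)
  l <- stats::lowess(sx, sy, f = span)
  lo <- stats::approxfun(l$x, l$y, rule = 2, ties = list("ordered", mean))
  fitted_logcount <- log2(1e-6 * t(t(2^fitted) * L1))
  w <- 1 / pmax(lo(fitted_logcount), 1e-10)^4
  dim(w) <- dim(y)
  dimnames(w) <- dimnames(y)
  structure(list(y = y, w = w, amean = amean, sigma = sigma,
                 trend = l, groups = gr, lib_size = x$lib_size),
            class = "voom_fit")
}

#' Per-site weighted least squares for the two-group model
#'
#' Fits \code{y ~ intercept + fast} by weighted least squares for every
#' site. With a single binary covariate the solution is the difference
#' of weighted group means; the residual variance uses n - 2 degrees of
#' freedom and the unscaled standard error of the group coefficient is
#' \code{sqrt(1/Sw_fast + 1/Sw_slow)} with \code{Sw} the group weight
#' sums.
#'
#' @param y numeric matrix of responses (sites x samples).
#' @param w positive weights, same shape.
#' @param groups character vector of \code{"fast"}/\code{"slow"} per
#'   column.
#' @return list with per-site vectors \code{beta} (fast - slow, so
#'   positive means hyper in fast), \code{intercept}, \code{s2}
#'   (residual variance), \code{u} (unscaled SE), scalar \code{df}, and
#'   the \code{fitted} matrix.
#' @export
wls_fit <- function(y, w, groups) {
  stopifnot(all(dim(y) == dim(w)), ncol(y) == length(groups))
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  fast <- groups == "fast"
  swf <- rowSums(w[, fast, drop = FALSE])
  sws <- rowSums(w[, !fast, drop = FALSE])
  mwf <- rowSums((w * y)[, fast, drop = FALSE]) / swf
  mws <- rowSums((w * y)[, !fast, drop = FALSE]) / sws
  fitted <- cbind(mwf, mws)[, ifelse(fast, 1L, 2L), drop = FALSE]
  dimnames(fitted) <- dimnames(y)
  d <- ncol(y) - 2L
  if (d < 1L) stop("need more than 2 samples", call. = FALSE)
  s2 <- rowSums(w * (y - fitted)^2) / d
  list(beta = mwf - mws, intercept = mws, s2 = s2,
       u = sqrt(1 / swf + 1 / sws), df = d, fitted = fitted)
}

# Newton inversion of the trigamma function (for prior-df moment matching)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderation of per-site variances
#'
#' Shrinks each site's residual variance toward a prior estimated by
#' moment matching on the log scale: with residual df \code{d}, the
#' statistic \code{e = log(s^2) - digamma(d/2) + log(d/2)} has variance
#' \code{trigamma(d0/2) + trigamma(d/2)} under the scaled-F model, so
#' the prior df \code{d0} solves \code{trigamma(d0/2) = var(e) -
#' trigamma(d/2)} and the prior variance follows from \code{mean(e)}.
#' When the observed spread is no larger than the sampling spread the
#' prior df is infinite and every posterior variance equals the common
#' prior (the mean observed variance). The moderated t statistic is
#' \code{beta / (u * s_post)} on \code{d + d0} degrees of freedom
#' (normal reference when \code{d0} is infinite).
#'
#' @param fit list from \code{\link{wls_fit}} (\code{beta}, \code{s2},
#'   \code{u}, \code{df}).
#' @param prior_df optional forced prior df; \code{0} gives the ordinary
#'   per-site t, \code{Inf} the fully pooled limit.
#' @return list with \code{d0}, \code{s02}, \code{s2_post}, and per-site
#'   \code{t}, \code{p} (two-sided).
#' @export
ebayes_moderate <- function(fit, prior_df = NULL) {
  s2 <- fit$s2
  d <- fit$df
  if (length(s2) < 2L) stop("need at least 2 sites", call. = FALSE)
  # guard against exactly-zero residual variances before taking logs
  m <- stats::median(s2)
  if (m == 0) m <- 1
  s2g <- pmax(s2, 1e-5 * m)
  z <- log(s2g)
  e <- z - digamma(d / 2) + log(d / 2)
  if (!is.null(prior_df)) {
    d0 <- prior_df
    s02 <- if (is.infinite(d0)) mean(s2) else
      exp(mean(e) + digamma(max(d0, 1e-8) / 2) - log(max(d0, 1e-8) / 2))
  } else {
    evar <- stats::var(e) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- mean(s2)
    }
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    if (d0 == 0) s2 else (d0 * s02 + d * s2) / (d0 + d)
  t <- fit$beta / (fit$u * sqrt(s2_post))
  p <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(t)) else
    2 * stats::pt(-abs(t), df = d + d0)
  list(d0 = d0, s02 = s02, s2_post = s2_post, t = t, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \code{q_(i) = min_{j >= i} p_(j) * m / j}, clipped to 1 and mapped
#' back to the input order; controls the false discovery rate under
#' independence.
#'
#' @param p numeric vector of p values.
#' @return q values in the input order.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  q[order(o)]
}

#' Classify differentially hydroxymethylated cytosines
#'
#' A site is a DhmC when its absolute log2 fold change exceeds
#' \code{lfc} and its BH-adjusted p value is below \code{q_threshold};
#' positive fold changes (hyper) mean higher 5hmC in the fast-growing
#' group.
#'
#' @param logFC per-site log2 fold changes (fast - slow).
#' @param q BH-adjusted p values.
#' @param lfc log2 fold-change threshold (default 1).
#' @param q_threshold adjusted-p threshold (default 0.05).
#' @return factor with levels \code{hyper}, \code{hypo}, \code{ns}.
#' @export
call_dhmcs <- function(logFC, q, lfc = 1, q_threshold = 0.05) {
  cls <- rep("ns", length(logFC))
  cls[logFC > lfc & q < q_threshold] <- "hyper"
  cls[logFC < -lfc & q < q_threshold] <- "hypo"
  factor(cls, levels = c("hyper", "hypo", "ns"))
}

#' Fit the differential hydroxymethylation model
#'
#' The full inference path for an RRHP count matrix: two-stage
#' low-signal filter, log2-CPM transform with precision weights,
#' per-site weighted least squares of the fast-vs-slow contrast,
#' empirical-Bayes variance moderation, BH adjustment and DhmC
#' classification.
#'
#' @param x \code{\link{rrhp_counts}} object.
#' @param lfc absolute log2 fold-change threshold for a DhmC call.
#' @param q_threshold BH-adjusted p threshold for a DhmC call.
#' @param k_zero,k_below filter thresholds (default: majority of
#'   samples, \code{floor(n/2) + 1}).
#' @param span LOWESS span of the mean-variance trend.
#' @param prior_df optional forced prior df (see
#'   \code{\link{ebayes_moderate}}).
#' @param filter set \code{FALSE} if \code{x} is already filtered.
#' @return object of class \code{dhmc_fit}; see
#'   \code{\link{summary.dhmc_fit}}. The per-site results are in
#'   \code{$table} (columns \code{site}, \code{chrom}, \code{pos},
#'   \code{logFC}, \code{AveExpr}, \code{t}, \code{P.Value},
#'   \code{adj.P.Val}, \code{class}).
#' @examples
#' g <- sim_genome(chrom_length = 20000, seed = 1)
#' tr <- sim_hmc_truth(g$ccgg, frac_differential = 0.1, seed = 2)
#' cnt <- sim_tag_counts(tr, lib_sizes = c(6000, 2000), seed = 3)
#' fit <- dhmc_fit(cnt)
#' summary(fit)
#' @export
dhmc_fit <- function(x, lfc = 1, q_threshold = 0.05, k_zero = NULL,
                     k_below = NULL, span = 0.5, prior_df = NULL,
                     filter = TRUE) {
  stopifnot(inherits(x, "rrhp_counts"))
  cl <- match.call()
  if (filter) {
    fl <- filter_low_signal(x, k_zero, k_below)
  } else {
    fl <- list(matrix = x, report = filter_report(nrow(x$counts), 0L, 0L))
  }
  xf <- fl$matrix
  v <- voom_transform(xf, span = span)
  fit <- wls_fit(v$y, v$w, v$groups)
  mod <- ebayes_moderate(fit, prior_df = prior_df)
  q <- bh_adjust(mod$p)
  cls <- call_dhmcs(fit$beta, q, lfc, q_threshold)
  tab <- data.frame(site = rownames(xf$counts),
                    chrom = xf$sites$chrom, pos = xf$sites$pos,
                    logFC = unname(fit$beta), AveExpr = unname(v$amean),
                    t = unname(mod$t), P.Value = unname(mod$p),
                    adj.P.Val = q, class = cls)
  rownames(tab) <- NULL
  structure(list(call = cl, counts = xf, filter = fl$report, voom = v,
                 fit = fit, moderation = mod, table = tab,
                 thresholds = list(lfc = lfc, q = q_threshold)),
            class = "dhmc_fit")
}

#' @export
print.dhmc_fit <- function(x, ...) {
  cat("Differential hydroxymethylation fit (voom / WLS / moderated t)\n")
  cat("call: ", deparse(x$call), "\n")
  cat(sprintf("  %s sites tested (of %s input), %d samples\n",
              format(x$filter$n_retained, big.mark = ","),
              format(x$filter$n_input, big.mark = ","),
              ncol(x$counts$counts)))
  n <- table(x$table$class)
  cat(sprintf("  DhmCs at |log2FC| > %g, q < %g: %d hyper, %d hypo\n",
              x$thresholds$lfc, x$thresholds$q, n[["hyper"]], n[["hypo"]]))
  invisible(x)
}

#' Summarise a differential hydroxymethylation fit
#'
#' @param object \code{dhmc_fit} object.
#' @param ... unused.
#' @return list of class \code{summary.dhmc_fit}: the filter report,
#'   moderation parameters and DhmC class counts.
#' @method summary dhmc_fit
#' @export
summary.dhmc_fit <- function(object, ...) {
  n <- table(object$table$class)
  structure(list(filter = object$filter,
                 d0 = object$moderation$d0, s02 = object$moderation$s02,
                 residual_df = object$fit$df,
                 n_hyper = n[["hyper"]], n_hypo = n[["hypo"]], n_ns = n[["ns"]],
                 thresholds = object$thresholds),
            class = "summary.dhmc_fit")
}

#' @export
print.summary.dhmc_fit <- function(x, ...) {
  print(x$filter)
  cat(sprintf("Variance moderation: prior df %s, prior variance %.4g, residual df %d\n",
              format(x$d0, digits = 4), x$s02, x$residual_df))
  cat(sprintf("DhmCs (|log2FC| > %g, q < %g): %d hyper, %d hypo, %d not significant\n",
              x$thresholds$lfc, x$thresholds$q, x$n_hyper, x$n_hypo, x$n_ns))
  invisible(x)
}

#' @method coef dhmc_fit
#' @export
coef.dhmc_fit <- function(object, ...) {
  stats::setNames(object$table$logFC, object$table$site)
}

#' @method residuals dhmc_fit
#' @export
residuals.dhmc_fit <- function(object, ...) {
  object$voom$y - object$fit$fitted
}

#' @export
fitted.dhmc_fit <- function(object, ...) object$fit$fitted

#' Diagnostic plots for a differential hydroxymethylation fit
#'
#' \code{"trend"} shows the mean-variance relationship (sqrt residual SD
#' against mean log2-count) with the fitted LOWESS curve that generates
#' the precision weights; \code{"volcano"} plots -log10 adjusted p
#' against log2 fold change with the DhmC thresholds; \code{"ma"} plots
#' log2 fold change against average log2-CPM.
#'
#' @param x \code{dhmc_fit} object.
#' @param type one of \code{"trend"}, \code{"volcano"}, \code{"ma"}.
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{x}.
#' @method plot dhmc_fit
#' @export
plot.dhmc_fit <- function(x, type = c("trend", "volcano", "ma"), ...) {
  type <- match.arg(type)
  tab <- x$table
  if (type == "trend") {
    sx <- x$voom$amean + mean(log2(x$voom$lib_size + 1)) - log2(1e6)
    graphics::plot(sx, sqrt(x$voom$sigma), pch = 16, cex = 0.4,
                   col = "grey50", xlab = "mean log2 count",
                   ylab = "sqrt(residual SD)", main = "mean-variance trend", ...)
    graphics::lines(x$voom$trend, col = "red", lwd = 2)
  } else if (type == "volcano") {
    col <- c(hyper = "firebrick", hypo = "steelblue", ns = "grey60")[as.character(tab$class)]
    graphics::plot(tab$logFC, -log10(tab$adj.P.Val), pch = 16, cex = 0.5,
                   col = col, xlab = "log2 fold change (fast - slow)",
                   ylab = "-log10 adjusted p", main = "DhmC calls", ...)
    graphics::abline(v = c(-1, 1) * x$thresholds$lfc, lty = 2)
    graphics::abline(h = -log10(x$thresholds$q), lty = 2)
  } else {
    col <- c(hyper = "firebrick", hypo = "steelblue", ns = "grey60")[as.character(tab$class)]
    graphics::plot(tab$AveExpr, tab$logFC, pch = 16, cex = 0.5, col = col,
                   xlab = "average log2 CPM", ylab = "log2 fold change",
                   main = "MA plot", ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
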