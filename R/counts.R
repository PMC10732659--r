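#' Construct an RRHP count matrix
#'
#' Bundles a sites-by-samples matrix of CCGG tag counts with the sample
#' table and per-sample library sizes. Library size is the total number
#' of accepted CCGG tags of that sample — the only abundance the
#' downstream model sees — and equals the column sum at construction.
#'
#' @param counts integer matrix, sites in rows (rownames
#'   \code{"chrom:pos"} or \code{"chrom:pos:strand"}), samples in columns.
#' @param samples data.frame with columns \code{sample_id} and
#'   \code{group} (levels \code{"fast"}, \code{"slow"}); row order must
#'   match the matrix columns.
#' @param sites data.frame with columns \code{chrom}, \code{pos} (and
#'   optionally \code{strand}); derived from rownames when omitted.
#' @return object of class \code{rrhp_counts}: a list with elements
#'   \code{counts}, \code{sites}, \code{samples}, \code{lib_size}.
#' @export
rrhp_counts <- function(counts, samples, sites = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative", call. = FALSE)
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("samples needs columns sample_id and group", call. = FALSE)
  if (nrow(samples) != ncol(counts))
    stop("sample table does not match matrix columns", call. = FALSE)
  if (!all(samples$group %in% c("fast", "slow")))
    stop("group labels must be 'fast' or 'slow'", call. = FALSE)
  colnames(counts) <- samples$sample_id
  if (is.null(sites)) {
    if (is.null(rownames(counts)))
      stop("provide sites or rowname keys 'chrom:pos'", call. = FALSE)
    parts <- strsplit(rownames(counts), ":", fixed = TRUE)
    sites <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                        pos = as.integer(vapply(parts, `[`, "", 2L)))
    if (all(lengths(parts) >= 3L))
      sites$strand <- vapply(parts, `[`, "", 3L)
  } else {
    rownames(counts) <- site_key(sites)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sites", call. = FALSE)
  structure(list(counts = counts,
                 sites = sites,
                 samples = data.frame(sample_id = as.character(samples$sample_id),
                                      group = as.character(samples$group)),
                 lib_size = colSums(counts)),
            class = "rrhp_counts")
}

site_key <- function(sites) {
  key <- paste(sites$chrom, sites$pos, sep = ":")
  if (!is.null(sites$strand)) key <- paste(key, sites$strand, sep = ":")
  key
}

#' @export
print.rrhp_counts <- function(x, ...) {
  cat(sprintf("RRHP count matrix: %d CCGG sites x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$group)
  cat("  groups: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  library sizes: ", paste(format(x$lib_size), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.rrhp_counts <- function(x) dim(x$counts)

#' Build the count matrix from accepted tag observations
#'
#' Tallies accepted CCGG tag observations into counts per sample and
#' CCGG location. Every observation contributes exactly one count, so
#' the matrix total equals the number of accepted tags.
#'
#' @param obs data.frame from \code{\link{extract_sites}} (columns
#'   \code{sample_id}, \code{chrom}, \code{pos}, optionally
#'   \code{strand}).
#' @param samples sample table (\code{sample_id}, \code{group}); every
#'   observation's sample must appear here.
#' @return \code{\link{rrhp_counts}} object.
#' @export
build_count_matrix <- function(obs, samples) {
  if (!all(obs$sample_id %in% samples$sample_id))
    stop("observation with unknown sample_id", call. = FALSE)
  if (nrow(obs) == 0L) {
    m <- matrix(0L, 0L, nrow(samples))
    return(rrhp_counts(m, samples,
                       sites = data.frame(chrom = character(), pos = integer())))
  }
  key <- site_key(obs)
  ukey <- sort(unique(key))
  m <- table(factor(key, levels = ukey),
             factor(obs$sample_id, levels = samples$sample_id))
  m <- matrix(as.integer(m), nrow = length(ukey),
              dimnames = list(ukey, samples$sample_id))
  parts <- strsplit(ukey, ":", fixed = TRUE)
  sites <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                      pos = as.integer(vapply(parts, `[`, "", 2L)))
  if (all(lengths(parts) >= 3L)) sites$strand <- vapply(parts, `[`, "", 3L)
  o <- order(sites$chrom, sites$pos)
  rrhp_counts(m[o, , drop = FALSE], samples, sites = sites[o, , drop = FALSE])
}

#' Group presence summary of 5hmC sites
#'
#' Classifies every site of the universe (non-zero count in at least one
#' sample) as present in both groups, only in fast-growing or only in
#' slow-growing fish; presence in a group means a positive summed count
#' over that group's samples.
#'
#' @param x \code{\link{rrhp_counts}} object.
#' @return list with counts \code{n_universe}, \code{n_common},
#'   \code{n_fast_only}, \code{n_slow_only} and the corresponding
#'   percentages \code{pct_common}, \code{pct_fast_only},
#'   \code{pct_slow_only}.
#' @export
presence_venn <- function(x) {
  stopifnot(inherits(x, "rrhp_counts"))
  fast <- x$samples$group == "fast"
  sf <- rowSums(x$counts[, fast, drop = FALSE])
  ss <- rowSums(x$counts[, !fast, drop = FALSE])
  universe <- sf + ss > 0
  n_common <- sum(universe & sf > 0 & ss > 0)
  n_fast <- sum(universe & sf > 0 & ss == 0)
  n_slow <- sum(universe & sf == 0 & ss > 0)
  n <- sum(universe)
  pct <- function(k) if (n == 0) NA_real_ else 100 * k / n
  list(n_universe = n, n_common = n_common,
       n_fast_only = n_fast, n_slow_only = n_slow,
       pct_common = pct(n_common), pct_fast_only = pct(n_fast),
       pct_slow_only = pct(n_slow))
}

#' Correlate per-sample 5hmC load with a phenotype
#'
#' RRHP library sizes track global hydroxymethylation, so the per-sample
#' 5hmC load (total accepted tags, or the column sums of a filtered
#' matrix) is itself a phenotype-relevant quantity. Computes the Pearson
#' correlation between load and a phenotype with the two-sided t test on
#' n - 2 degrees of freedom.
#'
#' @param x \code{\link{rrhp_counts}} object.
#' @param phenotype numeric vector, one value per sample in column order.
#' @param load \code{"lib_size"} (default) or \code{"colsum"} (column
#'   sums of the current, possibly filtered, matrix).
#' @return list with \code{r}, \code{p}, \code{df}, \code{load}.
#' @export
phenotype_correlation <- function(x, phenotype, load = c("lib_size", "colsum")) {
  stopifnot(inherits(x, "rrhp_counts"))
  load <- match.arg(load)
  v <- if (load == "lib_size") x$lib_size else colSums(x$counts)
  if (length(phenotype) != length(v))
    stop("phenotype length must equal the number of samples", call. = FALSE)
  if (length(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(phenotype) == 0 || stats::sd(v) == 0)
    stop("correlation undefined: constant phenotype or constant load", call. = FALSE)
  ct <- stats::cor.test(v, phenotype, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), load = unname(v))
}

#' Phenotype group summary
#'
#' Group means of each phenotype column and the fast/slow fold ratios,
#' plus Welch one-tailed t tests of fast > slow — the standard summary
#' for a two-group growth comparison.
#'
#' @param phenotypes data.frame with columns \code{sample_id},
#'   \code{group} and one column per measured trait (e.g. weight in
#'   grams, length in cm).
#' @param digits decimal places for the rounded fold ratios (default 1).
#' @return data.frame with one row per trait: group means, fold ratio
#'   (fast mean / slow mean) both exact and rounded, and the one-tailed
#'   p value.
#' @export
pheno_summary <- function(phenotypes, digits = 1) {
  stopifnot(all(c("sample_id", "group") %in% names(phenotypes)))
  traits <- setdiff(names(phenotypes), c("sample_id", "group"))
  fast <- phenotypes$group == "fast"
  rows <- lapply(traits, function(tr) {
    v <- phenotypes[[tr]]
    mf <- mean(v[fast]); ms <- mean(v[!fast])
    p <- if (sum(fast) > 1 && sum(!fast) > 1 && (stats::sd(v[fast]) > 0 || stats::sd(v[!fast]) > 0))
      stats::t.test(v[fast], v[!fast], alternative = "greater")$p.value
    else NA_real_
    data.frame(trait = tr, mean_fast = mf, mean_slow = ms,
               fold = mf / ms, fold_rounded = round(mf / ms, digits),
               p_one_tailed = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write count matrices as TSV
#'
#' Plain-text interchange: first column \code{site} (\code{chrom:pos}
#' key), one integer column per sample. The sample table travels
#' separately.
#'
#' @param x \code{\link{rrhp_counts}} object.
#' @param path TSV file path.
#' @param samples sample table for reading.
#' @name counts_tsv
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "rrhp_counts"))
  df <- data.frame(site = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname counts_tsv
#' @export
read_counts_tsv <- function(path, samples) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$site
  rrhp_counts(m[, samples$sample_id, drop = FALSE], samples)
}
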