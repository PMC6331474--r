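#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over reference genes of that
#' sample's count divided by the gene's geometric mean across samples;
#' reference genes are those with nonzero counts in every sample.
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (any(counts < 0)) stop("counts must be >= 0")
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) stop("no gene has nonzero counts in every sample")
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  apply(exp(sweep(logc, 1, loggeo)), 2, stats::median)
}

#' Normalize a count matrix by size factors
#' @param counts Gene x sample count matrix.
#' @param factors Optional precomputed size factors.
#' @return Matrix of normalized counts (count / factor).
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  sweep(counts, 2, factors, "/")
}

#' Fragments per kilobase per million (FPKM)
#'
#' FPKM(g, j) = count(g, j) / ((length_g / 1e3) * (total_j / 1e6)), with
#' gene length taken from the longest isoform.  By default the per-sample
#' totals are the column sums of the (normalized) matrix passed in;
#' alternative totals (e.g. raw library sizes) may be supplied.
#'
#' @param counts Gene x sample matrix (normalized counts by default
#'   convention).
#' @param lengths Named numeric vector of gene lengths in bp (> 0),
#'   covering all rownames of `counts`.
#' @param totals Optional per-sample totals; default `colSums(counts)`.
#' @return FPKM matrix with the dimensions of `counts`.
#' @export
fpkm <- function(counts, lengths, totals = colSums(counts)) {
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0)) stop("invalid gene lengths")
  if (any(totals <= 0)) stop("per-sample totals must be > 0")
  sweep(counts / (lengths / 1e3), 2, totals / 1e6, "/")
}

#' Expressed flags per gene and subtype
#'
#' A gene is expressed in a subtype when its FPKM exceeds the threshold
#' in every replicate of that subtype.
#'
#' @param fpkm_mat FPKM matrix (genes x samples).
#' @param subtype Factor/character of length `ncol(fpkm_mat)` mapping each
#'   sample to its subtype.
#' @param threshold FPKM threshold (default 1, strict >).
#' @return Logical gene x subtype matrix.
#' @export
expressed_flags <- function(fpkm_mat, subtype, threshold = 1) {
  subtype <- as.factor(subtype)
  vapply(levels(subtype), function(s) {
    rowSums(fpkm_mat[, subtype == s, drop = FALSE] > threshold) ==
      sum(subtype == s)
  }, logical(nrow(fpkm_mat)))
}

#' Subtype specificity Z-scores
#'
#' Per gene: average expression over each subtype's replicates, then
#' center and scale those subtype means by their mean and standard
#' deviation across subtypes.  Genes with zero across-subtype SD get
#' Z = 0 by convention.
#'
#' @param fpkm_mat FPKM matrix (genes x samples).
#' @param subtype Sample-to-subtype map (length `ncol(fpkm_mat)`).
#' @return Gene x subtype matrix of Z-scores (rows sum to 0).
#' @export
subtype_zscore <- function(fpkm_mat, subtype) {
  subtype <- as.factor(subtype)
  if (nlevels(subtype) < 2) stop("need at least 2 subtypes")
  means <- vapply(levels(subtype), function(s)
    rowMeans(fpkm_mat[, subtype == s, drop = FALSE]),
    numeric(nrow(fpkm_mat)))
  mu <- rowMeans(means)
  sdv <- apply(means, 1, stats::sd)
  z <- sweep(means, 1, mu)
  z <- sweep(z, 1, ifelse(sdv == 0, 1, sdv), "/")
  z[sdv == 0, ] <- 0
  z
}

#' Critical Pearson coefficient for a two-tailed t-test
#'
#' r_crit = t_c / sqrt(t_c^2 + n - 2) with t_c the two-tailed t critical
#' value at `alpha` on n - 2 degrees of freedom; |r| above r_crit is
#' significant at that level.  At n = 25, alpha = 0.05 this is 0.3961.
#'
#' @param n Number of paired observations (>= 3).
#' @param alpha Two-tailed significance level (default 0.05).
#' @return Scalar critical value in (0, 1).
#' @export
critical_pearson <- function(n, alpha = 0.05) {
  if (n < 3) stop("need n >= 3")
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(tc^2 + n - 2)
}

#' Pairwise Pearson correlations with a significance threshold
#'
#' Computes r over the full sample vector for each requested gene pair;
#' a pair is significant when |r| strictly exceeds `r_crit`.  Pairs
#' involving a zero-variance gene are excluded with a warning.
#'
#' @param expr Gene x sample matrix (FPKM by default convention).
#' @param pairs Two-column `data.frame`/matrix of gene-name pairs; NULL
#'   (default) means all unordered pairs.
#' @param r_crit Significance threshold on |r|
#'   (default `critical_pearson(ncol(expr))`).
#' @return `data.frame` with `gene1`, `gene2`, `r`, `significant`, `sign`
#'   (`"+"`/`"-"`).
#' @export
pairwise_correlations <- function(expr, pairs = NULL,
                                  r_crit = critical_pearson(ncol(expr))) {
  if (ncol(expr) < 3) stop("need >= 3 samples")
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(nrow(expr))), arr.ind = TRUE)
    pairs <- data.frame(gene1 = rownames(expr)[idx[, 1]],
                        gene2 = rownames(expr)[idx[, 2]])
  } else {
    pairs <- data.frame(gene1 = as.character(pairs[[1]]),
                        gene2 = as.character(pairs[[2]]))
  }
  v <- apply(expr, 1, stats::var)
  bad <- v[pairs$gene1] == 0 | v[pairs$gene2] == 0
  if (any(bad)) {
    warning(sum(bad), " pair(s) with a zero-variance gene excluded")
    pairs <- pairs[!bad, , drop = FALSE]
  }
  r <- vapply(seq_len(nrow(pairs)), function(i)
    stats::cor(expr[pairs$gene1[i], ], expr[pairs$gene2[i], ]),
    numeric(1))
  data.frame(pairs, r = r,
             significant = abs(r) > r_crit,
             sign = ifelse(r >= 0, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Welch-t differential expression stand-in
#'
#' A lightweight differential-expression test for synthetic runs only:
#' Welch's t-test on log2(normalized count + 1) per gene with
#' Benjamini-Hochberg adjustment.  Real analyses ingest an externally
#' computed differential-expression table (negative-binomial testing is
#' out of this package's scope); the output schema is identical so the
#' two are interchangeable downstream.
#'
#' @param counts Gene x sample raw count matrix.
#' @param groups Length-`ncol(counts)` labels; exactly two distinct values.
#' @param contrast Character pair `c(test, reference)`; log2FC is
#'   test - reference.  Default: the two group levels in order.
#' @return `data.frame` with `gene`, `log2fc`, `pvalue`, `padj`,
#'   `contrast`.
#' @export
de_welch <- function(counts, groups, contrast = NULL) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  if (is.null(contrast)) contrast <- lv
  if (min(table(groups)) < 2) stop("need >= 2 replicates per group")
  norm <- log2(normalize_counts(counts) + 1)
  a <- norm[, groups == contrast[1], drop = FALSE]
  b <- norm[, groups == contrast[2], drop = FALSE]
  res <- t(vapply(seq_len(nrow(norm)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(c(mean(x) - mean(y), if (mean(x) == mean(y)) 1 else 0))
    tt <- stats::t.test(x, y)
    c(mean(x) - mean(y), tt$p.value)
  }, numeric(2)))
  data.frame(gene = rownames(counts),
             log2fc = res[, 1],
             pvalue = res[, 2],
             padj = stats::p.adjust(res[, 2], method = "BH"),
             contrast = paste(contrast, collapse = "_vs_"),
             stringsAsFactors = FALSE)
}

#' Read an ingested differential-expression table
#' @param path TSV with header `gene`, `log2fc`, `padj` (and optionally
#'   `pvalue`, `contrast`).
#' @return `data.frame`.
#' @export
read_de_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "log2fc", "padj") %in% names(tab)))
    stop("DE table must have columns gene, log2fc, padj")
  if (any(tab$padj < 0 | tab$padj > 1, na.rm = TRUE))
    stop("padj outside [0, 1]")
  tab
}
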