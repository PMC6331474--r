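#' Histone-mark fold enrichment over input
#'
#' Per region and mark: (mean over ChIP replicates + pseudocount) /
#' (mean over input replicates + pseudocount).  A pseudocount keeps the
#' ratio (and its log2) defined when an input mean is 0.
#'
#' @param signals Long `data.frame` with columns `region`, `mark`,
#'   `replicate`, `signal` (summed ChIP coverage >= 0).
#' @param inputs Long `data.frame` with columns `region`, `replicate`,
#'   `signal` for the matched input datasets.
#' @param pseudocount Non-negative; default 0.
#' @param log2 Return log2-transformed enrichment.
#' @return Numeric matrix, rows = regions, columns = marks.
#' @export
mark_fold_enrichment <- function(signals, inputs, pseudocount = 0,
                                 log2 = FALSE) {
  if (any(signals$signal < 0) || any(inputs$signal < 0))
    stop("signals must be >= 0")
  chip <- tapply(signals$signal, list(signals$region, signals$mark), mean)
  inp <- tapply(inputs$signal, inputs$region, mean)
  if (any(is.na(chip))) stop("missing region x mark x replicate combinations")
  inp <- inp[rownames(chip)]
  if (any(is.na(inp))) stop("regions without matched input")
  if (pseudocount == 0 && any(inp == 0))
    stop("all-zero input for some region; supply a pseudocount (e.g. 0.5)")
  enr <- sweep(chip + pseudocount, 1, inp + pseudocount, "/")
  if (log2) base::log2(enr) else enr
}

#' Average region enrichment per associated gene
#'
#' The gene-level value is the unweighted mean of the enrichment of each
#' region (e.g. CSR) associated with the gene; genes with no mapped region
#' are dropped with a warning.
#'
#' @param region_matrix Region x mark matrix (from
#'   [mark_fold_enrichment()]).
#' @param gene_map `data.frame` with columns `gene`, `region`.
#' @return Gene x mark matrix.
#' @export
gene_level_enrichment <- function(region_matrix, gene_map) {
  known <- gene_map$region %in% rownames(region_matrix)
  if (any(!known)) {
    warning("dropping ", sum(!known), " gene-region link(s) to unknown regions")
    gene_map <- gene_map[known, , drop = FALSE]
  }
  if (nrow(gene_map) == 0) stop("no gene has an associated region")
  sub <- region_matrix[gene_map$region, , drop = FALSE]
  g <- factor(gene_map$gene)
  out <- rowsum(sub, g) / as.vector(table(g))
  out[levels(g), , drop = FALSE]
}

#' Hierarchically cluster regions by their mark profile
#'
#' Agglomerative clustering of the rows of an enrichment matrix
#' (defaults: Euclidean distance, average linkage) with a deterministic
#' leaf order.
#'
#' @param mat Numeric matrix with at least 2 rows and no missing values.
#' @param method Distance method passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `hclust` (the tree), `order` (leaf labels in
#'   dendrogram order) and `newick` (the tree serialized via \pkg{ape}).
#' @export
cluster_regions <- function(mat, method = "euclidean", linkage = "average") {
  if (anyNA(mat)) stop("matrix contains missing values")
  if (nrow(mat) < 2) stop("need at least 2 rows to cluster")
  hc <- stats::hclust(stats::dist(mat, method = method), method = linkage)
  list(hclust = hc,
       order = rownames(mat)[hc$order],
       newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Permutation test for SNP enrichment in a region set
#'
#' Counts trait-associated SNPs falling in the regions, then repeatedly
#' redraws the entire region set as length-matched random regions placed
#' uniformly over the genome and recounts.  The p-value uses the +1
#' correction: p = (1 + #\{Nperm_i >= Nobs\}) / (1 + n_permutations), so its
#' floor is 1 / (n_permutations + 1) and Nobs = 0 gives exactly 1.
#'
#' @param snps `data.frame` with columns `chrom`, `pos` (0-based bp).
#' @param regions `GRanges`.
#' @param sizes `ChromSizes`.
#' @param n_permutations Number of random redraws (>= 1; 1e6 at full
#'   scale, smaller for desk-scale runs).
#' @param seed Optional integer seed.
#' @return List of class `PermutationResult`: `n_obs`, `n_perm`
#'   (integer vector), `n_permutations`, `p_value`.
#' @export
snp_enrichment <- function(snps, regions, sizes, n_permutations = 10000,
                           seed = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_obs <- count_point_overlaps(snps, regions, sizes)
  # fast length-matched redraw: same placement model as
  # sample_matched_random, on plain vectors
  L <- as.numeric(unclass(sizes))
  chroms <- names(sizes)
  w <- width(regions)
  pos_by <- split(snps$pos, factor(snps$chrom, chroms))
  n_perm <- integer(n_permutations)
  for (i in seq_len(n_permutations)) {
    ci <- integer(length(w)); st <- numeric(length(w))
    for (uw in unique(w)) {
      idx <- which(w == uw)
      placeable <- pmax(L - uw + 1, 0)
      ci[idx] <- sample.int(length(L), length(idx), replace = TRUE,
                            prob = placeable / sum(placeable))
      st[idx] <- floor(stats::runif(length(idx), 0, placeable[ci[idx]]))
    }
    cnt <- 0L
    for (c in seq_along(chroms)) {
      p <- pos_by[[c]]
      if (!length(p)) next
      k <- which(ci == c)
      if (!length(k)) next
      inreg <- rep(FALSE, length(p))
      for (j in k) inreg <- inreg | (p >= st[j] & p < st[j] + w[j])
      cnt <- cnt + sum(inreg)
    }
    n_perm[i] <- cnt
  }
  p <- (1 + sum(n_perm >= n_obs)) / (1 + n_permutations)
  structure(list(n_obs = n_obs, n_perm = n_perm,
                 n_permutations = n_permutations, p_value = p),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat("Permutation SNP enrichment: Nobs =", x$n_obs,
      "| permutations =", x$n_permutations,
      "| p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Read a trait-associated SNP table
#'
#' @param path TSV with header columns `trait`, `rsid`, `chrom`, `pos`
#'   (1-based positions, converted to 0-based on read).
#' @return `data.frame` with 0-based `pos`.
#' @export
read_snps <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("trait", "rsid", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  tab$pos <- tab$pos - 1L
  tab
}
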