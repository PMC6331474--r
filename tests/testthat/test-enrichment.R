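long_signals <- function(mat3) {
  # mat3: region x mark x replicate array
  d <- dimnames(mat3)
  do.call(rbind, lapply(d[[1]], function(r)
    do.call(rbind, lapply(d[[2]], function(m)
      data.frame(region = r, mark = m, replicate = d[[3]],
                 signal = mat3[r, m, ])))))
}

test_that("fold enrichment is the ratio of replicate means over input means", {
  sig <- data.frame(region = "r1", mark = "H3K27ac",
                    replicate = c("a", "b"), signal = c(2, 4))
  inp <- data.frame(region = "r1", replicate = c("a", "b"), signal = c(1, 1))
  expect_equal(mark_fold_enrichment(sig, inp)[1, 1], 3)
  same <- data.frame(region = "r1", mark = "m", replicate = "a", signal = 5)
  insame <- data.frame(region = "r1", replicate = "a", signal = 5)
  expect_equal(mark_fold_enrichment(same, insame)[1, 1], 1)
  expect_equal(mark_fold_enrichment(same, insame, log2 = TRUE)[1, 1], 0)
  zero <- data.frame(region = "r1", replicate = "a", signal = 0)
  expect_error(mark_fold_enrichment(same, zero), "pseudocount")
  expect_equal(mark_fold_enrichment(same, zero, pseudocount = 0.5)[1, 1],
               5.5 / 0.5)
})

test_that("fold enrichment matches direct arithmetic on random tables", {
  set.seed(30)
  for (rep in 1:10) {
    a <- array(stats::runif(5 * 3 * 2, 0, 10),
               dim = c(5, 3, 2),
               dimnames = list(paste0("r", 1:5), paste0("m", 1:3),
                               c("rep1", "rep2")))
    inp_vals <- matrix(stats::runif(10, 0.5, 3), 5, 2,
                       dimnames = list(paste0("r", 1:5), c("rep1", "rep2")))
    inp <- data.frame(region = rep(rownames(inp_vals), 2),
                      replicate = rep(colnames(inp_vals), each = 5),
                      signal = c(inp_vals))
    got <- mark_fold_enrichment(long_signals(a), inp)
    want <- apply(a, c(1, 2), mean) / rowMeans(inp_vals)
    expect_equal(got[rownames(want), colnames(want)], want,
                 tolerance = 1e-12)
  }
})

test_that("gene-level enrichment is the unweighted mean over a gene's regions", {
  rm <- matrix(c(1, 3, 5), ncol = 1,
               dimnames = list(c("r1", "r2", "r3"), "H3K27ac"))
  map <- data.frame(gene = c("g1", "g1", "g2"),
                    region = c("r1", "r2", "r3"))
  out <- gene_level_enrichment(rm, map)
  expect_equal(out["g1", 1], 2)
  expect_equal(out["g2", 1], 5)
  expect_warning(gene_level_enrichment(rm,
    data.frame(gene = c("g1", "gX"), region = c("r1", "missing"))),
    "unknown region")
})

test_that("clustering is deterministic and separates planted blocks", {
  m <- rbind(a = c(0, 0), b = c(0, 0.0001), c = c(10, 10))
  cl <- cluster_regions(m)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))  # a,b merge first
  expect_s3_class(cl$hclust, "hclust")
  tree <- ape::read.tree(text = cl$newick)
  expect_setequal(tree$tip.label, rownames(m))
  # planted two-block scenario: cutting at k=2 recovers the blocks exactly
  set.seed(5)
  blockA <- matrix(stats::rnorm(40, 10, 0.5), 10, 4)
  blockB <- matrix(stats::rnorm(40, -10, 0.5), 10, 4)
  mm <- rbind(blockA, blockB)
  rownames(mm) <- c(paste0("th17_", 1:10), paste0("treg_", 1:10))
  cl2 <- cluster_regions(mm)
  grp <- stats::cutree(cl2$hclust, k = 2)
  expect_equal(length(unique(grp[1:10])), 1)
  expect_equal(length(unique(grp[11:20])), 1)
  expect_false(grp[1] == grp[11])
  expect_error(cluster_regions(mm[1, , drop = FALSE]), "at least 2")
  mm[1, 1] <- NA
  expect_error(cluster_regions(mm), "missing")
})

test_that("permutation p-value obeys its exact formula bounds", {
  sizes <- chrom_sizes(c(chr1 = 1e6))
  regions <- granges0("chr1", 0, 1000)
  # no observed SNP in regions -> p = 1 exactly
  res <- snp_enrichment(data.frame(chrom = "chr1", pos = 5e5),
                        regions, sizes, n_permutations = 50, seed = 1)
  expect_equal(res$n_obs, 0)
  expect_equal(res$p_value, 1)
  # all SNPs inside, no permutation can match -> floor 1/(n+1)
  snps <- data.frame(chrom = rep("chr1", 20),
                     pos = seq(10, 990, length.out = 20))
  res2 <- snp_enrichment(snps, regions, sizes, n_permutations = 999,
                         seed = 2)
  expect_equal(res2$n_obs, 20)
  expect_equal(res2$p_value, 1 / 1000)
  expect_error(snp_enrichment(snps, regions, sizes, n_permutations = 0),
               ">= 1")
})

test_that("permutation null agrees with the binomial tail on a toy genome", {
  # regions cover 50% of a 1 Mb genome; SNPs planted 100% inside
  sizes <- chrom_sizes(c(chr1 = 1e6))
  starts <- seq(0, 999000, by = 2000)  # 500 x 1000 bp = 50% coverage
  regions <- granges0(rep("chr1", length(starts)), starts, starts + 1000)
  set.seed(4)
  snps <- data.frame(chrom = "chr1",
                     pos = sample(starts, 30) + sample.int(1000, 30) - 1L)
  res <- snp_enrichment(snps, regions, sizes, n_permutations = 2000,
                        seed = 9)
  expect_equal(res$n_obs, 30)
  expect_lt(res$p_value, 0.01)
  # per-SNP coverage under the placement model: 500 independently placed
  # 1 kb regions may overlap, so a fixed point is covered with
  # probability 1 - (1 - w/placeable)^n, not the template's 50% coverage
  p_cov <- 1 - (1 - 1000 / (1e6 - 999))^500
  p0 <- stats::pbinom(29, 30, p_cov, lower.tail = FALSE)
  exceed <- sum(res$n_perm >= res$n_obs)
  expect_lte(abs(exceed - 2000 * p0),
             3 * sqrt(2000 * p0 * (1 - p0)) + 1e-9)
  # permutation counts near-binomial in distribution (mean check)
  expect_lt(abs(mean(res$n_perm) - 30 * p_cov),
            3 * sqrt(30 * p_cov * (1 - p_cov) / 2000) + 0.3)
})
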