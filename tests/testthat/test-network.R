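test_that("gene-SE association takes the nearest center within the limit", {
  se <- granges0(c("chr1", "chr1"), c(0, 500000), c(10000, 510000))
  # centers at 5000 and 505000
  genes <- data.frame(gene = c("at_center", "at_limit", "beyond", "offchrom"),
                      chrom = c("chr1", "chr1", "chr1", "chr2"),
                      tss = c(5000, 105000, 105001, 5000))
  out <- associate_genes_to_se(se, genes, expressed = genes$gene)
  expect_equal(out$gene, c("at_center", "at_limit"))
  expect_equal(out$distance, c(0, 100000))
  expect_equal(out$se_idx, c(1, 1))
  # unexpressed genes are never associated
  out2 <- associate_genes_to_se(se, genes, expressed = character(0))
  expect_equal(nrow(out2), 0)
})

test_that("association matches a brute-force nearest-center oracle", {
  set.seed(41)
  for (rep in 1:20) {
    n_se <- sample(3:8, 1)
    st <- sort(sample.int(900000, n_se))
    se <- granges0(rep("chr1", n_se), st, st + 5000)
    genes <- data.frame(gene = paste0("g", 1:15), chrom = "chr1",
                        tss = sample.int(1000000, 15))
    got <- associate_genes_to_se(se, genes, expressed = genes$gene,
                                 max_distance = 50000)
    centers <- st + 2500
    for (i in seq_len(nrow(genes))) {
      d <- abs(centers - genes$tss[i])
      j <- which.min(d)
      row <- got[got$gene == genes$gene[i], ]
      if (min(d) <= 50000) {
        expect_equal(row$se_idx, j)
        expect_equal(row$distance, min(d))
      } else expect_equal(nrow(row), 0)
    }
  }
})

toy_net <- function() {
  gene_map <- data.frame(gene = c("A", "B", "C"),
                         region = c("rA", "rB", "rC"))
  hits <- data.frame(region = c("rB", "rB", "rC"),
                     tf = c("A", "A", "B"),
                     start = 1:3, stop = 9:11, strand = "+",
                     score = 1, pvalue = 1e-4)
  build_network(gene_map, hits, tf_list = c("A", "B"))
}

test_that("network edges count motif hits at target regions", {
  net <- toy_net()
  expect_equal(nrow(net$edges), 2)
  ab <- net$edges[net$edges$regulator == "A" & net$edges$target == "B", ]
  expect_equal(ab$weight, 2)
  nb <- net$nodes[net$nodes$gene == "B", ]
  expect_equal(nb$indegree, 1)        # distinct regulators
  expect_equal(nb$indegree_hits, 2)   # total motif hits
  expect_equal(sum(net$nodes$indegree), nrow(net$edges))
  expect_equal(sum(net$nodes$outdegree), nrow(net$edges))
  expect_equal(sum(net$nodes$indegree_hits), sum(net$edges$weight))
  # no hits -> edgeless network over the node set
  no_hits <- data.frame(region = character(0), tf = character(0),
                        start = integer(0), stop = integer(0),
                        strand = character(0), score = numeric(0),
                        pvalue = numeric(0))
  net0 <- build_network(data.frame(gene = "A", region = "rA"),
                        no_hits, tf_list = "A")
  expect_equal(nrow(net0$edges), 0)
  expect_equal(net0$nodes$gene, "A")
})

test_that("removing a gene from the map removes its node and edges", {
  gene_map <- data.frame(gene = c("A", "B"), region = c("rA", "rB"))
  hits <- data.frame(region = "rB", tf = "A", start = 1, stop = 9,
                     strand = "+", score = 1, pvalue = 1e-4)
  full <- build_network(gene_map, hits, tf_list = c("A", "B"))
  expect_equal(nrow(full$edges), 1)
  dropped <- build_network(gene_map[gene_map$gene != "B", ], hits,
                           tf_list = c("A", "B"))
  expect_equal(nrow(dropped$edges), 0)
  expect_false("B" %in% dropped$nodes$gene)
})

test_that("CSR extraction applies the strict 1e-7 FDR filter", {
  gene_map <- data.frame(gene = c("T1", "T2", "T3", "G"),
                         region = paste0("r", 1:4))
  de <- data.frame(gene = c("T1", "T2", "G"),
                   log2fc = c(5, 4, 6),
                   padj = c(1e-8, 1e-7, 1e-12))
  expect_message(
    csr <- extract_csrs(gene_map, de, tf_list = c("T1", "T2", "T3")),
    "without DE entry")
  expect_equal(csr$tfs, "T1")          # 1e-7 exactly is excluded; G not a TF
  expect_equal(csr$regions, "r1")
  empty <- extract_csrs(gene_map, de[0, ], tf_list = "T1")
  expect_length(empty$tfs, 0)
})

test_that("core subnetwork restricts targets to CSR TFs", {
  net <- toy_net()
  all_csr <- structure(list(tfs = c("A", "B", "C"),
                            regions = c("rA", "rB", "rC"),
                            gene_map = NULL), class = "CsrSet")
  expect_equal(core_subnetwork(net, all_csr)$edges[, 1:3], net$edges[, 1:3])
  none <- structure(list(tfs = character(0), regions = character(0),
                         gene_map = NULL), class = "CsrSet")
  expect_equal(nrow(core_subnetwork(net, none)$edges), 0)
  only_b <- structure(list(tfs = "B", regions = "rB", gene_map = NULL),
                      class = "CsrSet")
  core <- core_subnetwork(net, only_b)
  expect_equal(core$edges$target, "B")
  expect_setequal(core$nodes$gene, c("A", "B"))
})

test_that("edge signs follow the correlation threshold", {
  net <- toy_net()
  cors <- data.frame(gene1 = c("A", "B"), gene2 = c("B", "C"),
                     r = c(0.5, -0.5))
  signed <- sign_edges(net, cors, r_crit = 0.3961)
  expect_equal(signed$edges$sign[signed$edges$target == "B"], "activatory")
  expect_equal(signed$edges$sign[signed$edges$target == "C"], "inhibitory")
  weak <- sign_edges(net, transform(cors, r = c(0.2, 0.2)),
                     r_crit = 0.3961)
  expect_true(all(weak$edges$sign == "unsigned"))
  expect_message(sign_edges(net, cors[0, ], r_crit = 0.3961),
                 "without a correlation")
})

test_that("ER-alpha target networks pass ERE counts through as weights", {
  counts <- c(T1 = 3, T2 = 1, T3 = 0, T4 = 2, T5 = 1, T6 = 1)
  de <- data.frame(gene = paste0("T", 1:6), log2fc = 1,
                   padj = c(1e-5, 0.5, 1e-9, 1e-4, 0.2, 0.9))
  core <- toy_net()
  net <- er_target_network(counts, de, p_threshold = 1e-3, core = core)
  expect_equal(nrow(net$edges), 5)           # all nonzero-count targets
  expect_equal(sum(net$nodes$de_flag, na.rm = TRUE), 2)  # T1, T4
  expect_equal(net$edges$weight[net$edges$target == "T1"], 3)
  zero <- er_target_network(c(T1 = 0), de)
  expect_equal(nrow(zero$edges), 0)
  expect_equal(zero$nodes$gene, "ESR1")
})

test_that("network exports round-trip and are byte-stable", {
  net <- sign_edges(toy_net(),
                    data.frame(gene1 = c("A", "B"), gene2 = c("B", "C"),
                               r = c(0.9, -0.9)), r_crit = 0.3961)
  p1 <- file.path(tempdir(), "netx")
  export_network(net, p1)
  back <- import_network(p1)
  expect_equal(back$nodes, net$nodes, ignore_attr = TRUE)
  expect_equal(back$edges, net$edges, ignore_attr = TRUE)
  g <- igraph::read_graph(paste0(p1, ".graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  p2 <- file.path(tempdir(), "nety")
  export_network(net, p2)
  expect_identical(readLines(paste0(p1, ".sif")),
                   readLines(paste0(p2, ".sif")))
  expect_identical(readLines(paste0(p1, "_edges.tsv")),
                   readLines(paste0(p2, "_edges.tsv")))
  # an edgeless network exports bare nodes in SIF
  lone <- build_network(data.frame(gene = "A", region = "rA"),
                        data.frame(region = character(0), tf = character(0),
                                   start = integer(0), stop = integer(0),
                                   strand = character(0), score = numeric(0),
                                   pvalue = numeric(0)), tf_list = "A")
  p3 <- file.path(tempdir(), "netz")
  export_network(lone, p3, formats = "sif")
  expect_equal(readLines(paste0(p3, ".sif")), "A")
  expect_error(export_network(net, p3, formats = "dot"), "unknown format")
})
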