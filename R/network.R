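#' Stable region identifier ("chrom:start-end", 0-based half-open)
#' @param x `GRanges`.
#' @return Character vector of ids.
#' @export
region_id <- function(x) {
  sprintf("%s:%d-%d", as.character(seqnames(x)), start(x) - 1L, end(x))
}

#' Associate expressed genes to their nearest super-enhancer
#'
#' Per expressed gene, the SE on the gene's chromosome whose center is
#' nearest the TSS is found; the gene is associated when that distance is
#' at most `max_distance` (boundary inclusive).  Ties go to the leftmost
#' SE.  One SE per gene; many genes may share an SE.
#'
#' @param se `GRanges` of super-enhancer regions.
#' @param genes `data.frame` with columns `gene`, `chrom`, `tss`
#'   (0-based TSS position).
#' @param expressed Character vector of expressed gene names (only these
#'   can be associated).
#' @param max_distance Maximum TSS-to-center distance in bp
#'   (default 100000).
#' @return `data.frame` with `gene`, `se_idx` (index into `se`),
#'   `distance`.
#' @export
associate_genes_to_se <- function(se, genes, expressed,
                                  max_distance = 100000) {
  genes <- genes[genes$gene %in% expressed, , drop = FALSE]
  if (nrow(genes) == 0 || length(se) == 0)
    return(data.frame(gene = character(0), se_idx = integer(0),
                      distance = numeric(0)))
  ord <- order(as.character(seqnames(se)), start(se))
  center <- (start(se) - 1L + end(se)) %/% 2L  # 0-based center
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    onchrom <- ord[as.character(seqnames(se))[ord] == genes$chrom[i]]
    if (!length(onchrom)) return(NULL)
    d <- abs(center[onchrom] - genes$tss[i])
    j <- onchrom[which.min(d)]  # which.min takes first = leftmost
    if (min(d) > max_distance) return(NULL)
    data.frame(gene = genes$gene[i], se_idx = j, distance = min(d))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), se_idx = integer(0),
                      distance = numeric(0))
  out
}

#' Map associated genes to their SE-ARR region ids
#' @param assoc Output of [associate_genes_to_se()].
#' @param se_arrs `GRanges` with an `se_idx` column
#'   (see [intersect_se_arrs()]).
#' @return `data.frame` with `gene`, `region` (region id), `se_idx`.
#' @export
gene_region_map <- function(assoc, se_arrs) {
  if (nrow(assoc) == 0 || length(se_arrs) == 0)
    return(data.frame(gene = character(0), region = character(0),
                      se_idx = integer(0)))
  ids <- region_id(se_arrs)
  rows <- lapply(seq_len(nrow(assoc)), function(i) {
    k <- which(se_arrs$se_idx == assoc$se_idx[i])
    if (!length(k)) return(NULL)
    data.frame(gene = assoc$gene[i], region = ids[k],
               se_idx = assoc$se_idx[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), region = character(0),
                      se_idx = integer(0))
  out
}

new_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat("RegulatoryNetwork:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Build the TF regulatory network from motif hits
#'
#' Nodes are the expressed SE-ARR-associated genes (the genes of
#' `gene_map`); a directed edge TF -> target exists when at least one
#' significant occurrence of the TF's motif lies in any of the target's
#' regions, weighted by the hit count.  Regulators are restricted to
#' TF-coding node genes; TFs without a PWM simply contribute no outgoing
#' edges.  Indegree is reported both as distinct regulators (`indegree`)
#' and as total incoming motif hits (`indegree_hits`).
#'
#' @param gene_map `data.frame` with `gene`, `region`
#'   (see [gene_region_map()]).
#' @param hits Motif hit table from [scan_sequences()].
#' @param tf_list Character vector of TF-coding gene names.
#' @param expression Optional `data.frame` with `gene`, `log2fc`, `padj`
#'   annotated onto nodes.
#' @return `RegulatoryNetwork` with `nodes` and `edges` data frames.
#' @export
build_network <- function(gene_map, hits, tf_list, expression = NULL) {
  genes <- unique(gene_map$gene)
  regulators <- intersect(genes, tf_list)
  edges <- data.frame(regulator = character(0), target = character(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  if (nrow(hits) > 0 && length(regulators)) {
    h <- hits[hits$tf %in% regulators, , drop = FALSE]
    m <- merge(h, gene_map[, c("gene", "region")], by = "region")
    if (nrow(m)) {
      agg <- stats::aggregate(list(weight = rep(1L, nrow(m))),
                              by = list(regulator = m$tf, target = m$gene),
                              FUN = sum)
      edges <- agg[order(agg$regulator, agg$target), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  nodes <- data.frame(gene = sort(genes),
                      is_tf = sort(genes) %in% tf_list,
                      stringsAsFactors = FALSE)
  nodes$indegree <- vapply(nodes$gene, function(g)
    sum(edges$target == g), integer(1))
  nodes$indegree_hits <- vapply(nodes$gene, function(g)
    sum(edges$weight[edges$target == g]), numeric(1))
  nodes$outdegree <- vapply(nodes$gene, function(g)
    sum(edges$regulator == g), integer(1))
  nodes$outdegree_hits <- vapply(nodes$gene, function(g)
    sum(edges$weight[edges$regulator == g]), numeric(1))
  if (!is.null(expression)) {
    nodes <- merge(nodes, expression[, intersect(names(expression),
                   c("gene", "log2fc", "padj"))], by = "gene",
                   all.x = TRUE, sort = TRUE)
  }
  new_network(nodes, edges)
}

#' Extract cell-type-specific regulatory regions (CSRs)
#'
#' CSRs are the SE-ARRs of TF-coding genes that are highly differentially
#' expressed versus naive cells: FDR-adjusted p strictly below the
#' threshold.  TFs missing from the DE table are excluded with a message.
#'
#' @param gene_map `data.frame` with `gene`, `region`.
#' @param de DE table with `gene`, `padj` (vs-naive contrast).
#' @param tf_list Character vector of TF-coding genes.
#' @param p_threshold FDR threshold (default 1e-7, strict <).
#' @return List of class `CsrSet`: `tfs` (passing TF names), `regions`
#'   (their region ids), `gene_map` (restricted map).
#' @export
extract_csrs <- function(gene_map, de, tf_list, p_threshold = 1e-7) {
  tfs <- intersect(unique(gene_map$gene), tf_list)
  missing <- setdiff(tfs, de$gene)
  if (length(missing))
    message("TF(s) without DE entry excluded: ",
            paste(missing, collapse = ", "))
  tfs <- intersect(tfs, de$gene)
  padj <- stats::setNames(de$padj, de$gene)[tfs]
  pass <- tfs[!is.na(padj) & padj < p_threshold]
  sub <- gene_map[gene_map$gene %in% pass, , drop = FALSE]
  structure(list(tfs = sort(pass), regions = unique(sub$region),
                 gene_map = sub), class = "CsrSet")
}

#' Core regulatory subnetwork over CSR-associated TFs
#'
#' Restricts the network to edges whose target is a CSR-associated TF;
#' regulators are retained when they hit at least one CSR.  Node degree
#' statistics are recomputed on the subnetwork.
#'
#' @param network `RegulatoryNetwork`.
#' @param csr_set `CsrSet` from [extract_csrs()].
#' @return `RegulatoryNetwork`.
#' @export
core_subnetwork <- function(network, csr_set) {
  edges <- network$edges[network$edges$target %in% csr_set$tfs, ,
                         drop = FALSE]
  keep <- union(csr_set$tfs, edges$regulator)
  nodes <- network$nodes[network$nodes$gene %in% keep, , drop = FALSE]
  nodes$indegree <- vapply(nodes$gene, function(g)
    sum(edges$target == g), integer(1))
  nodes$indegree_hits <- vapply(nodes$gene, function(g)
    sum(edges$weight[edges$target == g]), numeric(1))
  nodes$outdegree <- vapply(nodes$gene, function(g)
    sum(edges$regulator == g), integer(1))
  nodes$outdegree_hits <- vapply(nodes$gene, function(g)
    sum(edges$weight[edges$regulator == g]), numeric(1))
  rownames(nodes) <- rownames(edges) <- NULL
  new_network(nodes, edges)
}

#' Sign network edges by expression correlation
#'
#' Activatory when r > r_crit, inhibitory when r < -r_crit, otherwise
#' unsigned (retained and flagged); edges with no correlation entry stay
#' unsigned with a message.
#'
#' @param network `RegulatoryNetwork`.
#' @param correlations `data.frame` from [pairwise_correlations()].
#' @param r_crit Significance threshold on |r|.
#' @return `RegulatoryNetwork` with edge columns `r` and `sign`
#'   (`"activatory"`, `"inhibitory"`, `"unsigned"`).
#' @export
sign_edges <- function(network, correlations,
                       r_crit = critical_pearson(25)) {
  edges <- network$edges
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lut <- stats::setNames(correlations$r,
                         key(correlations$gene1, correlations$gene2))
  self <- edges$regulator == edges$target
  r <- unname(lut[key(edges$regulator, edges$target)])
  r[self] <- 1
  if (any(is.na(r)) && nrow(edges))
    message(sum(is.na(r)), " edge(s) without a correlation; left unsigned")
  edges$r <- r
  edges$sign <- ifelse(is.na(r), "unsigned",
                 ifelse(r > r_crit, "activatory",
                  ifelse(r < -r_crit, "inhibitory", "unsigned")))
  new_network(network$nodes, edges)
}

#' Predicted ER-alpha target network from ERE hit counts
#'
#' A star network from ER-alpha to every gene whose SE-ARRs contain at
#' least one significant ERE, weighted by the ERE count; targets passing
#' the DE filter and targets also present in the core subnetwork are
#' flagged.
#'
#' @param ere_counts Named integer vector from [ere_hits()].
#' @param de DE table (`gene`, `padj`) for the vs-naive contrast.
#' @param p_threshold DE flag threshold (default 1e-3, strict <).
#' @param core Optional core `RegulatoryNetwork` for the `in_core` flag.
#' @param er_name Name of the ER-alpha node (default `"ESR1"`).
#' @return `RegulatoryNetwork`; edge weights equal the ERE counts.
#' @export
er_target_network <- function(ere_counts, de, p_threshold = 1e-3,
                              core = NULL, er_name = "ESR1") {
  targets <- names(ere_counts)[ere_counts > 0]
  padj <- stats::setNames(de$padj, de$gene)[targets]
  nodes <- data.frame(
    gene = c(er_name, sort(targets)),
    is_er = c(TRUE, rep(FALSE, length(targets))),
    de_flag = c(NA, !is.na(padj[sort(targets)]) &
                    padj[sort(targets)] < p_threshold),
    in_core = c(NA, if (is.null(core)) rep(NA, length(targets))
                    else sort(targets) %in% core$nodes$gene),
    stringsAsFactors = FALSE)
  edges <- data.frame(regulator = rep(er_name, length(targets)),
                      target = sort(targets),
                      weight = as.integer(ere_counts[sort(targets)]),
                      stringsAsFactors = FALSE)
  new_network(nodes, edges)
}

#' Convert a RegulatoryNetwork to an igraph graph
#' @param network `RegulatoryNetwork`.
#' @return `igraph` directed graph with node/edge attributes.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$nodes)
}

#' Export a network as SIF, GraphML and attribute tables
#'
#' Writes `<prefix>.sif`, `<prefix>.graphml`, `<prefix>_nodes.tsv` and
#' `<prefix>_edges.tsv`; the TSV pair round-trips losslessly through
#' [import_network()].
#'
#' @param network `RegulatoryNetwork`.
#' @param prefix Output path prefix.
#' @param formats Subset of `c("sif", "graphml", "tsv")`.
#' @return Invisibly, the written file paths.
#' @export
export_network <- function(network, prefix,
                           formats = c("sif", "graphml", "tsv")) {
  bad <- setdiff(formats, c("sif", "graphml", "tsv"))
  if (length(bad)) stop("unknown format(s): ", paste(bad, collapse = ", "))
  paths <- character(0)
  if ("sif" %in% formats) {
    p <- paste0(prefix, ".sif")
    lonely <- setdiff(network$nodes$gene,
                      c(network$edges$regulator, network$edges$target))
    lines <- c(if (nrow(network$edges))
                 sprintf("%s\tregulates\t%s", network$edges$regulator,
                         network$edges$target),
               lonely)
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  if ("graphml" %in% formats) {
    p <- paste0(prefix, ".graphml")
    igraph::write_graph(as_igraph(network), p, format = "graphml")
    paths <- c(paths, p)
  }
  if ("tsv" %in% formats) {
    pn <- paste0(prefix, "_nodes.tsv"); pe <- paste0(prefix, "_edges.tsv")
    utils::write.table(network$nodes, pn, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(network$edges, pe, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, pn, pe)
  }
  invisible(paths)
}

#' Read a network back from its attribute tables
#' @param prefix Path prefix used by [export_network()].
#' @return `RegulatoryNetwork`.
#' @export
import_network <- function(prefix) {
  nodes <- utils::read.table(paste0(prefix, "_nodes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  edges <- utils::read.table(paste0(prefix, "_edges.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  new_network(nodes, edges)
}
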