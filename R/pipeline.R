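#' Read gene models (TSS and longest-isoform length)
#' @param path TSV with header `gene`, `chrom`, `tss` (0-based bp),
#'   `length` (bp > 0).
#' @return `data.frame`.
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "chrom", "tss", "length") %in% names(tab)))
    stop("gene models need columns gene, chrom, tss, length")
  if (any(tab$length <= 0)) stop("gene lengths must be > 0")
  tab
}

#' Read a one-column TF gene list
#' @param path File with header `gene`.
#' @return Character vector of TF gene names.
#' @export
read_tf_list <- function(path) {
  utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)$gene
}

#' Read a count matrix (genes x samples)
#' @param path TSV; first column `gene`, remaining columns samples.
#' @return Integer matrix with gene rownames.
#' @export
read_count_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Read the sample-to-subtype map
#' @param path TSV with header `sample`, `subtype`.
#' @return `data.frame`.
#' @export
read_sample_map <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Default pipeline parameters
#'
#' Every threshold of the analysis in one place: stitching distance
#' 12,500 bp, emission threshold 75, FPKM expression threshold 1,
#' DE significance 0.001, CSR filter 1e-7, ER-alpha target DE flag 1e-3,
#' motif p-value 0.001, correlation alpha 0.05 (two-tailed), SE-to-gene
#' distance 100,000 bp, and the number of SNP permutations (desk-scale
#' default 2,000; 1,000,000 reproduces the full-scale setting).
#'
#' @return Named list.
#' @export
default_pipeline_params <- function() {
  list(stitch_distance = 12500,
       tss_exclusion = 0,
       emission_threshold = 75,
       emission_marks = c("H3K27ac", "H3K4me1"),
       bin_size = 200,
       fpkm_threshold = 1,
       de_alpha = 0.001,
       csr_alpha = 1e-7,
       er_de_alpha = 1e-3,
       motif_p = 0.001,
       motif_pseudocount = 0.1,
       cor_alpha = 0.05,
       se_gene_distance = 100000,
       n_permutations = 2000,
       naive_label = "Naive",
       ere_name = "ESR1")
}

#' Run the full integrative analysis on a dataset bundle
#'
#' Executes every stage on a bundle laid out as written by
#' [generate_scenario()]: super-enhancer calling per lineage track,
#' active-state selection and ARR classification from the
#' segmentations, SE-ARR intersection, expression normalization / FPKM /
#' expressed flags / specificity Z-scores, vs-naive differential
#' expression (Welch stand-in), gene-to-SE association, motif scanning,
#' network assembly with CSR extraction, core subnetworks, correlation
#' signing and ER-alpha target networks, and SNP permutation enrichment.
#' When `out_dir` is given, tables and network exports are written and a
#' manifest with md5 checksums is returned; reruns with the same seed
#' and parameters reproduce identical checksums.
#'
#' @param bundle_dir Directory with the input files.
#' @param out_dir Optional output directory for exports.
#' @param params Parameter list (see [default_pipeline_params()]).
#' @param seed Integer seed (used for the permutation stage).
#' @return List with all stage results and `manifest`.
#' @export
run_pipeline <- function(bundle_dir, out_dir = NULL,
                         params = default_pipeline_params(), seed = 1) {
  pth <- function(f) file.path(bundle_dir, f)
  sizes <- read_chrom_sizes(pth("chrom.sizes"))
  tracks <- sub("^searr_(.*)\\.fasta$", "\\1",
                basename(Sys.glob(pth("searr_*.fasta"))))
  subtypes <- sub("^seg_(.*)\\.bed$", "\\1",
                  basename(Sys.glob(pth("seg_*.bed"))))

  ## super-enhancer calling
  se_calls <- list(); se_gr <- list()
  for (tr in tracks) {
    peaks <- read_bed(pth(sprintf("peaks_%s.bed", tr)), sizes)
    chip <- read_bedgraph(pth(sprintf("chip_%s.bedgraph", tr)))
    input <- read_bedgraph(pth(sprintf("input_%s.bedgraph", tr)))
    stitched <- stitch_peaks(peaks, params$stitch_distance,
                             tss_exclusion = params$tss_exclusion)
    quant <- quantify_region_signal(stitched, chip, input)
    se_calls[[tr]] <- call_superenhancers(quant)
    se_gr[[tr]] <- se_granges(se_calls[[tr]])
  }

  ## chromatin states -> ARRs -> SE-ARRs
  emis <- read_emission_matrix(pth("emissions.tsv"))
  active <- select_active_states(emis, params$emission_marks,
                                 params$emission_threshold)
  segs <- lapply(stats::setNames(subtypes, subtypes), function(s)
    read_segmentation(pth(sprintf("seg_%s.bed", s)), params$bin_size))
  classified <- classify_specific_arrs(segs, active, params$bin_size)
  se_arrs <- list()
  for (tr in tracks)
    se_arrs[[tr]] <- intersect_se_arrs(arrs_of(classified, tr), se_gr[[tr]])

  ## expression
  counts <- read_count_matrix(pth("counts.tsv"))
  smap <- read_sample_map(pth("samples.tsv"))
  smap <- smap[match(colnames(counts), smap$sample), ]
  genes <- read_gene_models(pth("genes.tsv"))
  tf_list <- read_tf_list(pth("tf_list.tsv"))
  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  fp <- fpkm(norm, stats::setNames(genes$length, genes$gene))
  expressed <- expressed_flags(fp, smap$subtype, params$fpkm_threshold)
  zs <- subtype_zscore(fp, smap$subtype)
  de <- list()
  for (tr in tracks) {
    keep <- smap$subtype %in% c(tr, params$naive_label)
    de[[tr]] <- de_welch(counts[, keep, drop = FALSE],
                         smap$subtype[keep],
                         contrast = c(tr, params$naive_label))
  }

  ## motif scanning
  pwms <- read_meme(pth("pwms.meme"))
  meta <- read_pwm_metadata(pth("pwm_metadata.tsv"))
  lib <- build_nonredundant_library(pwm_records(pwms, meta))
  hits <- list(); seqs <- list()
  for (tr in tracks) {
    seqs[[tr]] <- Biostrings::readDNAStringSet(
      pth(sprintf("searr_%s.fasta", tr)))
    hits[[tr]] <- scan_sequences(seqs[[tr]], lib,
                                 p_threshold = params$motif_p,
                                 pseudocount = params$motif_pseudocount)
  }

  ## networks
  r_crit <- critical_pearson(ncol(counts), params$cor_alpha)
  assoc <- list(); gene_maps <- list(); networks <- list()
  csrs <- list(); cores <- list(); ere <- list(); er_nets <- list()
  for (tr in tracks) {
    assoc[[tr]] <- associate_genes_to_se(
      se_gr[[tr]], genes,
      expressed = rownames(expressed)[expressed[, tr]],
      max_distance = params$se_gene_distance)
    gene_maps[[tr]] <- gene_region_map(assoc[[tr]], se_arrs[[tr]]$se_arrs)
    net <- build_network(gene_maps[[tr]], hits[[tr]], tf_list,
                         expression = de[[tr]])
    csrs[[tr]] <- extract_csrs(gene_maps[[tr]], de[[tr]], tf_list,
                               params$csr_alpha)
    core <- core_subnetwork(net, csrs[[tr]])
    pair_src <- rbind(net$edges[, c("regulator", "target")],
                      core$edges[, c("regulator", "target")])
    cors <- if (nrow(pair_src))
      pairwise_correlations(fp[unique(c(pair_src[[1]], pair_src[[2]])), ,
                               drop = FALSE],
                            pairs = unique(pair_src), r_crit = r_crit)
    else data.frame(gene1 = character(0), gene2 = character(0),
                    r = numeric(0))
    networks[[tr]] <- sign_edges(net, cors, r_crit)
    cores[[tr]] <- sign_edges(core, cors, r_crit)
    ere[[tr]] <- ere_hits(hits[[tr]], gene_maps[[tr]],
                          ere_tf = params$ere_name, library = lib)
    er_nets[[tr]] <- er_target_network(ere[[tr]], de[[tr]],
                                       params$er_de_alpha,
                                       core = cores[[tr]],
                                       er_name = params$ere_name)
  }

  ## SNP enrichment (per trait, against each track's SEs)
  snp_res <- list()
  if (file.exists(pth("snps.tsv"))) {
    snps <- read_snps(pth("snps.tsv"))
    for (tr in tracks) {
      snp_res[[tr]] <- list()
      for (trait in unique(snps$trait)) {
        sub <- snps[snps$trait == trait, , drop = FALSE]
        snp_res[[tr]][[trait]] <- snp_enrichment(
          sub, se_gr[[tr]], sizes,
          n_permutations = params$n_permutations,
          seed = seed + match(tr, tracks) * 1000 +
            match(trait, unique(snps$trait)))
      }
    }
  }

  ## exports + manifest
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    add <- function(f) files <<- c(files, f)
    for (tr in tracks) {
      f <- file.path(out_dir, sprintf("se_calls_%s.tsv", tr))
      utils::write.table(se_calls[[tr]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add(f)
      if (length(se_gr[[tr]]))
        add(write_bed(se_gr[[tr]], file.path(out_dir,
                      sprintf("se_%s.bed", tr))))
      arr <- arrs_of(classified, tr)
      if (length(arr))
        add(write_bed(arr, file.path(out_dir, sprintf("arr_%s.bed", tr))))
      add(export_network(networks[[tr]],
                         file.path(out_dir, sprintf("network_%s", tr))))
      add(export_network(cores[[tr]],
                         file.path(out_dir, sprintf("core_%s", tr))))
      add(export_network(er_nets[[tr]],
                         file.path(out_dir, sprintf("er_targets_%s", tr))))
    }
    f <- file.path(out_dir, "zscores.tsv")
    utils::write.table(data.frame(gene = rownames(zs), zs,
                                  check.names = FALSE), f,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add(f)
    files <- unlist(files)
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    manifest <- manifest[order(manifest$file), ]
    rownames(manifest) <- NULL
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(tracks = tracks, subtypes = subtypes, sizes = sizes,
       se_calls = se_calls, se = se_gr,
       active_states = active, classified = classified, se_arrs = se_arrs,
       size_factors = sf, fpkm = fp, expressed = expressed, zscores = zs,
       de = de, library = lib, hits = hits,
       assoc = assoc, gene_maps = gene_maps,
       networks = networks, csrs = csrs, cores = cores,
       ere = ere, er_networks = er_nets,
       snp = snp_res, r_crit = r_crit,
       params = params, seed = seed, manifest = manifest)
}

#' Run a single pipeline stage by name
#'
#' Thin dispatcher over the package's stage functions, for command-line
#' use.  `simulate` writes a synthetic bundle; every other stage runs
#' the full dependency chain via [run_pipeline()] and returns that
#' stage's result.
#'
#' @param stage One of `simulate`, `se-call`, `arr-call`, `expr`,
#'   `motif-scan`, `network`, `snp-enrich`, `all`.
#' @param bundle_dir Input bundle directory (ignored for `simulate`
#'   unless used as the output).
#' @param out_dir Output directory.
#' @param params Pipeline parameters.
#' @param seed Integer seed.
#' @return Stage result (invisibly for `simulate`).
#' @export
run_stage <- function(stage, bundle_dir, out_dir = NULL,
                      params = default_pipeline_params(), seed = 1) {
  stage <- match.arg(stage, c("simulate", "se-call", "arr-call", "expr",
                              "motif-scan", "network", "snp-enrich", "all"))
  if (stage == "simulate")
    return(generate_scenario(default_scenario_config(seed), bundle_dir))
  res <- run_pipeline(bundle_dir, out_dir, params, seed)
  switch(stage,
         "se-call" = res$se_calls,
         "arr-call" = res$classified,
         "expr" = res[c("size_factors", "fpkm", "expressed", "zscores", "de")],
         "motif-scan" = res$hits,
         "network" = res[c("networks", "csrs", "cores", "er_networks")],
         "snp-enrich" = res$snp,
         "all" = res)
}
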