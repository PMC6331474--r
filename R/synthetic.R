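#' Default synthetic scenario configuration
#'
#' The scenario mirrors the shape of the real study design: four
#' epigenome subtypes (Naive, Th, Th17, Treg) with 200-bp segmentations,
#' H3K27ac peak/coverage tracks for the Th17 and Treg lineages, a 5
#' expression subtypes x 5 replicates (25 sample) RNA-seq count matrix,
#' and planted ground truth throughout: 5 Th17 / 11 Treg super-enhancer
#' loci of which 4 and 10 host highly differentially expressed
#' master-regulator TFs (the planted CSR-TF sets), subtype-exclusive
#' regulatory runs engineered to satisfy the strict-majority rule
#' exactly, motif instances (including an ERE-like ER-alpha motif)
#' planted in SE-ARR sequences, and SNP sets with known in-region
#' fractions.
#'
#' @param seed Integer seed fixing every byte of the generated bundle.
#' @return Named list of class `ScenarioConfig`.
#' @export
default_scenario_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    genome = c(chr1 = 2e6, chr2 = 2e6),
    epi_subtypes = c("Naive", "Th", "Th17", "Treg"),
    expr_subtypes = c("Naive", "Th1", "Th2", "Th17", "Treg"),
    n_reps = 5,
    se_tracks = c("Th17", "Treg"),
    se_chrom = c(Th17 = "chr1", Treg = "chr2"),
    n_csr_tfs = c(Th17 = 4, Treg = 10),
    n_down_tfs = c(Th17 = 1, Treg = 2),
    n_regulators = c(Th17 = 3, Treg = 5),
    se_fold = 10,
    n_background_loci = 27,
    bin_size = 200,
    run_len_bins = 10,
    n_exclusive_runs = 8,
    n_mixed_runs = 2,
    n_shared_runs = 6,
    dispersion = 0.1,
    master_dispersion = 0.002,
    up_mu = 1e6, low_mu = 1000,
    down_mu_other = 1e6, down_mu_focal = 1000,
    flat_mu = 500, esr1_mu = 200,
    bg_meanlog = log(300), bg_sdlog = 0.8,
    motif_prob = 0.94,
    n_bg_genes = 200, n_bg_tfs = 4,
    snp_traits = list(
      autoimmune = list(n = 40, in_fraction = 0.9),
      control = list(n = 40, in_fraction = 0)),
    ere_name = "ESR1"
  ), class = "ScenarioConfig")
}

# deterministic consensus sequences; pairwise non-substring (incl. RC),
# non-palindromic. The ESR1 entry is a synthetic ERE-like motif.
scenario_consensi <- function() {
  list(Th17 = c(TH17_TF1 = "CTTAGGAC", TH17_TF2 = "GACCTTG",
                TH17_TF3 = "TGGCAA"),
       Treg = c(TREG_TF1 = "CCATCGT", TREG_TF2 = "GTTACGGA",
                TREG_TF3 = "ACGTCA", TREG_TF4 = "TCCGGAAT",
                TREG_TF5 = "GAATCCG"),
       ERE = c(ESR1 = "AGGTCAGG"))
}

consensus_pwm <- function(consensus, p = 0.94) {
  letters <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p) / 3, nrow = length(letters), ncol = 4,
              dimnames = list(NULL, DNA))
  m[cbind(seq_along(letters), match(letters, DNA))] <- p
  m
}

rand_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

rc_string <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# plant plan: per target gene a data.frame(tf, weight); ERE plan per track
edge_plan <- function(cfg, track) {
  m <- cfg$n_csr_tfs[[track]]
  k <- cfg$n_regulators[[track]]
  pre <- toupper(track)
  tfs <- sprintf("%s_TF%d", pre, seq_len(m))
  xtf <- sprintf("%s_XTF", pre)
  regs <- tfs[seq_len(k)]
  plan <- list()
  for (i in seq_len(m + 1)) {
    target <- if (i <= m) tfs[i] else xtf
    e1 <- regs[1 + (i - 1) %% k]; w1 <- 1 + i %% 3
    rows <- data.frame(tf = e1, weight = w1, stringsAsFactors = FALSE)
    if (i <= m) {
      e2 <- regs[1 + i %% k]
      if (e2 == e1) rows$weight <- rows$weight + 1
      else rows <- rbind(rows, data.frame(tf = e2, weight = 1))
    }
    plan[[target]] <- rows
  }
  plan
}

ere_plan <- function(cfg, track) {
  m <- cfg$n_csr_tfs[[track]]
  n_down <- cfg$n_down_tfs[[track]]
  pre <- toupper(track)
  counts <- c(2)
  names(counts) <- sprintf("%s_TF1", pre)
  if (m > 4) counts[sprintf("%s_TF2", pre)] <- 1
  counts[sprintf("%s_TF%d", pre, m - n_down + 1)] <- 1  # a down-regulated TF
  counts[sprintf("%s_XTF", pre)] <- 1
  counts
}

se_layout <- function(cfg, track) {
  n_se <- cfg$n_csr_tfs[[track]] + 1L
  spacing <- if (track == "Th17") 150000L else 120000L
  start <- as.integer(100000 + (seq_len(n_se) - 1) * spacing)
  list(chrom = cfg$se_chrom[[track]],
       start = start, end = start + 7600L,
       center = start + 3800L,
       arr_start = start + 2800L, arr_end = start + 4800L,
       peak_starts = lapply(start, function(s) s + c(0, 3200, 6400)),
       bg_start = if (track == "Th17") 1250000 else 1450000)
}

#' Generate the default synthetic dataset bundle
#'
#' Writes every input format the pipeline consumes into `out_dir`
#' (chrom sizes, emission matrix, four segmentation BEDs, peak BEDs and
#' chip/input bedGraphs per lineage track, gene models, TF list, count
#' matrix, SE-ARR FASTA per track, a redundant PWM file with metadata,
#' SNP tables) together with the serialized ground truth
#' (`ground_truth.json`).  The bundle is byte-deterministic given
#' `config$seed`: regenerating with the same seed reproduces every file
#' exactly.
#'
#' Background SE-ARR sequence is scrubbed of chance motif occurrences
#' (rescan and re-randomize until the only significant hits are the
#' planted ones), so the motif/edge ground truth is exact by
#' construction.
#'
#' @param config `ScenarioConfig` (see [default_scenario_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `truth` and `config`.
#' @export
generate_scenario <- function(config = default_scenario_config(),
                              out_dir) {
  cfg <- config
  set.seed(cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- chrom_sizes(cfg$genome)
  bs <- cfg$bin_size
  run_len <- cfg$run_len_bins * bs
  if (run_len > min(cfg$genome)) stop("run length exceeds chromosome size")
  write_chrom_sizes(sizes, file.path(out_dir, "chrom.sizes"))

  ## ---- emission matrix (toy 5-state model) ----
  emis <- rbind(
    `1_Quies`   = c(5, 5, 2, 0),
    `5_Tx`      = c(10, 60, 10, 5),
    `13_EnhA1`  = c(95, 90, 20, 1),
    `14_EnhA2`  = c(90, 80, 15, 2),
    `24_ReprPC` = c(0, 0, 1, 80))
  colnames(emis) <- c("H3K27ac", "H3K4me1", "H3K4me3", "H3K27me3")
  utils::write.table(data.frame(state = rownames(emis), emis,
                                check.names = FALSE),
                     file.path(out_dir, "emissions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- genomic layout ----
  layouts <- lapply(stats::setNames(cfg$se_tracks, cfg$se_tracks),
                    function(tr) se_layout(cfg, tr))

  # standalone segmentation runs on chr1, slots of (run + gap)
  slot <- function(i) as.integer(1000000 + (i - 1) * (run_len + 2000))
  si <- 0L
  pure_runs <- list(); mixed_runs <- list(); shared_runs <- list()
  for (s in cfg$epi_subtypes)
    for (j in seq_len(cfg$n_exclusive_runs)) {
      si <- si + 1L
      pure_runs[[length(pure_runs) + 1]] <-
        data.frame(subtype = s, chrom = "chr1", start = slot(si),
                   end = slot(si) + run_len)
    }
  for (s in cfg$epi_subtypes)
    for (j in seq_len(cfg$n_mixed_runs)) {
      si <- si + 1L
      mixed_runs[[length(mixed_runs) + 1]] <-
        data.frame(subtype = s, chrom = "chr1", start = slot(si),
                   end = slot(si) + run_len)
    }
  for (j in seq_len(cfg$n_shared_runs)) {
    si <- si + 1L
    shared_runs[[length(shared_runs) + 1]] <-
      data.frame(chrom = "chr1", start = slot(si), end = slot(si) + run_len)
  }
  pure_runs <- do.call(rbind, pure_runs)
  mixed_runs <- do.call(rbind, mixed_runs)
  shared_runs <- do.call(rbind, shared_runs)
  n_excl_bins <- 6L  # exclusive bins in a mixed run (6/10 > 1/2)

  ## ---- segmentation BEDs ----
  seg_paths <- character(0)
  for (s in cfg$epi_subtypes) {
    rows <- list()
    add <- function(chrom, start, end, state)
      rows[[length(rows) + 1]] <<- data.frame(chrom,
        start = as.integer(start), end = as.integer(end), state)
    # SE-internal exclusive runs (track subtypes only)
    for (tr in cfg$se_tracks) if (s == tr) {
      L <- layouts[[tr]]
      for (k in seq_along(L$start))
        add(L$chrom, L$arr_start[k], L$arr_end[k], "13_EnhA1")
    }
    pr <- pure_runs[pure_runs$subtype == s, ]
    for (k in seq_len(nrow(pr)))
      add(pr$chrom[k], pr$start[k], pr$end[k], "13_EnhA1")
    # mixed runs: exclusive head for the owner, shared tail for everyone
    for (k in seq_len(nrow(mixed_runs))) {
      mr <- mixed_runs[k, ]
      if (mr$subtype == s)
        add(mr$chrom, mr$start, mr$start + n_excl_bins * bs, "13_EnhA1")
      add(mr$chrom, mr$start + n_excl_bins * bs, mr$end, "14_EnhA2")
    }
    for (k in seq_len(nrow(shared_runs)))
      add(shared_runs$chrom[k], shared_runs$start[k], shared_runs$end[k],
          "14_EnhA2")
    act <- do.call(rbind, rows)
    # fill the rest of the genome with the quiescent state
    full <- list()
    for (ch in names(sizes)) {
      a <- act[act$chrom == ch, , drop = FALSE]
      a <- a[order(a$start), , drop = FALSE]
      pos <- 0
      for (k in seq_len(nrow(a))) {
        if (a$start[k] > pos)
          full[[length(full) + 1]] <-
            data.frame(chrom = ch, start = as.integer(pos),
                       end = as.integer(a$start[k]), state = "1_Quies")
        full[[length(full) + 1]] <- a[k, ]
        pos <- a$end[k]
      }
      if (pos < unclass(sizes)[[ch]])
        full[[length(full) + 1]] <-
          data.frame(chrom = ch, start = as.integer(pos),
                     end = as.integer(unclass(sizes)[[ch]]),
                     state = "1_Quies")
    }
    full <- do.call(rbind, full)
    p <- file.path(out_dir, sprintf("seg_%s.bed", s))
    utils::write.table(full, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    seg_paths <- c(seg_paths, p)
  }

  ## ---- peaks + coverage tracks per lineage ----
  for (tr in cfg$se_tracks) {
    L <- layouts[[tr]]
    peaks <- list(); chip <- list(); inp <- list()
    addp <- function(chrom, start, width, chip_val) {
      start <- as.integer(start); end <- as.integer(start + width)
      peaks[[length(peaks) + 1]] <<- data.frame(chrom, start, end)
      chip[[length(chip) + 1]] <<- data.frame(chrom, start, end,
                                              value = chip_val)
      inp[[length(inp) + 1]] <<- data.frame(chrom, start, end, value = 1)
    }
    for (k in seq_along(L$start)) {
      val <- if (cfg$se_fold > 1)
        1 + 2 * cfg$se_fold + 0.05 * k else 3
      for (ps in L$peak_starts[[k]]) addp(L$chrom, ps, 1200, val)
    }
    for (j in seq_len(cfg$n_background_loci)) {
      s0 <- L$bg_start + (j - 1) * 20200
      for (ps in s0 + c(0, 3200, 6400)) addp(L$chrom, ps, 1200, 3)
    }
    pk <- do.call(rbind, peaks)
    utils::write.table(pk, file.path(out_dir, sprintf("peaks_%s.bed", tr)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(do.call(rbind, chip),
                       file.path(out_dir, sprintf("chip_%s.bedgraph", tr)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(do.call(rbind, inp),
                       file.path(out_dir, sprintf("input_%s.bedgraph", tr)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }

  ## ---- gene models, TF list ----
  genes <- list()
  addg <- function(gene, chrom, tss, length, is_tf)
    genes[[length(genes) + 1]] <<- data.frame(gene, chrom,
      tss = as.integer(tss), length = as.integer(length), is_tf,
      stringsAsFactors = FALSE)
  gene_len <- function(i) 1000 + (i %% 5) * 400
  gi <- 0L
  for (tr in cfg$se_tracks) {
    L <- layouts[[tr]]; pre <- toupper(tr)
    m <- cfg$n_csr_tfs[[tr]]
    for (k in seq_len(m)) {
      gi <- gi + 1L
      addg(sprintf("%s_TF%d", pre, k), L$chrom, L$center[k] + 5000,
           gene_len(gi), TRUE)
    }
    gi <- gi + 1L
    addg(sprintf("%s_XTF", pre), L$chrom, L$center[m + 1] + 5000,
         gene_len(gi), TRUE)
    gi <- gi + 1L
    addg(sprintf("%s_SIL", pre), L$chrom, L$center[1] + 8000,
         gene_len(gi), FALSE)
  }
  bg_chrom <- rep(c("chr1", "chr2"),
                  c(ceiling((cfg$n_bg_genes + cfg$n_bg_tfs + 1) / 2),
                    floor((cfg$n_bg_genes + cfg$n_bg_tfs + 1) / 2)))
  bg_names <- c(sprintf("BG%02d", seq_len(cfg$n_bg_genes)),
                sprintf("BG_TF%d", seq_len(cfg$n_bg_tfs)), cfg$ere_name)
  pos1 <- 0L; pos2 <- 0L
  for (k in seq_along(bg_names)) {
    gi <- gi + 1L
    if (bg_chrom[k] == "chr1") {
      pos1 <- pos1 + 1L; tss <- 1850000 + (pos1 - 1) * 500
    } else {
      pos2 <- pos2 + 1L; tss <- 1455000 + (pos2 - 1) * 500
    }
    addg(bg_names[k], bg_chrom[k], tss, gene_len(gi),
         grepl("TF|ESR1", bg_names[k]))
  }
  genes <- do.call(rbind, genes)
  utils::write.table(genes[, c("gene", "chrom", "tss", "length")],
                     file.path(out_dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c("gene", genes$gene[genes$is_tf]),
             file.path(out_dir, "tf_list.tsv"))

  ## ---- expression: mean model + negative-binomial counts ----
  subt <- rep(cfg$expr_subtypes, each = cfg$n_reps)
  samples <- sprintf("%s_r%d", subt, rep(seq_len(cfg$n_reps),
                                         length(cfg$expr_subtypes)))
  base <- stats::setNames(
    exp(stats::rnorm(nrow(genes), cfg$bg_meanlog, cfg$bg_sdlog)),
    genes$gene)
  mu <- matrix(0, nrow(genes), length(samples),
               dimnames = list(genes$gene, samples))
  up_tfs <- character(0); down_tfs <- character(0)
  for (g in genes$gene) {
    if (grepl("^(TH17|TREG)_TF[0-9]+$", g)) {
      pre <- sub("_TF.*", "", g)
      tr <- cfg$se_tracks[toupper(cfg$se_tracks) == pre]
      m <- cfg$n_csr_tfs[[tr]]
      k <- as.integer(sub(".*_TF", "", g))
      focal <- subt == tr
      if (k > m - cfg$n_down_tfs[[tr]]) {        # down-regulated master TF
        mu[g, ] <- ifelse(focal, cfg$down_mu_focal, cfg$down_mu_other)
        down_tfs <- c(down_tfs, g)
      } else {                                    # up-regulated master TF
        mu[g, ] <- ifelse(focal, cfg$up_mu, cfg$low_mu)
        up_tfs <- c(up_tfs, g)
      }
    } else if (grepl("_XTF$", g)) mu[g, ] <- cfg$flat_mu
    else if (grepl("_SIL$", g))  mu[g, ] <- 0
    else if (g == cfg$ere_name)  mu[g, ] <- cfg$esr1_mu
    else mu[g, ] <- base[g]
  }
  disp <- ifelse(grepl("^(TH17|TREG)_TF[0-9]+$", rownames(mu)),
                 cfg$master_dispersion, cfg$dispersion)
  counts <- matrix(0L, nrow(mu), ncol(mu), dimnames = dimnames(mu))
  for (j in seq_len(ncol(mu)))
    counts[, j] <- stats::rnbinom(nrow(mu), mu = mu[, j], size = 1 / disp)
  utils::write.table(data.frame(gene = rownames(counts), counts,
                                check.names = FALSE),
                     file.path(out_dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = samples, subtype = subt),
                     file.path(out_dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## ---- PWM library (with redundant records) + metadata ----
  cons <- scenario_consensi()
  canonical <- c(cons$Th17, cons$Treg, cons$ERE)
  pwms <- list(); meta <- list()
  for (tf in names(canonical)) {
    id <- sprintf("%s_HOCOMOCO", tf)
    pwms[[id]] <- consensus_pwm(canonical[[tf]], cfg$motif_prob)
    meta[[id]] <- data.frame(motif_id = id, tf_name = tf,
                             species = "human", evidence = "experimental",
                             source_db = "HOCOMOCO")
  }
  # redundant lower-priority duplicates for two TFs
  for (tf in c("TH17_TF1", "TREG_TF1")) {
    id <- sprintf("%s_JASPAR_MOUSE", tf)
    pwms[[id]] <- consensus_pwm(canonical[[tf]], cfg$motif_prob)
    meta[[id]] <- data.frame(motif_id = id, tf_name = tf,
                             species = "mouse", evidence = "experimental",
                             source_db = "JASPAR")
  }
  write_meme(pwms, file.path(out_dir, "pwms.meme"))
  utils::write.table(do.call(rbind, meta),
                     file.path(out_dir, "pwm_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pwm_lib <- build_nonredundant_library(
    pwm_records(pwms, do.call(rbind, meta)))

  ## ---- SE-ARR sequences with planted motifs ----
  truth_edges <- list(); truth_ere <- list()
  seq_paths <- character(0)
  planted_hits_all <- list()
  for (tr in cfg$se_tracks) {
    L <- layouts[[tr]]; pre <- toupper(tr)
    m <- cfg$n_csr_tfs[[tr]]
    targets <- c(sprintf("%s_TF%d", pre, seq_len(m)), sprintf("%s_XTF", pre))
    rid <- sprintf("%s:%d-%d", L$chrom, L$arr_start, L$arr_end)
    names(rid) <- targets
    seqs <- stats::setNames(
      vapply(rid, function(x) rand_dna(run_len), character(1)), rid)
    plan <- edge_plan(cfg, tr)
    eplan <- ere_plan(cfg, tr)
    planted <- list()
    for (target in names(plan)) {
      joff <- 0L
      for (rr in seq_len(nrow(plan[[target]]))) {
        tf <- plan[[target]]$tf[rr]; w <- plan[[target]]$weight[rr]
        for (q in seq_len(w)) {
          off <- 120 + joff * 220; joff <- joff + 1L
          strand <- if (joff %% 2 == 0) "+" else "-"
          word <- if (strand == "+") canonical[[tf]]
                  else rc_string(canonical[[tf]])
          substr(seqs[[rid[target]]], off + 1,
                 off + nchar(word)) <- word
          planted[[length(planted) + 1]] <- data.frame(
            region = rid[target], tf = tf, start = off,
            stop = off + nchar(canonical[[tf]]), strand = strand,
            stringsAsFactors = FALSE)
        }
      }
      if (target %in% names(eplan)) for (q in seq_len(eplan[[target]])) {
        off <- 120 + joff * 220; joff <- joff + 1L
        substr(seqs[[rid[target]]], off + 1,
               off + nchar(canonical[[cfg$ere_name]])) <-
          canonical[[cfg$ere_name]]
        planted[[length(planted) + 1]] <- data.frame(
          region = rid[target], tf = cfg$ere_name, start = off,
          stop = off + nchar(canonical[[cfg$ere_name]]), strand = "+",
          stringsAsFactors = FALSE)
      }
    }
    planted <- do.call(rbind, planted)
    seqs <- scrub_to_planted(seqs, pwm_lib, planted)
    ss <- Biostrings::DNAStringSet(seqs)
    p <- file.path(out_dir, sprintf("searr_%s.fasta", tr))
    Biostrings::writeXStringSet(ss, p)
    seq_paths <- c(seq_paths, p)
    planted_hits_all[[tr]] <- planted
    # ground-truth edges: regulator motif hits at target regions
    ed <- list()
    for (target in names(plan)) {
      pp <- plan[[target]]
      dir_t <- if (target %in% down_tfs) -1 else 1
      for (rr in seq_len(nrow(pp)))
        ed[[length(ed) + 1]] <- data.frame(
          regulator = pp$tf[rr], target = target, weight = pp$weight[rr],
          sign = if (dir_t < 0) "inhibitory" else "activatory",
          stringsAsFactors = FALSE)
    }
    truth_edges[[tr]] <- do.call(rbind, ed)
    truth_ere[[tr]] <- data.frame(
      gene = names(eplan), count = as.integer(eplan),
      de_flag = !grepl("_XTF$", names(eplan)), stringsAsFactors = FALSE)
  }

  ## ---- SNP tables ----
  se_spans <- do.call(c, lapply(cfg$se_tracks, function(tr) {
    L <- layouts[[tr]]
    granges0(rep(L$chrom, length(L$start)), L$start, L$end, sizes = sizes)
  }))
  th17_spans <- layouts[["Th17"]]
  snp_rows <- list()
  ridx <- 0L
  for (trait in names(cfg$snp_traits)) {
    tt <- cfg$snp_traits[[trait]]
    n_in <- round(tt$n * tt$in_fraction)
    for (k in seq_len(tt$n)) {
      ridx <- ridx + 1L
      if (k <= n_in) {
        se_k <- 1 + (k - 1) %% length(th17_spans$start)
        pos <- th17_spans$start[se_k] +
          150 + (((k - 1) %/% length(th17_spans$start)) * 757) %% 7300
        ch <- th17_spans$chrom
      } else {
        repeat {  # uniform placement outside every SE span
          ch <- sample(names(sizes), 1)
          pos <- sample.int(unclass(sizes)[[ch]], 1) - 1L
          pt <- GRanges(ch, IRanges(pos + 1, width = 1))
          if (!any(overlapsAny(pt, se_spans))) break
        }
      }
      snp_rows[[ridx]] <- data.frame(trait = trait,
                                     rsid = sprintf("rs%06d", ridx),
                                     chrom = ch, pos = as.integer(pos) + 1L)
    }
  }
  utils::write.table(do.call(rbind, snp_rows),
                     file.path(out_dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## ---- ground truth ----
  truth <- list(
    planted_se = lapply(layouts, function(L)
      data.frame(chrom = L$chrom, start = L$start, end = L$end)),
    planted_arrs = rbind(
      do.call(rbind, lapply(cfg$se_tracks, function(tr) {
        L <- layouts[[tr]]
        data.frame(subtype = tr, chrom = L$chrom, start = L$arr_start,
                   end = L$arr_end, exclusive_fraction = 1)
      })),
      data.frame(subtype = pure_runs$subtype, chrom = pure_runs$chrom,
                 start = pure_runs$start, end = pure_runs$end,
                 exclusive_fraction = 1),
      data.frame(subtype = mixed_runs$subtype, chrom = mixed_runs$chrom,
                 start = mixed_runs$start, end = mixed_runs$end,
                 exclusive_fraction = n_excl_bins / cfg$run_len_bins)),
    csr_tfs = lapply(stats::setNames(cfg$se_tracks, cfg$se_tracks),
      function(tr) sprintf("%s_TF%d", toupper(tr),
                           seq_len(cfg$n_csr_tfs[[tr]]))),
    up_tfs = up_tfs, down_tfs = down_tfs,
    edges = truth_edges,
    ere_targets = truth_ere,
    planted_hits = planted_hits_all,
    snp_in_fraction = lapply(cfg$snp_traits, `[[`, "in_fraction"),
    expressed_nowhere = grep("_SIL$", genes$gene, value = TRUE))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(dir = out_dir, truth = truth, config = cfg))
}

# Re-randomize background windows until scanning yields exactly the
# planted hits (region/tf/start/strand); guarantees exact ground truth.
scrub_to_planted <- function(seqs, library, planted, p_threshold = 0.001,
                             max_iter = 40) {
  key <- function(df) paste(df$region, df$tf, df$start, df$strand)
  protected <- lapply(names(seqs), function(r) {
    pp <- planted[planted$region == r, , drop = FALSE]
    if (!nrow(pp)) return(integer(0))
    unlist(lapply(seq_len(nrow(pp)), function(i)
      (pp$start[i] + 1):(pp$stop[i])))
  })
  names(protected) <- names(seqs)
  for (iter in seq_len(max_iter)) {
    hits <- scan_sequences(seqs, library, p_threshold = p_threshold)
    extra <- hits[!key(hits) %in% key(planted), , drop = FALSE]
    missing <- planted[!key(planted) %in% key(hits), , drop = FALSE]
    if (nrow(missing))
      stop("planted motif lost during scrubbing; adjust layout")
    if (nrow(extra) == 0) return(seqs)
    for (i in seq_len(nrow(extra))) {
      r <- extra$region[i]
      span <- (extra$start[i] + 1):(extra$stop[i])
      span <- setdiff(span, protected[[r]])
      if (!length(span)) next
      ch <- strsplit(seqs[[r]], "")[[1]]
      ch[span] <- sample(DNA, length(span), replace = TRUE)
      seqs[[r]] <- paste(ch, collapse = "")
    }
  }
  stop("could not scrub chance motif occurrences within ", max_iter,
       " iterations")
}

#' Write / read a scenario configuration file
#'
#' JSON serialization of a `ScenarioConfig`; reading restores the named
#' vectors so that a config round-trips losslessly.
#'
#' @param config `ScenarioConfig`.
#' @param path JSON file path.
#' @return `write_scenario_config`: the path, invisibly;
#'   `read_scenario_config`: a `ScenarioConfig`.
#' @export
write_scenario_config <- function(config, path) {
  x <- unclass(config)
  # preserve vector names through JSON by writing named vectors as objects
  named <- vapply(x, function(e) is.atomic(e) && !is.null(names(e)),
                  logical(1))
  x[named] <- lapply(x[named], as.list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  vec_fields <- c("genome", "se_chrom", "n_csr_tfs", "n_down_tfs",
                  "n_regulators")
  for (f in intersect(vec_fields, names(raw)))
    raw[[f]] <- unlist(raw[[f]])
  structure(raw, class = "ScenarioConfig")
}
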