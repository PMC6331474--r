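DNA <- c("A", "C", "G", "T")

validate_pwm <- function(m, tf = "?") {
  m <- as.matrix(m)
  if (ncol(m) != 4 || nrow(m) < 1)
    stop("PWM for ", tf, " must be an L x 4 matrix")
  if (any(abs(rowSums(m) - 1) > 1e-6))
    stop("PWM rows for ", tf, " must each sum to 1")
  colnames(m) <- DNA
  m
}

#' A PWM record with provenance metadata
#'
#' @param tf_name Transcription factor name.
#' @param matrix L x 4 position probability matrix (columns A, C, G, T;
#'   each row sums to 1).
#' @param species One of `human`, `mouse`, `other`.
#' @param evidence One of `experimental`, `computational`.
#' @param source_db Source database label (e.g. `HOCOMOCO`, `JASPAR`).
#' @param motif_id Optional motif identifier (defaults to `tf_name`).
#' @return List of class `PwmRecord`.
#' @export
pwm_record <- function(tf_name, matrix, species = "human",
                       evidence = "experimental", source_db = "HOCOMOCO",
                       motif_id = tf_name) {
  species <- match.arg(species, c("human", "mouse", "other"))
  evidence <- match.arg(evidence, c("experimental", "computational"))
  structure(list(tf_name = tf_name, matrix = validate_pwm(matrix, tf_name),
                 species = species, evidence = evidence,
                 source_db = source_db, motif_id = motif_id),
            class = "PwmRecord")
}

#' Read motifs from a MEME minimal-format file
#'
#' @param path MEME minimal text file.
#' @return Named list of L x 4 probability matrices, plus attribute
#'   `background` when the file declares letter frequencies.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- NULL
  bgl <- which(grepl("^Background letter frequencies", lines))
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    bg <- stats::setNames(as.numeric(toks[c(2, 4, 6, 8)]), toks[c(1, 3, 5, 7)])
    bg <- bg[DNA]
  }
  starts <- which(grepl("^MOTIF\\s", lines))
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- s + which(grepl("^letter-probability matrix", lines[(s + 1):length(lines)]))[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])))
    out[[name]] <- validate_pwm(m, name)
  }
  if (!is.null(bg)) attr(out, "background") <- bg
  out
}

#' Write motifs as MEME minimal format
#' @param pwms Named list of L x 4 probability matrices.
#' @param path Output file.
#' @param background Length-4 base frequencies (A, C, G, T).
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               paste(DNA, formatC(background, format = "f", digits = 4),
                     collapse = " "), ""), con)
  for (nm in names(pwms)) {
    m <- pwms[[nm]]
    writeLines(c(paste("MOTIF", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                         nrow(m))), con)
    writeLines(apply(m, 1, function(r)
      paste(formatC(r, format = "f", digits = 6), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from JASPAR PFM text format
#'
#' Count matrices (`>ID NAME` header then four `A [ ... ]` rows) are
#' converted to probabilities by column.
#'
#' @param path JASPAR .pfm/.jaspar text file.
#' @return Named list of L x 4 probability matrices (named by TF name).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  heads <- which(grepl("^>", lines))
  out <- list()
  for (h in heads) {
    toks <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]]
    name <- if (length(toks) >= 2) toks[2] else toks[1]
    rows <- lapply(lines[(h + 1):(h + 4)], function(r) {
      as.numeric(strsplit(trimws(gsub("[][]", " ", sub("^\\s*[ACGT]", "", r))),
                          "\\s+")[[1]])
    })
    counts <- t(do.call(rbind, rows))
    out[[name]] <- validate_pwm(counts / rowSums(counts), name)
  }
  out
}

#' Read the PWM metadata sidecar table
#' @param path TSV with header `motif_id`, `tf_name`, `species`,
#'   `evidence`, `source_db`.
#' @return `data.frame`.
#' @export
read_pwm_metadata <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("motif_id", "tf_name", "species", "evidence", "source_db")
  if (!all(need %in% names(tab)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Assemble PwmRecords from matrices plus metadata
#' @param pwms Named list of matrices (names = motif ids).
#' @param metadata `data.frame` from [read_pwm_metadata()].
#' @return List of `PwmRecord`.
#' @export
pwm_records <- function(pwms, metadata) {
  lapply(names(pwms), function(id) {
    row <- metadata[metadata$motif_id == id, , drop = FALSE]
    if (nrow(row) != 1) stop("metadata missing or duplicated for ", id)
    pwm_record(row$tf_name, pwms[[id]], species = row$species,
               evidence = row$evidence, source_db = row$source_db,
               motif_id = id)
  })
}

#' Build a non-redundant PWM library
#'
#' Keeps exactly one PWM per TF by lexicographic priority: species first
#' (human over mouse; `other` is dropped outright), then evidence
#' (experimental over computational), then source-database priority, then
#' motif id for determinism.  TFs left with no human/mouse record are
#' dropped with a warning.
#'
#' @param records List of `PwmRecord`.
#' @param db_priority Source databases in decreasing priority.
#' @param background Length-4 background base frequencies.
#' @return List of class `PwmLibrary`: `records` (named by TF) and
#'   `background`.
#' @export
build_nonredundant_library <- function(records,
    db_priority = c("HOCOMOCO", "JASPAR", "Jolma2013", "CISBP"),
    background = rep(0.25, 4)) {
  if (length(records) == 0) stop("no PWM records supplied")
  keep <- vapply(records, function(r) r$species != "other", logical(1))
  dropped_tfs <- setdiff(vapply(records, `[[`, "", "tf_name"),
                         vapply(records[keep], `[[`, "", "tf_name"))
  if (length(dropped_tfs))
    warning("TF(s) with only non-human/mouse PWMs dropped: ",
            paste(unique(dropped_tfs), collapse = ", "))
  records <- records[keep]
  by_tf <- split(records, vapply(records, `[[`, "", "tf_name"))
  chosen <- lapply(by_tf, function(rs) {
    key <- vapply(rs, function(r) {
      db <- match(r$source_db, db_priority)
      if (is.na(db)) db <- length(db_priority) + 1
      sprintf("%d%d%02d%s", match(r$species, c("human", "mouse")),
              match(r$evidence, c("experimental", "computational")),
              db, r$motif_id)
    }, character(1))
    rs[[order(key)[1]]]
  })
  structure(list(records = chosen,
                 background = stats::setNames(background, DNA)),
            class = "PwmLibrary")
}

#' Log-odds scoring matrix from a probability PWM
#'
#' score(i, b) = log2(((p_ib + pc * bg_b) / (1 + pc)) / bg_b).
#'
#' @param pwm L x 4 probability matrix.
#' @param background Strictly positive length-4 base frequencies.
#' @param pseudocount Non-negative pseudocount weight (default 0.1).
#' @return L x 4 numeric matrix of log2 odds.
#' @export
log_odds_matrix <- function(pwm, background = rep(0.25, 4),
                            pseudocount = 0.1) {
  if (any(background <= 0)) stop("background frequencies must be > 0")
  background <- background / sum(background)
  adj <- sweep(pwm, 2, pseudocount * background, "+") / (1 + pseudocount)
  log2(sweep(adj, 2, background, "/"))
}

#' Exact p-value table for a log-odds matrix
#'
#' Position scores are discretized onto a shared integer grid (`n_bins`
#' bins over the achievable score range) and the distribution of the
#' total score of a random background k-mer is computed by dynamic
#' programming, position by position.  p(s) = Pr[score >= s].
#'
#' @param lom L x 4 log-odds matrix.
#' @param background Length-4 base frequencies.
#' @param n_bins Number of discretization bins; the default (`NULL`)
#'   uses 100 bins per score unit of the achievable range, with a floor
#'   of 1000 bins.
#' @return List of class `PwmPvalueTable` with the integer score matrix
#'   (`qmat`), bin width (`delta`), score offset (`offset`) and the tail
#'   distribution (`tail`, where `tail[k + 1] = Pr[Q >= k]`).
#' @export
exact_pvalue_table <- function(lom, background = rep(0.25, 4),
                               n_bins = NULL) {
  background <- background / sum(background)
  if (any(!is.finite(lom))) {
    # impossible letters (probability 0, no pseudocount): clamp far below
    # the finite range so they can never reach a significant score
    fin <- lom[is.finite(lom)]
    lom[!is.finite(lom)] <- min(fin) - (max(fin) - min(fin)) - 1
  }
  lo <- sum(apply(lom, 1, min)); hi <- sum(apply(lom, 1, max))
  if (is.null(n_bins)) n_bins <- max(1000, ceiling(100 * (hi - lo)))
  delta <- if (hi > lo) (hi - lo) / n_bins else 1
  shifted <- sweep(lom, 1, apply(lom, 1, min))
  qmat <- round(shifted / delta)
  storage.mode(qmat) <- "integer"
  qmax <- sum(apply(qmat, 1, max))
  dp <- numeric(qmax + 1); dp[1] <- 1
  cur_max <- 0L
  for (i in seq_len(nrow(qmat))) {
    new <- numeric(qmax + 1)
    for (b in 1:4) {
      q <- qmat[i, b]
      new[(q + 1):(q + cur_max + 1)] <-
        new[(q + 1):(q + cur_max + 1)] + background[b] * dp[1:(cur_max + 1)]
    }
    dp <- new
    cur_max <- cur_max + max(qmat[i, ])
  }
  tail <- rev(cumsum(rev(dp)))
  tail <- pmin(tail, 1)
  structure(list(qmat = qmat, delta = delta,
                 offset = sum(apply(lom, 1, min)), tail = tail),
            class = "PwmPvalueTable")
}

#' Look up the exact p-value of a raw log-odds score
#'
#' Per-position rounding can shift a k-mer's discretized total by up to
#' half a bin per position, so the lookup applies a guard band of L/2
#' bins: every k-mer whose true score reaches `score` is counted, and the
#' result can only err by the probability mass lying within L*delta below
#' `score` (zero for well-separated score levels, and bounded by the
#' stated discretization error otherwise).
#'
#' @param table `PwmPvalueTable`.
#' @param score Raw log-odds score(s).
#' @return p = Pr[score of a random background k-mer >= `score`].
#' @export
pwm_pvalue <- function(table, score) {
  guard <- nrow(table$qmat) / 2
  k <- ceiling((score - table$offset) / table$delta - guard - 1e-9)
  k <- pmax(pmin(k, length(table$tail) - 1), 0)
  table$tail[k + 1]
}

# integer codes 1..4 for A,C,G,T; NA otherwise
seq_codes <- function(s) {
  match(strsplit(toupper(as.character(s)), "")[[1]], DNA)
}

# integer window scores of one coded sequence under qmat; NA if window has N
window_qscores <- function(codes, qmat) {
  L <- nrow(qmat); n <- length(codes)
  if (n < L) return(integer(0))
  nw <- n - L + 1
  sc <- integer(nw)
  bad <- logical(nw)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + nw - 1)]
    bad <- bad | is.na(cj)
    sc <- sc + ifelse(is.na(cj), 0L, qmat[cbind(j, cj)])
  }
  sc[bad] <- NA_integer_
  sc
}

#' Estimate a 0-order background from sequences
#'
#' Base frequencies over A/C/G/T, strand-symmetrized so that forward and
#' reverse-complement scans share one background.
#'
#' @param seqs `DNAStringSet` or named character vector.
#' @return Length-4 frequency vector (A, C, G, T).
#' @export
estimate_background <- function(seqs) {
  seqs <- Biostrings::DNAStringSet(seqs)
  f <- colSums(Biostrings::letterFrequency(seqs, DNA))
  if (sum(f) == 0) return(stats::setNames(rep(0.25, 4), DNA))
  f <- f / sum(f)
  stats::setNames(c((f["A"] + f["T"]) / 2, (f["C"] + f["G"]) / 2,
                    (f["C"] + f["G"]) / 2, (f["A"] + f["T"]) / 2), DNA)
}

#' Scan sequences for significant motif occurrences
#'
#' Both strands are scanned with each library PWM; windows containing N
#' are skipped and hits with exact p-value strictly below the threshold
#' are emitted.  The reported offset is always on the forward strand of
#' the scanned sequence (0-based).
#'
#' @param seqs Named `DNAStringSet` or named character vector of region
#'   sequences.
#' @param library `PwmLibrary` from [build_nonredundant_library()].
#' @param p_threshold Emission threshold on the p-value (default 0.001,
#'   strict <).
#' @param background NULL (default: estimated from `seqs`) or a length-4
#'   frequency vector.
#' @param pseudocount Pseudocount for log-odds scoring (default 0.1).
#' @param n_bins Score discretization bins (default: adaptive, see
#'   [exact_pvalue_table()]).
#' @return `data.frame` of hits: `region`, `tf`, `start` (0-based),
#'   `stop` (exclusive), `strand`, `score`, `pvalue`.
#' @export
scan_sequences <- function(seqs, library, p_threshold = 0.001,
                           background = NULL, pseudocount = 0.1,
                           n_bins = NULL) {
  seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named")
  if (length(seqs) == 0)
    return(data.frame(region = character(0), tf = character(0),
                      start = integer(0), stop = integer(0),
                      strand = character(0), score = numeric(0),
                      pvalue = numeric(0)))
  if (is.null(background)) background <- estimate_background(seqs)
  fwd <- lapply(as.character(seqs), seq_codes)
  rev <- lapply(as.character(Biostrings::reverseComplement(seqs)), seq_codes)
  hits <- list()
  for (tf in names(library$records)) {
    rec <- library$records[[tf]]
    lom <- log_odds_matrix(rec$matrix, background, pseudocount)
    tab <- exact_pvalue_table(lom, background, n_bins)
    L <- nrow(lom)
    for (i in seq_along(seqs)) {
      n <- length(fwd[[i]])
      for (str in c("+", "-")) {
        codes <- if (str == "+") fwd[[i]] else rev[[i]]
        q <- window_qscores(codes, tab$qmat)
        if (!length(q)) next
        sraw <- q * tab$delta + tab$offset
        # exact lookup in the shared integer score space
        kk <- pmax(pmin(q, length(tab$tail) - 1L), 0L)
        p <- tab$tail[kk + 1L]
        ok <- which(!is.na(q) & p < p_threshold)
        if (!length(ok)) next
        start0 <- if (str == "+") ok - 1L else n - L - (ok - 1L)
        hits[[length(hits) + 1]] <- data.frame(
          region = names(seqs)[i], tf = tf,
          start = start0, stop = start0 + L,
          strand = str, score = sraw[ok], pvalue = p[ok],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(region = character(0), tf = character(0),
                      start = integer(0), stop = integer(0),
                      strand = character(0), score = numeric(0),
                      pvalue = numeric(0)))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$region, out$tf, out$start, out$strand), , drop = FALSE]
}

#' Count estrogen response element hits per target gene
#'
#' Tallies significant ERE (estrogen receptor alpha motif) occurrences
#' across each gene's associated regulatory regions.
#'
#' @param hits Hit table from [scan_sequences()].
#' @param gene_map `data.frame` with columns `gene`, `region`.
#' @param ere_tf Name of the ER-alpha PWM in the hit table
#'   (default `"ESR1"`).
#' @param library Optional `PwmLibrary`; when given, the ER-alpha PWM
#'   must be present in it (error otherwise).
#' @return Named integer vector: ERE hit count per gene (genes with
#'   mapped regions only; zero counts included).
#' @export
ere_hits <- function(hits, gene_map, ere_tf = "ESR1", library = NULL) {
  if (!is.null(library) && !ere_tf %in% names(library$records))
    stop("ER-alpha PWM '", ere_tf, "' missing from the library")
  eh <- hits[hits$tf == ere_tf, , drop = FALSE]
  genes <- unique(gene_map$gene)
  counts <- stats::setNames(integer(length(genes)), genes)
  if (nrow(eh)) {
    m <- merge(eh, gene_map, by = "region")
    tab <- table(m$gene)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}
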