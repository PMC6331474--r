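# Independent oracles used across tests: boolean base-mask arithmetic,
# linear scans and brute-force classifiers, kept deliberately naive.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# boolean coverage mask of a GRanges over a toy genome (list of vectors)
mask_of <- function(gr, sizes) {
  m <- lapply(sizes, function(L) logical(L))
  for (i in seq_along(gr)) {
    ch <- as.character(seqnames(gr))[i]
    m[[ch]][start(gr)[i]:end(gr)[i]] <- TRUE
  }
  m
}

# merge a mask back into 0-based intervals (per chrom)
mask_intervals <- function(mask) {
  out <- list()
  for (ch in names(mask)) {
    r <- rle(mask[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep])
  }
  if (!length(out)) return(data.frame(chrom = character(0),
                                      start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

gr_to_df0 <- function(gr) {
  d <- data.frame(chrom = as.character(seqnames(gr)),
                  start = start(gr) - 1L, end = end(gr))
  d <- d[order(d$chrom, d$start), ]
  rownames(d) <- NULL
  d
}

random_intervals <- function(n, sizes, max_w = 500) {
  ch <- sample(names(sizes), n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  st <- vapply(seq_len(n), function(i)
    sample.int(sizes[[ch[i]]] - w[i], 1) - 1L, integer(1))
  granges0(ch, st, st + w)
}

# brute-force tangent scan: for each candidate point count ranked points
# below the unit-slope line through it; cutoff = the point with fewest,
# ties to the higher-signal side
oracle_tangent_cutoff <- function(sig) {
  s <- sort(sig)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  below <- vapply(seq_len(n), function(i)
    sum(y <= y[i] + (x - x[i]) + 1e-12), numeric(1))
  i <- max(which(below == min(below)))
  s[i]
}

# brute-force ARR classifier on a per-bin matrix (bins x subtypes of
# active flags): returns, per subtype, 0-based bin intervals of regions
# that satisfy the strict-majority exclusivity rule
oracle_classify <- function(active_mat, bin = 200) {
  subtypes <- colnames(active_mat)
  res <- list()
  for (s in subtypes) {
    r <- rle(active_mat[, s])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    rows <- list()
    for (k in which(r$values)) {
      bins <- (starts[k] + 1):ends[k]
      excl <- vapply(bins, function(b)
        active_mat[b, s] && !any(active_mat[b, setdiff(subtypes, s)]),
        logical(1))
      if (mean(excl) > 0.5)
        rows[[length(rows) + 1]] <-
          data.frame(subtype = s, start = starts[k] * bin,
                     end = ends[k] * bin)
    }
    if (length(rows)) res[[s]] <- do.call(rbind, rows)
  }
  if (!length(res)) return(data.frame(subtype = character(0),
                                      start = integer(0), end = integer(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# segmentation GRanges for one subtype from a per-bin active matrix
seg_from_mat <- function(active_mat, s, bin = 200) {
  states <- ifelse(active_mat[, s], "13_EnhA1", "1_Quies")
  n <- length(states)
  granges0(rep("chrT", n), (seq_len(n) - 1) * bin, seq_len(n) * bin,
           state = states)
}

# exhaustive PWM p-values: enumerate all 4^L words
oracle_exhaustive_pvalues <- function(lom, background) {
  background <- background / sum(background)
  L <- nrow(lom)
  codes <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- numeric(nrow(codes))
  logp <- numeric(nrow(codes))
  for (j in seq_len(L)) {
    scores <- scores + lom[j, codes[, j]]
    logp <- logp + log(background[codes[, j]])
  }
  list(scores = scores, probs = exp(logp))
}

hand_bh <- function(p) {
  n <- length(p); o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# shared default scenario + pipeline results, built once per test run
scenario_env <- new.env(parent = emptyenv())
get_shared_scenario <- function() {
  if (is.null(scenario_env$res)) {
    dir <- file.path(tempdir(), "csrnet-shared-bundle")
    scenario_env$gen <- generate_scenario(default_scenario_config(1), dir)
    scenario_env$res <- suppressWarnings(
      run_pipeline(dir, out_dir = file.path(tempdir(), "csrnet-shared-out"),
                   seed = 1))
  }
  list(gen = scenario_env$gen, res = scenario_env$res)
}
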