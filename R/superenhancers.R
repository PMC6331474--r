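#' Read a bedGraph coverage track
#'
#' Piecewise-constant per-bp coverage; bases not covered by any record are
#' treated as 0 by all consumers.
#'
#' @param path bedGraph file.
#' @return `GRanges` with a numeric `score` column (values must be >= 0).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) stop("negative coverage values in ", path)
  gr
}

#' @export
write_bedgraph <- function(x, path) {
  rtracklayer::export(x, path, format = "bedGraph")
  invisible(path)
}

#' Stitch enhancer peaks into candidate regions
#'
#' Peaks whose boundary gap is at most `stitch_distance` bp are unioned
#' into a single stitched region (the rank-ordering algorithm's default
#' distance is 12.5 kb).  Optionally, peaks fully contained in TSS
#' exclusion windows are removed before stitching.
#'
#' @param peaks `GRanges` of significant H3K27ac peaks.
#' @param stitch_distance Maximum bridged gap in bp (default 12500).
#' @param tss Optional `data.frame` with `chrom`, `pos` (0-based TSS).
#' @param tss_exclusion Half-width in bp of the exclusion window around
#'   each TSS; 0 (default) disables exclusion.
#' @return `GRanges` of stitched regions with metadata column
#'   `n_constituents`, the number of input peaks per region.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500,
                         tss = NULL, tss_exclusion = 0) {
  if (!is.null(tss) && tss_exclusion > 0 && nrow(tss) > 0) {
    win <- GRanges(tss$chrom,
                   IRanges(pmax(tss$pos - tss_exclusion, 0) + 1L,
                           tss$pos + tss_exclusion))
    drop <- overlapsAny(peaks, win, type = "within")
    peaks <- peaks[!drop]
  }
  stitched <- merge_intervals(peaks, max_gap = stitch_distance)
  stitched$n_constituents <- countOverlaps(stitched, peaks)
  stitched
}

# Sum of track coverage (value * covered width) over each region;
# uncovered bases contribute 0.
region_track_sum <- function(regions, track) {
  out <- numeric(length(regions))
  if (length(track) == 0 || length(regions) == 0) return(out)
  hits <- findOverlaps(regions, track)
  if (length(hits) == 0) return(out)
  frag <- pintersect(regions[queryHits(hits)], track[subjectHits(hits)])
  contrib <- width(frag) * track$score[subjectHits(hits)]
  agg <- rowsum(contrib, queryHits(hits))
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Quantify background-subtracted ChIP signal over stitched regions
#'
#' Signal is the summed per-bp coverage (area) of the ChIP track minus the
#' matched input track over each region, floored at 0.
#'
#' @param regions `GRanges` (e.g. from [stitch_peaks()]).
#' @param chip,input bedGraph-style `GRanges` with `score` >= 0.
#' @return `regions` with metadata columns `chip_signal`, `input_signal`
#'   and `signal` (= max(0, chip - input)).
#' @export
quantify_region_signal <- function(regions, chip, input = NULL) {
  if (any(chip$score < 0) || (!is.null(input) && any(input$score < 0)))
    stop("track values must be >= 0")
  cs <- region_track_sum(regions, chip)
  is <- if (is.null(input)) numeric(length(regions))
        else region_track_sum(regions, input)
  regions$chip_signal <- cs
  regions$input_signal <- is
  regions$signal <- pmax(cs - is, 0)
  regions
}

#' Call super-enhancers by rank-ordered signal (tangent rule)
#'
#' Regions are ranked by ascending background-subtracted signal; ranks and
#' signals are rescaled to [0, 1] and the cutoff is placed at the tangent
#' point of the unit-slope line: the ranked point lying furthest below the
#' diagonal (minimum of scaled_y - scaled_x), which for a hockey-stick
#' curve is exactly where the curve's slope crosses 1.  Every region with
#' signal strictly above the cutoff signal is flagged super.  Ties in the
#' tangent criterion resolve to the higher-signal side; a perfectly linear
#' curve (all points on the diagonal) therefore yields the top region
#' only, and an all-equal curve is degenerate (warning, no calls).
#'
#' @param regions `GRanges` with a `signal` column
#'   (see [quantify_region_signal()]).
#' @return `data.frame` with one row per region: `chrom`, `start`, `end`
#'   (0-based half-open), `rank` (1 = lowest signal), `signal`,
#'   `scaled_x`, `scaled_y`, `cutoff_signal`, `is_super`.
#' @export
call_superenhancers <- function(regions) {
  n <- length(regions)
  if (n < 2) stop("need at least 2 regions to rank")
  sig <- regions$signal
  if (is.null(sig)) stop("regions carry no 'signal' column")
  ord <- order(sig)
  ssig <- sig[ord]
  rng <- ssig[n] - ssig[1]
  if (rng == 0) {
    warning("all signals equal; degenerate curve, no super-enhancers called")
    cutoff <- ssig[n]
  } else {
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (ssig - ssig[1]) / rng
    d <- y - x
    if (max(d) - min(d) < 1e-12) {
      cutoff <- ssig[n - 1]  # linear curve: tangent at the top
    } else {
      i <- max(which(d == min(d)))  # ties to the higher-signal side
      cutoff <- ssig[i]
    }
  }
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  df <- data.frame(
    chrom = as.character(seqnames(regions)),
    start = start(regions) - 1L,
    end = end(regions),
    rank = rank,
    signal = sig,
    scaled_x = (rank - 1) / (n - 1),
    scaled_y = if (rng == 0) rep(0, n) else (sig - ssig[1]) / rng,
    cutoff_signal = cutoff,
    is_super = sig > cutoff,
    stringsAsFactors = FALSE)
  df[order(-df$signal), , drop = FALSE]
}

#' Super-enhancer calls as a GRanges
#'
#' Returned in genomic (sorted) order so that downstream indices (SE-ARR
#' parents, gene associations) are consistent.
#'
#' @param calls `data.frame` from [call_superenhancers()].
#' @param super_only Keep only `is_super` rows (default TRUE).
#' @return Sorted `GRanges` with `rank`, `signal`, `is_super`.
#' @export
se_granges <- function(calls, super_only = TRUE) {
  if (super_only) calls <- calls[calls$is_super, , drop = FALSE]
  if (nrow(calls) == 0) return(GRanges())
  sort(granges0(calls$chrom, calls$start, calls$end,
                rank = calls$rank, signal = calls$signal,
                is_super = calls$is_super), ignore.strand = TRUE)
}
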