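#' @import GenomicRanges IRanges S4Vectors methods
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqnames
#' @importFrom stats setNames
NULL

#' Construct a chromosome-sizes reference frame
#'
#' A minimal genome model: chromosome names mapped to lengths in base pairs.
#' Every interval operation that needs genome bounds (random placement,
#' point containment checks) takes one of these.
#'
#' @param lengths Named numeric vector, `chrom -> length` (bp, > 0).
#' @return A named integer-valued numeric vector of class `ChromSizes`.
#' @examples
#' chrom_sizes(c(chr1 = 2e6, chr2 = 2e6))
#' @export
chrom_sizes <- function(lengths) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)) ||
      any(!nzchar(names(lengths))))
    stop("chromosome names must be unique and non-empty")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(floor(as.numeric(lengths)), names = names(lengths),
            class = "ChromSizes")
}

#' Read a two-column chrom-sizes file
#'
#' @param path Tab-separated file: chromosome name, length in bp.
#' @return A `ChromSizes` object.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  chrom_sizes(setNames(as.numeric(tab[[2]]), tab[[1]]))
}

#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), as.integer(unclass(sizes))),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

as_seqinfo <- function(sizes) {
  Seqinfo(seqnames = names(sizes), seqlengths = as.integer(unclass(sizes)))
}

#' Build a GRanges from 0-based half-open coordinates
#'
#' All on-disk coordinates in this package follow the BED convention
#' (0-based start, exclusive end); in memory everything is a `GRanges`
#' (1-based closed).  This constructor performs the conversion once.
#'
#' @param chrom,start,end Vectors of equal length; `start`/`end` 0-based
#'   half-open.
#' @param sizes Optional `ChromSizes`; when given, bounds are validated.
#' @param ... Further metadata columns (e.g. `name`, `score`).
#' @return `GRanges`
#' @export
granges0 <- function(chrom, start, end, sizes = NULL, ...) {
  if (any(start < 0) || any(end <= start))
    stop("require 0 <= start < end")
  gr <- GRanges(chrom, IRanges(start + 1L, end), ...)
  if (!is.null(sizes)) {
    if (!all(as.character(seqnames(gr)) %in% names(sizes)))
      stop("interval on unknown chromosome")
    if (any(end > unclass(sizes)[as.character(seqnames(gr))]))
      stop("interval exceeds chromosome length")
    GenomeInfoDb::seqlevels(gr) <- names(sizes)
    GenomeInfoDb::seqinfo(gr) <- as_seqinfo(sizes)
  }
  gr
}

#' Merge intervals, bridging gaps up to `max_gap`
#'
#' Two intervals separated by a gap of at most `max_gap` bp are unioned
#' (gap 0 means touching intervals merge).  The result covers exactly the
#' same bases as the input plus the bridged gaps, and any two output
#' intervals on a chromosome are separated by more than `max_gap`.
#'
#' @param x `GRanges`.
#' @param max_gap Non-negative gap in bp that may be bridged.
#' @return Sorted, disjoint `GRanges`.
#' @export
merge_intervals <- function(x, max_gap = 0) {
  if (length(max_gap) != 1 || is.na(max_gap) || max_gap < 0)
    stop("max_gap must be a single non-negative number")
  GenomicRanges::reduce(x, min.gapwidth = max_gap + 1)
}

#' Intersect two interval sets (bedtools `intersect` semantics)
#'
#' Returns each overlapping fragment of `a` with the merged cover of `b`.
#' On base masks this equals the boolean AND of the two covers.
#'
#' @param a,b `GRanges` on a shared coordinate frame.
#' @return `GRanges` of overlap fragments; metadata column `a_idx` gives the
#'   index of the parent interval in `a`, `b_idx` the parent in `reduce(b)`.
#' @export
intersect_intervals <- function(a, b) {
  bm <- GenomicRanges::reduce(b)
  hits <- findOverlaps(a, bm)
  if (length(hits) == 0) {
    out <- GRanges()
    out$a_idx <- integer(0); out$b_idx <- integer(0)
    return(out)
  }
  frag <- pintersect(a[queryHits(hits)], bm[subjectHits(hits)])
  mcols(frag) <- NULL
  frag$a_idx <- queryHits(hits)
  frag$b_idx <- subjectHits(hits)
  frag
}

#' Count points falling inside an interval set
#'
#' Positions are 0-based; a point at an interval's (exclusive) end is
#' outside.  Out-of-bounds points are dropped with a warning.
#'
#' @param points `data.frame` with columns `chrom`, `pos` (0-based bp).
#' @param x `GRanges`.
#' @param sizes Optional `ChromSizes` for bounds checking.
#' @return Integer count of points covered by at least one interval.
#' @export
count_point_overlaps <- function(points, x, sizes = NULL) {
  if (nrow(points) == 0) return(0L)
  keep <- rep(TRUE, nrow(points))
  if (!is.null(sizes)) {
    lim <- unclass(sizes)[as.character(points$chrom)]
    keep <- !is.na(lim) & points$pos >= 0 & points$pos < lim
    if (any(!keep))
      warning(sum(!keep), " point(s) out of chromosome bounds; excluded")
  }
  if (!any(keep)) return(0L)
  pg <- GRanges(points$chrom[keep], IRanges(points$pos[keep] + 1L, width = 1L))
  lv <- union(GenomeInfoDb::seqlevels(pg), GenomeInfoDb::seqlevels(x))
  GenomeInfoDb::seqlevels(pg) <- lv
  GenomeInfoDb::seqlevels(x) <- lv
  sum(countOverlaps(pg, x) > 0)
}

#' Draw a random interval set matching a template's lengths
#'
#' Produces intervals with exactly the template's multiset of lengths,
#' placed uniformly over the genome: for each interval the chromosome is
#' chosen with probability proportional to its placeable length
#' (`chrom_len - width + 1`) and the start uniformly among valid positions,
#' so intervals never cross chromosome ends.
#'
#' @param template `GRanges` whose widths are reproduced.
#' @param sizes `ChromSizes`.
#' @param seed Optional integer seed for reproducible draws.
#' @return `GRanges` with the same widths as `template` (same order).
#' @export
sample_matched_random <- function(template, sizes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- as.numeric(unclass(sizes))
  w <- width(template)
  if (length(w) && max(w) > max(L))
    stop("template interval longer than every chromosome")
  chroms <- names(sizes)
  starts <- integer(length(w))
  chr <- character(length(w))
  for (uw in unique(w)) {
    idx <- which(w == uw)
    placeable <- pmax(L - uw + 1, 0)
    if (sum(placeable) == 0) stop("no chromosome can host width ", uw)
    ci <- sample.int(length(L), length(idx), replace = TRUE,
                     prob = placeable / sum(placeable))
    chr[idx] <- chroms[ci]
    # uniform 0-based start in [0, L - w]
    starts[idx] <- floor(stats::runif(length(idx), 0, placeable[ci]))
  }
  granges0(chr, starts, starts + w, sizes = sizes)
}

#' Read a BED file (BED3/4/6) into a GRanges
#'
#' @param path BED file; column 4 becomes `name`, column 5 `score`.
#' @param sizes Optional `ChromSizes` attached as seqinfo.
#' @return `GRanges`
#' @export
read_bed <- function(path, sizes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(sizes)
    GenomeInfoDb::seqinfo(gr) <- as_seqinfo(sizes)
  }
  gr
}

#' Write a GRanges as BED
#' @param x `GRanges`; `name`/`score` metadata columns are kept.
#' @param path Output file.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}
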