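#' Read a chromatin-state emission matrix
#'
#' Tab-separated table: first column the state name (e.g. `13_EnhA1`),
#' remaining columns one per epigenetic mark, values in [0, 100].
#'
#' @param path TSV file with a header row naming the marks.
#' @return Numeric matrix, rows = states, columns = marks.
#' @export
read_emission_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate state names")
  if (any(m < 0 | m > 100)) stop("emission values must lie in [0, 100]")
  m
}

#' Select active regulatory states from an emission matrix
#'
#' A state is active when the emission of EVERY listed mark is at or above
#' the threshold; with the defaults this is the joint H3K27ac / H3K4me1 >= 75
#' rule that defines active-enhancer-class states in the 25-state model.
#'
#' @param emissions Matrix from [read_emission_matrix()].
#' @param marks Marks that must all pass (default H3K27ac and H3K4me1).
#' @param threshold Emission threshold (default 75).
#' @return Character vector of active state names.
#' @export
select_active_states <- function(emissions,
                                 marks = c("H3K27ac", "H3K4me1"),
                                 threshold = 75) {
  missing <- setdiff(marks, colnames(emissions))
  if (length(missing))
    stop("mark(s) not in emission matrix: ", paste(missing, collapse = ", "))
  pass <- rowSums(emissions[, marks, drop = FALSE] >= threshold) == length(marks)
  rownames(emissions)[pass]
}

#' Read a genome segmentation (BED4, fixed bin grid)
#'
#' Each record is one bin with its predicted chromatin state in the name
#' column.  Consecutive same-state records are allowed (runs); the reader
#' enforces that every record aligns to the `bin_size` grid so that
#' segmentations from different cell types are bin-comparable.
#'
#' @param path BED4 file (chrom, start, end, state).
#' @param bin_size Grid resolution in bp (default 200).
#' @return `GRanges` with metadata column `state`.
#' @export
read_segmentation <- function(path, bin_size = 200) {
  gr <- read_bed(path)
  if (is.null(gr$name)) stop("segmentation BED must carry a state column")
  st0 <- start(gr) - 1L
  if (any(st0 %% bin_size != 0) || any(width(gr) %% bin_size != 0))
    stop("segmentation records not aligned to the ", bin_size, "-bp grid")
  gr$state <- gr$name
  gr$name <- NULL
  gr
}

#' Extract merged regulatory regions from a segmentation
#'
#' Bins whose state is in the active set are selected and maximal runs of
#' consecutive active bins are merged into regulatory regions.
#'
#' @param seg `GRanges` from [read_segmentation()].
#' @param active Character vector of active state names.
#' @return Sorted, disjoint `GRanges` of regulatory regions.
#' @export
extract_regulatory_regions <- function(seg, active) {
  merge_intervals(seg[seg$state %in% active], max_gap = 0)
}

# Merged active cover of one segmentation.
active_cover <- function(seg, active) {
  GenomicRanges::reduce(seg[seg$state %in% active])
}

#' Classify subtype-exclusive active regulatory regions (ARRs)
#'
#' For each merged regulatory region of subtype `s`, every constituent
#' grid fragment is compared across all subtypes: a fragment is exclusive
#' to `s` when its bin is in an active state in `s` and in no other
#' subtype.  The region is an `s`-ARR when strictly more than half of its
#' fragments are exclusive to `s`.
#'
#' @param segmentations Named list of segmentation `GRanges`
#'   (one per cell subtype; shared bin grid).
#' @param active Character vector of active state names.
#' @param bin_size Grid resolution in bp (default 200).
#' @return `GRanges` of all candidate regions across subtypes with
#'   metadata columns `subtype`, `n_fragments`, `n_exclusive`,
#'   `exclusive_fraction` and `is_arr`.
#' @export
classify_specific_arrs <- function(segmentations, active, bin_size = 200) {
  if (is.null(names(segmentations)) || anyDuplicated(names(segmentations)))
    stop("segmentations must be a uniquely named list")
  covers <- lapply(segmentations, active_cover, active = active)
  for (cv in covers)
    if (length(cv) && any((start(cv) - 1L) %% bin_size != 0))
      stop("segmentations are not on a shared bin grid")
  out <- list()
  for (s in names(segmentations)) {
    regions <- extract_regulatory_regions(segmentations[[s]], active)
    if (length(regions) == 0) next
    frags <- unlist(tile(regions, width = bin_size))
    parent <- rep(seq_along(regions), width(regions) %/% bin_size)
    other <- rep(FALSE, length(frags))
    for (t in setdiff(names(segmentations), s))
      other <- other | overlapsAny(frags, covers[[t]], type = "within")
    excl <- !other  # fragments are active in s by construction
    n_frag <- as.integer(table(factor(parent, seq_along(regions))))
    n_excl <- as.integer(rowsum(as.numeric(excl),
                                factor(parent, seq_along(regions))))
    regions$subtype <- s
    regions$n_fragments <- n_frag
    regions$n_exclusive <- n_excl
    regions$exclusive_fraction <- n_excl / n_frag
    regions$is_arr <- regions$exclusive_fraction > 0.5
    out[[s]] <- regions
  }
  if (length(out) == 0) return(GRanges())
  ans <- unlist(GRangesList(out), use.names = FALSE)
  sort(ans, ignore.strand = TRUE)
}

#' ARRs of one subtype from a classification
#' @param classified Output of [classify_specific_arrs()].
#' @param subtype Subtype label.
#' @return `GRanges` of that subtype's ARRs (`is_arr` rows only).
#' @export
arrs_of <- function(classified, subtype) {
  classified[classified$subtype == subtype & classified$is_arr]
}

#' Intersect ARRs with super-enhancers (SE-ARRs)
#'
#' Overlap fragments of ARRs with called super-enhancer regions, each
#' fragment tagged with its parent ARR and parent SE.  Also reports the
#' fraction of ARRs having at least 1 bp of SE overlap.
#'
#' @param arrs `GRanges` of ARRs (one subtype).
#' @param se `GRanges` of super-enhancer regions.
#' @return List with `se_arrs` (`GRanges` with `arr_idx`, `se_idx`) and
#'   `fraction_overlapping` (scalar in [0, 1]).
#' @export
intersect_se_arrs <- function(arrs, se) {
  frag <- intersect_intervals(arrs, se)
  names(mcols(frag)) <- c("arr_idx", "se_idx")
  frac <- if (length(arrs) == 0) NA_real_
          else length(unique(frag$arr_idx)) / length(arrs)
  list(se_arrs = frag, fraction_overlapping = frac)
}
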