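---
title: "Methods: cell-type-specific regulatory regions and signed TF networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-specific regulatory regions and signed TF networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csrnet)
```

# The analysis

`csrnet` implements an integrative epigenomics workflow for CD4+ T-cell
subsets (naive, Th, Th17, Treg). Its goal is to nominate
*cell-type-specific regulatory regions* (CSRs) — the super-enhancer
segments that drive lineage identity genes such as RORC in Th17 and
FOXP3 in Treg cells — and to reconstruct the signed transcription-factor
(TF) network anchored on them, including predicted estrogen receptor
alpha (ERα) targets via estrogen response elements (EREs).

The pipeline composes six analysis layers:

1. **Super-enhancer (SE) calling.** H3K27ac peaks are stitched when
   their boundary gap is at most 12,500 bp (boundary-inclusive, i.e.
   stitching is exactly interval merging with a 12.5 kb bridgeable gap).
   Each stitched region is scored by its summed ChIP coverage minus the
   matched input coverage, floored at zero; signal is an *area*
   (coverage × width), not a density, so absolute cutoffs depend on any
   per-track scaling of the coverage files. Regions are ranked by
   ascending signal, both axes are rescaled to [0, 1], and the cutoff is
   the tangent point of the unit-slope line: the ranked point furthest
   below the diagonal (the minimum of scaled signal minus scaled rank).
   For a hockey-stick curve this is exactly where the curve's slope
   crosses 1. Everything strictly above the cutoff signal is a
   super-enhancer. Two degenerate situations are defined explicitly:
   a perfectly linear curve has all points on the diagonal, the tangent
   is taken at the top and only the maximum is flagged; an all-equal
   curve is degenerate and yields no calls (with a warning).
2. **Active regulatory regions (ARRs).** A 25-state-style genome
   segmentation (200 bp bins) is reduced to the states whose emission of
   *both* H3K27ac and H3K4me1 is at least 75 — the joint signature of
   active enhancers. Runs of consecutive active bins are merged; each
   merged region is then examined fragment by fragment across all four
   subtypes: a 200 bp fragment is *exclusive* to subtype *s* when it is
   active in *s* and inactive in every other subtype at the same bin.
   A region is an *s*-ARR when strictly more than half of its fragments
   are exclusive to *s*. The strict majority makes ARR assignment
   unambiguous: no region can be an ARR of two subtypes. When a region's
   exclusive fragments are split between subtypes, it is classified only
   if a single subtype owns more than half of all fragments, otherwise
   it stays unclassified.
3. **SE-ARRs and CSRs.** SE-ARRs are the base-wise intersection of a
   subtype's ARRs with its called SEs; the per-subtype summary statistic
   is the fraction of ARRs with at least 1 bp of SE overlap (not a
   base-pair fraction). CSRs are the SE-ARRs of TF-coding genes that are
   highly differentially expressed versus naive cells, at an
   FDR-adjusted p strictly below 1e-7.
4. **Expression integration.** Counts are normalized by median-of-ratios
   size factors (reference genes are those with nonzero counts in every
   sample), converted to FPKM using the longest-isoform length and
   per-sample totals of the *normalized* matrix (a documented choice; a
   `totals` argument switches to raw library sizes). A gene is
   *expressed* in a subtype when FPKM exceeds 1 in **all** replicates of
   that subtype. Subtype specificity is summarized as a Z-score of the
   per-subtype means across subtypes (zero across-subtype SD gives
   Z = 0). SEs are annotated to expressed genes whose TSS lies within
   100 kb (inclusive) of the nearest SE center, ties to the leftmost SE;
   one SE per gene, many genes per SE.
5. **Motif scanning.** The PWM library is made non-redundant per TF by a
   lexicographic rule: species first (human over mouse; other species
   dropped), then evidence (experimental over computational), then a
   configurable source-database priority (default HOCOMOCO > JASPAR >
   Jolma2013 > CISBP), then motif id for determinism. Scanning uses
   log2 odds with pseudocount 0.1 against a 0-order background estimated
   from the scanned sequences (strand-symmetrized; a uniform background
   can be supplied instead). P-values are exact: per-position scores are
   discretized onto an integer grid (at least 100 bins per score unit,
   floor 1000 bins) and the full null distribution of a random
   background k-mer is computed by dynamic programming. Both strands are
   scanned, windows containing N are skipped, and hits with p strictly
   below 0.001 are emitted. Log-odds entries that are −∞ (zero
   probability, no pseudocount) are clamped far below the finite score
   range so they can never score significantly.
6. **Network reconstruction.** Nodes are the expressed SE-ARR-associated
   genes; a directed edge TF → target exists when the TF's motif has at
   least one significant hit in any of the target's SE-ARRs, weighted by
   the hit count. Self-edges are allowed. Indegree is reported both as
   distinct regulators and as total incoming hits (both conventions are
   in use; the summed-hits variant matches node-size scaling by
   "number of significant TF binding motifs"). The core subnetwork keeps
   edges whose target is a CSR TF. Edges are signed by Pearson
   correlation over the full 25-sample expression matrix: activatory if
   r > r_crit, inhibitory if r < −r_crit, otherwise retained as
   unsigned; r_crit = t_c / sqrt(t_c² + n − 2) with the two-tailed t
   critical value at α = 0.05 and df = n − 2, which at n = 25 gives
   0.3961 to 4 decimals. ERα target networks are stars from ERα to every
   gene with at least one ERE hit in its SE-ARRs, weighted by the ERE
   count, with flags for targets passing a vs-naive DE filter
   (p < 1e-3) and for membership in the core subnetwork.

SNP enrichment in a region set is a permutation test: the observed count
of trait SNPs inside the regions is compared with counts obtained by
redrawing the *entire* region set as length-matched random regions
(chromosome chosen proportionally to placeable length, start uniform, so
regions never cross chromosome ends), using the +1-corrected p-value
p = (1 + #{N_perm ≥ N_obs}) / (1 + n_permutations). The p-value can
never be smaller than 1/(n_permutations + 1), and N_obs = 0 gives
exactly 1. The desk-scale default is 2,000 permutations; 1,000,000
reproduces the full-scale setting. Random placement is uniform
genome-wide; an exclusion list (e.g. assembly gaps) is not applied by
default because the placement model is deliberately minimal.

# Key parameters

| parameter | default | unit | role |
|---|---|---|---|
| `stitch_distance` | 12,500 | bp | peak stitching gap (boundary-inclusive) |
| `emission_threshold` | 75 | emission (0–100) | joint H3K27ac/H3K4me1 rule |
| `bin_size` | 200 | bp | segmentation grid |
| `fpkm_threshold` | 1 | FPKM | expressed flag, strict >, all replicates |
| `de_alpha` | 0.001 | FDR | differential expression call |
| `csr_alpha` | 1e-7 | FDR | CSR TF filter, strict < |
| `er_de_alpha` | 1e-3 | FDR | DE flag in the ERα target network |
| `motif_p` | 0.001 | p-value | motif hit emission, strict < |
| `cor_alpha` | 0.05 | two-tailed α | correlation significance (r_crit 0.3961 at n=25) |
| `se_gene_distance` | 100,000 | bp | TSS-to-SE-center association, inclusive |
| `n_permutations` | 2,000 | — | SNP permutation count (1e6 at full scale) |

All coordinates are 0-based half-open (BED convention) on disk and
converted once at the I/O boundary; a point at an interval's exclusive
end is outside it.

# The synthetic scenario

`generate_scenario()` emits every input the pipeline reads — peak BEDs,
chip/input bedGraphs, four segmentation BEDs with a toy emission matrix,
gene models, a TF list, a 5-subtype × 5-replicate count matrix, SE-ARR
FASTA files, a redundant PWM library (MEME minimal) with a metadata
sidecar, and SNP tables — together with a serialized ground truth. All
randomness flows from a single seed; the same seed reproduces every file
byte for byte.

What it plants, and why recovery is analytic:

* **SEs.** Each enhancer locus is a 3-peak cluster of identical
  geometry; super loci carry a `se_fold`-times background coverage
  (fold 10 by default, slightly staggered so signals are distinct).
  Coverage tracks are noiseless piecewise-constant summaries — read-level
  noise simulation is out of scope — so at fold 1 the rank curve is
  exactly degenerate and the caller correctly reports no SEs. Five Th17
  and eleven Treg loci are planted; with the tangent rule the cutoff
  lands on the highest background region, so exactly the planted loci
  are called.
* **ARRs.** Exclusive runs are built to satisfy the strict-majority rule
  exactly: pure runs (10 exclusive bins), mixed runs (6 exclusive +
  4 shared bins, fraction 0.6), shared runs (active in all subtypes,
  never ARRs), and one exclusive run inside each SE (the SE-ARR).
* **Expression.** Counts are negative-binomial with dispersion 0.1 on a
  log-normal baseline. Master-regulator TFs (4 Th17, 10 Treg, of which
  1 and 2 are lineage-repressed) get a 1000-fold expression contrast
  versus their off-state and a gene-wise dispersion of 0.002. These two
  choices are part of the planted-truth construction: with 5 vs 5
  replicates the Welch test's degrees of freedom can floor at 4, where
  an FDR below 1e-7 requires |t| in the hundreds; tightly regulated,
  strongly induced master regulators are exactly the regime in which
  that filter is meaningful. The background transcriptome has 200 genes
  so that median-of-ratios size factors are stable (with very few genes
  the factor noise both inflates one group's variance and cancels the
  dominant genes' own noise, collapsing the Welch df).
* **Correlation structure.** The lineage expression patterns are the
  shared latent factor: two co-induced TFs correlate near +1 across the
  25 samples, an induced/repressed pair near −1, giving planted pairs
  with |r| ≥ 0.8 and known sign.
* **Motifs.** Regulator PWMs are near-consensus matrices of length 6–8
  (so exhaustive 4^L enumeration can certify the p-value machinery),
  with consensi chosen pairwise non-substring including reverse
  complements and non-palindromic; the ERα entry is a synthetic
  ERE-like motif, not a published matrix. Planted instances alternate
  strands. Background sequence is *scrubbed*: the generator rescans and
  re-randomizes any window carrying a chance significant hit until the
  only hits are the planted ones, so edge-level ground truth (precision
  and recall of regulator → target edges, ERE counts) is exact. Real
  sequences contain chance hits at any p threshold, so perfect edge
  precision is a property of the construction, not a claim about real
  data.
* **SNPs.** The autoimmune trait has 90% of its SNPs placed inside Th17
  SE spans; the control trait is placed uniformly outside SE spans.

What the scenario does **not** emulate: genomic sequence composition,
assembly gaps, replicate-level ChIP noise, LD structure among SNPs,
isoform complexity, or batch effects. Passing the recovery tests
demonstrates that each stage implements its rule exactly and that the
stages compose correctly — not that the thresholds are optimal for real
data.

# Numerical choices and degenerate inputs

* Interval merging with `max_gap = g` bridges gaps of at most `g` bp
  (gap `g` merges, `g + 1` does not), which makes stitching and ARR run
  merging the same primitive.
* The SE tangent point resolves ties toward the higher-signal side; with
  fewer than two regions or all-equal signals the caller refuses or
  warns rather than guessing.
* Fold enrichment uses (mean replicates + pseudocount) /
  (mean input + pseudocount); an all-zero input without a pseudocount is
  an error with guidance (0.5 keeps log2 defined) rather than an Inf.
* Hierarchical clustering defaults to Euclidean distance with average
  linkage (none is dictated by the analysis itself); both are arguments.
* Z-scores use the sample standard deviation across subtype means; a
  zero SD yields Z = 0 by convention so flat genes do not produce NaNs.
* Correlation significance is strict (|r| > r_crit), matching the
  threshold's definition; zero-variance genes are excluded with a
  warning rather than returning NA edges.
* The motif p-value lookup for raw scores applies a guard band of L/2
  discretization bins so every k-mer whose true score reaches the query
  is counted; scanning itself works entirely in the integer score space,
  where the dynamic-programming distribution is exact.
* The Welch stand-in `de_welch()` exists so synthetic runs need no
  external differential-expression tool; real analyses ingest a DE table
  (`read_de_table()`) with the same schema. Negative-binomial testing is
  deliberately out of scope.

# Problem sizes

The default scenario uses a 2-chromosome × 2 Mb toy genome, 104
candidate regulatory regions, 70 stitched enhancer loci, 221 genes ×
25 samples, 16 SE-ARR sequences of 2 kb, and 2,000 SNP permutations;
a full pipeline run completes in well under a minute, and the complete
test suite (including 500 brute-force classifier comparisons and
exhaustive 4^L motif enumerations) in a few minutes on one CPU. These
sizes were chosen so that every oracle can be exhaustive; nothing in the
implementation depends on them.

# Known limitations

* The SE signal model has no read-level normalization (reads-per-million
  scaling is the caller's responsibility via track scaling); absolute
  signal cutoffs are therefore track-scale-dependent, though the tangent
  rule itself is scale-invariant.
* Random region placement ignores assembly gaps and does not preserve
  chromosome assignment; both are reasonable extensions but change the
  null distribution.
* The ARR exclusivity rule is defined on a shared fixed-width bin grid;
  segmentations from different sources must be grid-compatible (the
  reader enforces this).
* Motif scanning uses a 0-order background and raw p-values (no q-value
  step), matching the analysis it implements; higher-order backgrounds
  typically reduce false hits in repetitive sequence.
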