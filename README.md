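# csrnet

Integrative epigenomics of CD4+ T-cell subsets: identify
**cell-type-specific regulatory regions (CSRs)** and reconstruct the
signed transcription-factor networks they anchor, including predicted
estrogen receptor alpha (ERα) targets.

Lineage identity in T helper 17 (Th17) and regulatory T (Treg) cells is
driven by master-regulator transcription factors (RORC, FOXP3) whose
loci sit inside super-enhancers — clusters of enhancers with
exceptionally high H3K27ac. `csrnet` implements the complete
computational chain from epigenomic tracks to a signed regulatory
network:

* **Super-enhancer calling** by rank ordering: peaks within 12.5 kb are
  stitched, scored by input-subtracted H3K27ac coverage, and the cutoff
  is placed at the tangent point of the scaled rank/signal curve (the
  point where the curve's slope crosses 1).
* **Active regulatory regions (ARRs)** from 25-state chromatin
  segmentations: states with emission of both H3K27ac and H3K4me1 ≥ 75
  are active; merged runs of active 200-bp bins are subtype-exclusive
  ARRs when strictly more than half of their fragments are active in
  one subtype only.
* **SE-ARRs and CSRs**: ARRs intersected with super-enhancers; CSRs are
  SE-ARRs of TF genes with FDR < 1e-7 versus naive cells.
* **SNP enrichment** by permutation: observed trait-SNP counts against
  length-matched random region sets, with the +1-corrected p-value
  p = (1 + #{N<sub>perm</sub> ≥ N<sub>obs</sub>}) / (1 + n).
* **Expression integration**: median-of-ratios normalization, FPKM on
  the longest isoform, expressed flags (FPKM > 1 in all replicates),
  subtype-specificity Z-scores, and gene-to-SE association within
  100 kb of the nearest SE center.
* **Motif scanning** with exact p-values: a non-redundant PWM library
  (human > mouse, experimental > computational), log-odds scoring, and
  a dynamic-programming null distribution; hits at p < 0.001 on either
  strand. Includes ERE scanning for ERα target prediction.
* **Network reconstruction**: TF → target edges weighted by motif hit
  counts at target SE-ARRs, core subnetworks over CSR TFs, and edge
  signs from Pearson correlation over all 25 expression samples
  (significant when |r| > t_c/√(t_c² + n − 2) = 0.3961 at n = 25,
  α = 0.05 two-tailed).

A seeded synthetic-data generator (`generate_scenario()`) emits every
input format the pipeline consumes with planted ground truth, so the
whole chain is testable end to end without external downloads.

## Worked example

```r
library(csrnet)

bundle <- file.path(tempdir(), "demo")
generate_scenario(default_scenario_config(seed = 1), bundle)
res <- run_pipeline(bundle, seed = 1)

head(res$se_calls$Th17[, c("chrom", "start", "end", "rank", "signal",
                           "is_super")], 3)
#>   chrom  start    end rank signal is_super
#> 5  chr1 700000 707600   32  72900     TRUE
#> 4  chr1 550000 557600   31  72720     TRUE
#> 3  chr1 400000 407600   30  72540     TRUE

res$csrs$Th17$tfs
#> [1] "TH17_TF1" "TH17_TF2" "TH17_TF3" "TH17_TF4"

res$cores$Th17
#> RegulatoryNetwork: 4 nodes, 8 edges
head(res$cores$Th17$edges[, c("regulator", "target", "weight", "r", "sign")], 5)
#>   regulator   target weight          r       sign
#> 1  TH17_TF1 TH17_TF1      2  1.0000000 activatory
#> 2  TH17_TF1 TH17_TF3      1  0.9981825 activatory
#> 3  TH17_TF1 TH17_TF4      2 -0.8023553 inhibitory
#> 4  TH17_TF2 TH17_TF1      1  0.9975816 activatory
#> 5  TH17_TF2 TH17_TF2      3  1.0000000 activatory

res$snp$Th17$autoimmune
#> Permutation SNP enrichment: Nobs = 36 | permutations = 2000 | p = 0.0004998
```

Reading the output: the Th17 track recovers exactly the five planted
super-enhancer loci (ranks 28–32 of 32 stitched regions); all four
planted Th17 master TFs pass the CSR filter; the core network's edge
weights are the planted motif-hit counts, signed by expression
correlation — the repressed TF (`TH17_TF4`) receives inhibitory edges
(r ≈ −0.80). The autoimmune SNP set, 90% planted inside Th17
super-enhancers, is enriched at the permutation floor
(p = 1/2001 ≈ 5 × 10⁻⁴), while the control set is not (p = 1).

Every stage is also callable directly — `stitch_peaks()`,
`call_superenhancers()`, `classify_specific_arrs()`,
`snp_enrichment()`, `scan_sequences()`, `build_network()`, … — and a
thin command-line wrapper lives at `inst/cli/csrnet.R`:

```sh
Rscript inst/cli/csrnet.R simulate --out-dir bundle/ --seed 1
Rscript inst/cli/csrnet.R all --bundle bundle/ --out-dir results/ --seed 1
```

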