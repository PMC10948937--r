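# dmrscape

Cross-platform differential DNA-methylation analysis for pediatric brain
tumors, built as a reusable R package plus a numbered analysis workflow.

Atypical teratoid/rhabdoid tumors (AT/RT), medulloblastomas (MB) and
choroid plexus tumors (PLEX) differ sharply in their DNA methylation
landscapes: AT/RTs are broadly hypermethylated, MBs broadly
hypomethylated, and the affected regions overlap binding sites of neural
and polycomb (PRC2) transcriptional regulators. Analyzing this requires a
chain of steps that each carry their own thresholds and conventions:
calling differentially methylated regions (DMRs) on two very different
platforms (array probes and bisulfite-sequencing tiles), filtering against
normal controls, intersecting comparisons into cancer-specific region
sets, testing transcription-factor binding-site (TFBS) enrichment,
detecting topologically-associating-domain (TAD)-scale shifts,
categorizing regions against pluripotent stem cell (PSC) and fetal brain
(FB) methylomes, integrating methylation with expression (DM-DE genes),
and filtering CUT&RUN peaks. `dmrscape` implements that chain as tested,
composable functions, and ships a synthetic-study generator with planted
ground truth so the whole pipeline can be verified end to end.

## The statistics at the core

* **Tile DMRs** (bisulfite platform): per 1-kb tile with methylated/total
  read counts, a two-proportion z-test on pooled counts whose variance is
  inflated by a method-of-moments overdispersion factor
  φ = max(1, χ²/df), referred to a t distribution; BH-adjusted, kept at
  q < 0.05 and |Δβ| ≥ 0.25, after removing tiles with any sample under
  10 reads or outside the canonical autosomes.
* **Probe DMRs** (array platform): per-probe Welch t-tests (optional
  categorical covariate residualized out), BH; significant probes
  (|Δβ| ≥ 0.05) merged within 1 kb into regions, kept at region
  |Δβ| ≥ 0.20, then reduced to the base pairs shared with at least one
  tumor-vs-control comparison.
* **Cancer-specific regions**: member probes extended ±500 bp carrying
  their region's Δβ; same-direction overlap ≥ 600 bp between the two
  comparisons of a focal cancer (exact tile identity on the tile
  platform); only |Δβ| ≥ 0.25 inputs considered.
* **TFBS enrichment**: one-sided Fisher's exact test per TF on
  target-vs-background units (≥ 1 bp site overlap), BH across TFs,
  validated only when significant on *both* platforms; also run per
  sample-type category of the binding catalog, per DMR cluster
  (k-means with AIC(k) = WSS + 2kd), and pairwise for co-localization.
* **Large-scale TADs**: a TAD is flagged when, on both platforms, ≥ 5
  same-direction units with |Δβ| ≥ 0.25 hit it, opposite-direction hits
  are < 1/10 of hits, and the units span > 50 kb.
* **Developmental categories**: regions become PSC-like, FB-like, unique
  or ambiguous from their overlap (≥ 1 bp) with seven reference DMR sets
  (each tumor vs PSC/FB and PSC vs FB, length-filtered to 100–5,000 bp),
  with differentiation status read off the PSC-vs-FB direction.
* **DM-DE genes**: genes differentially expressed on both expression
  platforms (BH p < 0.05, |log2FC| ≥ 1) whose linked regulatory region —
  promoter (2 kb up/500 bp down of the TSS), enhancer (GeneHancer-style
  confidence ≥ 5), or ±200 kb neighborhood — carries a cross-platform
  validated DMR (≤ 5 kb apart, same direction, TAD-boundary-free span)
  with methylation change opposite to the expression change.
* **CUT&RUN**: replicate peak sets intersected per bp after control and
  chrX/chrY removal; peaks retained when they overlap a known binding
  site or contain the motif at an exact FIMO-style p < 0.001 threshold
  computed by dynamic programming over the discretized log-odds score
  distribution.

## Worked example

```r
library(dmrscape)

study <- simulate_study(study_config(seed = 1))   # planted synthetic study
res   <- run_study(study)                         # full pipeline
ev    <- evaluate_recovery(study, res)            # compare with the truth

ev$tile_sensitivity   # 0.993  - planted tiles recovered (AT/RT vs MB)
ev$tile_fdr           # 0.000  - called tiles without planted support
ev$tf_validated       # TRUE   - planted TF enriched on both platforms
ev$category_agreement # 0.98   - developmental labels matching the truth
ev$dmde_recall        # 1.00   - planted DM-DE genes recovered
```

The synthetic study plants 72 DMR regions (52 AT/RT-focal with a
hypermethylation bias, 12 MB, 8 PLEX), two TADs carrying large-scale
shifts, a TF at 5× background rate in AT/RT-hyper regions, a TF enriched
only through its PSC-category binding sites, 28 DM-DE genes (16 opposite,
8 parallel, 4 with TSS–DMR spans crossing a TAD boundary) and four
CUT&RUN cell lines. `evaluate_recovery()` reports how much of that the
pipeline got back: the numbers above say that 99% of planted tiles were
re-called with no false regions, the planted TF was the top enrichment
hit on both platforms, 98% of regions received their planted
developmental label, and all plantable DM-DE genes were recovered while
all four boundary-crossing pairs were excluded by the TAD filter.

The `analysis/` directory holds the same pipeline as numbered narrative
scripts (`01_simulate.R` … `07_cutrun.R`); each can be run on its own
from the repository root with `Rscript analysis/0X_*.R` and writes its
tables under `results/`.

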