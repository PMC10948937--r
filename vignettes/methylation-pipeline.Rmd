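---
title: "Cross-platform DMR analysis: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform DMR analysis: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrscape)
```

This vignette is the package's account of the science it implements: the
statistical models behind each stage, the thresholds and their units, what
the synthetic-study generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be made.

## The problem

Three pediatric brain tumor entities — AT/RT, medulloblastoma (MB) and
choroid plexus tumors (PLEX) — are compared on two methylation platforms
with very different measurement models. Methylation arrays report a
continuous beta value per ~50-bp probe; reduced-representation bisulfite
sequencing (RRBS) reports methylated/total read counts, summarized here on
1,000-bp non-overlapping tiles. Every downstream claim (cancer-specific
regions, TF enrichment, TAD-scale shifts, developmental categories, DM-DE
genes) rests on DMRs called from these two platforms and on a series of
overlap rules with explicit distances — so the package treats those
distances as first-class, tested quantities.

All intervals are held in `GRanges` (1-based, closed), the Bioconductor
convention; BED input and output (0-based, half-open) are converted at the
reader/writer boundary. This keeps every overlap, gap and extension rule
expressible with the standard `findOverlaps`/`reduce` machinery while the
package's tests pin the BED-style semantics (a "600 bp overlap" or a
"5 kb gap" means the same thing it would in bedtools).

## DMR calling

**Tiles.** Tiles with any sample under 10 reads, or outside the canonical
autosomes (`chr1`–`chr22`), are removed before testing. The two-group test
is a two-proportion z-test on pooled counts with its variance inflated by
a method-of-moments overdispersion factor
$\varphi = \max(1, \chi^2_{\text{Pearson}}/\text{df})$ estimated across
samples against the group-pooled proportions. Methylation counts are
overdispersed relative to binomial (sample-to-sample beta variation), and
$\varphi$ absorbs exactly that. Because $\varphi$ is itself estimated, the
statistic is referred to a t distribution with $n_1+n_2-2$ degrees of
freedom rather than a normal; on a 5,000-tile null study this choice makes
the p-value distribution indistinguishable from uniform
(Kolmogorov–Smirnov p ≈ 0.1–0.6 across seeds) where a normal reference
shows visible heavy-tail miscalibration. Tiles pass at BH q < 0.05 and
|Δβ| ≥ 0.25, where Δβ is the difference of group means of per-sample
methylation proportions. This caller is a deliberately transparent
stand-in for beta-binomial GLM machinery; it is exposed as an ordinary
function so it can be swapped.

**Probes.** Per-probe Welch t-tests on beta values, BH across probes. An
optional categorical covariate (e.g. tumor location) is residualized out
per probe before testing by removing covariate-level means; a covariate
that coincides with the group partition is refused with a warning, since
residualizing it would erase the effect under test. Significant probes
(q < 0.05, |Δβ| ≥ 0.05) of the same direction are merged when separated by
at most 1,000 bp (a gap of 1,001 bp splits); the region Δβ is the mean of
member-probe Δβ and the region q the maximum member q — the most
conservative member-wise summary, chosen so a region never looks more
significant than its weakest supporting probe. Regions are kept at
|Δβ| ≥ 0.20.

**Control filtering.** Each main tumor–tumor DMR is reduced to the base
pairs it shares with at least one tumor-vs-control DMR set; main DMRs with
no control support are dropped. No direction agreement is required between
main and control DMRs: the filter is an overlap rule, and requiring
direction agreement would silently drop regions where the control
comparison saw the same locus from the other side.

**Cancer-specific regions.** Member probes are extended ±500 bp, each
carrying its region's Δβ; extended probes from the two comparisons of a
focal cancer pair off when a same-direction pair overlaps by ≥ 600 bp
(evaluated per pair, not per merged region), and the merged pairwise
intersections — the most conservative region satisfying both
comparisons — are reported. On the tile platform the shared 1-kb grid
makes exact coordinate identity the natural pairing rule.

## Enrichment statistics

Fisher's one-sided test is computed as the hypergeometric tail
$P(X \ge a)$ via `phyper`; the unit of analysis is the background unit
(extended autosomal probe, or tile), and "bound" means ≥ 1 bp overlap with
any site of the TF — the smallest defensible association rule, exposed as
a parameter. BH correction is applied within one run (one target set, one
category). The categorized variant reruns the test once per sample-type
subset of the binding catalog and flags (TF, category) pairs with no
measured site instead of testing them. Co-localization tests each
unordered TF pair over the target regions, corrects over the unique pairs,
and mirrors the matrix. Cross-platform validation is a plain intersection
of significant TF sets for the matching (cancer, direction) class.

## Clustering

Pooled, control-filtered array DMRs are summarized as a region × sample
matrix (mean beta of probes hitting each region) and clustered with
Lloyd's k-means, 25 iterations, 50 random starts per k. Model selection
uses AIC(k) = WSS(k) + 2·k·d with d the number of samples — a standard
heuristic form, since k-means has no canonical likelihood. Two caveats are
worth stating. First, on beta-scale data (values in [0,1]) the WSS term is
numerically small, so at modest region counts the penalty dominates and
small k win; the curve is returned so users can inspect it. Second, the
chosen k on real cohorts is therefore not guaranteed to reproduce any
particular published value; the package asserts only the behavior that is
checkable — on clearly separated blobs it picks the right k with perfect
label agreement, and the best-of-starts WSS is non-increasing in k.

## TAD-scale shifts

A TAD is flagged for a comparison when, on each platform separately, the
qualifying units (|Δβ| ≥ 0.25) inside it have ≥ 5 hits in the majority
direction, strictly fewer than 1/10 of hits in the opposite direction
(9 hyper + 1 hypo fails; 10 + 1 passes), and a first-to-last span
strictly over 50 kb — and both platforms agree on the direction.
Direction ties fail. Evaluating the hit and span rules per platform (with
both required) is the stricter of the two available readings of
"with both approaches", and the one implemented; flagged TADs from all
cell-type TAD sets are pooled and reduced to single coordinates per
direction.

## Developmental categories

Seven reference comparisons (three tumors × {vs PSC, vs FB}, plus PSC vs
FB) are called with the probe DMR caller at |Δβ| ≥ 0.25 and region
lengths 100–5,000 bp inclusive. The footprint of the cancer-specific
regions is split into non-overlapping atoms, and each atom records, per
reference set, `none`/`hyper`/`hypo`/`both` (direction always with
respect to the first group). The category is a total function of these
flags, defined by an explicit truth table:

| focal dir d | tumor-vs-PSC | tumor-vs-FB | likeness |
|---|---|---|---|
| d | none | d | PSC-like |
| d | d | none | FB-like |
| d | d | d | unique |
| d | none | none | unique (zero evidence) |
| d | any `both`, or any flag opposite to d | | ambiguous |

Differentiation status comes from the PSC-vs-FB flag: `none` → unchanged;
`hyper` (PSC above FB, i.e. methylation lost from PSC to FB) →
demethylated during differentiation; `hypo` → methylated during
differentiation. The exhaustive 128-combination enumeration is asserted in
the tests; "similarly methylated" is operationalized as the *absence* of a
called DMR in the corresponding comparison, not as a beta-distance
threshold, which keeps the categorization a pure overlap computation.

## DM-DE integration

Differential expression uses a per-gene Welch t-test on log2 values
(counts first normalized to log2 counts per million), with multi-probe
genes collapsed by the mean — a transparent stand-in for the moderated
models used on real cohorts, with the same significance contract
(BH p < 0.05 and |log2FC| ≥ 1; the stricter p < 0.01 preset is a
parameter). DMRs link to genes through transcript promoters (2 kb
upstream / 500 bp downstream of the TSS, strand-aware), enhancers
(GeneHancer-like links pre-filtered to confidence ≥ 5; FANTOM-like links
unfiltered), or ±200-kb TSS neighborhoods. A pair is cross-platform
validated when the other platform links a same-direction DMR to the same
gene within 5 kb (5,001 bp fails).

The TAD-boundary rule counts TAD starts/ends strictly inside the open
span between the TSS and the DMR edge nearest to it, across all supplied
TAD sets. Two readings exist for the gene-level rule; both are
implemented. The literal reading (drop a gene when *any* pair crosses a
boundary) is the function default, but the pipeline preset uses the
"any clean pair" mode and keeps only boundary-free pairs: with 200-kb
neighborhoods over 150–300-kb TADs, essentially every gene eventually
acquires some unrelated distal DMR pair that crosses a boundary, and the
literal rule then degenerates to dropping nearly everything. Finally,
genes significant on both expression platforms with sign-consistent fold
changes are classified `opposite` (every supporting DMR against the
expression sign — the DM-DE genes), `parallel`, or `mixed` (excluded from
both lists).

## CUT&RUN filtering

Replicate peak sets are cleaned (canonical autosomes only; any peak
overlapping an input-DNA control peak by ≥ 1 bp removed) and unified by
per-bp intersection — the most conservative notion of "called in both
replicates"; a reciprocal-overlap mode would keep whole peaks and is left
to the caller by operating on the `GRanges` directly. Retention requires
a known binding site (≥ 1 bp) or a motif hit. The motif threshold is
exact: the log2-odds matrix (counts + 0.25 pseudocount over a uniform
background by default) is discretized into 0.001-bin integers, the full
score distribution under the background is obtained by dynamic
programming, and the threshold is the smallest binned score whose tail
probability is below the p-value bound (0.001). Scanning uses the same
binned matrix, so threshold and scores cannot disagree; both strands are
scanned. An `N` contributes the column's *expected* background log-odds
(negative for informative columns) — this keeps partially ambiguous
windows scored sensibly while guaranteeing that fully ambiguous sequence
never reaches the threshold, which a naive "N scores 0" rule does not
(0 can exceed the threshold when it falls into a gap between achievable
scores).

## The synthetic study

The generator emulates the statistical structure of a two-platform
methylome cohort, not its biology. Per unit and group it fixes a mean
beta; samples draw Beta(μc, (1−μ)c) values with concentration c = 50
(array platform) and beta-binomial counts (tiles: totals Poisson around
30× with ±30% per-sample scale factors). Baseline means are bimodal
(low ≈ 0.05–0.25, high ≈ 0.6–0.95), shared across groups. Planted DMR
regions (2–3 tiles) set the focal tumor group 0.4 above or below a 0.30/
0.70 baseline; PSC/FB means are set per the planted developmental
category, so categorization is exactly recoverable. Two chr1 TADs receive
six hyper regions each spread over >150 kb (large-scale signal); all other
planted regions sit in distinct TADs so the 5-hit/50-kb rules cannot fire
by accident. The TF catalog holds 30 TFs × 2,000 sites; one TF is placed
in AT/RT-hyper regions at 5× its background rate, one only through its
PSC-category sites, and a NEUROD1-like TF both in the catalog and under
the CUT&RUN peaks. DM-DE genes receive ±2 log2FC in AT/RT on both
expression platforms (negative-binomial counts, size 10; Gaussian
log-intensities, sd 0.4), with the linked DMR's direction opposite (or,
for the parallel set, equal); planted genes are given quantifiable
baseline expression, as real DM-DE candidates would have. Four
boundary-crossing genes have their TSS placed beyond the hosting TAD's
end to exercise the TAD filter.

What it does **not** emulate: spatial correlation of methylation beyond
the planted regions, probe-level measurement bias, chromatin covariance,
read-level artifacts, or realistic TF site clustering. Passing the
recovery tests therefore demonstrates that the pipeline's logic and
thresholds behave as specified on data with the right marginal structure —
not that the pipeline's power estimates transfer to real cohorts.

Default problem sizes — a 20.1-Mb genome with 20,000 autosomal tiles and
~40,600 probes, 10 samples per tumor/control group and 6 per PSC/FB, and
a 5,000-tile genome for the null-calibration runs — were chosen so that a
complete study generates and analyzes in about a minute while leaving
every planted signal comfortably powered; all of them are `study_config()`
parameters.

## Numerical and degenerate-input choices

* Sorting is deterministic: chromosome (lexicographic), start, end; stable
  beyond that.
* Empty interval sets propagate as empty results, never as errors, except
  where an argument is structurally required (no replicates, no TAD sets).
* Zero-variance genes/probes get p = 1 rather than NA.
* k-means with fewer distinct rows than centers short-circuits to one
  center per distinct row (WSS 0) instead of erroring.
* Missing beta values are mean-imputed per row before clustering, ignored
  (pairwise) in variance ranking and region means.
* BH inputs are validated to [0, 1]; Fisher inputs to non-negative
  integers.

## Known limitations

The DMR callers are transparent stand-ins, not reimplementations of
kernel-smoothed or beta-binomial GLM callers; regions from real cohorts
will differ near significance boundaries. The AIC form for k-means is a
heuristic and scale-sensitive. The developmental truth table is the
package's normative definition of a taxonomy that is often presented only
graphically. The enhancer and neighborhood link rules assume annotated
links and TADs are given; the package neither predicts enhancers nor
calls TADs.
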