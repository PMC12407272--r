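---
title: "Methods: subgenome dominance analysis on synthetic allotetraploid data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgenome dominance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`subdom` analyses subgenome dominance in an allotetraploid from
annotation- and summary-level inputs: gene models (GFF3), TE/ACR/peak
intervals, per-cytosine methylation counts, gene-by-sample read counts,
windowed MeRIP IP/input counts, and variants genotyped in the two
subgenomes and their two progenitor species. This vignette records the
models, parameter choices and numerical decisions behind each stage, and
what the synthetic data can and cannot establish.

## Coordinates and data model

All internal coordinates are 0-based half-open; GFF3 input/output
converts at the boundary (1-based closed), so conversion is an exact
bijection. Each gene carries one representative transcript (the mRNA
with the longest summed CDS — annotation pipelines rarely mark a
canonical isoform, and the longest CDS is the common proxy); UTRs are
derived from exons minus CDS when not annotated. Subgenome membership
lives on the chromosome record and is inherited by every feature; the
trailing-letter convention ("…A"/"…B") is recognised and an explicit
mapping can override it. An "unplaced" label exists for genes on
unanchored sequence, which real assemblies always have; such genes are
carried through but excluded from per-subgenome rates.

## Statistical primitives

The shared primitives are implemented in the package rather than
wrapped, so their conventions are pinned down and testable against
enumeration:

* **BH adjustment** is the step-up procedure with monotonicity
  enforcement. "Adjusted p" thresholds throughout are interpreted as
  BH-FDR.
* **Fisher's exact test** reports the two-sided p by the
  point-probability rule (sum over tables with probability not above the
  observed), the dominant convention and the one reference
  implementations use; the effect is the sample odds ratio with
  infinity allowed.
* **The rank-sum test** enumerates the exact U distribution (a
  dynamic-programming count over rank subsets) for combined n up to 25
  without ties, and otherwise uses the normal approximation with tie and
  continuity corrections. The effect is the Hodges–Lehmann shift. Exact
  and approximate branches agree to < 0.01 at the boundary.
* **Hypergeometric enrichment** is the upper-tail sum with fold
  enrichment as effect; enrichment consumes a user-supplied gene-to-term
  table, never a GO database.
* **Root activity** from the TTC assay is returned as mg g⁻¹ h⁻¹,
  i.e. ttc/(weight × time). The literal formula "ttc/(weight/time)"
  that assay write-ups sometimes print has inverted time units; it is
  available behind `literal = TRUE`, and the two coincide at one hour.

## The negative-binomial Wald test

Differential expression and homoeolog bias share one engine:
median-of-ratios size factors, per-gene method-of-moments dispersion on
normalised counts, and a Wald test of the log2 fold change with NB
variance (mu + alpha mu²)/n per group, pseudocount 0.5. With three
replicates a per-gene MoM dispersion is extremely noisy, so it is
moderated toward the genome-wide median with a prior weight of six
pseudo-degrees of freedom, and the Wald statistic is referred to a t
distribution whose df add that prior to the residual df. This keeps the
raw type-I rate at nominal 0.05 under the null (measured ≤ 0.05 on
10,000 null genes) while retaining power ≥ 0.9 at |log2FC| = 2, mean
100, dispersion 0.05 and n = 3 — the calibration the acceptance suite
re-measures. DEG calls use |log2FC| > 1 (strict) and FDR < 0.05
(strict).

For homoeolog bias, the A and B members of a pair measured in the same
library are treated as the two conditions with replicates as units, but
size factors are the *library-level* factors computed once from the full
count table: the A-half and B-half of one library share its depth, and
re-normalising the halves separately would absorb genuine genome-wide
dominance into the size factors. Per tissue, pairs are classed
A-dominant/B-dominant at adjusted p < 0.01 by the sign of log2(A/B);
the pooled call flags a pair biased in at least one tissue (default;
majority pooling is available), with direction by the
significance-weighted sign. The any-tissue pooling rule slightly
inflates the pooled biased fraction through per-tissue false positives
(about one point at five tissues), which stays well inside the ±3-point
recovery band the acceptance suite checks.

## Homoeolog pairing and fractionation

Anchor hits (e.g. syntenic orthologs) are chained in gene-rank space:
per chromosome pair and orientation, the longest chain in which
successive anchors advance by at most `max_gap + 1` ranks on both
genomes is extracted repeatedly (dynamic programming, no anchor reuse);
chains shorter than `min_block` anchors are dropped. Defaults
`max_gap = 10`, `min_block = 5` follow the common defaults of
collinearity detectors. Within a block, genes pair one-to-one by
descending similarity; extra tandem copies stay unassigned, and
unpaired genes inside a block's span become singletons. With noise-free
anchors the simulator's pairs are recovered with F1 = 1.0.

Retention profiles take the ancestral gene order as an *input* (an
outgroup order in real use, the simulator's true slot order in tests)
and report per-window fractions retained in A, in B and in both, for
100-slot windows by default. The balance test is a paired Wilcoxon
signed-rank across windows.

## Repeats and methylome

TE content is merged-interval coverage per subgenome, invariant to how
TE records are split. Gene-TE distance is the span-to-span gap (0 for
overlap), with genes on TE-free chromosomes excluded as undefined;
medians are compared between subgenomes with the rank-sum test.
Methylation levels are always *weighted* (sum mC / sum C over reads),
the field standard, robust to coverage variation, and distinct from the
mean of per-site levels whenever coverage varies. Metaprofiles use 20
length-normalised body bins and 20 fixed-width bins per 2-kb flank,
strand-aware; bins without covered cytosines are emitted as missing,
never zero-filled. LTR insertion age is divergence/(2µ); µ has no
default because no single rate is canonical across plant lineages.

## Accessible chromatin

Positional classes follow a strict priority: an ACR overlapping any
gene body is genic; otherwise an ACR within 5 kb upstream of a TSS
(strand-aware, boundary inclusive) is proximal and assigned to the
nearest TSS; otherwise distal. Upstream-only is the default because
promoter-proximal accessibility is the regulatory signal of interest; a
`flank_mode = "both"` switch classifies both flanks instead.

Conservation between subgenomes is called by projection: each ACR's
TSS-relative offsets at its anchor gene are transferred to the
homoeologous partner gene (strand-aware), and a partner-subgenome ACR of
the same tissue overlapping the projection by ≥ 1 bp makes the pair
conserved. Same-tissue overlap is required because accessibility is
tissue-specific; projection through the homoeolog anchor stands in for
whole-genome alignment, which summary-level inputs cannot provide —
ACRs anchored on singletons are therefore unprojectable and flagged
specific/no-anchor. Variant density is counted over the ACR plus its
projection, per kb. Ancestry attribution asks, for each variant in a
subgenome-specific ACR, whether the carrying subgenome's allele equals
its own progenitor's allele (A with progenitor A, B with progenitor B),
excluding missing genotypes from both numerator and denominator.

## m6A peak calling and comparisons

Windows are 50-bp non-overlapping bins on transcript coordinates. Per
window the caller computes the library-normalised IP/input ratio
(pseudocount 0.5, ratio only) and a Fisher exact test of the window's
IP/input counts against the library totals; windows with ratio ≥ 2
(inclusive) and p < 0.05 (strict) are significant, and adjacent
significant windows merge into peaks (count-weighted mean log2 ratio,
minimum window p). Calling is invariant to uniform scaling of both
library sizes. Borderline-enrichment peaks can fragment into multiple
called peaks when interior windows dip below threshold; this inflates
raw peak counts for weakly enriched conditions, which is why the
peak-loss experiment in the acceptance suite plants clean losses only.

Features are assigned by maximal overlap with the representative
transcript's 5'UTR/CDS/3'UTR, ties broken 3'UTR > 5'UTR > CDS (m6A
peak ambiguity at the stop codon conventionally resolves to the 3'UTR).
Differential methylation between conditions is computed per control
peak detected in both conditions, over the union span of the control
peak and the waterlogged peaks overlapping it (robust to
fragmentation): a Fisher test contrasts IP vs input between conditions
after correcting only the *relative* IP/input library imbalance
(scaling down the relatively larger input track, never inflating
counts), with flags at FDR < 0.05 and |Δlog2 ratio| ≥ 1 — thresholds
declared here, both configurable. Expression integration cross-tabulates
direction among genes significant in both analyses; an odds ratio below
1 indicates repressive coupling (m6A loss with expression gain).

## The synthetic generator

`generate_dataset` emulates the statistical structure the analyses
assume, at interval/count level (no sequence): two subgenomes of 5
chromosomes each; ancestral slots retained in both subgenomes with
probability 0.6 (pairs) or one (singletons, split evenly — unbiased
fractionation); ~10,000 genes on a jittered 5-kb grid with fixed
200/1500/300 bp UTR5/CDS/UTR3 structure. Defaults are the study
conditions: 70% of pairs biased with mean |log2FC| 2 (uniform ± 0.75),
80% toward subgenome A, applied as a gain to the favoured member; TE
densities 240 vs 280 per Mb with mean length 2.5 kb (≈ 45% vs 50%
genomic TE content); per-context methylation plateaus 0.90/0.65/0.18
inside TEs decaying exponentially (length scale 400 bp) to backgrounds
0.25/0.08/0.04 — TE-to-gene methylation spreading; proximal ACRs
retained per gene at 0.8 (A) vs 0.5 (B) with 10% of retained B copies
destroyed by a recorded 126-bp insertion; specific-ACR SNPs matching the
carrier's progenitor at 0.773; m6A peaks on pairs with correlated
status targeting 82/15/3 shared/A/B gene fractions, 80% in 3'UTRs,
spanning four windows with IP 30 vs input 10 inside peaks and a
depleted IP background of 1 (IP read mass concentrates into peaks);
16% of control peaks lost under waterlogging and 15% of the rest
dropped 3-fold (the substrate of differential methylation); per-subgenome
DEG rates 0.20/0.19 with 56% downregulated, |log2FC| in [1.5, 3], and
genes losing m6A coupled to upregulation with probability 0.7 *within*
the DEG budget; NB dispersion 0.05; five tissues × three replicates
plus a root CTL/WL contrast. One master seed forks into named
substreams per generator, so adding a generator does not perturb the
others, and every file written is byte-identical across runs at a fixed
seed.

Where a value had no stated target, the default is what a practitioner
would call realistic at desk scale (e.g. methylation site spacing 200 bp
at coverage 20; lognormal baseline expression with floor 20; gamma peak
scores), chosen once. Truth tables (pair bias class, ACR conservation
class, peak fate, DEG status) cover every simulated unit, so each
downstream classification is scored with confusion matrices.

What the generator does *not* emulate: sequence content and motifs,
read-level noise and mappability, isoform structure, spatially
clustered TEs or genes, correlated replicates or batch effects, and
partial ACR losses. Passing tests therefore demonstrate correctness of
the analysis logic and calibration of the statistics under the assumed
generative model — not robustness to alignment artefacts or biological
confounders in real sequencing data.

## Problem sizes and known limitations

The test and acceptance runs use 20,000 pairs for bias recovery,
~50,000 variants for ancestry, ~5,000 planted peaks for the m6A loss
experiment, 10,000 genes for calibration, and the 10,000-gene default
bundle for the end-to-end determinism check — sizes at which binomial
error bands (3σ) sit comfortably inside the recovery tolerances while a
full run stays in the minutes range on one CPU.

Known limitations: the m6A differential test flags |Δlog2| ≥ 1, so
drops of exactly 2-fold sit on the flag boundary and are detected about
half the time regardless of depth; peak fragmentation (above) biases
raw peak counts upward for weakly enriched samples; the any-tissue bias
pooling rule is anticonservative by about one point; and the collinear
chainer assumes anchors are mostly one-to-one — heavily duplicated
families should be collapsed before pairing.
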