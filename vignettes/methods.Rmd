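---
title: "Methods: classifying promoter conservation and convergence across an allotetraploid and its progenitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying promoter conservation and convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

An allotetraploid such as *Brassica napus* carries two subgenomes (An, Cn)
descended from two diploid progenitors (*B. rapa*, Ar; *B. oleracea*, Co).
After polyploidization the two subgenomes must coexist in one nucleus, and a
central question is whether their regulatory landscapes drift apart or
converge. `homeoconverge` implements the comparative machinery needed to ask
that question at the promoter level: for quartets of genes in strict
1:1:1:1 correspondence across Ar, Co, An and Cn ("homoeologous tetrads"), it
classifies, per epigenomic mark, whether promoter peaks are conserved at the
sequence layer, the epigenome layer, both, or neither, and whether
conservation between An and Cn arose where the progenitors had already
diverged — the signature of intersubgenomic convergence.

Because genome-scale inputs for this analysis are large and external, the
package ships a synthetic four-genome generator that emulates the
statistical structure of the real comparison with known truth at every
layer. All pipeline stages are exercised and scored against that truth.

## The analysis units and layers

**Tetrads.** Gene quartets are identified from per-genome gene sequences by
reciprocal best hits (banded global alignment, match +1 / mismatch −1 /
gap −2), filtered for collinearity: a pair survives only as part of a chain
of at least 4 anchor pairs monotone in both genomes with rank gaps of at
most 10, then filtered at cscore ≥ 0.99 (the score of a hit divided by the
best score of either gene). Quartets must agree across the Ar–Co, Ar–An and
Co–Cn maps; any gene appearing in two candidate quartets discards both.
Whether the An–Cn edge must additionally close the quartet is configurable
(`require_closed_quartet`, default off): closing the quartet is stricter but
discards tetrads whose An–Cn similarity is weakest, which is exactly the
class of genes a convergence analysis is about, so the default requires
agreement of the three derivation edges only.

**Promoters.** 1.5 kb upstream to 0.5 kb downstream of the TSS, in
transcription direction; minus-strand promoters are reverse-complemented so
all coordinates read 5′→3′. Windows are clipped at chromosome ends with a
warning.

**Alignment.** Each homoeologous promoter pair is aligned once, globally,
with affine gaps (match +2, mismatch −3, gap open −5, gap extend −2; a gap
of length L costs 5 + 2L). N bases never match. Traceback ties are broken
deterministically (diagonal, then gap in the first sequence). The
implementation runs the Gotoh recurrence inside a diagonal band that is
doubled until the score stabilises, falling back to the full matrix, so the
result always equals the full-matrix optimum; short instances (≤ 512 bp)
always use the full matrix. Genome-wide chain/net machinery is deliberately
not reimplemented: tetrads already provide synteny anchoring, and a single
global alignment per promoter pair is oracle-testable (the test suite
checks score equality against an independent implementation).

**Lift-over.** An interval in one promoter is projected through the
alignment: the target is the [min, max) hull of the aligned partner
positions of its bases; the lift fails when fewer than `min_lift` (default
0.5, a common lift-over success convention) of the source bases are
aligned.

## The classification rules

Per tetrad, genome pair and mark:

* **Sequence conservation** — every promoter peak of that mark (in
  whichever member has peaks) lifts with ≥ 50% of its bases aligned *and*
  ≥ 70% aligned identity inside the peak footprint. The identity threshold
  is the package's own operationalisation (exposed in `thresholds`): a
  lift-over can technically succeed across a fully substituted region, so
  lift success alone cannot stand in for sequence conservation.
* **Epigenome conservation** — some lifted peak region is covered ≥ 50% by
  a same-mark peak in the partner promoter; either direction suffices.
  Peak-boundary noise motivates coverage rather than exact interval
  equality.
* **Classes** — I: both layers conserved; II: sequence conserved, epigenome
  divergent; III: both divergent. Pairs with a conserved epigenome on a
  divergent sequence do not fit a three-class scheme and are reported
  `unclassified`; pairs with no peak on either side are `no_peak`. Both are
  excluded from class denominators, so forcing them into Class III cannot
  distort proportions.
* When a promoter carries several peaks of one mark, sequence conservation
  requires *all* of them and epigenome conservation *any* of them (both
  switchable): a single divergent footprint breaks the sequence claim,
  whereas one co-occurring peak suffices to show the mark is maintained.

**Convergence.** For tetrads whose An–Cn call is conserved at a layer, the
Ar–Co state assigns a category: `same` (also conserved in the diploids),
`convergent` (diploids have peaks but are not conserved), `others` (no
diploid peak). `unclassified` diploid calls count as `convergent` at the
epigenome layer by default (they do have peaks), with a flag to move them
to `others`. Convergence is computed per mark, never pooled, and H3K9me2 is
processed but excluded from class/convergence tables by default (the
heterochromatic mark is not part of the promoter-class analyses).

**Expression convergence.** log2FC = log2((max TPM + 1) / (min TPM + 1));
a tetrad is expression-convergent when the An–Cn log2FC falls below 1 while
the Ar–Co log2FC does not. The pseudocount of 1 keeps zero-TPM genes
finite; the threshold of 1 matches the package's DEG rule (p < 0.05 and
|log2FC| > 1, both strict). These definitions are the package's own,
exposed in configuration.

**TFBS conservation.** Promoters are scanned on both strands with a PWM
library (JASPAR-style counts, pseudocount 10⁻³, natural-log odds against a
uniform 0.25 background); hits require a score strictly above 10, and
windows containing N are skipped. A tetraploid hit is conserved when the
same motif is identified in the diploid homolog (motif-identity level; a
position-matched mode lifting each hit through the promoter alignment is
available behind a flag, since requiring positional overlap is a stricter
reading of "identified in both homologs"). CS = conserved / total
tetraploid hits on the [0, 1] scale, undefined for promoters without hits.
Only tetraploid-side gains can lower CS under this definition — a
consequence worth keeping in mind when interpreting CS distributions.

**Variants.** From the same pairwise alignments (one aligner, one traceback
convention — a multiple-sequence aligner adds nothing for n = 2): each
mismatch column is one SNV (no MNV merging); each maximal gap run in either
sequence is one InDel (≤ 50 bp) or SV (> 50 bp), with runs split by any
intervening aligned column. Coordinates are reported on the tetraploid
member. Variant lists are invertible: applying them to one sequence
reconstructs the other exactly, which the tests verify on a thousand
simulated pairs. Gap-run length is measured in the alignment, which for a
complex gap equals the length on whichever strand carries the extra bases.

## The synthetic benchmark

Each gene occupies a slot built in transcription direction: five fixed
160 bp mark windows (H3K4me3, H3K4me1, H3K27me3, H3K9me2, ACR) upstream of
the TSS separated by background segments, then a 600 bp gene body from the
TSS and an intergenic spacer. Keeping windows as bookkept pieces lets the
generator confine class-defining edits to a mark's own footprint, compute
exact peak coordinates after indels elsewhere, and derive truth labels from
piece identity instead of re-alignment.

Ar and Co diverge independently from a common ancestor; An and Cn derive
from Ar and Co. Defaults (the benchmark's study conditions): 1%
substitutions and 0.1% short indels per branch in background segments; 15%
of promoters receive one 60–120 bp SV downstream of the TSS per branch; the
An branch mutates at twice the base rates, encoding the subgenome asymmetry
of the study system; class mix I/II/III = 50/30/20% per mark and derivation
pair; 8% epigenomic-convergence and 8% sequence-convergence implants per
tetrad and mark. Class I inherits the window verbatim with peaks on both
sides; Class II inherits the window but drops one peak; Class III replaces
the window with random same-length sequence and keeps one peak.
Length-neutral replacement is deliberate: the region still lifts (as
mismatch columns) but fails the identity threshold — precisely the failure
mode the classifier must detect — and it keeps the other marks' windows at
their truth distances from the TSS. Epigenomic convergence equalises peak
presence in An/Cn over an untouched window while the diploids stay
divergent; sequence convergence copies the Ar window replacement to both An
and Cn while Co stays ancestral.

Motif instances (consensus of packaged synthetic PWMs with 10% per-position
noise) are implanted at up to 8 sites per ancestral promoter, with motifs
drawn under harmonic weights so per-motif target counts span a wide range,
as real TF target counts do. TFBS turnover
enters through three channels, all configurable: tetraploid-branch gains
(25% per promoter, doubled for An), novel motifs inside SV insertions
(50%), and novel motifs inside replaced windows (30%). These create the
tetraploid-only sites that lower CS, give An a lower CS distribution than
Cn, and couple total variant length to CS loss.

Expression is lognormal per tetrad (median 10, log-sd 1); each activating
peak (H3K4me3, ACR) multiplies the expectation by 4 and each repressive
peak divides by 4; diploids add 0.8 log2-sd noise and each subgenome adds
noise around its progenitor with sd 0.2/0.6/1.2 for worst pair class
I/II/III. TPM values are rounded to 3 decimals when written, so emitted
files and in-memory values agree.

A single PRNG is seeded from the configuration with per-stage sub-streams
(ancestor, genomes, expression), so stage outputs are individually
reproducible and a fixed seed yields byte-identical files.

What the generator does *not* emulate: read-level noise and peak-calling
artefacts, transposable-element landscapes, methylation, homoeologous
exchanges, and realistic gene/intergenic length distributions. Passing the
benchmark therefore demonstrates the correctness of the comparative
machinery under controlled divergence, not performance on raw sequencing
data.

## Numerical and statistical choices

* Coordinates are 0-based half-open internally everywhere; conversion
  happens only at the GFF3 boundary (1-based inclusive). Minus-strand
  promoters use the interval [tss − 500, tss + 1500), the mirror of the
  plus-strand window.
* The 2×2 chi-square applies the Yates continuity correction by default;
  on the published input counts this reproduces the printed statistic to
  one decimal (the uncorrected value differs in the first decimal), which
  is how the convention was fixed. P-values below 2.2e−16 are reported as
  "<2.2e−16".
* Marked-gene shift percentages use the tetrad total as denominator,
  the only convention arithmetically consistent with the printed values.
* Distribution comparisons (convergent vs Class III expression divergence)
  use a one-sided Mann–Whitney test; variant length vs CS uses Spearman
  correlation.
* TPM-difference bins are half-open: [0,1), [1,5), [5,10), [10,∞).

## Problem sizes

The shipped test suite runs the full pipeline on benchmarks of 2000 tetrads
(truth recovery), 200 tetrads (module-level checks) and 40 tetrads
(zero-divergence control); `scripts/acceptance.R` regenerates a 600-tetrad
benchmark plus the zero-divergence control and a 1000-pair variant
round-trip. These sizes give binomial standard errors well below the 5%
accuracy margins being tested while keeping a complete run in the minutes
range on one CPU.

## Known limitations

* Sequence-conservation thresholds (lift ≥ 0.5, identity ≥ 0.7) are
  package choices; the upstream tools the analysis emulates never define
  "conserved sequence" operationally. Both are exposed in `thresholds`.
* CS is insensitive to tetraploid-side losses by construction of its
  published formula (tetraploid denominator).
* The RBH + collinearity orthology stage is a desk-scale stand-in for
  proteome-graph clustering plus synteny blocks; it assumes largely
  collinear genomes and will under-recover tetrads across large
  rearrangements.
* With `--nogapped`-style seeded aligners the original pipeline's handling
  of indels inside lifted regions is not recoverable; the global
  affine-gap substitute is a declared design choice, not an inference.

## A worked run

```{r}
library(homeoconverge)
run <- run_pipeline(list(
  simulate = list(n_tetrads = 200, seed = 42),
  outdir = "demo_out"))
run
head(run$class_summary)
run$convergence_summary
run$high_cs
```

All tables are also written as TSV under `outdir`, with a manifest of MD5
checksums; re-running with the same config and seed reproduces the
checksums exactly.
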