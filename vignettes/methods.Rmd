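---
title: "Methods: allele-specific motif disruption in active chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific motif disruption in active chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Disease-associated non-coding variants are thought to act by altering
transcription-factor (TF) binding in regulatory chromatin. This package
implements a workflow for asking, in a cell population of interest
(here modelled on thymocytes), whether credible-set variants — SNVs and
indels — differentially match DNA sequence motifs that recur in that
population's active chromatin. The workflow has two arms:

1. **Regulatory-motif arm.** Histone-modification ChIP-seq peaks are
   filtered, pooled across individuals and restricted to
   transcriptionally active regions; motifs recurring in those regions
   are discovered de novo; each variant's REF and ALT flanking
   sequences are scanned against every motif; and an empirical
   statistic, `E_diff`, tests whether the allelic difference in match
   p-value (or score) is extreme relative to all variant–motif pairs of
   the same dataset.
2. **Biophysical arm.** A TRAP-style expected-occupancy model scores
   each allele's affinity for TF motifs, with empirical-null p-values
   and the absolute `log10` p-value difference as the allelic effect
   measure.

A dataset is one cell type × histone mark combination (peaks pooled
over individuals), or a *pseudostate*: the base-wise intersection of
several marks' pooled peak sets (e.g. pseudostate 12 = H3K4me3 ∩
H3K27ac), a stand-in for chromatin states when no individual carries
all marks.

# Peak processing

Per-sample peak calls carry an enrichment fold change and an
FDR-adjusted q-value. The fixed processing order is:

1. keep peaks with fold change ≥ 3 **and** q < 1e-4 (inclusive /
   strict, per the conventional statement of these filters);
2. keep peaks whose mean RNA-seq depth over the peak length is
   ≥ 0.001 (bases absent from the sparse coverage track count as
   depth 0; a switch restricts the mean to covered bases);
3. pool replicates of the same cell type and mark, merging overlapping
   and bookended intervals;
4. drop pooled calls shorter than 6 bp — *before* flanking, so a short
   call cannot be rescued by its flanks;
5. add 20 bp flanks (clipped at chromosome ends) so motifs on peak
   borders remain visible, and re-merge;
6. excise exonic bases last; fragments created by the excision are kept
   regardless of length (the length filter is applied once).

All coordinates are 0-based half-open internally (BED convention);
GFF3 exon input is converted on read. Pseudostates are intersections of
the *cleaned* pooled sets, skipped for a cell type that lacks a member
mark.

# Motif discovery

Discovery is seeded expectation–maximization under the ZOOPS model
(zero or one site per sequence, both strands) against an order-1
background fitted to the dataset's own sequences with both strands
pooled and a pseudocount of 1 — the order-1 model absorbs nucleotide
and dimer composition (e.g. CpG depletion). Up to 600 sequences are
subsampled for discovery. For each motif:

- **Seeding.** All `wmin`-mers are ranked by background-corrected
  enrichment `n log(n/E)` over both strands; the best unused seed
  initializes the PWM (0.85 on the seed base, background elsewhere).
- **EM.** Iterate until the observed-data log-likelihood gain drops
  below 1e-4 or 200 iterations. The ratio of site to background window
  likelihood uses the order-1 probability of the window given its
  preceding base; the transition out of the window is ignored, a
  standard simplification. Windows containing N are excluded. The EM
  trace is stored and asserted non-decreasing in the tests.
- **Width selection.** The seed is refined at each width of a
  geometric-ish grid spanning `[wmin, wmax]` (6–30 by default) and the
  width maximizing a penalized objective is kept: the expected total
  log-likelihood ratio of sites minus `1.5 w log(nsites)` — a
  BIC-style charge of 3 free parameters per column. The penalty is
  what makes widths comparable; without it EM pads motifs with
  uninformative columns.
- **Masking.** Sites with posterior > 0.5 are masked (set to N) and
  the search repeats for the next motif. If an accepted motif is
  low-complexity (≥ 90% one letter in its consensus) discovery stops —
  the degenerate-input guard.
- **Pseudocount.** The reported PWM re-normalizes the final expected
  counts with 0.1 per cell, so log-odds scores are finite everywhere.

**Discovery significance** is an empirical E-value rather than an
analytic one: the same "best seed, then EM" objective is recomputed on
`n_null` dinucleotide-preserving shuffles (Altschul–Erickson Eulerian
rearrangement, preserving all dimer counts and endpoints) *and on the
real set with the identical short procedure*, so the observed value
carries the same seed-selection optimism as the nulls; the empirical
p-value `(1 + #{null ≥ obs})/(n_null + 1)` is multiplied by the number
of widths examined. With the default 50 shuffles the smallest
attainable E-value is `n_widths/51`; the E-value is a screening
statistic here, and planted-motif recovery — not a tiny E-value — is
the acceptance property. Motif–library comparison (the known-motif
role) uses the best Pearson correlation of aligned probability columns
over all offsets and both orientations (minimum overlap
`max(4, floor(min(w)/2))`), a column-permutation p-value, and
Benjamini–Hochberg q-values across the library.

# Allele scanning

Variants are normalized to a minimal representation (shared leading and
trailing allele bases trimmed, position advanced over leading trims),
so a VCF anchored record and a dash-notation record ("-/G") meet in the
same form. For each variant, `seq_ref` and `seq_alt` are built from 30
bp of identical flanking sequence on each side of the respective
allele; an insertion therefore gives 60 vs 61 bp, a 12-bp deletion 72
vs 60 bp.

Scanning uses base-2 log-odds against an order-0 background fitted to
the dataset's active-region sequences (discovery keeps its order-1
model; scanning follows the common order-0 convention of
occurrence scanners). The null distribution of a window score is
computed **exactly** by dynamic programming: the log-odds matrix is
discretized to an integer grid (1000 bins over the total score range —
the tests verify agreement with exhaustive enumeration of all `4^w`
windows on the same grid, and that discretization distorts any real
score by at most `w/2` bins), and the per-position score distributions
are convolved to give P(score ≥ s). The best hit over all windows and
both strands (ties: forward strand, then smallest offset; N-containing
windows skipped) yields `Sc_REF, P_REF, Sc_ALT, P_ALT` per variant ×
motif × dataset. The whole flanking sequence is scanned, as an
occurrence scanner would; because the flanks are identical strings,
any allelic difference necessarily involves the allele.

# The allelic-difference statistic

Within one dataset, all variant×motif pairs where at least one allele
matches nominally (min(P) < 0.05, strict) form the empirical
distribution of differences `d = P_REF − P_ALT` (and separately
`d = Sc_REF − Sc_ALT`). For a pair with observed difference `d_obs`,

    z = (mean(d) − d_obs) / sd(d),    E_diff = 2 (1 − Φ(|z|)),

with the sample (n−1) standard deviation. The eligibility restriction
makes the statistic conservative by construction. Differences are taken
on raw p-values and raw scores; a switch offers −log10 p differences
for sensitivity analyses. Pass flags use the Bonferroni bound
`0.01 / n_datasets`. A dataset with fewer than 3 eligible pairs is
skipped; a zero-spread distribution returns E = 1 with a warning.

The normal conversion is exact for exchangeable Gaussian differences
(verified against numerical integration to 1e-10, with type-I control
on neutral Gaussian fixtures). On realistic scan output the `d`
distribution is a point mass at 0 (best hit in the shared flank) plus
heavy tails, and the z-score is then anticonservative in the extreme
tail — a property of the statistic itself, visible in the benchmark
below.

# TF affinity (TRAP) arm

For each window, the mismatch energy is
`E = (1/λ) Σ_i ln(p_max,i / p_base_i,i)` (0 for the consensus), the
occupancy `R0 e^{−E} / (1 + R0 e^{−E})` with
`ln R0 = 0.584 w − 5.66`, and the affinity is the occupancy sum over
both strands — λ = 0.7 and the R0 coefficients being the published
defaults of the TRAP energy model, exposed in `trap_params()`. P-values
are empirical against order-0 background sequences of matched length
(1000 by default; the human-promoter background of the original server
is replaced by the bundle's own background model, recorded in output
metadata). The allelic effect is `|log10 P_REF − log10 P_ALT|`,
reported to 2 decimals, with pairs ranked so the strongest difference
has the smallest percentile. Deep-learning TF models are out of scope
by design (trained weights are not re-implemented).

# The synthetic bundle

`sim_config()` defaults define the study conditions: 2 × 200 kb
chromosomes at GC 0.5; exons covering ~10%; 200 enhancers (truncated
normal lengths, mean 400 sd 150, clamped to 100–1000 bp, ≥ 100 bp
apart, avoiding exons — the 10²–10³ bp peak scale); one planted 12-bp
PWM at ~1.5 bits/column carried by 70% of enhancers (sites sampled
from the PWM, not the bare consensus); one cell type with H3K4me3 and
H3K27ac, two replicate samples each, peak borders jittered ≤ 20 bp;
fold changes Gamma(shape 2, scale 3) so roughly a quarter of calls
fail the ≥ 3 filter; q-values drawn log-uniform with a 15% failing
fraction; coverage 2 inside enhancers and 0 outside; 100 variants with
10% disruptive. These were chosen once as a realistic miniature of a
sparse-replicate histone ChIP compendium; q-values are drawn, not
derived from a read model — the generator emulates statistical
structure, not ChIP-seq realism, so passing tests speak to the
method's behavior under the stated structure, not to mapping, peak
calling or LD artifacts in real data.

Disruptive variants cycle through three constructions: an SNV at the
motif's most informative column mutated to its least probable base; a
deletion (1–10 bp) centred in a planted site; and a **creator
insertion** — a copy of the consensus with its central base removed is
written into background sequence, and the variant inserts that base
back, so the ALT allele carries the intact site — the classic pattern
of a protective G insertion creating a regulatory motif. The
central insertion point mirrors the centred deletion and maximizes the
REF-side frameshift. Neutral variants (mostly SNVs, every fifth an
insertion) sit ≥ 60 bp from anything planted. Indel records are stored
in fixed-point canonical form so a VCF write/read round-trip is exact
even next to an identical base. Everything is byte-deterministic under
the seed.

# Numerical and design choices

- Bookended intervals merge (union semantics of pooled peaks); bases
  absent from a coverage track are depth 0 (sparse bedGraph
  convention), with the covered-bases-only mean exposed as a switch
  because summary tools differ on this.
- Peaks failing the RNA gate are removed per sample, before pooling.
- Overlapping pooled peaks are merged by default; discovery operates
  on merged regions.
- Scan scores are base-2 log-odds; score scales of external scanners
  are not comparable numerically, only directionally.
- The Bonferroni-derived overlap bound (0.01 / n motifs / n variants)
  is the default significance rule; an explicit threshold can be
  supplied instead where a different printed value is preferred.
- RNG discipline: every stochastic helper takes a seed, saves and
  restores the caller's RNG state, and the generator derives its
  stage seeds from the master seed by small offsets.

# Problem sizes and the benchmark

The packaged tests and the acceptance script run the full workflow at
fixture scale: discovery fixtures of 200 × 100 bp sequences;
enumeration oracles up to width 6; and five end-to-end replicates of
the default bundle with the pipeline set to 2 motifs/dataset, widths
6–14 and a 120-sequence discovery subsample — sizes chosen so each
replicate recovers the planted motif in seconds to minutes while
exercising every stage.

On this benchmark the score-based `E_diff` pass set detects deletion
and creator-insertion disruptors essentially always and yields a
false-positive rate at or near 0 (well under 0.05), but single-column
SNV disruptors rarely pass: destroying one 1.5-bit column moves the
best-hit score by ~5 bits, about 2 standard deviations of the
pair-difference distribution, short of the 0.01/n_datasets bound. The
median sensitivity over all disruptive variants (40% of which are
SNVs under the cycling construction) therefore plateaus around 0.6–0.7
rather than 0.8. This is the method's documented indel bias — the
score-difference statistic captures only the most striking, typically
indel-driven, match changes — and we report it as a finding of the
benchmark rather than re-weighting the generator's disruptive-variant
mix to mask it.

# Known limitations

- The empirical discovery E-value is resolution-limited by `n_null`
  and is not comparable to analytic E-values of other motif suites.
- `E_diff` relies on a normal approximation that is anticonservative
  on heavy-tailed, zero-inflated difference distributions; its
  pass flags should be read jointly with the score direction.
- The affinity null uses genome-background sequences, not a promoter
  background; absolute affinity p-values shift accordingly while the
  allelic difference is robust to the choice.
- bigWig input is out of scope; coverage is read from bedGraph.
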