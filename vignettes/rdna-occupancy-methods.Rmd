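---
title: "Methods: input-normalized rDNA occupancy mapping, release kinetics, and gel densitometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: input-normalized rDNA occupancy mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnamap)
```

# The problem

Mouse cells carry a few hundred ribosomal RNA gene repeats of about 45.3 kb,
each holding one 47S transcription unit and a long intergenic spacer (IGS).
Because the repeats are near-identical, ChIP-Seq reads from all of them pile
onto a single rDNA reference added to the genome as an extra chromosome,
giving per-base coverage deep enough to map transcription-factor occupancy
at essentially nucleotide resolution. Two complications drive the design of
this package:

1. **Sequence-dependent coverage bias.** Raw coverage on the rDNA is
   strongly, but reproducibly, shaped by the underlying sequence, identically
   so in ChIP and input libraries. Dividing the ChIP track by a matched input
   track cancels this bias; everything upstream of that division
   (extension, coverage, smoothing, depth scaling) exists to make the two
   tracks commensurable.
2. **Repeat geography.** In the reference's native numbering, which starts
   at the 47S initiation site, the upstream regulatory elements (Spacer
   Promoter, Enhancer repeats, 47S Promoter) sit at the far end of the
   sequence. Displacing the origin of the circular repeat to the EcoRI site
   at native position 30,493 makes the functional gene unit contiguous; the
   initiation site then falls at position 14,815.

# The coverage model

For each library the pipeline runs a fixed stage order:

1. **Extension.** Single-end reads are extended to the estimated fragment
   length, 100 bp by default (fragment-size estimates fall between 75 and
   125 bp), anchored at the 5' end.
2. **Coverage.** `j(n)` counts fragments overlapping base `n`.
3. **Smoothing.** `J(n) = (1/w) * sum(j[n-k..n+k])` with `w = 25` bp. The
   window must be odd so it is centred; at track ends the window is
   truncated and the divisor reduced (linear mode) or wrapped (circular
   mode). Circular smoothing conserves the track total exactly.
4. **Depth scaling.** Reads per million, using the total aligned reads of
   the whole library — not just rDNA reads — so the subsequent ratio is
   depth-independent.
5. **Input normalization.** `Jnorm(n) = Jchip(n) / Jinput(n)`.

Smoothing and RPM scaling are both linear, so their order is immaterial;
the package asserts this as a property test.

## Numerical choices

* **Input floor.** The ratio is undefined where input coverage drops out.
  Rather than adding a pseudocount, which silently inflates enrichment in
  dropout regions, bases where smoothed input RPM falls below 5% of the
  input-track median are masked (`NA`) and carried as an explicit mask. The
  floor fraction is a documented, configurable choice; no specific value is
  claimed to match any published analysis.
* **Linear by default.** The repeat is carried as a single-copy linear extra
  chromosome in real alignments, so fragments are clipped at the reference
  ends by default. A circular mode (wrap at both extension and smoothing)
  is available and is what the conservation properties are stated in.
* **Strands are pooled** after extension; occupancy is unstranded.
  Duplicate fragments are retained: at rDNA coverage depths duplicate
  positions are expected from distinct molecules, and no deduplication is
  attempted.

# Release kinetics

The initiation factor Rrn3 joins RNA polymerase I for initiation and is
lost from the elongating complex. If release is stochastic with a constant
rate, the probability that a polymerase at distance `d` from the initiation
site still carries Rrn3 is `exp(-d / Lc)`, so the Rrn3 enrichment profile
downstream of the TSS is modelled as

```
E(d) = A * exp(-d / Lc) + B
```

fitted by constrained Levenberg-Marquardt least squares (`A > 0`, `Lc > 0`,
`B >= 0`) on the input-normalized enrichment itself. A log-linear fit is
deliberately avoided: the baseline `B` and near-zero tail values make the
log transform ill-posed. With a constant elongation rate `v` (60 nt/s by
default) the spatial decay length converts to a temporal half-life
`t_half = Lc * ln(2) / v`.

* **Fit window.** 200–6000 bp downstream of the TSS by default. The lower
  edge excludes the promoter-proximal pre-initiation peak, which is not part
  of the elongation-release process; the upper edge spans several decay
  lengths of the expected signal while staying inside the transcribed
  region. Both are configurable; recovering decay lengths much beyond
  ~1.5 kb benefits from a wider window (the parameter-recovery tests use
  `4 * Lc`), because a short window cannot separate a long decay from the
  baseline.
* **Multi-start.** The least-squares surface has a spurious minimum at
  `Lc -> 0`, where the exponential term vanishes over the whole window and
  the baseline absorbs the mean. The fit therefore starts from five decay
  length scales spanning `window/60` to the full window and keeps the lowest
  deviance.
* **No-decay flagging.** A fit whose decay length is pinned at its upper
  bound, or whose amplitude is below twice the residual RMS (or negligible
  against the profile level), is flagged rather than converted into a
  half-life; degenerate profiles must not produce silent numbers.

# Feature statistics and peak calls

Feature summaries (mean, max, share of total reference signal) are computed
over unmasked bases of annotated intervals; intervals may wrap the repeat
origin (`start > end`), as the 47S promoter region does in native
coordinates. Peaks are the argmax of the already-smoothed enrichment inside
a bounded window (default ±200 bp) around a named anchor — an intentionally
local operation, since peak offsets on the rDNA are read off profiles, not
called genome-wide. Ties break toward the anchor and no sub-bp
interpolation is attempted, because offsets are reported in integer base
pairs. Ratio statistics come in a single-track form (mean over feature 1 /
mean over feature 2) and a paired form in which a common scale factor
between two tracks cancels.

# Gel densitometry

Psoralen crosslinking separates nucleosome-free ("active", low mobility)
from nucleosomal ("inactive", high mobility) repeat DNA on a gel. The lane
intensity trace is fitted with an optional linear baseline plus two
Gaussians; the component at the smaller migration coordinate is labelled
active. Fractions use **areas** (`amplitude * sigma * sqrt(2*pi)`), not
amplitudes. Initialization mimics automatic peak picking: the two largest
local maxima of a lightly smoothed trace seed the centres and half-width at
half-maximum seeds the widths. Single-peak traces yield a flagged
single-component fit with the other area zero. The standard error of the
active fraction comes from a seeded residual-resampling bootstrap that
refits the *same* model structure — re-running model selection inside the
bootstrap would let noise-born second components contaminate the SE.

# The synthetic generator

`mef_scenario()` builds the study conditions with known ground truth; its
defaults are the conditions under which all recovery tests run:

* Rrn3 release half-life 15 s at 60 nt/s (decay length 1298.3 bp);
* a stalled polymerase point source 24 bp downstream of the Spacer
  Promoter initiation site, with the spacer terminator's TTF1 peak 13 bp
  further downstream;
* active repeat fraction 0.64; histone tracks are sampled from a mixture in
  which inactive repeats are nucleosomal throughout and active repeats
  carry histone only in the IGS. The complementary inactive fraction is
  taken as `1 - 0.64 = 0.36`;
* point-source footprint 50 bp (Gaussian with `sigma = footprint/4`) — a
  conventional protein-footprint scale, since no measured widths exist for
  these factors;
* fragment lengths uniform on 75–125 bp;
* a shared multiplicative bias field derived from the windowed GC content
  of a simulated repeat sequence (gene body GC-rich over a ~45% background),
  spanning a three-fold range by default.

Reads are simulated by drawing a crosslink position with probability
proportional to `occupancy * bias` and placing a fragment uniformly among
the positions that cover it. Drawing fragment *start* positions from the
occupancy profile directly — the obvious alternative — produces
strand-split pileups whose pooled, extended coverage has a ~150 bp flat top
over a point source, which no peak caller can localize; anchoring fragments
to the crosslink point reproduces the triangular, correctly centred pileups
that extension is designed for. For mixture factors the per-read choice of
repeat state is weighted by each state's total occupancy mass, which is
exactly sampling from the population-average profile; weighting by repeat
abundance alone would under-represent states with more bound protein.

## What the generator does not emulate

Mappability structure, PCR duplication, fragment-length dependence on GC,
read errors, and alignment artefacts are all absent; fragments are placed
directly, so tests passing on this generator demonstrate correctness of the
analysis given ideally aligned positions, not robustness to upstream
artefacts. The repeat sequence is random with a designed GC profile, not
the real repeat sequence, and the feature coordinates outside the
promoter-region amplicons are conventional approximations.

# Problem sizes

The recovery analyses are sized to be statistically comfortable while
keeping the full suite fast: 2×10^5 reads per library and 20 seeds for the
half-life and histone-ratio recoveries, 10^4-read factor libraries against
2×10^5-read inputs for peak geometry (at equal 10^4 depths the input noise
in the ratio denominator dominates peak localization), and 50 seeded lanes
at 2% intensity noise for the gel fits. Median recovered half-life is
within a few percent of the 15 s ground truth; recovered peak offsets sit
within ±3 bp of the planted geometry.

# Known limitations

* The exponential release model is phenomenological; no mechanistic
  polymerase translocation is simulated, and pausing would bias `Lc`.
* The half-life conversion assumes a single constant elongation rate; any
  error in `v` scales the half-life linearly.
* Enrichment ratios are descriptive; the package deliberately provides no
  significance testing for enrichment differences.
* With a single detectable gel band the active/inactive identity of the
  lone component cannot be inferred from the trace alone; the fit labels it
  active and flags the fit, leaving interpretation to the caller.
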