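---
title: "Analysing CRISPRi radiation modifier screens with radmod"
author: "radmod maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing CRISPRi radiation modifier screens with radmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmod)
```

# The experimental design this package models

A pooled CRISPRi modifier screen asks which gene knockdowns change how
cells grow under a treatment — here, clinically fractionated ionizing
radiation in glioma cells. A lentiviral library of sgRNAs (typically 10
per targeted TSS, plus on the order of a thousand non-targeting
controls) is infected into dCas9-KRAB cells in replicate. Cultures are
split into a treated arm (radiation delivered in 2 Gy fractions) and an
untreated growth arm, propagated for about twelve days, and the sgRNA
cassettes are counted by sequencing at the start (`T0`) and end
(`Tfinal`) of the screen. Knockdowns that change fitness shift their
guides' abundance between the two timepoints.

`radmod` takes the count tables from such a screen through phenotype
computation, gene scoring, empirical-FDR hit calling, neighbor
filtering, and radiation-sensitizer classification, and provides the
growth-assay statistics (doubling times and a Bliss-independence synergy
test) used to validate individual hits. A negative-binomial simulator
with known ground truth stands in for raw screen data in all tests.

# Data containers

Counts live in a `ScreenExperiment`, an S4 class extending
`SummarizedExperiment`: one `"counts"` assay (non-negative integers),
guide annotation (`target_id`, `is_control`, `protospacer`) in
`rowData`, and sample keys (`timepoint`, `replicate`, `arm`) in
`colData`. Validity checks enforce unique sgRNA ids, the reserved
non-targeting label, and exactly one sample per
(timepoint, replicate, arm).

TSS records are width-1 `GRanges`. On disk they are BED6(+biotype),
0-based half-open, with the TSS at `chromStart` for `+` records and
`chromEnd - 1` for `-` records; in memory `GRanges` is 1-based, which
leaves every point distance unchanged.

# The phenotype

For guide $s$ in one replicate and arm, with pseudocount $pc$ and sample
totals $N$:

$$\mathrm{raw}(s) = \log_2 \frac{c_{final}(s) + pc}{N_{final}}
                  - \log_2 \frac{c_{T0}(s) + pc}{N_{T0}},
\qquad
\mathrm{phenotype}(s) = \mathrm{raw}(s) - \mathrm{median}_{ctrl}(\mathrm{raw}).$$

Centering on the *median* of the non-targeting guides (rather than the
mean) is robust to the occasional active control; it makes the control
median exactly zero per replicate and arm. Replicates are combined by
arithmetic mean of the centered per-replicate phenotypes, and the
centering is done per replicate (not on pooled replicates) so that a
depth or growth difference between replicates cannot leak into the
average. Phenotypes are invariant to rescaling any sample's sequencing
depth, and relabeling the two timepoints negates them.

Two tunable parameters matter here:

* `pseudocount` (default 1.0 read): guards the logarithm at zero
  counts. At the recommended 1000x coverage a pseudocount of 1 shifts a
  typical guide frequency by under 0.1%. A value of 0 is accepted for
  exact-arithmetic work on strictly positive counts.
* `per_doubling` (default off): phenotypes are deliberately *not*
  divided by population doublings — the screen-score convention is plain
  relative log2 enrichment. Users wanting per-doubling growth-rate units
  can switch this on and supply the per-arm doubling counts.

`zStandardize()` divides gene-level phenotypes by the sample standard
deviation (n − 1 denominator) of pseudogene phenotypes; no mean is
subtracted because control centering has already anchored zero.

# Gene scores, pseudogenes and the empirical FDR

A gene's score is the signed mean of its three largest-|phenotype|
guides multiplied by $-\log_{10}$ of the two-sided Mann-Whitney U
p-value of all its guides against all non-targeting guides. Ranking the
top three by magnitude (while averaging signed values) preserves
direction and matches the established screen-scoring lineage; a p-value
of 1 forces a score of exactly 0. The Mann-Whitney test uses the exact
null distribution when the pooled sample is small (n + m ≤ 12, no
ties) and the tie-corrected normal approximation with continuity
correction otherwise; in the package's operating regime (a handful of
guides against a pool of hundreds of controls) the two branches agree
to well under 0.02 in p.

Significance is *not* controlled per gene. Instead, "pseudogenes" —
seeded, disjoint groups of `group_size` (default 10) non-targeting
guides, re-partitioned over `n_rounds` (default 5) shuffling rounds —
are scored exactly like genes, except that each pseudogene's own members
are excluded from its control pool to avoid self-comparison bias. The
empirical FDR at a candidate threshold $T$ is the pseudogene pass rate
scaled to the number of real genes over the observed number of passing
genes, and the chosen threshold is the smallest |score| grid value at or
below the target (default 0.0025, the operating point at which a score
threshold of about 5 emerges in the screens this package models). Five
rounds give 600 pseudogenes from 1202 controls, which keeps the
threshold grid reasonably fine; disjointness within a round keeps
pseudogenes independent there, and the residual correlation across
rounds only makes the procedure slightly conservative. Hits are
|score| ≥ threshold (an inclusive boundary, applied to the absolute
score so that protective hits — positive phenotypes under radiation —
are retained alongside sensitizing ones); direction follows the sign of
the top-3 mean.

On simulated pure-null screens (20 seeds of 1000 genes and 1202
controls) the test suite verifies that the realized false-call fraction
stays below the binomial envelope of the 5% target and lands inside the
two-sided envelope of the 0.25% operating point (about 2–3 calls per
1000 genes).

# Neighbor filtering

CRISPRi acts on any TSS within roughly 1 kb of the sgRNA site, so a hit
whose lncRNA TSS sits within `window_bp` (default 1000, inclusive) of a
protein-coding TSS *expressed in the screened line* may simply be
knocking down its coding neighbor. `classifyNeighbors()` computes
strand-agnostic point distances on the same chromosome, applies a TPM
floor (`tpm_min`, default 1.0 — the published cut is not knowable, so
the parameter is exposed) and flags a gene as a neighbor hit if *any* of
its annotated TSSs triggers the rule — the conservative choice, since
neighbor hits are excluded. When an expressed coding TSS exists on the
chromosome the nearest expressed one is reported; otherwise the nearest
unexpressed one is reported with `pc_expressed = FALSE` (and can never
be a neighbor). `partitionHits()` then splits the hit list into retained
lncRNA hits and excluded neighbor hits.

# Sensitizers and lncGRS ranking

`compareScreens()` joins the radiation-arm and growth-arm score tables
on shared targets at one common threshold (both screens must clear the
same bar). The sensitizer score is the ratio of radiation score to
growth score; a gene is a sensitizer iff it is a hit in both screens,
its radiation score is larger in magnitude than its growth score, and
its radiation phenotype is growth-inhibiting. The magnitude comparison
(rather than a signed one) plus the direction requirement ensures
protective hits can never classify as sensitizers. `rankLncgrs()` keeps
sensitizers expressed above `tpm_min` in *all* lines of a glioma panel
and ranks them by descending sensitizer score as lncGRS-1, lncGRS-2, …

# Growth-assay statistics and the synergy test

`doublingTime()` fits log2 counts against time by least squares and
returns the reciprocal slope, erroring when the fitted slope is not
positive. `fractionalDecrease()` is `1 - mean(treated)/mean(control)`.

The additive null for combining two treatments is Bliss independence:
survival fractions multiply, so
$f_{pred} = 1 - (1 - f_a)(1 - f_b)$. With a 71% decrease from radiation
alone and a 42% decrease from knockdown alone the predicted combined
decrease is $1 - 0.29 \times 0.58 = 0.8318$, i.e. 83% — the product of
the *decreases* themselves (0.30) would be inconsistent with any
observed combined effect and is not a null model of independence.

`synergyTest()` is a two-sample, two-tailed, pooled-variance Student's
t test (df = $n_1 + n_2 - 2$) of the observed combined decreases
against per-replicate predicted decreases, with synergy declared only
when the observed mean *exceeds* the prediction and p < `alpha`. The
pooled-variance form is computed directly so that the degenerate case
(observed ≡ predicted) is defined as t = 0, p = 1 rather than an error.

How the per-replicate predictions are paired was a genuinely open design
choice, and we settled it by type-I calibration at the n = 2 replicates
typical of these assays. Replicating a scalar prediction collapses the
prediction sample's variance and inflates the type-I error of the
two-sample test to ~27%; predictions built against the mean control
still run ~7%. `analyzeSynergy()` therefore forms predictions
batch-wise — each replicate's single-treatment survival ratios are taken
against that replicate's *own* control measurement and multiplied —
which puts batch-level measurement noise into the prediction sample the
way it enters the observations and holds the empirical type-I error at
4–5% across independent 1000-run batches (verified in the test suite),
with ~99% power against a 1.5-log2 interaction at 5% measurement noise.

# The simulator

`simulateScreen()` draws initial guide frequencies from a lognormal
(sigma `abundance_sigma`), multiplies guide $g$'s frequency by
$2^{D \cdot a_g (\gamma + \delta \cdot 1[\mathrm{radiation}])}$ over the
arm's $D$ doublings, renormalizes, and draws counts from a negative
binomial (variance $\mu + \phi\mu^2$) at the configured depth,
independently per replicate; both arms share each replicate's T0 counts,
mirroring a culture split after selection. Guide activity $a_g$ is Beta
distributed, which stresses the top-3 scoring the way variable guide
potency does in real libraries. Controls have $\gamma = \delta = 0$.

Default study conditions (fixed once, in `simConfig()`): 1000 genes x
10 guides + 1202 non-targeting controls; depth 1000x the library size;
7.1 doublings in the radiation arm and 14.2 without radiation
(fractionated 8 Gy approximately doubles the doubling time, and the two
arms run for the same twelve days); growth effects
$\gamma \in [-0.20, -0.05]$ per doubling for 10% of genes; sensitizer
interactions $\delta \in [-0.50, -0.25]$ on 5% of genes (which also
carry a growth effect — a sensitizer must be a hit in both arms);
protective interactions (mirrored positive $\delta$, $\gamma = 0$) on
2%; Beta guide activity with mean 0.75 and concentration 4; NB
dispersion 0.01; lognormal abundance sigma 0.5. Sensitizer interactions
are drawn larger in magnitude than growth effects because, with the
untreated arm accumulating twice the doublings, a radiation score can
only exceed its growth counterpart when $|\gamma + \delta|$ beats
$2|\gamma|$ — the same asymmetry a real radiation-modifier screen faces.

What the simulator does *not* emulate: selection dropout dynamics,
fraction-by-fraction radiation kinetics within the screen window,
guide-level off-target effects, or replicate-specific batch effects.
Passing recovery tests on simulated screens therefore demonstrates that
the statistical machinery is correct and calibrated under a faithful
noise model — not that any particular biological screen will reach the
same sensitivity.

`simulateAnnotation()` plants TSS geometry (expressed neighbors within
the window, unexpressed decoys, distant coding genes) and a TPM panel;
per-line lncRNA expression probability defaults to 0.77 so that roughly
a quarter of sensitizers survive the all-five-lines filter, similar to
observed glioma panels. `simulateGrowthAssay()` produces
control/A/B/AB replicate tables with a configurable excess interaction
on the log2 scale.

# Problem sizes used by the test suite

Unit and property tests run on scaled-down screens (200 genes, 300
controls) over seeded batches (20 recovery replicates, 50 ranking
replicates); the calibration checks run the full default geometry (1000
genes, 1202 controls) over 20 seeds, the default-config sensitizer
recovery at seed 7, and 1000 seeded growth assays for synergy type-I
error. These sizes are the package's own choices for routine
verification; all of them are re-derived at run time — no fixture data
ship with the package.

# Known limitations

* The empirical-FDR estimator assumes pseudogenes are exchangeable with
  true null genes; strong guide-composition artifacts (e.g. grossly
  unequal guides per gene) would violate that.
* The sensitizer definition compares score magnitudes at a single common
  threshold; genes sitting just under threshold in one arm are not
  rescued by strength in the other.
* `doublingTime()` assumes a single exponential phase; it will average
  over any lag or plateau present in the time course.
* With two replicates the synergy test has df = 2; only large excess
  effects reach significance, which matches the validation-assay use
  case but is not a substitute for a dose-response design.
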