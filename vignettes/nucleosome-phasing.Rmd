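---
title: "Distance correlations and sequence periodicity in nucleosome positioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance correlations and sequence periodicity in nucleosome positioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucphase)
```

## The problem

Paired-end sequencing of micrococcal-nuclease (MNase) digested chromatin
yields, for each nucleosome, the genomic interval of its protected DNA.
After restricting to core-particle lengths (147–152 bp), every analysis in
this package treats the data as a multiset of strandless intervals: how
often each position is occupied is the signal, so duplicate fragments are
never collapsed.

Two structural scales matter. *Translational* positioning — where the
nucleosome's dyad sits along the DNA — produces the nucleosome repeat
length (NRL, ~160–165 bp in budding yeast). *Rotational* positioning —
which helical face of the DNA contacts the histones — means that
alternative overlapping positions at a locus differ by multiples of the
DNA helical period (~10.25 bp), forming *position clusters*.

## The distance auto-correlation (DAC)

For a set of anchor positions $i$ with occurrence counts $c_i$ on one
chromosome, the multiplicity-weighted DAC at distance $d$ is

$$\mathrm{DAC}[d] \;=\; \sum_{i<j,\; j-i=d} c_i\, c_j ,$$

so a pair of positions occupied 5 and 10 times contributes
$5\times 10 = 50$ to its distance bin. The histogram is computed once on
left anchors (fragment starts) and once on right anchors (fragment ends)
and the two are summed; for strandless double-stranded fragments this is
the natural reading of counting start-to-start distances "on both
strands". The *coincidence* weighting clamps every count to 1 and recovers
the unweighted start-to-start statistic; the multiplicity weighting is far
more sensitive to changes at strongly occupied positions — two positions
occupied 19 and 5 times raise their distance bin by 95, not by 1. The
self-distance bin $d=0$ holds the within-position pair count and is
flagged; plots and peak detection skip it. The cross-correlation (DCC)
between two datasets sums $c^{(a)}_x c^{(b)}_y$ over ordered pairs with
$|x-y| = d$.

Internally each chromosome's sparse count vector is autocorrelated by FFT
(zero-padded past the maximum lag, so no circular wrap reaches the
reported distances) and the result is rounded back to exact integer pair
counts; an $O(n^2)$ enumeration oracle in the test suite checks the FFT
path on random instances.

Distances are only defined within a chromosome. Anchors may be fragment
starts or centers; centers use the dyad convention below. The two give
nearly identical histograms for fixed-length fragments, since all anchors
shift together.

### Dyads and coordinates

Coordinates are 0-based half-open internally (BED convention) and 1-based
inclusive in everything reported. The *dyad* is the central base of a
fragment; for even lengths the center falls between two bases and is
rounded **up**. In 0-based terms, `dyad = start + length %/% 2`. The
simulator emits fragments whose sampled lengths are centered on the true
dyad so that this rule recovers the truth exactly — a property the test
suite asserts.

## Estimating the repeat length and the helical period

Peak positions of the DAC are regressed on harmonic indices; the slope is
the period. Two scales use two smoothing settings:

* **sub-peaks** (the ~10-bp lattice): centered moving average of width
  3 bp. Peaks on a plateau report the plateau center.
* **main peaks** (the ~160-bp lattice): width 41 bp. Four helical turns is
  deliberate — a moving average of width $4\times 10.25 \approx 41$
  exactly nulls a 10.25-bp periodic component, so the rotational fine
  structure cannot displace the broad repeat-length peaks. (A narrower
  21-bp window leaves enough ~10-bp ripple that the maximum bin of a broad
  peak lands on a ripple top several bp off-center.) For broad peaks the
  optional `refine = "centroid"` replaces the maximum bin by the
  baseline-subtracted intensity centroid within one smoothing window.

Harmonic indices are `round(position / period_guess)`; repeats are
allowed, so the members of a split first peak (e.g. sub-peaks at 151, 162
and 171 bp around one repeat) all regress at index 1. An index of zero is
an error rather than being clamped — it signals a bad period guess, and
silently promoting it to 1 would corrupt the fit.

On simulated data the package fits sub-peaks over 5–90 bp. Distances
below ~90 bp can only arise from overlapping (within-cluster) positions,
where the rotational lattice is clean; beyond ~8 turns the within-cluster
pair mass has decayed to the point where detected maxima are dominated by
smeared neighbor-repeat structure. This is an analysis-window choice, not
a property of the estimator.

### Envelope continuity

The envelope of a DAC profile is the sequence of its values at the
sub-peaks. A population in which all arrays share one spacing yields a
smooth U-shaped envelope (within-cluster mass decaying, then the left
flank of the first repeat peak rising); coexisting spacings disturb it.
`envelope_discontinuity()` scores the largest positive jump between
consecutive envelope values inside a probe window, normalized by the
median absolute consecutive change outside the window, and calls a
discontinuity above a threshold of 3.

A caveat found during development and verified by the test suite: a
spacing *mixture* in which the long component's repeat length is drawn
smoothly (uniform 180–250 bp per cell) fills the envelope valley and moves
its upturn earlier, but produces no localized jump — the old-by-new pair
distances form smooth uniform bands. A sharply localized break requires
re-positioned nucleosomes at *discrete* offsets (~90–140 bp) from the old
positions, which the smooth mixture does not generate. The
mixture-location check in the acceptance suite documents this honestly
rather than relaxing the statistic.

## Occupancy, composites and dyad maps

Raw occupancy of a base is the number of fragments covering it; tracks are
normalized by the genome-wide mean coverage per bp, so the normalized
track has mean exactly 1 and libraries of different depth are comparable.
Composite TSS profiles average the normalized track across genes in
transcription coordinates (minus-strand genes are flipped); each usable
gene contributes equally, and genes whose window leaves the chromosome are
dropped with a warning rather than padded, to avoid edge artifacts in the
mean. The default window is 500 bp upstream to 2000 bp downstream.
Dyad histograms count fragment midpoints (round-up rule) per base of a
region — the per-locus view in which position clusters are visible.

The +1 nucleosome of a gene is defined by dyads falling in gene
coordinates [+1, +140] (the transcription start site is +1); −1 and +2
windows default to [−180, −41] and [+141, +300] and are configurable,
since only the +1 window is anchored in an explicit definition. Induction
groups sort genes by fold-change with ties broken lexicographically by
gene identifier, so the split is deterministic; group sizes default to the
ceiling of the requested fraction and can be overridden (a printed group
of 45 out of 234 genes corresponds to a slightly different rounding than
ceiling(0.2·234) = 47, so the size is a parameter, not a constant).

## WW/SS dinucleotide profiles

Sequences are extracted in a fixed dyad-centered frame — 73 bp plus the
linker extension (default 20 bp) on each side of the dyad — so cores of
147–152 bp share the 147-bp core frame with the dyad between base-pair
steps 73 and 74 (step 73.5). Fragments of minus-strand genes are
reverse-complemented so all rows read with transcription. At each step the
fraction of sequences whose dimer is WW (AA, AT, TA, TT), SS (GG, GC, CG,
CC), WS or SW is computed; steps containing N are excluded from that
step's denominator so the four classes always sum to 1 where defined.
Symmetrization averages the profile with its mirror image about the
central step; smoothing is a centered 3-bp running mean applied after
class fractions (and after symmetrization), with truncated edge windows.

### MNase cut contexts

Cut-site coordinates follow one convention everywhere: position 0 is the
last genomic base 5′ of the fragment and +1 the first fragment base; the
3′-end context is reverse-complemented into the same frame, so both ends
of every fragment contribute to the consensus. The consensus display rule
is: the plurality base when its frequency exceeds 0.5, else W or S when
that class reaches 0.75, else N — under which a T-rich cut with ~50% T but
>80% W prints as W or T exactly as the positions warrant.

The *non-preferred-cut subset* keeps fragments whose (0, +1) cut dimer is
not WW at both ends (`rule = "no_ww"`). With ~80% of cuts being W|W this
retains a few percent of fragments — consistent with the ~7% retention the
robustness comparison is designed around. The stricter reading (no A or T
at either cut position, `rule = "no_w"`) retains an order of magnitude
less and is kept as an option. Comparing the subset's core-region WW
profile with the full set's tests whether the observed periodicity is a
cleavage-bias artifact; on synthetic data with a planted signal the two
agree within 0.02.

On an i.i.d. genome with A+T fraction $w$, a WW dimer starts at any
position with probability $w^2$, so the expected spacing between possible
W|W cut sites is $1/w^2$ — about 3 bp at 60% AT, which is why the cut
preference barely constrains where core fragments can end.

## The simulator

`simulate_arrays()` generates the cell ensembles the analyses are tested
against; `simulate_genome_and_cuts()` adds a genome with a planted
rotational sequence signal and biased fragment ends. Design choices, all
fixed before the acceptance runs:

* **Loci.** Cells are divided among independent loci (default 24; the
  genome-scale recovery runs use 200), each a separate chromosome. Regular
  arrays at a locus share a frozen anchor lattice — that shared lattice
  *is* the position-cluster structure.
* **Repeat-length heterogeneity.** The regular component's repeat length
  varies between loci as `spacing + N(0, 5)` bp, reflecting observed
  peak separations of ~150–170 bp. Pooled over loci this keeps main DAC
  peaks centered on multiples of the nominal spacing while decohering them
  from the rotational lattice — without it, neighbor-repeat differences
  alias onto the 10-bp lattice and bias the helical-period fit. All
  regular arrays carry the same number of nucleosomes so that no repeat
  length is overweighted at any harmonic.
* **Rotational clusters.** Each nucleosome's dyad is offset by `k` helical
  turns, `k` drawn from a geometric distribution `0.6^|k|` over −7..7.
  The half-width of 7 turns lets within-cluster pairs differ by up to ~14
  turns, matching a sub-peak series that extends to ~144 bp; the geometric
  decay makes one dominant position per cluster. Offsets are realized on
  the integer lattice by *stochastic rounding* of `k × 10.25`, so the
  expected offset is exact and the pairwise difference lattice stays
  centered on multiples of the period (deterministic rounding loses the
  half-turns at `k = ±2, ±6` and flattens the fitted period).
* **Spacing mixture.** With probability `long_fraction` a cell's array
  instead uses a repeat length drawn uniformly from 180–250 bp, anchored
  at the same locus anchor — the two-population model of activated genes.
* **Fragment lengths** are uniform over 147–152 bp, centered on the dyad.
* **Sequence signal.** The genome is i.i.d. at 60% AT; around each true
  dyad the per-base W probability is modulated by
  `amplitude × cos(2π(i − dyad)/10.25)` within ±73 bp. The default
  amplitude used in the robustness checks is 0.05, chosen to reproduce a
  WW-fraction oscillation of roughly ±0.06 about its 0.36 baseline — the
  magnitude seen in real core-particle profiles.
* **Cut bias.** Fragment ends are re-sampled within ±2 bp of their nominal
  boundaries, each candidate weighted 12-fold when its (0, +1) dimer is
  WW; this yields W|W cut fractions in the 0.7–0.9 range.
* **Reproducibility.** One mandatory seed drives each generator; truth
  tables (per-nucleosome spacing model, base dyad, jitter index, realized
  dyad, fragment length) are first-class outputs so recovery tests never
  reach into the simulator's internals.

What the simulator does *not* emulate: nucleosome-free regions and +1/−1
asymmetry around promoters, remodeler-driven re-positioning with discrete
~90–140 bp offsets (see the envelope caveat above), mappability and
duplicate-read artifacts, and sequence-directed positioning (the planted
signal follows the simulated dyads rather than causing them). Passing
tests therefore demonstrate that the estimators recover the generative
parameters under the stated model, not that real chromatin satisfies that
model.

## Problem sizes and numerics

The test and acceptance runs use desk-scale ensembles chosen so that
Monte-Carlo error is comfortably inside each tolerance: 20 000 arrays over
200 loci (~460 000 fragments) for period recovery; 10 000 arrays over 50
loci (~110 000 core fragments, ~10 000 in the end-filtered subset) for the
cleavage-bias robustness check; 2 000 arrays over 24 loci for the envelope
comparisons. Histograms are exact integer pair counts (FFT results are
rounded; a brute-force oracle guards the path), regressions are ordinary
least squares via `lm`, and peak prominence uses flanking local minima
with a default threshold of 5% of the local baseline (2% in the envelope
analyses, whose sub-peaks sit on a tall shared pedestal).

## A minimal session

```{r example, eval = FALSE}
cfg <- array_sim_config(n_cells = 2000, region_length = 4000,
                        spacing = 162, seed = 1)
sim <- simulate_arrays(cfg)
h <- compute_dac(position_counts(sim$fragments, "start"),
                 max_distance = 1100)
sub <- find_peaks(h, smoothing_window = 3, from = 5, to = 90)
fit_period(sub$position, assign_indices(sub$position, 10.25))
```
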