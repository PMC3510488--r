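# nucphase

Nucleosome phasing analysis from paired-end MNase-seq fragments.

Chromatin is a chain of nucleosomes, each protecting ~147 bp of DNA.
Paired-end sequencing of MNase-digested chromatin yields one genomic
interval per nucleosome, and how often each position is occupied across
the cell population carries the structural signal. `nucphase` analyses
these fragment populations for users studying nucleosome organization —
repeat length, rotational positioning, promoter architecture and the DNA
sequence patterns underneath — without any nucleosome "calling" step.

The central statistic is the **inter-nucleosome distance auto-correlation
(DAC)**. For anchor positions $i$ with occurrence counts $c_i$ on a
chromosome,

$$\mathrm{DAC}[d] = \sum_{i<j,\; j-i=d} c_i\,c_j,$$

computed on left and right fragment anchors and summed. Two positions
occupied 5 and 10 times contribute 5 × 10 = 50 to their distance bin, so
strongly occupied positions dominate — unlike unweighted ("coincidence")
start-to-start statistics, which the package also provides. Peaks of the
DAC on the ~160-bp lattice measure the nucleosome repeat length; the
~10-bp sub-peak lattice measures the DNA helical period and shows that
overlapping nucleosome positions are rotationally related. Around these
sit supporting analyses: distance cross-correlation between datasets,
normalized occupancy tracks and TSS-aligned composites, dyad-position
histograms, WW/SS dinucleotide periodicity profiles with linker extension
and dyad symmetrization, MNase cleavage-consensus and end-bias robustness
filters, and a seeded cell-ensemble array simulator used to validate every
estimator.

## Worked example

Simulate a genome-scale ensemble of phased nucleosome arrays (200 loci,
20 000 arrays, 162-bp repeat, rotational position clusters on a 10.25-bp
lattice) and recover both periods from the DAC:

```r
library(nucphase)

cfg <- array_sim_config(n_cells = 20000, region_length = 4000,
                        spacing = 162, n_loci = 200, seed = 1)
sim <- simulate_arrays(cfg)
sim$fragments
#> FragmentSet: 420000 fragments [simulated]
#>   lengths: 147 - 152 bp; 200 chromosome(s)

h <- compute_dac(position_counts(sim$fragments, "start"),
                 max_distance = 1100)

# helical period from the ~10-bp sub-peak lattice (distances 5-90 bp)
sub <- find_peaks(h, smoothing_window = 3, from = 5, to = 90)
fit_period(sub$position, assign_indices(sub$position, 10.25))
#> period fit: slope = 10.32 bp/index (raw 10.3214), intercept = -0.321 bp, r = 0.9999, n = 8

# repeat length from the dominant main peak of each harmonic
main <- find_peaks(h, smoothing_window = 41, from = 100, to = 1000,
                   refine = "centroid")
idx <- assign_indices(main$position, 162)
dom <- vapply(split(seq_len(nrow(main)), idx),
              function(i) main$position[i][which.max(main$height[i])],
              numeric(1))
fit_period(dom, as.integer(names(dom)))
#> period fit: slope = 162.01 bp/index (raw 162.011), intercept = 0.289 bp, r = 1.0000, n = 6
```

The sub-peak slope estimates the DNA helical period (10.32 bp here,
against a generative value of 10.25); the main-peak slope recovers the
planted 162-bp repeat length. On real data the same calls apply to a
`FragmentSet` read from disk:

```r
fs <- read_fragments("nucs.bed")                  # BED, BEDPE or SAM
fs <- filter_fragments(fs, 147, 152,              # core-particle lengths
        exclude = data.frame(chrom = "chrXII",    # rDNA locus
                             start = 451419, end = 468930))
h <- compute_dac(position_counts(fs, "start"), max_distance = 1000)
```

A command-line interface wraps the same functions
(`exec/nucphase`; subcommands `filter`, `dac`, `dcc`, `fit-period`,
`occupancy`, `composite`, `dyads`, `dinuc`, `mnase-ends`, `plus-one`,
`simulate`, `verify-reference`). Every run writes a JSON parameter manifest
next to its outputs, and `nucphase verify-reference` re-runs the five worked
reference checks:

```
$ nucphase verify-reference
[PASS] DAC weighting 5 x 10 at pair distance: expected 50, observed 50
[PASS] DAC increment 5 x 19 at 109 bp: expected 95, observed 95
[PASS] sub-peak regression slope (bp): expected 10.25, observed 10.25
[PASS] main-peak regression slope (bp): expected 162, observed 162
[PASS] expected WW spacing at 60% AT (bp): expected 3, observed 3
```

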