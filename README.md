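# mitorecomb

Quantifying repeat-mediated recombination in circular plant mitochondrial
genomes from short paired-end reads.

## The problem

Plant mitogenomes usually assemble as one circle, but the molecule in vivo
is a mixture of conformations interconverted by recombination between
repeated sequences: a **direct** repeat pair can split the circle into two
subgenomic circles, an **inverted** pair flips the segment between its
copies. How active each repeat is — the stoichiometry of the alternative
conformations — can be read off ordinary Illumina libraries, because a
fragment that spans a repeat copy and anchors in the unique flanks on both
sides supports exactly one conformation.

For a pair with copies *a* and *b*, the four local conformations are the
references `aa`, `bb` and the recombined `ab`, `ba` (flank-exchanged).
With N<sub>aa</sub>, N<sub>bb</sub>, N<sub>ab</sub>, N<sub>ba</sub> the
counts of read pairs unambiguously supporting each, the **recombination
frequency** is

```
f = (Nab + Nba) / (Naa + Nbb + Nab + Nba)
```

with a Wilson 95% interval attached; f ≈ 50% indicates recombinational
equilibrium (equimolar conformations). The package provides every stage as
a tested function — maximal-exact-repeat detection on the circle,
conformation construction (including the 3+3 member sets of pairs with
overlapping copies), filtered read assignment, frequency estimation, circle
decomposition — plus a seeded simulator so the whole pipeline can be
validated against planted ground truth. Audience: researchers analysing
organellar genome structure who want the support counting to be explicit,
deterministic and reproducible rather than buried in a mapping pipeline.

## Worked example

Simulate a 10 kb circle carrying one 200 bp direct repeat pair, draw 5,000
error-free 150 bp read pairs (insert 300 ± 30) from a 50/50 molar mixture
of reference and recombined molecules, and estimate the frequency:

```r
library(mitorecomb)

cfg <- sim_config(genome_length = 10000, n_pairs = 5000, seed = 1,
                  repeats = list(list(length = 200, orientation = "direct")))
sim <- generate_genome(cfg)                     # closed-loop verified planting
rd  <- simulate_reads(sim$genome, sim$pairs[1, ], f = 0.5, cfg)
fit <- recomb_fit(sim$genome, rd$reads)
summary(fit)
```

```
Repeat-mediated recombination fit
genome sim: 1 repeat unit(s) detected, 1 pair(s) assessed, 0 unassessable
discriminative pairs per repeat: median 51 (range 51-51)
largest deviation from equimolar (50%): 2.9 points

Repeat-mediated recombination report
  pair length_bp   type Naa Nbb Nab Nba Nref Nrec frequency_pct ci_low_pct
1   R1       200 direct  13  14   9  15   27   24          47.1       34.1
  ci_high_pct   status
1        60.5 assessed
```

Of 5,000 simulated pairs, 51 are discriminative (both junctions anchored
with ≥ 25 bp of flank); 24 of them support the recombined conformations,
giving 47.1% — within one binomial standard error of the true 50%. `coef()`,
`confint()` and `plot()` work as usual on the fitted object.

Published support counts can be fed to the estimator directly:

```r
recombination_frequency(Naa = 235, Nbb = 206, Nab = 167, Nba = 163,
                        pair_id = "R2")
#> <recomb_result> R2: 42.8% recombined (Nref=441, Nrec=330, 95% CI 39.4-46.3%)
```

A thin command-line wrapper is included at `inst/cli/mitorecomb`
(subcommands `repeats`, `fit`, `simulate`).

## Layout

- `R/` — sequence/circular-coordinate layer, repeat finder, conformation
  builder, assignment engine, estimator, simulator
- `tests/testthat/` — unit, property and acceptance suites (the repeat
  finder is checked against an independent brute-force oracle)
- `vignettes/mitorecomb-methods.Rmd` — model, conventions, parameter
  defaults, simulator scope and limitations
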