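---
title: "Measuring repeat-mediated recombination in circular mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring repeat-mediated recombination in circular mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorecomb)
```

## The problem

Flowering-plant mitochondrial genomes usually assemble as a single circle,
but the molecule in vivo is a population of alternative conformations that
interconvert by homologous recombination between repeated sequences. A
direct repeat pair (both copies in the same orientation) can split the
master circle into two smaller subgenomic circles; an inverted pair flips
the segment between the copies, producing an isomeric circle of the same
size. The relative abundance of these conformations — their stoichiometry —
is measurable with ordinary short-read data, because a read pair that spans
a repeat copy *and* anchors in the unique sequence on both sides of it can
tell the conformations apart.

`mitorecomb` implements that measurement as a pipeline of small, testable
stages, plus a simulator that generates genomes and reads with known ground
truth so every stage can be validated end to end without external data.

## The estimator

For a repeat pair with copies *a* and *b*, four local conformations exist:
the two present in the assembly (`aa`, `bb`: each copy with its own flanks)
and the two produced by recombination (`ab`, `ba`: flank-exchanged). With
`Naa, Nbb, Nab, Nba` the numbers of read pairs unambiguously supporting
each, the recombination frequency is

$$ f \;=\; \frac{N_{ab} + N_{ba}}{N_{aa} + N_{bb} + N_{ab} + N_{ba}} $$

i.e. the fraction of conformation-discriminating read pairs that support
recombined conformations. Under the molar-mixture interpretation — reads
sampled uniformly from a population in which a fraction $f$ of molecules
are recombined — this is an unbiased binomial estimate of the recombined
stoichiometry, because reference and recombined molecules each expose the
same number of discriminating junction loci per molecule. A value near 50%
indicates recombinational equilibrium (equimolar conformations).

The package attaches a Wilson 95% score interval
(`stats::prop.test(..., correct = FALSE)`). No uncertainty statement is
traditional for these tables, but a count-based proportion without an
interval is uninterpretable at low support; the Wilson interval behaves
sensibly at the 0% and 100% extremes, where the Wald interval collapses.
We report `abs(frequency - 0.5)` alongside the interval and leave the call
of "equilibrium" to the reader; the package deliberately performs no
hypothesis test against 50%, which would suggest more inferential content
than the sampling design supports.

## Repeat detection

`find_repeats()` reports every **maximal exact repeated substring** of at
least `min_len` bp (default 30), in forward and reverse-complement
orientation, on the circle (copies straddling the linearisation origin are
found; all results are rotation-invariant). The algorithm is exact-k-mer
seeding (k = min(31, `min_len`)) over all circular positions, pairing of
identical seeds, clustering of seed pairs by (anti)diagonal, and maximal
bidirectional extension, with deduplication by canonical coordinates.

Two conventions matter and are fixed here deliberately:

* **Exactness.** Only literal exact repeats are reported. Surveys built on
  BLAST-type scans can merge near-identical copies into one unit; counts of
  units or repetitive bp from such tools are not expected to match ours
  base-for-base, and the package documents its convention rather than
  emulating any particular tool's fuzziness.
* **Units from pairwise matches.** Maximal pairwise matches sharing an
  identical copy interval are grouped into one unit; strands are propagated
  across the match graph from the leftmost copy. In the rare family whose
  pairwise-maximal lengths disagree, the matches are kept as separate
  units rather than force-fitted into one.

Bases outside `A/C/G/T` (including `N`) never seed or extend a match, and
never count as matching during read assignment: an assembly gap cannot
manufacture repeat structure or read support.

The test suite checks the finder against an independent brute-force oracle
(rotation-by-rotation comparison of the genome with itself and with its
reverse complement, reading maximal runs of agreement) on dozens of random
circles with planted direct, inverted and origin-spanning repeats.

## Conformation construction

For each assessable pair, `build_conformations()` assembles the four member
sequences as `upstream flank + repeat + downstream flank` with 300 bp
flanks by default — matching the insert size of the libraries the members
are probed with, so a full fragment fits inside a member. All members are
written in the reading direction of copy *a*; for inverted pairs, copy
*b*'s context is reverse-complemented into that frame. This frame choice is
arbitrary but must be fixed for `ab`/`ba` to be well defined; exchanging
flanks twice restores the reference set, which the tests assert.

Flanks must be single-copy to discriminate. When another repeat copy begins
within the flank distance, the flank is truncated at its boundary and the
truncation recorded; a flank that would start inside another copy is an
error suggesting a smaller `flank_len`.

**Overlapping copies.** When one copy of a pair shares bases with a copy of
another pair, the flank of the overlapped copy on the shared side runs
through the partner repeat — and what lies beyond the partner copy depends
on whether the partner pair is itself in reference or recombined state.
`build_overlap_conformations()` therefore enumerates that flank through
both partner exit contexts, giving each pair three reference and three
recombined members. The construction is generic in the overlap length
(any value from 1 bp up to, but not including, a whole copy) and in which
side of which copy is affected. The exact member set for shared-copy
context is a convention of this package; member labels carry a
`partner_context` annotation so the provenance of each variant is explicit.

## Read assignment

`assign_read_pairs()` scores each read pair against every member with an
internal seed-and-extend **gapless** aligner (20-mer seeds, full-overlap
diagonal scoring, clipping only at member ends, mismatch ceiling
`max_mismatch_rate`, default 2%). A pair supports a member only if:

1. its summed best score is **strictly** higher there than on every other
   member and every decoy — ties are counted `ambiguous`, never broken
   randomly, so assignment is fully deterministic;
2. each mate aligns over at least `min_aln` bp (default 100). This is the
   classic defence against nuclear copies of mitochondrial fragments,
   which produce short high-identity placements;
3. the pair is *discriminative*: jointly the mates cover both flank-repeat
   junctions with at least `min_anchor` bp (default 25) of aligned flank
   beyond each junction. A pair wholly inside the repeat, or touching only
   one flank, cannot tell conformations apart and is counted ambiguous. A
   pair is counted once however its junction coverage is distributed
   between the mates.

The 25 bp anchor default makes a 150 bp mate in a 300 bp flank comfortably
discriminative while excluding 1-2 bp overhangs that chance matches could
satisfy. Decoy sequences (typically the plastid genome) absorb contaminant
pairs: a pair whose best placement is strictly on a decoy is tallied
`decoy-filtered`; a tie between best member and decoy is ambiguous, since
support requires the member to win outright. The aligner is internal by
design — it makes the `min_aln` filter exact and keeps the package
dependency-free — but assignment consumes plain sequence containers, so a
SAM-derived workflow can be plugged in upstream by constructing
`read_pairs()` from any source.

Assessability is decided before assignment:
`repeat_length <= insert_size - 2 * min_anchor`. A repeat at or beyond the
fragment span (e.g. the multi-kilobase class) cannot be bridged by one
fragment with anchors in both flanks, and is reported as "unassessable by
short reads" rather than estimated; such repeats need long-range PCR or
long reads, which are out of scope here.

## The simulator

`generate_genome()` builds a uniform-random circle (default 43% GC, typical
of angiosperm mitogenomes) and plants each configured repeat as two copies,
reverse-complementing the second for inverted pairs, optionally overlapping
consecutive units' second copies by a configured number of bases. Two
safeguards make the planted structure the *exact* ground truth: boundary
bases are rewritten (in background sequence only) so no planted match can
extend by chance beyond its intended ends, and the finished genome is
verified in closed loop with `find_repeats()` — any accidental background
repeat at or above `min_len` triggers regeneration, with a bounded retry
count.

`simulate_reads()` draws fragments uniformly from a molecule population:
fraction $1-f$ from the reference circle, $f$ from the recombination
products of the pair under study (for a direct pair, the two subgenomic
circles, sampled in proportion to their lengths — equivalent to uniform
sampling over the recombined state's total DNA). Fragment lengths are
Normal(300, 30) by default, truncated to `[read_length, molecule length)`;
mates are the fragment's two ends in standard FR orientation; errors are
independent per-base substitutions. Substitutions-only is intentional: the
assignment engine is gapless, and keeping simulator and engine consistent
means closed-loop deviations measure estimator error, not model mismatch.

All randomness flows from the single config seed (genome generation and
read simulation use fixed offsets of it), so equal configs give
byte-identical FASTQ output.

What the simulator does **not** emulate: platform-specific error and
quality profiles, indels, GC-coverage bias, chimeric fragments, and
heteroplasmic mixtures of more than two states per pair. Passing
closed-loop tests therefore shows the estimator is correct under clean
sampling assumptions, not that real libraries are free of mapping bias.

## Problem sizes and numerical choices

The validation suite runs at deliberately desk-sized scales, chosen once as
realistic miniatures of the target setting: 10 kb circles with one planted
200 bp direct pair, 2,500-5,000 read pairs per closed-loop run, 50 random
2-3 kb circles for the finder-vs-oracle equivalence. On a 10 kb circle,
uniform fragment sampling yields roughly 1% discriminative pairs (the
junction-spanning windows are ~50 bp per junction locus), so a 5,000-pair
run gives on the order of 40-60 discriminative pairs, and closed-loop
checks accept estimates within three binomial standard errors computed at
that yield — e.g. `f = 0` must return exactly 0 under error-free reads,
which it does because a tie can never masquerade as support.

Other fixed choices: coordinates are 0-based half-open internally and in
BED output, 1-based inclusive in human-readable tables; zero-support pairs
return `NA` with a warning rather than an error; a `flank_len` of 0 is
allowed but flagged, since all members then collapse to the bare repeat;
rejoining the two circles of a direct split is exact string concatenation
at the shared copy and regenerates a rotation of the parent, which the
tests assert together with length and base-content conservation.

## Known limitations

* Exact repeats only; a pair of copies differing by a single substitution
  is reported as the flanking exact fragments, not one unit.
* The aligner is gapless; indel-bearing reads lose score linearly and are
  filtered by the mismatch ceiling rather than realigned.
* Frequencies from different repeat pairs are reported side by side but not
  tested against each other; cross-pair comparisons need a sampling model
  for shared fragments that the package does not impose.
* Genome-scale conformational inference (enumerating the full combinatorial
  space of multi-pair recombination states) is out of scope; the package
  predicts products one pair at a time.
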