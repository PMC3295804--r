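---
title: "Models and methods behind bscapture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bscapture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bscapture` models the computational half of a liquid hybridization
capture bisulfite sequencing assay: enrich a target fraction of the
genome, bisulfite-convert, sequence 90 bp paired ends, and recover
per-cytosine methylation, capture QC and two-sample differential calls.
This vignette records the models, the parameter choices and the numerical
decisions, in the spirit of a methods supplement. Everything stated here
is computed by the package's own tests or scripts; nothing is imported
from external data.

## The generative model

**Genome and methylome.** The simulated reference draws i.i.d. bases at a
configurable GC fraction, optionally overwriting intervals with CpG-dense
sequence (islands). The truth methylome assigns every cytosine on both
strands a level in [0, 1]. CpG dinucleotides draw one level per
Watson/Crick pair from a two-component Beta mixture — default 70%
`Beta(8, 1)` (mean 0.89, the methylated genomic background) and 30%
`Beta(1, 9)` (mean 0.10, hypomethylated island-like sites) — so the
landscape is bimodal, and symmetric CpG methylation is assumed: both
strand members of a pair carry the identical level. Non-CpG cytosines get
a constant low level (default 0.002), reflecting the near-absence of
non-CpG methylation in human somatic tissue; this same assumption is what
lets the caller estimate conversion failure from non-CpG sites.

**Library.** Each attempted fragment draws a Normal(250, 30) length
(redrawn below 1 bp) and a uniform placement; at 90 bp reads, pairs from
short fragments overlap, and fragments shorter than a read yield
truncated reads. Capture is a Bernoulli retention: probability 0.8 for
fragments overlapping a target by at least 1 bp, 0.01 otherwise — an
aggregate two-probability model rather than a probe-hybridization energy
model, which is all that is needed to reproduce assay-level enrichment.
The molecule's source strand is sampled uniformly (a
`watson-informative-only` mode restricts to the original top strand,
mimicking single-strand probe designs). Heterozygous sites are phased:
homolog 2 carries the alternate allele, and each fragment comes from one
homolog.

**Conversion and amplification.** Per molecule, each source-strand
cytosine is methylated with probability equal to its truth level
(Bernoulli per molecule, so read-level heterogeneity is real); it then
reads as T with probability `conversion_rate` (default 0.99) if
unmethylated, or `inappropriate_conversion_rate` (default 0, a knob for
over-conversion) if methylated. Guanines on a read — cytosines of the
opposite strand — are never altered by that read's conversion. The
converted molecule is amplified into `1 + Poisson(pcr_duplicate_mean - 1)`
copies (default mean 1.7), each copy then receiving independent per-base
substitution errors (default 0.001). Read names encode
`chrom:start:end:strand:fragment:copy`, and three truth tables (fragments,
molecules, per-cytosine conversion events) make every downstream statistic
checkable without auxiliary formats.

**Calibration.** Defaults were set so the default pipeline reproduces the
aggregate operating point of a deeply sequenced captured human library:
25 targets of 300–600 bp on a 100 kb toy genome (≈ 11% span) with
0.8/0.01 capture probabilities give a read-level on-target rate around
72–75%, and a duplicate mean of 1.7 gives a duplication rate around 40%.
The fragment mean of 250 bp was chosen from the two plausible protocol
values (sonication to ~200 bp versus library mode ~250 bp); both are
reachable through `sim_params()`.

## Alignment

Bisulfite-converted reads live in a reduced alphabet, so the aligner
searches two converted views of the reference: C→T (informative for
original-top-strand molecules) and G→A (original bottom). Each read is
queried in both spaces and both orientations — four combinations that
cover read 1 and read 2 of both source strands. Candidate placements come
from exact k-mer anchors: the 30 bp seed is split into
`seed_max_mismatches + 1` chunks of `k = 10`, so by pigeonhole any
placement with at most 2 seed mismatches contains an exact anchor; this
makes the seeded search provably equivalent to an exhaustive scan under
the stated budgets, which the test suite verifies against a brute-force
oracle on a 20 kb genome with 500 read pairs.

Mismatches are counted in the *original* base space: read T over
reference C (C→T space) and read A over reference G (G→A space) are
bisulfite-consistent and free; every other substitution counts. A
placement needs ≤ 2 mismatches in the first 30 sequenced bases and ≤ 5
overall. Whether bisulfite-consistent substitutions should count toward
the seed budget is genuinely open; the package exempts them (they carry
methylation signal, not sequencing error), and documents this as an
interpretation. Alignment is gap-free: gap counts appear in the ranking
interface but default to disabled, keeping the desk-scale aligner exact
and oracle-comparable.

Pair resolution ranks properly paired placements (same chromosome and
conversion space — one physical fragment has one informative space —
opposite strands, plus-strand mate leftmost, outer span ≤ 1000 bp) above
single-end ones, then fewer gaps-plus-mismatches. A read is *unique* only
if exactly one top-ranked placement survives; ties become *multi* and are
recorded but never counted downstream, which on repeat-containing genomes
is what produces systematically uncovered regions. Duplicates are
collapsed by the placement key (chromosome, pair outer start/end,
conversion space, strand), keeping the fewest-mismatch member with
deterministic tie-breaks (highest summed base quality, then smallest read
name). The duplication rate denominator is unique-aligned pairs before
collapse — a documented choice.

## Methylation calling and conversion correction

C→T-space records inform Watson cytosines (read C ⇒ methylated, read T ⇒
unmethylated), G→A-space records inform Crick cytosines; other read bases
at a cytosine are ignored. The raw level is `100 · mC / (mC + C)`.
Because a fraction `e` of unmethylated cytosines fails to convert, raw
levels are biased upward by approximately `e · (1 − m)`. The package
estimates one global `e` per library as the pooled methylated fraction at
non-CpG sites (both strands) — pooled, not per-site, because conversion
failure is a library-level chemistry property — and corrects CpG levels
by background subtraction with renormalization:

```
corrected = max(0, (raw − e) / (1 − e))
```

The correction direction ("adjust levels by the conversion rate") admits
subtraction, renormalization or filtering; the renormalized form above is
adopted because it is invertible, keeps levels in [0, 100] and recovers
truth in simulation (regression of corrected on true levels at a 0.95
conversion rate and depth ≥ 50 has slope within [0.95, 1.05] and
intercept within ±2 points — an acceptance test). The raw level is always
retained next to the corrected one. When a known fully unmethylated
carrier (a lambda spike-in) is present as its own chromosome,
`estimate_nonconversion(calls, carrier_chroms = ...)` uses all its
cytosines instead; non-CpG estimation is the default. Note the non-CpG
estimate absorbs any true non-CpG methylation and T→C sequencing errors
into `e`; with the default 0.002 non-CpG level the estimate runs a few
tenths of a percentage point above the pure chemistry rate, which is the
correct behaviour for background subtraction.

## Capture QC and allele dropout

A read is on target if its span overlaps any capture region by ≥ 1 bp; a
region is *covered* with ≥ 1 unique read ("covered" is deliberately the
most permissive reading) and *well covered* with ≥ 10. Mean target depth
is summed per-base unique-read depth over target bases divided by target
span, and the suite checks depth additivity against per-read overlap
lengths.

Allele dropout uses planted heterozygous sites. C/T and A/G pairs are
excluded up front: bisulfite conversion manufactures exactly those
apparent genotypes. Remaining sites qualify at depth strictly greater
than 10, and a site is *recovered* when both alleles have at least 2
conversion-safe observations — a base counts only where its identity
cannot be a conversion artifact (read T is unsafe in C→T space, read A in
G→A space). The per-allele read threshold is a knob (`min_allele_reads`,
default 2) because no standard criterion exists; the arithmetic
`dropout = 100 · (truth − recovered) / truth` reproduces the worked
example of 7,172 qualifying sites with 6,992 recovered giving 2.5%.

## Differential methylation

Region counts pool methylated and unmethylated CpG observations (both
strands) per capture target. Two samples are compared per region with
three conjunctive gates: two-sided Fisher's exact test `p < 0.01` (exact
hypergeometric enumeration, summing all tables with probability ≤ the
observed, with a 1e-7 relative tie tolerance; verified against full
enumeration to 1e-12), fold change `> 2`, and absolute difference `> 20`
points. Fold change is `max / min` of the two levels — symmetric because
the gates are directionless — with one zero level and one positive level
passing (infinite fold). No multiple-testing correction is applied by
default, matching the raw-p procedure the three-gate design assumes; a
`p_adjust` argument exists but defaults off. The planted-DMR generator
(`simulate_dmr_counts`) draws base levels Uniform(0.05, 0.25): the
three-gate rule with a two-fold requirement can only detect a +40-point
shift when the base is below 40%, and hypomethylated promoter-like
regions gaining methylation are the canonical DMR; at depth 200 this
yields ≥ 0.9 recall with the null p < 0.01 fraction inside its binomial
band (an acceptance test). Note the gates are not mutually redundant: a
40% → 75% change at high depth is significant and > 20 points but fails
the fold gate.

## Metagene profile and concordance

The metagene axis has 70 ordered sections: 2 kb upstream of the TSS in 20
equal 100 bp sections, first exon in 10, internal exons concatenated in
transcript order in 10, terminal exon in 10, and 2 kb downstream of the
TTS in 20. Coordinates flip for minus-strand genes so the axis follows
transcription. Each covered CpG is assigned to one section per feature by
equal base-pair width, and a section's mean is the unweighted mean of CpG
levels pooled across genes — pooled rather than per-gene means of means,
which is stable for sparsely covered genes and stated here as the
convention. Genes with fewer than three exons skip the internal sections;
a single-exon gene's exon serves as both first and terminal.

Replicate concordance is the Pearson correlation of per-cytosine levels
at sites with depth ≥ 9 in both call sets (the depth restriction removes
shot-noise-dominated sites), with a 95% interval from Fisher's
z-transform. Per-site validation against clone sequencing uses a 2×2
chi-square test with continuity correction when all expected counts reach
5 and the exact test otherwise — the switch rule is a documented
convention, since "chi-square or Fisher" alone does not define one.

## Reproducibility and numerical choices

All randomness flows from one seed, fanned out to stages through stable
string-labelled substreams (`substream_seed`), so stages rerun standalone
reproduce their in-pipeline draws and the full pipeline is byte-identical
across runs — verified by hashing every artifact of two runs. Degenerate
inputs have defined behaviour: empty capture yields an explicit
empty-library warning; an all-zero 2×2 table has p = 1; a non-conversion
rate of 1 is a hard error; cytosines too close to a chromosome end to
classify default to CHH; records overhanging a chromosome end are a hard
error rather than a silent clamp.

## Test scale and limitations

The suite runs on toy genomes of 5–100 kb with 10²–2×10⁴ fragment pairs,
sizes chosen so the exhaustive oracles (position-exhaustive alignment,
full hypergeometric enumeration, placement enumeration for capture) stay
exact and fast; statistical checks use 3σ binomial bands at their stated
n. What the simulator does *not* emulate: repetitive sequence and
paralogy (so unique map rates are ~100% on the toy genome, versus ~80–85%
on a real genome where multi-mapping drives losses), base-quality
degradation along reads, insert-size biases of probe chemistry, chimeric
fragments, and GC-dependent amplification bias. Passing tests therefore
validate the *logic* of alignment, counting, correction and testing — not
performance on repeat-rich real data. Gapped alignment, per-read
methylation phasing and hemimethylation inference (symmetry is assumed)
are out of scope.
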