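---
title: "Methods: population genetics of yeast point centromeres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics of yeast point centromeres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pointcen)
```

## The scientific problem

The point centromeres of *Saccharomyces* yeasts are unusual among
eukaryotic centromeres in being short and sequence-defined: an 8 bp CDEI
and a 25 bp CDEIII protein-binding motif flank an ~87 bp AT-rich CDEII core
whose length and base composition, but not primary sequence, are conserved.
Despite their essential role in chromosome segregation, these centromeres
evolve several-fold faster than selectively unconstrained DNA. Three
mechanisms could produce that pattern: recurrent selective sweeps under
centromere meiotic drive (which predicts *low* within-population
polymorphism), mutagenic gene conversion (which predicts recombination
signals and a conversion-like mutation spectrum), or simply an elevated
mutation rate (which predicts high polymorphism, no recombination signal,
and a spontaneous-like spectrum). Distinguishing them requires, in order:
per-locus polymorphism statistics robust to heavy missing data,
recombination tests that are not fooled by repeat mutation (homoplasy) at
high mutation density, and a polarized mutation spectrum normalised for the
extreme AT-richness of the core. This package implements that chain of
analyses, plus a coalescent simulator that generates data with the same
statistical structure so every stage can be validated without external
sequence downloads.

## Alignment handling and haplotype reduction

Alignments are per-locus character matrices over `A C G T N -`, where `N`
marks a base call below the quality threshold (or a site not covered by
shotgun data) and `-` an alignment gap. Indels and `N` are treated as
missing data in every polymorphism statistic, so slippage in homopolymer
runs cannot masquerade as point substitution.

Haplotype reduction collapses the alignment so each haplotype is
represented once, by its least-ambiguous member — a prerequisite for
polarization, since otherwise a clonal set of strains would let one
mutation be counted many times. Two sequences are assigned to the same
haplotype class iff they agree at every column where both carry a
determinate state; `N` is a wildcard, and the gap is treated as a fifth
matchable state so indel haplotypes remain distinct (how gaps interact with
haplotype identity is genuinely open; treating `-` as matchable-but-distinct
is this package's choice, made so that unique indels survive reduction and
can be classified downstream). Because wildcard compatibility is not
transitive, classes are formed greedily and deterministically: strains are
sorted by number of non-`N` characters (descending, ties by strain id in
the C locale), seeded as representatives in that order, and each strain
joins the first compatible representative. The procedure is idempotent and
never increases the strain count.

All coordinates in this package are 1-based inclusive — the native indexing
of R's matrices and of the Bioconductor ranges infrastructure used for
export — in memory and in every report; GFF3 output is 1-based, BED 0-based
half-open, both via `rtracklayer`.

## Centromere annotation

CDEI and CDEIII are located by exact IUPAC-degenerate matching on both
strands (`Biostrings::matchPattern` with literal subject letters, so `N`
never matches), and every same-strand CDEI/CDEIII pair whose gap length
falls in a configurable window is reported as a candidate centromere with
the gap as CDEII. The consensus strings are *configuration with shipped
defaults* (`RTCACRTG` for CDEI; a 25 bp degenerate string,
`TGTTTWTGNTTTCCGAANNNNAAAA`, capturing the conserved TGT-box, CCGAA core
and terminal A-run for CDEIII), echoed into report headers: the canonical
motif definitions live in the experimental literature, and hard-coding one
rendition as truth would hide an assumption the user may want to change.
The default CDEII window is 75–100 bp, bracketing the canonical 80–90 bp
core with margin for indel-bearing alleles. Absence of an acceptable pair
is a valid (empty) result: one of the 16 centromere loci can fail
annotation in real data. No probabilistic motif scoring is attempted —
point-centromere motifs are short, near-invariant, and present in single
copy, so exact degenerate matching is both sufficient and transparent.

## Polymorphism with missing data

All statistics use only columns with at least two valid bases
(pairwise-deletion handling, the behaviour of low-coverage population
data pipelines). At a column with local sample size $n$ and allele
frequencies $p_b$:

* heterozygosity uses the unbiased form
  $h = \frac{n}{n-1}\left(1 - \sum_b p_b^2\right)$, which equals the
  fraction of differing pairs among the $\binom{n}{2}$ valid pairs;
* the segregation indicator contributes $1/a(n)$ to Watterson's estimator,
  with $a(n) = \sum_{k=1}^{n-1} 1/k$ evaluated at the *local* $n$.

Per-locus $\pi$ and $\theta_W$ divide by the number of analysed columns,
not the alignment length, so appending uncovered sequence changes nothing.
For two sequences $\pi = \theta_W$ exactly. $D_{xy}$ is the raw (not net)
between-population divergence: the mean, over columns with at least one
valid base in each population, of the proportion of differing
cross-population base pairs. Locus-set uncertainty comes from a bootstrap
over loci (resample with replacement, percentile 2.5/97.5 bounds; 10,000
replicates by default), bit-reproducible under a fixed seed.

The exact binomial test used for transition bias is the two-sided
minimum-likelihood convention, i.e. `stats::binom.test`: all outcomes with
point probability not exceeding the observed one are summed. Against the
null of 1/3 (four of the twelve directed substitution types are
transitions, and every site offers twice as many possible transversions),
the published count checks 46/114, 12/31 and 142/394 give P = 0.11, 0.57
and 0.26 under this convention, which is why the convention matters enough
to document.

## Recombination versus homoplasy

The four-gamete test is applied to every pair of biallelic columns:
observing all four two-site haplotypes among strains valid at both sites
implies either a crossover between them or repeat mutation at one of them.
At CDEII-like mutation densities homoplasy is *expected*, so three layers
separate the explanations:

1. **Hudson–Kaplan $R_{min}$** — the minimum number of crossover events
   needed if recombination explained everything: the classic greedy
   interval-removal bound (sort incompatible-pair intervals by right
   endpoint; count disjoint ones), which is exact for this objective.
2. **Minimum homoplasy set** — the minimum number of *sites* whose removal
   explains all incompatibilities: an exact minimum vertex cover of the
   conflict graph (sites = vertices, incompatible pairs = edges), via
   branch and bound with a deterministic tie-break (the lexicographically
   smallest among minimum covers). The exact search is capped at 32
   conflict-graph vertices; beyond that the error advises splitting the
   region rather than silently approximating. Columns with three or more
   valid alleles are excluded from pair testing — they are themselves
   direct homoplasy evidence — and logged.
3. **Randomization null** — how many multiply-hit sites repeat mutation
   alone would produce: each replicate drops mutations uniformly at random
   on the region's analysed sites until the observed number of segregating
   sites is reached, and counts sites hit twice or more; the empirical
   p-value is add-one smoothed, $(1 + \#\{k_{null} \ge k_{obs}\})/(R + 1)$.
   The published description of this null is compatible with two readings —
   condition on $S$ *distinct* sites (mutate until coverage) or on $S$
   total mutations; the first is the default because the observed $S$ is a
   count of distinct segregating sites, and the second is available as
   `model = "total"`.

Cores and flanks are analysed separately (the null assumes a uniform rate,
and centromere cores mutate faster than flanks), then the inferred sites
are removed and the *full* locus re-tested: surviving incompatibilities
are the recombination candidates. Because $k_{obs}$ is a minimum — and
because homoplasy reduces observed $S$, making the conditioned null
generous — the test is conservative: under simulated zero recombination
its rejection rate at the 5% level is well below 5%.

## The polarized mutation spectrum

Without an alignable outgroup, polarity comes from the unique-haplotype
rule: an allele carried by exactly one haplotype of the reduced alignment
is assumed derived. A column is polarizable when it has at least three
valid haplotypes, exactly two alleles, and a singleton minor allele; the
three-haplotype floor is forced by the rule itself (with two, both alleles
are "unique"). Columns with two-way ties or three or more alleles are
skipped and tallied. This is conservative — tree-based polarization would
accept more sites — and it mis-polarizes the rare column where the
*ancestral* allele survives in a single haplotype, a known and accepted
property of the method.

Counts $n_{i \to j}$ are normalised by base availability $\alpha_i$ — the
total count of base $i$ over all sequences of the reduced alignment, the
post-reduction reading of availability (counting over all strains instead
is a documented switch: pass the unreduced alignment to
`spectrum_counts`). Relative rates on the six complement-collapsed classes
are

$$ r_{i \to j} = \frac{(n_{i \to j} / \sum n_{i \to j})\,/\,p_i}
   {\sum \left[(n_{i \to j} / \sum n_{i \to j})\,/\,p_i\right]} $$

with $p_i$ the composition fraction of the source base pair ($p_{AT}$ or
$p_{GC}$), so $\sum r = 1$ by construction, for the point estimate and for
every bootstrap replicate (loci resampled with replacement; percentile
CIs). The twelve-type directed table is also emitted for transition/
transversion tallies and for use as a count/offset table in downstream
Poisson GLMs, which this package deliberately does not refit — `glm` is a
solved problem.

Unique indels (maximal gap runs unique to one haplotype, the same
derived-state assumption) are classified by length and direction, and any
single-base event inside a homopolymer run of ≥ 5 bp — measured on a
gap-free reference sequence around the event — is diverted to the "other"
bucket together with multi-base events, because slippage in long runs has
its own, much higher rate and would otherwise contaminate the
deletion-frequency comparison. The in-run and multi-base sub-tallies are
reported separately since published tables pool them ambiguously. The
derived deletion-to-substitution frequency is defined here explicitly as
(1 bp deletions outside runs) / (Ts + Tv); published renditions of this
column are not all consistent with a single denominator, so the report
header states the definition used.

## The coalescent simulator

`simulate_coalescent_alignment` draws a Kingman genealogy (time in units of
$2N$ generations; the implementation's pairwise-distance expectation was
checked against `ape::rcoal`'s), places mutations as a Poisson process on
branches at per-site rate $\theta/2$ — so $E[\pi] = \theta$ — under a
finite-sites model in which repeat hits create genuine homoplasy, and
applies target-base choice from a configurable 12-type relative-rate
matrix. Defaults are the study conditions the package is aimed at: 34
strains, 87 bp, $\theta = 0.04$, 95% A+T — i.e. a CDEII core in a global
strain panel, fully resequenced (so no masking by default; shotgun-like
coverage is added with `degrade_alignment`, e.g. `missing_fraction = 0.6`
for ~40% site coverage). Flank-like sequence uses $\theta \approx
0.006$–$0.01$.

Design simplifications, deliberate and visible in the ground truth the
simulator returns:

* **Recombination** is modelled as independent genealogies in blocks split
  at uniform breakpoints, not an ancestral recombination graph. This
  suffices to create four-gamete-detectable discordance for power
  analyses; linkage *within* a block is exact, between blocks absent.
* **Indels** are single-base events on terminal branches only (hence unique
  to one strain, matching the unique-indel analysis), with the rate
  multiplied by `slippage_multiplier` (default 10) inside homopolymer runs
  of ≥ 5 bp. Multi-base and internal-branch indels are not simulated.
* **Masking** is i.i.d. per base. Real shotgun coverage is correlated along
  reads; i.i.d. masking is the harder case for per-site estimators (no long
  jointly-covered stretches) and the simpler model.

Consequently, passing tests show that the estimators are correct under
panmictic neutral evolution with uniform rates; they do not validate
behaviour under population structure, selection, or coverage correlation —
on real data those remain the analyst's responsibility (population
structure in particular is why within-population statistics are computed
separately via the population map).

## Calibration and problem sizes

The test suite validates each estimator against an independent brute-force
oracle (pairwise enumeration for $\pi$ and $D_{xy}$; exhaustive subset
search for vertex covers and $R_{min}$; full outcome enumeration for the
binomial test; an exact occupancy argument for the randomization null at
$L = S = 2$), then checks calibration at study scale: 200 replicates at
$n = 50$, $L = 10^4$, $\theta = 0.01$ recover $E[\pi]$ within three
standard errors; 500 no-recombination CDEII-like replicates keep the
homoplasy null's rejection rate at or under ~7%; 200 one-crossover
replicates give four-gamete detection in at least 80%. The crossover-power
scenario runs at full-locus scale (487 bp — core plus two 200 bp flanks)
rather than the 87 bp core alone: a uniform breakpoint inside 87 bp often
leaves one block with almost no segregating sites, which is a test of
breakpoint placement, not of the four-gamete machinery; at locus scale both
blocks are reliably polymorphic. Spectrum recovery
(16 loci per batch, C:G→T:A at five times the other classes, 50 batches) is
run at *balanced* base composition: at 95% A+T only a handful of polarized
changes per batch are C:G-sourced, so the C:G classes are statistically
unresolvable there — the same reason published AT-rich spectra cannot
assess C:G→A:T levels. These sizes keep the whole suite in a few minutes
while leaving Monte-Carlo margins wide relative to the thresholds tested.

## Known limitations

* Exact minimum-homoplasy search is exponential in the conflict-graph size;
  the 32-vertex cap covers point-centromere loci comfortably but not long
  recombining regions (split them, or rely on $R_{min}$).
* The unique-haplotype rule under-counts mutations (it discards shared
  derived alleles) and its mis-polarization rate grows with the frequency
  of near-root singleton lineages; spectrum *ratios* are robust to the
  former but not entirely to the latter.
* $D_{xy}$ is raw divergence; with very recent splits it is dominated by
  ancestral polymorphism.
* Likelihood-based recombination-rate estimation (the LDhat family) is out
  of scope; on real data the four-gamete/homoplasy analysis here is one of
  two lines of evidence, and published practice requires both to call
  recombination at a locus.
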