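---
title: "Models and methods: diploid resequencing analysis against a draft reference"
author: "cynoseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: diploid resequencing analysis against a draft reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cynoseq)
```

# The problem

A single diploid macaque genome is resequenced at high depth against the
draft reference assembly of a closely related species (divergence roughly
0.4%). From the mapped evidence one wants, in order: diploid genotypes at
every site; a defensible filter against reference-assembly artefacts;
variant-effect annotation; comparisons against other sequenced macaque
genomes; within- and between-species population-genetic summaries;
structural variants from mate-pair libraries; and the ancestral
population-size history from the heterozygosity pattern of the one genome.

`cynoseq` implements each step as an explicit, tested model, and ships a
synthetic-data generator that produces references, gene models, pileups and
mate-pair records with known truth, so every stage of the pipeline can be
validated end to end without any external data.

# The synthetic-data generator

## Coalescent TMRCA tracts

For a diploid individual, the two haplotypes at a site coalesce at time
$T$ (the TMRCA). Along a recombining chromosome $T$ is piecewise constant.
`simulateTmrca()` walks each chromosome under the sequentially Markovian
coalescent (SMC) for a sample of two: given the current $T$ in
generations, the distance to the next recombination breakpoint is
exponential with rate $2\rho T$ per bp ($\rho$ = recombination rate per
site per generation; the pairwise tree has total branch length $2T$). At a
breakpoint the recombination point is uniform on $[0, T]$ and the detached
lineage re-coalesces under the piecewise-constant history
$N(t)$ — the plain SMC, with no re-coalescence into the removed branch.
Because the first tract is drawn from the stationary pairwise coalescent,
the per-site marginal of $T$ is exactly the stationary coalescent
distribution $F(t) = 1 - e^{-H(t)}$, $H(t) = \int_0^t ds / (2 N(s))$
(available as `tmrcaCdf()`). An earlier design that redrew $T$ from the
stationary distribution at every breakpoint was rejected: tract lengths
are $\propto 1/T$, so that scheme length-biases the site marginal toward
tiny $T$ and breaks the identity $\pi = 4 N \mu$ the estimators rely on.

## Variants, pileups, mate pairs

`imposeVariants()` places heterozygous SNVs per site with probability
$2\mu T$ (small-rate regime; inputs with $\mu T \ge 0.5$ are rejected) and
homozygous SNVs — fixed differences against the reference — at the
configured divergence (default 0.004). Substitution types follow a
transition/transversion bias (default 2.39, giving an expected emitted
Ts/Tv ratio equal to the bias). On a designated X chromosome of the male
sample no heterozygous variants are placed. Small indels arise at a
configurable rate (default 2e-4/bp, 62% deletions, geometric lengths capped
at 11 bp for deletions and 3 bp for insertions, matching the detectable
range of the small-indel caller being emulated).

`emitPileup()` draws per-site depth as Poisson (default mean 41.5), reads
from either allele with probability 1/2 at heterozygous sites, and flips
each read to one of the three other bases with probability $\varepsilon$
(default 0.01), spread evenly. `emitMatePairs()` samples pairs uniformly
along the SV-carrying sample genome with inserts uniform in each library's
range (defaults: library A 600-800 bp, library B 800-1,000 bp) and maps tag
positions back to reference coordinates, so deletions inflate and
insertions deflate observed spans, and pairs straddling exactly one
inversion breakpoint carry an orientation-incongruence flag. Sequencing
indel errors are not simulated; small-indel evidence instead carries
explicit support counts (`emitGapEvidence()`), with spurious low-support
candidates injected at a low rate to exercise the filters.

The reference simulator (`simulateReference()`) draws the assembly-QV
track in blocks (mean 200 bp) so that a configurable fraction of bases
(default 94%) sits at QV 60, places N-run gaps and a repeat mask, and the
gene-model simulator (`simulateAnnotation()`) places multi-exon
protein-coding genes and then patches the reference so every CDS starts
with ATG, ends with a stop and has no internal stop (transcripts that
overlapping genes leave unresolvable are dropped).

What the generator does *not* emulate: read-level errors correlated along
reads, mapping ambiguity in repeats, colorspace artefacts, GC-dependent
coverage, or gene conversion. Passing tests therefore demonstrate internal
consistency of the methods under their stated models, not performance on
real sequencing data.

All stages derive their RNG streams from one root seed
(`simulationConfig(seed = )`); identical configurations give byte-identical
outputs regardless of evaluation order.

# Genotype calling and quality-stratified filtering

At each pileup column the likelihood of the unordered diploid genotype
$\{a,b\}$ treats every read as drawn from $a$ or $b$ with probability 1/2
and observed correctly with probability $1-\varepsilon$, otherwise
uniformly as one of the other three bases. The prior puts mass
`hetPrior` (default 0.003, the heterozygosity scale of macaques) on the
three reference-containing heterozygotes, `homAltPrior` (default 0.004,
the divergence scale) on the three homozygous-alternative genotypes, a
second-order mass `hetPrior*homAltPrior` on hets containing no reference
allele, and the remainder on homozygous-reference. The call is the MAP
genotype's zygosity class with Phred quality
$-10\log_{10}(1 - p_{MAP})$ capped at 99; if the best genotype of a
*different* zygosity class is within a posterior ratio of
`ambiguityMargin` (default 10, which makes ambiguity rare at depth 40),
the site is called ambiguous and excluded from SNV counts. Ties break
toward the conservative class (hom-ref over het over hom-alt).

Variant calls are retained iff depth $\ge 5$, call QV $\ge 40$ and
reference-assembly QV $\ge 45$; rejections are tallied by the first
failing rule in that order. `discoveryProfile()` reports per-reference-QV
het and hom SNV rates per callable site *before* the reference-QV filter
— it is that filter's diagnostic: real assemblies show inflated
homozygous rates (apparent fixed differences that are really assembly
errors) at low QV while the heterozygous rate stays flat, and the
simulator can inject exactly that pattern. On the male X chromosome only
homozygous SNVs are counted (`maleXMode()`).

# Annotation

Site classes follow a strict priority: coding exon > non-coding (UTR)
exon > intron > intergenic, applied over all transcripts overlapping a
site. Coding effects are computed by codon substitution with the standard
nuclear code (reverse-complementing on minus strands); when several
transcripts' CDS cover a site the highest-impact effect is kept
(nonsense > nonsynonymous > synonymous) and its gene recorded. Transcript
validation rejects CDS lengths not divisible by 3, internal stops,
out-of-bounds intervals, and genes mapped to multiple loci (transcript
clusters on more than one chromosome or disjoint on one). Those three
sequence checks are this package's explicit definition of transcript
"inconsistency"; start-codon presence is deliberately not enforced.
Variants spanning a class boundary take the class of their leftmost
reference base.

# Comparative and population-genetic summaries

`genotypePanel()` aligns per-individual calls on shared coordinates with
species-group labels. Shared SNVs require the same alternative allele in
any non-reference genotype; private SNVs require every other individual
to be homozygous reference (sites with a missing call elsewhere are
dropped); completely differentiated sites require all members of one
group homozygous for one allele and all members of the other group
homozygous for a different allele, no heterozygotes, no missing — the
strictest reading of "completely segregating". The candidate-gene screen
restricts to homozygous nonsynonymous SNVs at differentiated sites and
groups genes by user-supplied category labels (GO ids are treated as
opaque strings).

Diversity and divergence use the resequencing identities: $\pi$ = het
SNVs / callable sites, $d_{xy}$ = (hom + het/2) / callable sites. The
nonsynonymous/synonymous ratio is computed over heterozygous SNVs within
species; between species each SNV is weighted hom + het/2, chosen for
consistency with $d_{xy}$ (raw pooled counts are a one-line variant).
The 2x2 chi-square test is Pearson without continuity correction — at
genome-scale counts the correction is irrelevant — with the p-value from
the $\chi^2_1$ upper tail. The callable-site denominator mirrors the SNV
filters (depth and reference-QV thresholds).

# Structural variants

Small-indel candidates (pre-extracted gapped-alignment evidence with
support counts) are retained when support $\ge 3$, length within the
caller limits (deletions < 12 bp, insertions < 4 bp) and reference QV
$\ge 45$; zygosity is heterozygous below a supporting fraction of 0.75.
Large indels come from mate-pair span deviations: spans above the
library's insert maximum signal deletions, below the minimum insertions;
same-sign discordant pairs with overlapping tag intervals are clustered,
and clusters of $\ge 3$ pairs become calls with size = |median span −
insert midpoint| (robust to outliers; the approximation is exact in
expectation for uniform inserts). Calls from the two libraries merge at
50% reciprocal overlap, transitively; since an insertion occupies almost
no reference footprint, its effective interval for the merge test is its
estimated length centred on the breakpoint. The inversion scan counts
orientation-incongruent pairs by leftmost tag in 500-bp windows sliding
by 250 bp and flags windows with $\ge 50$ incongruent pairs.
Inter-chromosomal pairs cannot be represented in the single-chromosome
mate-pair schema and are out of scope. The module reports its detectable
range from the library specs rather than adopting any fixed empirical
range.

# Demographic inference

The genome is cut into 100-bp bins; a bin is `K` if it contains a retained
heterozygous SNV, `N` if less than half of it is callable, else `T`. A
hidden Markov model over discretised TMRCA intervals is fitted by EM:

* **Time grid.** Boundaries
  $t_k = \alpha(\exp(\frac{k}{n}\ln(1 + t_{max}/\alpha)) - 1)$ with
  $\alpha = 0.1$, $t_{max} = 15$ (scaled in units of $2N_0$ generations —
  more than a million years at macaque parameters), and a grouping
  pattern such as `"6+29*2"` (one group of 6 atomic intervals plus 29
  groups of 2; 64 atomic intervals, 30 free size parameters). The pattern
  grammar is `s` or `n*s` joined by `+`.
* **States.** Atomic interval $k$ is represented by the conditional mean
  TMRCA $\bar t_k$ under the current sizes $\lambda$; the last interval
  extends to infinity for both its prior mass and its mean.
* **Emission.** $P(K \mid t) = 1 - e^{-\theta \bar t}$ with $\theta$ the
  per-bin scaled mutation rate; `N` bins emit 1 in every state.
* **Transition.** Stay with probability $e^{-\rho \bar t_i}$, else jump to
  a state drawn from $q_j \propto \pi_j (1 - e^{-\rho \bar t_j})$, where
  $\pi$ is the coalescent prior over intervals. The weighting by
  $1 - e^{-\rho \bar t_j}$ matters: a jump straight to $\pi$ would not
  leave $\pi$ stationary (short-TMRCA states stay longer and would
  accumulate), while the weighted target makes the chain reversible with
  stationary $\pi$, so the coalescent marginal is preserved along the
  sequence and a fully missing genome has posterior exactly $\pi$
  everywhere. This discretised transition is an approximation to the full
  SMC transition integral; its correctness as an HMM is guarded by an
  exhaustive path-enumeration oracle in the tests rather than by
  comparison with any external implementation.
* **EM.** The E-step is a scaled forward-backward pass (compiled; the
  rank-one transition makes it $O(\text{bins} \times \text{states})$)
  collecting expected emission and transition counts; the M-step
  numerically maximises the expected complete-data log-likelihood over
  $\theta$ and the grouped $\log\lambda_k$, accepting the update only if
  it improves the objective (a generalised EM step, so the log-likelihood
  trace is non-decreasing; the trace is stored in the fit). $\rho$ is held
  fixed at `rhoOverTheta` times the initial $\theta$ (default 0.2; when
  the true ratio of recombination to mutation rate is known, as for
  simulated data, passing it improves tract-length modelling). Forward
  and backward passes share one scaling vector, so no underflow occurs at
  any genome length.
* **Scaling.** $N_0 = \theta / (4 \mu b)$ for bin size $b$;
  $N_k = N_0 \lambda_k$; boundary times in years are $2 N_0 t_k g$ with
  generation time $g$ (default 6 years). Times scale linearly in $g$ and
  inversely in $\mu$.
* **Bootstrap.** Contiguous 5-Mb blocks of bins are resampled with
  replacement to the original length and refitted; percentile intervals
  per atomic interval. The desk-scale default is 20 replicates (the
  percentile band from a small number of replicates is wide, which is the
  conservative direction).

On a 20-Mb simulation of a three-epoch bottleneck (20,000 to 4,000 to
15,000 diploids, epoch changes 20,000 and 60,000 generations ago) the
fitted trajectory places its size minimum inside the bottleneck epoch and
recovers the middle-epoch size within a factor of 2 — the package's
headline property, checked by the test suite and recomputed by
`scripts/acceptance.R`. The most recent and most ancient intervals are
weakly constrained by single-genome data, as with any method of this
family, and should be read with the bootstrap band.

# Numerical and interface choices

* Coordinates are 0-based half-open in memory; pileup, mate-pair and VCF
  positions become 1-based only on disk; BED and bedGraph stay 0-based.
* Percentages in summary tables round half-up (`percentOf()`), matching
  the convention of the emulated report tables. Summary totals are always
  column sums, and the tests verify that on the bundled tables.
* Library coverage-depth totals add per-library depths; since the
  per-library values are themselves rounded to one decimal, this total
  can differ from a depth recomputed from raw base counts in the last
  digit (41.6 vs 41.5 on the bundled table).
* `chiSquare2x2` coerces counts to double before forming products:
  genome-scale counts overflow 32-bit integers.
* The EM refuses degenerate bin sequences (no `K` or no `T` bins), the
  bootstrap refuses genomes shorter than two blocks, and
  `imposeVariants()` rejects $\mu T \ge 0.5$.

# Problem sizes used by the tests and the acceptance script

End-to-end calling is validated on 10 Mb at depth ~41.5; diversity and
divergence on the same simulation; structural variants on 10 Mb with five
planted indels (300-600 bp) and one 100-kb inversion; demographic
recovery on 20 Mb with the `6+29*2` pattern and 25 EM iterations; the
bootstrap coverage check runs at reduced scale (3 Mb, 12 replicates).
These sizes give stable statistics for every property tested while a full
run of the suite stays comfortably on a single desk-scale machine.

# Known limitations

* The caller has no mapping-quality model (the evidence schema carries
  none) and no indel realignment or base-quality recalibration.
* Between-species N/S weighting (hom + het/2) is one defensible choice;
  the within/between contrast is insensitive to it at realistic counts.
* The demographic model's recent and ancient intervals are weakly
  identified; only interior intervals should be interpreted.
* The simulator's neutral model means nonsynonymous/synonymous ratios in
  synthetic data reflect codon structure only, not selection; the N/S
  machinery is validated by counting oracles, not by recovering any
  particular published ratio.
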