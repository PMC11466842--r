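---
title: "Multi-SNP marker screening and error-corrected mixture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-SNP marker screening and error-corrected mixture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmix)
library(dplyr)
set.seed(1)
```

## The problem

Forensic DNA mixtures — traces contributed by several people in very unequal
amounts — defeat conventional STR typing once a minor contributor falls below
roughly 5% of the template. Panels of *multi-SNP markers* (microhaplotype-style
loci: two to five tightly linked SNPs inside a window short enough for one
amplicon read pair) offer an alternative: each locus is multi-allelic, alleles
are read digitally from sequencing, and a minor contributor betrays itself
through alleles the major contributor does not carry. The obstacles are (a)
finding enough polymorphic short windows in the genome and (b) telling a
genuine 0.5%-frequency allele from the cloud of PCR and sequencing artifacts
at comparable abundance.

`msmix` implements a complete desk-scale workflow for this problem: marker
screening from phased population genotypes, allele extraction from aligned
paired-end reads, locus-specific error-rate estimation, an iterative binomial
artifact test under FDR control, genotyping rules, forensic summary
statistics, mixture scoring, and a simulator that generates every input with
ground truth.

## Marker screening: the D-value

For a fixed genomic window (default 75 bp) and a phased cohort of $N$
individuals, the **D-value** is

$$D = \frac{t}{\binom{N}{2}},$$

where $t$ counts unordered pairs of individuals whose *diploid genotypes*
differ at two or more SNP positions inside the window. Two differences are
required because a single biallelic SNP can never separate more than a
fraction of pairs, and an isolated difference is indistinguishable from a
genotyping error. Windows with $D \ge 0.6$ that are free of homopolymer runs
($\ge 6$ bases) and short tandem repeats (2–6 bp motif, $\ge 3$ contiguous
copies) become candidate loci; amplicons are laid out under 140 bp so one
read covers the whole locus.

Two genuinely open choices are worth recording:

* **Genotype vs haplotype comparison.** "Distinguishable pairs of
  individuals" most naturally compares unordered diploid genotypes per
  position, which is what `compute_d_value()` does by default; phase-aware
  comparison (minimum mismatch over the two haplotype pairings) is available
  via `compare = "haplotype"` and is at least as strict.
* **Overlapping windows.** With a 1-bp scan step, good regions produce runs
  of overlapping qualifying windows. `filter_windows()` resolves them
  greedily, keeping the highest-D window of each overlapping cluster. Both
  the step and the policy are arguments.

One property the screener does *not* have: adding a duplicate individual can
raise $D$ (duplicating someone distinguishable from everyone adds $N$ pairs
of which $N-1$ count toward $t$). The test suite pins the exact combinatorial
behaviour instead of a false monotonicity claim.

## From reads to allele profiles

An allele is the concatenated base calls at the locus's SNP positions, read
from a single mate. A mate is used only if fully mapped (no clipping) and
spanning every SNP of the locus; a SNP is masked when it lies within 2 bp of
a repeat tract, an alignment indel, or a run of two or more consecutive
mismatches — the classic signatures of local misalignment. The decisive
filter is **pair concordance**: a read pair counts only when both mates
report the identical allele. Sequencing errors strike mates independently at
rate $e \approx 10^{-3}$ per base, so the probability that both mates agree
on the same wrong base is $e^2/3$ per site — concordance suppresses
sequencing errors by roughly three orders of magnitude. PCR errors, by
contrast, enter the template molecule itself, are inherited by both mates,
and *survive* concordance; they are what the caller must handle statistically.

Base qualities are deliberately ignored by default (`min_baseq = 0`): the
paired-identity rule already dominates, and quality-aware masking is an
optional extra.

## The locus error profile $e_l(n)$

In a single-source sample, at most two alleles per locus are real. Everything
else is an artifact whose **mismatch count** $n$ is its minimum Hamming
distance to a true allele. Averaging, over a cohort of single-source samples,
the fraction of a locus's retained reads carried by distance-$n$ artifacts
yields $e_l(n)$ — an error rate specific to the locus (sequence context
matters) and to $n$ (multiple errors on one molecule are rarer than one).

Implementation decisions:

* **Denominator** = all retained (concordant) reads of the locus in that
  sample.
* **Homozygotes.** A second-ranked allele below `hom_alpha = 0.05` of the top
  count is treated as an artifact, not a true allele — otherwise every
  homozygote's strongest artifact would be declared real and the profile
  would be biased low. Ties for second place are conservatively treated as
  artifacts.
* **Floor and monotonicity.** Unobserved mismatch counts receive
  `floor_rate = 1e-6` so the binomial test is always defined, and the profile
  is made non-increasing in $n$ by a pool-adjacent-violators fit.

The floor rate has a real consequence discussed under *Limitations*.

## The iterative binomial caller

Given a locus profile and its error entry, `call_alleles()` runs:

1. The top-count allele is the **major** allele (count ties break to the
   lexicographically smallest string, making results deterministic).
2. Every remaining candidate with count $c$ at distance $n$ from the major is
   tested against the null "pure artifact of the major": under it,
   $c \sim \mathrm{Binomial}(N, e_l(n))$ with $N$ = major + candidate counts,
   and the evidence is the exact upper tail $P(X \ge c)$.
3. The round's p-values are Benjamini–Hochberg corrected together; candidates
   with $q < 0.005$ become **minor** (true) alleles.
4. Subsequent rounds re-test the remainder against the *most similar*
   accepted allele (minimum Hamming distance, lexicographic tie-break), with
   $N$ = template + candidate counts, until a round accepts nothing.

FDR correction scope is per locus per round by default; `fdr_scope =
"sample"` pools each round's p-values across all loci of a sample. Candidates
with $c = 1$ are tested like any other — there is no count pre-filter.

## Genotyping rules

For single-source samples, loci whose major allele depth exceeds 50 are
genotyped by the ratio $\alpha$ = minor count / major count: all
$\alpha < 0.05$ means homozygous; exactly one allele with
$\alpha \in [0.05, 0.2]$ (both ends inclusive, the lower end forced by the
homozygote rule being a strict inequality) and the rest below 0.05 means
heterozygous; anything else fails. These thresholds are implemented exactly
as stated, which has a counter-intuitive consequence: a *balanced* true
heterozygote ($\alpha \approx 1$) fails the rule. The package asserts this
behaviour verbatim in its tests rather than silently "fixing" it, and the
caller-based route (`genotype_sample(..., use_calls = )`, or simply the
caller's accepted-allele set) is the robust way to recover balanced
genotypes.

## Forensic statistics

`locus_stats()` computes counting-method allele frequencies, observed and
expected heterozygosity ($H_o$, $H_e = 1 - \sum p_i^2$), match probability
(MP, the sum of squared *observed* genotype frequencies), discrimination
power $DP = 1 - MP$, and power of exclusion $PE = h^2(1 - 2hH^2)$ with
$h = H_o$, $H = 1 - h$. These formula variants are stated conventions of
standard forensic software, not facts fixed by the method itself; an
alternative choice (e.g. HWE-expected MP) would change third decimals, not
conclusions. Hardy–Weinberg equilibrium is tested exactly: complete
enumeration of the Levene distribution for biallelic loci, Monte-Carlo
permutation of the allele vector (conditional-probability statistic,
default $10^5$ permutations) for three or more alleles. Panel-level values —
combined match probability, total discrimination power, combined power of
exclusion, and the Bonferroni threshold $0.05/L$ (which is `0.00008818` for
the 567-locus panel) — are accumulated in log space, and `log10_cmp` is
reported because the plain product of 567 match probabilities underflows.

Exact-test p-values are discrete and conservative; the calibration test
checks type-I control rather than strict uniformity, which no faithful exact
test would pass.

## The simulator and its assumptions

`sim_panel()` → `sim_population()` → `sim_reads()` generates the full study
with ground truth. The generative model, per locus:

1. **Templates.** Each contributor haplotype contributes
   $\mathrm{Poisson}(m \cdot f / 0.0033)$ template molecules, where $m$ is
   total input in ng, $f$ the contributor's mass fraction, and 3.3 pg the
   haploid genome mass. This molecule model links nanogram inputs to dropout:
   at the lowest dilution-series input (0.00976563 ng ≈ 3 haploid copies) a
   haplotype drops out with probability $e^{-2.96} \approx 5\%$ per slot.
2. **PCR layer.** Each molecule's allele is mutated once at `pcr_error` per
   base (default $10^{-4}$); both mates of every descendant read inherit the
   mutation, so these errors survive concordance. A single-hit layer (rather
   than per-cycle branching) is enough to exercise the caller, which
   abstracts the compound process through $e_l(n)$.
3. **Depth.** $\mathrm{Poisson}(\texttt{mean\_depth})$ read pairs per locus
   (default 1150, matching the deep-sequencing regime the panel targets),
   assigned to molecules uniformly.
4. **Sequencing layer.** Each mate misreads each base independently at
   `seq_error` (default $10^{-3}$, the typical short-read figure); pairs are
   then concordance-filtered exactly as the extractor would.

Two presentation modes exist: `detail = "counts"` draws the sequencing layer
at molecule-group level from its exact per-pair outcome law (identical in
distribution, fast enough for hundreds of samples), while `detail = "pairs"`
emits every read pair with its molecule id and post-PCR allele so tests can
re-count truth independently, and `write_sim_sam()` can render pairs as
SAM + FASTA for integration-testing the extractor.

Fixed generator choices, made once:

* **Haplotype frequencies** are symmetric Dirichlet over the $2^S$ haplotype
  space with concentration 0.25, which gives simulated panels a mean expected
  heterozygosity near 0.55 — the level reported for real panels of this kind.
* **Category mix** defaults to the 567-locus kit's printed composition
  (48/157/246/91/25 loci with 1–5 linked SNPs), allocated by largest
  remainder so the default panel reproduces it exactly.
* **SNP spacing** within a window is at least 3 bp, so substituted alleles
  never mimic the extractor's consecutive-mismatch artifact signature.
* The synthetic reference is generated free of repeat tracts inside
  amplicons, keeping the repeat mask neutral on simulated data.

What the simulator does **not** model: per-cycle PCR branching, amplification
efficiency differences between loci or alleles (beyond an optional depth
multiplier), primer-binding bias, fragmentation/degradation, or instrument
quality scores. Passing tests on simulated data therefore demonstrate the
*statistical machinery* under the stated error model, not performance on any
particular instrument or chemistry.

## Study-level results the package computes

`run_minor_detection_study()` reproduces the mixture-study conditions at desk
scale: a 567-locus panel, an error profile from 100 simulated single-source
samples, then 2-, 3- and 4-person mixtures (four replicates each) at 1 ng
total with the minor contributor at 0.5% of template mass, depth 1150,
sequencing error $10^{-3}$, PCR error $10^{-4}$, caller FDR 0.005. It reports
the pooled fraction of *minor-unique* alleles (alleles of the minor absent
from every other contributor at that locus) the caller recovered. Under these
conditions the minor contributes about 1.5 template molecules per haplotype,
so molecule dropout alone caps detection near 78%; the measured value sits in
the mid-60s percent range.

`run_fdr_study()` simulates 200 single-source samples, estimates $e_l(n)$ on
half, calls the other half, and reports the pooled false-discovery proportion
among accepted minor alleles (in a single-source sample every accepted allele
beyond the individual's two haplotypes is false by construction).

## Limitations worth knowing

* **Molecule-level error clustering defeats the per-read null.** At depth
  1150 over ~600 templates, every template yields ~2 read pairs, so one
  PCR-mutant molecule surfaces as 2–4 concordant pairs. The binomial null
  with $e_l(1) \approx 3 \times 10^{-4}$ expects ~0.3 artifact reads per
  locus and therefore flags such a cluster as a real allele — which is
  *exactly* the signature of a genuine 0.5% contributor. Consequently the
  empirical false-discovery proportion on single-source samples under the
  full two-layer model runs in the percent range, far above the nominal 0.5%
  FDR, and no threshold can lower it without sacrificing minor-allele
  detection at the same read counts. The FDR guarantee holds in the regime
  the test assumes: read-independent errors and a correctly specified error
  profile (verified in the test suite).
* **The floor rate under-covers rare error classes.** Finite training
  cohorts leave some $(l, n)$ classes unobserved; the floor $10^{-6}$ then
  lets single stray pairs through at those loci. Larger cohorts shrink the
  effect; the floor is a parameter.
* **The $\alpha$-window genotyper fails balanced heterozygotes** (see
  above) — use the caller route when that matters.
* HWE enumeration is exact only for biallelic loci; multi-allelic loci use
  the standard Monte-Carlo exact test with a seedable permutation count.

## Problem sizes used by the shipped checks

The packaged tests and the acceptance script run the full 567-locus panel
with 100-sample error profiles for the mixture study and 200 single-source
samples for the FDR study; oracle-based property tests use cohorts up to
$N = 20$ and windows up to 10 SNPs, where exhaustive enumeration is cheap.

## A worked mini-example

```{r example}
panel <- sim_panel(60, seed = 7)
pop <- sim_population(panel, 30, seed = 8)

# error profile from 20 single-source samples
profiles <- sim_cohort_profiles(panel, pop, sprintf("I%03d", 1:20), seed = 9)
ep <- estimate_error_profile(profiles, panel = panel)
glance(ep)

# a 99.5 : 0.5 two-person mixture
mix <- sim_reads(panel, pop, c(I021 = 0.995, I022 = 0.005), seed = 10)
calls <- call_sample(mix$profile, ep)
glance(calls)

minor_distinguishability(calls, mix$truth$alleles, "I022")
```

```{r plots, fig.width=6, fig.height=4}
autoplot(ep)
```
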