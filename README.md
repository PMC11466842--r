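# msmix

Multi-SNP marker screening, error-corrected allele calling and DNA mixture
evaluation.

`msmix` is an R toolkit for forensic analysis of DNA mixtures with short
**multi-SNP** (microhaplotype-style) amplicon panels — loci of 1–5 tightly
linked SNPs inside a 75-bp window whose phased base combination forms a
multi-allelic haplotype allele. It is aimed at forensic genetics and
bioinformatics researchers who need to (a) screen phased population
genotypes for polymorphic short-window markers, (b) call alleles from deep
amplicon sequencing while separating genuine sub-percent minor-contributor
alleles from PCR/sequencing artifacts, and (c) quantify what such a panel
can and cannot detect — all reproducibly, with a simulator supplying ground
truth.

## The statistics at the core

**Marker screening.** For a window over a phased cohort of N individuals,
the diversity value is

    D = t / C(N, 2)

where `t` counts unordered pairs of individuals whose diploid genotypes
differ at ≥ 2 SNP positions inside the window. Windows with D ≥ 0.6, free of
homopolymers and short tandem repeats, and coverable by a < 140 bp amplicon
become panel loci (`scan_windows()`, `filter_windows()`).

**Error-corrected allele calling.** Read pairs are kept only when both mates
report the identical allele (independent sequencing errors almost never
coincide), and a locus-specific error profile `e_l(n)` — the mean read
fraction of artifact alleles carrying `n` mismatches to a true allele,
estimated from single-source samples — feeds an iterative exact binomial
test: a candidate allele with count `c` against template count `N − c` is an
artifact under `c ~ Binomial(N, e_l(n))`, and candidates with
Benjamini–Hochberg `q < 0.005` are accepted as true minor alleles, round by
round, each round re-templating on the most similar accepted allele
(`estimate_error_profile()`, `call_alleles()`, `call_sample()`).

Around this core sit α-ratio genotyping rules (`genotype_sample()`),
forensic panel statistics — He/Ho, match probability, discrimination power,
power of exclusion, exact HWE tests, combined panel values and Bonferroni
thresholds (`locus_stats()`, `combine_panel()`) — mixture scoring
(`detection_rate()`, `minor_distinguishability()`), and a two-layer
(molecule-level PCR + per-base sequencing) read simulator with full ground
truth (`sim_panel()`, `sim_population()`, `sim_reads()`, `design_grid()`).

## Worked example

Simulate a 60-locus panel and population, train an error profile on 20
single-source samples, then call a 99.5 : 0.5 two-person mixture:

```r
library(msmix)

panel <- sim_panel(60, seed = 7)
pop   <- sim_population(panel, 30, seed = 8)

profiles <- sim_cohort_profiles(panel, pop, sprintf("I%03d", 1:20), seed = 9)
ep <- estimate_error_profile(profiles, panel = panel)
glance(ep)
#>   n_loci n_usable  mean_e1 floor_rate
#> 1     60       60 0.000300   0.000001

mix   <- sim_reads(panel, pop, c(I021 = 0.995, I022 = 0.005), seed = 10)
calls <- call_sample(mix$profile, ep)
glance(calls)
#>   n_loci n_alleles_tested n_major n_minor n_artifact max_iteration
#> 1     60              143      60      75          8             2

minor_distinguishability(calls, mix$truth$alleles, "I022")
#>   minor_id n_unique n_called  rate
#> 1 I022           50       35   0.7
```

Reading the numbers: the trained profile's mean distance-1 error rate is
3.0e-4 (set by the molecule-level PCR error layer); in the mixture the
caller tested 143 alleles across 60 loci, accepted 75 minors and rejected 8
as artifacts; of the 50 alleles unique to the 0.5% minor contributor, 35
(70%) were recovered — e.g. a 7-read allele at one locus was accepted with
p ≈ 4e-25 against its 1100-read template. `autoplot()` methods exist for
error profiles, call sets and locus statistics; `tidy()`/`glance()` return
plain tibbles.

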