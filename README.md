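# haplofine

Fine-mapping toolkit for disease loci where a handful of tag SNPs define
common local haplotypes and one haplotype — often common in one ancestry
group and rare in another — is suspected of carrying extra,
population-specific causal variation. The package is aimed at statistical
geneticists who have (i) unphased tag-SNP genotypes with a binary outcome
in case-control cohorts, and (ii) phased sequence over the locus in a
subset of individuals, and who want to go from haplotype association all
the way to candidate causal variants and their downstream molecular and
clinical correlates.

## What it computes

**Haplotype association.** Haplotype frequencies `p_h` are estimated from
unphased genotypes by EM on the multinomial likelihood
`sum_i log sum_{ {h,h'} ~ g_i } c_hh' p_h p_h'`, and haplotype effects on
disease are tested with a posterior-weighted logistic regression: each
individual is expanded over its compatible haplotype pairs, weighted by
the phase posterior, and an additive dosage model relative to a reference
haplotype is iterated to convergence (haplotypes with frequency < 0.05
pooled as rare).

**Chromosome painting.** Phased chromosomes are painted against a donor
panel under a Li–Stephens copying HMM — switch probability
`1 − exp(−ρ·d_j)` per interval with a uniform donor prior, emission
mismatch `θ` — using scaled forward–backward (posteriors) and Viterbi
(hard paths). Donor posteriors are collapsed to tag-haplotype labels.

**Critical region and specific variants.** The critical region is the
maximal run of sites at which every painted target-homozygote chromosome
carries the target label, bounded by observed switch events (≥ 2 distinct
chromosomes per flank) and extended by 5% per side (23.9 kb → +1.2 kb per
side → 26.3 kb). Per-group majority consensus sequences are compared, and
a site is called *specific* when the target allele differs from every
other group's unambiguous consensus. Per-group frequency tables and
phased-haplotype LD r² complete the layer.

**Association stages.** Cis-eQTL scan (OLS, ±500 kb, MAF ≥ 0.05, latent
factors from residualised SVD, one BH family), conditional effects,
single-component REML kinship mixed model, proportional-odds severity
regression, stratified additive modifier tests, and a Monte Carlo
global-null test: the probability of at least `k` of `m` correlated tests
reaching `p < α`, with `z ~ MVN(0, R)`.

**Synthetic cohorts.** A generator with ground-truth records (founder
mosaics with controllable LD contrast, injected haplotype-specific
variants, phenotypes under additive haplotype log-odds, correlated
traits, ordinal severity, family kinship) drives every calibration and
recovery test.

## Worked example

```r
library(haplofine)
cfg <- sim_config(seed = 11)          # two-population synthetic cohort
res <- run_pipeline(cfg, "haplofine_run")

print(res$haplotypes$short$glm)
#> haplo_glm_fit (reference 00000, 24 iterations):
#>   haplotype       freq        beta        se                or ...
#> 1     11111 0.33680390  0.30058210 0.3232222 1.35 [0.72, 2.54]
#> 2     11100 0.20569164  0.79087052 0.3410827 2.21 [1.13, 4.30]
#> 3     10110 0.15005393  0.58467730 0.3708963 1.79 [0.87, 3.71]
#> ...

res$summary$specific_variants
#> $n_called 14   $recall 1   $precision 0.643   $segment_overlap 1
res$summary$eqtl_top
#>     variant     gene     beta            p            q
#> 249  var_95 cis_gene 0.425691 2.006315e-06 0.0008707408
res$summary$severity_beta
#> [1] 1.511492
```

The short-LD population carries a planted odds ratio of 1.67 on the
`11100` haplotype; the fitted OR here is 2.21 with 95% CI [1.13, 4.30]
(covering the truth — the package's calibration suite verifies 95%
coverage over 200 replicates). All nine injected specific variants are
recovered (`recall = 1`); the extra calls are genuine consensus
differences arising from founder backgrounds, which is why the controlled
group generator (`simulate_group_panel()`) is the setting where precision
is exactly 1. The injected variants are cis-eQTLs for the planted target
gene (`q = 8.7e-4` at FDR ≤ 0.10), and the planted ordinal severity
effect (β = 1.58) is estimated at 1.51.

A thin command-line wrapper is installed at
`system.file("scripts/run_pipeline.R", package = "haplofine")`:

```sh
Rscript run_pipeline.R --config my_config.yml --out run_dir --seed 7
```

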