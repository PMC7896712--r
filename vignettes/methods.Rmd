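---
title: "Benchmarking genomic inbreeding coefficients as estimators of inbreeding depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking genomic inbreeding coefficients as estimators of inbreeding depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

The rate of inbreeding depression (ID) of a quantitative trait is
conventionally estimated as the slope of the regression of individual
phenotypes on individual inbreeding coefficients *F*.  With dense SNP
data, *F* itself must be estimated, and the available genomic measures
differ in what they actually track: SNP-by-SNP measures (VanRaden's
diagonal, the Hardy–Weinberg excess measures, the
correlation-between-uniting-gametes measure that up-weights rare
alleles) describe deviations of homozygosity from expectations under
current allele frequencies, while runs-of-homozygosity (ROH) measures
target identity by descent directly.  Empirical comparisons cannot
settle which measure estimates ID best because the true ID of real
populations is unknown.  `idbench` provides a genetically explicit
simulation in which the true ID *is* known, together with every
estimator in the comparison, so that bias and root-mean-square error
(RMSE) of each *F* measure can be quantified under controlled
population-genetic conditions.

## The simulation model

`run_replicate()` simulates a diploid monoecious Wright–Fisher
population of constant size *N* with discrete generations and random
mating.  The genome is a single continuous sequence of length *L*
(default 100 Mb) with per-adjacent-bp recombination rate *c* (default
1e-8, i.e. 1 cM/Mb and a 1 Morgan map — the scale of a mammalian
chromosome).  Starting from a population devoid of variation, mutations
enter at rate *U* per haploid genome and generation, at uniformly drawn
bp positions under an infinite-sites convention (occupied positions are
redrawn; no back mutation).  A fraction `prop_causal` (default 5%) of
mutations are QTLs with a pleiotropic effect on fitness and on the
trait; the rest are neutral SNPs.

Genotypic values at a QTL are 0, *ah*, *a* for the trait and 1, 1 + *sh*,
1 + *s* for fitness.  Fitness is multiplicative across loci (floored at
zero), the trait additive; phenotypes carry no environmental noise, so
every deviation of an ID estimate from truth is attributable to the
*F* measure itself.  Homozygous effects |*s*| and |*a*| are
gamma-distributed with mean |`mean_s`| (default 0.03) and shape `beta`
(default 1, i.e. exponential); `rho` (default 1) is the Pearson
correlation between |*a*| and |*s*|.  For `rho < 1` the two gamma
marginals are coupled through a Gaussian copula whose latent
correlation is solved by Gauss–Hermite quadrature so that the Pearson
correlation of the marginals equals `rho` exactly — the construction is
our choice, as only the marginals and their correlation are specified
by the study conditions.  Dominance is constant (*h* = 0.2 by default;
*h* = 0 gives full recessives) or, under `h_model = "variable_CK"`,
drawn per locus as *h* ~ U[0, exp(−*k*|*s*|)] with *k* solved in closed
form so that E[*h*] matches the target mean — the classical
inverse relationship between dominance and selection strength.

Each generation, every one of the *N* offspring draws two parents
independently with probability proportional to fitness (fecundity-style
selection; the monoecious model permits selfing, including drawing the
same parent twice).  Each parent transmits one gamete formed with a
Poisson(*c*(*L*−1)) number of crossovers at uniform positions without
interference, plus Poisson(*U*) new mutations.  Sites fixed or lost are
compacted out of the state after every generation with logged counters;
fixed trait effects shift the population mean uniformly and therefore
cannot affect any regression on *F*.  All randomness flows from R's
RNG, so a replicate is fully reproducible from one integer seed.

## Truth: the inbreeding load

The true ID is the inbreeding load *B* = Σ 2*dpq* over segregating
QTLs, with *d* = *a*(*h* − ½) (`true_id_2dpq()`).  Because effects are
deleterious and partially recessive, every *d* > 0 (directional
dominance) and *B* > 0.  As a cross-check, `true_id_forced_homozygosity()`
forces complete homozygosity *in expectation* — each heterozygous QTL
value *ah* is replaced by the homozygote average *a*/2 — and measures
the decline of the trait mean.  Computing the replacement in
expectation rather than by random allele fixing removes Monte Carlo
noise from a quantity that equals Σ 2*dpq* exactly under Hardy–Weinberg
proportions and tracks it within a few percent on simulated data.  The
population's own mean *F* (≈ −1/2*N*) is treated as zero when reading
the mean change as a per-unit-*F* rate; at the population sizes
considered the distinction is far below the replicate noise.

## Calibration

Two rates are calibrated to the study conditions rather than fixed a
priori (`calibrate_rates()`):

* *U* targets ≈ 30,000 segregating neutral SNPs in the final
  generation.  The initial value comes from the neutral Watterson
  expectation E[S] = 4*N U* Σ 1/*i* (≈ 12.8 at *N* = 100), and pilot
  replicates rescale it linearly to the observed count.
* `trait_scale` multiplies all trait effects so that the realized *B*
  is ≈ 1 (about 1% trait decline per 1% inbreeding; one haploid lethal
  equivalent).  Trait effects have no influence on allele dynamics —
  selection acts through *s* only — so *B* is exactly linear in
  `trait_scale` and one pilot round suffices.  Note that all reported
  *proportional* deviations are invariant to this scale.

## The measurement chain

`extract_marker_panel()` takes *all* individuals and *all* segregating
neutral SNPs (QTLs removed, no MAF pruning — sampling noise is excluded
by design) and recodes genotypes to minor-allele dosages with
current-generation frequencies; ties at frequency 0.5 keep the derived
allele.  PLINK PED/MAP text files are supported as the exchange format
(`write_ped_map()` / `read_ped_map()`); PED cannot encode which allele
is derived, so that flag does not survive a round trip.

The SNP-by-SNP estimators `f_I()`, `f_II()`, `f_III()` and `f_hom()`
are the GCTA `--ibc` trio and PLINK `--het` measure.  `f_III_delta()`
is an algebraically equivalent reformulation of `f_III()` through
per-genotype weights (1/*p* for minor homozygotes, 1/(1 − *p*) for
major homozygotes) kept solely as an independent numerical cross-check;
the two agree to 1e-12 by test.  All four estimators are invariant to
allele relabelling, and with panel frequencies the population means of
`f_I`, `f_II` and `f_III` are *identical* (an algebraic identity the
tests assert at 1e-10), while `f_hom`, a ratio of sums, agrees only
approximately.  Supplying frequencies recorded at an earlier reference
generation instead makes the estimators measure IBD relative to that
generation; under neutral drift their mean then follows the pedigree
expectation 1 − (1 − 1/2*N*)^*t*, which is verified as a property test.

For the ROH route, the panel is first LD-pruned (`ld_prune()`, PLINK
`--indep-pairwise 50 5 0.9` semantics).  PLINK's choice of which SNP
of a flagged pair to drop is version-dependent, so the rule is pinned:
the smaller-MAF member goes, ties drop the downstream SNP.  `call_roh()`
then applies the PLINK 1.9 `--homozyg` default window scan: 50-SNP
windows with at most one heterozygote are homozygous, SNPs covered by
at least 5% homozygous windows are eligible, and maximal eligible runs
are split at gaps > 1,000 kb and filtered by ≥ 100 SNPs, the length
threshold and ≥ 1 SNP per 50 kb.  Segment span is the first-to-last-SNP
distance, and `f_roh()` divides the spanned length by the configured
genome length *L* (not the SNP-covered range) — both conventions are
stated because the source protocols leave them implicit.  The length
thresholds 0.1 / 1 / 5 Mb replace PLINK's single default.  Because the
window scan needs several homozygous windows to cover a SNP, called
segments can be a few SNPs short of (or beyond) an idealized
homozygous tract; the unit tests therefore compare against an explicit
window-enumeration oracle rather than naive tract boundaries.

`hml_counts()` reports the homozygous mutation load: the count of loci
homozygous for the *derived* (mutant) allele over all neutral SNPs
(HML), over neutral SNPs with MAF ≤ 0.05 (HML_MAF; the boundary is
inclusive), and over QTLs (HML_QTL).  "Homozygous mutation" is read as
derived-allele homozygosity rather than minor-allele homozygosity; at
the low frequencies where the load matters the two coincide.

`estimate_id()` returns minus the OLS slope of phenotype on *F*, so
estimates carry the same sign as *B*.  `analyze_replicate()` assembles
everything — per-individual *F* table, loads, phenotypes, true ID,
per-estimator proportional deviations (Est − True)/True, and the full
Pearson correlation matrix — and `run_scenario()` /
`aggregate_replicates()` summarize replicates: mean deviation with the
empirical central 95% interval (2.5% trimmed each side), RMSE of the
proportional deviations with a nonparametric bootstrap SE (1,000
resamples; the SE method is our choice), and averaged correlation
matrices with SEs.  RMSE is computed on proportional deviations; with
*B* calibrated to ≈ 1 this coincides numerically with the absolute
scale.  Correlations are stored with their mathematical signs; because
trait effects are negative, phenotype–load and phenotype–*F*
correlations are negative, and summaries that quote the published
positive convention report their magnitudes.

## Scenario presets and problem sizes

`scenario_config()` exposes the variant conditions as named presets:
`c_high`/`c_low` (recombination ×10/÷10), `quarter_density` (SNP target
7,500, i.e. *U*/4), `pc10` (10% causal), `s01` (mean *s* = −0.1),
`beta01`/`beta2` (gamma shape 0.1/2), `h0` (full recessives), `rho05`.
A short-genome variant (60 Kb, 1 Morgan, `variable_CK` dominance, ROH
threshold 1 Kb) is likewise expressible through `sim_config()` and
`roh_params()` arguments.

The default replicate — *N* = 100 run for 10*N* = 1,000 generations to
≈ 30,000 SNPs on 100 Mb — takes roughly 13 s of simulation plus 2 s of
analysis on one core.  The packaged analyses therefore use 30–40
replicates at *N* = 100; means and RMSEs are consistent estimators, so
the reduced replicate count relative to a large simulation study widens
confidence intervals without moving the targets.  Larger population
sizes (*N* = 1,000–10,000 at 10*N*/5*N* generations) are supported by
the same configuration but are cluster-scale computations, and the
cross-*N* trends (the shrinking upward bias of the rare-allele-weighted
measure, the growing ROH underestimation) are not asserted by the test
suite.

## What the generator does and does not emulate

The simulated populations are idealized: constant census size equal to
effective size, a single chromosome with uniform recombination and
mutation, no population structure or migration, no environmental
variance, no heterozygote advantage, pleiotropy of every causal locus,
and one shared effect-size distribution.  Passing tests therefore
demonstrate the estimators' behaviour under drift, recombination and
purifying selection — the mechanisms the benchmark isolates — not their
performance under stratification, assortative mating, genotyping error
or LD heterogeneity of real data sets.

## Numerical and degenerate-case choices

Monomorphic sites never reach the estimators (the state keeps only
segregating sites), so no frequency clamping is applied; externally
supplied frequencies of 0 or 1 are an error, not a silent skip.
Missing genotypes exist only through the PED reader (PLINK code 0) and
are rejected by the estimators, which assume complete data.  A
replicate whose individuals all have zero fitness aborts with a
diagnostic, and `run_scenario()` logs and excludes failed replicates.
A zero-variance *F* vector flags the replicate rather than producing an
infinite slope.  The effect-sampler's copula correlation is solved to
1e-9; `f_III` and its delta form agree to 1e-12.

## Reading the output

In the default *N* = 100 conditions the package reproduces the known
contrast between the measures: the rare-allele-weighted SNP measure
(`F_III`) overestimates ID by about half of its value, the
Hardy–Weinberg excess measure (`F_HOM`) underestimates by about a
third, the VanRaden and second GCTA measures are strongly downward
biased, and the ROH measures are essentially unbiased with the smallest
RMSE — numbers the test suite and `scripts/acceptance.R` recompute from
scratch on every run rather than this vignette asserting them as
constants.
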