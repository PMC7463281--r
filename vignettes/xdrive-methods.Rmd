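---
title: "Methods: models and estimators in xdrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and estimators in xdrive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(xdrive)
```

`xdrive` studies a driving Sex-Ratio (SR) X chromosome: a haplotype of
linked inversions whose carrier males sire almost exclusively daughters.
The package couples pooled-sequencing population genomics (F~ST~,
diversity, divergence dating, site classification), a coalescent null
model, haplotype-panel linkage disequilibrium, and deterministic
two-locus drive models, plus seeded generators for every input format.
This vignette records the models and the derivations behind the less
standard pieces, and documents where our computed values disagree with
the target values the package set out to reproduce.

## Notation

Gametes are tracked at two loci: locus A marks the basal + medial
inversion unit, locus B the terminal inversion. The four gamete types
are ST (`ab`), SR (`AB`), and the recombinants BM (`Ab`, basal + medial
only) and T (`aB`, terminal only). Measured segregation proportions
(proportion of female progeny from carrier fathers) are:

```{r}
measured_k()
```

## Gametic decay and survey LD

With recombination fraction `c` in female double heterozygotes and no
selection, the association `D` between the two loci decays as
`D(t) = D(0) (1 - c)^t`, so the half-life is `log(0.5)/log(1 - c)`:

```{r}
half_life(0.0012)
```

Note the exact value is 577.2768 generations; we round to 577.

`survey_ld()` computes `D`, `r^2`, and `d'` from a four-type frequency
vector. On the pooled survey frequencies shipped with the package:

```{r}
survey <- sr_survey_table()
pooled <- survey[survey$pooled, ]
survey_ld(c(ST = pooled$ST, SR = pooled$SR, BM = pooled$BM, T = pooled$T))
```

## The diploid drive recursion

`diploid_step()` iterates the exact genotype recursion for an X-linked
two-locus system: females are ordered pairs of gametes (a 4×4 matrix
`F`), males a hemizygous 4-vector `m`.

Each generation:

1. **Viability selection.** A recessive cost `costs[g]` removes a
   fraction of `g/g` homozygous females and — by default — of
   hemizygous `g` males. The female-only variant
   (`male_expressed = FALSE`) is retained as an option, but it cannot
   balance strong drive: the drive advantage of SR is linear in its
   frequency while the recessive female cost is quadratic, so with
   `k = 0.969` no female-limited cost of any size holds SR as low as its
   observed equilibrium frequency of 0.135. Expressing the recessive
   cost in hemizygous males as well (the standard X-linked exposure)
   restores a balance, which is why `male_expressed = TRUE` is the
   default. This is a deliberate, documented deviation from a
   female-only formulation.
2. **Female gametogenesis.** Double heterozygotes recombine with
   probability `c`; all other genotypes transmit their gametes
   Mendelian. Recombination is female-limited (no crossing over in
   males).
3. **Male gametogenesis with drive.** A father of type `g` contributes
   X-bearing sperm in proportion `k[g]` (daughters) and Y-bearing in
   proportion `1 - k[g]` (sons); paternal gametes to daughters are
   therefore weighted by `m[g] k[g]`, normalized.
4. **Union** of maternal and paternal gametes forms the next `F`;
   maternal gametes alone form the next `m`.

The pooled X-chromosome gamete frequency is `2/3` female + `1/3` male,
reflecting the 2:1 residence of X chromosomes in the two sexes.

The recursion is verified against an independent exhaustive
mating-table enumeration at tolerance 1e-12 in the test suite.

### Drive–selection balance (`find_balance_cost`)

With ST Mendelian (`k = 0.5`) and `k_SR = 0.969`, bisection on the SR
cost for an interior pooled equilibrium at frequency 0.135 gives:

```{r}
find_balance_cost(k_full = 0.969, target = 0.135)$percent
```

This 42.0% is within one percentage point of the 43% target.

### LD half-life in the full recursion

`ld_decay_experiment()` initializes the population at the
drive–selection balance for the full four-type system (all four
measured `k` values, balance cost solved internally), starts from
complete association between the two inversion loci, and iterates with
`c = 0.0012`:

```{r}
ex <- ld_decay_experiment(t_max = 150)
ex$half_life
```

The pooled-pool `D` reaches half its initial value after **54**
generations (53 in the female pool, 55 in the male pool), against a
target of **47**. We scanned the defensible variants honestly before
settling on the default: Mendelian ST gives 81 generations, starting
from an unburned (non-equilibrium) state gives 60, and the half-life of
`r^2` rather than `D` gives 44. None reproduces 47 exactly; the target
evidently depends on model details that are not derivable from the
headline quantities. The fallback property suite (one-generation oracle
equivalence, fixed-point stationarity at balance, monotone decay)
passes at tight tolerances, and the 54-vs-47 discrepancy is reported in
the acceptance test output rather than hidden.

### Recombinant exclusion costs (`min_cost_to_exclude`)

`min_cost_to_exclude(type)` bisects on a recessive cost applied to a
recombinant class and classifies the long-run outcome of the full
recursion as SR *lost* or *persists*, returning the threshold cost at
which a cost-free recombinant would just fail to displace SR.

```{r, eval = FALSE}
min_cost_to_exclude("BM", tol = 5e-3)$percent # 6.84
min_cost_to_exclude("T")$percent # 0, with no_threshold = TRUE
```

Our computed values are **6.84%** for BM (target 29%) and **0** for T
(target 1%). For T the disagreement is structural: with its measured
`k = 0.426`, below the ST baseline of 0.439, the terminal-only
recombinant can never accumulate against SR at any cost, so no
threshold exists (`no_threshold = TRUE`); the numeric value 0 happens
to fall within the ±1 percentage-point tolerance, but the model
behavior differs in kind from a small positive threshold. For BM we
scanned ST `k` of 0.5 vs 0.439, male-expressed vs female-only costs,
and an SR-loss vs recombinant-overtakes-SR criterion; the SR-loss
threshold is 6–9% and the overtake threshold about 24% under every
variant. The 29% target is not reproducible from the headline
quantities; the computed values are reported as-is.

## The haploid pairing model (`fit_haploid_s`)

Rare recombinant classes can be analyzed with a reduced haploid model.
A class `g` at frequency `y` obeys

`y' = (1 - s_g) (lambda_g y + P)`,

where `P = (c/2) p_SR p_ST` is per-generation recombinant production
(the factor 1/2 because only one of the two recombinant products is of
type `g`), and

`lambda_g = (2 + 2 k_g) / (2 + 2 k_ST)`

is the relative per-generation transmission of an X-linked type with
segregation proportion `k_g`: of the three X chromosomes per
male-female pair, two pass through the female Mendelian and one through
the male weighted by `k`, normalized to the measured ST baseline. The
equilibrium is `y* = (1 - s) P / (1 - (1 - s) lambda)`, which inverts
in closed form for `s`. Fitted to the pooled survey frequencies:

```{r}
fit <- fit_haploid_s(c(ST = pooled$ST, SR = pooled$SR,
                       BM = pooled$BM, T = pooled$T), c = 0.0012)
fit$fits
```

The fitted coefficients, s_T = 0.313 and s_BM = 0.652, are within 0.003
of the targets (0.316, 0.649). The textbook four-gamete recursion with
production `cD` cannot reproduce those targets (it gives roughly
0.93/0.48); the halved production term and the pairing transmission
ratio above are what make the inversion work.

## Pooled sequencing estimators

**F~ST~** (`fst_windows`, `fst_region`) is the method-of-moments
pool-seq estimator in identity-probability form. Per site, within-pool
identity is estimated from read counts with a read-resampling
correction, `D2 = sum c(c-1) / (r(r-1))`, then corrected for the finite
pool of `n` chromosomes, `Q1 = (D2 - 1/n)/(1 - 1/n)`; between-pool
identity is `Q2 = sum p1 p2`. The multilocus estimate is a ratio of
sums, `F_ST = (sum(Q1 - Q2)) / (sum(1 - Q2))`, with SNP-bootstrap
confidence intervals. Negative estimates near zero differentiation are
expected and flagged, not clipped. The test suite checks agreement with
an independent loop transcription at 1e-12.

**Diversity** (`diversity_windows`) implements min-count corrected
pooled π and Watterson's θ: each correction factor is a sum over the
neutral SFS (weight `1/k`) of the binomial probability that a site at
chromosome frequency `k` is observed with at least `min_count` copies
of each allele in the reads. At `min_count = 1` and deep coverage the
corrections recover the classical `(n-1)/n` and `a_n` limits. Tajima's
D uses the classical constants at the pool haploid size — a documented
approximation. Windows with too little callable sequence are skipped
rather than extrapolated.

**d~XY~** (`dxy_region`) uses exact per-site `1 - sum(p1 p2)` averaged
over callable sites, with optional frequency-draw uncertainty and a
site bootstrap.

**Site classification** (`classify_sites`) polarizes biallelic sites
against an outgroup into fixed-derived (per pool), shared, private,
and monomorphic categories, with windowed summaries.

**Divergence dating** (`window_scaled_ages`) scales a focal
differentiation measure by a calibration measure window-by-window,
after a Budowle-style transform to a time-linear scale, excluding
windows where the calibration is zero and optionally weighting by SNP
count; a self-calibration run returns the calibration age exactly.

## Coalescent null model

`demography_scenario()` + `simulate_neutral_replicates()` implement a
Kingman coalescent with a piecewise demography: an SR subpopulation of
a chosen fraction of the X-linked effective size (with the ×3/4
X-chromosome correction), forced common ancestry of the SR sample at
the SR origin time, and species-split coalescence deeper still.
`neutrality_test()` compares an observed π ratio to the simulated null;
rejection is one-sided in the low tail (an SR chromosome with *less*
diversity than even a recent-origin neutral model predicts). Closed
forms (`E[T2] = N`, Watterson's `E[S]`) are verified to within Monte
Carlo error in the test suite.

## Haplotype panels and mapping statistics

`read_haplotype_panel()` reads aligned FASTA with `strain|arrangement`
names; `build_segregating_matrix()` drops indel columns and minor
alleles below `min_minor`, optionally polarizing against an outgroup
sequence. `ld_matrix()` gives pairwise `r^2` with chi-square or
permutation significance; `arrangement_fet()` runs Fisher's exact test
of each site against arrangement, both with Benjamini–Hochberg
q-values and a `min_attainable_p` power guard.

Mapping helpers: `recomb_fraction()` (Clopper–Pearson),
`kosambi_cm()`, `chi2_reciprocal()` (including the exact binomial
p-value `2 × 0.5^n` for an n:0 split), and `segregation_k()`.

## Synthetic data

Every input format has a seeded generator: `sim_pooled_counts()`
(sync-format pooled counts from a coalescent scenario, with a truth
sidecar), `sim_haplotype_panel()`, `sim_testcross_progeny()`,
`sim_segregation_counts()`, and `sim_survey_sample()`. These back the
recovery and calibration tests.

## Reproducing the acceptance numbers

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

writes `{t6: 54, t7: 42.04, t8: 0.3135, t9: 0.6520, t11: 6.84,
t12: 0}`. All models involved are deterministic, so the output does not
depend on the seed. The discrepancies (t6 = 54 vs 47, t11 = 6.84 vs 29,
and the structural `no_threshold` finding behind t12) are discussed
above.
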