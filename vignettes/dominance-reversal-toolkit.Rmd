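---
title: "Models and methods behind domrev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind domrev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domrev)
```

# The scientific problem

A genetic trade-off arises when alternative alleles at one locus are favoured
in alternative contexts — sexes, environments, life stages. Additive
antagonistic polymorphisms are fragile: deterministic maintenance requires
strong and/or nearly symmetric selection, and drift removes the rest. A
*beneficial reversal of dominance* — each allele dominant where it helps,
recessive where it hurts — raises heterozygote fitness in every context,
producing marginal overdominance that both reduces the genetic load and
stabilizes the polymorphism. This package implements, end to end, the pieces
needed to study that idea quantitatively: a biophysically explicit model of
how a dominance modifier can live in *cis*-regulatory sequence, a forward-time
simulator that lets it evolve, the deterministic single-locus theory of when
reversal protects a polymorphism, and two data-level methods for detecting
reversals (diallel dominance ordination and allele-specific-expression
reversal calling), with synthetic-data generators carrying ground truth.

# The regulatory-network model

The network has three parts. A sex-limited regulatory stimulus `D` (constant
concentration `[D]`, one recognition sequence per sex) binds the mutable
cis-regulatory site `alpha_i` of Gene A. Each A haplotype couples its alpha
site to an immutable coding allele: `A1` (male-benefit, low effect on the
downstream gene) or `A2` (female-benefit, high effect). The two A products
compete for the mutable site `beta_i` of Gene B. Only the alpha and beta
sites mutate; `D`, `A` and `B` are unlinked while each binding site is fully
linked to its coding domain.

Binding follows thermodynamic occupancy with mismatch-dependent affinity.
The allele-specific concentration of an A product is

$$[A_i] = A_{max}\,\frac{[D]/k^{m}}{1 + 2[D]/k^{m}},$$

where `m` is the proportion of mismatched nucleotides between the stimulus
recognition sequence *of the carrier's sex* and the haplotype's alpha site,
and `k` is the stepwise change in the dissociation constant. The factor 2 in
the denominator represents the two diploid copies of the regulated gene
competing for the stimulus, so occupancy is bounded by 1/2. A mutation in the
alpha site linked to `A1` that lowers its male-stimulus mismatch raises the
*relative* concentration of `A1` in males — that is the dominance modifier.

At the beta site the two products compete:
$occ_i = (c_i/k^{m_i}) / (1 + \sum_j c_j/k^{m_j})$ with `m_i` the mismatch of
product `i`'s recognition sequence to the beta site. The expression level of
Gene B is the *bound-fraction share* of allele effects summed over the two
beta sites,

$$[B] \;=\; \sum_{\text{sites}} \sum_i \frac{occ_i}{\sum_j occ_j}\, e_i ,$$

and the selected trait is the standardized level
$\varphi = \min(1, [B]/B_{max})$ with $B_{max} = 2\,e_{A2}$, the all-`A2`
maximum. Fitness is linear and sexually antagonistic by default:
$w_f = 1 - s_f(1-\varphi)$, $w_m = 1 - s_m\varphi$ (a gaussian map with
sex-specific optima is available).

## Why the bound-fraction share

This was the one genuinely open design choice, and the naive alternative
fails instructively. If `[B]` were the plain occupancy-weighted *sum* of
allele effects, absolute expression would respond to concentration, so a cis
mutation silencing the female-benefit allele in males would benefit male
*homozygotes* as well as heterozygotes. The network then resolves the
conflict by evolving sex-limited expression of `A2`, which makes `A2`
unconditionally favourable and *fixes* it — the polymorphism collapses and no
dominance reversal is observable. We verified this outcome across wide ranges
of `k` and `A_max`. Under the share form (the saturation limit of the same
occupancy logic), homozygote phenotypes depend only on their coding alleles
— `A1A1` sits at $\varphi = 0$ and `A2A2` at $\varphi = 1$ whenever any
product is present — while the heterozygote tracks the *relative* allelic
occupancy. Cis variation can then act only as a dominance modifier, which is
exactly the mechanism under study.

## Parameter defaults and what they mean

| parameter | default | meaning / rationale |
|---|---|---|
| `Lsite` | 8 nt | site length; small enough for desk-scale mutation dynamics, long enough for graded mismatch |
| `k` | 256 | dissociation step; `k^m` with `m` a proportion, so 256 = 2^8 is a twofold affinity change per mismatched nucleotide |
| `[D]` | 1 | stimulus concentration (units of the alpha-site dissociation scale) |
| `Amax` | 1 | occupancy-to-concentration proportionality; a pure scale under the share form |
| `effectA1`, `effectA2` | 0, 1 | allelic effects on `[B]` |
| `stimF` / `stimM` | differ at 4/8 positions | bounds the achievable sex-differential regulation: matching one sex's target perfectly leaves at least 4/8 mismatch freedom toward the other |
| founding alpha | 2/8 from both stimuli | neither coding allele starts with a sex-biased cis advantage |
| founding beta / `recogA2` / `recogA1` | exact match / 1 mismatch | `A2` is intrinsically dominant (2x binding weight; initial heterozygote $\varphi = 2/3$) |
| `N` | 500 | population size (even; N/2 per sex) |
| `muSite` | 1e-3 /nt/gen | cis-site mutation rate; high enough to supply modifier variation within 5000 generations |
| `sF`, `sM` | 0.2 | linear antagonistic selection, symmetric |
| generations | 5000 | horizon at which additive runs have typically lost the polymorphism to drift while modifier runs have not |

With these defaults the founding heterozygote sits at $\varphi = 2/3$
(mildly `A2`-dominant), and the maximal evolvable allele-specific expression
ratio in a heterozygote is about 0.85 : 0.15 — set by the stimulus
divergence (4/8) and `k`.

# The simulator

Discrete non-overlapping generations; soft selection within sexes (each of
the N offspring samples a mother and a father with replacement, probability
proportional to fitness within sex); one random haplotype per gene per
parent, the A and B genes assorting independently while each binding site is
transmitted with its coding domain; offspring sexes a random permutation of
N/2 and N/2; per-nucleotide mutation last. Sex is assigned independently of
genotype — `D` is conceptually downstream of sex determination. With equal
sex numbers and multinomial sampling the variance effective size is
$N_e \approx N$, which the neutral calibration (heterozygosity decay at rate
$1 - 1/(2N_e)$, checked to within 15% at N = 100 over 200 replicates by the
acceptance suite) confirms. The decay rate is estimated from the conditional
one-step identity $E[\Delta H \mid p] = -2\,E[(\Delta p)^2 \mid p]$ pooled
over all replicate-by-generation transitions; a naive log-linear fit to the
mean trajectory is an order of magnitude noisier at this replication because
replicate drift paths make its errors strongly autocorrelated.

The per-generation loop is implemented twice: a compiled engine (Rcpp) used
by default, and a pure-R composition of the exported operations
(`initPopulation()`, `nextGeneration()`, `popMetrics()`, ...). The two paths
implement the identical model and the test suite asserts their metric-level
equivalence on shared populations; runs are bit-reproducible from
`(config, seed)` within each engine. Polymorphism loss is assessed on the A
coding alleles only; alpha/beta sequence diversity is unconstrained.

The three-arm experiment (`replicateExperiment()`) pairs replicates by seed:
*off* (alpha sites frozen — the additive control), *on* (the full modifier),
and *eq* (male recognition sequence replaced by the female one — the
network-dependence control, which removes the sex-specific comparison target
while leaving mutation and selection untouched). Reported per run: retention
time of the polymorphism (right-censored at the horizon), final
allele-specific expression ratio of heterozygotes per sex, final mean
heterozygote $\varphi$ per sex against its generation-0 additive baseline,
and final mean fitness per sex. Arm contrasts use an exact paired sign test
(retention) and a paired Wilcoxon test (allele-specific-expression sex gap).

# Deterministic theory

The two-sex viability model tracks gamete frequencies by sex: zygotes by
random union, sex-specific viabilities
(`w_FF, w_FM, w_MM` = `1, 1 - hF sF, 1 - sF` in females and
`1 - sM, 1 - hM sM, 1` in males), then gametogenesis. Boundary
linearizations give the invasion eigenvalues

$$\lambda_F = \tfrac12\!\left(\frac{1 - h_F s_F}{1 - s_F} + (1 - h_M s_M)\right),
\qquad
\lambda_M = \tfrac12\!\left((1 - h_F s_F) + \frac{1 - h_M s_M}{1 - s_M}\right),$$

and the polymorphism is protected when both exceed 1. Because the paper-level
claims are qualitative, every closed form here is cross-checked against the
brute-force recursion (`iterateToEquilibrium()`, vectorized over parameter
grids) — the recursion is the arbiter. Protection at `h = 0.5` demands
near-symmetric selection; lowering `h` expands the protected region
monotonically (nesting is asserted pointwise) until `h = 0` protects every
`s < 1`. One subtlety: under perfectly symmetric selection the two sexes'
gamete frequencies do *not* both equal 1/2 — they deviate
mirror-symmetrically (`pF + pM = 1`); it is the sex-averaged frequency that
is exactly 1/2 at equilibrium.

Numerical conventions: convergence when per-generation change falls below
`1e-12`; frequencies within `1e-6` of a boundary classify as fixation;
`lambda` within `1e-12` of 1 is reported as a boundary case, not protected;
non-convergence is flagged in the result, never raised.

# Genotype-fitness composition

`composePanel()` crosses a genotype-phenotype map (additive, or
dominance-reversed with displacement `d`) with a phenotype-fitness map
(linear antagonistic, or gaussian with per-context optima and shared width
`omega`) and reports the effective dominance of the locally deleterious
allele, $h_{eff} = (w_{best} - w_{het})/(w_{best} - w_{worst})$, unclipped so
values below 0 encode overdominance and above 1 underdominance. Linear maps
preserve trait-level dominance exactly (affine invariance); gaussian maps
produce $h_{eff} < 0.5$ in both contexts precisely when the heterozygote
lies within one width of both optima (the concave-overlap condition), and
widely separated optima with narrow widths yield *net underdominance*
(marginal heterozygote inferiority), exhibited by `scanUnderdominance()` via
grid search rather than reproduced from any published parameter set. The
`h_eff = 0.5` boundary uses a `1e-9` tolerance.

# Detection methods

**Dominance ordination.** For each strain `r` of a full diallel and each
context, the array covariance `W_r` is the covariance between strain `r`'s
cross means (replicates and reciprocals averaged) and the partners' self
values. The self pair `(r, r)` is included in strain `r`'s array: with it, a
purely additive diallel gives the constant `W_r = var(selfs)/2` for every
strain (the degenerate case, flagged rather than tested), and a fully
dominant strain gives `W_r = 0`; excluding the self would make even additive
`W_r` vary with `r` through the partner set. Strains are thus ordered along
a dominant–recessive continuum per context; the cross-context Pearson
correlation of the two `W` vectors is the statistic, with a two-sided
permutation null (strain labels of one context shuffled). Pearson with a
permutation null was chosen over rank or parametric alternatives because
panels are small (~16 strains) and no distributional model is assumed.

**ASE reversal calling.** Per gene and context, the allele-1 read fraction is
tested against 1/2 with an exact binomial test; p-values are adjusted across
genes within each context (Benjamini–Hochberg by default; Bonferroni and
none available). A gene is a *reversal* only when significant in both
contexts independently *and* the two point estimates fall on opposite sides
of 1/2 — same-direction imbalances can never be reversals regardless of
p-values (a hard rule, tested by exhaustive enumeration of count pairs).
One-context significance is *context-dependent* dominance; both-context
same-direction significance is *consistent imbalance*. Direction is judged
on point estimates, significance on adjusted p-values. Overdispersion
(beta-binomial) is deliberately out of scope.

# Synthetic data

`simulateDiallel()` builds fixed homozygous strain panels at biallelic loci
whose allele-1 effect is `+e` in context 1 and `-e` in context 2.
Heterozygous loci contribute the midpoint displaced by `d*e` toward the
context-beneficial allele in both contexts (*dominance_reversed*), toward a
per-locus globally dominant allele (*unconditional*), or not at all
(*additive*), plus gaussian measurement noise; selfs and both reciprocals
are generated with no parent-of-origin effects. The `(e, d)`
parameterization maps to a dominance coefficient as `d = 0` ⇔ `h = 0.5` and
`d = 1` ⇔ `h ∈ {0, 1}`. Defaults (16 strains, 50 loci, `e = 1`, `d = 0.8`,
noise sd 0.5, 2 replicates) give a strong polygenic architecture with modest
measurement noise — the regime in which the ordination's sign behaviour is
the question, not marginal power.

`simulateAseCounts()` draws allele-1 counts Binomial(depth, 0.7) /
Binomial(depth, 0.3) across the two contexts for reversed genes and
Binomial(depth, 0.5) for null genes, at fixed or Poisson depth. What these
generators deliberately do **not** emulate: linkage and shared ancestry among
strains, parent-of-origin and maternal effects, read-mapping bias, and
overdispersion of RNA-seq counts. Passing tests therefore demonstrate the
methods' behaviour under their own model assumptions, not robustness to the
full messiness of real data.

# Problem sizes and numerical choices

The shipped checks use: a 41 x 41 selection grid at three dominance levels
for the theory cross-validation (≥ 99% agreement required, excluding
`|lambda - 1| < 1e-3` boundary points); 50 paired replicates of N = 500 over
5000 generations for the three-arm experiment; 200 replicates of N = 100
over 300 generations for the neutral calibration; 200 synthetic diallels per
architecture (2000 permutations each) for the ordination; and 2000-gene count
tables for the caller's error rates. All generator and experiment seeds are
explicit arguments.

# Known limitations

Single antagonistic locus; no recombination map, demography, overlapping
generations, or multiple interacting loci; no X-linkage, gene duplication or
epigenetic resolution channels; linear/gaussian fitness only; detection
methods assume complete diallels and clean allele-assignable counts. The
deterministic module assumes an infinite population with equal sex ratio and
no mutation. The regulatory model uses a single shared `k` for both binding
steps and no cooperativity, chromatin state, or transcription kinetics.
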