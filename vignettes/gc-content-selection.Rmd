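---
title: "Detecting selection on bacterial GC-content from synonymous polymorphism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection on bacterial GC-content from synonymous polymorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcsel)
```

## The question and the model

Under a mutation-bias-only, stationary model of base composition, the
numbers of GC→AT and AT→GC synonymous mutations segregating within a
species are expected to be equal: however AT-biased mutation is, at
equilibrium the excess of GC sites exactly compensates the excess per-site
GC→AT rate. `gcsel` measures the direction spectrum of GC↔AT SNPs at
degenerate third codon positions, summarized as Z = U/(U+V), and compares
it against that null — with an explicit correction for the one mechanism
that breaks the null without selection: violation of the infinite-sites
assumption at high mutation rates.

The population model is Wright's stationary diffusion for a haploid,
constant-size population with a biallelic site (GC class vs AT class),
reversible mutation and genic selection. With scaled rates
U = θ(1−f) (GC→AT), V = θf (AT→GC), θ = 2N~e~µ, equilibrium GC fraction
f = v/(u+v) and scaled selection S = 2N~e~s favouring GC:

$$\varphi(x) \propto e^{Sx}\, x^{V-1} (1-x)^{U-1},$$

normalized by $B(V,U)\,{}_1F_1(V; U+V; S)$. Sampling $n$ strains gives

$$P(i) = \binom{n}{i}
  \frac{B(V+i,\,U+n-i)\; {}_1F_1(V+i;\,U+V+n;\,S)}
       {B(V,\,U)\; {}_1F_1(V;\,U+V;\,S)},\qquad i = 0,\dots,n.$$

Applying the minor-allele direction rule to this spectrum yields the
predicted proportion of GC→AT calls: classes with GC in the majority
(i > n/2) are counted as GC→AT, classes with GC in the minority as AT→GC,
exact ties (even n, i = n/2) are excluded, as are the monomorphic classes.
The expected sample diversity is
$\pi = \sum_i P(i)\, 2i(n-i)/(n(n-1))$ — the *sample-based* form, chosen
over the population integral $\int 2x(1-x)\varphi\,dx$ because the
calibration target is a sample statistic measured the same way on data;
the two differ by O(1/n).

### Model assumptions

* stationary base composition and constant population size;
* free recombination between sites (sites independent), no linkage;
* genic (additive) selection on the GC class; no dominance, no demography;
* every strain sampled at each valid site (sites with any gap or ambiguity
  are dropped entirely so that n is constant per site, which the sampling
  formula assumes).

## Key parameters

| parameter | meaning | default / typical |
|---|---|---|
| `theta` | scaled total GC↔AT mutation rate 2N~e~µ (per site, dimensionless) | calibrated from observed π; bracket 10⁻⁶–10 |
| `f` | equilibrium GC fraction under mutation alone, (0,1) | set to observed GC4 under the null |
| `S` | scaled selection 2N~e~s, >0 favours GC | 0 for the null model |
| `n` | strains sampled | data; ≥8 required by the species filter |
| `rate_model` | `"constant"` or `"exponential"` per-site rates | both reported |
| filters | min strains 8, min GC↔AT 4-fold SNPs 10, max π 0.1 | pipeline defaults |

The exponential rate model represents substantial rate heterogeneity: the
95th/5th quantile ratio of an exponential is ln(20)/ln(20/19) ≈ 58.4
(scale-free), and the 99th/1st ratio ≈ 458 — `exponential_quantile_ratio()`
computes these. The mixture spectrum is the constant-rate spectrum averaged
over rate r·θ with r ~ Exponential(mean 1).

## Direction inference

**Frequency method.** The minor allele is taken to be the derived state;
equal counts are discarded as ties. Deterministic and order-invariant, but
it misinfers direction whenever the derived allele has drifted above 50%.
`misinference_rate()` quantifies this by forward Wright–Fisher simulation
with mutation-origin tracking: the ancestral allele of a segregating site
is defined as the allele the population was last monomorphic for. In the
low-θ limit the rate reduces to the classic derived-allele spectrum
calculation, $\sum_{i>n/2}^{n-1} i^{-1} / \sum_{i\ne n/2}^{n-1} i^{-1}$
(≈ 0.21 for n = 10), which the simulation reproduces; the test suite
asserts this. Sampling epochs are spaced N generations apart because closer
spacing resamples the same polymorphisms and makes the reported Monte-Carlo
standard error optimistic.

**Parsimony method.** A neighbor-joining tree on pairwise p-distances over
all alignment columns (NJ is in the minimum-evolution family; negative
branches are clamped to 0) is rooted at the point, on any edge, that
minimizes the variance of root-to-leaf path lengths — a closed-form
quadratic per edge — operationalizing molecular-clock rooting; midpoint
rooting is available as a fallback. A Fitch bottom-up pass then assigns the
root state set: a singleton set gives the ancestral allele and hence the
direction, a two-allele set is recorded as `ambiguous` and excluded from
parsimony counts (the same discard convention as frequency-method ties).

Two subtleties found while validating Fitch behaviour are worth recording.
First, a singleton tip adjacent to the root — e.g. (((A,B),C),D) with
states C,C,C,T — has *two* equally parsimonious root states (the mutation
can sit on the pendant branch or on the root-adjacent internal edge), so
the correct Fitch output is `ambiguous`, not the majority allele. Second,
the intuitive property "ambiguity increases with diversity" is not
exhibited by either of the package's generators: on infinite-sites tree
data the ambiguity rate equals the probability that the mutation falls on a
root-adjacent branch, independent of θ, and on independent-site stationary
data the genealogy is star-like, so the estimated tree (and with it the
ambiguity rate) is dominated by reconstruction noise. The suite therefore
tests the property that *is* provable: with one mutation per site, Fitch on
the true tree is either ambiguous or correct, never confidently wrong.

## Recombination screens

The four-gamete test scans all pairs of biallelic sites (any site class —
recombination acts on the locus) for the presence of all four two-site
haplotypes; it can never fire on data generated by a single tree without
recurrent mutation, which the suite verifies on tree simulations.

The maxchi scan evaluates, for every strain pair, every breakpoint between
consecutive polymorphic sites with the 2×2 left/right × match/mismatch
table, and assesses the overall maximum by permuting site order and
re-maximizing. The implementation ranks candidate tables (and computes the
permutation statistic) by the **exact hypergeometric tail** of the table
rather than the raw chi-square. This is the package's sensitivity
adjustment, and it matters: the raw chi-square reaches its ceiling
(χ² = K, the number of polymorphic sites) for *any* pair whose two or three
mismatches happen to sit together at one end, so under permutation such
tiny-margin flukes dominate the null distribution and genuine mosaics are
rarely significant. The exact tail accounts for the margins; the chi-square
of the winning table is still reported (a clean 20/0/0/20 mosaic scores
χ² = 40 with permutation p ≈ 0.001). Breakpoint position is reported as the
midpoint of the plateau of equivalent breakpoints, since any breakpoint
between the last left mismatch and the first right mismatch scores
identically. Chi-squares use no continuity correction; zero-margin tables
score 0; fewer than 4 polymorphic sites yields a not-evaluable report;
permutation p-values are seeded and reproducible.

## Synthetic data: what it emulates, and what it does not

`simulate_alignment()` draws each site's GC-class count directly from the
stationary sampling spectrum and assigns the GC allele to a uniformly
random strain subset; first two codon positions come from fourfold (or
twofold, using the synonymous transition pair) templates. This reproduces
exactly the site-frequency structure the theory describes — independent
sites, free recombination, no genealogy — so it validates the estimators
and the theory pipeline, not tree-based inference. `simulate_tree_alignment()`
generates a Yule genealogy and places at most one mutation per site
(branch chosen proportionally to length, rate proportional to θ(1−f) or
θf by root state), recording every SNP's true direction; it validates
parsimony and the four-gamete screen. `simulate_recombinant()` replaces one
strain's left-of-breakpoint haplotype with a diverged donor.
`simulate_cohort()` draws per-species (f, θ, S) and supports planting a
selection–GC association.

What passing tests on these generators do **not** show about real data:
real loci have linkage, shared genealogies across sites, rate variation
beyond the exponential model, alignment error, and non-stationary
demography. The screens and the Z_pred correction address specific,
modelled violations only.

## Numerical choices

* **₁F₁** is evaluated by the Kummer series in the stable direction
  (for S < 0 via the transform $_1F_1(a;b;s) = e^s\,_1F_1(b-a;b;-s)$);
  beyond S > 50 the integral representation is integrated in log space with
  the $e^S$ factor pulled out and endpoint singularities removed by the
  substitutions $x = t^{1/a}$, $1-x = t^{1/c}$. Tests cross-validate the
  closed form against an independent quadrature oracle (10⁻⁶) and a forward
  Wright–Fisher oracle (3 Monte-Carlo s.e. per class).
* **Exponential mixture** by 64-node Gauss–Laguerre quadrature.
* **Exact symmetry**: when U = V and S = 0 the spectrum is symmetrized
  bitwise, and tail sums are accumulated in sorted order, so the neutral
  prediction is *exactly* 0.5 rather than 0.5 ± 1 ulp.
* **Tie classes**: odd n has no tie class; for even n the class i = n/2 is
  excluded from both direction sums, mirroring the data-side tie discard.
* **Calibration** inverts the monotone map θ ↦ π by bracketed root finding
  on log θ over [10⁻⁶, 10], after verifying the bracket spans the target.
* **NJ/rooting determinism**: `ape::nj` is deterministic; negative branch
  lengths are clamped to 0; the clock root position is the closed-form
  variance minimizer clamped inside its edge.
* **Attrition accounting** attributes each excluded species to the first
  filter it fails, so input = passed + Σ exclusions holds exactly.
* **Infinite-sites guard**: the tree generator errors when the requested
  pressure implies more than ~3 expected mutations per site, where the
  one-mutation truncation badly misrepresents the requested process.

## Design choices where the design was open

* Twofold-site direction counts (U2/V2) apply the same tie-discard rule as
  fourfold sites.
* When genes within a species differ in strain count, Z_pred is the median
  of per-gene predictions (at the pooled π and GC4).
* GC-rich classification defaults to the crossing point re-fitted from the
  data, with a fixed override available.
* Gene allowlists (e.g. an HGT-resistant gene set) match by gene name.
* Screen-based exclusions produce parallel summaries rather than mutating
  the primary one, so filtered and unfiltered results sit side by side.
* Bootstrap: species are the resampling unit; 1000 percentile resamples by
  default, fully seeded.

## Problem sizes used in validation

The suite and the acceptance script run at sizes chosen to make each
stochastic check statistically decisive: 10⁴–5·10⁴ sites for spectrum and
calibration checks (3 s.e. criteria), forward simulations with N = 200–400
and 6·10³–5·10⁴ sites, cohorts of 30–60 species × 2500–3000 fourfold
sites, 20–25 replicates for screen operating characteristics, and 200–1000
permutations for maxchi p-values. Two fixture-design points deserve note:
the neutral cohort used for the crossing check carries appreciable
diversity (θ up to 0.25, π up to ~0.07) because the regression's slope —
and hence its crossing — is only identifiable through the symmetric
infinite-sites bias, which vanishes at low diversity; and the NJ topology
check conditions on Yule draws whose shortest internal edge is at least 2%
of tree height, since an internal edge that receives no mutation is
unidentifiable for any method.

## Known limitations

* The misinference simulation supports the neutral model only (origin
  tracking under selection would need the same machinery but a different
  equilibrium argument for its initialization).
* Parsimony counts discard ambiguous root states rather than fractionally
  assigning them; with many root-adjacent singletons this loses data.
* The maxchi permutation null permutes site order globally, which is
  conservative when many pairs are nearly identical.
* p-distances (not model-corrected) underlie the NJ tree; at the low
  within-species divergences targeted here this is immaterial, but the
  tree module is not meant for deep phylogenies.
* Real-data reproduction of published species tables requires the
  corresponding per-species inputs; the package ships only generators and
  expects alignments as input.
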