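---
title: "Models and methods for uniparental marker analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for uniparental marker analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniparent)
```

# Scope

`uniparent` implements the analysis chain typically applied to human
uniparental markers — mtDNA HVS-I haplotypes and Y-chromosomal SNP/STR
profiles — in population surveys: haplogroup classification, molecular
diversity, frequency-spectrum neutrality tests, rho-statistic clade
dating, median-joining networks, frequency PCA and STR distances, and
coalescent (BATWING-style) TMRCA estimation, plus a synthetic-data
generator that emulates a four-population study design so every stage is
testable offline.

This vignette records the models, the tunable parameters that matter,
and the design choices made where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

# Coordinates, motifs, and variant calling

All mtDNA coordinates are 1-based rCRS positions; windows are inclusive.
The HVS-I analysis window defaults to 16024–16488 (the region bounded by
the usual amplification primers), and motif strings follow the
field's convention: `16223` is a transition, `16265C` a transversion,
`16166d` a deletion, `16193.1C` an insertion; hyphens, en and em dashes
and whitespace all separate tokens. Length variants in the 16184–16193
poly-C tract are parsed but flagged hypervariable, and indels are
excluded from distances, diversity, and rho by default (switchable) —
standard HVS-I practice, since indel calls in that tract are alignment
artefacts more often than mutations.

# Haplogroup classification

Trees are data, not code: small JSON fixtures ship with the package
(a Y panel topology; a ~40-node mtDNA subtree) and any phylotree build in
the same schema can be substituted. Classification is therefore
reproducible against a *stated* tree version — reproducing any
particular published call set exactly is build-dependent and out of
scope.

For Y profiles, classification descends the tree hierarchically: an edge
is traversed when its typed defining markers are derived; fully untyped
edges are traversed only under sibling exclusion (no typed alternative
derived) and only when derived evidence exists deeper, so the reported
node always has derived support on its terminal edge. Derived states on
mutually exclusive branches raise a conflict error naming the markers.
A `*` suffix (paragroup) is appended when child-defining markers were
typed and all are ancestral. Untyped markers never count for or against —
important because hierarchical genotyping leaves most panel markers
untyped in any given sample.

For mtDNA, every node is scored `matched − λ·missed` over its
path-defining variants, with coding-region matches weighted twice the
HVS-I matches (coding sites are slow and nearly homoplasy-free; HVS-I
sites are fast). λ defaults to 0.5: a missed defining variant is real
evidence against a placement, but weaker than a positive match, since
back mutation at fast sites is common. Ties across branches are
**reported, not broken** — mirroring the real ambiguity of samples
carrying diagnostic mutations of two clades — while ties along one
root-to-tip path resolve to the deepest node.

# Diversity and neutrality statistics

Gene diversity uses the unbiased estimator `n/(n−1)(1 − Σp²)` with Nei's
(1987) sampling variance. The mean number of pairwise differences (MNPD)
is the average symmetric-difference of variant sets; its variance is the
total (stochastic + sampling) variance of Tajima (1993), the convention
reported by Arlequin. Nucleotide diversity is MNPD divided by the window
length actually analysed (465 by default, configurable): the effective
alignment length behind published tables is rarely stated, so per-site
values carry that caveat.

Tajima's D uses the 1989 constants. Fu & Li's D and F (with outgroup) and
D* (without) follow the coefficient sets that reference implementations
agree on; for F* the literature carries several variants, and this
package uses the Simonsen–Churchill–Aquadro (1995) corrected
coefficients. A Monte-Carlo moment check (run during development, and
kept as a property test at lower resolution) showed that *no* published
normalization matches the exact numerator moments — these statistics'
constants are approximations — so oracle tests pin frozen reference
values rather than simulated truth. Fu's Fs evaluates
`Pr(K ≥ k | θ̂, n)` under the Ewens sampling distribution with
θ̂ = MNPD (Fu's convention), computed entirely in log space with
Stirling numbers by a log-sum-exp recurrence, so n in the hundreds is
safe; an exact integer oracle validates the recurrence for small n.
Undefined statistics (monomorphic samples) are `NA` sentinels, never
exceptions, so pooled tables render.

Simulation p-values condition on the observed number of segregating
sites (mutations placed along a neutral constant-size coalescent
genealogy proportionally to branch length) and report the lower tail
with ties counted — the convention when the alternative is population
growth. The compiled simulator returns the spectrum ingredients (S, π,
singletons, haplotype count), so any statistic expressible in those
terms can be calibrated.

# Rho dating

ρ is the mean mutational distance from each sampled haplotype to the
clade founder, restricted to the calibrated window 16090–16365, with the
clock 18,845 years per mutation. The standard error follows Saillard et
al. (2000): σ_ρ = √(Σ nⱼ²)/n over mutation links; without an explicit
genealogy the star approximation √(ρ/n) is used (with an optional
warning) — appropriate for the near-star genealogies of expanding
clades, and exactly the Saillard value when each link subtends one
sample. Founder motifs are supplied as data (a fixture ships with the
generator's founders); recurrent hits at one site count once per link,
transversions count, indels do not. These conventions are explicit
because published analyses rarely state them.

# Median-joining networks

Characters are linearly ordered integer states (binary sites or STR
repeat counts) under weighted single-step (Manhattan) distance; for
ordered states the quasi-median of a triplet is the unique
component-wise median, which simplifies Bandelt's construction without
changing it. The algorithm iterates: ε-relaxed minimum spanning network
over the current node set; candidate medians from triplets centred on
shared network neighbours; admission of medians within ε of the round's
minimum connection cost; pruning of latent nodes left at degree ≤ 1. At
ε = 0 the result contains a minimum spanning network, and `epsilon`
monotonically enriches the output. `network_length()` reports the MST
length over observed + median nodes — the Steiner value the medians
realise — which never exceeds the observed-haplotype MST and is checked
against a brute-force Steiner search on small binary instances. A
`max_medians` guard aborts combinatorial blow-ups. The full
reduced-median preprocessing is *not* implemented; `reduced = TRUE`
performs only the uncontroversial part (merging identically-split binary
characters with summed weights), and is documented as such.

Taxa are sorted lexicographically before iteration, so output is
reproducible regardless of input order.

# Y-STR coalescent simulation and TMRCA

The demographic model is exponential growth from an initially
constant-sized haploid population: `N(t) = N_anc·e^{α(t_onset−t)}` for
`t < t_onset` (time in generations before present), `N_anc` earlier;
generation time defaults to 25 years. Genealogies are simulated by
time-rescaling the standard coalescent through the closed-form inverse
of the integrated intensity, and validated against the constant-size
closed forms E[T₂] = N and E[TMRCA] = 2N(1−1/n). STR mutation is strict
single-step (±1 with equal probability, Poisson counts per branch) with
alleles reflected into the plausible 5–40 repeat range.

Bayesian TMRCA estimation runs Metropolis-within-Gibbs over (genealogy
node times and topology, N, α, growth onset, mutation rate) with a
pruning likelihood over the bounded allele lattice (the lattice
generator's eigensystem is computed once; compiled code does the rest).
Topology mixes through periodic independence redraws of the genealogy
from the coalescent prior, which is effective at the small per-clade
sample sizes this analysis targets. Priors default to lognormal N
(median 1000), exponential growth rate (mean 0.01/generation), lognormal
onset (median 240 generations ≈ 6 kya), and a gamma mutation-rate prior
centred on the chosen calibration set; all are overridable, because the
original study's prior settings are not recoverable from its text. For
that reason published posterior numbers are *not* targets; what is
tested instead is calibration (90% credible intervals cover
prior-drawn truths — a Cook–Gelman check) and the qualitative
consequence of rate choice: evolutionary-rate TMRCAs exceed
genealogical-rate TMRCAs on identical data, because the posterior age
scales like 1/μ.

The bundled mutation-rate sets (EMR, OMRB, OMRS, lmMR) are set-level
average calibrations with sources annotated in the fixture file; the
original per-locus tables are not reproduced. Only their ordering
(EMR ≪ genealogical rates) matters to any test.

The ASD moment estimator (mean squared allele distance from the founder,
divided by μ) is kept as an independent cross-check of the MCMC's scale;
E[ASD] = μt makes it unbiased on star genealogies.

# Population structure

Haplogroup-frequency PCA is the classical covariance-mode
eigendecomposition of the row-normalised population × haplogroup matrix
(correlation mode optional); the original study's SPSS settings being
unknown, its two-PC variance figure is not a target. R_ST follows the
Arlequin sum-of-squared-size-differences convention
`(S̄ − S_W)/S̄` per population pair, with negative estimates clamped to
zero and flagged; haplotype-identity F_ST is the alternative mode.
Neighbour-joining is delegated to `ape::nj` (Saitou–Nei), with additive
matrices recovered exactly — a property the tests verify over random
trees.

# Synthetic data: what it emulates, and what a green test establishes

The generator emulates a four-population design — two small populations
(18/16 males, 46/40 mtDNA samples) and two larger ones (46/47 and
119/192) — with per-population haplogroup count tables inferred from
published percentage frequencies. Those tables are a documented
*synthetic reconstruction* (`study_design()`), not deposited data; the
mtDNA counts were chosen so the per-population totals (46/40/119/192,
397 pooled) and the macrohaplogroup-M fractions (65.22% … 57.98%, 59.70%
pooled) match the printed values, with unstated cells filled by
plausible allocation.

Within a haplogroup, HVS-I variation arises on a simulated coalescent
under a post-glacial-expansion default demography (N_anc 500, growth
0.008/generation from 400 generations BP), with finite-sites mutation at
total window rate 25/18845 per generation (clock-consistent), a 3:1
hotspot:other site-rate mix and a 20:1 transition:transversion bias.
These defaults were chosen once to produce haplotype diversities around
0.98–0.99 and MNPD around 5–6 at realistic sample sizes — the regime the
analyses assume — and are not tuned per test. Y-STR haplotypes evolve by
single-step mutation on per-haplogroup genealogies from per-haplogroup
founder haplotypes; SNP states are derived exactly along the true path.

What generated data cannot establish: agreement with the real study's
per-sample tables (haplotype sharing between populations, exact
site-frequency spectra, the deposited motifs). Tests that require the
deposited supplementary table are present and deliberately red in
offline builds; everything property-based (estimator calibration,
classification recovery, statistic oracles) is established on synthetic
data with fixed seeds.

# Numerical choices and degenerate inputs

* Statistics undefined at S = 0 return `NA`; Fu's Fs returns ±∞
  sentinels with a warning when the Ewens tail under/overflows.
* Stirling rows and the SMM lattice eigensystem are memoised per call
  site; likelihood pruning rescales partials to avoid underflow.
* The MCMC root-time move uses a state-dependent window with the exact
  proposal-density correction, and rejects moves whose reverse window
  cannot reach the current state.
* `allocate_counts()` uses largest-remainder rounding so frequency-based
  specs produce exact deterministic counts.
* Ties in `assign_mt` exit with success and a `tied` flag rather than an
  arbitrary call.

# Known limitations

* The haplogroup fixtures are compact subtrees, not full phylotree
  builds; calls are only as fine as the fixture.
* F* coefficients are a documented choice among published variants.
* The MJ implementation targets the small condensed haplotype sets of
  intraspecific surveys; it is not a Steiner-tree solver for large
  inputs.
* The BATWING-style sampler supports the single-population
  growth-from-constant model only (no population splitting, no UEP
  integration), and its effective sample sizes at default settings are
  modest — adequate for calibration, not for publication-grade posterior
  summaries without longer chains.
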