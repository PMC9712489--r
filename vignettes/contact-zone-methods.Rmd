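---
title: "Models and methods behind clinepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clinepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinepop)
```

`clinepop` analyses avian contact zones where phenotypically distinct
lineages (morphotypes) meet: it quantifies mitochondrial and
microsatellite differentiation between the groups, fits geographic clines
to molecular and phenotypic traits across the contact transect, classifies
individuals by morphometric or genetic features, and provides the
bias-aware sampling and tuning machinery used around presence-only
distribution models. This vignette explains the models, their
assumptions, the tunable parameters, and the numerical choices; it states
no result that the package's tests or acceptance script do not themselves
compute.

## Sequence diversity and neutrality tests

For an aligned panel of $n$ mitochondrial sequences of length $L$:

* **Segregating sites** $S$ count alignment columns with two or more
  distinct non-missing states. The gap `-` is a fifth character state;
  `N` is missing. This matches the convention of including gapped and
  invariable sites in the dataset.
* **$\theta_\pi$** is the mean number of pairwise differences over all
  $\binom{n}{2}$ pairs; **$\pi$** is the per-site analogue, where each
  pair is compared only at its mutually valid sites (`N` and `-` excluded
  pairwise for any distance-type quantity). The reported standard
  deviations use the classical variance of the mean-pairwise-difference
  estimator, $\mathrm{Var}(\theta_\pi) = b_1\theta + b_2\theta^2$ with
  $b_1 = (n+1)/3(n-1)$ and $b_2 = 2(n^2+n+3)/9n(n-1)$; the per-site SD
  divides by $L$. Program-specific variance conventions differ in small
  terms, so printed "±" values from other software need not match
  exactly.
* **Watterson's $\theta_S$** is $S/a_1$ with $a_1 = \sum_{i<n} 1/i$, with
  $\mathrm{Var}(\theta_S) = \theta/a_1 + a_2\theta^2/a_1^2$.
* **Tajima's D** contrasts $\theta_\pi$ with $S/a_1$, normalized by the
  1989 constants; it is `NA` when $S = 0$ or $n < 4$.
* **Fu's $F_S$** takes $\hat\theta = \theta_\pi$, computes
  $S' = \Pr(K \ge H_{obs})$ under the Ewens sampling distribution
  $\Pr(K = k) = |s(n,k)|\,\hat\theta^k / (\hat\theta)_n$, and reports
  $\ln(S'/(1-S'))$. Unsigned Stirling numbers of the first kind are built
  by the two-term recursion entirely in log space, so the statistic stays
  finite up to panels of many hundreds of sequences; the computed Ewens
  distribution sums to one within $10^{-10}$ for $n \le 200$. When $S'$
  reaches 1 or 0 within summation accuracy ($10^{-10}$ in log space) the
  statistic is reported as signed infinity with a `"degenerate"` flag —
  with $H_{obs} = 1$, for example, $\Pr(K \ge 1)$ is exactly one.
* **Significance** of D and $F_S$ is assessed, on request, against a
  coalescent null simulated under the fitted $\theta_\pi$ (default
  10,000 seeded replicates; two-tailed for D, lower tail for $F_S$).

**Haplotype identity** needs a rule for `N`. Three are provided:
`strict` (default; `N` is its own state, so `AAN` ≠ `AAT`), `mask`
(columns containing any `N` are masked panel-wide before comparing), and
`n_matches` (`N` is a wildcard; greedy merge into the first compatible
class). The rules disagree on purpose — ambiguity handling is a
convention, not a fact — and all three are deterministic.

**Minimum spanning networks** flag, within the complete Hamming-distance
graph over haplotypes, every edge that occurs in at least one minimum
spanning tree: distance classes are visited in increasing order and all
edges joining components not yet connected at smaller distances are
retained. The flagged subgraph is connected, spans all haplotypes, and
has total weight equal to the Kruskal optimum.

**Between-group divergence** reports the minimum, mean and maximum raw
p-distance over cross-group pairs, and `clockTime()` converts a
divergence into an age under a strict molecular clock (default 2.1%
pairwise divergence per million years, the conventional avian
mitochondrial rate). Dividing an observed divergence by a clock rate is
a back-of-envelope conversion; model-based Bayesian dating of the same
split will generally give an older value because it integrates over
genealogical variance.

## Microsatellite statistics

Observed heterozygosity is the fraction of heterozygous typed
individuals; expected heterozygosity uses Nei's unbiased correction
$\frac{2n}{2n-1}(1 - \sum p_i^2)$. The exact Hardy–Weinberg test
conditions on allele counts: the Levene distribution over genotype
tables is either enumerated completely (recursively over margin
allocations, when the table space is within `enum_limit`, default
$10^6$) or sampled by an allele-swap Monte Carlo chain. Because the
uniform distribution over arrangements of the $2n$ allele copies *is*
the conditional null, the swap proposal is symmetric and every move is
accepted; the chain's table log-probability is maintained by exact
sequential single-cell updates. The p-value is the probability mass of
tables no more probable than the observed one (the two-sided "exact"
ordering); the Monte Carlo standard error reported is the binomial
$\sqrt{p(1-p)/\text{steps}}$, which ignores autocorrelation and is
therefore optimistic — treat it as a floor.

Allelic richness rarefies to a common number of genes $g$ (allele
copies, the FSTAT convention): $R_S = \sum_a [1 - \binom{2N-N_a}{g} /
\binom{2N}{g}]$. The default $g$ is the smallest typed gene count across
groups at each locus; reproducing any particular published richness
table requires knowing the $g$ it used, so $g$ is always reported
alongside $R_S$.

Private alleles are locus-specific alleles observed in exactly one
group; the report aggregates counts, percentages and the mean
within-group frequency per group, with the full allele list attached as
an attribute.

The linkage-disequilibrium test is genotypic (unphased): a $G$
log-likelihood-ratio statistic on the two-locus genotype table, with the
null built by permuting one locus's genotypes across individuals within
the group and the standard $(+1)/(+1)$ p-value correction. The exact
Markov-chain schedule of dedicated LD software is not reproduced; the
permutation scheme is the package's stated substitute.

DAPC-style assignment encodes individuals as 0/1/2 allele counts,
imputes missing cells with the group-blind overall mean (group means
would leak labels into features), reduces by PCA, and classifies with
linear discriminants. When the number of retained components is not
given it maximizes the a-score (observed reassignment minus mean
reassignment under permuted labels, 10 seeded permutations per
candidate). Note the reassignment rate is computed on the training data,
as is conventional for the a-score; it is optimistic relative to
cross-validation.

## Geographic clines

A cline along a one-dimensional transect is the sigmoid
$$f(x) = \frac{1 + \tanh\!\big(2(x-c)/w\big)}{2},$$
with center $c$ (km), width $w$ (km, the inverse of the maximum slope
scaled to the trait range), and the trait value
$p(x) = p_{min} + (p_{max}-p_{min})f(x)$. Transect positions are
cumulative haversine distances (mean Earth radius 6371.0088 km), each
leg rounded to 0.1 km before accumulation; whether the original distance
measurements were great-circle or projected is a convention, and
haversine is the default here.

**Exponential tails.** Beyond attachment points $c-\delta_L$ and
$c+\delta_R$ the sigmoid can hand over to decaying tails with shape
parameters $\tau \in (0,1]$. The exact tail equations of the classical
cline software are not printed in the descriptions this package follows,
so the tail form here is a design choice with the required properties
stated up front. We use the geometric interpolation
$$f_{tail}(x) = f_L^{\,1-\tau_L} f(x)^{\tau_L}, \qquad x < c-\delta_L$$
(mirrored on $1-f$ on the right), where $f_L = f(c-\delta_L)$. This
form (i) decays asymptotically exponentially at rate $4\tau/w$, (ii) has
log-slope at the attachment point exactly $\tau$ times the sigmoid's own
log-slope there, (iii) is $C^1$-continuous and monotone for
$\tau \in (0,1]$, and (iv) reduces *identically* to the sigmoid at
$\tau = 1$ for every $\delta$ — a literal exponential segment
$f_L e^{r(x-x_L)}$ satisfies (i)–(iii) but cannot satisfy (iv), which is
why the interpolating form was chosen. At $\delta = 0$ with $\tau < 1$
the curve differs from the sigmoid below the center, as any tailed form
must.

**Architectures and likelihoods.** Five tail configurations (none,
right, left, mirror, both) cross three scalings — asymptotes fixed to
0/1, fixed to the observed extremes, or free — giving the 15 candidate
models. For frequency traits the likelihood is product-binomial with
$p$ clamped to $[10^{-9}, 1-10^{-9}]$; for quantitative traits it is
Gaussian, evaluated from per-locality sufficient statistics
$(n_i, \bar{y}_i, s_i)$ with free residual SD $\sigma$. For quantitative
traits the 0/1 scaling is meaningless, so the "fixed" scaling pins the
asymptotes to the observed extremes instead; the model count stays 15.
Admixture Q scores are proportions, analysed as frequency traits with
the number of genotyped individuals as the effective trial count — a
deliberately conservative effective sample size.

**Free parameters** are counted per architecture: center and width
always (2); each independent tail side adds $(\delta, \tau)$ (mirror
adds one shared pair); free scaling adds 2; $\sigma$ adds 1. AICc is
$-2\hat\ell + 2K + 2K(K+1)/(n-K-1)$ with $n$ = localities carrying data,
and is $+\infty$ with a warning when $n \le K+1$.

**Fitting.** Priors are uniform within scale-aware bounds: $c$ over the
transect span extended by half a span on each side, $w \in (0, 10\,
\mathrm{span}]$, $\delta \in [0, \mathrm{span}]$, $\tau \in (0,1]$,
free asymptotes ordered by construction ($p_{max} = p_{min} +
(\mathrm{hi}-p_{min})\cdot g$ with $g \in (0,1]$), and $\sigma$ bounded
by half the observed data range (the per-locality mean ± 2 SD
envelope). Sampling works on logistic-transformed coordinates with the
Jacobian included. Phase 1 is a single adaptive random-walk chain
(default $10^6$ steps, first half discarded) whose batch-wise adaptation
targets a 0.23 acceptance rate and estimates the proposal covariance;
phase 2 runs three independent fixed-kernel chains (default
$3\times10^6$ steps each) using the $2.38^2/d$-scaled phase-1
covariance, started from overdispersed draws of the phase-1 tail.
Adaptation happens only in phase 1, so no diminishing-adaptation
argument is needed. The ML point is the best-likelihood draw refined by
local optimization; intervals are central posterior quantiles (the
default; a profile-likelihood interval would be the alternative reading
of "95% interval" and can be derived from the returned draws); a
split-chain potential scale reduction factor above 1.1 sets a
`non_convergence` flag without failing, and a posterior width at its
prior bound flags an unidentifiable (flat) trait. `modelSelect()`
obtains the 15-model AICc table by bounded multi-start maximum
likelihood — the table needs only $\hat\ell$ and $K$ — and runs the MCMC
on the winning architecture when asked; this keeps selection affordable
without changing what is selected. The Metropolis kernel is compiled
(Rcpp) and uses R's RNG, so seeded runs are bit-reproducible.

The recovery and selection simulations in the tests and acceptance
script use 11 localities over 400 km, a true center of 200 km and width
of 50 km, 30 individuals per locality, and reduced chain lengths
($10^5$ adaptation, $3\times10^5$ total phase-2 steps) — sizes chosen so
the full suite completes in minutes while leaving the posterior
diagnostics clean (split-chain $\hat R < 1.01$ in the cases inspected).

## Classification

PCA is computed on the covariance matrix of complete cases by default —
the conventional choice for morphometric measurements on a common scale
(mm/g) — with correlation mode available; published variance fractions
can depend on that choice and on transformations (e.g. log-mass), which
is why both modes are exposed. Loadings are oriented so each one's
largest-magnitude entry is positive. Discriminant classification uses
pooled within-group covariance and leave-one-out cross-validation
implemented as explicit per-row refits: the held-out row demonstrably
never influences its own training fold (closed-form LOO shortcuts can
diverge from a genuine refit on extreme points, so the explicit loop is
the honest implementation of that property). Missing trait values are
handled by complete-case analysis, never imputation. Mixed-model
inference on trait differences is out of scope; the module exports tidy
tables for external tools.

## Distribution-model support

The package implements the *procedures* around presence-only modeling,
not the model engine: bias-weighted pseudo-absence sampling (cells drawn
proportionally to a weight surface, e.g. $1 -$ scaled distance to
roads, jittered within cells), greedy 10-km proximity thinning that
prefers specimen records, enumeration of the feature-class × smoothing
tuning grid (every non-empty subset of {linear, quadratic, hinge} times
the smoothing sequence; 1–12 in steps of 0.5 gives 161 cells), an
iterative collinearity filter (drop the higher-VIF member of the
most-correlated pair above $|r| = 0.8$ until none exceeds it), and
permutation-importance backward selection. The selection driver is
engine-agnostic via a fitter contract — `fitter(data, features, cell)`
returning log-likelihood, a parameter count and a predictor — and ships
a penalized logistic presence/pseudo-absence fitter (L1, penalty
proportional to the smoothing value, hinge bases at interior quantile
knots) so the whole procedure is testable hermetically. AICc for that
fitter counts nonzero coefficients, mirroring the usual MaxEnt-AICc
convention, with $n$ = presence records. Permutation importance is the
drop in model log-likelihood when one predictor's column is shuffled,
averaged over 10 seeded permutations, clipped at zero and normalized to
sum to 100%; predictors are dropped, worst first, until all importances
reach the 1% threshold. The replicate count and normalization inside the
original engine are not public; 10 seeded permutations summing to 100%
is this package's stated substitute.

## Synthetic data: what it emulates, and what it does not

Every generator takes an explicit seed, returns its ground truth
alongside the data, and is bit-reproducible (generator version recorded
in the truth record).

* `simulateSequences()` builds each group on a Kingman coalescent
  (exponential waiting times, uniform pairwise merging) with
  infinite-sites mutations placed by a Poisson process at rate
  $\theta/2$ per unit branch length, each mutation hitting a previously
  unmutated site so that p-distances equal mutation counts over $L$;
  group ancestors differ at $\mathrm{Binomial}(L, d)$ fixed sites. A
  spec whose expected mutation count $\theta a_1$ exceeds $L$ is
  refused. Because cross-group pairs also carry within-group
  polymorphism, realized between-group mean divergence slightly exceeds
  $d$ unless $\theta = 0$; moment checks therefore set $\theta = 0$ when
  they target $d$ itself.
* `simulateGenotypes()` draws per-locus ancestral frequencies uniformly
  on the simplex and group frequencies from the Balding–Nichols
  Dirichlet with concentration $(1-F_{ST})/F_{ST}$ (capped at 0.999;
  $F_{ST}=0$ is the shared-frequency limit), then genotypes as two
  independent draws (HWE within groups) with a missingness mask.
* `simulateTransect()` samples binomial counts or Gaussian individual
  values under a true cline; `simulateLandscape()` produces smooth
  Gaussian-kernel-filtered random fields, the road-distance surface
  min-max rescaled to $[0,1]$.

The within-clade $\theta$ defaults used in examples and the pipeline are
package choices — reasonable for intraspecific mitochondrial data — not
estimates of any particular population. The generators deliberately
omit recombination, selection, spatial coalescent structure, null
alleles and genotyping error; passing tests on these data demonstrate
the correctness of the estimators and the fitting machinery under their
own assumptions, not robustness to the messiness of field data.

## Degenerate inputs and tie-breaking

Monomorphic loci give HWE p = 1 and NA LD tests; all-missing group-locus
cells give NA summaries; a flat transect trait drives the width
posterior to its prior bound and is flagged rather than failing;
coalescent topology ties are broken by the seeded RNG; occurrence
thinning breaks within-priority ties by a seeded shuffle; zero-width
likelihood evaluations are protected by the $10^{-9}$ frequency clamp;
components constant within groups are ridge-jittered before LDA with a
warning. All file outputs are plain text and diff-able, and a run log
records operation, parameters, seed and input/output digests for every
pipeline invocation.

## Known limitations

Clines are fitted per trait (no joint likelihood across traits, matching
standard practice); only one spatial dimension is supported; no
model-corrected distances (HKY etc.), no tree inference, no admixture
inference (Q matrices are consumed, not computed), no MaxEnt internals.
The "observed" scaling fixes asymptotes to noisy sample extremes, which
slightly favours it in AICc comparisons at small locality counts — the
model table reports all 15 architectures so that such near-ties are
visible rather than hidden.
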