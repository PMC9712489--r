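# clinepop

Integrative population-genetic analysis of avian contact zones, built
for studies where phenotypically distinct lineages (morphotypes) meet
along a transect: mitochondrial diversity and neutrality statistics,
haplotype networks, between-clade divergence with strict-clock dating,
microsatellite summaries (heterozygosity, exact Hardy–Weinberg tests,
rarefied allelic richness, private alleles, linkage disequilibrium,
DAPC-style assignment), geographic cline fitting with AICc selection
over 15 sigmoid-plus-tail architectures, cross-validated discriminant
classification, and the bias-aware sampling / tuning-grid / backward-
selection procedures used around presence-only distribution models.
Seeded synthetic-data generators with recorded ground truth make every
analysis testable end to end.

## The models in brief

* **Diversity and neutrality.** For $n$ aligned sequences:
  $\theta_S = S/a_1$ (Watterson), $\theta_\pi$ = mean pairwise
  differences, per-site $\pi$ with pairwise-valid denominators;
  Tajima's $D = (\theta_\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$;
  Fu's $F_S = \ln\!\big(S'/(1-S')\big)$ with
  $S' = \Pr(K \ge H_{obs})$ under the Ewens sampling formula, computed
  in log space via the Stirling-number recursion.
* **Clines.** Trait value
  $p(x) = p_{min} + (p_{max}-p_{min})\,\frac{1+\tanh(2(x-c)/w)}{2}$
  along a transect of haversine positions, optionally with exponential
  tails beyond attachment distances; 5 tail configurations × 3 scalings
  = 15 models ranked by
  $AICc = -2\hat\ell + 2K + 2K(K+1)/(n-K-1)$; posteriors by adaptive
  random-walk MCMC (compiled kernel, three fixed-kernel chains after a
  discarded adaptation phase).
* **Microsatellites.** Unbiased $H_E$, exact conditional HWE test
  (complete enumeration or an allele-swap Monte Carlo whose stationary
  law is the Levene null), rarefaction
  $R_S = \sum_a [1-\binom{2N-N_a}{g}/\binom{2N}{g}]$, private-allele
  reports, genotypic LD permutation tests.
* **SDM support.** Pseudo-absences sampled proportionally to a bias
  surface; feature-class × smoothing tuning grids (the conventional
  {linear, quadratic, hinge} × 1–12-by-0.5 grid has 161 cells);
  VIF-guided collinearity filtering; permutation-importance backward
  selection around a pluggable fitter (penalized logistic by default).

See `vignettes/contact-zone-methods.Rmd` for assumptions, parameter
defaults and numerical choices.

## Worked example

Simulate a two-clade mitochondrial panel at 7.8% ancestral divergence
and an 11-locality contact-zone transect, then summarise and fit:

```r
library(clinepop)

sim <- simulateSequences(n_per_group = 15, L = 1041, theta_within = 4,
                         d_between = 0.078, groups = c("CI", "RM"),
                         seed = 42)
panel <- sim$panel
panel
#> SequencePanel: 30 sequences x 1041 sites, 2 populations, 2 groups

print(diversityStats(panel), digits = 3)
#>   group  n  S H      pi   pi_sd theta_S theta_S_sd theta_pi theta_pi_sd     FS
#> 1    CI 15 10 8 0.00298 0.00184    3.08       1.53     3.10        1.91 -1.586
#> 2    RM 15 11 8 0.00371 0.00222    3.38       1.66     3.87        2.31 -0.922
#>        D
#> 1 0.0363
#> 2 0.5511

div <- groupDivergence(panel, "CI", "RM")
round(div, 4)
#>    min   mean    max
#> 0.0836 0.0859 0.0884
round(clockTime(div[["mean"]]), 2)   # Myr under the 2.1%/Myr clock
#> [1] 4.09
```

Each group retains 8 of 15 sequences as unique haplotypes with low
within-clade diversity ($\pi \approx 0.003$), while cross-clade
p-distances sit near 8.6% — the requested 7.8% ancestral split plus the
within-group polymorphism both clades carry — which the strict clock
converts to roughly 4 Myr.

```r
st <- simulateTransect(seq(0, 400, length.out = 11),
                       list(mt = c(center = 200, width = 50)),
                       n_per_locality = 30, seed = 42)
ms <- modelSelect(st$transect, "mt", seed = 1)
print(head(ms$table, 3), digits = 4)
#>   tail_config  scaling K  maxLL  AICc failed     dAICc
#> 1        none  fixed01 2 -32.81 71.13  FALSE 0.000e+00
#> 2        none observed 2 -32.81 71.13  FALSE 4.562e-09
#> 3        left observed 4 -32.81 80.29  FALSE 9.167e+00

fit <- fitClineMCMC(st$transect, "mt", seed = 1,
                    n_adapt = 1e5, n_iter = 1e5)
fit
#> ClineFit [mt]: tails=none scaling=fixed01  K=2  maxLL=-32.813  AICc=71.126
#>   params: center=201.3  width=52.38  deltaL=0  tauL=1  deltaR=0  tauR=1  pmin=0  pmax=1  sigma=NA
round(clineCI(fit), 1)
#>         2.5% 97.5%
#> center 192.7 209.8
#> width   38.4  78.3
```

The tail-free architecture wins the 15-model AICc table (tailed models
pay their extra parameters for no likelihood gain on tail-free truth),
and the posterior recovers the generating center of 200 km and width of
50 km inside the 95% intervals.

`runPipeline(config)` chains the stages — simulate, sequence
diversity, microsatellites, classification, clines — writing plain-text
tables, truth sidecars, a manifest and a run log under one output
directory.

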