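---
title: "Power analysis along the multi-omics causal chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power analysis along the multi-omics causal chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainpower)
```

## The model

`chainpower` works with a linear structural chain for the central dogma:

$$X_2 = \beta_1 X_1 + e_2, \qquad X_3 = \beta_2 X_2 + e_3, \qquad
  Y = \beta_3 X_3 + e_4,$$

with $X_1$ the minor-allele count (0/1/2) of a causal SNP, $X_2$ RNA
expression, $X_3$ protein expression, $Y$ a quantitative trait, and mutually
independent zero-mean exogenous errors $e_2, e_3, e_4$. Under Hardy–Weinberg
equilibrium $\mathrm{var}(X_1) = 2p(1-p)$ at minor allele frequency $p$.
Variances propagate forward as
$\sigma^2_{X_{k+1}} = \beta_k^2 \sigma^2_{X_k} + \sigma^2_{e_{k+1}}$, the
squared mediate correlations are
$r_k^2 = \beta_k^2 \sigma^2_{X_k} / \sigma^2_{X_{k+1}}$, and the SNP
heritability of the trait factorises as $h^2 = r_1^2 r_2^2 r_3^2$.
Marginalising the chain, the squared correlation of each level with the
trait is $h^2$ (SNP), $r_2^2 r_3^2$ (RNA) and $r_3^2$ (protein): every extra
link attenuates the signal, which is the whole story the power analysis
quantifies.

Model assumptions that matter for everything downstream: the chain is
linear with homoscedastic, mutually independent errors; the genetic effect
is additive (no dominance or epistasis, a single causal SNP); and for the
analytic theory the errors are Gaussian. Slope signs never enter any power
formula (only squared correlations do), so the inverse solver
`params_from_correlations()` returns non-negative slopes by convention.

## Association tests and sampling designs

Under **simple random sampling** the level–trait association is tested by
the classical t-test for the regression slope; with population squared
correlation $\rho^2$ and $n$ samples the statistic is approximately
noncentral $t_{n-2}$ with noncentrality
$\delta = \sqrt{n}\,\rho/\sqrt{1-\rho^2}$.

Under **extreme phenotype sampling** an identical number of individuals is
drawn from the top and bottom $100\alpha\%$ tails of the trait distribution
and the level variable is compared between tails by a pooled two-sample
t-test ($n/2$ per tail, $n-2$ degrees of freedom). For a standardized
predictor with correlation $\rho$ to the standardized trait, truncation
selection theory gives conditional means $\pm\rho\lambda(\alpha)$, where
$\lambda(\alpha) = \phi(z)/\alpha$ at $z = \Phi^{-1}(1-\alpha)$, and
conditional variance $1 - \rho^2(1 - v(\alpha))$ with within-tail trait
variance $v(\alpha) = 1 + z\lambda - \lambda^2$. The noncentrality is
therefore

$$\delta_{\mathrm{EPS}} =
  \frac{\rho\,\lambda(\alpha)\,\sqrt{n}}
       {\sqrt{1 - \rho^2\,(1 - v(\alpha))}}.$$

The denominator (the "shrinkage" term) follows from exact bivariate-normal
selection algebra and is the default. `shrink = FALSE` drops it, treating
the within-tail predictor spread as 1; the two variants bracket the common
selection-theory approximations. The Monte-Carlo simulator sides with the
shrinkage version (see below), which is why it is the default. For the SNP
level the predictor is a discrete genotype, so the bivariate-normal
selection argument is only an approximation there; the simulator shows it
is accurate to about a percentage point of power in the designs the package
targets, and the test suite holds it to an absolute 0.02 band.

Power is the noncentral-$t_{n-2}$ tail mass beyond the central-$t$ critical
value. At $\delta = 0$ the power is set to the significance level exactly
(it is the size by construction), which keeps the null-calibration
identity exact rather than at the mercy of the noncentral algorithm's last
digits. A `normal_approx = TRUE` option replaces the noncentral t with the
large-sample normal formula
$\Phi(\delta - z_{1-\alpha/2}) + \Phi(-\delta - z_{1-\alpha/2})$.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `maf` | minor allele frequency (fraction) | 0.25 | a common-variant working value used by all reference tables |
| `error_var` | exogenous error variances $(e_2,e_3,e_4)$ | (1, 1, 1) | unit scale; with the anchor slopes below it places $h^2$ at exactly 1.0% |
| `sig_level` | nominal significance | 2.5e-6 | Bonferroni-style gene-based genome-wide level, 0.05 over ~20,000 protein-coding genes |
| `sides` | sidedness of the t-tests | 2 | direction of effect unknown a priori |
| `trunc_alpha` | per-tail EPS fraction | 0.2 | typical reported truncation in extreme-sampling protein studies (0.1–0.2); note it is *per tail*, so 2α of the population is eligible |
| `target_power` | power for sample-size inversion | 0.80 | conventional design power |

The anchor effect sizes $\beta = (0.5744, 0.7183, 0.4564)$ give
$r^2 = (0.110, 0.367, 0.248)$ and $h^2 = 1.0\%$ — squarely inside the
ranges reported for eQTL effect sizes (genotype–RNA $r_1^2$ up to ~15%),
RNA–protein coupling ($r_2^2$ up to ~50%) and protein–trait correlations
implied by reported fold changes ($r_3^2$ up to ~34%).

## The heritability path

Curves indexed by $h^2$ need a rule for how the three mediate correlations
move together; the mapping $h^2 \mapsto (r_1^2, r_2^2, r_3^2)$ is genuinely
underdetermined, and this was an open design choice. The package uses a
**common cube-root scaling**: each $r_k^2$ is multiplied by
$(h^2 / h^2_{\mathrm{anchor}})^{1/3}$, anchored at the reference effect
sizes above. This keeps the relative layering of the three levels intact
while hitting the requested heritability exactly, and it reproduces the
package's reference sample-size table consistently across its heritability
rows. It is one defensible path among several (one could instead scale only
the genotype link, or move along reported effect-size ranges); results at a
*given* $(r_1^2, r_2^2, r_3^2)$ never depend on it, only curves
parameterised by $h^2$ do.

## Fold-change conversion

Extreme-sampling protein studies report between-tail fold changes rather
than correlations. The package models protein intensity as log-normal with
standardized log intensity; the expected between-tail difference in mean
log intensity is $2 r_3 \lambda(\alpha)$, hence
$r_3 = \ln(\mathrm{fc}) / (2\lambda(\alpha))$. At $\alpha = 0.2$ a 5-fold
change converts to $r_3^2 = 33.05\%$. Conversions in this range are often
quoted rounded to ~34%; the package reports the exact closed form above and
does not adjust constants to match any rounded figure. The conversion is
exactly self-inverse (`r3sq_to_fold_change()`), which the tests hold to
1e-10.

## The simulator

`simulate_cohort()` draws genotype Binomial(2, `maf`) and Gaussian errors;
`simulate_eps()` simulates a pool of $\lceil n/(2\alpha)\rceil$ individuals
and retains the $n/2$ most extreme per trait tail, so the selected set is
exactly the empirical $\alpha$ tails of the pool. `empirical_power()`
replays the full design — simulate, select, test at `sig_level` — over
seeded replicates and reports the rejection frequency with its binomial
standard error. Replicate $r$ uses derived seed `seed + r − 1`, so results
are bit-reproducible and independent of any chunking. Ties in the trait
have probability zero under continuous errors; `order()` resolves any
future discrete ties by sample index.

The simulator is the package's oracle: the closed-form variance chain,
heritability factorisation, truncation moments and both noncentrality
reconstructions are all validated against it in the test suite (moment
contracts at $10^6$ samples within 3 Monte-Carlo standard errors; analytic
versus empirical power at $10^4$ replicates). What the simulator
deliberately does *not* emulate: linkage disequilibrium and multi-SNP
architectures, population structure, omics measurement error and batch
effects, non-linear or heteroscedastic links, and non-Gaussian errors
(an `error_rng` hook exists for robustness experiments, but the analytic
formulas are not expected to hold there). Passing tests therefore certify
the mathematics of the idealised chain, not the messiness of any real
multi-omics dataset.

## Numerical choices

- Sample-size inversion brackets by doubling from $n = 16$ and finishes
  with integer bisection; power is strictly increasing in $n$, so the
  result is the unique smallest admissible $n$ (even $n$ only under EPS,
  since both tails contribute $n/2$). The bracketing invariant — power at
  the next smaller admissible $n$ falls below target — is asserted in the
  tests.
- Distribution functions are evaluated at library precision
  (`stats::pt(..., ncp = )`, `qt`, `qnorm`); the only special case is the
  exact size at zero noncentrality described above.
- The two-sample test is pooled-variance (not Welch) so that its degrees of
  freedom match the $n - 2$ convention of the power engine; a Welch option
  exists for data analysis (`welch = TRUE` in `two_sample_t_test()` /
  `chain_test()`).
- Degenerate inputs: a constant predictor is a domain error; a constant
  response gives slope 0 and $t = 0$; a zero residual variance with a
  non-zero effect is flagged `degenerate` with p-value 0.

## Problem sizes in the shipped tests

The test suite keeps its Monte-Carlo blocks at sizes a laptop handles in
seconds while leaving the binomial error bars tight enough to be
discriminating: $10^4$ replicates for the analytic-versus-empirical power
comparisons and the null-calibration checks (Monte-Carlo standard error
about 0.005 at power 0.5, 0.002 at size 0.05), $10^6$ draws for moment
contracts, and 2 × 10^5 selected samples for the truncation-moment check.
These are the package's chosen validation sizes, stated here so the
reported tolerances (3 Monte-Carlo standard errors) can be read correctly.

## Known limitations

- The EPS noncentrality treats the selected predictor as normal within each
  tail; it is exact bivariate-normal selection algebra for the mean and
  variance but ignores within-tail skewness, so analytic EPS power can sit
  a few tenths of a percentage point above the simulated truth at moderate
  $\rho^2$ and small $n$ (visible in the simulator comparisons). The
  simulator, not the closed form, is the final arbiter in that regime.
- Genotype discreteness makes all SNP-level formulas normal
  approximations.
- Single causal SNP, no covariates, quantitative traits only, fixed
  Bonferroni-style significance level; none of the multi-stage screening or
  causal-inference machinery that would sit downstream of a designed study
  is included.
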