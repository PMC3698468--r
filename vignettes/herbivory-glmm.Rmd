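---
title: "Methods: phylogenetic diversity, crossed binomial mixed models, and the parametric bootstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic diversity, crossed binomial mixed models, and the parametric bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbdiv)
```

## The scientific setting

`herbdiv` analyzes invertebrate leaf herbivory in plant communities as a
function of two community properties: how many plant species a plot holds
(species richness, SR) and how much evolutionary history those species span
(abundance-weighted phylogenetic diversity, PD, measured as Phylogenetic
Species Evenness). The unit of analysis is an individual plant: for each
sampled plant we observe the number of damaged leaves out of the total leaf
count. The question is whether plot-level diversity predicts the
probability that any given leaf is damaged, once the large differences
between plant species (some are heavily defended, some are palatable) and
idiosyncratic plot effects are absorbed by random effects.

## Phylogenetic Species Evenness

For the species present in a plot, the Brownian-motion correlation matrix
$C$ of the (pruned) phylogeny gives $c_{ij}$ = shared root-to-MRCA path
length standardized to unit diagonal — for an ultrametric tree, MRCA depth
over tree depth. Phylogenetic Species Variability is

$$\mathrm{PSV} = \frac{n\,\mathrm{tr}(C) - \sum_{ij} c_{ij}}{n(n-1)} = 1 - \bar c_{\mathrm{off}},$$

the expected variance of a neutral Brownian trait across the community,
standardized by its expectation on a star phylogeny. PSE extends this to
abundances $m_i$ (here the 0–4 quadrat-count coding): conceptually each
species is expanded into $m_i$ individuals joined by zero-length branches
and the trait variance is taken over individuals,

$$\mathrm{PSE} = \frac{N \sum_i m_i c_{ii} - m^\top C m}{N^2 - N \bar m},
\qquad N = \sum_i m_i,\; \bar m = N/n.$$

The denominator is the *evenness* standardization: it equals the
numerator's maximum, attained only on a star phylogeny with equal
abundances, so $\mathrm{PSE} \in [0,1]$ and reduces exactly to PSV under
equal abundances. Our test suite verifies the numerator algebra against a
brute-force oracle that literally enumerates individual pairs on the
expanded correlation structure, and cross-checks whole values against
picante's reference implementation. Note that a naive reading of the
individual-expansion picture — "PSV of the expanded matrix" — uses
denominator $N(N-1)$ and is *not* the published index; the two differ
whenever abundances are uneven (e.g. two species, $c = 0.25$, abundances
(3, 1): 0.5625 vs 0.375). We follow the reference implementation's
denominator.

Two practical details. First, pruning: removing tips from a rooted tree can
leave the remaining species' MRCA below the original root; the intervening
stem is shared history of every remaining pair and is retained as a root
edge, so pruning commutes with taking submatrices of $C$. Second,
independence from richness: the phylogenetic component of PSE (PSV; PSE
under even abundances) is uncorrelated with SR under uniform community
assembly, which we verify by simulation. The abundance-evenness component
adds a small positive SR–PSE coupling (r ≈ 0.15 in our generator's uniform
1–4 abundance draw) because random abundances are less even at low
richness; this is a property of the index, not of the assembly process.

## The damage model

With $\mathit{Damaged}_i \sim \mathrm{Binomial}(p_i, N_i)$ for plant $i$,

$$\mathrm{logit}(p_i) = \alpha + \mu^{\mathrm{species}[i]} + \mu^{\mathrm{plot}[i]}
 + \mu^{\mathrm{obs}[i]} + \beta_{pd}\,PD + \beta_{sr}\,SR
 + \beta_{pd*sr}\,(PD{\times}SR) + \beta_{date}\,DATE,$$

where the three random effects are independent Gaussians with variances
$\sigma^2_{\mathrm{species}}, \sigma^2_{\mathrm{plot}},
\sigma^2_{\mathrm{obs}}$. The observation-level effect (one level per
plant) absorbs extra-binomial dispersion, which the binomial itself cannot
represent. All continuous predictors are centered by their plot-table
means before the analysis, and the interaction column is the product of the
*centered* main effects and is not itself re-centered — each main effect is
then the slope at the mean of the other variables. Species-level damage
summaries use the species random effect ($p_k =
\mathrm{logit}^{-1}(\alpha + \hat\mu_k^{\mathrm{species}})$); plot-level
summaries use the plot effect plus the plot-level fixed terms, excluding
DATE (because DATE is centered, excluding it equals evaluating it at its
mean).

## The Laplace fit

The marginal likelihood integrates over all random effects; with crossed
factors this integral has no useful product structure, so we use the
Laplace approximation: with spherical effects $b = \Lambda u$, $u \sim
N(0, I)$, the criterion is

$$-2\,\ell(\beta, \sigma) \approx d(y, \hat\mu) + \hat u^\top \hat u +
 \log\det(I + \Lambda^\top Z^\top W Z \Lambda),$$

where $\hat u$ is the conditional mode found by penalized IRLS and $W$ the
binomial weights there. The observation factor contributes a diagonal block,
so each IRLS step reduces by a Schur complement to a dense core of dimension
(number of fixed effects + species levels + plot levels) — about 70 for a
full-size study — at cost $O(nk^2)$ per iteration; the log-determinant
splits into a sum over observations plus the core's Cholesky diagonal.

Fitting proceeds in two stages. Stage one profiles $\beta$ through the
joint $(\beta, u)$ penalized mode and searches the SDs alone; it is cheap
and supplies starting values only. Stage two — the production fit — moves
$(\sigma, \beta)$ jointly in a derivative-free Nelder–Mead simplex (run in
compiled code, with one restart from the incumbent) while PIRLS solves for
$u$ only. The distinction matters: the profiled shortcut ignores the
log-determinant's dependence on $\beta$, and in our replicate experiments
at the default operating point that bias cost the richness coefficient
about nine points of 95% Wald-interval coverage (82/100 vs 91/100); the
joint stage matches lme4's `glmer` Laplace fit to optimizer precision, which
we assert in the test suite.

Numerical choices: the outer search runs on the SD scale directly — the
criterion is even in each SD, so the boundary $\sigma = 0$ is a smooth
interior point, whereas a log parameterization has an infinitely flat tail
that simplex methods crawl through. SDs are capped at 50 (far beyond any
plausible logit-scale value) to keep the normal equations conditioned while
exploring, and estimates below $10^{-6}$ are reported as 0 with a boundary
flag. The inner PIRLS uses step-halving and never accepts an increase of
the penalized deviance; a divergent warm start falls back to the origin.
Default tolerances: $10^{-8}$ relative on the outer objective, $10^{-12}$
on the inner penalized deviance. Wald $z$ is estimate/SE with SEs from the
fixed-effect block of the inverse joint $(\beta, u)$ Hessian at the
optimum; conditional SDs of every random-effect level come from the
corresponding blocks of the same inverse (unlike lme4's `condVar`, which
conditions on $\beta$; ours therefore includes fixed-effect uncertainty).
Display intervals for damage estimates are the back-transformed conditional
mode ± 1 conditional SD, asymmetric on the probability scale.

## The parametric bootstrap

Wald $z$ statistics from a Laplace fit have no exact reference
distribution, so significance is assessed by simulation: for the factor
under test, the reduced model (that column removed; all others, including
the interaction, retained — the literal "without the factor of interest"
reading, with the marginality caveat that removing a main effect while
keeping the interaction changes its meaning) is fitted to the observed
data; `B` response vectors are simulated from it (fresh random effects at
every level, binomial damage at fixed $N_i$ and predictors); the full model
is refitted to each; and

$$p = \#\{|z_{sim}| \ge |z_{obs}|\} / B,$$

with non-converged refits (rare; warned about above 2% of `B`) excluded
from the denominator. A $p$ of 0 prints as "< 1/B". Refits are
warm-started at the observed-data optimum, skip the simplex restart, and
run at an outer tolerance of $10^{-6}$ — efficiency devices that leave $z$
noise far below the Monte Carlo resolution of the simulated distribution
(we verified on matched simulations that production-tolerance refits give
the same $z$ to correlation 0.99 and equal spread).
The study-scale default is `B = 1000`; our calibration tests use `B = 199`
with 200 outer replicates, which resolves the null rejection rate at
$\alpha = 0.05$ to within about ±0.04.

An important finite-sample caveat that the test suite measures directly:
the bootstrap simulates from *estimated* variance components, and with few
random-effect levels the ML estimates are biased low (there is no REML
analogue here), so the simulated $|z|$ reference is narrower than the true
null sampling distribution and p-values skew small. At the suite's
deliberately tiny calibration design — 8 plots and 6 phytometer species —
the effect is visible: the observed null $z$ varies more across replicate
datasets than the bootstrap reference built from any one of them, the
rejection rate at $\alpha = 0.05$ runs above nominal, and the p-value
distribution departs from uniformity (Kolmogorov–Smirnov distance
above 0.1). The bias shrinks with the number of levels, as ML variance
bias does; a study-sized design (38 plots, 27 species) is the regime the
procedure is intended for. Users applying the bootstrap to designs with
fewer than roughly 15–20 plots should treat p-values near the threshold
with caution.

## The synthetic-data generator

The generator emulates the field design end to end and is the ground truth
for every calibration claim: a pure-birth (Yule) tree with depth normalized
to 1 over a 52-species forb pool; 38 plots whose richness is uniform on
3–17; community assembly that picks a focal species and admits others with
probability $\propto e^{-\lambda\,d}$ in patristic distance ($\lambda = 0$,
the default, is uniform assembly — the regime in which SR and the index's
phylogenetic component are independent; large $\lambda$ yields clustered,
low-PSE plots); quadrat abundances uniform on 1–4; sampling dates uniform
on a 14-day window; damage measured on the 27 most frequently occurring
species (the phytometers), 10 plants per phytometer per plot, leaf counts
$1 + \mathrm{Poisson}(15)$ (the leaf-count law is a declared convention —
field data would pin it down, none is available to us). True parameters
default to the reported operating point of the study this design mirrors:
fixed effects (0.15, 0.10, 0.23, −0.19, −0.28) for intercept, date, SR,
PD, SR×PD, and latent variances (2.4, 0.26, 0.82). Under these defaults a
study realizes roughly 1,900–2,300 plants with mean leaf damage near 50%,
and species-level damage spans low single digits to the high nineties —
the qualitative shape of the motivating dataset.

What the generator does *not* emulate: real abundance distributions (it
draws quadrat counts uniformly), non-Brownian trait or defense evolution,
spatial structure among plots, herbivore movement or diet-breadth
mechanisms, and observation error in leaf counts. Passing the recovery and
calibration tests therefore shows the estimator is correct *under the
model*, not that the model is adequate for any particular field system.

## Problem sizes used by the test suite

Scientific checks run at sizes chosen to make their Monte Carlo error
meaningful: parameter recovery uses 100 replicate studies at the full
default size; bootstrap size calibration uses 200 replicates × B = 199 on a
scaled-down design (8 plots, 12-species pool, richness 3–6, 6 phytometers,
3 plants per species-plot) whose smaller fits keep the experiment at desk
scale; quadrature agreement uses 50 random single-factor datasets against a
25-point adaptive Gauss–Hermite oracle; the evenness oracle runs 200 random
tree/abundance draws; positive-semidefiniteness and range properties run on
1000 random trees.

## Known limitations

The Laplace approximation is least accurate for binary-like data (small
$N_i$) with large variances; with leaf counts around 16 it tracks 25-point
adaptive quadrature to well under 0.1 nats in our tests, but users with
sparse leaf counts should expect some approximation error. The bootstrap
refits the full model once per simulation — cost scales linearly in `B`.
Only logit links, intercept random effects, and the three-factor crossed
design are supported; REML-style criteria, random slopes, and model
selection are out of scope. Evenness (Pielou's index on the 0–4 codes) is
provided as an exploratory utility only and never enters the model.
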