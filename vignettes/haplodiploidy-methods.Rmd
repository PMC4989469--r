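---
title: "Models and methods for the evolution of haplodiploidy and chromosome number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for the evolution of haplodiploidy and chromosome number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyshift)
```

## The scientific question

Haplodiploidy — male haploidy via arrhenotoky or paternal genome
elimination — has evolved repeatedly in arthropods, nowhere more often
than in mites (Acari). Because haploid males express every recessive
deleterious allele they carry, the transition from diplodiploidy should
be easiest in lineages where males are already effectively haploid for
much of the genome: under male heterogamety (XO/XY), that means
lineages with *few chromosomes*, where the X is a large fraction of the
genome. `ploidyshift` implements the comparative machinery needed to
interrogate this hypothesis on time-calibrated phylogenies:

1. **Is haplodiploidy (nearly) irreversible?** Two continuous-time
   Markov models of the binary reproductive system are compared by
   AICc: a *one-rate* model allowing only D→H transitions with the
   root fixed diplodiploid, and a *two-rate* model allowing reversal,
   with stationary root frequencies.
2. **How many origins?** Stochastic character mapping draws complete
   histories conditional on the tips and fitted rates; origins are
   counted per map and summarized over maps and trees.
3. **Do origins sit on low-chromosome-number branches?** Haplodiploid
   tips are pruned, diploid chromosome number (2n) is reconstructed
   under Brownian motion on the remaining tree, and the mean
   reconstructed count at origin-subtending nodes is compared with a
   Monte Carlo null of randomly chosen nodes.
4. **How strong is the ploidy–karyotype association?** A Bayesian
   phylogenetic mixed model (and a taxonomic analogue) regresses
   log(2n) on ploidy; the liability threshold model estimates the
   correlation between the binary trait's latent liability and
   log(2n) with both heritabilities fixed at 1.

## Models

### Binary-state Markov models

The reproductive system evolves as a 2-state chain with rates
$q_{DH}$ and $q_{HD}$. Transition probabilities are closed-form,
$P_{DD}(t) = \pi_D + \pi_H e^{-(q_{DH}+q_{HD})t}$, and the tip
likelihood is computed by Felsenstein's pruning algorithm with
per-node scaling. The one-rate model ($q_{HD}=0$) must use a root
fixed in state D: its stationary distribution is degenerate, and the
package refuses `root_mode = "stationary"` in that case rather than
returning `NaN`. Impossible data (an H tip when $q_{DH}=0$) give
$-\infty$, a value that orders below every finite likelihood and
deliberately poisons AICc.

Fits maximize the log-likelihood over log-rates in
$[10^{-8}, 10^3]$ with `L-BFGS-B` from five Latin-hypercube starting
points. The hypercube is a *fixed* stratified design (midpoints of
five strata, second axis permuted), so a fit is deterministic and
independent of the RNG state — important because fits are embedded in
larger seeded simulations. Monomorphic data produce a flagged
boundary fit instead of an error.

AICc uses $n =$ number of tips; the comparison is reported as
$\Delta\mathrm{AICc} = \mathrm{AICc}_{two} - \mathrm{AICc}_{one}$, so
negative values favor reversibility. Both AIC and AICc are stored.

### Stochastic character mapping

Histories are sampled by drawing node states *jointly* root-to-tip
from their exact conditional distributions (sampling independent
marginals would not produce a valid joint history), then filling each
branch with a path conditioned on its endpoints. Branch paths are
drawn by rejection sampling of unconditioned chains; after $10^4$
rejections the sampler falls back to a uniformization bridge, which
matters for irreversible bridges with unlike endpoints under small
rates. An origin is a D→H event; a haplodiploid root counts as one
additional origin on the stem. That root convention is the package's
own (an origin outside the observed tree cannot be localized), and is
recorded with the summaries.

### Brownian-motion ancestral reconstruction

Ancestral values are the exact Gaussian conditional means given the
tips, computed by two-pass message passing on the tree (equivalent to
the dense GLS solve with the full phylogenetic covariance matrix, but
linear-time). $\sigma^2$ is the ML estimator (quadratic form divided
by $n$). Reported per-node variances are GLS *prediction* variances:
they include the uncertainty from estimating the root mean, which is
why they exceed the known-mean conditional variances some other
implementations report. Chromosome counts are reconstructed on the
log scale by default (counts are strictly positive and
right-skewed); results are back-transformed per node by `exp()`
without bias correction, a reporting convention chosen so observed
and expected means are on the raw 2n scale people recognize. A
raw-scale reconstruction is available through the same functions.

### The origin-node Monte Carlo test

For each sampled history: the $k$ origin-subtending nodes are
identified; all haplodiploid tips are pruned (so reconstruction never
touches haplodiploid counts — a property asserted by a
poisoned-input test); 2n is reconstructed on the pruned tree; the
observed statistic is the mean reconstructed count at the origin
nodes mapped to their nearest surviving ancestors; the null is built
from $R$ draws of $k$ internal nodes taken uniformly without
replacement; and the one-sided add-one p-value
$p = (1 + \#\{\text{null} \le \text{obs}\})/(R+1)$ is reported, so
$p \ge 1/(R+1)$ by construction. The test is one-sided because the
hypothesis is directional (origins at *low* counts). Results are
pooled across maps (and trees) by ranking the pooled observed mean in
the union of null replicates — per-map results share one dataset, so
independence-based combinations such as Fisher's method would be
anticonservative.

Two mapping conventions deserve note. First, an origin's parent node
is almost always suppressed by pruning (its haplodiploid child clade
is gone), so its image on the pruned tree is the nearest surviving
ancestor — one step rootward. Second, this displacement plus the
pruning itself erase much of the signal: the lineages that actually
carried low counts into the transition are exactly the ones removed.
Power analysis during development showed the per-dataset
standardized effect rarely exceeds $|z| \approx 1.5$ at 60 tips
unless the trait variance is large and origins are replicated; the
validation suite therefore defines its "strong dependence" power
regime as $\beta = 3$ with $\sigma^2 = 0.5$, a mean transition
hazard of 0.8 per unit time, at least 8 true origins and at least 15
surviving diplodiploid tips. Users should expect single small trees
with one or two origins to be nearly uninformative in this test no
matter how strong the underlying dependence is.

### Mixed models and the threshold model

The phylogenetic mixed model is the Gaussian animal model
$y = \mu + \beta z + u + e$, $u \sim N(0, \sigma^2_p C)$,
$e \sim N(0, \sigma^2_e I)$, with $y = \log(2n)$ and $z$ the ploidy
indicator (diplodiploid = 0, haplodiploid = 1, so the expected effect
is $\beta < 0$). $C$ is scaled to unit height so variance components
are comparable across trees; phylogenetic heritability is
$\sigma^2_p/(\sigma^2_p + \sigma^2_e)$. Sampling is Gibbs in the
eigenbasis of $C$, which makes every update $O(n)$. Priors: a vague
inverse-gamma(0.001, 0.001) on the residual variance and a
parameter-expanded half-Cauchy(1) on the phylogenetic variance
(implemented through the standard double inverse-gamma hierarchy);
both hyperparameters are exposed as arguments. Significance is
reported as $P_{MCMC}$, twice the smaller tail posterior probability
of $\beta$'s sign, floored at $2/n_{samples}$. Passing a tree set
runs one chain per tree and pools the posteriors, marginalizing over
phylogenetic uncertainty. The taxonomic analogue replaces $u$ with
nested random intercepts (infraorder/family/genus); a level whose
groups are all singletons is inseparable from the residual and is
dropped with a warning.

The threshold model treats ploidy as the sign of a latent liability
that evolves jointly with log(2n) as a bivariate Brownian motion over
the tree with no residual (both heritabilities fixed at 1). The
liability variance is fixed at 1 for identifiability by rescaling
after every inverse-Wishart update of the 2x2 trait covariance; the
reported quantity is the posterior of the between-trait correlation
$r$. Liabilities are updated site by site as truncated normals using
the precision matrix $V^{-1} \otimes C^{-1}$, with rank-one updates
so a full sweep is $O(n^2)$.

Default chain lengths are desk-scale (50k/10k for the mixed models,
15k/5k for the heavier data-augmented threshold sampler); all
samplers are seed-deterministic and report a split-half Rhat on the
focal parameter, warning above 1.1.

## The synthetic data generator

`sim_config()` fixes the study conditions every downstream stage is
validated against:

| parameter | default | meaning |
|---|---|---|
| `n_tips` | 100 | extant tips of the birth–death tree |
| `birth_rate`, `death_rate` | 1, 0 | per-lineage rates; pure birth by default |
| `q_DH0` | 4.5 | D→H hazard at log(2n) = 0 |
| `q_HD` | 0 | reversal rate (irreversible truth) |
| `beta` | 1.5 | state dependence: hazard is `q_DH0 * exp(-beta * x)` |
| `sigma2` | 0.05 | BM rate of x = log(2n) per unit time |
| `x_root` | log(18) | root log count |
| `ploidy_effect` | -0.15 | drift of x per unit time while haplodiploid |

With these defaults the mean transition hazard at the root count is
about 0.06 per unit time, which on a 100-tip pure-birth tree (total
length near 100, height near 4.2) yields a handful — roughly 4 to 13
— of origins; the hazard ratio across one BM standard deviation of x
is about `exp(1.5 * 0.45) ≈ 2`, a noticeable but not overwhelming
state dependence; and tip counts span roughly 4–28 around 2n ≈ 18.
`ploidy_effect` is a constant drift applied while in state H, so the
accumulated shift grows linearly with time since the transition;
−0.15 per unit time with typical post-origin times near 2 gives a
shift of about −0.3 on the log scale, i.e. roughly five chromosomes
at 2n ≈ 19. The generator records the complete true history
(per-branch transition times, node values, origin count), so
inference can be scored against ground truth rather than against
itself.

The tree generator is a forward Gillespie birth–death simulation
started from two lineages, stopped at the instant the (n+1)-th extant
lineage would appear, with extinct lineages pruned and whole-tree
retries on extinction. For a pure-birth tree the expected crown age
is $\sum_{k=2}^{n} 1/(k\lambda)$, which the test suite checks against
simulation.

Numerical choices in the joint trait simulation: Euler steps of
height/1000 per branch, halved (up to 64-fold) wherever
hazard × dt would exceed 0.1; tip counts are `round(exp(x))` clamped
at 4, matching the smallest observed mite karyotypes and keeping
`log` well-defined.

What the generator does *not* emulate: phylogenetic error (trees are
known without uncertainty, unlike the posterior tree sets real
analyses marginalize over), sampling biases in which taxa get
karyotyped, measurement error or intraspecific variation in counts,
karyotype evolution by discrete fusions/fissions (log-BM is a
diffusion approximation), and state-dependent diversification.
Passing tests therefore demonstrate the *machinery* is correct and
calibrated, not that real mite data satisfy these models.

## Tip matching conventions

Matching a tree to a taxon-level compilation proceeds species →
genus → family. Labels are compared case-insensitively with
underscores as spaces; the genus is the first whitespace token. A
genus with no species-level match is collapsed to one tip whose
branch ends at the genus crown-node depth — the compilation tells us
about the genus, and the crown is the latest time the genus is a
single reconstructable lineage; this necessarily leaves the collapsed
tip short of the present, which `check_ultrametric()` reports but
nothing enforces. Multiple matching records contribute their mean
count; records disagreeing on the *discrete* state are an error, not
a vote, because silently resolving a reproductive-system conflict
could manufacture or destroy origins. Trees without branch lengths
are rejected outright — every model here is time-calibrated.

## Validation problem sizes

The package's validation suite runs at deliberately chosen desk
scales: exact-oracle equivalence on 200 random ≤6-tip trees
(enumeration) and 1000 random rate/time pairs (matrix exponential);
model-selection calibration on 50 + 50 datasets of 200 tips;
stochastic-mapping consistency over 10^4 maps on 5-tip fixtures and
origin-count recovery on a 100-tip dataset with 6 true origins;
origin-test calibration on 200 independent 60-tip datasets (R = 100)
plus 50 power datasets in the strong-dependence regime; and
mixed-model coverage over 50 datasets of 100 tips with reduced chain
lengths (15k iterations), with the threshold model checked on three
100-tip replicates at its default chains. These sizes give stable
pass/fail behavior while keeping the full suite in the tens of
minutes.

## Known limitations

* The Mk machinery is strictly 2-state; no hidden-rate or
  correlated-evolution (Pagel-style) models, and no state-dependent
  diversification — ploidy is assumed not to affect speciation or
  extinction, which is untestable here.
* Stochastic maps are empirical-Bayes (rates fixed at their ML
  values), so mapping uncertainty understates total uncertainty.
* The origin-node test inherits the identified power ceiling: pruning
  the haplodiploid tips removes the very lineages that carry the
  signal.
* Back-transformed reconstructions `exp(x̂)` are slightly
  downward-biased for the mean on the raw scale; observed and
  expected means share the bias, so the test's comparison is
  unaffected, but absolute reported counts are conventions, not
  unbiased estimators.
* The threshold sampler fixes the liability variance by rescaling
  rather than marginal augmentation; with complete separation (a
  perfectly predictable binary trait) the prior dominates the
  correlation's magnitude.
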