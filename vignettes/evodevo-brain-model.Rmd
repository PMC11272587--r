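---
title: "An evo-devo dynamics model of hominin brain life history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An evo-devo dynamics model of hominin brain life history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evodevoBrain)
```

## The model

`evodevoBrain` couples a mechanistic model of female hominin development to
mutation-limited evolutionary dynamics, and exposes the machinery needed to
separate the action of selection from the action of developmental
constraint in the resulting evolution of brain size.

### Development

An individual is described at each of `N_a` age bins (default 470 bins of
0.1 yr spanning 0-47 yr) by four phenotypic traits: brain mass `x_b` (kg),
preovulatory ovarian follicle count in mass units `x_r` (kg), remaining
somatic tissue `x_s` (kg) and skill level `x_k` (TB). The newborn state is
fixed and does not evolve. Development is an energy-conservation recurrence
(the developmental map `g_a`): at each bin,

- the resting metabolic rate follows Kleiber's law, `B_rest = K M^(3/4)`
  with `M = x_b + x_r + x_s`;
- the individual realizes the fraction `e` of that budget by overcoming
  energy-extraction challenges (below); maintenance (`B_b x_b + B_r x_r +
  B_s x_s`) is paid from the realized income, and the surplus is the growth
  metabolic rate `B_syn`;
- genotypic growth efforts `y_b, y_r, y_s` (one unconstrained real per
  tissue per bin; the evolving variables) set the allocation fractions
  `q_i = exp(y_i) / (1 + sum_j exp(y_j))` of `B_syn`; tissue `i` grows by
  `q_i B_syn dt / E_i` at synthesis cost `E_i` (MJ/kg). The softmax has an
  idle class, so allocation can be shut down and adults can plateau;
- if maintenance exceeds income, the shortfall is covered by catabolism in
  proportion to each tissue's maintenance share, at yield `E_i` per kg —
  this produces the decay-dominated "failed" organisms whose bodies end up
  almost entirely brain (brain has the slowest per-kg decay rate
  `B_b/E_b`);
- a fraction `s_k` of the brain's energy consumption
  (`B_b x_b + E_b dx_b/dt`) funds skill: it pays the memory cost `B_k x_k`
  and the learning cost `E_k` per TB gained. Skill therefore equilibrates
  near `s_k B_b x_b / B_k`, i.e. about 3.1 TB per kg of brain, which ties
  adult skill to adult brain size;
- all states are floored at zero.

### Energy extraction and social development

Challenges come in four types with probabilities `P_1..P_4`: ecological,
cooperative, between-individual competitive and between-group competitive.
Competence grows with own skill, either exponentially
(`c = c0 exp(gamma x_k)`, Regime 1, weakly diminishing returns of
learning) or as a power law (`c = c0 (1 + gamma x_k)^nu`, Regime 2,
strongly diminishing returns). Each challenge type is a contest of the own
side's competence against the environmental difficulty `alpha` times the
opposing side's competence:

- ecological: `c / (c + alpha)` — independent of social partners;
- cooperative: `C(c, cbar) / (C + alpha)`, where the pair competence `C` is
  additive (`c + cbar`) or submultiplicative (`(sqrt(c) + sqrt(cbar))^2`);
- between-individual: `c / (c + alpha cbar)`;
- between-group: `C(c, cbar) / (C + alpha C(cbar, cbar))`.

Because cooperative and competitive challenges involve the resident
(same-age peer) skill `xbar_k`, development is social whenever `P_1 < 1`.
At the resident, the two competitive types yield the skill-independent
efficiency `1/(1 + alpha)`: competitive skill investment is an arms race
with no resident-level return.

### Fitness and selection

Fertility is proportional to follicle count and survival per bin is a
constant `p`. The mutant's relative fitness then reduces to a ratio of
survivorship-discounted follicle schedules, which is affine in the mutant's
schedule and exactly 1 at the resident. Direct selection is therefore
supported only on follicle count, with gradient `p^(a-1)` (declining force
of selection), and is identically zero on brain, soma, skill and all
genotypic traits. Nothing in the challenge mix or competence regime touches
fitness directly: ecology and culture act purely through the developmental
map.

### Constraint: sensitivities and socio-genetic covariance

Per-age Jacobians of the developmental map are computed analytically
(finite differences serve only as test oracles). Forward accumulation gives
the total effects of the genotype on the phenotype, `dx^T/dy`, which is
block lower-triangular in age (no reverse-time effects). The stabilized
effects `sx/sy^T` additionally let the resident skill perturbation equal
the population's own skill perturbation; because the map depends only on
same-age resident skill, this social feedback resolves sequentially along
the forward recursion (the skill column of each Jacobian is augmented by
the resident-skill channel), and it reduces exactly to the total effects
when `P_1 = 1`. With a diagonal mutational covariance `H_y`, the
mechanistic socio-genetic covariance of the phenotype is
`L_x = (sx/sy^T) H_y (dx^T/dy)^T`; over the geno-phenotype `z = (x; y)`,
`L_z` is singular by construction (rank at most `N_g N_a`) and asymmetric
under social development.

### Evolution

Genotypic traits follow the canonical equation of adaptive dynamics,
`Delta ybar = iota H_y (dw/dy) Delta tau`, a plain forward-Euler loop with
`Delta tau = 1`. The total genotypic selection gradient `dw/dy` is computed
by the backward (adjoint) recursion, which is exactly
`(dx^T/dy) (dw/dx-direct)`. The phenotype change per step is, to first
order, the `x`-rows of `iota L_z (dw/dz)`; [phenotypeRateCheck()] verifies
this and the brain-row reconstruction (the sum over ages of the
brain-follicle covariance times direct follicle selection), and lets one
zero the brain-follicle covariance block to show that brain size then
stops evolving.

## Parameter choices

Maintenance and skill costs are the model's headline parameters: brain
313, follicle 2,697, soma 30 (MJ kg^-1 yr^-1), memory 50 MJ TB^-1 yr^-1,
learning 250 MJ TB^-1, brain allocation to skill 0.5, environmental
difficulty 1.15, skill effectiveness 0.6 TB^-1, newborn skill 0.

The remaining constants were fixed once from literature anchors and from
internal-consistency requirements of the model itself, and are carried in
each scenario file:

- **Kleiber coefficient** `K = 125` MJ yr^-1 kg^-3/4. The measured female
  resting metabolic rate corresponds to roughly 105; the model's `B_rest`
  funds both maintenance and production, so a value between resting and
  total energy expenditure is appropriate. The marginal balance
  `e K (3/4) M^(-1/4) = B_s` then puts the energetic ceiling on somatic
  growth at human-scale body sizes (tens of kg).
- **Synthesis costs** `E_b = 300`, `E_r = 50`, `E_s = 25` MJ kg^-1. Soma
  near measured tissue-deposition costs; brain much more expensive
  (lipid-rich, slow assembly). The ordering `B_b/E_b < B_s/E_s < B_r/E_r`
  makes brain the slowest-decaying tissue under energy deficit, so failed
  organisms end up all brain.
- **Baseline competence** `c0 = 1.2`: an unskilled newborn retains a
  baseline ability to extract energy (efficiency near `c0/(c0 + alpha)`,
  about 0.5), which keeps newborns marginally viable while leaving a wide
  dynamic range of returns to learning up to adult skill levels.
- **Power regime exponent** `nu = 1.5` for Regime 2.
- **Newborn phenotype** (0.15, 0.001, 1.35) kg. The developmental
  Kleiber's law underestimates resting metabolic rate at small sizes, so
  the modeled newborn is lighter than a real one; what matters is that her
  maintenance sits just under her extractable income.
- **Survival** `p = 0.9985` per 0.1-yr bin, i.e. about half the cohort
  reaches 47 yr, a hunter-gatherer-scale survivorship.
- **Challenge mixes**: sapiens (0.60, 0.30, 0, 0.10), the ecology-heavy
  mix with weakly diminishing returns and submultiplicative cooperation;
  afarensis (0.40, 0.50, 0, 0.10) with power competence, and intermediate
  mixes for the other scenarios; ecological is (1, 0, 0, 0).
- **Mutational input** `iota = 2e4` (with unit mutational variance). The
  canonical-equation time unit is the time from mutation to fixation, so
  `iota` is absorbed into the evolutionary time scale; it is set once so
  that the two-stage hominin protocol approaches its equilibrium within
  500 time units, the duration used throughout.
- **EQ reference**: expected mammalian brain mass
  `0.0585 (body g)^0.76` g, converted to kg units.

## The two-stage protocol

```r
grid <- ageGrid()
afar <- scenarioPreset("afarensis")
sap  <- scenarioPreset("sapiens")
anc  <- ancestralGenotype("somewhatNaive2", grid)
stage1 <- runEvoDevo(anc, evolutionConfig(afar, Tend = 500))
g2     <- genotype(stage1@genotypes[501, , ], grid)
stage2 <- runEvoDevo(g2, evolutionConfig(sap, Tend = 500))
```

The somewhatNaive2 ancestor is a smooth parametric effort profile chosen
so that it develops australopithecine-scale adult sizes under the
afarensis scenario (brain around 0.44 kg, body around 33 kg). Stage 1
equilibrates at australopithecine scale. Switching parameters to the
sapiens scenario produces an immediate plastic change in the developed
phenotype with the genotype held fixed, and stage 2 then expands brain,
body and skill towards human scale, with the selection angle pinned near
90 degrees: all the while there is direct selection only for follicle
count, and the expansion is driven by the socio-genetic covariance between
brain size and developmentally late follicle count.

## What the tests do and do not show

The derivative machinery (Jacobians, total and stabilized effects, total
selection gradients, parameter sensitivities) is validated against central
finite differences on reduced grids (10 age bins, 1-yr bins), against
closed forms of a scalar linear social map, and against hand-computed
fitness examples. Reduced grids keep the finite-difference oracles to
seconds; tolerances are 1e-4 to 1e-5 relative on smooth fixtures, and
fixtures are kept inside the surplus-energy branch because the tissue
floors and the growth/deficit switch create kinks where one-sided
derivatives differ (clamped regions are excluded from comparisons).

The synthetic random-genotype survey draws every growth effort i.i.d.
Normal(0, 4) and develops each genotype as its own resident. It emulates
unconstrained genotypic variation under a fixed scenario; it does not
emulate standing variation in a real population, linkage, plasticity
beyond the modeled social channel, or measurement error in fossil data, so
a passing survey says the developmental map canalizes random allocation
into a tight log-log brain-body allometry — not that real hominin data
would show the same intercept.

## Known limitations

The exact algebra here is a reconstruction: the published description
fixes the energy-bookkeeping structure, the challenge types, the
competence regimes and the headline costs, but not every functional form
or constant, and several quantitative outcomes are sensitive to those
choices. Under this package's defaults the two-stage protocol yields an
adult brain near 1 kg (rather than 1.3), an adult body in the mid-40s of
kg, a plastic change at the scenario switch that transiently shrinks
rather than enlarges the developed body, essentially no failed organisms
in the random-genotype survey (the newborn's energy margin is too thin
for misallocation to be lethal), and a trajectory allometry slope
somewhat above 1. The qualitative structure — selection only on
follicles, expansion driven by brain-follicle socio-genetic covariance,
near-orthogonality of evolution and selection, declining evolvability,
bistability in the ancestral genotype — is insensitive to these details
and is what the test suite pins down. One evolutionary time unit is one
mutation-to-fixation event; no drift, branching or two-sex demography is
modeled, and survival is age-constant by assumption.
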