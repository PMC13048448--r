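---
title: "Selection on traits shaping ontogeny: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection on traits shaping ontogeny: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontosel)
```

## The model class

`ontosel` analyses gradual evolution of *non-plastic* quantitative traits in
populations structured by a finite number of birth-assigned classes (sexes,
ploidies, habitats) and by continuous ontogeny. Each individual of class $j$
carries a vector of internal states $x_j(a)$ (size, condition, ...) whose
rates of change $g_j(z_j, x_j, v)$, together with the mortality rate
$\mu_j(z_j, x_j, v)$ and the class-oriented fecundity rates
$f_{ij}(z_j, x_j, v)$, depend on the individual's constant trait values
$z_j$, its current states, and the resident-determined environment. Because
the resident population is assumed to sit at an ecological equilibrium, all
environmental feedbacks are functions of the resident allelic values $v$
alone; a model therefore declares a `prepare(v)` hook that rebuilds its
environment (densities, competition kernels) from $v$, and the rate
functions receive that environment.

The fate of a rare mutant allele is governed by its basic reproductive
number $R_0(u, v)$, the leading eigenvalue of the next-generation matrix
with entries $\gamma_{ij} R_{ij}(u_j, v)$, where
$R_{ij} = \int_0^\infty l_j(a) f_{ij}(z_j(u_j,v_j), x_j(a), v)\,da$ is the
expected lifetime production of class-$i$ offspring and $\gamma_{ij}$
converts offspring into transmitted allele copies (1/2 throughout a diploid
two-sex system; 1 and 0 for a haploid male's daughters and sons). At a
resident demographic equilibrium $R_0(v,v) = 1$.

Directional selection on trait $(j,l)$ decomposes into age-specific
coefficients
$$\hat s_{j,l}(a, v) = \sum_i \nu_i^\circ \gamma_{ij}\,
  \frac{\partial H_{ij}}{\partial z_{j,l}}\Big|_{z=v} q_j^\circ, \qquad
  H_{ij} = l_j f_{ij} - \lambda^l_{ij}\,\mu_j\,l_j + \lambda^x_{ij}\cdot g_j,$$
with $q^\circ$, $\nu^\circ$ the right and left leading eigenvectors of the
resident next-generation matrix (newborn allele-class frequencies and
reproductive values) and the costates $\lambda^l, \lambda^x$ pricing current
survivorship and states in units of expected remaining class-oriented
reproduction. The survivorship costate starts at the resident lifetime
fecundity ($\lambda^l_{ij}(0) = R^\circ_{ij}$) and equals remaining
reproduction divided by survivorship at every age; the state costates
satisfy a terminal condition $\lambda^x(\infty) = 0$. The total coefficient
is the age integral of the kernel times the genetic exposure
$\partial z/\partial u$ (1/2 diploid, 1 haploid).

Singular strategies are the zeros of all total coefficients; their
convergence stability is read off the Jacobian of the gradient map
(strongly convergence stable when the symmetric part is negative definite;
the report also carries the Jacobian's own spectrum, which decides
attraction under isotropic mutational covariance — the two can disagree,
and do at the sex-asymmetric parameter set below). Quadratic selection at a
singular strategy is assembled from six age-resolved pathways: direct trait
curvature (`zz`), state-mediated (`xx`), trait-state (`zx`),
trait-survivorship (`zl`), survivorship-state (`lx`) and birth-frequency
(`zq`) components, the last being the only between-class pathway. The
sensitivities entering these pathways (state propagators $\Psi_j$, state
and survivorship derivatives with respect to traits, birth-frequency
derivatives from a linear solve around the next-generation matrix) are
produced by `compute_perturbations()`. A Hessian that is not negative
semidefinite at a convergence-stable point marks a *candidate* evolutionary
branching point — for several co-evolving traits, sufficiency of this
condition for branching is an open theoretical question, and the package
phrases its classification accordingly.

When class proportions at birth are constant (declared via
`class_proportions`), costates and Hamiltonians collapse from one system
per (offspring, parent) class pair to one per parent class; both modes are
implemented and agree on such models, which the test suite exercises.

## The worked example

The shipped model (`sexual_niche_model()`) follows two sexes whose single
evolving trait is a basal growth rate $v_f, v_m$ of a sexually relevant
size module: growth $g = z - \alpha x$, mortality
$\mu = \mu_e + \beta z^2$ (survival cost of growth), female fecundity
$x_f (1 - N_T/K)$, and male fecundity from competition for eggs weighted by
the size-matching kernel $e^{-\kappa (x_m - x_f)^2}$ against the standing
female size distribution, normalised over resident males so that every egg
has exactly one sire (Fisher's condition). Resident survivorship, sizes,
total density, secondary sex ratio and size densities are closed-form;
these closed forms are *not* used by the generic solvers, which makes the
model a complete independent oracle for them.

Parameters and defaults (`sexual_niche_params()`): `c = 0.5` (primary sex
ratio), `alpha = 0.2` (size loss, per time), `mu_e_f = mu_e_m = 0.1`
(extrinsic mortality, per time), `beta_f = beta_m = 0.2` (survival cost,
per squared trait unit), `kappa = 1` (size matching, per squared size
unit), `K = 1e4` (density-dependence scale, individuals). The asymmetric
set used for the branching analyses is `alpha = 0.1, mu_e_m = 0.05,
beta_f = 0.1, beta_m = 0.01, kappa = 2`: weak male survival costs and
strong size matching concentrate competition among large males while
female demography keeps many small females in the population, which is
exactly the regime in which the state-mediated male component of quadratic
selection turns positive.

Two deliberately distinct routes locate singular strategies:

* the generic route differentiates Hamiltonians by finite differences and
  runs a damped Newton iteration on the gradient (`find_singular_strategy`,
  default `method = "newton"`; `method = "grid"` prefixes a coarse scan of
  the gradient norm). Newton is the default because the natural fixed-point
  map of the example, $v_j \mapsto \tfrac{1}{2\beta_j}\int\lambda^x_j\,da /
  \int \lambda^l_j l_j\,da$, is *not* a contraction in the male component
  (its local slope is below $-1$; plain or damped iteration diverges);
* `sn_fixed_point()` solves that same implicit characterisation as a root
  problem, built entirely on the closed-form demography.

The two agree to better than $10^{-3}$ at all tested parameter sets, and
the female component additionally agrees with the exact algebraic root of
$2\beta_f v_f^2(\alpha + 2\mu_f) = \mu_f(\mu_f + \alpha)$.

Under a shared-trait genetic constraint (the same pleiotropic locus
expressed in both sexes), the gradient of the shared value is the sum of
the sex-specific gradients and the quadratic coefficient is the sum of the
corresponding Hessian blocks (the between-sex block is identically zero in
this model, which the tests verify); the constrained equilibrium falls
below *both* sex-specific optima — sexual antagonism feeding back through
size matching — and suppresses the disruptive regime.

The "average size" reported by `resident_demography()` is the mean of the
resident size density, $v_j/(\mu_j^\circ + \alpha)$; this mean-of-density
reading is a package choice, verified against symbolic integration of the
density but not against any external table.

Boundary behaviour: with `kappa = 0` male size carries no reproductive
benefit, directional selection on the male trait is negative throughout
$(0, 1]$, and the singular male value is pinned at the lower boundary 0.
`find_singular_strategy` detects such pinning (outward gradient at an
active bound) and labels the component accordingly.

## Numerical choices

* **Age truncation.** All lifetime integrals run on a uniform grid over
  $[0, a_{\max}]$ with $a_{\max}$ chosen so every class's survivorship has
  fallen below $10^{-9}$ (root-finding on the survivorship ODE). Default
  grid: 2001 points.
* **Quadrature.** Composite Simpson weights for totals; a cumulative
  local-parabola rule for running integrals. Costate tails
  $\int_a^{a_{\max}}$ are accumulated from the old-age end: computing them
  as total-minus-cumulative and multiplying by $e^{\alpha a}$ (the
  integrating factor of the state costate) amplifies roundoff
  catastrophically.
* **Size-distribution integrals.** The resident size densities have an
  integrable endpoint singularity when $\alpha > \mu_j^\circ$ (the density
  diverges at the maximum size). All partner-size integrals (male
  fecundity, its normalisation, competition curvature) are therefore
  evaluated on the *age* axis — stationary ages are exponentially
  distributed and sizes are monotone in age — with 240 Gauss–Legendre
  nodes, where the integrands are smooth.
* **Finite differences.** First derivatives of rates and Hamiltonians use
  central differences with relative step $10^{-6}$; the Jacobian of the
  gradient uses $10^{-3}$; second derivatives of Hamiltonians use
  $10^{-3}$ — with quadrature-backed rate functions a $10^{-4}$ step leaves
  visible noise in the curvature of the male fecundity, and $10^{-3}$ was
  chosen by validating the finite differences against the analytic
  curvature of the competition kernel.
* **Eigenvector scale.** $\nu^\circ$ is normalised by
  $\nu^\circ \cdot q^\circ = 1$; all gradient zeros and stability labels
  are invariant to this scale (it multiplies every kernel by one positive
  constant).
* **Haplodiploidy.** Transmission $\gamma_{fm} = 1, \gamma_{mm} = 0$, male
  exposure 1 under complete dosage compensation. Class proportions at
  birth are kept at $(1-c, c)$ for both parent columns as a bookkeeping
  convention (male-sired sons are weighted out by $\gamma_{mm} = 0$); this
  reproduces the newborn allele-class frequencies
  $q^\circ = (2(1-c), c)/(2-c)$ and leaves singular strategies identical
  to the diploid case, while male haploidy amplifies the male block of the
  Hessian through the exposure products in its assembly.
* **Degenerate males.** At $v_m = 0$ the male size distribution is a point
  mass at zero; the age-axis quadrature handles this limit without special
  casing (all male partner sizes are zero).
* **Birth-frequency perturbations** are computed only at singular
  strategies (the linear-solve form used is the at-singularity one); with
  constant class proportions they vanish identically, which is asserted in
  the tests.

## The individual-based simulator

`simulate_ibm()` emulates the worked model as a stochastic, finite
population with explicit genetics: fixed time steps of $\Delta t = 0.2$;
per-step death probability $\mu_j(z_j)\Delta t$; Euler growth; Poisson
clutches with the live head count over $K$ as the density-dependence
factor; exact categorical sire sampling proportional to the size-matching
kernel (Gumbel-max); one allele per locus per parent with haplodiploid
sons unfertilised; mutation with probability $10^{-2}$ per transmitted
allele, Gaussian kernel of sd $10^{-2}$ trait units reflected at zero.
Populations are initialised monomorphic with ages and sizes drawn from the
resident equilibrium distributions.

What it emulates — and what it does not: demographic stochasticity,
mutation limitation, Mendelian segregation and the mating-market feedback
are explicit; space, environmental fluctuation, resource dynamics,
condition-dependent tactics and mate/sperm limitation are not. Agreement
between simulator and analytics therefore validates the selection
calculus under the model's own assumptions; it says nothing about data
from systems where those excluded forces matter.

Desk-scale study conditions (used by the test suite): $K = 1000$ rather
than $10^4$, horizons of $3\times 10^4$ time units for the branching
demonstration and $2\times 10^4$ for the stabilising and shared-trait
controls, and mutation probability raised to $0.05$ per transmitted allele
(step size unchanged). The rate matters because the *onset* of branching
is a mutation-supply-limited waiting time: at the default rate its
realization-to-realization spread exceeds desk-scale horizons at
$K = 1000$ (some replicates separate within $3\times 10^4$ time units,
others show no onset by $4.5\times 10^4$), whereas raising the supply of
small-step mutations makes separation reproducible across replicates
without inflating drift the way a fatter mutation kernel does (a kernel of
sd $0.03$ was tried and rejected: it blurs the stabilising control).

Branching verdict: over the recorded allele samples of the last fifth of a
run, the median between-cluster gap of a 2-means split of male allelic
values must exceed six mutation standard deviations. Under stabilising
selection the standing allelic variation sits at the mutation-kernel scale
and the measured gap stays at three to five mutation steps; in branched
runs it reaches fifteen to twenty and keeps growing. The gap is preferred
over the overall allelic spread because it is insensitive to unequal
branch sizes (the smaller-allele branch is systematically rarer, since it
mostly occurs in heterozygotes), and over a within-cluster-sd ratio
because diverging branches keep internal spread, leaving such ratios
uninformative throughout divergence.

## Problem sizes and runtimes

Default analyses use 2001 age-grid points and 240 partner nodes; one full
gradient evaluation (resident solve, costates, kernels) takes a fraction
of a second, a Newton search for a singular strategy seconds, and a full
Hessian with its six component kernels a few seconds. The simulator runs
at roughly one second per thousand time units at $K = 1000$. The test
suite's simulation block is its dominant cost.

## Known limitations

Classes are fixed at birth (no class transitions during life); traits are
constant over life (plasticity can only be represented by enriching the
state space); resident environments are stationary; the grid/Newton search
reports the singular strategies it converges to from the supplied guesses
and makes no uniqueness or global-search claim; Hessians are only offered
at (approximately) singular residents; and for jointly evolving traits a
positive leading Hessian eigenvalue labels a *candidate* branching point
rather than a guarantee.
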