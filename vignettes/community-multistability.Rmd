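---
title: "Modeling multistability in microbial communities with horizontal gene transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling multistability in microbial communities with horizontal gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

plasmidLV asks a simple ecological question with a genetic twist: when
competing microbes trade mobile genetic elements (MGEs) such as
conjugative plasmids, how does that gene flow reshape the set of stable
community compositions? This vignette lays out the models the package
implements, the numerical and statistical choices behind the analyses,
and what the built-in synthetic experiments can and cannot tell you
about real communities.

## The model family

### Competition backbone

Every variant is built on generalized Lotka-Volterra competition with
dilution. With abundances $s_i$ scaled to carrying capacity, the
plain (plasmid-free) system is

$$\frac{ds_i}{dt} = \mu_i s_i \Big(1 - s_i - \sum_{j \ne i}
\gamma_{ji} s_j\Big) - D s_i,$$

where $\mu_i$ is the maximum per-capita growth rate (1/hr),
$\gamma_{ji} \ge 0$ the competitive effect of species $j$ on species
$i$, and $D$ a dilution or death rate common to all cells. For two
species this system has four fixed points (extinction, two
single-species states, coexistence), available in closed form through
`lv_fixed_points()`, and is bistable exactly when
$\gamma_1 > \phi_2/\phi_1$ and $\gamma_2 > \phi_1/\phi_2$ with
$\phi_i = (\mu_i - D)/\mu_i$ (`lv_bistable()`). The dilution rate is
load-bearing: at $D = 0$ the thresholds collapse to
$\gamma_i > 1$ regardless of growth rates, which is why growth-modifying
MGEs cannot move the stability landscape of an undiluted community —
one of the package's invariant tests.

### Carriers and gene flow

Each species $i$ hosts carrier subpopulations $p_{ij} \le s_i$: cells
that have acquired the MGE originating in species $j$. Species never
lose their own element entirely, so $p_{ii} \equiv s_i$. Carriage
multiplies growth: the species-$j$ element carries effect
$\lambda_{ij} > -1$, and the effective growth rate is

$$\mu_i^e = \mu_i \prod_{j \ne i}
\Big(1 + \lambda_{ij}\, \frac{p_{ij}}{s_i}\Big),
\qquad \mu_i = \mu_{i0} (1 + \lambda_{ii}),$$

splitting growth into a chromosomal (basal) part $\mu_{i0}$ and the
resident element's contribution. Transfer follows mass action: carriers
of element $j$ in any host donate to non-carriers of species $i$ at
rate $\eta_{jki}$ (a single scalar $\eta$ by default — intra- and
inter-species transfer at the same rate), and elements segregate away
at rate $\kappa$:

$$\frac{dp_{ij}}{dt} = \underbrace{\mu_i (1 + \lambda_{ij})
\prod_{k \ne i,j} \Big(1 + \lambda_{ik} \frac{p_{ik}}{s_i}\Big)
p_{ij} \, c_i}_{\text{growth}} +
\underbrace{(s_i - p_{ij}) \sum_k \eta_{jki}\, p_{kj}}_{\text{conjugation}}
- (D + \kappa_{ij})\, p_{ij},$$

with $c_i$ the shared competition term. The model's units are hours
and dimensionless abundances; an empirical conjugation efficiency
$\eta_c$ (per cell per mL per hour) maps onto the model rate as
$\eta = N_m \eta_c$ (`eta_from_empirical()`), so $\eta = 10^{-2}$/hr
corresponds to $\eta_c = 10^{-11}$ at a carrying capacity of $10^9$
cells/mL.

### Variants

All variants share this machinery and differ in a single mechanism;
`community_model()` selects them by `variant`:

* **`interaction_mod`** — carriage modifies competition: the effective
  strength of $j$ on $i$ becomes
  $\gamma_{ji} + \delta\, p_{ji}/s_j$. Positive $\delta$ means shared
  genes increase niche overlap; negative $\delta$ relaxes competition.
  Only the two-species form of this mechanism is fully printed in the
  sources the package follows; the multispecies generalization above
  is the natural one (carriage of $i$-originated elements by $j$
  increases $j$'s overlap with $i$) and reduces exactly to the printed
  two-species expressions.
* **`epistasis`** — the growth effect depends on the host genome.
  For two species the ratios $\xi_1 = \lambda_{21}/\lambda_{11}$ and
  $\xi_2 = \lambda_{12}/\lambda_{22}$ parameterize it: positive ratios
  preserve the sign of the effect across hosts (magnitude epistasis),
  negative ratios flip it (sign epistasis).
* **`selection`** — strong environmental selection (the
  antibiotic-resistance limit): only carriers grow at all, so each
  species reduces to one carrier pool $p_i$ and non-carriers decay at
  $D$. One species is the initial donor.
* **`niche`** — species are assigned to niches with their own
  capacities; only species sharing a niche compete, transfer still
  crosses niche boundaries.
* **`two_species_hgt`** — the dimensionless two-species form, with an
  optional carrying-capacity ratio $\varrho = N_{m,2}/N_{m,1}$
  (default 1, as both capacities are assumed equal throughout).

## Numerical choices

**Integration.** The right-hand sides are compiled C called through
deSolve's lsoda (adaptive, stiff-capable) with `rtol = 1e-6`,
`atol = 1e-9`; at printed fixed points the residuals are below
$10^{-12}$. Negative solver output is clamped to zero and carriers to
$[0, s_i]$ *after* integration, never inside the right-hand side,
which stays smooth. One guard lives in the RHS itself: the carrier
fraction $p_{ij}/s_i$ of a species below an abundance of $10^{-8}$ is
taken as 0 — below that floor the ratio of two vanishing quantities is
numerical noise, and letting it rattle against its bounds stalls the
integrator at high transfer rates. The same convention ($p/s = 0$ for
an extinct species) defines the model at $s_i = 0$.

**Steady states.** `find_steady_state()` integrates for 2000 hr and
then checks the equilibrium residual $\max |dy/dt| < 10^{-6}$/hr,
extending in 500-hr increments (to at most 10,000 hr) if the state is
still moving; a fixed horizon alone can mistake a slow transient for
an equilibrium. The transfer-rate scan `eta_scan()` deliberately does
*not* extend: it reproduces a fixed 2000-hr experimental window and
clusters every final state. The distinction matters at small $\eta$,
where beneficial elements seeded by even a trickle of transfer are
slowly amplified by selection; within a fixed window those sweeps are
incomplete, while integrating "to equilibrium" completes them and
changes which attractors exist on the experimental timescale.

**Attractor counting.** Ensembles start from $s_i \sim U(0,1)$ with
native carriers only ($p_{ii} = s_i$, $p_{ij} = 0$; an alternative
mode draws $p_{ij} \sim U(0, s_i)$). Steady compositions are grouped
by single-linkage transitive closure — two states share an attractor
iff a chain of pairwise Euclidean distances below the threshold
connects them, the unique partition consistent with the pairwise rule
— after flooring abundances below $10^{-6}$ to zero so near-extinct
tails do not split clusters. Thresholds default to 0.01 for
two-species analyses and 0.05 for larger communities; for the
five-species worked example the count is unchanged across thresholds
0.02-0.1. The all-extinct state, if reached, counts as an attractor
like any other. Distances at exactly the threshold do not join
(strictly-smaller rule).

**The multistability coefficient.** Basin sizes $x_i$ are estimated
as the fraction of converged initializations reaching attractor $i$
(the natural Monte-Carlo estimator), and
$\chi = \exp(-\sum_i x_i \log x_i)$ is the effective number of basins:
1 when monostable, the attractor count when basins are even, and
insensitive to the spurious tiny clusters that finite ensembles
produce — the reason to prefer it over the raw count when comparing
noisy scans.

**Reproducibility.** Every ensemble function takes one master seed
from which per-initialization substream seeds are drawn sequentially,
so enlarging an ensemble preserves its earlier members, and every seed
is recorded for replay. Identical model, seed and tolerances give
bitwise-identical results on one platform.

## The synthetic experiments

The package ships the parameterizations its analyses are demonstrated
on (`preset_community()`): a near-neutral two-species pair
($\mu$ = 0.4, 0.6/hr) that HGT flips from monostable to bistable, a
strongly asymmetric pair (0.3, 0.8/hr) that stays monostable at any
transfer rate, a five-species community ($\mu$ = 0.52, 0.48, 0.44,
0.60, 0.31/hr, $\gamma$ = 1.05) that is monostable without transfer
and develops exactly four attractors at $\eta = 0.4$/hr, and
strong-selection communities ($\gamma$ = 1.5). Shared defaults:
$\mu_0$ = 0.5/hr, $\kappa$ = 0.005/hr, $D$ = 0.2/hr.

Randomized analyses (`sampler_spec()`, `bistability_fraction()`,
`eta_scan()`) redraw growth rates — uniformly on a range, or through
element effects $\lambda \sim U(-\alpha, \alpha)$ where $\alpha$
measures distance from ecological neutrality — and optionally
heterogeneous $\gamma_{ij}$, niche structures ($l \in \{2, \dots,
m/2\}$ niches with $U(0,1]$ capacities), or selection-variant rates
$\mu_i \sim U(0.3, 0.7)$/hr. That $U(0.3, 0.7)$ range, printed only
for the selection experiments, is also adopted as the default for
multispecies growth-rate replicates; the exact distribution behind the
original eight-species scans is not recorded in the available sources.

Paired designs are used wherever a *direction* is asserted: in
`bistability_fraction(..., eta_values = ...)` the same randomized
parameter draws are evaluated at every transfer rate, so statements
like "positive $\delta$ makes the bistable fraction non-decreasing in
$\eta$" are tested against sampling noise that cancels between arms.

**Metacommunities.** A $u \times v$ grid of patches shares one patch
model; species and carriers disperse to the four nearest neighbours at
rate $\omega$, with no-flux boundaries. The dispersal rate is not
recorded in the sources either; the default $\omega = 10^{-3}$/hr was
chosen once so that dispersal is slow relative to local dynamics
(rates of order 0.1-0.5/hr) — local attractors then survive coupling,
which is the regime of interest, whereas $\omega \gtrsim 10^{-2}$
visibly synchronizes the grid. Regional diversity is the exponential
Shannon index of patch-summed abundances; local diversity the same
index per patch. The headline pattern — regional diversity rising with
$\eta$ while every patch stays dominated by one species — is checked
on a 5×5 grid of 10-species patches, which this implementation
integrates in under a second per run (the full 10×10 grid is equally
available).

## Problem sizes used in the test suite

The shipped tests trade ensemble size for runtime while keeping every
conclusion stable under the chosen seeds: 500 initializations for the
five-species attractor counts (the full published ensemble size), 200
for the two-species state diagnoses, 100 per cell on the 21×21
competition-strength grid checked against the analytic bistability
condition (boundary-adjacent cells excluded, where basins genuinely
vanish), 40-50 draws × 50 initializations for the paired
bistability-fraction directions, and 4 replicates × 150
initializations per decade for the transfer-rate scan. The
bitwise-replay tests pin these choices.

## Known limitations

* Dynamics are deterministic ODEs: no demographic noise, so basin
  boundaries are sharp and rare-event switching between attractors
  cannot occur.
* Plasmid-plasmid interactions (entry exclusion, incompatibility,
  copy-number regulation) are not modeled; multiple elements co-infect
  a host independently.
* Within a species, cells are only carrier/non-carrier per element —
  no finer genotype structure.
* The multispecies forms of the competition-modification and epistasis
  mechanisms generalize printed two-species expressions; alternative
  generalizations are conceivable.
* Attractor counts from finite ensembles are estimates: rare basins
  can be missed (undercounting) and slow transients within a fixed
  window can be split (overcounting). The residual checks, the
  threshold-robustness tests and $\chi$ are the package's mitigations,
  but near bifurcation boundaries counting is intrinsically fragile —
  the analytic-numeric comparison therefore excludes cells adjacent to
  the boundary. On the transfer-rate scan this fragility is visible as
  genuine rare attractors (basins of ~1%) already at
  $\eta \sim 10^{-4}$/hr, well below the decade where the mean
  attractor count rises appreciably.
* Passing synthetic tests shows the machinery reproduces the model's
  phenomenology under the stated parameterizations; it does not
  validate the model against any real community time series.
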