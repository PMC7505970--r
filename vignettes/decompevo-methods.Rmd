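---
title: "Methods: a multi-scale eco-evolutionary model of microbial decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-scale eco-evolutionary model of microbial decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decompevo)
```

## The system

Soil microbes decompose soil organic carbon (SOC) by secreting extracellular
enzymes (exoenzymes) that depolymerise SOC into dissolved organic carbon
(DOC), the only form cells can take up. Because DOC diffuses, exoenzyme
production is a public good: a mutant strain that allocates a smaller
fraction of its uptake to enzymes ("cheater") free-rides on the DOC produced
by its neighbours. `decompevo` simulates this system at three nested scales
and asks when exoenzyme production is evolutionarily stable, and what the
evolved allocation does to ecosystem function.

The evolving trait is the allocation fraction $\varphi \in [0,1]$: of the
carbon a cell assimilates, a fraction $\varphi\gamma_Z$ becomes enzyme,
$(1-\varphi)\gamma_M$ becomes biomass, and the remainder is respired
($\gamma_M$, $\gamma_Z$ are the biomass and enzyme production efficiencies;
energetic synthesis costs leave as CO~2~).

## The deterministic microsite model (cdmz)

A well-mixed microsite carries four carbon pools (mg): SOC $c$, DOC $d$,
cell biomass $m$, enzyme $z$. With Michaelis–Menten uptake
$u(d) = V_{\max}\, d/(K_m + d)$ per unit biomass:

$$
\begin{aligned}
\dot c &= I_C - l_C c - \theta z c + (1-l)\,p\,d_M m\\
\dot d &= I_D - l_D d + \theta z c + (1-l)\,d_Z z + (1-l)(1-p)\,d_M m - u(d)\,m\\
\dot m &= (1-\varphi)\gamma_M u(d)\, m - d_M m\\
\dot z &= \varphi\gamma_Z u(d)\, m - d_Z z
\end{aligned}
$$

SOC enters at rate $I_C$ and is decomposed by mass action ($\theta z c$);
dead cells are recycled (fraction $p$ to SOC, $1-p$ to DOC) after leaching a
fraction $l$; deactivated enzymes return to DOC. The recycling routes of the
$\dot c$ and $\dot d$ equations are reconstructed from the event rules of
the stochastic algorithm below, under the constraint — asserted in the test
suite — that the model closes its carbon budget exactly:
inputs = leaching + respiration at equilibrium.

`steady_state()` solves the positive equilibrium: the $\dot m$ balance
fixes the DOC level in closed form, $d^* = K_m x/(1-x)$ with
$x = d_M/((1-\varphi)\gamma_M V_{\max})$; the $\dot z$ and $\dot c$ balances
are then linear, leaving one scalar root-find on the DOC balance for $m^*$
(bracketed by the respiration bound $m \le (I_C+I_D)/(u^*\cdot
\text{respired fraction})$; residual tolerance $10^{-9}$ relative to each
equation's gross flux). A population is viable only on an interior window of
$\varphi$ (`viability_threshold()`): too little allocation produces too
little enzyme to generate DOC; too much starves growth below mortality
($x \ge 1$).

In this well-mixed setting the selection gradient of $\varphi$ is
$-\gamma_M V_{\max} d^*/(K_m+d^*) < 0$ (`selection_gradient()`): cheating
always pays, allocation erodes, and because viability requires
$\varphi$ above a positive threshold, the erosion ends in extinction —
evolutionary suicide. Spatial structure is what can rescue cooperation.

## The hybrid stochastic-deterministic microsite

At realistic microsite volumes a site holds on the order of ten cells, so
demographic stochasticity matters for cells while molecule pools remain
effectively continuous. The hybrid model treats $c, d, z$ as deterministic
flows and the cell population as discrete individuals (a piecewise
deterministic Markov process):

* each cell accrues stored reserve at rate
  $\dot S = (1-\varphi)\gamma_M u(d)\,\omega_M$ ($\omega_M$ = carbon mass of
  one cell) and divides deterministically when $S$ reaches $\omega_M$;
  mother and daughter each keep half the excess, $(S-\omega_M)/2$ (a
  variant that resets both reserves to zero is available but discards the
  excess carbon);
* cell death is the only stochastic event: one exponential clock with rate
  $d_M \times$ (total cells); the victim is uniform among all cells, and its
  structural mass plus reserve is recycled like any dead biomass;
* between events, pools follow the ODE flows with the cell count frozen.

Numerical choices: flows are integrated with an adaptive explicit Euler
scheme — sub-steps capped so the relative DOC change per sub-step stays
below 1%, outflows capped so no pool can cross zero (clipping events are
counted and reported); the integrator accumulates inputs, leaching and
respiration with the same discrete fluxes it applies, so the carbon ledger
closes to floating-point accuracy rather than to scheme order. A plain-R
implementation of every step operation mirrors the compiled core and the
test suite checks the two routes agree to $10^{-10}$ on event-free runs.

### The cell count of the hybrid model

A consequence of threshold division with uniform random death is worth
stating explicitly because it calibrates expectations against the
deterministic model. Stationarity of the division–death renewal process
requires $2e^{-d_M\tau_{\text{div}}} = 1$, i.e. each cell must divide every
$\tau_{\text{div}} = \ln 2/d_M$; the population therefore equilibrates
where $(1-\varphi)\gamma_M u(d) = d_M/\ln 2$, slightly above the
deterministic DOC level, and the stationary cell count is
$\ln 2 \approx 0.69$ times the naive biomass-equivalent count
$m^*/\omega_M$, while the *total* cell carbon (structural plus reserves,
mean reserve $\approx (1/\ln 2 - 1)\,\omega_M$ per cell) converges exactly
to the deterministic biomass $m^*$, as do the SOC and enzyme pools. The
large-system-size test asserts convergence on those limits, plus the
$\ln 2$ count ratio itself.

## The lattice

Microsites are coupled on an $L \times L$ grid (default $10 \times 10$)
with reflecting (Neumann) boundaries:

* **DOC diffusion** — one explicit Euler step of
  $\partial_t d = \sigma_{\text{diff}}\Delta d$ per event-loop iteration,
  stencil factor $f = \sigma_{\text{diff}}\tau/(Vk)^{2/3}$ (the denominator
  is the squared inter-site distance). Missing neighbours contribute
  nothing, so total DOC is conserved exactly. Stability needs $4f < 1$;
  the standalone operation errors beyond the limit, and the simulators cap
  the internal step at half the stability limit, so the user-level
  `tau_diff` (default 1 h) is only an upper bound on the cadence. The
  update is applied over the *elapsed* interval when a death pre-empts the
  full step, which keeps the scheme consistent however short the interval;
  applying the full step regardless is available behind a flag
  (`fixed_tau`), as both cadences are defensible discretisations.
* **Dispersal** — a newborn stays home with probability $1-p_{\text{disp}}$;
  otherwise it moves to a uniformly chosen *empty* neighbour site if one
  exists; if all are occupied, with probability $p_{\text{open}}$ a
  micro-disturbance kills a uniformly chosen neighbour's whole population
  (recycled locally) and the newborn colonises the opened site; otherwise
  dispersal fails. Multiple newborns in one interval are placed one after
  another in uniformly random order.
* **Death** — a single lattice-wide exponential clock, victim uniform over
  all cells (equivalent in law to per-site clocks).

Dead-cell recycling uses one convention throughout, matching the definition
of the parameter $p$ ("fraction of recycled dead carbon flowing into SOC"):
a fraction $p$ goes to SOC, the rest to DOC, for single deaths and
micro-disturbances alike. Routing $p$ to DOC instead for single deaths is
available behind a flag (`route_p_to_doc`); at the default $p = 0.5$ the
two conventions are numerically identical. Likewise the stored reserve of a
dying or disturbed cell is recycled along with its structural mass —
discarding reserve carbon would leak the budget the tests enforce.

## Parameters and system-size scaling

Parameters follow the standard biomass-model defaults (masses in mg, times
in hours): $\gamma_M = 0.3$, $\gamma_Z = 0.4$, $\omega_M = 10^{-9}$ mg,
$d_M = 2\times10^{-4}$ h^-1^, $d_Z = 2\times10^{-3}$ h^-1^,
$V_{\max} = 0.42$ h^-1^, and unit-volume values $\theta = 7\times10^5$
mg^-1^h^-1^, $K_m = 3\times10^{-10}$ mg, $I_C = 5\times10^{-13}$ mg h^-1^,
$I_D = 0$. The system size $k$ is the number of unit soil volumes $V$
(each expected to hold one cell) per microsite; the volume-dependent
parameters scale as $I_C, I_D, K_m \propto k$ and $\theta \propto 1/k$.

The package interprets the tabulated volume-dependent values as unit-volume
($k=1$) quantities and `soil_params(k = 10)` applies the scaling to build
the default microsite. This was a genuinely open reading — the alternative
treats them as already-scaled microsite values — and was fixed by two
consistency requirements: the scaling example $I_C: 5\times10^{-13}
\rightarrow 5\times10^{-12}$ mg h^-1^ at $k=10$, and the equilibrium
population size, which lands at 5.6 cells per microsite under this reading
(order 10, as expected for a microsite calibrated to hold ~10 interacting
cells) but at 0.56 cells under the other. `rescale_params()` re-applies the
relations for any other $k$; per-unit-volume equilibrium densities are
$k$-invariant, which the tests assert by solving steady states at $k$ and
$2k$.

## Evolution: mutation, contests, ESS

At division the daughter inherits $\varphi$ except with probability
$p_{\text{mut}}$, when it is drawn from a normal centred on the maternal
value with sd $\sigma_{\text{mut}}$ (default 0.05, the middle of the
plausible small-effect range). Draws outside $[0,1]$ are rejected and
redrawn rather than clipped — clipping would pile probability mass onto the
boundary values and break the small-mutation assumption. Each mutation
founds a new strain in a registry (id, parent, founding trait and time).

Long-term evolution at lattice scale is predicted by adaptive dynamics
rather than brute-force mutation-limited simulation: `run_contest()` starts
every site at the resident's deterministic equilibrium (cell reserves
uniform on $[0,\omega_M)$), replaces 5% of the residents (rounded up, at
least one cell) in five plus-shaped central sites by mutants, and runs
replicated lattice simulations without mutation. The invasion-fitness proxy
is

$$\text{survival fraction} \times \overline{\tfrac{1}{T_{\max}}\log
\tfrac{\text{final mutant count}}{\text{initial mutant count}}}
\times T_{\max},$$

where the growth average runs over surviving replicates only (the log of an
extinct population is undefined; extinction enters through the survival
factor). `ess_scan()` runs cheater ($\varphi-\delta$) and cooperator
($\varphi+\delta$) contests along a trait grid and brackets the ESS between
the largest grid value where the cooperator has positive fitness and the
smallest where the cheater does; purely directional patterns return the
bracket pinned to the grid end, and a noisy non-directional pattern is
flagged rather than resolved. Replicates are seeded from a master seed via
a pre-drawn seed table, so contests are reproducible and independently
re-runnable.

`ecosystem_function()` closes the loop: a monomorphic run at a fixed
(evolved) allocation reports the lattice decomposition rate — the
time-average of $\theta \times$ total enzyme mass — and the mean SOC stock
per microsite over a post-burn-in window.

## What the generator emulates, and what it does not

Initial states are generated from the deterministic equilibrium
(`make_fixture()`), which is how the package's experiments are initialised;
the spatially homogeneous lattice, constant abiotic inputs, and a single
evolving trait are deliberate idealisations. Passing tests therefore say
nothing about heterogeneous soils, fluctuating inputs, multi-trait
physiology, or molecule-level stochasticity of enzyme–substrate complexes
(the complex pool is already reduced out of the model the package
implements). Cell uptake is deterministic given the DOC trajectory; only
death (and dispersal/disturbance/mutation) is stochastic.

## Study sizes used by the test suite

The full-scale study design runs at $T_{\max} = 10^6$–$10^8$ h with 20
replicates per contest. The packaged suite keeps the full $10\times10$
lattice but scales horizons and replication down to desk scale, as stated
in each test: invasion scans use $T_{\max} = 10^5$ h and 8 replicates per
contest across $\sigma_{\text{diff}} \in \{10^{-5}, 10^{-6}, 10^{-7}\}$
(asserting the qualitative ordering of the ESS, not its printed value);
ecosystem feedback uses $T_{\max} = 10^5$ h with a $2.5\times10^4$ h
burn-in; single-site and convergence checks use $2\times10^4$–$4\times10^5$
h. At these sizes the ESS estimates carry visible Monte-Carlo error;
full-scale runs through the command-line interface reproduce the reference
design.

## Known limitations

* The continuous recycling routes of the cdmz model are chosen to mirror
  the event rules of the hybrid algorithm and to close the carbon budget;
  alternative routings that also close the budget would shift the
  equilibrium cell count, which is why a factor-two band is used wherever
  that count is asserted.
* The ESS bracket inherits the sign noise of small contests; at desk scale
  a stray surviving replicate can flip a grid point's sign. The
  `direction = "non-directional"` flag marks scans whose pattern is not
  cleanly directional.
* No stability analysis of the deterministic equilibrium is provided, and
  no reduced two- or three-pool models: the four-pool structure is the
  smallest consistent with the individual-level processes.
* Diffusion of SOC and enzymes is not modelled (only DOC moves),
  consistent with the mobility gap between small dissolved products and
  polymeric substrates or bound enzymes.
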