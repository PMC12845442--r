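---
title: "Modelling local drug delivery in the oral cavity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling local drug delivery in the oral cavity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralpbpk)
```

## The problem

Drugs placed in the mouth — mouthrinses, periodontal chips, microspheres,
in situ gels — face an environment unlike any systemic compartment.
Saliva turns over in minutes and swallows most of a dose; the salivary
pellicle binds cationic antiseptics and releases them slowly; the dental
biofilm is a diffusion barrier hundreds of micrometres thick; and the
periodontal pocket, the therapeutic target for subgingival products, is a
microlitre-scale chamber continuously flushed by gingival crevicular
fluid (GCF). `oralpbpk` implements a reduced ("mini") physiologically
based pharmacokinetic model of exactly this system, coupled to a library
of dissolution kinetics models on the input side and antimicrobial PK/PD
indices on the output side.

## Model structure

Five regions are modelled. Four are well mixed; the biofilm is spatially
resolved in one dimension.

**Saliva (S).** A single well-mixed pool of volume $V_S$ with flow $Q_S$
(swallowed outflow), optional zero-order input $R_{in}$, and interfacial
losses:

$$\frac{dC_S}{dt} = \frac{1}{V_S}\left(R_{in} - Q_S C_S
  - J_{SM}A_{SM} - J_{SB}A_{SB} - J_{SP}A_{SP}\right)
  - \frac{A_{SM}}{V_S}\frac{d\Gamma}{dt}$$

The final term debits pellicle adsorption from the saliva pool. Without
it, drug bound to the pellicle would be created from nothing; with it the
whole system is exactly mass conserving, which the test suite checks to a
relative tolerance of $10^{-6}$.

**Pellicle (M).** Reversible Langmuir binding with capacity
$\Gamma_{max}$:

$$\frac{d\Gamma}{dt} = k_{ads} C_S (\Gamma_{max} - \Gamma)
  - k_{des}\Gamma$$

The desorption term is first order in $\Gamma$, the standard Langmuir
kinetic form consistent with $k_{des}$ carrying units of min$^{-1}$.
This reservoir is why surface-avid antiseptics such as chlorhexidine
remain active long after salivary levels collapse.

**Mucosal tissue (T).** Permeability-limited uptake referenced to the
tissue:saliva partition coefficient, with first-order local clearance:

$$J_{SM} = P_{SM}\left(C_S - \frac{C_T}{K_{p,T}}\right), \qquad
\frac{dC_T}{dt} = \frac{P_{SM}A_{SM}}{V_T}
  \left(C_S - \frac{C_T}{K_{p,T}}\right) - \frac{CL_{local}}{V_T}C_T$$

**Biofilm (B).** A one-dimensional reaction–diffusion slab on
$[0, L_B]$:

$$\frac{\partial C_B}{\partial t} =
  D_{eff}\frac{\partial^2 C_B}{\partial x^2} - k_{bind}C_B$$

with a Dirichlet condition $C_B(0,t) = C_S(t)$ at the saliva face. The
$k_{bind}$ term is an irreversible first-order sink (matrix binding),
accumulated in its own ledger so the mass balance still closes.

**Pocket (P).** A microlitre chamber receiving flux across the
biofilm–pocket face, direct formulation release, and GCF wash-out:

$$\frac{dC_P}{dt} = \frac{J_{BP}A_{BP} + R_{release}(t)
  - Q_{GCF}C_P}{V_P}$$

With sources off this gives the pocket's natural half-life
$t_{1/2} = V_P\ln 2/Q_{GCF}$ — about 2.3 min at $V_P = 1$ µL and
inflamed-range $Q_{GCF} = 0.3$ µL/min, which is the whole clinical
argument for sustained-release carriers.

### The far boundary of the biofilm

A literal reading of the boundary conditions is contradictory: a zero
gradient at $x = L_B$ together with a biofilm-to-pocket flux defined
from that same gradient forces $J_{BP} = 0$. Both readings are shipped
as explicit modes:

* **sealed** — zero flux at $x = L_B$; the biofilm exchanges only with
  saliva. Default when no pocket formulation is present.
* **coupled** — a mass-transfer (Robin-type) flux
  $J_{BP} = k_m\,(C_B(L_B) - C_P)$. Default for pocket-delivery
  scenarios, since the biofilm pathway must be able to carry mass for
  those.

The coefficient $k_m$ defaults to $D_{eff}/(L_B/200)$: the
discrete-gradient surrogate evaluated at the package's reference spatial
resolution of 200 cells. It is deliberately *not* tied to the runtime
grid spacing — if it were, refining the grid would change the physics
rather than converge on it. Users can pass any physical $k_m$
explicitly. Neither mode is asserted to be the "intended" one; they
bracket the plausible physics.

Similarly, the saliva-side fluxes into biofilm and pocket have no
published constitutive forms. $J_{SB}$ is taken as the discrete
diffusive flux into the biofilm's first cell (which keeps saliva–biofilm
exchange mass-consistent by construction), and the direct saliva–pocket
leak defaults to zero ($P_{SP} = 0$; the pocket is semi-isolated), with
an optional permeability-type term available.

## Units

Published oral-physiology values mix mL/min, µL/min, cm²/s and cm/min.
Internally everything is converted once to a canonical system (cm, min,
µg, mL): $D_{eff}$ and $k_{bind}$ are per-second quantities and are
multiplied by 60, $V_P$ and $Q_{GCF}$ are divided by 1000. Parameter
objects carry a units tag so double conversion is impossible — the
µL/mL mix in the pocket equation is otherwise the single most likely
implementation bug in this model class. Although `to_canonical()`'s
conversion list nominally targets only $D_{eff}$, $V_P$ and $Q_{GCF}$,
$k_{bind}$ is declared in s$^{-1}$ and must follow the same time-unit
change; leaving it per-second would silently inflate biofilm binding
sixty-fold.

## Release model library

Seven cumulative-release families $F(t) = M_t/M_\infty$ are provided:
Higuchi ($k_H\sqrt t$), Korsmeyer–Peppas ($k t^n$), Peppas–Sahlin
($k_1 t^m + k_2 t^{2m}$), Hixson–Crowell (cube-root erosion law),
Baker–Lonsdale (spherical-matrix implicit relation
$\tfrac32[1-(1-F)^{2/3}]-F = k_{BL}t$, solved by bracketed root finding
— the bracket $[0,1]$ always contains exactly one root because the left
side increases monotonically from 0 to $\tfrac12$), Weibull
($1 - e^{-a t^b}$, no lag-time parameter), and a biphasic
burst-plus-zero-order convenience form for chip-type profiles (a burst
fraction released first order, the remainder at a constant rate until
`t_end`). The biphasic family is an engineering convenience, not a
classical dissolution law, and is documented as such.

Three numerical choices matter when these feed the simulator:

* **Clamping.** Higuchi, Korsmeyer–Peppas and Peppas–Sahlin are
  early-time approximations that exceed 1 at late times; $F$ is clamped
  to $[0,1]$ and the release rate is zero once the unclamped fraction
  reaches 1, so a formulation is a globally defined, mass-conserving
  source.
* **Rate floor.** Families with $dF/dt \to \infty$ as $t \to 0^+$
  (Higuchi; KP with $n<1$; Peppas–Sahlin with $m<1$; Weibull with
  $b<1$; Baker–Lonsdale) are evaluated at $\max(t, 10^{-6}\,\text{min})$.
  This keeps the stiff integrator bounded while altering released mass
  by less than $10^{-4}$ of the dose. The mass-balance audit compares
  stores plus outflows against the *integrated* release ledger, so the
  floor cannot produce a spurious conservation violation.
* **Hixson–Crowell in fractions.** The cube-root law is printed in mass
  units ($W_0$, $W_t$); it is expressed here as
  $F = 1 - \max(W_0^{1/3} - k_{HC}t,\,0)^3/W_0$, i.e. the whole initial
  mass is assumed releasable. This is an interpretation, flagged in the
  function documentation. When *fitting* fraction data, $W_0$ only
  rescales $k_{HC}$ and is therefore fixed at 1.

## Fitting and model selection

`fit_release()` is Levenberg–Marquardt nonlinear least squares on the
cumulative fraction, with positivity bounds and shape-exponent caps
($n, m \le 1.5$; Weibull $b \le 5$). Start values come from the
linearizations each family admits (log–log regression for KP,
double-log for Weibull, and so on). A fit is refused unless the number
of observations exceeds the number of estimated coefficients.

AIC and BIC use the Gaussian profile log-likelihood,
$n\ln(\mathrm{RSS}/n) + 2p$ and $n\ln(\mathrm{RSS}/n) + p\ln n$. A
Gaussian additive error model is an explicit choice — no error model
accompanies the published discussion — and is documented so users can
interpret $\Delta$AIC accordingly. `select_model()` ranks families by
AIC with ties broken by parsimony and then by name; per-family failures
are reported as skipped entries rather than aborting the comparison.
For the biphasic family the phase end `t_end` is pinned to the data
span rather than estimated, since it is not identifiable inside the
observation window.

## Numerics of the transport solver

* **Discretization.** The biofilm PDE uses a cell-centred finite-volume
  scheme (uniform grid, second-order interior stencil, half-cell
  coupling to the Dirichlet saliva face). The conservative form makes
  the semi-discrete system conserve mass exactly; the only conservation
  error left is the time integrator's, which is why the $10^{-6}$ audit
  passes with orders of magnitude to spare at default tolerances.
* **Integration.** Adaptive stiff-capable integration (`deSolve`'s
  lsoda) with defaults rtol $10^{-8}$, atol $10^{-10}$ µg/mL and
  $N_x = 200$ cells; the stiffness ratio $D_{eff}/\Delta x^2$ at that
  resolution demands an implicit method.
* **Events.** Saliva boluses are instantaneous increments of
  `amount`/$V_S$ with the integrator restarted at the event time, and
  infusion/formulation start and stop times also break the integration,
  so the solver never steps across a source discontinuity. Reported
  state at an event time is the post-event state.
* **Ledgers.** Cumulative outflows (swallowed, GCF, tissue clearance,
  biofilm-bound) and inputs (released, infused) are integrated as
  auxiliary states, so the audit is a pure post-processing check.
* **Non-negativity.** Trajectories are clamped at zero; an excursion
  beyond $-10\cdot$atol aborts with the failure time and a state
  snapshot, since that signals a genuine solver problem rather than
  roundoff.
* **Degenerate inputs.** Flows, rates and interface areas may be zero —
  that is how individual pathways (and whole compartments: $A_{SB}=0$
  disables the biofilm) are switched off. Volumes, lengths, the binding
  capacity, diffusivity and partition coefficient must be positive.
  `validate_physiology()` is stricter: it errors on non-positive flows,
  because a zero-flow physiology is a numerical device, not a clinical
  scenario; out-of-range values only warn, because the published ranges
  are illustrative.

## Scenario presets and the synthetic-data generator

Five presets (`periochip_like`, `arestin_like` with healthy/inflamed
variants, `atridox_like`, `healthy_pocket`, `inflamed_pocket`) are
shipped as YAML configuration files and parsed through the same
`parse_config()` path users' own configs take. All range-checked
physiology values sit inside published typical ranges; interface areas
($A_{SM} = 4$, $A_{SB} = 2$, $A_{BP} = 0.1$, $A_{SP} = 0.05$ cm²), the
biofilm binding rate ($5\times10^{-5}$ s$^{-1}$) and the preset MICs
(1 µg/mL) have no published values and are documented assumptions —
the MIC in particular is a placeholder, and biofilm-adjusted MICs
should be supplied by the user where known. Release coefficients were
chosen once so that each preset's release window matches its product
class's reported duration (burst + 8.5 days for the chip; ~8 days for
the microspheres; ~7 days, 90% released, for the gel) and are not
tuned further.

`synth_release_data()` emulates an in vitro dissolution experiment:
log-spaced sampling over the release window (1%–95% released),
multiplicative Gaussian noise with a user CV (capped at 30%), and
clamping to $[0, 1.05]$ to mimic small experimental overshoot. It uses
R's default Mersenne-Twister stream under an explicit required seed and
restores the caller's RNG state. What it does *not* emulate —
apparatus effects, autocorrelated drift, pH/ionic-strength sensitivity,
inter-batch variability — bounds what passing recovery tests show: they
demonstrate estimator correctness under idealized noise, not robustness
to real dissolution-lab artefacts.

## Problem sizes used in the tests

The suite exercises the full model at reduced sizes chosen to keep each
check sharp: biofilm grids of 10–200 cells ($N_x = 200$ for the
analytic-oracle comparisons, where the erfc solution is matched to
within 1%; 400 only for the refinement check), simulation horizons from
1 min (dilution) to 9 days (chip scenario), and 100 seeded replicates
for the exponent-recovery study. The dose-doubling linearity check runs
at rtol $10^{-11}$ so that the $10^{-8}$ superposition tolerance
measures model linearity rather than integrator noise.

## Known limitations

* The biofilm is a homogeneous 1-D slab; real biofilms have channels,
  density gradients and 2-D/3-D structure. No spatial variation in
  salivary shear or pellicle load is represented.
* The pellicle is a single lumped surface density over $A_{SM}$ and
  exchanges only with saliva; drug does not pass pellicle-to-tissue
  directly (the tissue flux is written saliva↔tissue).
* Saturable (Michaelis–Menten) elimination is available in the
  classical one-compartment module but not inside the oral transport
  loop, which is fully linear apart from Langmuir binding.
* Single deterministic parameter sets only: population variability is
  out of scope, with presets standing in for patient classes.
* PK/PD links (Hill kill, indirect response, effect compartment) use
  the standard pharmacometric forms; their parameters are not fitted to
  clinical endpoints here, and simulated exposure–effect relationships
  inherit all the usual caution that extrapolation from concentration
  to outcome deserves.
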