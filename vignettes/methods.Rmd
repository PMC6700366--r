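---
title: "Models and numerical methods in biofilmsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in biofilmsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`biofilmsim` is an individual-based model (IbM) of microbial biofilms: every
cell is a discrete spherical agent with its own mass, position and metabolic
state, embedded in a three-dimensional diffusion-reaction field that is in
turn coupled to a stirred-tank reactor and a gas headspace. This vignette
explains the science implemented in each module, the parameters that matter,
and the numerical choices behind the implementation.

## Thermodynamic growth yields

Each functional group carries one catabolic reaction (written per mol of
electron donor) and one anabolic reaction (per C-mol of biomass, formula
CH~1.8~O~0.5~N~0.2~, formation energy -67 kJ/C-mol). The maximum growth
yield follows from a Gibbs energy balance: building one C-mol of biomass
costs the anabolic energy $\Delta G_{ana}$ plus a dissipation term
$\Delta G_{dis}$, and this cost is paid by running the catabolic reaction,
which harvests $|\Delta G_{cat}|$ per donor:

$$Y_{XS} = \frac{|\Delta G_{cat}|}{\Delta G_{ana} + \Delta G_{dis}}
\quad \left[\frac{\text{C-mol X}}{\text{mol donor}}\right].$$

Dissipation energies are group parameters (they can be obtained from
correlations of the Tijhuis/Heijnen type or supplied directly): 3,500
kJ/C-mol for the two nitrifier guilds, 236 (glucose fermenter), 700
(hydrogenotrophic methanogen) and 500 (acetoclastic methanogen) kJ/C-mol.

Reaction energies are evaluated as
$\Delta G = \Delta G^0 + RT \ln Q$ with the biochemical-standard convention:
solutes at 1 mol/L, water activity 1, and the proton at $10^{-7}$ mol/L.
Several of the packaged catabolic reactions release protons and would be
endergonic at the 1 M proton standard state, so the pH-7 reference is the
meaningful one. Inside a running simulation ("coupled thermodynamics") the
same expression is re-evaluated per agent per refresh with the local
concentrations of every participating form; activities are floored at
$10^{-12}$ mol/L so depleted cells do not produce singular logarithms.

**Calibration of the constant table.** The shipped table
(`inst/extdata/thermo_constants.csv`) starts from standard aqueous formation
energies (Thauer-type compilation). Standard values alone do not reproduce
the published yield set for these five guilds (they give, e.g., 0.081
instead of 0.155 for the ammonia oxidizers under every evaluation convention
we examined), and the primary-source derivation is not available in the main
text of the literature the parameters come from. The table is therefore
calibrated: a uniform shift is applied to the nitrite chain (-252.3 kJ/mol),
the nitrate chain (-430.5), glucose (+50.7), dissolved H~2~ (+13.9) and
dissolved CH~4~ (-19.1), solving a 5x5 linear system so that all five
published yields are reproduced exactly. Shifting a whole protonation chain
uniformly leaves every pK~a~ untouched, so speciation and pH are unaffected;
element and charge balances are unaffected by construction. The CSV retains
the uncalibrated standard value and a source tag per row, and the calibrated
entries should be read as *effective* formation energies that make the
packaged energetics consistent with the published parameter set. The
nitrogen-chain shifts are large, which we flag openly: they absorb whatever
convention the original yield derivation used.

**Maintenance.** The maintenance rate is
$m_{bac} = Y_{XS}\, \Delta G_{dis,m} / |\Delta G_{cat}|$ (1/h), where
$\Delta G_{dis,m}$ is a maintenance energy *rate* in kJ (C-mol X)^-1^ h^-1^.
A bare ratio of dissipation to catabolic energy is dimensionless and cannot
be a rate; multiplying a specific maintenance energy demand by the yield
converts it to the growth scale and makes the growth equation dimensionally
consistent. Defaults are 4.5 kJ C-mol^-1^ h^-1^ for the aerobic guilds
(Tijhuis-type) and 0.5 for the anaerobic guilds (anaerobic maintenance
demands are roughly an order of magnitude lower; with 4.5 the acetoclastic
methanogen could never grow because its catabolic harvest is only ~34
kJ/mol). A direct override `m_bac_direct` is available per group.

## Growth kinetics and the agent life cycle

The specific growth rate combines the thermodynamic yield with Monod
kinetics over the *uptake forms* of the limiting substrates:
$\mu = q_{max} Y_{XS} \prod_i \frac{C_{S_i}}{K_{S_i}+C_{S_i}} - m_{bac}$.
Cells take up one protonation form only: free ammonia for the ammonia
oxidizers, nitrous acid for the nitrite oxidizers, undissociated acetic acid
for the acetoclastic methanogens. This matters enormously in practice - at
pH 7.5 only $5.6\times10^{-5}$ of total nitrite is HNO~2~, so a
half-saturation constant of $3.94\times10^{-9}$ mol/L on HNO~2~ makes
micromolar total-nitrite environments strongly limiting, which is what
drives the fixed-boundary scenario outcome described below.

Each biological step classifies every active agent by comparing the
uptake-linked energy flux $q_{max} Y_{XS} \Pi$ with the maintenance demand,
using a relaxation band ($\alpha = 1.2$, $\beta = 0.8$): above
$\alpha\,m_{bac}$ the agent grows ($dX/dt = \mu X$), below $\beta\,m_{bac}$
it decays first-order at $k_{decay}$, in between its mass is constant. (The
growth and decay inequalities are implemented in the physically coherent
orientation: growth when energy harvest exceeds maintenance.) Mass updates
are exact exponentials over the step. Decayed biomass is returned to the
dissolved pools as the carbon and nitrogen sources of the group's anabolic
reaction (1 C-mol and 0.2 mol N per C-mol biomass), so carbon and nitrogen
are closed exactly; hydrogen/oxygen closure is not attempted because decay
is not a redox-balanced process without an explicit electron acceptor.

Agents divide instantaneously at a threshold diameter (default 1.36 um,
dry density 290 fg/um^3^, giving ~1 um average cells). The parent's mass is
split at a fraction drawn uniformly from 0.4-0.6; one daughter keeps the
parent position and the other is placed in a uniformly random direction at
a centre distance equal to the sum of the daughter radii, with the
subsequent mechanical relaxation resolving the overlap pressure. An active
agent whose mass falls to 10% of its division mass (boundary inclusive)
becomes inert irreversibly: it stops reacting but keeps its mechanical
presence. All stochastic draws (division fractions, directions, seeding
jitter) flow from R's global RNG, seeded once per run from the scenario
seed, which makes trajectories bit-reproducible.

## Chemical speciation and pH

Each chemical species is a total concentration partitioned over an ordered
chain of at most four protonation forms (three deprotonations). Equilibrium
constants come from the formation energies,
$K = \exp(-\Delta G_{rxn}/RT)$; the CO~2~ hydration step
(CO~2~ + H~2~O -> HCO~3~^-^ + H^+^) is lumped into the first apparent
dissociation constant, which is observationally equivalent under the
equilibrium assumption. The partition of a total $C_T$ over its forms is
closed-form in the proton concentration (cumulative products of $K_j/H$),
so form concentrations always sum to the total exactly.

The pH solves the charge balance
$\sum_j z_j c_j + [H^+] - K_w/[H^+] + [Na^+] - [Cl^-] = 0$, a strictly
decreasing function of pH, by a damped Newton iteration in
$\log_{10}[H^+]$ with an analytic derivative, steps clamped to one pH unit,
a maintained bracket, and bisection fallback - vectorized over grid cells.
Default residual tolerance is $10^{-12}$ mol/L. Activity corrections, ion
pairing and precipitation are out of scope (ideal dilute solution);
$K_w = 10^{-14}$. No reaction enthalpies ship with the table, so constants
are temperature-independent unless the user attaches them.

Proton production by metabolism is implicit: reactions are charge-balanced,
totals are updated per species, and re-solving the charge balance yields
the new pH - the standard treatment in speciation-aware bioprocess models.
The strong-ion (Na^+^/Cl^-^) pool initialises the system electroneutral at
the configured starting pH; in buffered mode, whenever the bulk pH falls
below the trigger (default 6.5) the closed-form strong-ion addition that
restores the setpoint is applied (the residual is linear in the inert ions,
so no nested root-finding is needed).

## Transport

Solute fields live on a regular cell-centred grid (full scale 50 x 10 x 150
cells of 2 um). Totals diffuse (all forms of a species share the reference
diffusivity); speciation is local and instantaneous. Effective diffusivity
is 0.8 D~water~ inside the biofilm and D~water~ in a 40 um boundary layer
that rides on top of the biofilm front (the highest agent top, rounded up
to a grid plane); cells above the boundary layer are bulk and are pinned to
the current bulk concentration (Dirichlet). The bottom face is zero-flux,
lateral faces are periodic. A biomass-density-dependent diffusivity
correction is deliberately not applied (the uniform 0.8 factor is the
conservative literature estimate).

The solver is a fully explicit 7-point-stencil march run to steady state
within each biological step (quasi-steady decoupling of the ~seconds
transport scale from the ~hour biology scale). Face diffusivities are
harmonic means, so the scheme is flux-conservative across the
biofilm/boundary-layer interface. Each species marches at 0.9 of its
stability bound $h^2/6D$; convergence is declared when the largest relative
field change per step falls below $10^{-6}$. Reaction rates, per-cell pH
and (in coupled mode) per-cell yields are refreshed between chunks of 600
inner steps rather than at every step - refreshing every step is
prohibitively expensive and changes nothing measurable at steady state,
since the refreshed quantities are themselves functions of the slowly
converging fields. Concentrations driven negative by stiff sinks are
clipped to zero and the clipped mass is accumulated in a per-species
deficit ledger for diagnostics.

## Reactor and gas coupling

The bulk compartment represents a CSTR containing `A_F` square metres of
biofilm. Its balance is
$dC/dt = (Q/V)(C_{in} - C) + \frac{A_F}{L_x L_y V}\iiint r\,dV$,
integrated by backward Euler with the dilution term implicit; the volume
integral of the converged reaction-rate fields is scaled by the ratio of
reactor biofilm area to domain footprint. In dynamic-boundary mode the
updated bulk values become the Dirichlet values for the next biological
step; in fixed-boundary mode the reactor balance is skipped entirely and
the boundary stays at its initial values. Aerated species (O~2~ and CO~2~
in the nitrification scenarios, CO~2~ in the anaerobic ones) are pinned to
their initial boundary values in all modes.

Gas-liquid exchange follows two-film theory, $r_{L-G} = k_La(C_L - H p)$,
evaluated per liquid cell, added to the rate fields, and averaged over the
domain to drive the headspace balance
$dp/dt = \bar r_{L-G}\frac{V}{V_{gas}}RT - \frac{Q_{gas}}{V_{gas}}p$
(ideal gas; headspace volume defaults to the liquid volume, initial
composition inert at zero product partial pressures). With the transfer
term treated explicitly on both sides, a closed system conserves total
moles to machine precision.

Reactor parameters are not fully specified by the scenario tables we
implement; the defaults (V = 0.1 L, Q = 0.02 L/h, A~F~ = 0.05 m^2^ at full
scale, scaled with the domain footprint at reduced scale) correspond to a
5 h hydraulic residence time and a realistic carrier-type area-to-volume
ratio, and are exposed in the configuration.

## Mechanics

After growth and division the community is out of mechanical equilibrium.
Agents interact as soft spheres: a Kelvin-Voigt normal contact
(spring + dashpot), a tangential dashpot capped by the Coulomb criterion
$\|F_t\| \le \mu_f \|F_n\|$, an attractive adhesion spring whose strength
scales with the product of the two agent masses and ramps to zero at a
0.2 um gap, and one-way Stokes drag against a user-supplied flow field
(zero by default). A tangential *spring* would require per-pair contact
history; in a quasi-static relaxation whose endpoint is a static packing,
the dashpot-with-Coulomb-cap form gives the same terminal configurations,
so `k_t` is accepted but unused by default.

The equation of motion $m\,dv/dt = F_c + F_a + F_f$ is integrated
semi-implicitly (drag implicit), which is unconditionally stable in the
strongly overdamped regime that 1 um cells in water occupy: drag dominates
inertia by four orders of magnitude, so velocities are effectively
terminal. The default stiffness ($k_n = 5\times10^{-6}$ N/m) is a
*relaxation* spring chosen so overlaps decay with a time constant of a few
milliseconds of pseudo-time, i.e. tens of steps at $\Delta t_{mech} =
10^{-3}$ s - the endpoint packing, not the transient, is the meaningful
output. Relaxation terminates when the largest overlap is below 1% of the
mean diameter and motion has died down. The substratum is a rigid plane,
lateral faces are periodic, and neighbour search uses uniform cell binning
(identical results to the all-pairs loop, which the tests verify).
Coincident centres (possible only by pathological input) get a
deterministic fallback direction, keeping runs bit-reproducible. Agents
whose centre rises above the height cap (250 um at full scale) are shaved
off: removed from the domain entirely, with the removed mass recorded in
an audit ledger rather than returned to the bulk.

## The simulation loop

Per biological step, in order: (1) speciation/pH refresh; (2)
diffusion-reaction to steady state, refreshing pH, thermodynamics and
agent rates between chunks; (3) agent mass balances; (4) reactor and
headspace balances and the Dirichlet update (dynamic mode); (5) the pH
buffering check (buffered mode); (6) division and inert checks; (7)
shaving; (8) mechanical relaxation (run when divisions or shaving changed
the packing). The biological step (default 1 h) is adaptively shortened so
that no agent changes mass by more than ~10% per step, with a floor of
$\Delta t_{bio}/64$. A run stops at `t_end`, or earlier once the height
cap has been reached and every group's biomass has changed by less than 1%
over a trailing 48 h window (the stationarity criterion is ours - declared,
not inferred from the original implementations this class of model follows).

## Scenarios and the reduced scale

`scenario_library()` packages ten configurations: five nitrification runs
(1a-5a: AOB + NOB seeded 1:1 in 8 layers; O~2~ 9, CO~2~ 88, NH~3~ 30 mg/L,
pH 7.5) and five anaerobic runs (1b-5b: glucose fermenter +
hydrogenotrophic + acetoclastic methanogens 1:1:1, interleaved so each
methanogen sits next to fermenters; glucose 94, NH~3~ 1.7, CO~2~ 4.4,
acetate 0.6, H~2~ 0.0013 mg/L, pH 7.5), crossing fixed/dynamic boundary
conditions, constant/free/buffered pH and coupled/decoupled
thermodynamics. Initial agent masses are drawn uniformly from 50-90% of
the division mass, so the population does not divide synchronously.

The reduced scale exists because the full domain with these autotrophic
growth rates ($q_{max} Y_{XS} \approx 5\times10^{-3}$ h^-1^) needs
~10^6^ agent-updates over ~45 simulated days. The reduced grid is
10 x 4 x 40 cells (20 x 8 x 80 um) and the height cap 25 um - low enough
that the slow nitrifier growth reaches it within a few hundred simulated
hours. The reactor biofilm area is scaled with the domain footprint and
then raised fivefold: the reduced biofilm column is an order of magnitude
shorter than the full one, and without that correction the reactor never
experiences enough conversion to draw the bulk substrate down, the fast
guild is never throttled, and the coupled scenario degenerates into
washout of the slower guild - a scale artifact rather than the mechanism
under study. With the corrected coupling the bulk ammonia settles near its
limiting level and the community self-organizes. Reduced runs complete in
one to two minutes each on one CPU.

The headline scenario contrast reproduces at this scale mechanistically:
with fixed boundary conditions (1a) nitrite is exported through the
boundary at its initial zero value, total nitrite near the biofilm stays
micromolar, HNO~2~ stays orders of magnitude below the NOB half-saturation
constant, and the NOB guild decays into inert particles while the AOB
grow. With dynamic boundary conditions (2a) nitrite accumulates in the
bulk within hours, is re-supplied to the biofilm from the top, and the
steady community retains both guilds. What the reduced runs do *not*
emulate is everything that needs the full 250 um column: deep-biofilm
oxygen exclusion zones, the large inert cores of mature biofilms, and
absolute removal efficiencies - those are full-scale quantities and are
not claimed by the desk-scale tests.

## What the synthetic scenarios do and do not show

The packaged scenarios are synthetic study conditions, not data fits: they
demonstrate that the coupled model produces the qualitative regime
structure expected of nitrifying and anaerobic biofilms (cross-feeding,
boundary-condition sensitivity, pH-dependent substrate availability).
Passing tests show internal consistency against closed-form limits and
independent oracles - exact speciation algebra, analytic diffusion
profiles, CSTR exponentials, force antisymmetry - and reproducibility of
the published yield set given the calibrated table. They do not validate
the model against measured biofilm data, and parameters that live in
supplementary material of the source literature (exact mechanical
constants, division sizes) are defensible defaults, not fitted values.
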