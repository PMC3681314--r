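---
title: "Gradient-forming mechanisms in the root tip: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-forming mechanisms in the root tip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootflux)
```

## The scientific question

A morphogen gradient conveys positional information through concentration
thresholds, and its usefulness is governed by two numbers: the
characteristic length $\lambda$ over which it decays by $1/e$, and the
maximum $C_0$ from which that decay starts.  For auxin in the root tip the
relevant tissue scale is hundreds of micrometres to millimetres, yet auxin
is a very small, very fast-diffusing molecule.  `rootflux` implements three
candidate mechanisms for building such a gradient and the machinery to
compare them quantitatively:

1. **Source–decay**: production localised at the tip, diffusion at $D$,
   linear turnover at $d$.  The steady state is exponential with
   $\lambda = \sqrt{D/d}$ and $C_0 = J/\sqrt{Dd}$.
2. **Unidirectional polar transport**: a file of cells pumping auxin
   rootward towards a dead end.  With polar efflux rate $p$ on top of a
   bidirectional leak $q$, consecutive cells equilibrate at a ratio
   $(p+q)/q$, i.e. $\lambda = 1/\ln\!\big((p+q)/q\big)$ cell lengths.
3. **Reflux loop**: rootward pumping through the stele, shootward pumping
   through the outer files, and lateral inward-facing carriers in the ground
   tissue coupling the two streams.  The lateral flux bends a constant
   fraction $\alpha$ of the shootward stream back per unit length, which
   yields an exponential profile with $\lambda = 1/\alpha$ *independent of
   the absolute kinetic constants* — the property the robustness scans
   quantify.

## Parameters and their defaults

All concentrations are in arbitrary units (a.u.); there is no unit
conversion layer.  Distances are in µm, time in seconds.

| parameter | default | meaning |
|---|---|---|
| $D_\mathrm{cyt}$ | 600 µm²/s | cytosolic diffusion of auxin |
| $D_\mathrm{wall}$ | 40 µm²/s | apoplastic diffusion (15× reduced) |
| $d$ | $10^{-6}$ /s | net turnover, a half-life of ~8 days |
| $J$ | 1000 a.u./s | total influx (shoot) or production (tip source) |
| $P_\mathrm{pin,s}$, $P_\mathrm{pin,w}$ | 20, 5 µm/s | strong / weak PIN-mediated efflux |
| $P_\mathrm{bg}$ | 1 µm/s | carrier-free background efflux |
| $P_\mathrm{aux}$ | 20 µm/s | apolar influx (chemiosmotic + AUX/LAX) |
| cell lengths | 16 µm (MZ), 60 µm (EZ) | zone rule of the layout |
| wall thickness | 0.5 µm | apoplast around every cell |

The membrane flux law is $F = P_\mathrm{efflux} C_\mathrm{in} -
P_\mathrm{aux} C_\mathrm{out}$ with $P_\mathrm{efflux}$ set per membrane
segment by the PIN map.  Note one non-obvious consequence used repeatedly in
the tests: a closed membrane equilibrates at $C_\mathrm{in}/C_\mathrm{out} =
P_\mathrm{aux}/P_\mathrm{efflux}$, so the "source-decay" map (strong PIN on
all sides) makes membranes concentration-transparent and the tissue behaves
like its 1D idealisation.

## The synthetic root layout

`build_root_layout()` generates the package's own study system — a
"minimal root": mirror-symmetric longitudinal files (vascular, pericycle,
endodermis, cortex, epidermis from the midline outward; widths 10, 8, 10,
12, 10 µm per half), a quiescent-centre row capping the stele, and three
columella tiers distal to it.  Rows follow the zone rule; the meristem
spans 350 µm above the QC by default and the elongation zone continues to
the requested segment length.  The full-scale segment is 3 mm; the
desk-scale experiments in this package use the most distal 1200 µm, which
contains the entire gradient region.  Cell widths, the MZ/EZ boundary and
the columella tier count are not printed quantities anywhere; they are
modelling choices, configurable in the layout config.

What the generator deliberately does **not** emulate: curved cell shapes,
growth, division, root hairs, intracellular signalling, AUX1 patterning, or
stochasticity.  Passing tests therefore demonstrate the transport logic on
an idealised geometry, not agreement with imaged root anatomy.

The PIN maps encode the mechanism variants: strong PIN on every side
(source–decay), basal-only PIN in the stele (unidirectional; plus apical
carriers at 85% of basal strength in the back-engineered variant), and the
reflux arrangement (basal in the stele, apical in the outer files, lateral
inward-facing in the ground tissue, apolar in the columella, weak apolar on
the QC).  The tissue-by-tissue strong/weak assignment is a reconstruction —
the source imagery is only described qualitatively — and every entry can be
overridden.  One choice deserves emphasis: the default **lateral** strength
is the weak level (5 µm/s) on all three ground-tissue files.  With strong
(20 µm/s) lateral carriers on the endodermis the loop returns
$\lambda \approx 80$ µm in this geometry; the uniform weak assignment
returns $\lambda \approx 125$ µm (vascular) and $\approx 110$ µm
(epidermal), matching the tissue-scale gradient length inferred for the
root (100–200 µm).  Because the absolute lateral leak
depends on geometric details (file widths, how many files carry lateral
carriers) that are themselves reconstructed, we anchor the reconstruction
on the reported gradient length rather than on any single permeability.

## Discretisation and numerics

The tissue model is a finite-volume compartment system assembled by
`build_tissue_model()`:

* each cell interior becomes an $n_x \times n_y$ grid of cytosol pixels
  (target spacing 4 µm by default) with harmonic two-point diffusion fluxes;
* each cell–cell or cell–boundary interface becomes **one** apoplast
  compartment of nominal volume (interface length × 0.5 µm), connected to
  neighbouring wall compartments through the cell-corner junctions with
  conductance $D_\mathrm{wall} t_\mathrm{wall}/\Delta$.  This "interface
  wall" representation avoids rasterising 0.5 µm walls over a millimetre of
  tissue; its exchange terms are independent of the cytosol resolution, so
  grid refinement studies refine the only discretised axis (the cytosol),
  and the 1D solver carries the formal second-order convergence test
  (error ratio ≈ 4 under halving);
* membrane segments carry the carrier flux law, converted to concentration
  rates by segment length over compartment volume.

Everything is linear, so the semi-discrete system is $\dot{C} = AC + b$
with a sparse Metzler matrix $A$ (non-negative off-diagonals).  That
structure buys three guarantees used throughout: positivity is preserved
exactly by backward Euler for any step and by forward Euler for
$\Delta t \le 1/\max_i(-A_{ii})$ (the `stable_dt()` bound); the mass ledger
$\mathrm{d}(\text{total})/\mathrm{d}t = \text{influx} - \text{decay}$ holds
to rounding; and steady states are available either exactly (`method =
"direct"`, one sparse LU) or by marching with geometrically growing
implicit steps.

**Tolerances.**  The marching criterion is the maximum relative
concentration change per simulated minute (default $10^{-5}$).  With the
default decay of $10^{-6}$/s the slowest system mode relaxes on the
$1/d \approx 1.7\times 10^4$ minute scale, so a change-per-minute tolerance
$\tau$ leaves a relative distance of order $\tau/(60 d)$ from the exact
fixed point (≈2% at the default).  Where exactness matters the tests
tighten $\tau$ or use the direct solve; `run_to_steady_state()` reports the
simulated time used and errors out with diagnostics if its time cap is hit.

**Transients** use backward Euler with a fixed step (default 1/20 of the
output spacing); the dynamics of interest here are relaxations over minutes
to hours and are insensitive to the first-order damping.

**1D source–decay solver.**  Finite volumes with the influx as a flux
boundary condition at $x=0$ and a zero-flux wall at $x=L$.  Its closed-form
counterpart is the exact finite-domain steady state $C(x) = (J\lambda/D)
\cosh((L-x)/\lambda)/\sinh(L/\lambda)$, evaluated in overflow-safe
exponential form; for $L \gg \lambda$ this is indistinguishable from the
semi-infinite exponential $C_0 e^{-x/\lambda}$, the form usually quoted.

**Amplitude mapping between 1D and 2D.**  The 2D simulations prescribe a
*total* influx (a.u./s); the 1D reduction prescribes an influx per unit
cross-section.  Since total steady mass equals $J/d$ in both, profiles are
compared shape-normalised (divided by their value at the source/QC
position); no absolute amplitude claim crosses dimensionality.

## Profiles, fits, elbows and zonation

`extract_profile()` follows one file's column of the layout from the distal
tip upward, across the QC and columella rows that sit in that column.  Polar
pumping superimposes a within-cell sawtooth (each membrane crossing steps
the concentration by up to $P_\mathrm{efflux}/P_\mathrm{aux}$); the
`per_cell = TRUE` variant collapses to one volume-weighted mean per cell and
is what the default gradient fit uses.

`fit_exponential()` is a log-linear least-squares fit; $\lambda$ is minus
the inverse slope and $\alpha = 1/\lambda$.  The default window runs from
two cell lengths above the concentration maximum (excluding the QC
accumulation spike) down to the detected elbow.  `detect_elbow()` scores
every two-segment split of the log-profile by summed RSS and only reports a
change-point whose distal slope is negative and at least 4× the proximal
slope in magnitude — absence is a valid result, returned as `NA`.

`threshold_zonation()` converts a monotone profile and strictly decreasing
thresholds into zone boundaries by linear interpolation; thresholds above
the maximum yield empty zones rather than errors.  Two consequences worth
remembering when interpreting zonation: equal-$\lambda$ gradients with
halved $C_0$ shift *every* boundary distally by $\lambda\ln 2$, and a
$\lambda$ far larger than the tissue (Thiele modulus $L/\lambda \ll 1$, the
default-auxin source-decay case) cannot place boundaries at all.

## Events, ablation and the experiments

Scenario events (`cut_influx`, `ablate`, `rescale_permeabilities`,
`set_polarity_ratio`) are applied atomically at their times; the transport
operator is rebuilt and the field carried over by matching compartments on
kind and centre coordinates.  Ablation follows the strict no-flux reading:
the selected cells' footprints become obstacles, membrane segments facing
them are sealed outright (their shared wall compartments are removed along
with any stored content), and the surrounding apoplast remains.

One numerical subtlety shapes the ablation summary.  At the new dead end of
the unidirectional mechanism the post-ablation balance is *exactly* neutral
in the cell-file caricature — the inflow $(p+q)C_{n-1}$ equals the
remaining outflow $qC_n$ whenever the per-cell ratio is $(p+q)/q$ — so a
discretised 2D run settles within a fraction of a percent of the
pre-ablation level, on either side of it.  `run_ablation_experiment()`
therefore reports cells as "increased" only beyond a documented 1% relative
tolerance.  The reflux loop's genuine replenishment of the cells above the
removed QC reaches several-fold within 20 simulated minutes, three orders
of magnitude away from that tolerance in $\Delta C/C$.

The robustness scans hold the net influx fixed (it is prescribed
independently of the permeabilities) and scale either every permeability
uniformly or the lateral:apical ratio of the ground tissue.  The polarity
knob is applied to **all** lateral-carrier-bearing files by default — the
ratio between effective lateral and axial flux is the quantity that sets
$\alpha$, so the mechanism-level scan moves all of it together, while
`set_polarity_ratio()` accepts any subset for finer dissection.

## Problem sizes used by the shipped tests

The test suite and the worked examples run the desk-scale 1200 µm layout
(~370 cells, ~9000 compartments; steady states in roughly a second via
sparse LU), a 300 µm structural layout for property tests, and a two-cell
closed system for conservation and membrane-equilibrium checks.  The full
3 mm segment is available through the layout config; nothing in the code
depends on the segment being short.

## Known limitations

* Static geometry: no growth, division or tissue deformation, so the slow
  proximal shift of the gradient cannot feed back onto zone sizes.
* One wall compartment per interface: apoplastic gradients *along* a single
  interface are not resolved (wall-to-wall transport happens only at
  junctions).  Consequently apoplastic micro-gradients at the QC are
  smoothed.
* Linear kinetics only: no saturable carriers, no quadratic decay, no
  intrinsic noise.  Intracellular gradients produced by high through-flux
  are reported as outputs but not validated against measured magnitudes.
* The PIN map is a qualitative reconstruction; conclusions that depend on
  the precise strong/weak assignment (rather than on its topology) should
  be re-checked against the overridable map entries.
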