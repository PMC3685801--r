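---
title: "Plasmodesmal bulk flow and the high-pressure manifold: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasmodesmal bulk flow and the high-pressure manifold: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phloemanifold)
```

## The model

Phloem sap leaves the sieve element/companion cell (SE/CC) complexes of
release phloem symplasmically, through plasmodesmata whose cytoplasmic sleeve
is subdivided into microchannels a few nanometres wide. The high-pressure
manifold picture holds that (i) the sieve-tube system is pressurised near
source values along its entire length, with minimal axial gradient, and
(ii) the dominant hydraulic resistance — and therefore the control of both
unloading rate and inter-sink partitioning — sits in these plasmodesmal
interfaces.

The package treats each microchannel as a cylinder of radius $r$ and length
$L$ (the cell-wall thickness). Bulk flow obeys the Hagen–Poiseuille law,

$$R_v = \frac{\pi r^4 \Delta P}{8 \eta L}, \qquad
  L_o = \frac{\pi r^4}{8 \eta L},$$

with $\Delta P$ the trans-plasmodesmal hydrostatic pressure differential and
$\eta$ the sap viscosity; solute carriage by that flow is advective,
$R_v \times C$. Diffusion of a solute with coefficient $D$ follows Fick's
first law, $R_i = D \, \pi r^2 \, \Delta C / L$. Both laws are linear in
their driving force and signed, so the same primitives serve the network
solver symmetrically.

**Assumptions.** Channels are rigid, flow is laminar Stokes flow with no-slip
walls (no nanoconfinement enhancement; reported nanotube flows exceeding the
Poiseuille prediction are deliberately not modelled), viscosity is uniform
and temperature fixed at 25 °C, and solutes do not interact with channel
walls (no hindered diffusion). Osmotic generation of the boundary pressures
(loading, retrieval, aquaporin exchange) is outside the model: pressures are
inputs, not state variables.

## Units

Everything internal runs in nm–MPa–s–mol, the system in which the published
constants are stated (viscosity $2 \times 10^{-9}$ MPa s, lengths in nm,
flows in nm$^3$ s$^{-1}$). Laboratory units convert exactly at the boundary:
$1\,\mu L = 10^{18}$ nm$^3$, 86 400 s day$^{-1}$,
$1\,\mathrm{mM} = 10^{-27}$ mol nm$^{-3}$, 1 Pa s $= 10^{-6}$ MPa s. The
10 µL day$^{-1}$ grain import is therefore $1.157 \times 10^{14}$
nm$^3$ s$^{-1}$. In this system no formula carries a hidden factor, which is
the main defence against the unit errors this kind of calculation invites.

## The feasibility procedure

For a target organ (defaults: the developing wheat grain — import
10 µL day$^{-1}$, observed $4.4 \times 10^7$ plasmodesmata at the
SE/CC–parenchyma interface, differential 1.0 MPa, wall 500 nm):

1. per-microchannel flow $R_v(r)$ from the Poiseuille law;
2. microchannels required = target flow / $R_v(r)$;
3. microchannels per plasmodesma from the annular packing rule;
4. plasmodesmata required = (2) / (3), compared with the observed count.

**Packing rule.** Microchannel equators (diameters) are placed in a single
row on a circle of radius 10.5 nm (half the plasmodesmal internal radius),
occupying 50% of its circumference. The published counts are reproduced only
when the occupied arc is first quantised to a whole nanometre
($0.5 \times 2\pi \times 10.5 = 32.99 \to 33$ nm) and the quotient
$33 / 2r$ then rounded half-up: this yields 33 channels at $r = 0.5$ nm and
17 at $r = 1.0$ nm (where the unquantised arc would give 16.49 → 16). We
adopt that two-stage rule as the package default, with a floor rule available
as an option; a minimum of one channel is enforced for any admissible radius.

`min_pressure_differential()` exploits the exact $1/\Delta P$ scaling of the
required count, walking a pressure grid (default 0.1 MPa steps, capped at
5 MPa — above any measured sieve-tube pressure) to find the smallest feasible
differential; at $r = 1$ nm this is 0.4 MPa.

## Diffusion versus bulk flow

The bulk/diffusion rate ratio is
$\Delta P \, C \, r^2 / (8 \eta D \, \Delta C)$: quadratic in radius, hence a
single crossover at
$r^* = \sqrt{8 \eta D \, \Delta C / (\Delta P \, C)}$. `crossover_radius()`
computes both this closed form and a bisection root of the rate balance
(tolerance $10^{-3}$ nm; the two agree to that tolerance by construction and
by test). "Comparable" is operationalised as a ratio within a factor of 2
(configurable): no numeric criterion exists in the source analyses, and a
factor-2 band both brackets $r = 2$ nm under the wheat-grain pairing
($\Delta C = 400$, $C = 450$ mM, the mid-grid pairing used by default) and
keeps the classification monotone.

## Pressure scenarios

All decompositions assume flux strictly proportional to $\Delta P$. The
fruit-excision decomposition is multiplicative and lossless by construction:
`residual_fold * dP_fold` equals the observed fold exactly. The published
residual folds (17.8/14.2) cannot be reconstructed from the stated arithmetic
(19 divided by the differential ratios gives 17.1/15.2); the package reports
its closed form next to the published figures and asserts neither as the
other. Likewise the published claim that a 10% bulk-flow gain corresponds to
a 1.3% radius increase does not follow from the $r^4$ law (which gives
2.41%); both numbers appear in `report_scenarios()` with an annotation.

## The conductance network

`build_manifold()` realises the manifold as a comb: source → axial segments →
junctions, one plasmodesmal interface edge per junction down to a sink held
at its turgor. `conductance_network()` accepts arbitrary topologies. The
solver does direct dense linear nodal analysis (Kirchhoff conservation at
free nodes, $flow = L_o \Delta P$ per edge) with a fixed node ordering — no
iteration, no randomness; networks of interest have a handful of nodes, so a
dense solve is exact and instant. Interior conservation residuals are below
$10^{-9}$ (relative) by test.

`manifold_regime_check()` quantifies the two manifold signatures: the axial
drop as a fraction of the source-to-mean-sink differential, and the maximum
deviation of partition fractions from normalised sink conductances. Both
converge to zero as the axial/sink conductance ratio grows (verified over a
sweep from 1 to $10^3$); the conventional "manifold regime" label at 2% is a
package convention — the source model gives no numeric threshold. Note that
in a comb the drop accumulates over segments: with three segments each 100×
the summed sink conductance the partition deviation is below 1% but the
cumulative axial drop fraction is ≈2.4%.

## Synthetic bundles

`sample_bundle()` draws measurement bundles uniformly from the published
physiological ranges — SE pressures 0.5–2.4 MPa, sink turgors 0.08–0.33 MPa,
SE sucrose 450–600 mM, parenchyma sucrose 200–260 mM, microchannel radii
0.5–10 nm — with the orderings SE pressure > sink turgor and SE sucrose >
parenchyma sucrose enforced by rejection. Plasmodesma counts are drawn
log-uniformly over $10^7$–$10^8$ (an order of magnitude around the observed
$4.4 \times 10^7$) and import rates uniformly over 5–15 µL day$^{-1}$ around
the measured 10; these two ranges are package choices where no published
range exists. Sampling is a pure function of the seed (no hidden global
state). What the generator emulates is the *range structure* of the
measurements, not their error model: real micromanometry data oscillate with
transpiration load, are serially correlated, and co-vary between quantities,
none of which is simulated — so passing pipeline tests on bundles
demonstrates numerical robustness across the physiological envelope, not
statistical validity on real traces.

## Numerical choices and degenerate inputs

- Half-up rounding (`floor(x + 0.5)`) for channel counts; base R's
  round-half-even would give 16 at the 16.5 boundary.
- Empty radius vectors yield empty tables, not errors; zero driving forces
  yield exact zeros; negative driving forces yield signed flows.
- Non-finite or non-physical quantities (negative radii, zero viscosity,
  pressures) raise classed errors at the boundary rather than propagating
  NaNs.
- Feasibility at the exact boundary (required = observed) counts as feasible
  with margin 1.
- Problem sizes throughout tests are desk-scale (grids of ≤60 radii, networks
  of ≤12 nodes, hundreds of sampled bundles), keeping the full suite under a
  minute.

## Known limitations

- The published feasibility table's $r = 10$ nm row is internally
  inconsistent and is flagged rather than matched; the $r = 8$ nm row's
  counts are printed to one significant digit and are compared at that
  precision.
- The two bulk-flow cells at $r = 0.5$ nm in the published mode-comparison
  table do not follow from $R_v \times C$ and are annotated.
- No Münch-style coupling of concentration to viscosity or osmotic pressure
  along the path; boundary pressures are static, so turgor-homeostat dynamics
  and plasmodesmal gating kinetics are out of scope (gating can only be
  represented by editing a conductance).
- No slip-flow enhancement, hindered diffusion, or electro-osmosis at the
  nanochannel scale.
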