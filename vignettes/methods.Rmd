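---
title: "Methods: force-field parameterization and hydration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: force-field parameterization and hydration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromring)
```

# Scope and model assumptions

`aromring` implements the analysis layer of a GROMOS-style force-field
parameterization and validation workflow for small (hetero)aromatic
molecules. The quantum-chemistry and molecular-dynamics engines are out of
scope: they enter only through their output files (GRO/XYZ coordinates, an
ITP topology subset, XVG-like observable tables). Everything downstream of
those files — charge fitting, torsion fitting, liquid observables,
thermodynamic-integration bookkeeping, hydrogen-bond kinetics, and
solvation-shell structure — is computed here, in the GROMACS unit system
(nm, ps, kJ/mol, e, K, bar) with CODATA 2018 constants
(`aromring_constants`). Boxes are assumed orthorhombic; triclinic inputs
are rejected rather than silently mishandled.

# Dipole-constrained charge fitting

Partial charges are adjusted to reproduce a target (QM) dipole while
preserving the charge-group structure of a GROMOS topology. The problem is
posed as equality-constrained linear least squares: minimize
\(\lVert A q - \mu_\mathrm{target} \rVert^2\) subject to integer
per-group charge sums, frozen atoms, and (optionally) atoms shared between
two superimposed groups appearing in both group constraints. It is solved
by an SVD pseudo-inverse: the minimum-norm particular solution of the
constraint system plus a minimal-norm least-squares correction in the
constraint null space. This gives a deterministic answer even when the
problem is under-determined (e.g. planar molecules, whose dipole map has a
null direction). The per-atom shift bound (`max_shift`, default 0.5 e) is
checked *a posteriori*: a violation warns and flags the result instead of
distorting the optimum, because a hard box constraint would turn the
problem nonlinear for little practical gain at these shift magnitudes.

The angle between achieved and target dipole is computed as
`atan2(|a x b|, a . b)` rather than `acos` of the normalized dot product;
near 0° the `acos` form loses half the available precision and reports
spurious micro-degree angles for exactly solved fits.

# Torsion-potential fitting

Dihedral terms use the GROMOS functional form
\(V(\phi) = \sum_n k_n (1 + \cos(n\phi - \phi_0))\) with multiplicities
\(n \le 6\) and phases restricted to 0° or 180°. The difference between a
QM scan and the MM background (both shifted to a zero minimum) is fitted
by ordinary least squares onto an intercept plus \(\cos(n\phi)\) basis;
the two allowed phases differ only in the sign of the cosine coefficient,
so a negative fitted coefficient is mapped to a positive \(k_n\) with the
opposite phase. The default multiplicity set \{1, 2, 3, 6\} covers the
symmetry orders that occur in ring–substituent torsions; the full set 1–6
may be requested. A substituent is classified as rotationally "spread"
when the fitted profile's barrier on a 1° grid falls below 2.5 kJ/mol
(about RT at 298 K), i.e. when thermal motion delocalizes the rotamer.

# Liquid-phase observables

* **Density** is block-averaged (5 contiguous blocks by default; a tail
  remainder shorter than a block is dropped) from the volume series:
  \(\rho = n M / (N_A \langle V \rangle)\).
* **Enthalpy of vaporization**:
  \(\Delta H_\mathrm{vap} = (E_\mathrm{gas} + RT) - E_\mathrm{liq}/n\).
* **Thermal expansion** \(\alpha_P = -\Delta \ln \rho / \Delta T\) and
  **heat capacity** \(C_P = \Delta U / (n\,\Delta T)\) use the two
  endpoint states of a 2- or 3-state scan (central difference; a middle
  state, when present, is deliberately unused).
* **Isothermal compressibility** is reported as a positive quantity,
  \(\kappa_T = +\Delta \ln \rho / \Delta P\) in 1/GPa: density increases
  with pressure for a stable liquid, and the sign convention is chosen so
  the tabulated values are positive.
* **Dielectric constant** uses the box-dipole fluctuation formula
  \(\varepsilon = 1 + (\langle M^2 \rangle - \langle M \rangle^2) /
  (3 \varepsilon_0 V k_B T)\), with a running-average trace; the estimate
  is marked converged when the relative spread of the trace over its final
  20% is below 2%.
* **Energy drift QC** is the absolute OLS slope of the total-energy
  series, normalized to J/(mol ns DoF), with a 0.5 pass threshold.

# Hydration free energy (thermodynamic integration)

Solute decoupling proceeds in two stages (Coulomb, then van der Waals),
each over a 25-point λ grid that is dense near the endpoints
(0, 0.02, 0.04, 0.07, 0.1, 0.15, then 0.05 steps from 0.2 to 0.8, then
0.85, 0.9, 0.93, 0.96, 0.98, 1) — 50 windows in total — with soft-core
power 1 and α_LJ = 0.5 recorded as schedule metadata.
\(\langle dH/d\lambda \rangle\) curves are integrated by the trapezoidal
rule; the uncertainty is propagated through the trapezoid weights,
\(\sigma^2 = \sum_i w_i^2\,\mathrm{sem}_i^2\), and stages add in
quadrature. The hydration free energy is the negative of the decoupling
integral, so a solute that binds water (positive mean
\(dH/d\lambda\)) gets a favorable, negative \(\Delta G_\mathrm{hyd}\).

# Hydrogen-bond kinetics

Detection is geometric: donor–acceptor distance ≤ 0.35 nm and
H–D–A angle ≤ 30°, with minimum-image distances. These are the common
defaults of trajectory H-bond tools; the criteria object makes them
explicit and overridable.

Residence times are estimated from *completed* bonded intervals (runs
touching either end of the trajectory are censored and dropped). The
interval durations imply the uninterrupted-bond survival function
\(C(t) = \sum_j \max(L_j - t, 0) / \sum_j L_j\), which is exactly
\(e^{-t/\tau}\) in expectation for exponential dwell times; a single
exponential is fitted by log-linear least squares over \(C \ge 0.01\).
Sites with fewer than 20 completed intervals are flagged
`insufficient_sampling` and suppressed (reported as empty cells), sites
with \(\tau\) at or below the frame spacing are flagged `short_lived`.
Note that a trajectory save interval comparable to \(\tau\) aliases the
bonded indicator, which is why the synthetic generator also returns its
continuous ground-truth dwell times. The lifetime column is \(1/\tau\) by
definition, and the breakage free energy inverts the Eyring rate
equation: \(\Delta G = RT \ln(\tau\, k_B T / h)\) at 298.15 K.

# Solvation-shell structure

The RDF uses exact shell volumes \(\tfrac{4}{3}\pi (r_2^3 - r_1^3)\) per
histogram bin and supports multiple reference atoms. The coordination
number integrates the histogram binwise,
\(CN = \rho_N \sum_i V_{\mathrm{shell},i}\, g_i\), which with the
piecewise-constant estimator is *exactly* the mean pair count inside the
first minimum — so constructed shells integrate to their true occupancy
with no quadrature error. The optimal binding distance is the first local
maximum with \(g > 1\) whose height is at least 1.05 times the following
minimum; curves with no qualifying peak are flagged rather than assigned
a fake shell. Water orientation uses rigid 3-site geometry (O–H 0.1 nm,
109.47°): the mean cosine between the water dipole bisector and the
oxygen-to-reference vector classifies the shell H-oriented (≥ +0.25),
O-oriented (≤ −0.25), or Undefined.

# Synthetic generators: realism and limits

Each generator (`gen_*`) seeds the RNG itself and returns its ground
truth as attributes, so tests never re-derive it.

* `gen_hbond_markov` draws alternating exponential bound/unbound dwells
  from the stationary state and discretizes at the save interval. It is a
  two-state renewal model — no reformation correlation, no distance
  dynamics — which is exactly the model the residence-time estimator
  assumes; it validates the estimator, not the physics.
* `gen_liquid_series` fluctuates volumes log-normally around
  \(V(T,P) = V_0 e^{\alpha (T-T_0)} e^{-\kappa (P-P_0)}\) and energies
  normally around a linear \(U(T)\), so finite-difference estimators are
  exact on the noiseless means. Default noise (relative volume SD 1e-3,
  energy SD 0.05 kJ/mol per molecule) is of the order of NPT fluctuations
  for ~1000 molecules.
* `gen_hydration_shell` places rigid waters on a tight shell with
  controlled dipole orientation; `gen_uniform_gas` provides the flat-RDF
  null case; `gen_ti_curve` carries a closed-form polynomial integral.

Problem sizes used in the test-suite (e.g. 500 particles × 50 frames for
the RDF flatness check, 250-ns-equivalent Markov series) are the
package's own choices, selected by pre-run power analysis so the asserted
bounds have comfortable statistical margin at those sizes.

# Limitations

No dynamics is integrated anywhere: trajectories are generated directly
in configuration space. Force-field deviations from experiment across a
full molecule set, regression equations over a benchmark campaign,
ensemble dipole-angle averages, and absolute hydration free energies of
specific solutes require QM and multi-ns MD campaigns and are outside
what this package can reproduce; the package covers them with the
property-based suites described above.
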