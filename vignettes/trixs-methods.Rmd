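---
title: "Models and methods behind trixs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trixs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trixs)
```

`trixs` analyses time-resolved X-ray solution scattering (TR-XSS)
difference signals from photoexcited triiodide. This vignette documents
the model, the estimators, the synthetic-data generator and the numerical
and design choices, in the spirit of a methods section: everything the
code computes is stated here with its assumptions and defaults.

## The scattering model

### Solute term

The three-iodine solute is parameterized by the I2⁻ bond length $r_{12}$,
the interfragment distance $r_{23}$ and the I–I–I angle $\alpha$; the
third distance follows by the law of cosines. Its orientationally
averaged coherent scattering is the Debye double sum

$$S(q) = \sum_{i}\sum_{j} F^{DW}_i(q)\,F^{DW}_j(q)\,
         \frac{\sin(q d_{ij})}{q d_{ij}},$$

with self-terms equal to 1 and the small-argument limits of the sinc
evaluated by series expansion below $10^{-4}$ (well before cancellation
sets in). Atomic form factors use the International Tables four-Gaussian
parameterization for neutral iodine; at $q=0$ the curve reproduces the
coherent forward limit $(3\times 53)^2$ electron units. Structural
heterogeneity of the probed ensemble is represented by a
Debye–Waller-like damping of the *atomic* form factors,
$F^{DW}_i(q) = F_I(q)\,e^{-q^2\sigma_i^2/2}$, with per-atom rms
displacements $\sigma = (0.5, 0.5, 0.7)$ Å by default — the terminal,
dissociating atom is the most disordered. The −1 excess charge is *not*
folded into the form factors: its distribution over the three atoms
matters for the solvent arrangement (the RDFs), not for the neutral-atom
Debye sum, and ionic form-factor corrections at these $q$ are far below
the other model uncertainties.

Difference curves are plain subtractions
$\Delta S_{\text{solute}} = S(q;\mathbf{R}_{es}) - S(q;\mathbf{R}_{gs})$
against the per-solvent ground-state geometries (acetonitrile
2.95/3.06 Å/172°, water 2.92/3.14/170, ethanol 2.94/3.07/171, methanol
2.94/3.09/172). The ground state itself is fixed, never refined: with
seven free parameters per delay it is already strongly correlated with
the excited-state structure.

### Anisotropic term

Linearly polarized excitation photoselects molecules whose transition
dipole is aligned with the field, which imprints a $P_2$ azimuthal
modulation on the 2-d pattern. The leading anisotropic component is

$$S_2(q) = c_2 \sum_{i \ne j} F^{DW}_i F^{DW}_j\,
           P_2(\cos\zeta_{ij})\, j_2(q d_{ij}),$$

where $\zeta_{ij}$ is the angle between the pair vector and the
transition dipole and $j_2$ is the second spherical Bessel function
(series limit below $5\times10^{-2}$). Self-terms carry no orientational
information and are excluded. Two conventions had to be fixed here:

- **Dipole direction.** For a quasi-linear ion excited at 400 nm the
  transition is conventionally polarized along the molecular axis; the
  default dipole is the end-to-end I1→I3 unit vector, configurable.
- **Sign.** The photoselection prefactor is absorbed into the fitted
  amplitude $A_{ani}(t)$ together with $c_2$ and rotational dephasing, so
  only the *relative* sign between $S_2$ and the generator matters; the
  package uses a positive prefactor throughout, and generator and
  refinement share it by construction.

The ground state is isotropically oriented and contributes no $S_2$, so
the species anisotropy is the excited structure's $S_2$ alone, and the
anisotropic model contains no cage or heating terms (bulk-solvent
anisotropy from the optical Kerr effect is much weaker than the solute
contribution and is excluded).

### Cage term

Restructuring of the solvent around the dissociating solute contributes

$$S_{\text{cross}}(q) = \sum_{i}\sum_{v} F_I(q) F_v(q)\,4\pi\rho_v
  \int r^2\,(g_{Iv}(r) - 1)\,\frac{\sin qr}{qr}\,dr$$

per solvent atom type $v$ (number densities from bulk composition),
plus a displaced-volume term: a Gaussian dummy-solvent sphere at each
iodine site (Fraser–MacRae–Suzuki form factor
$f_{dv} = \rho_e V e^{-q^2 V^{2/3}/4\pi}$, radius = iodine van der Waals
radius 1.98 Å by default), entering as the dummy–dummy Debye sum minus
twice the solute–dummy cross sum. Cage differences are taken between
excited and ground geometry.

The RDFs come from a *parametric generator* rather than molecular
dynamics: an excluded core, a Gaussian first solvation shell (default
position 3.5 Å, width 0.4 Å, amplitude 0.8 above bulk), hydrogen shells
displaced 0.4 Å outward at reduced amplitude, an attenuated shell around
the buried central atom, and a bulk limit of 1. A linear coupling rule
shifts the shell around each terminal iodine with that atom's
nearest-neighbour I–I distance (saturating at 5.5 Å — once the fragment
has escaped the first shell its own solvation no longer tracks the
partner distance). The geometry-independent default (`coupling = 0`)
gives the simplest testable stand-in; the default *scenario* uses
`coupling = 0.25` so that the cage term genuinely varies with structure
and the interpolation path is exercised. This generator reproduces the
qualitative features that matter for the analysis — a first-shell peak
whose position sets the cage size, decay to bulk, excluded volume — but
not solvent-specific shell substructure, hydrogen-bond anisotropy, or
cage relaxation dynamics; conclusions about real solvents require an
MD-derived library in its place.

Cross-term curves are tabulated on a $(r_{12}, r_{23}, \alpha)$ grid and
evaluated off-node by per-$q$ trilinear interpolation over the eight
enclosing nodes — exact at nodes and for fields linear in the
coordinates, continuous across cell faces. Geometries outside the hull
are clamped to the nearest edge with a warning; in particular the
solvent-separated species at $r_{23} = 100$ Å uses the largest tabulated
$r_{23}$ (13.8 Å in the full grid), where the cage has already decomposed
into fragment contributions. The radial integral uses trapezoidal
quadrature on the RDF grid with a cosine taper of $(g-1)$ over the last
10% of the grid to suppress truncation ringing; a warning is raised if
$g$ has not reached bulk at the edge. The default pipeline grid is
$7\times15\times13$ nodes (steps 0.2 Å, 0.8 Å, 0.262 rad) — coarser than
the 0.2-Å/0.131-rad grid a production MD library would use, which is
adequate because the parametric cross-term varies smoothly on these
scales and keeps the library build to seconds.

### Heating term and composite model

Energy released by recombination heats the bulk solvent isochorically;
its difference-scattering signature is a fixed reference shape scaled by
$A_{heat}(t)$. The synthetic reference is a derivative-of-peak curve
centred on the solvent's main diffraction peak, sign-changing and
integrating to ~0 over the experimental range; no absolute temperature
calibration is attempted, so $A_{heat}$ is reported in reference-curve
units. Its correlation with solute difference shapes is below 0.9 on the
default grid, which keeps the amplitudes separable.

The total isotropic model per delay is

$$\Delta S_0 = A_{iso}\,[A_{GP}\,\Delta S_{0,GP}(\mathbf{R}) +
  (1-A_{GP})\,\Delta S_{0,NG}] + A_{heat}\,\Delta S_{heat},$$

with the solvent-separated species sharing the refined $r_{12}$, at
$r_{23} = 100$ Å and $\alpha = \pi$ (no structural freedom of its own;
its interfragment anisotropy terms are retained but numerically
negligible). The model is exactly linear in the blocks
$(A_{iso}A_{GP},\ A_{iso}(1-A_{GP}),\ A_{heat},\ A_{ani})$.

## Refinement

Each timepoint minimizes

$$\chi^2(\mathbf{x}) + f(\mathbf{x}),\qquad
  \chi^2 = \sum_q \left(\frac{\Delta S_0^{data}-\Delta S_0^{model}}{\sigma_0}\right)^2
         + \sum_q \left(\frac{\Delta S_2^{data}-\Delta S_2^{model}}{\sigma_2}\right)^2,$$

with a quadratic penalty on jumps from the previous delay's optimum,
$f = \lambda \sum_k w_k (x_k - x^{prev}_k)^2$, unit weights on the
natural scales (Å, rad, amplitude). The series is refined in increasing
time order. The first delay of a series precedes (or straddles)
excitation, so its excited-state geometry is unconstrained by data; an
unanchored seven-parameter fit there happily overfits noise and seeds
the whole chain with arbitrary structure. The chain is therefore
anchored by regularizing the first timepoint against the known
pre-excitation reference — ground-state geometry, zero amplitudes —
exactly as later delays are regularized against their predecessor. An
additional parsimony guard applies to unchained single-timepoint fits:
the full model is accepted only if it beats the heating-only reduced
model (excitation amplitude zero, heating amplitude solved in closed
form) by a clear chi-square margin. With $\lambda = 0$ the series
reduces exactly to independent per-timepoint fits (no warm start
either), a property the tests pin down.

Numerical choices:

- **Soft bounds.** The optimizer works in an unconstrained space:
  logistic transforms keep $r_{12} \in (2.45, 4.1)$,
  $r_{23} \in (2.45, 14.2)$, $\alpha \in (0.05, \pi)$ and
  $A_{GP} \in (0,1)$; a softplus keeps $A_{iso} \ge 0$; $A_{heat}$ and
  $A_{ani}$ are free.
- **Multi-start.** 10 minimizations per timepoint from starts drawn
  uniformly in physically feasible ranges; when a previous optimum exists
  the first start warms from it. Nelder–Mead exploration is followed by a
  BFGS polish of the three most promising simplex results (the simplex
  value alone ranks basins unreliably). Lowest objective wins, ties to
  the earliest restart; everything is deterministic given the seed.
- **Regularization factor.** Chosen by an L-curve sweep on the synthetic
  scenario: the total misfit is flat for $\lambda$ between about 3 and
  30 while the trajectory roughness keeps falling, and the misfit rises
  sharply past $\lambda \approx 100$ as the penalty starts dragging the
  fast ballistic rise. The default $\lambda = 30$ takes the smooth end
  of that corner, which also stabilizes the signal-dead delays around
  $t = 0$.
- **Uncertainties.** Per-parameter sensitivity scans: the interval is
  bounded where $\chi^2 + f$ has risen by $\Delta = 1$ above the minimum
  (one-dimensional scan, other parameters held fixed — a deliberate
  simplification that ignores parameter correlations). Directions with no
  crossing inside the scan range are flagged flat; the amplitude of an
  absent species is the canonical case.

Before excitation the geometry coincides with the ground state, the GP
species difference vanishes, and $A_{iso}$ becomes unidentifiable (only
$A_{iso}(1-A_{GP})$ is weakly constrained). The refinement reports
whatever the flat direction yields there; the kinetics estimators
therefore evaluate amplitude-based quantities on post-excitation delays
only.

## Kinetics estimators

- **GP decay.** $A_{iso}(t)A_{GP}(t)$ is fitted by
  $A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$ convolved with the Gaussian
  IRF, evaluated in closed form via the exponentially modified Gaussian,
  so noiseless synthetic curves are recovered exactly; $\tau_1 < \tau_2$
  by output ordering, and a component below 2% of the total amplitude
  collapses the fit to a flagged single exponential.
- **Cage escape.** $P_e = \langle A_{NG} A_{iso}\rangle_{[1,2]\,ps} /
  \max A_{iso}$. The refinement defines $A_{NG}$ as a *fraction* of the
  excited population while the escape probability compares *amounts*, so
  the windowed quantity is the product $A_{NG}A_{iso}$; with $A_{iso}$
  approximately constant over the window the two readings coincide. The
  ratio is invariant under common rescaling of the amplitudes.
- **Speeds.** $v_d$ is the least-squares slope of $r_{23}(t)$ from
  $t = 0$ to the cage-arrest point, identified as the *first local
  maximum* of the displacement within the 2 ps window (above 60% of the
  window maximum) — using the first rather than the global maximum keeps
  slow post-arrest drift out of the slope. The $t = 0$ baseline is the
  known ground-state value, not the refined pre-excitation trace (which
  is unconstrained by data). Individual delays can be excluded (outlier
  handling). The angular speed $\omega$ applies the same estimator to
  $\alpha(t)$ and reports a magnitude.
- **Energy partitioning.** $E_{trans} = \frac12 \mu v_d^2$ with the
  two-body reduced mass $\mu = \frac{2}{3}m_I$ of the I + I2⁻ system;
  $E_{rot} = \frac12 I \omega^2$ with the I2⁻ inertia about its own
  centre, $I = 2 m_I (r_{12}/2)^2$. The translational convention is
  validated against all four published speed/energy pairs; for the
  rotational energy no single rigid-rotor convention reproduces the
  published values from the *rounded* printed speeds, so the own-centre
  convention is adopted and $E_{rot}$ is reported as derived.
- **IRF.** An error-function step (amplitude, baseline, $t_0$, width)
  fitted to the integrated $|\Delta S_0|(t)$ rise, restricted to early
  delays (default $t \le 0.45$ ps) so that population decay and
  structural evolution do not bias the width; widths below half a time
  bin are flagged as unresolved.

## The synthetic-data generator

The generator encodes the reaction scheme as ground truth:
$r_{23}$ rises linearly at `v_true` (default 6.0 Å/ps) from the
ground-state value to the arrest distance (5.5 Å), then relaxes
exponentially (0.7 ps) to the geminate-pair plateau (4.0 Å); $\alpha$
advances at `omega_true` (4.0 rad/ps) until arrest; $r_{12}$ starts
stretched by 0.2 Å (the vibrationally hot nascent I2⁻) and relaxes to
3.15 Å with a 2 ps time constant. Populations follow
$N_{GP} = a_0[a_1 e^{-t/\tau_1} + (1-a_1)e^{-t/\tau_2}]$ (defaults 0.1,
0.7, 0.4 ps, 38 ps) and
$N_{NG} = a_0 P_e (1 - e^{-t/\tau_{NG}})$ ($P_e = 0.38$,
$\tau_{NG} = 0.3$ ps), all convolved analytically with the Gaussian IRF
(0.175 ps fwhm); $A_{iso} = N_{GP} + N_{NG}$ and
$A_{GP} = N_{GP}/A_{iso}$, so the refined GP amplitude product is an
exact IRF-convolved biexponential. The anisotropy amplitude decays
exponentially (rotational dephasing, 2 ps; initial value 0.05, of the
order of the photoselection prefactor after partial dephasing) and the
heating amplitude ramps with a 10 ps energy-release time. Defaults mirror
the acetonitrile regime throughout, so recovered trajectories can be read
against that narrative; they are generator inputs, not claims about any
measurement.

Datasets evaluate the forward model at each delay on the nominal
geometry (amplitude dynamics, not structural coordinates, carry the IRF
broadening) and add seeded Gaussian noise — homoscedastic at a stated
fraction (default 1%) of the peak $|\Delta S_0|$, with a heteroscedastic
option. The default scenario uses $q = 0.5$–$4.5$ Å⁻¹ in steps of 0.02
(201 points) and 41 delays from −0.1 to 500 ps, linear to 1 ps and
logarithmic beyond.

2-d azimuthal patterns are generated and decomposed with the flat-detector
small-angle convention $\cos\theta = \cos\phi$ for vertical polarization
(the exact curvature correction is a sub-percent effect at
$q \le 4.5$ Å⁻¹ and 12 keV): slices carry
$\Delta S_0 + P_2(\cos\phi_k)\Delta S_2$ at 15 azimuth centres, and the
per-$q$ least-squares inversion on the basis $\{1, P_2\}$ is exact for
noiseless input.

What passing the synthetic closure test shows — and what it does not:
the pipeline run end-to-end (simulate → refine → kinetics) recovers the
generating speeds, lifetimes, escape probability and IRF within the
stated tolerances at 1% noise. Because generator and refinement share
the forward model, this validates identifiability, the optimizer, the
regularization and the estimators, but not the physical fidelity of the
forward model itself (form-factor, cage and heating approximations),
which is instead pinned term-by-term against independent quadrature
oracles in the tests.

## Problem sizes and determinism

The shipped study conditions were sized for a desk machine: the default
scenario refines 41 delays × 201 q-points with 10 restarts in a few
minutes on one CPU; the test fixtures use an 81-point q grid and a
5×8×5-node library. All stochastic steps (noise, restarts) draw from
explicitly passed seeds, and repeated runs are bit-identical.

## Data formats

Datasets are stored as a plain-text directory (JSON metadata + TSV
matrices for $q$, $t$, $\Delta S_0$, $\Delta S_2$ and both uncertainty
matrices) written at full double precision, so a write–read roundtrip is
lossless for analysis purposes; single curves export as two-column text
with `#` headers (units: Å⁻¹, ps, electron units per solute molecule).
This self-describing text layout was chosen as the package's native
container; it diffs cleanly under version control and needs no binary
dependencies.

## Known limitations

- The cage term rests on the parametric RDF model; quantitative
  solvent-specific cage sizes require MD-derived RDFs on the same grid
  interface.
- The displaced-volume construction (independent Gaussian spheres per
  atom site) double-counts excluded volume where spheres overlap at small
  $r_{12}$; differences between similar geometries largely cancel this.
- Sensitivity intervals are one-dimensional scans and understate
  uncertainty where parameters are strongly correlated (notably
  $A_{iso}$ with $A_{GP}$ near signal onset).
- The NG species is structure-less by convention; any internal dynamics
  of escaped fragments is absorbed into the GP parameters.
- Single-solute-species model: three-body dissociation channels or
  isomeric intermediates are out of scope.
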