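---
title: "Modelling base-base FRET in nucleic acids: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling base-base FRET in nucleic acids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basefret)
```

## The problem

Fluorescent nucleobase analogues such as the tricyclic cytosines tC^O
(donor) and tC~nitro~ (acceptor) base-pair and stack inside duplex DNA in
place of a natural cytosine. Unlike dyes on flexible linkers, their
transition dipoles have a well-defined position and orientation relative to
the host base pair, so Förster resonance energy transfer (FRET) between two
such probes reports not only on the donor-acceptor distance but also, through
the orientation factor $\kappa^2$, on the local geometry and the nanosecond
rotational dynamics of the bases. `basefret` implements the complete
simulation and analysis chain for such experiments:

1. **Geometry**: all-atom duplex models built from rigid-body base-pair and
   base-pair-step parameters (shift, slide, rise, tilt, roll, twist;
   shear, stretch, stagger, buckle, propeller, opening), using the mid-step
   (CEHS) construction, plus multi-unit models joined by a six-parameter
   kink (translation $v_x, v_y, v_z$ and intrinsic ZXZ Euler angles
   $\alpha, \beta, \gamma$).
2. **Photophysics**: $\kappa$, $R$, the critical distance $R_0$, the
   transfer rate $k_T$ and the efficiency $E$.
3. **Dynamics**: directional distributions of the dipoles sampled from
   Boltzmann densities over physical angular potentials, averaged into
   $\langle\kappa^2\rangle$.
4. **Observables**: time-resolved donor decays convolved with the
   instrument response of a time-correlated single-photon-counting (TCSPC)
   measurement, with Poisson counting statistics.
5. **Inference**: global fits of many donor decays against the forward
   model, with steric/connectivity constraints for kinked-DNA
   reconstruction, $\chi^2$ surfaces and F-statistic confidence intervals.

## Geometry construction

A reference frame is an origin plus a right-handed orthonormal axis set. In
a base-pair frame the y axis runs along the line between the anchor atoms
of the paired bases (strand II toward strand I), z points 5'→3' along
strand I and x completes the set; the origin is the anchor-line midpoint.
Strand-II base frames are the pair frame flipped 180° about x, so each
base's own z axis follows its strand's 5'→3' sense.

Successive pair frames are related by the mid-step construction: the
tilt/roll pair acts as one rotation of magnitude $\Gamma=\sqrt{\tau^2+\rho^2}$
about a hinge in the mid-step frame at phase $\phi=\mathrm{atan2}(\tau,\rho)$
from the roll axis, twist is split symmetrically about the mid-step frame,
and (shift, slide, rise) is applied along the mid-step axes.
`transform_to_step()` inverts the construction exactly (round trips to
1e-8 over the full ±5 Å / ±60° range; frames re-orthonormalized against
drift, which stays below 1e-8 over 1000 chained steps).

Two units joined by a kink: unit 2 is expressed in its own first-pair
frame, rotated by $R_z(\alpha)R_x(\beta)R_z(\gamma)$, translated by
$(v_x,v_y,v_z)$, and mapped through the last pair frame of unit 1. The
order makes $\beta$ alone the bend angle between the two helix axes, and at
$\beta=0$ only the sum $\alpha+\gamma$ matters — the degeneracy that shapes
the fitting strategy below. Expressing the native B-form step as a kink
(`step_as_kink()`) reproduces a continuous duplex to numerical precision,
and joining is associative, so chains of units are unrestricted.

Helix presets are fiber-model averages (B-form: rise 3.38 Å, twist 36°;
A-form: slide −1.48 Å, rise 2.81 Å, roll 8.6°, twist 32.7°), shipped as
editable defaults; per-structure tables are exchanged through the `.par`
dialect (`read_par()`/`write_par()`).

### Residue and probe templates

The shipped atom templates are *idealized synthetic* planar rings built
from regular polygon geometry, anchored so the pair-frame origin is the
anchor-atom midpoint. They are deliberately simple: the FRET arithmetic
needs only the dipole centers and directions, with atoms used for PDB
export (visual inspection) and steric screening. The sugar-phosphate
backbone is omitted by default. Real template sets can be dropped in as
plain-text files (`read_template()`, `register_probe()`); the registry, not
any hard-coded geometry, is the contract.

The probes' transition-dipole geometry within the base frame is not
publicly tabulated, so the shipped values are documented placeholders
chosen on two grounds: (i) physical plausibility — the dipole runs roughly
along the long axis of the tricyclic framework (in-plane angles −60°/−25°
from the pair y axis for tC^O/tC~nitro~), centered mid-framework (1.5 Å
and 3.0 Å from the base-frame origin); and (ii) scientific adequacy — a
fully symmetric placeholder (both dipoles along y, centers at the origin)
creates artificial degeneracies (an exact donor/acceptor bend-angle swap
symmetry, and near-degenerate kink manifolds) that the real probe geometry
does not have and that would misrepresent what the method can resolve.
Users with measured dipole data should override these defaults.

The out-of-plane bend $\phi_b$ rotates the dipole about the in-plane axis
perpendicular to it, so the bent dipole makes exactly $\phi_b$ with the
base plane, positive toward the host strand's 3' side on either strand.

## Dipole dynamics

Each probe's orientation wobbles during energy transfer. Two independent
1D Boltzmann densities describe it: the in-plane angle $\theta$
(hydrogen-bonding mode, 12-6 Lennard-Jones potential with dissociation
energy 0.1 eV by default — an average C–G hydrogen-bond energy — evaluated
along $r(\theta) = r_{eq} + s\,\theta$, which gives the steep-compression /
soft-stretch asymmetry of a hydrogen bond) and the out-of-plane angle
$\phi$ (base-stacking mode, harmonic, hence Gaussian). Both are
parameterized by the FWHM of the resulting angular density; `calibrate_width()`
solves for the potential length scale by bisection (0.5% accuracy). The
in-plane domain is truncated at ±60° (the Lennard-Jones density has a
dissociation plateau of about $e^{-D/k_BT}$ and is normalizable only on a
bounded domain). Default temperature: 295 K.

Samples are drawn independently for $\theta$ and $\phi$ by inverse-CDF on
the gridded densities, then mapped to unit vectors
$\cos\phi\cos\theta\,\hat e_1 + \cos\phi\sin\theta\,\hat e_2 +
\sin\phi\,\hat e_3$ with $\hat e_1$ the resolved dipole direction — the
distribution mode sits on the dipole and nothing piles up at the sphere
poles. A guard refuses out-of-plane densities with mass beyond
$|\phi| = 85°$ rather than distorting them.

$\langle\kappa^2\rangle$ is the arithmetic mean of $\kappa^2$ over all
$N_D \times N_A$ ordered sample pairs ($10^6$ combinations at the default
$N = 1000$), evaluated exactly through the second-moment matrices
$S = N^{-1}\sum \hat\mu\hat\mu^{\mathsf T}$:
$\langle\kappa^2\rangle = \mathrm{tr}(S_D S_A) - 6\,\hat R^{\mathsf T} S_D
S_A \hat R + 9 (\hat R^{\mathsf T} S_D \hat R)(\hat R^{\mathsf T} S_A \hat
R)$, an algebraic identity with the pairwise sum (verified against the
brute-force oracle in the tests). The spread of
$\langle\kappa^2\rangle$ across seeds at $N=1000$ stays below 0.1.

## Decays and goodness of fit

In the dynamic averaging regime a coupled donor decays as
$\exp(-t/\tau_D - k_T t)$ with a single rate
$k_T = \tfrac{3}{2}\langle\kappa^2\rangle \tau_D^{-1} (R_0/R)^6$, where
$R_0$ carries the isotropic average ($R_0^6 = 8.79\times10^{-5}\cdot
\tfrac23\,\Phi_D J \eta^{-4}$, Å and M$^{-1}$cm$^{-1}$nm$^4$), so
$E = 0.5$ at $R = R_0$. Only orientational fluctuations are modelled;
distance (translational) fluctuation of the rigidly stacked probes is
neglected. The total decay adds the uncoupled-donor fraction $(1-a)$ and a
non-donor component $(1-b)$ with lifetime $\tau_2$:
$I(t) = I_0\{b[a\,e^{-t/\tau_D - k_T t} + (1-a)e^{-t/\tau_D}] +
(1-b)e^{-t/\tau_2}\}$.

Model curves are convolved with the unit-normalized instrument response by
FFT (equal to the direct sum to 1e-9 relative). Goodness of fit is the
reduced $\chi^2$ with Poisson weights $1/\max(I_m, 1)$ and denominator
$n - p$. Because measured-count weights are increasingly biased in sparse
channels, the default fit range runs from 0.5 ns before the IRF peak to the
last channel with at least 30 counts; with that convention $\chi^2_r$ on
Poisson data drawn from the true model is $1.00 \pm 0.10$. Per-curve
amplitudes are profiled analytically (weighted least squares) rather than
searched.

## Global fitting

`fit_spec()` bundles curves, geometries, free parameters with bounds, fixed
values, constraints and seeds; `global_chi2()` pools Poisson-weighted
residuals over all curves. Objective evaluations reuse fixed per-curve
uniform draws mapped through the current densities, so the objective is
deterministic given the spec and varies continuously with the width
parameters.

Strategy dispatch (`fit_parameters()`):

* **Sampling-stage parameters** ($\theta$/$\phi$-FWHM, bend angles): the
  sampling step makes the objective non-differentiable, so a compass
  pattern search is used, multistarted from a latin-hypercube prescreen,
  with an explicit donor/acceptor bend-exchange restart ($\kappa^2$ is
  invariant under exchanging the two dipoles, so a swapped near-twin basin
  always exists). The objective is averaged over several independent
  samplings (4 by default for the study-1 layout) — the same
  repetition-averaging used for $\chi^2$ surfaces — which stabilizes the
  minimum location against sampling scatter.
* **Kink parameters**: a staged global search — latin-hypercube prescreen;
  a *planar stage* scanning the twist sum on the $\beta=0$ family (where
  $\alpha+\gamma$ is the only angle and the landscape is exactly
  180°-periodic, so only one period is scanned) with the translation
  fitted at each node; a *bent-kink stage* seeding a coarse
  ($\beta$, $\alpha+\gamma$, $\alpha-\gamma$) Euler grid the same way;
  pattern refinement of the candidates, simplex polish, constraint-aware
  simulated annealing, bounded quasi-Newton refinement, a polish in rotated
  $(\alpha+\gamma, \alpha-\gamma)$ coordinates (the $\chi^2$ valley runs
  along the sum), and a final polish against the sampling-averaged
  objective.
* **Smooth nuisance parameters**: bounded quasi-Newton directly.

Geometries violating the constraints — any inter-unit atom pair closer
than twice the 1.3 Å van der Waals radius, or neighboring same-strand
base origins further than 11 Å apart (the covalent-linker limit) — are
rejected with a sentinel that optimizers treat as a large penalty and
surfaces leave blank. All inter-unit atom pairs are checked, including the
junction-flanking residues: a kink that collapses unit 2 onto unit 1 must
fail, while a regular B-form continuation passes (stacked neighbors are a
full rise, 3.38 Å, apart).

Confidence intervals follow the F-statistic criterion at $P = 0.05$:
the interval is where $\chi^2_r \le \chi^2_{min}\,[1 + \tfrac{p}{n-p}
F_{0.95}(p, n-p)]$ with the other free parameters re-optimized, located by
outward march and bisection; ends clipped by the bounds are flagged
open-ended. $\chi^2$ surfaces (`map_chi2_surface()`) average repeated
samplings per grid point with per-repetition seeds and keep the raw matrix.

At $\beta \approx 0$ fits report the identifiable combination
$\alpha+\gamma$; the 180° branch can be resolved by an optional preference
window on $\alpha+\gamma$ (off by default), expressing the prior that DNA
bending follows the right-handed helical twist ($\alpha+\gamma \approx
55°$ for the bent bulge).

## Synthetic demonstration studies

`study_fixture()` generates the two study designs as self-contained
datasets (TCSPC acquisition: 2048 channels, 100 ns window, 60 ps FWHM
Gaussian IRF, $10^4$ expected peak counts, Poisson noise; donor lifetime
4.3 ns and $R_0 = 27$ Å, representative tC^O/tC~nitro~ values; coupled
fraction 0.95, donor fraction 0.98, $\tau_2 = 1$ ns):

* **study1** — B-form duplex, nine donor-acceptor separations of 5–13
  base pairs (donor fixed, acceptor stepped along the complementary
  strand). Generating parameters: $\theta$-FWHM 13.1°, $\phi$-FWHM 2°,
  $\phi_b$ 8.2° (donor) and 25° (acceptor). Free parameters in the fit:
  those four.
* **study2_0A / study2_3A** — two 10-mer units joined by a kink placed at
  two alternative sequence positions (one kink per sample, both positions
  sharing one parameter set), donors and acceptors flanking the junction
  at 2–4 pairs on either side: 18 combinations (0A) and 16 (3A, one
  combination fewer per position). Generating kinks: the unbent control
  $v = (-0.55, -1.1, 3.3)$ Å, $\alpha = 15°, \beta = 1°, \gamma = 16°$,
  and the bent bulge $v = (7.4, -0.55, 5.5)$ Å, $\alpha = 101°,
  \beta = 57°, \gamma = -43°$. Free parameters: the six kink parameters,
  with the study-1 dynamics fixed as prior knowledge.

The generator samples the dipole ensemble densely ($N_{gen} = 20000$)
because measured decays reflect the physical orientational ensemble, not
the analysis' Monte-Carlo noise; the analysis side uses $N = 1000$.
Sequence motifs are synthetic (guanine hosts at acceptor positions);
analysis-side sampling seeds differ from generation-side ones, so fits
never see the generator's draws.

What passing recoveries do and do not show: they demonstrate that the
forward model is internally consistent and that the search machinery finds
the generating parameters under realistic counting statistics and sampling
noise. They do not validate the idealized probe templates against real tC
photophysics, nor the behaviour of the model under real-world artifacts
(IRF drift, background, acceptor emission bleed-through, heterogeneous
labelling), none of which the generator emulates.

Typical problem sizes used throughout the package's own tests and scripts:
single-parameter demonstrations use 3 curves x 512 channels with N = 300;
the full study fits use the complete layouts above. A study-1 fit takes
about two minutes and a study-2 fit a few minutes on one core.

## Numerical choices and edge cases

* Angles are degrees at every interface, radians internally; twist and
  Euler angles wrap to (−180°, 180°], $\beta \in [0°, 180°]$.
* The mid-step hinge phase resolves $\mathrm{atan2}(0, 0) = 0$ at
  tilt = roll = 0.
* Frames are re-orthonormalized (Gram-Schmidt) whenever numerical drift
  exceeds 1e-12.
* A boundary parameter fitted near its bound (the bend $\beta$ of an
  essentially unbent junction) folds its noise upward; point estimates a
  degree or two above zero with confidence intervals reaching 0 are the
  expected behaviour, and the interval, not the point, carries the
  scientific conclusion.
* The equal-channel-spacing contract is enforced on decay curves; the IRF
  and decay must share one grid (the optional fitted channel shift
  defaults to 0 and a baseline/dark-count term is deliberately omitted).
* Empty dipole sets, zero donor-acceptor separation and non-orthonormal
  rotations raise immediate errors rather than propagating NaNs.

## Known limitations

* Atom templates and probe dipole parameters are idealized placeholders
  (exact tC coordinates are not publicly tabulated); steric screening
  inherits their footprint.
* Distance fluctuations and acceptor-side decays are out of scope;
  $J$ is an input, never computed from spectra.
* The kink search is a global optimization over a rugged 6-D landscape;
  pathological data can still trap it in a local basin even with the
  staged strategy. Inspect `glance()`, the per-curve $\chi^2_r$ and a
  surface scan around the optimum before trusting a reconstruction.
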