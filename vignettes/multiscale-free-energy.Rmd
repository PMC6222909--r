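---
title: "Desk-scale alchemical and multi-scale free-energy calculations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale alchemical and multi-scale free-energy calculations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

`alchemr` implements the machinery of hydration free-energy calculation by
staged alchemical annihilation, and of *multi-scale* ("bookend") corrections
that carry a free energy computed under one Hamiltonian (an inexpensive
molecular-mechanics force field, MM) to another (an expensive target
Hamiltonian that in production work would be a quantum-chemical method).
Everything runs at desk scale on toy systems whose statistical mechanics is
known in closed form, so every stage of the pipeline can be validated against
quadrature or analytic results rather than against other simulation codes.

The hydration free energy is obtained from a thermodynamic cycle: the solute
is annihilated (its nonbonded interactions switched off) once in the gas
phase and once in solution,

$$\Delta G_\mathrm{hyd} = \Delta G_\mathrm{annih}(\mathrm{gas})
  - \Delta G_\mathrm{annih}(\mathrm{aq}).$$

Annihilation is staged: the solute charges are scaled to zero first
($\Delta G_\mathrm{char}$, coupling parameter $\lambda_\mathrm{elec}$), then
the van der Waals interactions are removed through a soft-core potential
($\Delta G_\mathrm{vdw}$, $\lambda_\mathrm{vdw}$).  The staging constraint
$\lambda_\mathrm{vdw} > 0 \Rightarrow \lambda_\mathrm{elec} = 1$ is enforced
by `alchemical_state()`: bare charges inside a decaying repulsive core are
never sampled.

## The energy model and its conventions

Units are fixed package-wide: angstrom, kcal/mol, elementary charges,
Kelvin, with $k_e = 332.0716$ kcal·Å/(mol·e²) and
$k_B = 0.0019872041$ kcal/(mol·K).

* **Bonded terms** use the force-field convention $K(x - x_0)^2$ *without*
  the 1/2 prefactor, for both bonds and angles.  Surrogate targets may
  replace harmonic bonds by a Morse well $D(1 - e^{-a(b-b_0)})^2$ with
  $a = \sqrt{K/D}$, which matches the harmonic curvature at the minimum but
  introduces the anharmonicity that makes reweighting between levels
  nontrivial.
* **Lennard-Jones** interactions use Lorentz–Berthelot combining and a cubic
  switching function that is exactly 1 up to `r_on` and exactly 0 beyond
  `r_off`.  Sampling evaluations on periodic systems default to
  `r_on = 0.35·edge`, `r_off = 0.45·edge` (the box-scaled analog of a
  10–12 Å switch in a ~37 Å cell); bookend evaluations use no cutoff and no
  switching.
* **Soft core**: with $\lambda = \lambda_\mathrm{vdw}$,
  $\sigma = R_\mathrm{min}/2^{1/6}$ and
  $u = \sigma^2/(r^2 + \delta\lambda\sigma^2)$, the pair energy is
  $(1-\lambda)\,4\varepsilon(u^6 - u^3)$.  The form is finite at $r = 0$
  whenever $\lambda > 0$, reduces exactly to plain LJ at $\lambda = 0$ and
  vanishes at $\lambda = 1$.  The shift parameter defaults to
  $\delta = 0.5$, the standard separation-shifted choice; it is recorded in
  every result file because reference implementations differ in this
  default.
* **Electrostatics** are plain Coulomb sums over non-excluded charge-site
  pairs, minimum-image when periodic, never switched.  Ewald summation is
  deliberately out of scope at desk scale; minimum-image-only periodic
  electrostatics is a stated limitation.
* **Drude polarizability.**  A polarizable site carries an auxiliary charge
  $q_D = -\sqrt{\alpha k_D}$ on a spring.  The spring self-energy is
  $\tfrac12 k_D d^2$ — note the 1/2, unlike the bonded terms — because that
  is the convention under which the textbook identities
  $\alpha = q_D^2/k_D$, $d^\ast = q_D E/k_D$ and
  $\mu_\mathrm{ind} = \alpha E$ hold exactly, and those identities are the
  package's acceptance checks for the Drude model.  With the package's
  Coulomb convention, $\alpha$ carries units of e²·Å²·mol/kcal; the toy
  solvent value 0.003 corresponds to roughly 1 Å³ after multiplying by
  $k_e$, a realistic water-like polarizability with $q_D \approx -1.7$ e.
* **Smoothness of the periodic Drude energy.**  For a charge-site pair the
  periodic image is chosen from the *core–core* separation, and Drude
  displacements are added afterwards.  Choosing the image from the
  displaced site positions instead makes the energy discontinuous in $d$
  whenever a pair sits near half the box edge, and the self-consistent
  relaxation then oscillates across the discontinuity without converging.
  Fixing the image at the cores keeps the energy smooth in $d$ at the cost
  of an $O(d/L)$ inconsistency far inside the box, which is negligible for
  $|d| \sim 0.1$ Å.

## Samplers

The primary sampler is single-particle-move Metropolis Monte Carlo: it has
the exact stationary distribution, which is what the acceptance tests
require.  A BAOAB Langevin integrator is provided for parity with
dynamics-based workflows but is approximate at finite timestep and is tested
only against generous sanity bands.

Two Drude handling modes mirror the two regimes of polarizable simulation:
`scf_each_step` relaxes the Drude particles to the energy minimum before
every energy evaluation (the cold-Drude/self-consistent limit), while
`lagged` applies a single damped relaxation step per move, so the particles
trail the minimum the way thermostatted extended-Lagrangian dynamics does.
The dual-thermostat machinery itself is out of scope; the *contrast* between
the two regimes is the scientifically relevant content.

Drude relaxation is a damped successive-substitution iteration
($d \leftarrow d - \gamma\, \nabla_d U / k_D$, damping $\gamma = 0.5$,
tolerance $10^{-8}$ kcal/mol/Å on the gradient, 500-iteration cap) rather
than conjugate gradient: it converges to the same fixed point, is trivially
testable against the linear-response closed form, and raises a
polarization-catastrophe error if the energy ever increases along the
iteration.  An optional radius restricts relaxation to Drude sites near the
solute, the post-processing optimization used when only the solute's
environment responds; whether that radius should scale with the box is left
as a configuration knob.

## Replica exchange and the λ schedules

`make_lambda_schedule()` returns the published annihilation grids: charge
stage `0, 0.20, 0.55, 1` (fixed-charge family) and
`0, 0.10, 0.25, 0.5, 0.75, 1` (Drude family); van der Waals stage
`0, 0.15, 0.30, 0.45, 0.60, 0.75, 0.87, 0.96, 1` and the 11-point uniform
grid.  (The four-state charge grid is sometimes described as "three steps" —
three intervals between four states; the operation returns the four printed
states.)  `lambda_schedule()` builds custom desk-scale grids.

Neighbouring λ states attempt swaps with the standard criterion
$\min\{1, e^{-\beta[U_i(x_j) + U_j(x_i) - U_i(x_i) - U_j(x_j)]}\}$,
alternating even/odd pairs each sweep.  Every energy entering a swap
decision is logged, and the replica-to-state assignment is asserted to stay
a bijection.  Each (repeat, window) pair owns an independent RNG stream
(seeded `seed + 1000·repeat + window`, with saved/restored generator
states), and exchange decisions draw from a separate per-repeat stream, so
repeats are reproducible and independent.

Free energies per window come from Bennett's acceptance ratio; stage totals
and the mean ± sample standard deviation over four repeats (the default)
are reported, mirroring the repeat-based uncertainty protocol.  Per-repeat
BAR uncertainties are intentionally not reported; effective sample sizes
carry the per-window diagnostics instead.

## Estimators

All exponential averages run through log-sum-exp with max-subtraction, so
$|\beta\Delta U|$ up to several hundred — the poor-overlap regime that is
the whole point of multi-scale corrections — cannot overflow.

* **Zwanzig (EXP/FEP)**:
  $\Delta G = -\beta^{-1}\ln\langle e^{-\beta \Delta U_f}\rangle$.
* **BAR** solves, with $M = \ln(n_f/n_r)$,
  $$\sum_f \left[1 + e^{\beta(\Delta U_f - C) + M}\right]^{-1}
    = \sum_r \left[1 + e^{\beta(\Delta U_r + C) - M}\right]^{-1},
    \qquad \Delta G = C,$$
  by bisection on the monotone objective, bracketed by the two one-sided
  exponential estimates widened by 50 kcal/mol (with automatic expansion,
  and an overlap-diagnostic error if no bracket exists).  Bisection rather
  than Newton: guaranteed convergence on a monotone function.
* **NBB** is the same self-consistent equation with each sample weighted by
  a normalized $w_i \propto e^{+\beta b_i}$, where $b = U_\mathrm{sampling}
  - U_\mathrm{target}$ is the bias of the non-Boltzmann state the frame was
  actually drawn from.  With all biases zero it reduces to BAR exactly
  (asserted to $10^{-12}$), and on 1-dof systems it is tested against
  deterministic quadrature of both partition functions; those two
  properties, not any particular reference implementation, define
  correctness of the weighting.  Sides whose weights collapse
  (ESS < 2) are refused with diagnostics.

Overlap diagnostics report $\mathrm{ESS} = (\sum w)^2/\sum w^2$ of the
exponential weights and the gap between the two one-sided estimates.

## Bookend corrections and the component selection

A bookend correction evaluates $\Delta U = U_B - U_A$ between Hamiltonian
levels on frames from the physical end points, and carries only the
components that do not cancel between levels sharing the same solvent
model: solute–solute nonbonded, solute bonded, and *electrostatic*
solute–solvent interactions.  Solvent–solvent terms and solute–solvent vdW
terms are identical at both levels, so omitting them changes nothing while
keeping long-range electrostatics in the difference.  Bookend evaluations
use full minimum-image sums with no cutoff, after recentring the box on the
solute (`recenter()` wraps solvent molecules whole and leaves minimum-image
energies invariant — both asserted).

Three routes connect MM to the target:

(a) **direct** — one-sided Zwanzig from the MM ensemble;
(b) **via MM′** — BAR between MM and a tailored force field MM′, plus
    Zwanzig from the MM′ ensemble to the target;
(c) **NBB** — both ensembles combined, the MM′ frames reweighted by their
    bias against the target.

The three are theoretically equivalent; they differ in variance according
to which overlap each exploits.  When the MM′–target overlap dominates, the
NBB answer sits numerically closest to route (b) — asserted as a 10-repeat
median property.

## The tailored force field (MM′)

`make_tailored_parameters()` implements the tailoring procedure: minimize
the target Hamiltonian's gas-phase geometry (BFGS with analytic gradients,
convergence at gradient infinity norm ≤ 10⁻⁶ kcal/mol/Å; an unconverged
geometry is *refused*), give every atom its own unique type, set every
bond's $b_0$ and angle's $\theta_0$ to the values measured in that
geometry, and copy charges, LJ parameters, polarizabilities and force
constants unchanged from the base types.  Copying the force constants is a
deliberate, literal reading of the procedure and its main limitation: only
the equilibrium values are adapted.  The toy model family has no dihedrals,
so tailoring covers bonds and angles exactly.  Tailored models serialize
with a provenance block and round-trip bit-for-bit through the package's
text schema.

## What the synthetic systems emulate — and what they do not

The generator builds three kinds of objects:

* **toy solutes** (`build_solute()`): small bonded clusters with per-atom
  charges and LJ parameters, one unique type per atom, all 1–2/1–3 pairs
  excluded;
* **toy solvent boxes** (`build_solvent_box()`): a water-like rigid-by-
  stiff-springs 3-site model (b₀ = 1 Å, θ₀ = 104.52°, charges −0.8/+0.4)
  on a jittered lattice, optionally with a Drude site on the heavy atom.
  Rigidity by stiff springs replaces constraint algorithms, which are out
  of scope;
* **surrogate targets** (`make_surrogate_target()`): the base model with
  shifted equilibrium geometry, scaled charges and optionally Morse bonds.
  The surrogate plays the role of the high-level Hamiltonian: a displaced
  energy minimum is exactly the pathology that degrades Hamiltonian
  reweighting in production work, where an MM bond minimum can sit several
  tenths of an ångström from the target method's minimum.

The headline surrogate uses a **+0.36 Å bond shift** on a deliberately soft
bond ($k_b = 10$ kcal/mol/Å², $b_0 = 1.153$ Å).  The choice is overlap
arithmetic, made when the toy family was designed: at 300 K the bond-length
standard deviation is $\sigma_b = \sqrt{1/(2\beta k_b)} \approx 0.17$ Å, so
the shift is ≈ 2.1 σ — large enough that the direct one-sided route is
visibly ill-conditioned (forward ESS collapses to a few percent of the
sample count), yet small enough that two-sided estimation converges at the
2000-samples-per-repeat scale the test suite can afford.  With a stiff
chemical bond ($k_b \sim 300$) the same shift is ≈ 12 σ and *no* desk-scale
estimator converges — which is faithful to the production-scale pathology
but useless for a quantitative test.  For the variance-reduction property
the surrogate additionally uses Morse bonds (depth 50 kcal/mol), so that
MM′ matches the target's minimum but not its exact shape and the
MM′ → target reweighting stays nontrivial.

None of this emulates real water models, real force-field parameter
libraries, Ewald electrostatics, constant-pressure ensembles or the
chemical realism of actual solutes.  Passing tests demonstrate that the
*machinery* — samplers, estimators, cycles, tailoring — is correct against
closed-form statistical mechanics, not that any particular molecule's
hydration free energy is reproduced; the printed reference values at
production scale are recomputed only at the level of their summary metrics
from the packaged tables.

## Numerical choices and degenerate inputs

* Bisection bracket for Bennett solves: the two one-sided estimates
  ± 50 kcal/mol, expanded by 100 up to eight times before giving up with
  overlap diagnostics.
* Root tolerance 10⁻⁸ kcal/mol; Drude gradient tolerance 10⁻⁸ kcal/mol/Å;
  minimizer gradient tolerance 10⁻⁶ kcal/mol/Å.
* Included pairs closer than 10⁻⁶ Å raise an overlap error in the
  singular (plain LJ, Coulomb) paths; the soft-core path is finite at
  $r = 0$ for $\lambda > 0$ by construction.
* Angle gradients guard $\sin\theta$ at 10⁻¹⁰; angle parameters are
  restricted to $0 < \theta_0 < \pi$.
* A zero-width MC proposal is accepted with probability 1 (the degenerate
  move contract).  A non-finite starting energy aborts sampling
  immediately.
* The aggregate standard deviation uses the sample (n−1) convention; a
  single repeat reports SD 0.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's own desk-scale study conditions: estimator oracle
checks at 10⁵ total samples (5 repeats × 2×10⁴); the λ-interpolated
harmonic leg at 4 repeats × 4 windows × 10³ saved samples; replica-exchange
acceptance over 10⁴ sweeps; tailoring properties at 10 repeats × 2000
saved frames; machine-precision identities (NBB = BAR, linear response)
at 50 random instances.  Statistical assertions use three standard errors
estimated from independent repeats.

## Known limitations

Minimum-image-only electrostatics (no Ewald); no pressure coupling or
virials; no Thole screening, charge transfer or many-body exchange in the
polarizable model; Langevin sampling is approximate at finite timestep;
tailoring adapts equilibrium values only, not force constants or charges
(re-optimizing vdW parameters against the target is explicitly future
work); the recomputed summary metrics are the arbiter where a printed
summary sentence and a printed column disagree (the Drude-column RMSD of
the packaged hydration table recomputes to 0.53 kcal/mol).
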