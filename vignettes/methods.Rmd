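---
title: "Models and methods in cgfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cgfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgfret)
```

`cgfret` integrates two views of a protein with intrinsically
disordered regions (IDRs): single-molecule FRET spectroscopy, which
measures distances and dynamics of the chain in solution, and
coarse-grained (CG) Langevin dynamics, which produces explicit
conformational ensembles.  The package implements the full analysis
path on both sides and the loop that reconciles them — back-calculated
FRET efficiencies from simulation are compared with measured ones and
a single interaction-strength parameter is refined.  This vignette
explains the models, the defaults, and the choices made where the
design was genuinely open.

## The SAW-$\nu$ polymer model

A disordered chain segment between two fluorophores samples a
distribution of inter-dye distances $r$.  We describe it with a
self-avoiding-walk density with a variable scaling exponent $\nu$:

$$P(r) = A\,\frac{4\pi}{R}\left(\frac{r}{R}\right)^{2+(\gamma-1)/\nu}
  \exp\!\left(-\alpha\left(\frac{r}{R}\right)^{1/(1-\nu)}\right),$$

with critical exponent $\gamma \approx 1.1615$ and $R =
\sqrt{\langle r^2\rangle}$ the root-mean-square inter-dye distance.
The two constants are fixed by normalisation and the second-moment
constraint.  Writing $p = 2+(\gamma-1)/\nu$ and $q = 1/(1-\nu)$, both
integrals are Gamma functions, so

$$\alpha = \left[\frac{\Gamma((p+3)/q)}{\Gamma((p+1)/q)}\right]^{q/2},
\qquad
A = \frac{q\,\alpha^{(p+1)/q}}{4\pi\,\Gamma((p+1)/q)}.$$

We use these closed forms (evaluated on the log scale for stability)
rather than numerical root finding; the unit tests verify both
constraints by quadrature to $10^{-6}$ for a grid of $(R, \nu)$.

The measured mean transfer efficiency relates to $P(r)$ through the
Foerster curve $E(r) = 1/(1+r^6/R_0^6)$ (with $R_0 = 6.0$ nm for the
Cy3B/CF660R pair):

$$\langle E\rangle = \int_0^\infty E(r)\,P(r)\,dr.$$

`invert_efficiency()` solves this transcendental equation for $R$
after eliminating $\nu$ with the scaling closure $R = b N^\nu$, i.e.
$\nu = \ln(R/b)/\ln N$, where $N$ is the number of monomers between
the fluorophores and $b \approx 0.55$ nm for polypeptides.  The
forward map is strictly decreasing in $R$, so the root is unique; we
bracket it on $(b N^{0.02}, b N^{0.98})$ (keeping $\nu$ inside its
valid range) and use Brent's method to an $R$ tolerance of $10^{-9}$
nm, with the mean-efficiency integral evaluated by adaptive quadrature
split at the density peak.

A note on the closure: with $b = 0.55$ nm and $N = 195$, an observed
$\langle E\rangle = 0.43$ at $R_0 = 6$ nm inverts to $R \approx 7.5$
nm and hence $\nu = \ln(R/b)/\ln N \approx 0.50$.  A scaling exponent
of $0.57$ for the same chain would require $b \approx 0.38$ nm.  Both
conventions appear in the polymer-FRET literature; `b` is therefore an
explicit argument of `scaling_closure()` rather than a constant.

Two derived quantities complete the module: the radius of gyration
$R_g \approx R\sqrt{\gamma(\gamma+1)/(2(\gamma+2\nu)(\gamma+2\nu+1))}$
and the relative donor lifetime
$\langle\tau_{DA}\rangle/\tau_D = 1-\langle E\rangle +
\sigma^2/(1-\langle E\rangle)$ with $\sigma^2$ the variance of $E(r)$
over $P(r)$.  A static distance lies on the diagonal
$1-\langle E\rangle$; chain dynamics push points above it, which is
the diagnostic used in efficiency-versus-lifetime maps.

## Photon streams, bursts, and filters

Photon streams are tables of arrival time, detection channel,
excitation branch (pulsed interleaved excitation, 40 MHz) and
microtime.  Burst search combines consecutive photons separated by
less than 100 µs; the minimum burst size is a configuration parameter
(default 50 photons) since no universal value exists.  Per burst we
compute

* $E = n'_A/(n'_A + n'_D)$ from corrected counts, where the
  corrections remove background (per-channel rates times burst
  duration), donor-to-acceptor crosstalk, direct acceptor excitation,
  and apply the detection-efficiency/quantum-yield factor $\gamma$ to
  the donor counts;
* the PIE stoichiometry
  $S = (n_D^D + n_A^D)/(n_D^D + n_A^D + n_A^A)$ from
  background-corrected counts, used to reject donor-only ($S \to 1$)
  and acceptor-only ($S \to 0$) molecules with the usual window
  $S \in [0.3, 0.7]$;
* the mean donor microtime, a per-burst lifetime estimator (a delta
  instrument response is assumed throughout; only the mean detection
  time enters the lifetime ratio, so IRF deconvolution is not
  needed).

Two further filters mirror standard practice: bursts overlapping 1-s
bins whose photon count exceeds three times the mean binned signal are
discarded as aggregates, and bursts whose acceptor bleaches in transit
are removed by an efficiency-drift test — the burst is split in half
by photon index and rejected when the two halves' raw acceptor
fractions differ by more than 0.3 (applied to bursts with at least 20
photons).  The drift test is a practical proxy for more elaborate
bleach detection; its thresholds are configurable.

Efficiency histograms (40 bins over $[-0.1, 1.1]$ by default) are
fitted with sums of Gaussian or log-normal peaks by least squares;
several histograms can be fitted globally with shared means/widths
while the areas stay free, which is how bound/unbound fractions are
extracted in titrations ($\theta$ = bound area over total).

## nsFCS and the reconfiguration time

`correlate()` computes photon-pair correlations directly from
timestamps on a uniform lag grid (1 ns bins over ±1 µs for nsFCS),
cross-correlating distinct detectors.  The curve can be returned
mean-subtracted (the $\delta n$ definition, baseline 0) or as the raw
intensity ratio (baseline 1); the multiplicative nsFCS model

$$g(\tau) = a\,(1 - c_{ab} e^{-|\tau|/\tau_{ab}})
           (1 + c_{cd} e^{-|\tau|/\tau_{cd}})$$

describes the ratio form, with antibunching (ab) and chain-dynamics
(cd) components; for donor–acceptor cross-correlations the cd term is
anti-correlated ($c_{cd} < 0$).  Fits use Levenberg–Marquardt with
bound constraints and flag near-degenerate $\tau_{ab} \approx
\tau_{cd}$ solutions.

The chain-dynamics time converts to the chain reconfiguration time
$\tau_r$ by modelling the inter-dye distance as overdamped diffusion
on the potential of mean force $-k_BT\ln P(r)$ of the SAW-$\nu$
density.  We discretise the 1-D Smoluchowski operator as a
nearest-neighbour hopping chain obeying detailed balance
($w_{i\to i+1} \propto \sqrt{P_{i+1}/P_i}$), diagonalise the
symmetrised generator, and compute integral relaxation times
$\tau_f = \sum_k a_k^2/\lambda_k / \sum_k a_k^2$ for an observable
$f$.  Since every relaxation time scales as $1/D$, matching the
measured $\tau_{cd}$ to the relaxation of $E(r(t))$ fixes $D$ in
closed form, and

$$\tau_r = \tau_{cd}\,\frac{\tau_r^{(D=1)}}{\tau_E^{(D=1)}}$$

is exact within the model.  The discretisation reproduces the
Ornstein–Uhlenbeck limit ($\tau = \sigma^2/D$ for a Gaussian $P$) to
2% with 400 grid points, and a full synthetic chain — Brownian
dynamics on the PMF emitting photons, correlation, fit, conversion —
recovers the model $\tau_r$ within 20%.

## Titration estimators

All fits are (weighted) nonlinear least squares via `minpack.lm`, with
standard errors from the Jacobian covariance and t-based 95% intervals.

* Weak denaturant binding:
  $E(c_D) = (E_0 + \Delta E K_a c_D)/(1 + K_a c_D)$.  As written,
  $\Delta E$ is the saturating value of the observable (asymptote
  convention), and $E_0$ the zero-denaturant value.
* 1:1 binding isotherm: the mass-action quadratic for the bound
  fraction of the species held at fixed total concentration.  The
  physical branch is the minus root
  $\theta = \big(c_X + K_D + c_Y - \sqrt{(c_X+K_D+c_Y)^2 -
  4c_Xc_Y}\big)/2c_Y$; the plus root exceeds 1 for generic inputs.
  The implementation is cross-checked in tests against a brute-force
  numerical equilibrium solve.
* NMR shift titration: the same quadratic form scaled by
  $\Delta\delta_{max}$, fit for $K_D$ (optionally globally across
  residues sharing $K_D$).  Weighted chemical-shift perturbations use
  $\sqrt{(\Delta\delta_H^2 + (0.154\,\Delta\delta_N)^2)/2}$.
* Mean residue ellipticity, $mdeg/(10\,L\,C\,N)$, and
  single-exponential $T_1/T_2$ relaxation fits with 95% confidence
  intervals.

## The coarse-grained force field

Proteins are one bead per residue at the C$\alpha$ position; DNA is
three beads per nucleotide at the P, C4$'$ and N1 atoms.  The
potential is

* harmonic bonds and angles with equilibrium values taken from the
  starting structure;
* cosine dihedrals $\sum_m k_m(1+\cos(m\phi - \delta_m))$, $m = 1..4$.
  The shipped residue-pair table (`inst/extdata/dihedral_params.csv`)
  contains deliberately weak generic defaults (0.2 kJ/mol per term;
  softer around glycine, stiffer around proline) — sequence-specific
  statistical potentials exist but are not redistributable here, and
  for disordered regions the dihedral term is intentionally a minor
  contribution;
* screened Coulomb (Debye–Hückel) interactions
  $q_iq_j e^{-d/\lambda_D}/(4\pi\epsilon_0\epsilon_d d)$ with
  $\epsilon_d = 80$ and
  $\lambda_D = \sqrt{\epsilon_0\epsilon_d k_BT/(2N_Ae^2I)}$ (0.96 nm
  at 0.1 M, 298 K); lysine/arginine carry +1, aspartate/glutamate −1,
  histidine +0.5, DNA phosphates −1.  The potential is truncated and
  shifted at $4\lambda_D$;
* native contacts (Gō recipe) with the 12-10-6 form
  $\varepsilon_{ij}[13s^{12} - 18s^{10} + 4s^6]$, $s = \sigma_{ij}/d$,
  whose minimum of $-\varepsilon_{ij}$ sits exactly at $d =
  \sigma_{ij}$ (the native distance).  Protein–protein native
  contacts use a uniform 3 kJ/mol default; protein–DNA native
  contacts (any-atom distance < 0.5 nm in the reference complex) use
  2 $k_BT$ with $\sigma$ = 0.5 nm;
* generic 12-6 terms by bead-class pair: disordered/any protein pairs
  at $\varepsilon_{pp}$ = 0.16 $k_BT$ ($\approx$ 0.4 kJ/mol at the
  300 K reference), $\sigma$ = 0.6 nm — the single refined parameter;
  DNA stacking 3.0 $k_BT$ and Watson–Crick pairing 3.5 $k_BT$ with
  $\sigma$ placing the minimum at the built B-form distance;
  non-specific DNA 0.04 $k_BT$ ($\sigma$ = 0.45 nm) and non-native
  protein–DNA 0.06 $k_BT$ ($\sigma$ = 0.5 nm).

Forces are analytic and validated against central finite differences
to $10^{-6}$ relative for every term class; energies are invariant
under rigid motion to $10^{-9}$.  Dihedral quadruples that pass
through a collinear geometry (where the torsion angle is undefined and
its gradient diverges) are skipped while near-collinear, which bounds
the energy error by the small torsional amplitude.

### DNA bending stiffness

The bonded constants of the DNA model are not observable-independent:
they are chosen so that the duplex reproduces a persistence length of
about 50 nm, the standard value for B-DNA.  Backbone angle stiffness
alone saturates well below that, because the soft radial Watson–Crick
term lets the two strands shear.  The model therefore includes weak
cross-strand "support" bonds between paired and diagonally adjacent
sugar beads.  The shipped defaults (`ktheta_dna` = 600 kJ/mol/rad²,
`kdih_dna` = 60 kJ/mol, `k_support_dna` = 10 kJ/mol/nm²) were
calibrated on 45-ns equilibrium trajectories of a 100-bp duplex and
give $L_p \approx 50$ nm; all are configurable.

## Langevin dynamics

The integrator is BAOAB with Maxwell–Boltzmann initial velocities,
default timestep 10 fs and friction 1 ps$^{-1}$ — standard, mildly
underdamped settings for C$\alpha$-resolution models that sample
equilibrium efficiently (neither constant is printed in typical
method sections; both are arguments).  At zero friction the scheme
reduces to velocity Verlet, which is used as an energy-conservation
check.  Runs are bitwise deterministic given a seed; replicates use
consecutive seeds.  Nonbonded terms use minimum-image periodic
boundaries, per-pair cutoffs (2.5$\sigma$, capped at 1.5 nm) with
energy shifts, and Verlet neighbour lists (0.6 nm skin, cell-list
rebuild on a half-skin displacement trigger).  Protocol presets scale
from a 10-ns "smoke" run to the cluster-scale 4 × 5 µs protocol with
the first 20% of each replicate discarded as equilibration.  Box edges
of 30 nm (protein) and 120 nm (protein–DNA) are used; a "30 nm³"
volume could not contain the chain, so these figures are read as edge
lengths.

## Ensemble observables

Mean FRET efficiencies are back-calculated per labelled pair as the
frame average of $E(r_{ij})$ with $R_0 = 6$ nm, bead-to-bead (dye
linkers ignored).  Agreement with experiment is scored with Lin's
concordance coefficient
$\rho_c = 2s_{xy}/(s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ (population
variances), which penalises systematic offset as well as scatter;
`refine_epsilon_pp()` scans $\varepsilon_{pp}$ over a grid (default
0.05–0.4 $k_BT$), runs unrestrained simulations, and reports the
$\rho_c$ curve and its argmax.  The closed-loop acceptance test
generates synthetic "experimental" efficiencies at 0.16 $k_BT$ and
recovers the argmax within one grid step.

Contact maps report per-pair contact fractions (centre-of-mass
distance < 1.0 nm at domain granularity; the same cutoff bead-to-bead
at residue granularity, mirroring the domain-level definition since no
residue-level value is standard).  Contact kinetics fits
$A e^{-t/\tau_1} + B e^{-t/\tau_2}$ to the autocorrelation of the
binary contact indicator, on lags up to 20% of the trajectory,
weighted by the number of contributing frame pairs, with
$\tau_1 \le \tau_2$ by convention.

The DNA persistence length comes from tangent correlations of the
base-pair midpoint axis, $\langle\hat t_i\cdot\hat t_{i+n}\rangle =
e^{-n\ell/L_p}$, averaged over frames and interior positions (three
terminal base pairs trimmed for fraying).  Two estimator details
matter.  First, base-pair midpoints do not lie on the helix axis; they
trace a small helix around it, which imprints a 10.5-bp oscillation on
the raw tangent correlations.  The axis is therefore smoothed with a
running mean over one helical turn (11 bp) before tangents are taken,
after which the correlation decays as a clean single exponential.
Second, the log-linear fit uses a free intercept: any residual
per-point axis noise decorrelates adjacent tangents and would
otherwise bias $L_p$ downward; the intercept absorbs that white-noise
floor while the slope carries the bending correlation.

Persistence-length runs use a low Langevin friction (0.05 ps$^{-1}$).
The slowest bending mode of a 100-bp duplex relaxes on $\tau \approx
\gamma/\omega_1^2$, about 40 ns at the 1 ps$^{-1}$ default but under
2 ns at 0.05 ps$^{-1}$; since friction does not affect the sampled
equilibrium, the low value buys an order of magnitude in effective
samples per nanosecond.  Even so, a single 30-45 ns trajectory carries
a realisation-to-realisation spread of roughly 15% in $L_p$, which is
the dominant uncertainty at desk scale.

## Synthetic data and what it does not show

Every pipeline stage is testable against generators with known ground
truth: photon streams with species mixtures, PIE branches, background,
crosstalk/direct-excitation/gamma corruption and exponential
microtimes; telegraph and PMF-diffusion photon emitters for nsFCS;
titration series for each closed-form model; and toy structures — a
compact, slightly jittered lattice fold with self-avoiding tails whose
charge pattern mimics a +13 DNA-binding domain with net-neutral
polyampholyte tails, plus an ideal B-form CG duplex (rise 0.34 nm,
twist 34.3°, one phosphate per nucleotide including the 5$'$ ends).

The generators reproduce the *statistical* structure the analyses
assume, not the physics they omit: no dye photophysics (blinking,
triplets), no IRF width, no real protein fold, no sequence-dependent
DNA elasticity.  Passing closed-loop tests therefore demonstrates the
estimators are self-consistent and correctly implemented — not that
these idealisations hold for any particular experimental system.

## Problem sizes and numerical choices

Desk-scale defaults keep the full test suite and the acceptance script
within routine single-CPU budgets: the persistence-length runs use a
100-bp duplex for 30–48 ns at a 30-fs timestep (the stiff-bond period
is ~650 fs, so this remains well resolved), and the refinement loop
uses an isolated disordered 60-mer for 8 ns per grid point at 20 fs,
read out at a mid-range Foerster radius so the synthetic efficiencies
sit on the steep part of the transfer curve.
Published-scale protocols (µs sampling, 147-bp nucleosomal DNA) use
the same code paths via `protocol_preset("paper")` on cluster
hardware.  Quadrature tolerances are $10^{-8}$ absolute for mean
efficiencies; root finding is $10^{-9}$ nm; minimisation is steepest
descent with backtracking to a 10 kJ/mol/nm force tolerance before
dynamics.

## Known limitations

* The burst-search minimum photon count and all correction factors
  are configuration, not estimation; no automatic background fitting.
* The acceptor-bleach filter is a half-burst drift test, a proxy for
  photon-resolved bleach detection.
* The dihedral table is generic, not sequence-statistical; folded
  domains rely on their native-contact network instead.
* Electrostatics is Debye–Hückel with uniform dielectric: no explicit
  ions, no dielectric heterogeneity at the protein–DNA interface.
* Kinetic quantities from Langevin runs depend on the friction
  choice; equilibrium ensembles do not, and only the latter feed the
  FRET back-calculation.
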