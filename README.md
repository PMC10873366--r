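# cgfret

Integrative single-molecule FRET analysis and coarse-grained
simulation of disordered protein–DNA ensembles.

Transcription factors such as Sox2 combine a folded DNA-binding domain
with long intrinsically disordered regions (IDRs) whose dimensions and
dynamics change on DNA binding.  Characterising such systems takes two
ingredients that rarely live in one place: the single-molecule FRET
(smFRET) analysis stack that turns photon streams into mean transfer
efficiencies, distances and reconfiguration times, and a
coarse-grained simulation model whose ensembles can be compared with —
and refined against — those measurements.  `cgfret` implements both
ends and the loop between them, for spectroscopists and simulators
working on IDR–nucleic-acid systems.

## What is inside

**Polymer FRET (SAW-ν model).**  Mean transfer efficiencies are
related to inter-dye distance distributions through the Förster curve
$E(r) = 1/(1+r^6/R_0^6)$ and the self-avoiding-walk density

$$P(r) \propto \frac{4\pi}{R}\Big(\frac{r}{R}\Big)^{2+(\gamma-1)/\nu}
  \exp\left(-\alpha (r/R)^{1/(1-\nu)}\right),$$

inverted under the scaling closure $R = bN^\nu$ to obtain the
root-mean-square distance $R_{\rm RMS}$ and scaling exponent ν from a
single ⟨E⟩.  Radius of gyration, lifetime–efficiency relations
(static vs dynamic lines) and denaturant-corrected Förster radii are
included.

**Photon tools.**  Burst identification (100 µs interphoton
threshold), corrected per-burst E, PIE stoichiometry S with the
0.3–0.7 window, aggregate and acceptor-bleach filters,
Gaussian/log-normal histogram fitting with global parameter sharing,
photon-pair correlators (ns resolution), the nsFCS
antibunching/chain-dynamics model, and conversion of the
chain-dynamics time τ_cd to the reconfiguration time τ_r by diffusion
on the SAW-ν potential of mean force.

**Binding models.**  Weak denaturant binding, the exact 1:1
quadratic-root isotherm, NMR chemical-shift titrations (single and
global), weighted CSPs, mean residue ellipticity and exponential
relaxation fits — all with standard errors and 95% confidence
intervals.

**Coarse-grained force field and Langevin engine.**  Cα protein beads
and three-bead DNA (P/C4'/N1) with harmonic bonds/angles, cosine
dihedrals, Debye–Hückel screened electrostatics, Gō-type 12-10-6
native contacts, and class-based 12-6 terms (ε_pp = 0.16 k_BT for
disordered regions; DNA stacking 3.0, pairing 3.5, non-specific
0.04 k_BT; protein–DNA native 2, non-native 0.06 k_BT).  A compiled
BAOAB integrator with neighbour lists runs deterministic, seeded
replicates in periodic boxes; the DNA bonded constants are calibrated
to a ~50 nm persistence length.

**Ensemble analysis.**  Back-calculated per-pair FRET efficiencies,
Lin's concordance coefficient ρ_c against experiment, grid refinement
of the single disordered-interaction parameter ε_pp, residue/domain
contact maps and signed difference maps, contact-lifetime
autocorrelations with double-exponential fits, and DNA persistence
length from tangent correlations.

**Synthetic data.**  Ground-truth generators for photon streams
(species mixtures, donor-only fractions, corruption factors),
telegraph and PMF-diffusion photon emitters, titration series, and toy
structures (compact folded domain + disordered tails; ideal B-form CG
DNA), making every stage testable end to end without external data.

## Worked example

Invert a measured mean efficiency to chain dimensions:

```r
library(cgfret)

inv <- invert_efficiency(0.43, forster_model(R0 = 6.0),
                         scaling_closure(b = 0.55, N = 195))
d <- saw_distribution(inv$R, inv$nu)
c(R_rms = inv$R, nu = inv$nu, Rg = radius_of_gyration(d))
#>    R_rms       nu       Rg
#> 7.453595 0.494317 3.208786
```

A mean efficiency of 0.43 between labels 195 residues apart
corresponds to an RMS inter-dye distance of 7.45 nm — a chain more
expanded than a globule (ν ≈ 0.49) with a radius of gyration of about
3.2 nm.  Repeating with the DNA-bound value 0.28 gives 9.19 nm: the
IDR expands by more than 20% on binding.

Simulate a toy disordered protein and back-calculate efficiencies:

```r
toy  <- generate_toy_protein(toy_structure_spec(folded_size = 30,
                                                n_tail = 70, seed = 5))
topo <- build_protein_topology(toy$structure, toy$disordered)
traj <- run_simulation(topo,
                       simulation_protocol(n_steps = 3e5, seed = 31),
                       electrostatics_model(ionic_strength = 0.165))
ensemble_efficiency(traj, c(31, 100))$E_mean
#> [1] 0.3139929
```

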