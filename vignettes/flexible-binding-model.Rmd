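---
title: "A flexible binding model for diubiquitin landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A flexible binding model for diubiquitin landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubscape)
```

## The model

Polyubiquitin chains link two identical 76-residue ubiquitin (Ub) units
through a covalent bond between the C-terminal carboxyl of one unit (the
*distal* unit, G76) and either a lysine side-chain amine (K6, K11, K27, K29,
K33, K48, K63 — isopeptide bond) or the N-terminal M1 amine (linear chains —
peptide bond) of the other (*proximal*) unit.  All eight chain types are
chemically identical apart from the attachment point, yet they signal
different cellular outcomes.  `ubscape` implements a coarse-grained model
designed to ask how that single topological difference reshapes the
dimer's conformational landscape.

Each residue is reduced to two beads: a backbone bead at the C-alpha position
and, for non-glycine residues, a sidechain bead at the centre of mass of the
sidechain heavy atoms.  The Hamiltonian splits into a folding and a binding
part,

$$H = V_\text{folding} + V_\text{binding},$$

with *intra*-monomer interactions taken structure-based (Go-like) from a
reference monomer structure, and *inter*-monomer interactions physics-based,
so that no information about any dimer structure enters the model:

* **Folding (per monomer).** Harmonic bonds ($V = k_b(r-r_0)^2$) along the
  backbone and from each backbone bead to its sidechain bead; harmonic angles
  for backbone triplets and sidechain orientation; a cosine dihedral series
  $k_\phi[(1-\cos\Delta\phi) + \tfrac12(1-\cos 3\Delta\phi)]$ on backbone
  quadruplets plus a single-term dihedral fixing each sidechain's chirality;
  a 12-10 native-contact attraction
  $\varepsilon_c[5(r_n/r)^{12} - 6(r_n/r)^{10}]$ with its minimum at the
  native bead distance $r_n$; and a $(\sigma/r)^{12}$ excluded-volume
  repulsion between all remaining pairs.
* **Binding (between monomers).** Debye-Hückel screened electrostatics over
  charged sidechain beads,
  $V_{ij} = \frac{q_i q_j}{4\pi\epsilon_0\epsilon_r r}e^{-r/\lambda_D}$,
  with charges $+1$ (Lys, Arg), $-1$ (Asp, Glu) and $+0.5$ (His) at neutral
  pH; and a non-native hydrophobic attraction between sidechain beads,
  $V_{ij} = -\lambda_\text{HP}\,\varepsilon_{ij}\,
  \tfrac12[1+\tanh(C(r_0^\text{HP}-r))]$, whose pair strengths
  $\varepsilon_{ij}\in[0,1]$ derive from the Miyazawa-Jernigan (MJ)
  contact-energy table.
* **Linkage.** For a linked chain, exactly one extra harmonic bond between
  the distal G76 backbone bead and the proximal acceptor bead, with reference
  length 0.40 nm (isopeptide) or 0.38 nm (M1 peptide).

### Hydrophobic strengths from the MJ table

The raw MJ contact energies $e_{ij}$ (most attractive entry: Leu-Leu at
$-7.37$) are mapped to
$\varepsilon_{ij} = (\bar e + \alpha(e_{ij}-\bar e))/(2\bar e)$ and clamped
to $[0,1]$; entries whose transform would be negative are set to zero so that
charge-charge effects are not double-counted (they are modelled separately by
the screened Coulomb term).  Defaults: $\alpha = 1$ (the "sequence-flavoured"
choice, full heterogeneity) and $\bar e = -3.7$, which maps the deepest MJ
entry close to 1.  The overall scale $\lambda_\text{HP} = 0.92$ balances
hydrophobicity against electrostatics; it was calibrated (in the modelling
tradition this package follows) so that the free-monomer binding affinity
lands in the experimentally observed millimolar range.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k_bond` | 10000 | $\varepsilon$/nm$^2$ | backbone/sidechain/linkage bond stiffness |
| `k_angle` | 20 | $\varepsilon$/rad$^2$ | angle stiffness |
| `contact_dihedral_ratio` | 2 | — | total contact : total dihedral energy |
| `eps_contact` | 1 | $\varepsilon$ | native-contact depth (the energy unit) |
| `rep_sigma` | 0.4 | nm | excluded-volume diameter |
| `lambda_hp` | 0.92 | — | hydrophobic scale |
| `hp_r0` | 0.8 | nm | optimal hydrophobic pair distance |
| `hp_c` | 10 | nm$^{-1}$ | switching steepness (1 per Å) |
| `eps_r` | 80 | — | relative dielectric |
| `salt_conc` | 0.1 | mol/L | sets $\lambda_D \approx 1.0$ nm ($\approx 10$ Å) |
| `temperature` | 50 | reduced | below the folding temperature |
| `dt` | 0.0005 | reduced | time step |
| `coupling_time` | 1.0 | reduced | Langevin friction $\gamma = 1/\tau$ |
| `concentration` | 0.005 | mol/L | two molecules in an 8.7 nm periodic box |

Energies are in native-contact units; with
$k_B = 0.00831451\ \varepsilon/\text{K}_\text{reduced}$ the reduced
temperature scale matches the convention of Gromacs-style structure-based
models, so $T = 50$ corresponds to $k_BT \approx 0.416\,\varepsilon$.

The native-contact recipe is the
standard all-heavy-atom map: residue pairs at sequence separation $\ge 3$
with any heavy-atom pair within 4.5 Å, realised between the coarse-grained
beads of the participating atom groups.  Contact strengths are uniform and
the dihedral strengths are rescaled so total contact energy : total dihedral
strength is 2:1, the usual stabilising-energy balance of such models.  The
histidine charge (+0.5) is the common Debye-Hückel coarse-grained convention
at pH 7; termini are uncharged because only sidechain charge carriers enter
the model.  All of these are exposed as configuration, not hard-coded.

## Sampling

`langevin_run()` integrates with the BAOAB splitting of Langevin dynamics,
chosen for its accurate configurational averages at practical time steps;
friction is the inverse coupling time.  Bead masses are uniform (1.0).  The
effective protein concentration is realised as a cubic periodic box sized by
`box_from_concentration()` (8.7 nm for two molecules at 5 mM); the periodic
minimum-image convention applies to inter-monomer non-bonded pairs only,
since monomers are never wrapped and the folding terms are intramolecular.
Eight independent replicas with distinct seeds are the production default
(`sim_config()`), and every run records seeds, parameters and package version
in a manifest.  Trajectories are kept as in-memory arrays (and R-native
serialisations in the pipeline); coarse-grained structures are written as
standard PDB pseudo-atom files readable by any structure viewer.

Identical seeds give bit-identical trajectories: the integrator uses its own
serialisable xoshiro256** generator with Box-Muller normals, consuming a
fixed number of draws per step, so a run resumed from a checkpoint
concatenates exactly with an uninterrupted one.

### Numerical choices

All truncations are smooth to the precision the integrator can see.  The
excluded-volume and Debye-Hückel terms are energy- *and* force-shifted to
zero at their cutoffs (1.0 nm and $3\lambda_D$); the hydrophobic switch is
truncated where it has decayed below $2\times10^{-7}$ of its depth.  Forces
are the exact analytic gradient of the implemented Hamiltonian, verified
against central finite differences on hundreds of random configurations.  A
run aborts with diagnostics when any bead moves more than half a box in one
step.  Degenerate geometry (collinear angles) is guarded by clamping
$\cos\theta$ and flooring $\sin\theta$; dihedral forces are skipped when the
bracketing cross products vanish.

## Analysis stack

Per frame, `compute_order_params()` reports the inter-unit centre-of-mass
distance $d_\text{com}$ (equal bead weights), the distances between the
hydrophobic patch centres — the I44 patch (L8, I44, V70) and the I36 patch
(L8, I36, L71, L73), centroids over all beads of the member residues — the
minimum cross-pairing distance d(I36–I44), the distal-M1 to proximal-G76
distance (the observable a FRET dye pair would report), and RMSDs to
reference structures after Kabsch superposition over backbone beads.

Frames are classified with fixed precedence (`classify_frame()`): **open**
when $d_\text{com} \ge 3.2$ nm; otherwise **closed** when
$d(\text{I44–I44}) \le 0.86$ nm; otherwise **I36-I36** (0.96 nm) or
**I36-I44** (0.93 nm) when the corresponding interface is formed and the
higher-precedence ones are not; otherwise **other-compact**.  The patch
cutoffs sit at the transition-state maxima of the corresponding free-energy
profiles; the open cutoff reuses the interfacial-analysis filter of 3.2 nm.
`state_populations()` averages per-replica fractions and reports the
standard deviation across replicas.  Free-energy surfaces are
$-k_BT\ln P$ over 2-D histograms with the populated minimum shifted to zero
and empty bins flagged, never imputed.  `interfacial_contact_profile()`
counts inter-monomer bead pairs within 0.8 nm (aligned with the hydrophobic
optimum) for frames with $d_\text{com} \le 3.2$ nm, and `symmetry_score()`
is the Pearson correlation between the distal and proximal per-residue
profiles — near 1 for the free pair, lower where a covalent linkage breaks
interface symmetry.  `entropy_enthalpy()` splits $F(x) = H(x) - TS(x)$
bin-wise ($H$ is the conditional mean potential energy; 50 bins, bins with
fewer than 10 samples excluded from the correlation coefficients
$\rho_{SF}$, $\rho_{HF}$).  `estimate_kd()` converts a bound fraction into a
dissociation constant under an explicit two-particle convention,
$K_d = (1-P_b)^2/(P_b N_A V)$ — finite-size definitions are genuinely
convention-dependent, so the convention travels with the result.
`three_state_apparent()` reports what a closed-referenced and an
open-referenced two-state experiment would each see for a three-state
system: with a substantial compact population, "apparent open" ($1 -$
closed) and "apparent closed" ($1 -$ open) can both be large at once, which
is precisely how seemingly contradictory equilibrium readouts reconcile.
`loop_entropy()` quantifies the entropic cost of the linkage constraint with
a Gaussian-chain loop-closure probability,
$P = (3/2\pi N_\text{eff} b^2)^{3/2}(4\pi/3)I^3$, with constraints already
present absorbed as $N_\text{eff} = N/(m+1)$.

## Synthetic fixtures, and what passing tests show

No experimental structure ships with the package, and none can be fetched at
test time, so the test suite runs on two generated inputs:

* `make_mini_dimer()` — a 12-residue helical-hairpin domain duplicated into
  a dimer, with hydrophobic, charged and glycine residues so every energy
  term is exercised.  Its native conformation is the minimum of its own
  generated topology by construction.
* `make_ub_monomer()` — a **synthetic surrogate**: the true 76-residue
  ubiquitin sequence (hence exact bead counts, charges, glycine handling and
  linkage-site chemistry) threaded onto an idealized compact fold (a
  constant-speed spherical spiral C-alpha trace, radius 1 nm, 3.8 Å steps,
  sidechain pseudo-atoms alternating between surface and core).

Passing tests on these fixtures demonstrate that the machinery is correct:
energies match independent brute-force oracles, forces are exact gradients,
the thermostat samples the target distribution, classification and
population estimation invert a ground-truth generator exactly.  They do
*not* demonstrate ubiquitin biology: the surrogate's contact map, patch
geometry and linkage-site distances differ from the real fold, so
fold-specific results (the open-population ordering across linkages, the
K48 open/closed/compact signature, the M1-K63 0.54 nm proximity) are only
meaningful when the user supplies the experimental monomer structure
(`inst/extdata/1ubq.pdb`, see the README there).  The corresponding
acceptance checks fail loudly rather than silently degrade when only the
surrogate is available.

Sampling scale is the other deliberate simplification: the desk-scale
defaults (hundreds of thousands of steps, 2-8 replicas) characterise the
machinery and produce stable state populations for linked dimers, but
free-monomer association is diffusion-limited (centre-of-mass friction grows
with bead count), so free-model binding statistics converge only at
production scale — order 10^8 steps per replica, the regime the original
study ran.  The `sim_config()` defaults are therefore smoke-scale, with all
knobs exposed for paper-scale runs.

## Known limitations

* Interactions between units are strictly pairwise and implicit-solvent;
  there is no pH titration machinery (pH enters only through the fixed
  charges) and no explicit ions beyond Debye screening.
* The two-bead resolution cannot resolve sidechain rotamers; interface
  definitions rest on patch centroids.
* Only dimers are modelled: no chains longer than two units, no nucleic
  acids or ligands, and no kinetic (rate) analysis — the landscape is
  equilibrium-only.
* The contact/dihedral rescaling constants and the native-contact recipe
  follow standard structure-based-model practice; both are configuration,
  not fixed model content, and alternatives can be swapped in.
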