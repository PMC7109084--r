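---
title: "Modelling pH-dependent groove plasticity with groovescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pH-dependent groove plasticity with groovescope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovescope)
```

CD1d presents lipid antigens from a deep hydrophobic groove whose entrance
("portal") is flanked by helices α1 and α2. The protein surveys acidic
compartments, so two coupled questions arise: how does dropping the pH from
7 to 4.5 change its charge and the electrostatic landscape around the
portal, and how plastic is the groove itself — its cavity volume, portal
aperture and helix bending — over time and in complex with helper proteins?
This vignette records the models behind each stage, the defaults and why
they were chosen, and what the synthetic test systems do and do not show.

## Protonation model

Side-chain pKa values are taken from external predictors (the package
consumes their tabulated output; it does not reimplement them). Because
individual predictors carry substantial uncertainty, a **consensus rule** is
applied per residue: the accepted value is the arithmetic mean of the
largest subset of predictor values that agree pairwise within
`agreement_tol` (default 0.5 pK units, configurable — "similar" is not a
quantity the source methods define, so the tolerance is an explicit knob).
Subsets of size one are never accepted; a residue with no agreeing pair is
flagged unresolved and must be handled by the caller. Ties between equally
large subsets go to the smaller internal spread, then to the subset whose
predictor names sort first — an arbitrary but deterministic convention.

At a target pH, states follow titration logic with an inclusive margin
`margin = 0.1` pH units on the threshold (pKa ≥ pH − margin), acknowledging
that predicted pKas are not exact:

* Asp/Glu: protonated → charge 0, else −1.
* His: protonated → +1, else 0. A widely circulated phrasing of this rule
  with the inequality reversed ("protonated if pKa ≤ pH") contradicts
  acid–base chemistry — the protonated imidazolium is the majority species
  when the pKa lies *above* the pH — and would protonate His at neutral
  rather than acidic pH. The package deliberately implements the
  chemically correct direction, which also reproduces the worked examples
  below (4 His protonating upon acidification, not the reverse).
* Lys/Arg: +1 unless pKa < pH − margin; Tyr/Cys: neutral unless
  pKa < pH − margin (then −1). In the 4.5–7 range these residues
  essentially never change state.

Net charge is the plain sum of formal side-chain charges; backbone termini
are excluded by default because the bookkeeping of the reference systems is
side-chain-only (e.g. 18 basic − 17 acidic = +1 for the CD1d α1/α2 domain).
Away from the margin region this rule coincides with the
Henderson–Hasselbalch majority species, and the test suite checks that
correspondence property-style.

Four scenario presets encode published charge arithmetic exactly:

```{r}
sapply(c("CD1d_a1a2", "GM2AP", "SapA_dimer", "PruP3"), scenario_net_charges)
```

The presets fix only what is published: residue-type counts and the "flip
set" that changes state between pH 7 and 4.5. Where a total is unpublished
(the number of non-flipping His in CD1d α1/α2), the preset contains exactly
the flip set. Consensus pKas are placed at 3.5 (acids that never
protonate), 5.5 (acids that flip), 6.0 (His that flip), 4.0 (His that do
not), 10.5/12.5 (Lys/Arg); flips require values in (4.4, 6.9) under the
margin rule, and the placements sit safely inside. The three synthetic
predictor columns agree within 0.1 so the consensus rule always resolves.

For the grid solver, each residue's formal charge is placed on one
representative side-chain atom (carboxylate C for Asp/Glu, Nζ for Lys, Nε2
for His, guanidinium C for Arg); radii are element-based van der Waals
values. This residue-level charge model matches the resolution of the
protonation analysis — it is not a force-field charge set, and potentials
near the surface should be read qualitatively (sign and shape), which is
the level at which pH comparisons are made.

## Linearized Poisson–Boltzmann solver

The solver discretizes ∇·(ε(r)∇V) − ε_s κ̄²(r) V = −4π l_B Σ qᵢ δ(r−rᵢ) on
a regular lattice, with V in kT/e (l_B = e²/4πε₀kT ≈ 539 Å·kT/e at 310 K).
Choices, in order of physical importance:

* **Linearized PB.** At 0.150 M and the |V| ≲ a few kT/e relevant around
  the portal, the linear operator captures the sign/shape changes that the
  pH comparison rests on, and makes superposition and sign-negation exact
  solver invariants that the tests exploit. A nonlinear Picard loop would
  slot in above the same kernel but is not implemented.
* **Dielectric boundary.** ε = `eps_protein` (4) at nodes inside the van
  der Waals union of atom spheres, `eps_solvent` (78.54) outside; face
  values are harmonic means. No solvent-excluded-surface reconstruction is
  attempted — a deliberate simplification relative to molecular-surface
  tools, adequate for potentials sampled off the surface.
* **Screening.** κ̄² = 8π l_B n for a monovalent salt (n = per-species
  number density), zeroed inside the molecule plus a 2 Å ion-exclusion
  shell. At 0.150 M / 310 K / ε 78.54 the Debye length is ~8.0 Å.
* **Focusing.** Two levels: a coarse lattice (default 65³) spanning 1.7×
  the molecular extent with Debye–Hückel monopole boundary values centred
  at the charge centroid, then the fine lattice (default 129³ at 0.5 Å)
  with boundary values interpolated from the coarse solution. The fine
  boundary equals the coarse solution by construction, which the tests
  assert.
* **Kernel.** Red-black SOR with ω = 2/(1 + sin(π/n)) to a relative
  residual of 1e-6, implemented in C++. Against the Coulomb and
  Debye–Hückel closed forms on a homogeneous medium the focused 129³
  solution is accurate to well under 1% for r ∈ [5, 15] Å (the tests
  enforce 5%).

Fields are central differences (exact for linear potentials, one-sided at
boundaries); grids round-trip through OpenDX text with z-fastest ordering.

## Pocket detection and occupancy

The default criterion is the protein–solvent–protein (PSP) scan: on a
lattice (0.8 Å default), a voxel is protein when within atom radius + probe
(1.4 Å) of any atom centre; a solvent voxel is a pocket candidate when at
least `scan_threshold` (3) of 7 scan lines — the three axes and four body
diagonals — hit protein on both sides before leaving the lattice. Rays are
deliberately unlimited within the lattice (parameter-free, deterministic).
Candidates cluster by 26-connectivity; clusters under 30 voxels (~15 Å³)
are noise and are dropped. A difference-of-Gaussians alternative
(`method = "dog"`) thresholds the wide-minus-narrow (ratio 1.5:1) smoothed
protein density at half its positive maximum — enclosed solvent accumulates
more density at the wide scale. Neither of the tools that inspired these
criteria publishes its grid parameters, so all defaults here are calibrated
against analytic fixtures: hollow shells of known interior volume must be
recovered within 15% for radii 3–8 Å, and volumes must be
rotation-invariant within 10%.

Trajectory analyses (volume traces, occupancy) bin every frame on the
lattice of frame 1 — occupancy is only meaningful on a shared lattice, so
frames should be superposed first (`align_frames()`, least-squares proper
rotation); an unaligned trajectory triggers a warning, not an error, since
rigid-motion-free trajectories are legitimate. Occupancy is the fraction of
frames in which a voxel is pocket; shells (lo, hi] partition persistence
classes. Savitzky–Golay smoothing (window 51 frames, order 3 — unpublished
in the reference workflow, chosen as a mild smoother at 2,500-frame scale)
is delegated to `signal::sgolayfilt`.

## Gaussian network model

The Kirchhoff matrix is the graph Laplacian of the Cα contact network at a
7.3 Å cutoff (the customary GNM choice; configurable). Eigenvalues are
computed densely; modes with λ < 1e-8·λ_max are zero modes — their count
equals the number of connected components, a property the tests verify on
randomized contact graphs — and mode 1 is the lowest non-zero mode.
Profiles use the squared-fluctuation convention amplitude_i = Σ_k u²_{ki}/λ_k
(switchable to plain u²; the convention is recorded in the output's
`weighting` attribute, since "amplitude" axes in the literature are often
unlabelled and comparisons should be made in shape, not scale). Modes are
computed on the full complex and profiles then restricted per chain.

## Groove geometry

Aperture is the per-frame Cα–Cα distance of a flanking residue pair; the
bundled per-isotype defaults name the conventional pairs (CD1d F77–D151,
CD1e F73–Y144, ...), and residue-name mismatches warn rather than error so
renumbered structures remain analysable. Bending angles use three anchor
pairs whose midpoints m1, m2, m3 track the helix axis; the reported value
is 180° − angle(m1−m2, m3−m2), i.e. deviation from straightness. The
anchor-defining figure of the reference workflow is not recoverable, so the
default convention splits a helix range into thirds; anchors are fully
configurable, and the tests show that anchors straddling a synthetic 30°
hinge recover it within 2°. RMSD uses closed-form least-squares
superposition with reflections excluded; the structure-set projection is
classical metric MDS of the pairwise RMSD matrix (three structures embed
exactly in 2D, another test anchor).

## Synthetic systems: what they emulate, and what they do not

* `make_portal_scaffold()` builds two ideal antiparallel α-helices (rise
  1.5 Å/residue, 100°/residue, Cα radius 2.3 Å) with a designated mid-helix
  aperture pair whose separation is pinned exactly, above a flat
  pseudo-atom platform. The platform sits well below the helices (axes at
  z = 8, platform at z = −25, a narrow 2-row strip under the midline):
  geometric analysis and a parameter sweep showed that a platform close
  under the helices forms genuine sealed tunnels at *any* separation under
  the PSP criterion, defeating the intended contrast — with the final
  geometry the only enclosed region is the inter-helix crevice, present at
  8 Å separation and absent beyond ~20 Å.
* `make_breathing_trajectory()` realizes a prescribed aperture time course
  d(t) = d_∞ + (d₀ − d_∞)e^{−t/τ} + N(0, σ) by rigid displacement of one
  helix (an Ornstein–Uhlenbeck option gives stationary traces). Defaults
  echo the magnitudes seen in groove-closure simulations (15.7 → 11.9 Å,
  σ = 0.7 Å, 2,500 frames ≙ 100 ns at 0.04 ns/frame); they are generator
  parameters for testing recovery, not reproductions of any particular
  molecular-dynamics run.
* `make_cavity_probe()` surrounds an empty sphere of radius r with
  Fibonacci-lattice shells of pseudo-atoms, placed so the detected cavity
  radius is exactly r; construction fails loudly if the shell leaks.
* `make_pka_scenario()` produces the charge-arithmetic scenarios above.

These fixtures validate the *machinery* — recovery of known volumes,
distances, angles, charges and spectra. They are idealized: rigid helices,
residue-level charges, no side-chain packing, no solvent structure, no
force field. Passing them shows the pipeline computes what it claims on
inputs with known answers; it does not certify agreement with experiment or
with all-atom simulation on real proteins, and full molecular-dynamics
observables (e.g. time-averaged apertures of solvated complexes) are
outside the package's scope.

## Numerical choices and degenerate inputs

* Altlocs collapse to the highest-occupancy conformer (ties → "A");
  insertion codes join the residue key; author numbering is authoritative
  throughout and is never rewritten.
* Hydrogens absent from inputs are never built; protonation is bookkeeping
  on heavy-atom residues.
* Superposition requires ≥ 3 non-collinear atoms (checked via the second
  singular value); degenerate selections error.
* The SOR solver reports non-convergence with its final residual rather
  than returning an unconverged grid; zero total charge switches the
  boundary condition to zero.
* Empty protonation states give net charge 0; empty pocket sets give
  volume 0; coincident bend midpoints raise an undefined-angle error.
* All generators draw from a locally seeded RNG stream and restore the
  caller's RNG state, so identical seeds give bit-identical fixtures
  without perturbing the session.

## Problem sizes used in the checks

The bundled verification runs keep desk-scale sizes: the solver oracle uses
a 65³ coarse + 129³ fine focused solve (≈1 minute); pocket calibration uses
cavity radii 3–8 Å on 0.8 Å lattices; geometry recovery uses 2,500-frame
noiseless trajectories of small scaffolds; GNM checks run on up to
50-residue random clouds plus 100 randomized contact graphs. Crystal-derived
aperture values (13.1/14.3 Å for the bound/unbound chains of the CD1d
lipid complex) are checked against the public PDB entry 1ZT4 when it can be
fetched; that is the one check requiring network access.

## Known limitations

Single-conformer dielectric maps (no conformational averaging); no
solvent-excluded surface; linear PB only; residue-level charges; multi-model
PDB is the only trajectory format; pocket criteria are lattice-resolution
limited (expect ~10–15% volume discretization error at 0.8 Å); DALI-style
structural alignment scores are out of scope — the MDS projection uses
superposed RMSD, which is a coarser similarity.
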