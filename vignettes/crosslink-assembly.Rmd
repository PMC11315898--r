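---
title: "Cross-link-restrained docking and combinatorial assembly: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-link-restrained docking and combinatorial assembly: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cross-linking mass spectrometry (CLMS) reports pairs of residues that were
close enough in solution for a chemical linker to join them. Given partial
rigid-body structures of the subunits of a complex — from crystallography or
structure prediction — those residue pairs become distance restraints, and
the modelling task is to find relative placements of all subunits that
satisfy as many restraints as possible without steric overlap. `xlassemble`
implements this pipeline for complexes of the Mis18 kind: a hetero-octamer
of 4 Mis18α, 2 Mis18β and 2 Mis18BP1 segments whose Yippee-like globular
domains stack in a line flanked by two triple-helix bundles.

## Scoring model

A cross-link between residues *i* and *j* is **satisfied** in a model when
the Cα–Cα Euclidean distance is strictly less than a threshold, 22 Å by
default, and the score of a model is the **fraction of satisfied
cross-links** over the mappable ones. Three conventions matter:

* **Copy ambiguity.** When a protein has several copies (Mis18α has four),
  the minimum distance over all copy-pair combinations decides satisfaction;
  a residue is never paired with itself on the same copy. An
  `inter_copy_only` flag restricts homo-oligomer links to different copies
  for interface analysis.
* **Unmappable links** (residues with no Cα in any copy, e.g. because a
  partial model truncates a region) are excluded from the denominator rather
  than counted violated, so model truncation is not penalised.
* The threshold is **strict** (`<`), so a link at exactly 22.00 Å is
  violated.

## Pairwise docking

`dock_pair()` searches relative placements of a mobile subunit B against a
fixed subunit A:

1. **Rotation grid.** A deterministic quasi-uniform cover of rotation space
   built from super-Fibonacci quaternion spirals. An n-point spiral has
   covering radius ≈ 225·n^(−1/3) degrees; the grid is sized as
   n = ⌈(250/step)³⌉ so every rotation lies within `step` degrees of a grid
   member (verified by a property test against random rotations). The
   identity is always included.
2. **Closed-form translation.** For each rotation, the translation
   minimising the mean squared restraint distance is the mean of the
   per-link offset vectors from the rotated B anchor to the A anchor.
3. **Refinement.** Deterministic greedy coordinate descent over small
   body-centred rotation tweaks (±step/2, ±step/4, ±step/8 about the lab
   axes) and axis translations (±2, ±1, ±0.5 Å), at most three sweeps. The
   refinement objective is the satisfied fraction plus two small shaping
   terms that never enter the reported score:
   * a **hinge penalty** on distances above a per-linker soft bound — 12 Å
     for EDC (a zero-length carboxyl–amine coupler) and 18 Å for sulfo-SDA
     (a short photoactivatable spacer). Restraints are upper bounds, so
     distances below the bound are never rewarded further; the linker-aware
     bound uses information the data actually carries, while satisfaction
     itself keeps the single 22 Å rule.
   * a **capped contact reward** for Cα pairs within 6 Å (at 2×10⁻⁴ per
     pair, capped at 40). This is a transparent stand-in for the shape
     complementarity that surface-matching docking engines enforce
     structurally; without it, restraint-only search happily returns poses
     in which the subunits do not touch.
4. **Retention and clash filters.** A configuration survives only if its
   satisfied fraction **strictly exceeds** 0.7 and its Cα–Cα clash count
   (< 4 Å) is at most 5. Survivors are deduplicated by pose (3 Å Cα RMSD),
   scored as `fraction − 0.02 × clashes`, and the top 200 returned. The
   whole procedure is deterministic.

## Hierarchical assembly

`assemble()` builds N-subunit models from pairwise configurations:

* The **connectivity graph** has an edge between subunits sharing ≥ 2
  mappable links; a disconnected graph is an error naming the components.
* A maximum-link-support **spanning tree** fixes the join order (strongest
  available edge first); the first subunit is anchored at the identity.
* **Beam search**: each partial assembly is extended along the next tree
  edge by (a) every composed pairwise configuration and (b) a handful of
  poses from re-docking the incoming subunit against the whole placed
  partial assembly, using every context link — including the non-tree
  "cycle closure" edges, which therefore act as validation constraints.
  Partials are pruned when their satisfied fraction over currently-mappable
  links does not strictly exceed 0.7 or their total clash count exceeds 20,
  and the best 50 (by fraction − clash penalty − hinge tiebreak) survive.
* After the last join, the top 10 assemblies get a deterministic cyclic
  **re-dock polish** (each subunit in turn against the rest), are
  re-anchored, **rescored from scratch** with the full scorer, and
  deduplicated by greedy leader clustering on all-Cα RMSD (5 Å radius).

Identical copies of a protein are distinct subunit ids sharing one
structure; symmetry-equivalent solutions collapse in the clustering step.

## SAXS validation

Theoretical profiles use the Debye formula over one bead per residue at the
Cα position with a uniform form factor:
I(q) = Σᵢⱼ f² sin(q·rᵢⱼ)/(q·rᵢⱼ), with the sinc limit at q = 0. The default
evaluation accumulates the double sum over a 0.1 Å pair-distance histogram;
the exact O(N²) sum is kept as the oracle (they agree to well under 0.5%).
`fit_scale_chi2()` interpolates the model onto the experimental grid
(no extrapolation), applies the analytic least-squares scale
c = Σ IₑIₘ/σ² / Σ Iₘ²/σ², and reports χ² divided by N (a switch selects
N − 1). `guinier_rg()` fits ln I against q² on an iteratively chosen window
with q·Rg ≤ 1.3. Residue-specific form factors and hydration layers are out
of scope, so χ² values against real curves are not comparable to
full-atom tools.

## Sequence and surface properties

* `isoelectric_point()` solves Z(pH) = 0 by bisection on [0, 14], where Z is
  the Henderson–Hasselbalch sum over N-terminus, H, K, R (positive) and
  C-terminus, D, E, C, Y (negative). Bisection runs to interval convergence
  (10⁻⁸ pH) and verifies |Z| < 10⁻⁴ at the root; Z is monotone decreasing,
  so the root is unique. pKa tables: EMBOSS (default), Sillero, Bjellqvist.
* `shrake_rupley_sasa()` samples a fixed golden-spiral point set (960 points
  per atom) on each solvent-expanded sphere; the point set is fixed in the
  lab frame, so rigid-transform invariance holds at the ~1% sampling level,
  not exactly. Coarse Cα-only models use a configurable uniform radius.
* `buried_surface_area()` reports ΔASA = SASA(A) + SASA(B) − SASA(AB); the
  optional linear ΔG estimate is off by default because the literature
  coefficient is context-dependent.

## The synthetic fixture generator

`make_mis18_mimic()` is first-class, tested code, not a stored fixture. It
builds an idealised ground-truth assembly with the Mis18-core topology:

* six Yippee-like **globules** (blue-noise bead packings, 45 beads in a
  10 Å-radius sphere, ≥ 3.6 Å bead separation) in a line at 25 Å spacing,
  in α/β/α–α/β/α type order;
* two **triple-helix bundles** directly above the line (ideal α-helical Cα
  traces: 1.5 Å rise, 100° twist, 36 residues), each holding the C-terminal
  helices of its two α-type and one β-type subunit, the β helix
  antiparallel — each α or β protein copy is one rigid subunit owning its
  globule and its helix;
* two **bp1-type adaptor segments** (22-residue helices) across the outer
  α/β globule interfaces.

The envelope is compact (~150 × 45 × 40 Å), in the spirit of the real
complex's ~220 × 105 × 80 Å envelope at reduced bead scale. The generator is
a pure function of (seed, scale); different seeds change only the bead
jitter, never the topology.

`simulate_crosslinks()` samples true links per designed interface **at the
distances the linker chemistry can produce** — EDC below 12 Å, sulfo-SDA
below 18 Å, both inside the 22 Å satisfaction bound — and adds decoys
(false-positive identifications) at ≥ 35 Å so that decoys are a chosen
fraction of the table (n_decoy = round(n_true·f/(1−f))). True/decoy labels
live only in a sidecar. Defaults: 8 links per interface (88 true links for
the core fixture, the scale of a dense experimental linkage map) and 10%
decoys. `perturb_subunits()` scrambles each subunit with a seeded random
rotation and translation plus a 60 Å dispersal, recording the applied
transforms so recovery can be scored.

## What the fixtures do and do not emulate

The generator captures the topology, copy ambiguity, linker-length physics,
false-positive contamination, and the rigid-body character of the inputs.
It does **not** emulate sequence realism, side chains, flexible linkers,
spectra, or EM maps. Passing recovery tests therefore demonstrate that the
search and scoring machinery behave correctly under the published rules —
not that the method resolves real complexes at any particular resolution.

## Measured limits of fraction-based scoring

Two limits surfaced by the package's own experiments are worth stating
plainly, because they are properties of the published score, not bugs:

* **Plateau width.** Any pose satisfying all restraints scores 1.0, and with
  ≤ 18 Å links under a 22 Å bound the satisfied set is wide: interfaces are
  pinned to roughly 4–8 Å (interface RMSD), not better. Recovery assertions
  therefore use the docking convention of interface RMSD over contact
  residues; whole-body RMSD is unidentifiable for single-patch interfaces
  (rotation about the interface normal is data-free).
* **Decoy capture.** With 10% decoys, the global score optimum is generally
  *not* the ground truth: mildly distorted assemblies that fold at the one
  unbraced hinge of the topology capture several ≥ 35 Å decoy pairs and
  outscore the truth (measured: truth 0.898 vs optima 0.91–0.96 across ten
  seeds). The recovered contact graph (requiring ≥ 2 satisfied links per
  contact, `assembly_adjacency()`) is robust to this; fine interface
  geometry of the top-ranked model is not always. The original study
  anchored global shape with EM maps, which are outside this package's
  scope. At 0% decoys the designed topology is recovered on every seed
  tested.

## Problem sizes and numerical choices

Test and example runs use the core fixture (8 subunits, ~660 beads, 97
links) at a 20° rotation grid (≈ 2 000 rotations, one run ≈ 25–40 s on one
CPU), beam width 50 and 50 configurations per edge; property suites run 10
full assembly seeds and 20 docking seeds. Hot kernels (grid scans, clash
counts, pose refinement) are compiled C++; all of them are deterministic,
and every stochastic stage takes an explicit seed — there is no hidden
entropy. Ties in rankings are broken by clash count and then by a
deterministic provenance/transform key so that reruns are byte-identical.

Degenerate inputs are handled explicitly: collinear point sets refuse to
superpose, empty selections and unmappable links raise named errors, a link
table with zero mappable links cannot form a fraction and says so, and
geometrically unsatisfiable docking restraints return an empty
configuration list rather than an error.
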