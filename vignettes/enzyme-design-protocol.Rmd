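---
title: "The enzdes design protocol: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The enzdes design protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzdes)
```

# The problem

A theozyme is a minimal theoretical active site: a transition-state model of
the substrate surrounded by disembodied catalytic groups at idealized
geometry. enzdes implements the downstream half of computational enzyme
design: express the theozyme as geometric constraints, find scaffold
positions where the constellation can be built (*matching*), redesign the
surrounding residues under those constraints, and score/filter the results.
This vignette documents the models, the tunable parameters and the numerical
decisions, in enough detail that every number a test asserts can be traced
to a definition here.

# The constraint representation

Each catalytic interaction couples three atoms on each partner through six
internal coordinates: one distance (`distanceAB`, between atom 1 of each
partner, in Å), two bond angles (`angle_A`, `angle_B`, degrees), and three
dihedrals (`torsion_A`, `torsion_AB`, `torsion_B`, degrees). Atom maps give
the three atoms either by name or by atom type; a typed map resolves to one
candidate triple `(atom, base atom, base of base)` per matching atom, and
scoring takes the lowest-penalty candidate, which resolves the ambiguity of
chemically equivalent atoms (the two carboxylate oxygens of Asp, say)
automatically.

## The penalty

The printed form of the restraint penalty is a flat-bottomed harmonic. With
$\Delta$ the deviation of the measured value from the nearest periodic copy
of the ideal value $x_0$ (plain $|x - x_0|$ for the distance),

$$p(x) = k \cdot \max(0, \Delta - x_{tol})^2 .$$

This reproduces the documented behaviour exactly: zero anywhere inside the
tolerance band, curvature $k$ outside it, continuity at the boundary, and
minima at every periodic copy of $x_0$ — three minima over a full turn for
periodicity 120°, two (at 120° and 300°) for $x_0 = 120$ with periodicity
180°. `penalty_minima()` verifies this numerically by scanning a 0.1° grid
over the circular domain and counting the disjoint regions attaining the
global minimum.

## Sampling

Classic matching samples $2n+1$ equally spaced points spanning
$[x_0 - x_{tol},\, x_0 + x_{tol}]$ around every periodic copy of $x_0$
within one turn. The number of ligand placements attempted per rotamer is
the product of the six per-parameter sample counts; for the worked example
block shipped in the documentation that is $1\cdot3\cdot3\cdot3\cdot7\cdot3
= 567$.

# Matching

**Classic matching** builds, at every candidate position, side-chain
rotamers of the block's allowed residue types, then for each rotamer and
each sampled parameter tuple places the ligand by internal-coordinate (NeRF)
construction: partner atom 1 from (distance, `angle_A`, `torsion_A`), atom 2
from (`angle_B`, `torsion_AB`) plus the ligand's internal bond, atom 3 from
`torsion_B`, then a rigid transform of the full conformer onto those
anchors. A placement survives if no ligand heavy atom comes closer to a
backbone atom (N/CA/C/O/CB) than `clash_factor` times the summed van der
Waals radii (default 0.7). Each survivor is a *hit*.

**Secondary matching** never builds the ligand: candidate rotamers are
checked against the ligand placements of previously generated hits, and only
the parameters the block defines are evaluated — an interaction for which
two dihedrals are chemically irrelevant simply omits them. Acceptance is
exactly "every defined parameter within its flat-bottom band", which the
test suite cross-checks against a brute-force zero-penalty oracle. An
accepted pair copies the prior hit's pose, so secondary hits can never leave
the bins populated by earlier interactions. Side-chain/side-chain blocks are
supported by realizing the partner rotamer stored in the prior hit. The
first interaction must use classic matching, since secondary matching needs
prior hits to exist.

**Hashing.** A hit's pose is the position of the ligand's reference frame
(origin at the first frame atom, x toward the second, the third fixing the
plane; frame atoms default to the first block's ligand map) plus z-x-z Euler
angles wrapped to [0°, 360°). Bins are `floor(value / width)` with defaults
1 Å and 15°; these widths are configuration, chosen so that a bin is
comfortably smaller than the tolerance bands of a typical hydrogen-bond
constraint. There is deliberately no cross-bin neighbor merging: two poses
0.2° either side of a bin boundary do not match, a documented limitation of
plain floor hashing. Bins holding at least one hit from every interaction
emit the Cartesian combinations of their hits (capped per bin, best
realized restraint score first, position index as tie-break), discarding
combinations that reuse a scaffold position, deduplicated by (positions,
residue types, bin).

## The rotamer library

A full statistical rotamer library is out of scope; the reduced library uses
three canonical samples per rotatable chi (-60°, 60°, 180°). `ex1`/`ex2` add
satellites ±10° (half of the documented 20° extra-sampling step) around each
chi1/chi2 sample, tripling that chi's count — Asp goes from 9 to 27 rotamers
under `ex1`. `use_input_sc` appends the position's native rotamer. Proline
is restricted to a single ring-closed rotamer; rings and planar groups use
fixed idealized internal coordinates. Side chains are heavy-atom only.

# The simplified energy model

The full all-atom score function is out of scope, so all design stages run
on a documented stand-in with the same architecture:

* **Repulsive/attractive**: a Lennard-Jones 12-6 with contact distance
  $\sigma = s\,(r_i + r_j)$, $s = 0.92$ (0.85 for the soft-repulsive design
  variant so near-contacts are forgiven during sequence selection), well
  depth 0.15, repulsion capped at 10 per pair, 6 Å cutoff. The positive part
  is reported as `fa_rep`, the negative part as the attractive term. The
  scale $s$ is chosen so that the contact distances of ideal secondary
  structure sit at the LJ minimum rather than inside the wall.
* **Hydrogen bonds**: donor and acceptor heavy atoms at distance $r$
  contribute $-f(r)\,g(\theta)$ with $f$ an inverted parabola peaking at
  2.9 Å (support 2.4–3.4 Å) and $g$ ramping linearly from 0 at a 100° donor
  base angle to 1 at 180°. Hydrogens are never modelled; donor geometry is
  evaluated through the donor's base (parent) atom, which is why polar
  hydrogens never need rebuilding.
* **Reference energies**: small per-residue-type constants that mildly
  penalize the largest side chains, standing in for unfolded-state free
  energies.
* **Restraints**: the flat-bottom penalty above, weight `w_cst`.

Intra-residue pairs are excluded (rotamers are rigid and ideal, and bonded
1-2/1-3 pairs would swamp the repulsion); adjacent-residue backbone/backbone
pairs are excluded as bonded. A constraint whose distance record carries the
covalent flag exempts the constrained atom pair and their 1-2/1-3 bonded
neighbors from the LJ terms, the standard treatment for covalent catalytic
attachments. Absolute values of this model are meaningful only relative to
each other; no comparison to published energy statistics is intended.

# The design stages

**Shell detection** applies four rules in order, first match wins: CA within
`cut1` of any ligand heavy atom → designable; CA within `cut2` with CB
closer to *that* ligand atom → designable; CA within `cut3` → repackable;
CA within `cut4` with CB closer → repackable; otherwise static. Defaults are
6/8/10/12 Å; a tighter 4/6/10/12 variant is equally valid configuration for
small sites. Glycine has no CB and falls back to the CA-only test. Catalytic
residues are always repackable (never designed) unless `fix_catalytic_aa`
makes them static. Designable positions allow every amino acid except
cysteine. A resfile (commands NATRO/NATAA/ALLAA/PIKAA, default AUTO) can
override individual positions; AUTO defers to the detected shell.

**cst_opt** mutates non-catalytic shell residues to alanine and minimizes
the ligand rigid body (plus catalytic chi angles under `chi_min`) with the
attractive term removed and restraints on — the substrate is pulled to the
most catalytically ideal position without sticky contacts interfering.
Movable-region CA atoms are restrained by a flat-bottom harmonic of 0.5 Å
tolerance. Minimization is quasi-Newton (BFGS) on the movable DOFs with
numerical gradients, at most a few hundred objective evaluations; the result
never exceeds the starting objective (the start is kept if line search
fails), which gives the monotonicity the tests assert.

**cst_predock** is the Monte-Carlo alternative: rigid-body moves with
translations drawn per axis from `trans_magnitude` times a standard normal
and rotations of `rot_magnitude` times a standard normal about a random axis
through the centroid of the ligand atoms that carry distance restraints (so
sampling is efficient with respect to the restraints), Metropolis-accepted
at kT = 1, seeded and reproducible. Designable residues are reduced to
alanine first.

**Design cycles** (default 2) alternate simulated-annealing packing with
minimization (`cst_min`). The packer optimizes rotamer and, at designable
positions, identity choices; its energy multiplies protein–ligand pair terms
by `lig_packer_weight` (default 1.6, favoring sequences that bind the
ligand), credits the native identity at each designable position with
`native_bonus` (default 0.8 REU, damping gratuitous mutations), and keeps
the restraint contribution of catalytic rotamers on throughout. Annealing
uses a geometric schedule (kT from 3 down to ~0.01 over eight stages); at
the final near-zero temperature only energy-nonincreasing moves are
accepted, and the best state seen is returned.
`packer_energy_breakdown()` exposes exactly these components, so the linear
entry of `lig_packer_weight` and `native_bonus` is directly auditable.

**Unrestrained repack** re-packs with the sequence fixed and the restraint
weight at zero, then minimizes the catalytic chi angles (the ligand rigid
body is held fixed in this stage: without restraints the reduced model's
shallow attraction cannot be trusted to keep a marginal binder in the
pocket, and the stage's purpose is to interrogate the side chains).
`final_repack_without_ligand` additionally removes the ligand, repacks, and
reports each catalytic residue's side-chain heavy-atom RMSD against the
liganded model — the preorganization measure: a well-designed site holds its
catalytic geometry without restraints or ligand.

**bb_min** is supported as small rigid translations of the catalytic
residues' local backbone units under the 0.5 Å CA restraint plus
peptide-bond continuity penalties; full torsion-space backbone minimization
with fold-tree bookkeeping is out of scope, and the flag defaults to off.

# Evaluation metrics

All metrics are geometric, rigid-motion invariant, and heavy-atom based:
hydrogen bonds (donor–acceptor ≤ 3.3 Å, donor base angle ≥ 120°; whole
protein and the catalytic subset), buried unsatisfied polar atoms (polar,
≥ 12 heavy neighbors within 5.2 Å, no hydrogen bond), non-local contacts
(sequence separation ≥ 6, any heavy-atom pair ≤ 4.5 Å), a packing proxy
(mean occupied fraction of buried atoms' 5.2 Å neighbor shells, reported
with and without the ligand), and the protein–ligand interface score (the
pairwise model makes it exactly score(complex) − score(protein) −
score(ligand)). The thresholds are configuration with the defaults above.
The scorefile has one line per design; `total_score` excludes the restraint
score, `all_cst` equals the sum of the per-partner SR columns by
construction, and with N catalytic residues the ligand is always SR(N+1).
`filter_designs()` applies cutoff tables (`metric < threshold` /
`metric > threshold`) and reports per-cutoff pass counts;
`score_reference()` repacks and minimizes a reference structure under the
same restraints to provide the benchmark record that scaffold-relative
cutoffs should be computed against.

# Synthetic fixtures and what they do (not) show

`make_toy_scaffold()` folds two antiparallel poly-alanine helices around a
wedge-shaped groove on ideal covalent geometry; the seed perturbs torsions
by a degree or two, so structures vary while bond lengths stay ideal. 40
residues keeps a full match–design–evaluate cycle in seconds.
`make_theozyme_tim()` mirrors a triosephosphate-isomerase-like mechanism: a
Glu/Asp carboxylate poised to abstract the substrate C1 proton (classic,
all six parameters), a His hydrogen-bonding the carbonyl oxygen in the
substrate plane (classic), and a Lys polarizing the same oxygen via an
interaction whose `torsion_AB`/`torsion_B` are deliberately undefined
(secondary matching). Its numeric values are fixture data chosen as
chemically sensible hydrogen-bond geometry, not measurements of any real
enzyme.

`plant_site()` provides ground truth by inverse construction. A fixed
backbone and a discrete chi library cannot realize an arbitrary
pre-specified six-parameter geometry for more than one interaction at once
— the problem is overdetermined — so the input theozyme acts as a template:
the generator picks positions, library rotamers and a ligand placement
satisfying the template within fixed chemical windows, then sets each
block's ideal values to the realized geometry. The planted theozyme
therefore scores the planted site exactly zero, and classic matching, whose
sample grids are centred on the ideal values, reproduces the planted pose
bin exactly — that is what makes 25/25 recovery a sharp test. The negative
control offers the matcher fewer candidate positions than the theozyme has
interactions, so a reported match is impossible by construction
(matches require distinct positions); a geometric negative (a 2 Å pose
perturbation leaving every recovered bin) is tested separately.

What passing these fixtures does *not* show: behaviour on real scaffolds
(real pockets are lined by diverse residues, not alanine), the energetics of
real sequence design (the simplified model has no solvation or
electrostatics), or match statistics of real theozyme/scaffold pairs.

# Numerical conventions

Angles in degrees everywhere; torsions in [-180°, 180°); Euler angles z-x-z
wrapped to [0°, 360°); collinearity below sin ≈ 1e-8 is degenerate and
either raises an error (construction) or flags the torsion as undefined NA
(measurement); a flagged torsion under a nonzero force constant scores
infinite. Sample enumeration deduplicates wrapped periodic copies at 1e-6°.
Trailing-dot numerics ("100.") parse as floats; cstfile writing keeps enough
digits for an exact parse-back. All stochastic stages take explicit seeds
and save/restore the global RNG state, so fixture generation never perturbs
a caller's random stream.

# Problem sizes used by the shipped checks

The test suite runs the full pipeline at fixture scale: 40-residue
scaffolds, a 6-atom ligand, 25 planted matcher-recovery cases with matched
negative controls, 10^4 random internal-coordinate round trips, 100 random
structures for the shell-detection oracle, and single design runs for the
stage contracts. These sizes were chosen so the entire suite exercises every
stage end to end in a few minutes on one core while leaving every numerical
assertion at full precision.
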