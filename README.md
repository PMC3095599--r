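# enzdes

Desk-scale de novo enzyme design in R: graft a minimal model active site (a
*theozyme*) into protein scaffolds and design the surrounding shell, following
the classic four-stage protocol used for computational enzyme design:

1. **Theozyme definition** — each catalytic interaction between a ligand
   (transition-state model) and a disembodied functional group is written as a
   block of a geometric-constraint file (*cstfile*): six internal coordinates
   `distanceAB, angle_A, angle_B, torsion_A, torsion_AB, torsion_B` with ideal
   value `x0`, tolerance `xtol`, force constant `k`, covalent flag or
   periodicity, and a matcher sample count `n` (the matcher samples `2n+1`
   points across `x0 ± xtol` around every periodic copy of `x0`).
2. **Matching** — *classic matching* builds side-chain rotamers at candidate
   scaffold positions and places the ligand outward through every sampled
   parameter tuple; *secondary matching* re-evaluates candidate rotamers
   against previously generated ligand placements, checking only the
   parameters the block defines. Collision-free placements ("hits") are hashed
   by the ligand's 6D pose (3 Euclidean + 3 z-x-z Euler coordinates); a hash
   bin holding a hit from every interaction is a "match".
3. **Design** — automatic shell detection by the four CA/CB distance rules
   (`cut1 < cut2 < cut3 < cut4`), restrained optimization of the catalytic
   geometry on a poly-alanine site (`cst_opt`), optional Monte-Carlo rigid-body
   predock, then cycles of simulated-annealing sequence design (protein-ligand
   interactions upweighted, native identities credited a small bonus,
   restraints on throughout) and minimization, ending with an unrestrained
   fixed-sequence repack.
4. **Evaluation** — per-design metrics (total/repulsive/hydrogen-bond scores,
   per-residue restraint scores SR1..SRN with the ligand as SR(N+1), a packing
   proxy with and without the ligand, buried unsatisfied polar atoms,
   non-local contacts, protein-ligand interface score, apo-repack RMSDs of the
   catalytic residues) written to a scorefile and filtered by cutoffs.

Restraints use a flat-bottomed periodic harmonic: zero while the deviation
from the nearest periodic copy of `x0` is within `xtol`, then
`k * (delta - xtol)^2`. The all-atom score function of the original protocol
is replaced by a documented simplified pairwise model (capped soft
Lennard-Jones, geometric hydrogen-bond term, reference energies); absolute
energies are therefore **not** comparable to published REU statistics — the
protocol logic, not the force field, is the point. Likewise `tot_pstat_pm` is
a documented packing proxy in [0, 1], not the published packstat algorithm.

Everything runs on deterministic synthetic fixtures (a helix-loop-helix
pocket scaffold, a simplified dihydroxyacetone-like ligand, a
triosephosphate-isomerase-style Glu/His/Lys theozyme), so no structure
downloads are needed.

## Worked example

```r
library(enzdes)

scaffold <- make_toy_scaffold(40, seed = 1)
site     <- plant_site(scaffold, seed = 1)          # fixture ground truth

res <- run_matcher(scaffold, site$theozyme, site$ligand,
                   attr(scaffold, "pocket_positions"), match_config())
#> 5 match(es) from 37341 hit(s)
res$summary[1, c("bin", "positions", "restypes")]
#>               bin positions    restypes
#> 1 10/17/2/11/5/15  30,10,14 GLU,HIS,LYS

out <- run_design(res$structures[[1]], site$theozyme,
                  design_config(seed = 1, final_repack_without_ligand = TRUE))
score_design(out$structure, site$theozyme, apo_rmsd = out$apo_rmsd)
```

The matcher summary above says that 37,341 collision-free ligand placements
were generated across the three catalytic interactions and that 5 pose bins
contained all of them at distinct positions; the first match grafts
Glu30/His10/Lys14 around a consistent ligand pose (bin key = the six floor
indices of the 1 Å / 15° 6D hash). `score_design` then reports the metric
vector of the designed model; `all_cst` is the total flat-bottom restraint
score and equals the sum of the SR columns.

A command-line wrapper with the protocol's flag names lives in
`inst/cli/enzdes.R` (`fixture`, `match`, `design` subcommands).

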