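# Structure-level restraint evaluation: map each theozyme block to its
# partner residues via the catalytic annotations, resolve the atom maps and
# sum the flat-bottom penalties. The per-residue breakdown follows the
# scorefile convention: each block's score is split evenly between its two
# partners, with the ligand accumulating the final SR column.

# coordinate triples of one side of a block on a concrete structure
.side_triples <- function(s, map, block_resi = NULL, ligand = NULL) {
  if (!is.null(ligand) && !is.na(s$ligand_name) &&
      s$ligand_name %in% map$allowed_residues) {
    coords <- ligand_coords(s)
    trs <- resolve_atom_triples(map, ligand)
  } else {
    if (is.null(block_resi)) stop("no catalytic annotation for a protein-side map")
    coords <- res_atoms(s, block_resi)
    rt <- res_table(s)
    trs <- resolve_atom_triples(map, rt$resname[match(block_resi, rt$resi)])
  }
  out <- list()
  for (tr in trs) {
    if (!all(tr %in% rownames(coords))) next
    out[[length(out) + 1]] <- coords[tr, , drop = FALSE]
  }
  out
}

#' Evaluate all theozyme restraints on a structure
#'
#' Uses the structure's catalytic annotations to locate each block's
#' protein partner(s); the ligand partner comes from the structure's
#' ligand. Returns the total restraint score, the per-block scores and the
#' per-residue SR breakdown (catalytic residues SR1..SRN in annotation
#' order, the ligand as the last SR).
#'
#' @param s an annotated `enz_structure` carrying its ligand topology.
#' @param theo the `theozyme` the structure was built for.
#' @return list with `total`, `per_block`, `sr` (named numeric vector).
#' @export
all_cst <- function(s, theo) {
  if (is.null(s$ligand)) stop("structure carries no ligand topology")
  catal <- catalytic_residues(s)
  nb <- length(theo$blocks)
  per_block <- numeric(nb)
  # SR order: one slot per catalytic annotation (block order), ligand last
  sr <- setNames(numeric(nb + 1), c(paste0("SR", seq_len(nb)), paste0("SR", nb + 1)))
  for (i in seq_len(nb)) {
    b <- theo$blocks[[i]]
    resi <- catal$resi[catal$block == i]
    lside <- .ligand_side(b, s$ligand_name)
    t1 <- .side_triples(s, b$map1, block_resi = if (!identical(lside, "map1")) resi[1] else NULL,
                        ligand = s$ligand)
    ri2 <- if (identical(lside, "map1")) resi[1] else if (length(resi) > 1) resi[2] else resi[1]
    t2 <- .side_triples(s, b$map2, block_resi = if (!identical(lside, "map2")) ri2 else NULL,
                        ligand = s$ligand)
    bs <- block_score_triples(t1, t2, b)
    per_block[i] <- bs$score
    half <- bs$score / 2
    if (is.na(lside)) {
      sr[i] <- sr[i] + bs$score  # side-chain pair: whole score on the block slot
    } else {
      sr[i] <- sr[i] + half
      sr[nb + 1] <- sr[nb + 1] + half
    }
  }
  list(total = sum(per_block), per_block = per_block, sr = sr)
}
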