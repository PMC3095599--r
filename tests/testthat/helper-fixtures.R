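# Shared fixtures, built once per test run and cached.

.fix_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fix_cache[[key]])) .fix_cache[[key]] <- force(expr)
  .fix_cache[[key]]
}

# the worked example block used throughout the cstfile documentation
example_cst_text <- c(
  "CST::BEGIN",
  "  TEMPLATE::   ATOM_MAP: 1 atom_name: C1 C2 O2",
  "  TEMPLATE::   ATOM_MAP: 1 residue3: 1n1",
  "  TEMPLATE::   ATOM_MAP: 2 atom_type: OOC,",
  "  TEMPLATE::   ATOM_MAP: 2 residue1: ED",
  "  CONSTRAINT:: distanceAB:    3.06   0.2  100.  0    0",
  "  CONSTRAINT:: angle_A:      73.60  10.0   80.0  360. 1",
  "  CONSTRAINT:: angle_B:     120.00  15.0   80.0  360. 1",
  "  CONSTRAINT:: torsion_A:  -101.20  15.0   60.0  360. 1",
  "  CONSTRAINT:: torsion_AB:  180.00  90.0    0.00 360. 3",
  "  CONSTRAINT:: torsion_B:   180.00  15.0    0.00 360. 1",
  "CST::END")

example_block <- function() cached("example_block", {
  parse_cstfile(example_cst_text)$blocks[[1]]
})

fixture_scaffold <- function(seed = 1) cached(paste0("scaffold", seed), {
  make_toy_scaffold(40, seed)
})

fixture_planted <- function(seed = 1) cached(paste0("planted", seed), {
  plant_site(fixture_scaffold(seed), seed = seed)
})

fixture_tim <- function() cached("tim", make_theozyme_tim())

# apply a rigid motion to every atom of a structure (test utility)
transform_structure <- function(s, R, t) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  s$atoms[, c("x", "y", "z")] <- sweep(m %*% t(R), 2, t, "+")
  for (at in c("pocket_centroid")) {
    v <- attr(s, at)
    if (!is.null(v)) attr(s, at) <- as.numeric(R %*% v + t)
  }
  s
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# minimal hand-built structure from a residue list; each residue is a list
# with chain/resno/resname and a named coordinate matrix
build_structure <- function(residues, ligand_atoms = NULL, ligand = NULL,
                            catalytic = NULL) {
  rows <- list()
  for (i in seq_along(residues)) {
    r <- residues[[i]]
    m <- r$coords
    rows[[i]] <- data.frame(resi = i, chain = r$chain %||% "A",
                            resno = r$resno %||% i,
                            resname = r$resname, name = rownames(m),
                            element = enzdes:::.element_from_name(rownames(m)),
                            x = m[, 1], y = m[, 2], z = m[, 3], het = FALSE)
  }
  atoms <- do.call(rbind, rows)
  lig_name <- NA_character_
  if (!is.null(ligand_atoms)) {
    lig_name <- if (!is.null(ligand)) ligand$name else "LIG"
    atoms <- rbind(atoms, data.frame(
      resi = NA_integer_, chain = "A", resno = 900L, resname = lig_name,
      name = rownames(ligand_atoms),
      element = enzdes:::.element_from_name(rownames(ligand_atoms)),
      x = ligand_atoms[, 1], y = ligand_atoms[, 2], z = ligand_atoms[, 3],
      het = TRUE))
  }
  new_structure(atoms, catalytic, ligand_name = lig_name, ligand = ligand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# an idealized residue (N/CA/C/O + side chain) placed near the origin
make_residue <- function(resname = "ALA", chi = NULL, origin = c(0, 0, 0)) {
  bb <- rbind(N = c(0, 0, 0) + origin, CA = c(1.458, 0, 0) + origin,
              C = c(2.01, 1.42, 0) + origin)
  if (is.null(chi)) chi <- rep(-60, n_chi(resname))
  sc <- build_sidechain(bb, resname, chi)
  O <- place_atom(bb["N", ], bb["CA", ], bb["C", ], 1.231, 120.5, 60)
  coords <- rbind(bb, O = O)
  if (nrow(sc)) coords <- rbind(coords, sc)
  coords
}
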