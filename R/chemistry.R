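# Chemical reference data: element radii, atom types and polarity, amino-acid
# codes, idealized side-chain internal-coordinate topologies, and the reduced
# chi-sample rotamer library.
#
# Side chains are built from idealized bond lengths/angles with heavy atoms
# only. Each topology row places one atom by NeRF from three reference atoms;
# the torsion is either one of the residue's chi angles (plus an offset for
# branch atoms) or a fixed value (ring / planar-group atoms).

.ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.10)

# donor/acceptor capability per atom type (heavy-atom model: "donor" means
# the atom carries at least one polar hydrogen in the modeled protonation
# state, "acceptor" that it has a lone pair available)
.TYPE_PROPS <- list(
  OH   = c(don = TRUE,  acc = TRUE),
  OOC  = c(don = FALSE, acc = TRUE),
  ONH2 = c(don = FALSE, acc = TRUE),
  NH2O = c(don = TRUE,  acc = FALSE),
  Nlys = c(don = TRUE,  acc = FALSE),
  Nhis = c(don = TRUE,  acc = TRUE),
  Ntrp = c(don = TRUE,  acc = FALSE),
  Narg = c(don = TRUE,  acc = FALSE),
  Nbb  = c(don = TRUE,  acc = FALSE),
  OCbb = c(don = FALSE, acc = TRUE)
)

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
          "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
             E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
             M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
             Y = "TYR", V = "VAL")

.AA3TO1 <- setNames(names(.AA1TO3), .AA1TO3)

.N_CHI <- c(ALA = 0, GLY = 0, SER = 1, CYS = 1, THR = 1, VAL = 1, PRO = 2,
            LEU = 2, ILE = 2, ASP = 2, ASN = 2, HIS = 2, PHE = 2, TYR = 2,
            TRP = 2, MET = 3, GLU = 3, GLN = 3, LYS = 4, ARG = 4)

# improper dihedral C-N-CA-CB for an L-amino acid (sign fixes chirality)
.CB_TORSION <- 122.6

.sc_row <- function(name, p3, p2, p1, d, theta, chi, tors, elem, type) {
  data.frame(name = name, p3 = p3, p2 = p2, p1 = p1, d = d, theta = theta,
             chi = chi, tors = tors, elem = elem, type = type,
             stringsAsFactors = FALSE)
}

.CB <- function() .sc_row("CB", "CA", "N", "C", 1.53, 110.5, 0L, .CB_TORSION, "C", "CH")

# per-residue side-chain topology tables (heavy atoms beyond the backbone)
.SC_TOPO <- local({
  r <- .sc_row
  list(
  GLY = r(character(0), character(0), character(0), character(0),
          numeric(0), numeric(0), integer(0), numeric(0), character(0), character(0)),
  ALA = .CB(),
  SER = rbind(.CB(),
    r("OG",  "CB", "CA", "N", 1.417, 110.8, 1L, 0, "O", "OH")),
  CYS = rbind(.CB(),
    r("SG",  "CB", "CA", "N", 1.808, 114.4, 1L, 0, "S", "S")),
  THR = rbind(.CB(),
    r("OG1", "CB", "CA", "N", 1.433, 109.5, 1L, 0,    "O", "OH"),
    r("CG2", "CB", "CA", "N", 1.521, 110.5, 1L, -120, "C", "CH")),
  VAL = rbind(.CB(),
    r("CG1", "CB", "CA", "N", 1.527, 110.5, 1L, 0,     "C", "CH"),
    r("CG2", "CB", "CA", "N", 1.527, 110.5, 1L, 122.6, "C", "CH")),
  LEU = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.530, 116.3, 1L, 0,     "C", "CH"),
    r("CD1", "CG", "CB", "CA", 1.521, 110.7, 2L, 0,     "C", "CH"),
    r("CD2", "CG", "CB", "CA", 1.521, 110.7, 2L, 122.6, "C", "CH")),
  ILE = rbind(.CB(),
    r("CG1", "CB", "CA", "N",  1.530, 110.4, 1L, 0,      "C", "CH"),
    r("CG2", "CB", "CA", "N",  1.521, 110.5, 1L, -122.6, "C", "CH"),
    r("CD1", "CG1", "CB", "CA", 1.513, 113.8, 2L, 0,     "C", "CH")),
  MET = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.520, 114.1, 1L, 0, "C", "CH"),
    r("SD",  "CG", "CB", "CA", 1.807, 112.7, 2L, 0, "S", "S"),
    r("CE",  "SD", "CG", "CB", 1.789, 100.9, 3L, 0, "C", "CH")),
  ASP = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.516, 112.6, 1L, 0,   "C", "COO"),
    r("OD1", "CG", "CB", "CA", 1.249, 118.4, 2L, 0,   "O", "OOC"),
    r("OD2", "CG", "CB", "CA", 1.249, 118.4, 2L, 180, "O", "OOC")),
  ASN = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.516, 112.6, 1L, 0,   "C", "CNH2"),
    r("OD1", "CG", "CB", "CA", 1.231, 120.8, 2L, 0,   "O", "ONH2"),
    r("ND2", "CG", "CB", "CA", 1.328, 116.4, 2L, 180, "N", "NH2O")),
  GLU = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.520, 114.1, 1L, 0,   "C", "CH"),
    r("CD",  "CG", "CB", "CA", 1.516, 112.6, 2L, 0,   "C", "COO"),
    r("OE1", "CD", "CG", "CB", 1.249, 118.4, 3L, 0,   "O", "OOC"),
    r("OE2", "CD", "CG", "CB", 1.249, 118.4, 3L, 180, "O", "OOC")),
  GLN = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.520, 114.1, 1L, 0,   "C", "CH"),
    r("CD",  "CG", "CB", "CA", 1.516, 112.6, 2L, 0,   "C", "CNH2"),
    r("OE1", "CD", "CG", "CB", 1.231, 120.8, 3L, 0,   "O", "ONH2"),
    r("NE2", "CD", "CG", "CB", 1.328, 116.4, 3L, 180, "N", "NH2O")),
  LYS = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.520, 114.1, 1L, 0, "C", "CH"),
    r("CD",  "CG", "CB", "CA", 1.520, 111.3, 2L, 0, "C", "CH"),
    r("CE",  "CD", "CG", "CB", 1.520, 111.3, 3L, 0, "C", "CH"),
    r("NZ",  "CE", "CD", "CG", 1.489, 111.9, 4L, 0, "N", "Nlys")),
  ARG = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.520, 114.1, 1L, 0,   "C", "CH"),
    r("CD",  "CG", "CB", "CA", 1.520, 111.3, 2L, 0,   "C", "CH"),
    r("NE",  "CD", "CG", "CB", 1.461, 112.0, 3L, 0,   "N", "Narg"),
    r("CZ",  "NE", "CD", "CG", 1.330, 124.2, 4L, 0,   "C", "aroC"),
    r("NH1", "CZ", "NE", "CD", 1.326, 120.0, 0L, 0,   "N", "Narg"),
    r("NH2", "CZ", "NE", "CD", 1.326, 120.0, 0L, 180, "N", "Narg")),
  HIS = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.500, 113.8, 1L, 0,   "C", "aroC"),
    r("ND1", "CG", "CB", "CA", 1.378, 122.7, 2L, 0,   "N", "Nhis"),
    r("CD2", "CG", "CB", "CA", 1.356, 131.0, 2L, 180, "C", "aroC"),
    r("CE1", "ND1", "CG", "CB", 1.321, 109.3, 0L, 180, "C", "aroC"),
    r("NE2", "CD2", "CG", "CB", 1.374, 107.2, 0L, 180, "N", "Nhis")),
  PHE = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.510, 113.8, 1L, 0,   "C", "aroC"),
    r("CD1", "CG", "CB", "CA", 1.390, 120.8, 2L, 0,   "C", "aroC"),
    r("CD2", "CG", "CB", "CA", 1.390, 120.8, 2L, 180, "C", "aroC"),
    r("CE1", "CD1", "CG", "CB", 1.390, 120.8, 0L, 180, "C", "aroC"),
    r("CE2", "CD2", "CG", "CB", 1.390, 120.8, 0L, 180, "C", "aroC"),
    r("CZ",  "CE1", "CD1", "CG", 1.390, 120.0, 0L, 0,  "C", "aroC")),
  TYR = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.510, 113.8, 1L, 0,   "C", "aroC"),
    r("CD1", "CG", "CB", "CA", 1.390, 120.8, 2L, 0,   "C", "aroC"),
    r("CD2", "CG", "CB", "CA", 1.390, 120.8, 2L, 180, "C", "aroC"),
    r("CE1", "CD1", "CG", "CB", 1.390, 120.8, 0L, 180, "C", "aroC"),
    r("CE2", "CD2", "CG", "CB", 1.390, 120.8, 0L, 180, "C", "aroC"),
    r("CZ",  "CE1", "CD1", "CG", 1.390, 120.0, 0L, 0,  "C", "aroC"),
    r("OH",  "CZ", "CE1", "CD1", 1.376, 119.9, 0L, 180, "O", "OH")),
  TRP = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.500, 113.6, 1L, 0,   "C", "aroC"),
    r("CD1", "CG", "CB", "CA", 1.365, 126.9, 2L, 0,   "C", "aroC"),
    r("CD2", "CG", "CB", "CA", 1.433, 126.6, 2L, 180, "C", "aroC"),
    r("NE1", "CD1", "CG", "CB", 1.374, 110.2, 0L, 180, "N", "Ntrp"),
    r("CE2", "CD2", "CG", "CB", 1.409, 107.2, 0L, 180, "C", "aroC"),
    r("CE3", "CD2", "CG", "CB", 1.398, 133.9, 0L, 0,   "C", "aroC"),
    r("CZ2", "CE2", "CD2", "CG", 1.394, 122.4, 0L, 180, "C", "aroC"),
    r("CZ3", "CE3", "CD2", "CG", 1.391, 118.7, 0L, 180, "C", "aroC"),
    r("CH2", "CZ2", "CE2", "CD2", 1.368, 117.5, 0L, 180, "C", "aroC")),
  PRO = rbind(.CB(),
    r("CG",  "CB", "CA", "N",  1.492, 104.5, 1L, 0, "C", "CH"),
    r("CD",  "CG", "CB", "CA", 1.503, 105.4, 2L, 0, "C", "CH"))
  )
})

#' Side-chain topology table for a residue type
#'
#' @param restype 3-letter amino-acid code.
#' @return data.frame with one row per side-chain heavy atom (NeRF reference
#'   atoms, ideal bond length/angle, chi assignment, element, atom type).
#' @export
res_topology <- function(restype) {
  topo <- .SC_TOPO[[toupper(restype)]]
  if (is.null(topo)) stop("unknown residue type: ", restype)
  topo
}

#' Number of side-chain chi angles of a residue type
#' @param restype 3-letter code.
#' @export
n_chi <- function(restype) {
  v <- .N_CHI[toupper(restype)]
  if (is.na(v)) stop("unknown residue type: ", restype)
  unname(v)
}

# parent ("base atom") map of a residue: each atom's parent in the tree
# rooted at the backbone, growing out along the side chain
.res_parent_map <- function(restype) {
  topo <- res_topology(restype)
  p <- c(N = NA_character_, CA = "N", C = "CA", O = "C")
  if (nrow(topo)) p <- c(p, setNames(topo$p3, topo$name))
  p
}

# atom -> type map (backbone + side chain)
.res_atom_types <- function(restype) {
  topo <- res_topology(restype)
  ty <- c(N = if (toupper(restype) == "PRO") "Npro" else "Nbb",
          CA = "CAbb", C = "CObb", O = "OCbb")
  if (nrow(topo)) ty <- c(ty, setNames(topo$type, topo$name))
  ty
}

.type_is_donor <- function(type) {
  vapply(type, function(t) {
    p <- .TYPE_PROPS[[t]]
    !is.null(p) && p[["don"]]
  }, logical(1))
}

.type_is_acceptor <- function(type) {
  vapply(type, function(t) {
    p <- .TYPE_PROPS[[t]]
    !is.null(p) && p[["acc"]]
  }, logical(1))
}

.element_radius <- function(elem) {
  r <- .ELEMENT_RADII[toupper(elem)]
  r[is.na(r)] <- 1.7
  unname(r)
}

# element guessed from a PDB-style atom name (digits stripped, first letter)
.element_from_name <- function(name) {
  e <- sub("^[0-9]*", "", name)
  substr(e, 1, 1)
}

#' Build side-chain heavy atoms from backbone coordinates and chi angles
#'
#' @param bb named 3x3 matrix (rows N, CA, C) of backbone coordinates.
#' @param restype 3-letter code.
#' @param chi numeric vector of chi angles (degrees), length `n_chi(restype)`.
#' @return coordinate matrix with atom-name rownames (CB first), possibly
#'   zero rows for glycine.
#' @export
build_sidechain <- function(bb, restype, chi = numeric(0)) {
  restype <- toupper(restype)
  topo <- res_topology(restype)
  if (length(chi) != n_chi(restype))
    stop(restype, " needs ", n_chi(restype), " chi angles, got ", length(chi))
  coords <- rbind(bb)
  if (!all(c("N", "CA", "C") %in% rownames(coords)))
    stop("backbone must provide N, CA, C")
  if (nrow(topo) == 0) return(matrix(numeric(0), 0, 3))
  for (i in seq_len(nrow(topo))) {
    row <- topo[i, ]
    tors <- if (row$chi > 0) chi[row$chi] + row$tors else row$tors
    q <- place_atom(coords[row$p1, ], coords[row$p2, ], coords[row$p3, ],
                    row$d, row$theta, tors)
    coords <- rbind(coords, matrix(q, 1, 3, dimnames = list(row$name)))
  }
  coords[topo$name, , drop = FALSE]
}

#' Measure the chi angles of a residue from its coordinates
#'
#' @param coords coordinate matrix with atom-name rownames (backbone and
#'   side-chain heavy atoms).
#' @param restype 3-letter code.
#' @return numeric vector of chi angles in degrees.
#' @export
measure_chis <- function(coords, restype) {
  restype <- toupper(restype)
  topo <- res_topology(restype)
  nc <- n_chi(restype)
  if (nc == 0) return(numeric(0))
  chis <- numeric(nc)
  for (k in seq_len(nc)) {
    row <- topo[topo$chi == k & topo$tors == 0, ][1, ]
    chis[k] <- dihedral_deg(coords[row$p1, ], coords[row$p2, ], coords[row$p3, ],
                            coords[row$name, ])
  }
  chis
}

# --- reduced rotamer library -------------------------------------------------

.EX_STEP <- 20  # ex1/ex2 add +-(step/2) = +-10 degree satellites

#' Chi-sample grid of the reduced rotamer library
#'
#' Three canonical samples per rotatable chi (-60, 60, 180); `ex1`/`ex2`
#' triple the chi1/chi2 samples by adding satellites 10 degrees either side
#' of each canonical value. Proline is restricted to its single ring-closed
#' rotamer.
#'
#' @param restype 3-letter code.
#' @param ex1,ex2 logical extra-sampling flags.
#' @return list of numeric sample vectors, one per chi.
#' @export
chi_sample_grid <- function(restype, ex1 = FALSE, ex2 = FALSE) {
  restype <- toupper(restype)
  nc <- n_chi(restype)
  if (nc == 0) return(list())
  if (restype == "PRO") return(list(-27, 36))
  base <- c(-60, 60, 180)
  grid <- rep(list(base), nc)
  half <- .EX_STEP / 2
  if (ex1) grid[[1]] <- sort(.wrap180(c(base - half, base, base + half)))
  if (ex2 && nc >= 2) grid[[2]] <- sort(.wrap180(c(base - half, base, base + half)))
  grid
}
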