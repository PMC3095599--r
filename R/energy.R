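# Simplified pairwise energy model used by all design stages. This is a
# documented stand-in score with the protocol-relevant structure - a capped
# soft Lennard-Jones repulsion, a short-range attractive well, a geometric
# hydrogen-bond term, per-residue-type reference energies and the restraint
# term - not a reproduction of any published force field; absolute values
# are not comparable to published REU scales, only the protocol logic is.

#' Construct the simplified energy model
#'
#' @param w_rep,w_atr,w_hb,w_cst non-negative term weights (repulsive,
#'   attractive, hydrogen bond, restraint).
#' @param soft_rep use the softer repulsive variant (contact radii scaled
#'   down), as selected during design.
#' @param ref named per-residue-type reference energies (REU), added once
#'   per residue; mildly penalizes large side chains.
#' @return an `energy_model`.
#' @export
energy_model <- function(w_rep = 1, w_atr = 1, w_hb = 1, w_cst = 1,
                         soft_rep = FALSE, ref = NULL) {
  stopifnot(w_rep >= 0, w_atr >= 0, w_hb >= 0, w_cst >= 0)
  if (is.null(ref)) {
    ref <- setNames(rep(0, length(.AA3)), .AA3)
    ref[c("TRP", "TYR", "PHE", "ARG", "LYS", "MET")] <- 0.4
    ref[c("LEU", "ILE", "GLU", "GLN", "HIS")] <- 0.2
  }
  structure(list(w_rep = w_rep, w_atr = w_atr, w_hb = w_hb, w_cst = w_cst,
                 soft_rep = soft_rep, ref = ref), class = "energy_model")
}

# contact-distance scale on summed vdW radii; the LJ minimum sits at the
# scaled sum, so 0.92 places it at the close-packing distances of ideal
# secondary structure instead of flagging them as overlap
.sigma_scale <- function(em) if (isTRUE(em$soft_rep)) 0.85 else 0.92

# per-atom physical properties plus donor base coordinates for a set of
# structure atom rows
.atom_props <- function(s, rows) {
  a <- s$atoms[rows, , drop = FALSE]
  n <- nrow(a)
  rad <- .element_radius(a$element)
  don <- logical(n); acc <- logical(n)
  base <- as.matrix(a[, c("x", "y", "z")])  # fallback: own position
  # protein atoms: types/parents from the residue topology tables
  pr <- which(!a$het)
  if (length(pr)) {
    for (i in pr) {
      ty <- .res_atom_types(a$resname[i])[a$name[i]]
      if (!is.na(ty)) {
        don[i] <- .type_is_donor(ty)
        acc[i] <- .type_is_acceptor(ty)
      }
      pmap <- .res_parent_map(a$resname[i])
      par <- pmap[a$name[i]]
      if (!is.null(par) && is.na(par) && a$name[i] == "N") par <- "CA"
      if (!is.null(par) && !is.na(par)) {
        hit <- s$atoms$resi == a$resi[i] & !s$atoms$het & s$atoms$name == par
        if (any(hit)) base[i, ] <- as.numeric(s$atoms[which(hit)[1], c("x", "y", "z")])
      }
    }
  }
  lg <- which(a$het)
  if (length(lg) && !is.null(s$ligand)) {
    lp <- s$ligand
    ix <- match(a$name[lg], lp$atoms$name)
    don[lg] <- .type_is_donor(lp$atoms$type[ix])
    acc[lg] <- .type_is_acceptor(lp$atoms$type[ix])
    for (k in seq_along(lg)) {
      par <- lp$parent[[a$name[lg[k]]]]
      if (!is.null(par) && !is.na(par)) {
        hit <- s$atoms$het & s$atoms$name == par
        if (any(hit)) base[lg[k], ] <- as.numeric(s$atoms[which(hit)[1], c("x", "y", "z")])
      }
    }
  }
  heavy <- a$element != "H"
  list(xyz = as.matrix(a[, c("x", "y", "z")])[heavy, , drop = FALSE],
       rad = rad[heavy], don = don[heavy], acc = acc[heavy],
       base = base[heavy, , drop = FALSE])
}

# raw pair-term sums between two atom-row groups
.group_energy <- function(s, rows_a, rows_b, em, skip = NULL) {
  if (!length(rows_a) || !length(rows_b)) return(list(rep = 0, atr = 0, hb = 0))
  A <- .atom_props(s, rows_a)
  B <- .atom_props(s, rows_b)
  if (is.null(skip)) skip <- matrix(0L, 0, 2)
  cpp_pair_energy(A$xyz, A$rad, A$don, A$acc, A$base,
                  B$xyz, B$rad, B$don, B$acc, B$base,
                  .sigma_scale(em), skip)
}

.weighted <- function(e, em) em$w_rep * e$rep + em$w_atr * e$atr + em$w_hb * e$hb

# rows of a residue's atoms / the ligand's atoms
.res_rows <- function(s, resi) which(!s$atoms$het & s$atoms$resi == resi)
.lig_rows <- function(s) which(s$atoms$het)

# 1-2/1-3 neighborhood of an atom within a residue or the ligand topology
.bonded_13 <- function(parent_map, children_map, atom) {
  nb <- unique(c(atom,
                 parent_map[[atom]],
                 children_map[[atom]],
                 parent_map[[parent_map[[atom]] %||% "."]] %||% character(0),
                 unlist(lapply(children_map[[atom]], function(k) children_map[[k]])),
                 children_map[[parent_map[[atom]] %||% "."]] %||% character(0)))
  nb[!is.na(nb)]
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

# covalent-flag exclusions: for blocks whose distanceAB is declared
# covalent, the constrained atom pair and their 1-2/1-3 bonded neighbors
# are exempt from the LJ terms between that residue and the ligand
.covalent_pairs <- function(s, theo) {
  out <- list()
  if (is.null(theo)) return(out)
  catal <- catalytic_residues(s)
  for (i in seq_along(theo$blocks)) {
    b <- theo$blocks[[i]]
    dp <- b$params[["distanceAB"]]
    if (is.null(dp) || dp$fourth != 1) next
    lside <- .ligand_side(b, s$ligand_name)
    if (is.na(lside)) next
    resi <- catal$resi[catal$block == i][1]
    if (is.na(resi)) next
    rt <- res_table(s)
    restype <- rt$resname[match(resi, rt$resi)]
    pm_prot <- b[[if (lside == "map1") "map2" else "map1"]]
    prot_atoms <- unique(unlist(lapply(resolve_atom_triples(pm_prot, restype),
                                       `[`, 1)))
    lig_atoms <- unique(unlist(lapply(resolve_atom_triples(b[[lside]], s$ligand),
                                      `[`, 1)))
    # expand both sides to their 1-2/1-3 bonded neighbors
    ppar <- as.list(.res_parent_map(restype))
    pch <- split(names(ppar)[!is.na(unlist(ppar))], unlist(ppar)[!is.na(unlist(ppar))])
    prot_nb <- unique(unlist(lapply(prot_atoms, function(a2) .bonded_13(ppar, pch, a2))))
    lpar <- as.list(s$ligand$parent)
    lch <- split(names(lpar)[!is.na(unlist(lpar))], unlist(lpar)[!is.na(unlist(lpar))])
    lig_nb <- unique(unlist(lapply(lig_atoms, function(a2) .bonded_13(lpar, lch, a2))))
    out[[length(out) + 1]] <- list(resi = resi, res_atoms = prot_nb,
                                   lig_atoms = lig_nb)
  }
  out
}

# skip-pair matrix (0-based heavy-atom indices) for a residue/ligand pair
.skip_matrix <- function(s, rows_res, rows_lig, excl) {
  if (is.null(excl)) return(matrix(0L, 0, 2))
  ar <- s$atoms[rows_res, ]; al <- s$atoms[rows_lig, ]
  hr <- which(ar$element != "H"); hl <- which(al$element != "H")
  ia <- which(ar$name[hr] %in% excl$res_atoms) - 1L
  ib <- which(al$name[hl] %in% excl$lig_atoms) - 1L
  if (!length(ia) || !length(ib)) return(matrix(0L, 0, 2))
  as.matrix(expand.grid(ia, ib))
}

#' Score a structure under the simplified energy model
#'
#' Sums the pairwise terms over residue pairs (adjacent-residue backbone
#' pairs excluded as bonded), protein-ligand terms, reference energies and,
#' when a theozyme is given, the restraint score (reported separately;
#' `total` excludes it, following the scorefile convention).
#'
#' @param s structure.
#' @param theo optional `theozyme` for the restraint term and covalent
#'   exclusions.
#' @param em an `energy_model`.
#' @return list with total, fa_rep, fa_atr, hbond_sc, ref, all_cst, sr.
#' @export
score_structure <- function(s, theo = NULL, em = energy_model()) {
  rt <- res_table(s)
  n <- nrow(rt)
  ca <- t(vapply(rt$resi, function(r) {
    m <- res_atoms(s, r); m["CA", ]
  }, numeric(3)))
  rows <- lapply(rt$resi, function(r) .res_rows(s, r))
  rep_s <- atr_s <- hb_s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sum((ca[i, ] - ca[j, ])^2) > 144) next
      ri <- rows[[i]]; rj <- rows[[j]]
      if (abs(i - j) == 1) {  # exclude bonded backbone/backbone pairs
        ri <- ri[!s$atoms$name[ri] %in% c("N", "CA", "C", "O")]
        if (!length(ri)) next
      }
      e <- .group_energy(s, ri, rj, em)
      rep_s <- rep_s + e$rep; atr_s <- atr_s + e$atr; hb_s <- hb_s + e$hb
    }
  }
  lrows <- which(s$atoms$het)
  cov <- .covalent_pairs(s, theo)
  if (length(lrows)) {
    for (i in seq_len(n)) {
      excl <- NULL
      for (cv in cov) if (cv$resi == rt$resi[i]) excl <- cv
      skip <- .skip_matrix(s, rows[[i]], lrows, excl)
      e <- .group_energy(s, rows[[i]], lrows, em, skip = skip)
      rep_s <- rep_s + e$rep; atr_s <- atr_s + e$atr; hb_s <- hb_s + e$hb
    }
  }
  refE <- sum(em$ref[rt$resname], na.rm = TRUE)
  cst <- if (!is.null(theo)) all_cst(s, theo) else list(total = 0, sr = numeric(0))
  list(total = em$w_rep * rep_s + em$w_atr * atr_s + em$w_hb * hb_s + refE,
       fa_rep = rep_s, fa_atr = atr_s, hbond_sc = hb_s, ref = refE,
       all_cst = cst$total, sr = cst$sr)
}

#' Protein-ligand interface score
#'
#' The sum of the weighted pairwise terms between protein and ligand atoms
#' (restraints excluded). Equals score(complex) - score(protein alone) -
#' score(ligand alone) for this pairwise-decomposable model.
#'
#' @param s structure with a ligand.
#' @param em energy model.
#' @param theo optional theozyme for covalent exclusions.
#' @return interface energy (REU-like).
#' @export
interface_score <- function(s, em = energy_model(), theo = NULL) {
  lrows <- .lig_rows(s)
  if (!length(lrows)) stop("structure has no ligand")
  rt <- res_table(s)
  cov <- .covalent_pairs(s, theo)
  tot <- 0
  for (r in rt$resi) {
    excl <- NULL
    for (cv in cov) if (cv$resi == r) excl <- cv
    rr <- .res_rows(s, r)
    skip <- .skip_matrix(s, rr, lrows, excl)
    tot <- tot + .weighted(.group_energy(s, rr, lrows, em, skip = skip), em)
  }
  tot
}
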