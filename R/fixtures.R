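# Deterministic synthetic fixtures: a helix-loop-helix toy scaffold with a
# concave groove, a simplified dihydroxyacetone-like ligand (phosphate
# omitted), a three-interaction triosephosphate-isomerase-style theozyme
# (Glu/Asp base, His polarizing the carbonyl, Lys polarizing the same
# oxygen), and planted-match ground truth for end-to-end matcher tests.
#
# The theozyme numbers here are fixture data chosen to be chemically
# sensible hydrogen-bond/proton-abstraction geometries; they are not taken
# from any crystal structure.

# ideal backbone geometry
.BB <- list(d_n_ca = 1.458, d_ca_c = 1.525, d_c_n = 1.329, d_c_o = 1.231,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.5)

# build a backbone chain (N, CA, C, O per residue) from phi/psi, omega = 180
.build_chain <- function(phi, psi) {
  n <- length(phi)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$d_n_ca, 0, 0)
  C[1, ] <- place_atom(c(0, 0, 1), N[1, ], CA[1, ], .BB$d_ca_c, .BB$ang_n_ca_c, 57.8)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], .BB$d_c_n,
                         .BB$ang_ca_c_n, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], .BB$d_n_ca,
                          .BB$ang_c_n_ca, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], .BB$d_ca_c,
                         .BB$ang_n_ca_c, phi[i])
  }
  for (i in 1:n) {
    ps <- if (i < n) psi[i] else 180
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], .BB$d_c_o, .BB$ang_ca_c_o,
                         ps + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

#' Build a deterministic toy scaffold with a concave pocket
#'
#' Two antiparallel helices joined by a turn form a wedge-shaped groove
#' (the pocket). Residues are poly-alanine on an idealized-geometry
#' backbone; the seed adds small torsion jitter only, so bond lengths stay
#' ideal. The pocket centroid and the pocket-lining positions are attached
#' as attributes `pocket_centroid` and `pocket_positions`.
#'
#' @param n_residues chain length (>= 20).
#' @param seed RNG seed; equal seeds give bit-identical structures.
#' @return an `enz_structure`.
#' @export
make_toy_scaffold <- function(n_residues = 40, seed = 1) {
  stopifnot(n_residues >= 20)
  nl <- 4
  nh1 <- floor((n_residues - nl) / 2)
  nh2 <- n_residues - nl - nh1
  loop <- rbind(c(-60, 130), c(60, 30), c(60, 30), c(-90, 0))
  phi <- c(rep(-57, nh1), loop[, 1], rep(-57, nh2))
  psi <- c(rep(-47, nh1), loop[, 2], rep(-47, nh2))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  jit <- function(x, sd, cap) x + pmax(-cap, pmin(cap, rnorm(length(x), 0, sd)))
  hel <- c(seq_len(nh1), (nh1 + nl + 1):n_residues)
  phi[hel] <- jit(phi[hel], 1.5, 3); psi[hel] <- jit(psi[hel], 1.5, 3)
  lo <- (nh1 + 1):(nh1 + nl)
  phi[lo] <- jit(phi[lo], 0.5, 1); psi[lo] <- jit(psi[lo], 0.5, 1)
  ch <- .build_chain(phi, psi)
  rows <- list()
  for (i in seq_len(n_residues)) {
    bb <- rbind(N = ch$N[i, ], CA = ch$CA[i, ], C = ch$C[i, ])
    cb <- build_sidechain(bb, "ALA", numeric(0))
    m <- rbind(bb, O = ch$O[i, ], CB = cb["CB", ])
    rows[[i]] <- data.frame(resi = i, chain = "A", resno = i, resname = "ALA",
                            name = rownames(m),
                            element = .element_from_name(rownames(m)),
                            x = m[, 1], y = m[, 2], z = m[, 3], het = FALSE)
  }
  s <- new_structure(do.call(rbind, rows))
  pk <- scaffold_pocket(s)
  attr(s, "pocket_centroid") <- pk$centroid
  attr(s, "pocket_positions") <- pk$positions
  s
}

# save/restore global RNG state so fixture generation is self-contained
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Locate the pocket of a toy scaffold
#'
#' The centroid is the midpoint of the facing CA pair closest to 10.5 A
#' apart across the two chain halves; pocket positions are residues whose
#' CA lies within 9 A of the centroid with the CB vector pointing inward.
#'
#' @param s a scaffold structure.
#' @return list with `centroid` (xyz) and `positions` (residue indices).
#' @export
scaffold_pocket <- function(s) {
  rt <- res_table(s)
  n <- nrow(rt)
  ca <- t(vapply(rt$resi, function(r) res_atoms(s, r)["CA", ], numeric(3)))
  half1 <- rt$resi[seq_len(floor(n / 2) - 2)]
  half2 <- rt$resi[(floor(n / 2) + 3):n]
  best <- NULL
  for (i in half1) for (j in half2) {
    d <- sqrt(sum((ca[i, ] - ca[j, ])^2))
    if (d > 8.5 && d < 13 && (is.null(best) || abs(d - 10.5) < best$dev))
      best <- list(i = i, j = j, dev = abs(d - 10.5))
  }
  if (is.null(best)) stop("scaffold has no groove of pocket-like width")
  centroid <- (ca[best$i, ] + ca[best$j, ]) / 2
  pos <- integer(0)
  for (r in rt$resi) {
    m <- res_atoms(s, r)
    if (sqrt(sum((m["CA", ] - centroid)^2)) > 9) next
    if (!"CB" %in% rownames(m)) next
    v <- m["CB", ] - m["CA", ]
    if (sum(v * (centroid - m["CA", ])) > 0) pos <- c(pos, r)
  }
  list(centroid = centroid, positions = pos)
}

.DHAP_PARAMS <- c(
  "NAME DHL",
  "ATOM C1 C CH2",
  "ATOM C2 C CObb",
  "ATOM O2 O OCbb",
  "ATOM C3 C CH3",
  "ATOM O1 O OH",
  "ATOM HO1 H Hpol",
  "BOND C1 C2", "BOND C2 O2", "BOND C2 C3", "BOND C1 O1", "BOND O1 HO1",
  "ICOOR C1 0.0 0.0 0.0 C1 C2 O2",
  "ICOOR C2 1.50 0.0 0.0 C1 C2 O2",
  "ICOOR O2 1.23 120.0 0.0 C2 C1 O2",
  "ICOOR C3 1.50 121.0 180.0 C2 C1 O2",
  "ICOOR O1 1.42 109.5 0.0 C1 C2 O2",
  "ICOOR HO1 0.96 107.0 180.0 O1 C1 C2",
  "FRAME C1 C2 O2")

#' The fixture ligand: a simplified dihydroxyacetone (phosphate omitted)
#'
#' Atoms C1 (the carbon bearing the abstractable proton), C2 with carbonyl
#' oxygen O2, terminal C3, hydroxyl O1 with its polar hydrogen. The 6D-pose
#' frame is C1/C2/O2.
#'
#' @return an `enz_ligand` topology.
#' @export
make_ligand_dhap <- function() {
  tf <- tempfile(fileext = ".params")
  on.exit(unlink(tf))
  writeLines(.DHAP_PARAMS, tf)
  read_ligand_params(tf)
}

#' The fixture theozyme: three TIM-like catalytic interactions
#'
#' Block 1: a Glu/Asp carboxylate oxygen poised to abstract the C1 proton
#' (classic matching, all six parameters). Block 2: a His imidazole
#' nitrogen hydrogen-bonding the carbonyl O2 in the substrate plane
#' (classic). Block 3: a Lys ammonium nitrogen polarizing O2 (secondary
#' matching; torsion_AB and torsion_B are deliberately undefined - they do
#' not matter for that interaction).
#'
#' @return list with `theozyme` and `ligand`.
#' @export
make_theozyme_tim <- function() {
  lig <- make_ligand_dhap()
  b1 <- cst_block(
    atom_map_spec(1, "by_name", names = c("C1", "C2", "O2"), allowed_residues = "DHL"),
    atom_map_spec(2, "by_type", type_symbol = "OOC",
                  allowed_residues = c("GLU", "ASP")),
    list(cst_param("distanceAB", 3.2, 0.3, 100, 0, 0),
         cst_param("angle_A", 109.5, 15, 60, 360, 1),
         cst_param("angle_B", 120, 15, 60, 360, 1),
         cst_param("torsion_A", 90, 20, 60, 360, 1),
         cst_param("torsion_AB", 180, 60, 0, 360, 1),
         cst_param("torsion_B", 180, 15, 60, 180, 0)),
    algorithm = "classic")
  b2 <- cst_block(
    atom_map_spec(1, "by_name", names = c("O2", "C2", "C1"), allowed_residues = "DHL"),
    atom_map_spec(2, "by_type", type_symbol = "Nhis", allowed_residues = "HIS"),
    list(cst_param("distanceAB", 2.9, 0.3, 100, 0, 0),
         cst_param("angle_A", 120, 15, 60, 360, 1),
         cst_param("angle_B", 120, 15, 60, 360, 1),
         cst_param("torsion_A", 180, 20, 60, 180, 0),
         cst_param("torsion_AB", 0, 90, 0, 360, 1),
         cst_param("torsion_B", 180, 20, 60, 180, 0)),
    algorithm = "classic")
  b3 <- cst_block(
    atom_map_spec(1, "by_name", names = c("O2", "C2", "C1"), allowed_residues = "DHL"),
    atom_map_spec(2, "by_type", type_symbol = "Nlys", allowed_residues = "LYS"),
    list(cst_param("distanceAB", 2.9, 0.4, 100, 0, 0),
         cst_param("angle_A", 109.5, 25, 60, 360, 0),
         cst_param("angle_B", 109.5, 25, 60, 360, 0),
         cst_param("torsion_A", -60, 30, 60, 360, 0)),
    algorithm = "secondary")
  list(theozyme = theozyme(list(b1, b2, b3), ligand_name = "DHL"), ligand = lig)
}

# acceptance windows (vs the template values) for realized planted geometry
.PLANT_WINDOWS <- c(distanceAB = 0.6, angle_A = 35, angle_B = 35,
                    torsion_A = 50, torsion_AB = 180, torsion_B = 50)

#' Plant a theozyme match into a scaffold (inverse construction)
#'
#' Chooses pocket positions and library rotamers realizing each theozyme
#' interaction, places the ligand from the first block's geometry, and
#' records the ground truth. Because library rotamers on a fixed backbone
#' cannot hit arbitrary pre-specified geometry exactly, the input theozyme
#' acts as a template: each planted block's ideal values are set to the
#' realized geometry of the chosen rotamer (kept within chemically sensible
#' windows of the template), so the returned theozyme scores the planted
#' site exactly zero.
#'
#' @param scaffold a toy scaffold from [make_toy_scaffold()].
#' @param theo template `theozyme` (default [make_theozyme_tim()]).
#' @param ligand ligand topology (default the fixture ligand).
#' @param seed RNG seed for deterministic candidate ordering.
#' @param cfg `match_config` whose clash factor is honored.
#' @return a planted site: list with `scaffold` (clean input scaffold),
#'   `planted` (scaffold with grafted residues + ligand + annotations),
#'   `theozyme` (adjusted), `ligand`, and `truth` (positions, restypes,
#'   chis, ligand coordinates and 6D pose).
#' @export
plant_site <- function(scaffold, theo = NULL, ligand = NULL, seed = 1,
                       cfg = match_config()) {
  if (is.null(theo) || is.null(ligand)) {
    tz <- make_theozyme_tim()
    if (is.null(theo)) theo <- tz$theozyme
    if (is.null(ligand)) ligand <- tz$ligand
  }
  validate_theozyme(theo)
  centroid <- attr(scaffold, "pocket_centroid")
  positions <- attr(scaffold, "pocket_positions")
  if (is.null(centroid)) {
    pk <- scaffold_pocket(scaffold)
    centroid <- pk$centroid; positions <- pk$positions
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  wall <- .wall_atoms(scaffold)
  lig_hv <- ligand$atoms$element != "H"
  lig_rad <- .element_radius(ligand$atoms$element[lig_hv])

  b1 <- theo$blocks[[1]]
  lside1 <- .ligand_side(b1, ligand$name)
  if (is.na(lside1)) stop("first theozyme block must involve the ligand")
  prot_map1 <- b1[[if (lside1 == "map1") "map2" else "map1"]]
  lig_map1 <- b1[[lside1]]
  lig_triple1 <- resolve_atom_triples(lig_map1, ligand)[[1]]
  free <- names(b1$params)[vapply(b1$params, function(p) p$k == 0, logical(1))]
  sc_rows <- function(coords) coords[setdiff(rownames(coords), c("N", "CA", "C")), , drop = FALSE]
  rad_of <- function(m) .element_radius(.element_from_name(rownames(m)))

  # plant blocks 2..N against a fixed ligand placement; NULL when impossible
  plant_rest <- function(placement) {
    chosen <- list(placement)
    used <- placement$pos
    planted_sc <- sc_rows(placement$rot$coords)
    hv <- placement$lig[lig_hv, , drop = FALSE]
    for (bi in seq_along(theo$blocks)[-1]) {
      b <- theo$blocks[[bi]]
      lside <- .ligand_side(b, ligand$name)
      if (is.na(lside)) stop("fixture planting supports ligand-mediated blocks only")
      prot_map <- b[[if (lside == "map1") "map2" else "map1"]]
      ltr <- resolve_atom_triples(b[[lside]], ligand)[[1]]
      lig_t <- placement$lig[ltr, , drop = FALSE]
      best <- NULL
      for (relax in c(1, 1.5, 2.1)) {
        for (pos in setdiff(positions, used)) {
          rots <- build_rotamers(scaffold, pos, intersect(prot_map$allowed_residues, .AA3))
          for (r in rots) {
            trs <- resolve_atom_triples(prot_map, r$restype)
            for (tr in trs) {
              if (!all(tr %in% rownames(r$coords))) next
              pt <- r$coords[tr, , drop = FALSE]
              meas <- if (lside == "map1") measure_params(lig_t, pt)
                      else measure_params(pt, lig_t)
              dev <- 0; ok <- TRUE
              for (p in b$params) {
                v <- meas[[p$name]]
                if (is.na(v)) { ok <- FALSE; break }
                dlt <- if (p$name == "distanceAB") abs(v - p$x0)
                       else periodic_delta(v, p$x0, 360)
                w <- .PLANT_WINDOWS[[p$name]] * relax
                if (dlt > w) { ok <- FALSE; break }
                dev <- dev + (dlt / w)^2
              }
              if (!ok) next
              sc <- sc_rows(r$coords)
              if (cpp_has_clash(sc, rad_of(sc), hv, lig_rad, 0.6)) next
              if (cpp_has_clash(sc, rad_of(sc), planted_sc, rad_of(planted_sc), 0.6)) next
              if (is.null(best) || dev < best$dev)
                best <- list(pos = pos, rot = r, triple = tr, meas = meas, dev = dev)
            }
          }
        }
        if (!is.null(best)) break
      }
      if (is.null(best)) return(NULL)
      chosen[[bi]] <- best
      used <- c(used, best$pos)
      planted_sc <- rbind(planted_sc, sc_rows(best$rot$coords))
    }
    chosen
  }

  chosen <- NULL
  tries <- 0
  for (pos in sample(positions)) {
    rots <- build_rotamers(scaffold, pos, intersect(prot_map1$allowed_residues, .AA3))
    for (r in sample(rots)) {
      trs <- resolve_atom_triples(prot_map1, r$restype)
      for (tr in sample(trs)) {
        if (!all(tr %in% rownames(r$coords))) next
        # candidate tuples: the template center, then random draws inside the
        # flat-bottom region (free k=0 parameters roam their whole range)
        for (ci in seq_len(12)) {
          tup <- vapply(b1$params[.PORDER], function(p) p$x0, numeric(1))
          names(tup) <- .PORDER
          if (ci > 1) {
            for (pn in .PORDER) {
              p <- b1$params[[pn]]
              spread <- if (p$k == 0) p$xtol else 0.8 * p$xtol
              tup[pn] <- p$x0 + runif(1, -spread, spread)
            }
          }
          tup_k <- if (lside1 == "map1") .swap_params(tup) else tup
          lp <- build_ligand_placement(r$coords[tr, ], tup_k, ligand, lig_triple1)
          hv <- lp[lig_hv, , drop = FALSE]
          if (max(sqrt(rowSums(sweep(hv, 2, centroid)^2))) > 10) next
          if (sqrt(sum((colMeans(hv) - centroid)^2)) > 6) next
          if (cpp_has_clash(hv, lig_rad, wall$xyz, wall$rad, cfg$clash_factor)) next
          sco <- sc_rows(r$coords)
          if (cpp_has_clash(hv, lig_rad, sco, rad_of(sco), 0.55)) next
          tries <- tries + 1
          if (tries > 800) break
          chosen <- plant_rest(list(pos = pos, rot = r, triple = tr, lig = lp))
          if (!is.null(chosen)) break
        }
        if (!is.null(chosen) || tries > 800) break
      }
      if (!is.null(chosen) || tries > 800) break
    }
    if (!is.null(chosen) || tries > 800) break
  }
  if (is.null(chosen))
    stop("could not plant the theozyme after ", tries,
         " candidate placements; try a larger pocket")
  placement <- chosen[[1]]
  # adjust every block's ideal values to the realized geometry
  meas1 <- if (lside1 == "map1") {
    measure_params(placement$lig[lig_triple1, ], placement$rot$coords[placement$triple, ])
  } else {
    measure_params(placement$rot$coords[placement$triple, ], placement$lig[lig_triple1, ])
  }
  for (pn in names(theo$blocks[[1]]$params))
    theo$blocks[[1]]$params[[pn]]$x0 <- unname(meas1[[pn]])
  used <- vapply(chosen, `[[`, 0L, "pos")
  for (bi in seq_along(theo$blocks)[-1]) {
    for (pn in names(theo$blocks[[bi]]$params))
      theo$blocks[[bi]]$params[[pn]]$x0 <- unname(chosen[[bi]]$meas[[pn]])
  }

  planted <- scaffold
  for (ch in chosen)
    planted <- mutate_residue(planted, ch$pos, ch$rot$restype, ch$rot$chi)
  rt <- res_table(planted)
  lrows <- data.frame(resi = NA_integer_, chain = rt$chain[1],
                      resno = max(rt$resno) + 1L, resname = ligand$name,
                      name = rownames(placement$lig),
                      element = ligand$atoms$element[match(rownames(placement$lig),
                                                           ligand$atoms$name)],
                      x = placement$lig[, 1], y = placement$lig[, 2],
                      z = placement$lig[, 3], het = TRUE, backbone = FALSE)
  catal <- data.frame(block = seq_along(chosen),
                      chain = rt$chain[match(used, rt$resi)],
                      resno = rt$resno[match(used, rt$resi)],
                      resname = vapply(chosen, function(ch) ch$rot$restype, ""))
  planted <- new_structure(rbind(planted$atoms[!planted$atoms$het, ], lrows),
                           catal, ligand_name = ligand$name, ligand = ligand)
  truth <- list(positions = used,
                restypes = vapply(chosen, function(ch) ch$rot$restype, ""),
                chis = lapply(chosen, function(ch) ch$rot$chi),
                lig_coords = placement$lig,
                pose = pose6d_of(placement$lig, ligand))
  list(scaffold = scaffold, planted = planted, theozyme = theo,
       ligand = ligand, truth = truth)
}

#' Write a complete worked fixture directory
#'
#' Emits scaffold.pdb (the clean scaffold), ligand.params, theozyme.cst
#' (the planted, self-consistent theozyme) and positions.pos, so the
#' matcher can be run on them end to end and recovers the planted site.
#'
#' @param dir output directory (created if needed).
#' @param seed fixture seed.
#' @param n_residues scaffold size.
#' @return the planted site, invisibly.
#' @export
write_fixture_set <- function(dir, seed = 1, n_residues = 40) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- make_toy_scaffold(n_residues, seed)
  ps <- plant_site(sc, seed = seed)
  write_pdb(sc, file.path(dir, "scaffold.pdb"))
  tf <- tempfile(); writeLines(.DHAP_PARAMS, tf)
  file.copy(tf, file.path(dir, "ligand.params"), overwrite = TRUE); unlink(tf)
  write_cstfile(ps$theozyme, file.path(dir, "theozyme.cst"))
  rt <- res_table(sc)
  writeLines(paste(rt$resno[match(attr(sc, "pocket_positions"), rt$resi)],
                   collapse = " "),
             file.path(dir, "positions.pos"))
  invisible(ps)
}
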