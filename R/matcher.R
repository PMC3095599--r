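# Matching: place the theozyme into a scaffold. Classic matching builds the
# ligand outward from each candidate side-chain rotamer through the sampled
# constraint parameters; secondary matching re-evaluates candidate rotamers
# against previously generated ligand placements. Hits are binned by the
# ligand's 6D pose and bins holding one hit per interaction become matches.

#' Matcher configuration
#'
#' @param euclid_bin Euclidean bin width (Angstrom) of the 6D hash.
#' @param euler_bin Euler-angle bin width (degrees).
#' @param clash_factor multiplier on summed vdW radii below which a
#'   ligand/backbone atom pair counts as a collision.
#' @param max_per_bin cap on matches extracted per hash bin.
#' @param ex1,ex2 extra chi1/chi2 rotamer sampling flags.
#' @param use_input_sc include each scaffold position's native rotamer.
#' @param algorithms optional character vector assigning "classic" or
#'   "secondary" per theozyme block (overrides the block's own setting).
#' @export
match_config <- function(euclid_bin = 1.0, euler_bin = 15, clash_factor = 0.7,
                         max_per_bin = 10, ex1 = FALSE, ex2 = FALSE,
                         use_input_sc = FALSE, algorithms = NULL) {
  stopifnot(euclid_bin > 0, euler_bin > 0,
            clash_factor > 0, clash_factor <= 1)
  structure(list(euclid_bin = euclid_bin, euler_bin = euler_bin,
                 clash_factor = clash_factor, max_per_bin = max_per_bin,
                 ex1 = ex1, ex2 = ex2, use_input_sc = use_input_sc,
                 algorithms = algorithms),
            class = "match_config")
}

#' Build side-chain rotamers at a scaffold position
#'
#' Chi samples come from the reduced library (three canonical values per
#' rotatable chi; see [chi_sample_grid()]); side chains are rebuilt by
#' internal-coordinate construction from the existing backbone. Glycine has
#' no side chain and yields no rotamers.
#'
#' @param s scaffold structure.
#' @param resi residue index to build at.
#' @param residue_types 3-letter codes to build.
#' @param ex1,ex2 extra chi1/chi2 sampling.
#' @param use_input append the position's native rotamer (measured chis).
#' @return list of rotamers: each has resi, restype, chi and a coordinate
#'   matrix `coords` (backbone + side chain).
#' @export
build_rotamers <- function(s, resi, residue_types, ex1 = FALSE, ex2 = FALSE,
                           use_input = FALSE) {
  bb_all <- res_atoms(s, resi)
  if (!all(c("N", "CA", "C") %in% rownames(bb_all)))
    stop("position ", resi, " lacks backbone N/CA/C")
  bb <- bb_all[c("N", "CA", "C"), ]
  native_type <- res_table(s)$resname[match(resi, res_table(s)$resi)]
  out <- list()
  for (ty in toupper(residue_types)) {
    if (n_chi(ty) == 0 && nrow(res_topology(ty)) == 0) next  # glycine
    grid <- chi_sample_grid(ty, ex1, ex2)
    combos <- if (length(grid)) as.matrix(expand.grid(grid)) else
      matrix(numeric(0), 1, 0)
    for (i in seq_len(nrow(combos))) {
      chi <- as.numeric(combos[i, ])
      sc <- build_sidechain(bb, ty, chi)
      out[[length(out) + 1]] <- list(resi = resi, restype = ty, chi = chi,
                                     coords = rbind(bb_all[c("N", "CA", "C"), ], sc))
    }
    if (use_input && ty == native_type && n_chi(ty) > 0) {
      chi <- tryCatch(measure_chis(bb_all, ty), error = function(e) NULL)
      if (!is.null(chi) && !anyNA(chi)) {
        sc <- build_sidechain(bb, ty, chi)
        out[[length(out) + 1]] <- list(resi = resi, restype = ty, chi = chi,
                                       coords = rbind(bb_all[c("N", "CA", "C"), ], sc))
      }
    }
  }
  out
}

# empty hit set
.empty_hits <- function(lig_names) {
  structure(list(meta = data.frame(interaction = integer(0), resi = integer(0),
                                   restype = character(0), score = numeric(0)),
                 chi = matrix(NA_real_, 0, 4),
                 coords = matrix(NA_real_, 0, 3 * length(lig_names)),
                 pose = matrix(NA_real_, 0, 6), lig_names = lig_names,
                 rejected = 0),
            class = "enz_hits")
}

#' Number of hits in a hit set
#' @param x an `enz_hits` object.
#' @export
n_hits <- function(x) nrow(x$meta)

#' Concatenate hit sets
#' @param ... `enz_hits` objects over the same ligand.
#' @export
bind_hits <- function(...) {
  hs <- list(...)
  hs <- hs[vapply(hs, n_hits, integer(1)) > 0 | seq_along(hs) == 1]
  out <- hs[[1]]
  for (h in hs[-1]) {
    stopifnot(identical(out$lig_names, h$lig_names))
    out$meta <- rbind(out$meta, h$meta)
    out$chi <- rbind(out$chi, h$chi)
    out$coords <- rbind(out$coords, h$coords)
    out$pose <- rbind(out$pose, h$pose)
    out$rejected <- out$rejected + h$rejected
  }
  out
}

#' @export
print.enz_hits <- function(x, ...) {
  cat("hit set:", n_hits(x), "hits")
  if (n_hits(x)) cat(" (interactions ", paste(sort(unique(x$meta$interaction)),
                                              collapse = ","), ")", sep = "")
  cat("; rejected placements:", x$rejected, "\n")
  invisible(x)
}

.chi_pad <- function(chi) c(chi, rep(NA_real_, 4 - length(chi)))

# batch 6D poses from flattened ligand coordinate rows
.batch_pose6d <- function(coords, lig_names, frame) {
  H <- nrow(coords)
  idx <- match(frame, lig_names)
  if (anyNA(idx)) stop("frame atoms missing from ligand")
  sl <- function(i) coords[, (3 * (i - 1) + 1):(3 * i), drop = FALSE]
  a1 <- sl(idx[1]); a2 <- sl(idx[2]); a3 <- sl(idx[3])
  pose <- matrix(NA_real_, H, 6,
                 dimnames = list(NULL, c("tx", "ty", "tz", "e1", "e2", "e3")))
  for (h in seq_len(H)) {
    Fm <- .frame_from_triple(a1[h, ], a2[h, ], a3[h, ])
    pose[h, ] <- c(a1[h, ], .euler_zxz(Fm))
  }
  pose
}

# canonical parameter order used by the kernels
.PORDER <- c("distanceAB", "angle_A", "angle_B", "torsion_A", "torsion_AB", "torsion_B")

# parameter arrays (x0/xtol/per/defined) of a block in canonical order,
# optionally swapped to exchange the Res1/Res2 roles
.block_param_arrays <- function(block, swap = FALSE) {
  x0 <- xtol <- per <- rep(NA_real_, 6)
  defined <- rep(FALSE, 6)
  for (p in block$params) {
    i <- match(p$name, .PORDER)
    x0[i] <- p$x0; xtol[i] <- p$xtol
    per[i] <- if (p$name == "distanceAB") 0 else p$fourth
    defined[i] <- TRUE
  }
  if (swap) {
    sw <- c(1, 3, 2, 6, 5, 4)
    x0 <- x0[sw]; xtol <- xtol[sw]; per <- per[sw]; defined <- defined[sw]
  }
  list(x0 = x0, xtol = xtol, per = per, defined = defined)
}

# Cartesian sample grid of a classic block, as a kernel-ready tuple matrix
# with Res1 = the protein side (columns in .PORDER order)
.classic_tuples <- function(block, ligand_is_map1) {
  samples <- lapply(block$params[.PORDER], enumerate_samples)
  g <- as.matrix(expand.grid(samples, KEEP.OUT.ATTRS = FALSE))
  colnames(g) <- .PORDER
  if (ligand_is_map1) g <- g[, c(1, 3, 2, 6, 5, 4), drop = FALSE]
  colnames(g) <- .PORDER
  g
}

# backbone wall atoms (N/CA/C/O/CB) within reach of a point
.wall_atoms <- function(s, center = NULL, reach = Inf) {
  a <- s$atoms[!s$atoms$het & s$atoms$name %in% c("N", "CA", "C", "O", "CB"), ]
  m <- as.matrix(a[, c("x", "y", "z")])
  if (!is.null(center) && is.finite(reach)) {
    keep <- rowSums(sweep(m, 2, center)^2) < reach^2
    a <- a[keep, ]; m <- m[keep, , drop = FALSE]
  }
  list(xyz = m, rad = .element_radius(a$element))
}

#' Classic matching for one theozyme interaction
#'
#' For every rotamer at every candidate position and every Cartesian sample
#' tuple of the block's six parameters, the ligand is placed by
#' internal-coordinate construction and kept as a hit when no ligand heavy
#' atom collides with the scaffold backbone.
#'
#' @param s scaffold structure.
#' @param block a `cst_block` defining all six parameters.
#' @param positions residue indices to match at.
#' @param ligand ligand topology.
#' @param cfg a `match_config`.
#' @param interaction index recorded on the hits.
#' @return an `enz_hits` set.
#' @export
classic_match_interaction <- function(s, block, positions, ligand, cfg = match_config(),
                                      interaction = 1L) {
  lside <- .ligand_side(block, ligand$name)
  if (is.na(lside))
    stop("classic matching needs a ligand-mediated block")
  lig_map <- block[[lside]]
  prot_map <- block[[if (lside == "map1") "map2" else "map1"]]
  types <- intersect(prot_map$allowed_residues, .AA3)
  lig_triples <- resolve_atom_triples(lig_map, ligand)
  tuples <- .classic_tuples(block, ligand_is_map1 = (lside == "map1"))
  lig_names <- rownames(ligand$conformer)
  lig_rad <- .element_radius(ligand$atoms$element[match(lig_names, ligand$atoms$name)])
  lig_heavy <- ligand$atoms$element[match(lig_names, ligand$atoms$name)] != "H"
  hits <- .empty_hits(lig_names)
  for (pos in positions) {
    rots <- build_rotamers(s, pos, types, cfg$ex1, cfg$ex2, cfg$use_input_sc)
    if (!length(rots)) next
    ca <- res_atoms(s, pos)["CA", ]
    wall <- .wall_atoms(s, ca, reach = 18)
    # anchor rows: one per (rotamer x resolved protein triple)
    anc <- list(); owner <- integer(0)
    for (ri in seq_along(rots)) {
      r <- rots[[ri]]
      trs <- tryCatch(resolve_atom_triples(prot_map, r$restype),
                      error = function(e) list())
      for (tr in trs) {
        if (!all(tr %in% rownames(r$coords))) next
        anc[[length(anc) + 1]] <- as.numeric(t(r$coords[tr, ]))
        owner <- c(owner, ri)
      }
    }
    if (!length(anc)) next
    anchors <- do.call(rbind, anc)
    for (lt in lig_triples) {
      aidx <- match(lt, lig_names) - 1L
      res <- cpp_classic_place(anchors, tuples, ligand$conformer, aidx,
                               wall$xyz, wall$rad, lig_rad, lig_heavy,
                               cfg$clash_factor)
      hits$rejected <- hits$rejected + res$rejected
      H <- length(res$rot)
      if (!H) next
      ri <- owner[res$rot]
      meta <- data.frame(interaction = interaction, resi = pos,
                         restype = vapply(rots[ri], `[[`, "", "restype"),
                         score = 0)
      chi <- do.call(rbind, lapply(rots[ri], function(r) .chi_pad(r$chi)))
      pose <- .batch_pose6d(res$coords, lig_names, ligand$frame)
      hits <- bind_hits(hits, structure(
        list(meta = meta, chi = chi, coords = res$coords, pose = pose,
             lig_names = lig_names, rejected = 0), class = "enz_hits"))
    }
  }
  hits
}

#' Secondary matching for one theozyme interaction
#'
#' Candidate rotamers are evaluated against previously generated hits: the
#' ligand (or partner rotamer) is realized from each prior hit and only the
#' block's defined parameters are checked; parameters absent from the block
#' are ignored. An accepted pair becomes a new hit whose 6D pose is copied
#' from the prior hit.
#'
#' @param s scaffold structure.
#' @param block a `cst_block` (any subset of parameters defined).
#' @param prior_hits an `enz_hits` set from earlier interactions.
#' @param positions residue indices to match at.
#' @param ligand ligand topology.
#' @param cfg a `match_config`.
#' @param interaction index recorded on the hits.
#' @return an `enz_hits` set.
#' @export
secondary_match_interaction <- function(s, block, prior_hits, positions, ligand,
                                        cfg = match_config(), interaction = 2L) {
  lig_names <- prior_hits$lig_names
  if (n_hits(prior_hits) == 0) {
    warning("secondary matching with no prior hits yields no hits")
    return(.empty_hits(lig_names))
  }
  lside <- .ligand_side(block, ligand$name)
  if (is.na(lside)) return(.secondary_sc_sc(s, block, prior_hits, positions, cfg, interaction))
  lig_map <- block[[lside]]
  prot_map <- block[[if (lside == "map1") "map2" else "map1"]]
  types <- intersect(prot_map$allowed_residues, .AA3)
  lig_triples <- resolve_atom_triples(lig_map, ligand)
  arr <- .block_param_arrays(block, swap = (lside == "map2"))
  # Res1 of the screen = the ligand side when the ligand is map1
  H <- n_hits(prior_hits)
  lig_rows <- list(); lig_owner <- integer(0)
  for (lt in lig_triples) {
    idx <- match(lt, lig_names)
    cols <- as.numeric(vapply(idx, function(i) (3 * (i - 1) + 1):(3 * i), numeric(3)))
    lig_rows[[length(lig_rows) + 1]] <- prior_hits$coords[, cols, drop = FALSE]
    lig_owner <- c(lig_owner, seq_len(H))
  }
  lig_mat <- do.call(rbind, lig_rows)
  hits <- .empty_hits(lig_names)
  for (pos in positions) {
    rots <- build_rotamers(s, pos, types, cfg$ex1, cfg$ex2, cfg$use_input_sc)
    if (!length(rots)) next
    anc <- list(); owner <- integer(0)
    for (ri in seq_along(rots)) {
      r <- rots[[ri]]
      trs <- tryCatch(resolve_atom_triples(prot_map, r$restype),
                      error = function(e) list())
      for (tr in trs) {
        if (!all(tr %in% rownames(r$coords))) next
        anc[[length(anc) + 1]] <- as.numeric(t(r$coords[tr, ]))
        owner <- c(owner, ri)
      }
    }
    if (!length(anc)) next
    anchors <- do.call(rbind, anc)
    ok <- if (lside == "map1") {
      t(cpp_secondary_screen(lig_mat, anchors, arr$defined, arr$x0, arr$xtol,
                             pmax(arr$per, 1e-9)))
    } else {
      cpp_secondary_screen(anchors, lig_mat, arr$defined, arr$x0, arr$xtol,
                           pmax(arr$per, 1e-9))
    }
    # ok: rows = anchor rows, cols = ligand triple rows; aggregate to
    # (rotamer, hit) acceptance over the triple candidates
    acc <- which(ok, arr.ind = TRUE)
    if (!nrow(acc)) next
    pair <- unique(data.frame(rot = owner[acc[, 1]], hit = lig_owner[acc[, 2]]))
    meta <- data.frame(interaction = interaction, resi = pos,
                       restype = vapply(pair$rot, function(i) rots[[i]]$restype, ""),
                       score = 0)
    chi <- do.call(rbind, lapply(pair$rot, function(i) .chi_pad(rots[[i]]$chi)))
    hits <- bind_hits(hits, structure(
      list(meta = meta, chi = chi,
           coords = prior_hits$coords[pair$hit, , drop = FALSE],
           pose = prior_hits$pose[pair$hit, , drop = FALSE],
           lig_names = lig_names, rejected = 0), class = "enz_hits"))
  }
  hits
}

# side-chain/side-chain secondary matching: the partner triple comes from
# the prior hit's rotamer instead of the ligand
.secondary_sc_sc <- function(s, block, prior_hits, positions, cfg, interaction) {
  prot1 <- block$map1; prot2 <- block$map2
  # partner = whichever map's allowed types include the prior hits' types
  partner_is_map1 <- all(prior_hits$meta$restype %in% prot1$allowed_residues)
  new_map <- if (partner_is_map1) prot2 else prot1
  arr <- .block_param_arrays(block, swap = !partner_is_map1)
  H <- n_hits(prior_hits)
  part_rows <- list(); part_owner <- integer(0)
  for (h in seq_len(H)) {
    resi <- prior_hits$meta$resi[h]
    ty <- prior_hits$meta$restype[h]
    chi <- prior_hits$chi[h, seq_len(n_chi(ty))]
    bb <- res_atoms(s, resi)[c("N", "CA", "C"), ]
    coords <- rbind(bb, build_sidechain(bb, ty, chi))
    pm <- if (partner_is_map1) prot1 else prot2
    for (tr in resolve_atom_triples(pm, ty)) {
      if (!all(tr %in% rownames(coords))) next
      part_rows[[length(part_rows) + 1]] <- as.numeric(t(coords[tr, ]))
      part_owner <- c(part_owner, h)
    }
  }
  hits <- .empty_hits(prior_hits$lig_names)
  if (!length(part_rows)) return(hits)
  part_mat <- do.call(rbind, part_rows)
  types <- intersect(new_map$allowed_residues, .AA3)
  for (pos in positions) {
    rots <- build_rotamers(s, pos, types, cfg$ex1, cfg$ex2, cfg$use_input_sc)
    if (!length(rots)) next
    anc <- list(); owner <- integer(0)
    for (ri in seq_along(rots)) {
      r <- rots[[ri]]
      for (tr in resolve_atom_triples(new_map, r$restype)) {
        if (!all(tr %in% rownames(r$coords))) next
        anc[[length(anc) + 1]] <- as.numeric(t(r$coords[tr, ]))
        owner <- c(owner, ri)
      }
    }
    if (!length(anc)) next
    anchors <- do.call(rbind, anc)
    ok <- cpp_secondary_screen(anchors, part_mat, arr$defined, arr$x0, arr$xtol,
                               pmax(arr$per, 1e-9))
    acc <- which(ok, arr.ind = TRUE)
    if (!nrow(acc)) next
    pair <- unique(data.frame(rot = owner[acc[, 1]], hit = part_owner[acc[, 2]]))
    meta <- data.frame(interaction = interaction, resi = pos,
                       restype = vapply(pair$rot, function(i) rots[[i]]$restype, ""),
                       score = 0)
    chi <- do.call(rbind, lapply(pair$rot, function(i) .chi_pad(rots[[i]]$chi)))
    hits <- bind_hits(hits, structure(
      list(meta = meta, chi = chi,
           coords = prior_hits$coords[pair$hit, , drop = FALSE],
           pose = prior_hits$pose[pair$hit, , drop = FALSE],
           lig_names = prior_hits$lig_names, rejected = 0), class = "enz_hits"))
  }
  hits
}

#' Bin hits by their 6D pose
#'
#' Bin index is `floor(coordinate / width)` per dimension; Euler dimensions
#' are wrapped modulo 360 before binning. No neighbor merging is done.
#'
#' @param hits an `enz_hits` set.
#' @param cfg a `match_config`.
#' @return character vector of bin keys, one per hit.
#' @export
hash_hits <- function(hits, cfg = match_config()) {
  if (n_hits(hits) == 0) return(character(0))
  p <- hits$pose
  eb <- floor(p[, 1:3, drop = FALSE] / cfg$euclid_bin)
  ab <- floor((p[, 4:6, drop = FALSE] %% 360) / cfg$euler_bin)
  k <- cbind(eb, ab)
  do.call(paste, c(lapply(seq_len(6), function(j) k[, j]), sep = "/"))
}

#' Extract matches from binned hits
#'
#' Every hash bin holding at least one hit from each of the N interactions
#' yields matches: the Cartesian combinations of per-interaction hits
#' (capped per bin), discarding combinations that put two hits on the same
#' scaffold position, deduplicated by (positions, residue types, bin).
#'
#' @param hits combined `enz_hits` over all interactions.
#' @param n_interactions N, the number of theozyme blocks.
#' @param cfg a `match_config`.
#' @return list of match records (bin key, per-interaction hit indices,
#'   positions, residue types, match score).
#' @export
find_matches <- function(hits, n_interactions, cfg = match_config()) {
  stopifnot(n_interactions >= 1)
  if (n_hits(hits) == 0) return(list())
  keys <- hash_hits(hits, cfg)
  # qualifying bins: those holding at least one hit from every interaction
  tab <- table(keys, factor(hits$meta$interaction, levels = seq_len(n_interactions)))
  qual <- rownames(tab)[rowSums(tab > 0) == n_interactions]
  if (!length(qual)) return(list())
  in_qual <- keys %in% qual
  by_key <- split(which(in_qual), keys[in_qual])
  matches <- list()
  for (key in names(by_key)) {
    idx <- by_key[[key]]
    ints <- hits$meta$interaction[idx]
    per_int <- lapply(seq_len(n_interactions), function(i) {
      v <- idx[ints == i]
      v[order(hits$meta$score[v], hits$meta$resi[v])]
    })
    combos <- as.matrix(expand.grid(per_int, KEEP.OUT.ATTRS = FALSE))
    seen <- character(0)
    taken <- 0
    for (ci in seq_len(nrow(combos))) {
      if (taken >= cfg$max_per_bin) break
      sel <- combos[ci, ]
      pos <- hits$meta$resi[sel]
      if (anyDuplicated(pos)) next
      ty <- hits$meta$restype[sel]
      dk <- paste(paste(pos, collapse = ","), paste(ty, collapse = ","))
      if (dk %in% seen) next
      seen <- c(seen, dk)
      taken <- taken + 1
      matches[[length(matches) + 1]] <-
        list(bin = key, hit_idx = as.integer(sel), positions = pos,
             restypes = ty, score = sum(hits$meta$score[sel]))
    }
  }
  matches
}

#' Run the matcher end to end
#'
#' Reads scaffold, theozyme, ligand topology and position list, runs classic
#' or secondary matching per interaction (classic is mandatory for the
#' first), hashes all hits and extracts matches. Each match can be written
#' as a PDB with the grafted catalytic side chains, the placed ligand, and
#' one `REMARK CATALYTIC` annotation per block.
#'
#' @param scaffold an `enz_structure` or PDB path.
#' @param theo a `theozyme` or cstfile path.
#' @param ligand an `enz_ligand` or params path.
#' @param positions residue indices, a posfile path, or a posfile data.frame.
#' @param cfg a `match_config`.
#' @param outdir optional directory for match PDBs and the summary TSV.
#' @return list with `matches`, the combined `hits`, per-match structures
#'   (`structures`) and a `summary` data.frame.
#' @export
run_matcher <- function(scaffold, theo, ligand, positions,
                        cfg = match_config(), outdir = NULL) {
  if (is.character(ligand)) ligand <- read_ligand_params(ligand)
  if (is.character(scaffold)) scaffold <- read_pdb(scaffold, ligand_name = ligand$name)
  if (is.character(theo)) theo <- read_cstfile(theo)
  if (is.character(positions)) positions <- read_posfile(positions)
  if (is.data.frame(positions)) positions <- .positions_to_resi(scaffold, positions)
  if (!is.null(cfg$algorithms)) {
    stopifnot(length(cfg$algorithms) == length(theo$blocks))
    for (i in seq_along(theo$blocks)) theo$blocks[[i]]$algorithm <- cfg$algorithms[i]
  } else {
    # the algorithm assignment lives outside the cstfile; when none is
    # given, blocks that do not define all six parameters can only be
    # matched by the secondary algorithm
    for (i in seq_along(theo$blocks)[-1]) {
      b <- theo$blocks[[i]]
      if (b$algorithm == "classic" && !all(.PORDER %in% names(b$params))) {
        message("block ", i, ": incomplete parameter set, using secondary matching")
        theo$blocks[[i]]$algorithm <- "secondary"
      }
    }
  }
  validate_theozyme(theo)
  N <- length(theo$blocks)
  all_hits <- .empty_hits(rownames(ligand$conformer))
  for (i in seq_len(N)) {
    b <- theo$blocks[[i]]
    h <- if (b$algorithm == "classic") {
      classic_match_interaction(scaffold, b, positions, ligand, cfg, interaction = i)
    } else {
      secondary_match_interaction(scaffold, b, all_hits, positions, ligand, cfg,
                                  interaction = i)
    }
    all_hits <- bind_hits(all_hits, h)
  }
  matches <- find_matches(all_hits, N, cfg)
  structures <- lapply(matches, function(m)
    .realize_match(scaffold, theo, ligand, all_hits, m))
  summary <- data.frame(
    match = seq_along(matches),
    bin = vapply(matches, `[[`, "", "bin"),
    positions = vapply(matches, function(m) paste(m$positions, collapse = ","), ""),
    restypes = vapply(matches, function(m) paste(m$restypes, collapse = ","), ""),
    score = vapply(matches, `[[`, 0, "score"))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- character(length(matches))
    for (i in seq_along(structures)) {
      files[i] <- file.path(outdir, sprintf("match_%04d.pdb", i))
      write_pdb(structures[[i]], files[i])
    }
    if (length(matches)) summary$file <- files
    write.table(summary, file.path(outdir, "matches.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  message(length(matches), " match(es) from ", n_hits(all_hits), " hit(s)")
  list(matches = matches, hits = all_hits, structures = structures,
       summary = summary)
}

# graft a match into the scaffold: mutate catalytic residues, place the
# ligand (from the first interaction's hit), annotate
.realize_match <- function(scaffold, theo, ligand, hits, m) {
  s <- scaffold
  rt <- res_table(s)
  for (k in seq_along(m$hit_idx)) {
    hi <- m$hit_idx[k]
    ty <- hits$meta$restype[hi]
    chi <- hits$chi[hi, seq_len(n_chi(ty))]
    s <- mutate_residue(s, hits$meta$resi[hi], ty, chi)
  }
  lig_xyz <- matrix(hits$coords[m$hit_idx[1], ], ncol = 3, byrow = TRUE,
                    dimnames = list(hits$lig_names))
  lrows <- data.frame(resi = NA_integer_, chain = rt$chain[1],
                      resno = max(rt$resno) + 1L, resname = ligand$name,
                      name = hits$lig_names,
                      element = ligand$atoms$element[match(hits$lig_names,
                                                           ligand$atoms$name)],
                      x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
                      het = TRUE, backbone = FALSE)
  a <- s$atoms[!s$atoms$het, ]
  rt2 <- res_table(s)
  catal <- data.frame(
    block = seq_along(m$hit_idx),
    chain = rt2$chain[match(m$positions, rt2$resi)],
    resno = rt2$resno[match(m$positions, rt2$resi)],
    resname = m$restypes)
  out <- new_structure(rbind(a, lrows), catal, ligand_name = ligand$name,
                       ligand = ligand)
  out
}
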