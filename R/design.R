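# Stage 3 - designing a matched site: automatic shell detection, resfile
# merging, restrained optimization of the catalytic geometry (cst_opt), an
# optional Monte-Carlo rigid-body predock, cycles of simulated-annealing
# sequence design plus minimization under the catalytic restraints, and the
# final unrestrained repack.

#' Design-stage configuration
#'
#' @param cut1,cut2,cut3,cut4 increasing CA-distance thresholds (Angstrom)
#'   from ligand heavy atoms defining the designable and repackable shells.
#' @param design_min_cycles iterations of design + minimization.
#' @param lig_packer_weight multiplier on protein-ligand interactions in
#'   the packer energy.
#' @param native_bonus energy credit (REU) for keeping the native identity
#'   at a designable position.
#' @param trans_magnitude,rot_magnitude predock move scales (Angstrom /
#'   degrees; one standard deviation of the Gaussian draws).
#' @param dock_trials number of predock rigid-body moves.
#' @param seed RNG seed for the stochastic stages.
#' @param cst_opt,cst_predock,cst_design,cst_min,bb_min,chi_min,
#'   soft_rep_design,fix_catalytic_aa,no_unconstrained_repack,
#'   final_repack_without_ligand,ex1,ex2,use_input_sc protocol flags.
#' @export
design_config <- function(cut1 = 6, cut2 = 8, cut3 = 10, cut4 = 12,
                          design_min_cycles = 2, lig_packer_weight = 1.6,
                          native_bonus = 0.8, trans_magnitude = 0.5,
                          rot_magnitude = 5, dock_trials = 100, seed = 1,
                          cst_opt = TRUE, cst_predock = FALSE,
                          cst_design = TRUE, cst_min = TRUE, bb_min = FALSE,
                          chi_min = TRUE, soft_rep_design = FALSE,
                          fix_catalytic_aa = FALSE,
                          no_unconstrained_repack = FALSE,
                          final_repack_without_ligand = FALSE,
                          ex1 = FALSE, ex2 = FALSE, use_input_sc = TRUE) {
  if (!(cut1 < cut2 && cut2 < cut3 && cut3 < cut4))
    stop("shell cutoffs must increase: cut1 < cut2 < cut3 < cut4")
  structure(as.list(environment()), class = "design_config")
}

#' Automatic detection of the designable/repackable shells
#'
#' Applies the four distance rules in order (first match wins): (i) CA
#' within cut1 of any ligand heavy atom - designable; (ii) CA within cut2
#' and CB closer to that ligand atom than the CA - designable; (iii) CA
#' within cut3 - repackable; (iv) CA within cut4 with the CB closer -
#' repackable; everything else static. Catalytic residues are always
#' repackable (unless `fix_catalytic_aa`, which makes them static).
#' Designable positions allow every amino acid except cysteine. Glycine
#' (no CB) falls back to the CA-only test in rules ii/iv.
#'
#' @param s structure with a ligand.
#' @param cfg a `design_config`.
#' @return a packer task: data.frame with resi, label and allowed residue
#'   types (list column).
#' @export
detect_design_shell <- function(s, cfg = design_config()) {
  lig <- .ligand_heavy(s)
  rt <- res_table(s)
  label <- character(nrow(rt))
  for (k in seq_len(nrow(rt))) {
    m <- res_atoms(s, rt$resi[k])
    ca <- m["CA", ]
    dca <- sqrt(colSums((t(lig) - ca)^2))
    cb_closer <- if ("CB" %in% rownames(m)) {
      dcb <- sqrt(colSums((t(lig) - m["CB", ])^2))
      dcb < dca
    } else rep(TRUE, length(dca))  # glycine: CA-only fallback
    label[k] <-
      if (any(dca <= cfg$cut1)) "designable"
      else if (any(dca <= cfg$cut2 & cb_closer)) "designable"
      else if (any(dca <= cfg$cut3)) "repackable"
      else if (any(dca <= cfg$cut4 & cb_closer)) "repackable"
      else "static"
  }
  catal <- catalytic_residues(s)
  label[rt$resi %in% catal$resi] <- if (cfg$fix_catalytic_aa) "static" else "catalytic"
  allowed <- lapply(seq_len(nrow(rt)), function(k) {
    if (label[k] == "designable") setdiff(.AA3, "CYS") else rt$resname[k]
  })
  task <- data.frame(resi = rt$resi, label = label)
  task$allowed <- allowed
  class(task) <- c("packer_task", "data.frame")
  task
}

#' Read a resfile
#'
#' Dialect: lines before `start` set the default command (AUTO, NATRO,
#' NATAA or ALLAA); lines after are `<resno> <chain> <command>` with
#' commands NATRO, NATAA, ALLAA, AUTO or `PIKAA <letters>`.
#'
#' @param path resfile path.
#' @return list with `default` and a data.frame of per-residue commands.
#' @export
read_resfile <- function(path) {
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- trimws(lines[nzchar(trimws(lines))])
  st <- match("start", tolower(lines))
  header <- if (is.na(st)) character(0) else lines[seq_len(st - 1)]
  body <- if (is.na(st)) lines else lines[-seq_len(st)]
  default <- "AUTO"
  for (h in header) {
    cmd <- toupper(strsplit(h, "[[:space:]]+")[[1]][1])
    if (cmd %in% c("AUTO", "NATRO", "NATAA", "ALLAA")) default <- cmd
  }
  rows <- list()
  for (b in body) {
    t <- strsplit(b, "[[:space:]]+")[[1]]
    if (length(t) < 3) stop("malformed resfile line: ", b)
    cmd <- toupper(t[3])
    if (!cmd %in% c("NATRO", "NATAA", "ALLAA", "AUTO", "PIKAA"))
      stop("unknown resfile command: ", cmd)
    rows[[length(rows) + 1]] <-
      data.frame(resno = as.integer(t[1]), chain = t[2], command = cmd,
                 spec = if (cmd == "PIKAA") t[4] else NA_character_)
  }
  list(default = default, commands = if (length(rows)) do.call(rbind, rows)
       else data.frame(resno = integer(0), chain = character(0),
                       command = character(0), spec = character(0)))
}

#' Merge a resfile with the automatically detected shell
#'
#' Explicit per-residue resfile commands override the shell assignment;
#' residues under an AUTO default keep it.
#'
#' @param resfile result of [read_resfile()] (or a path), or NULL.
#' @param shell a packer task from [detect_design_shell()].
#' @param s the structure the task refers to.
#' @return the merged packer task.
#' @export
merge_resfile <- function(resfile, shell, s) {
  if (is.null(resfile)) return(shell)
  if (is.character(resfile)) resfile <- read_resfile(resfile)
  rt <- res_table(s)
  task <- shell
  apply_cmd <- function(k, cmd, spec) {
    switch(cmd,
      NATRO = { task$label[k] <<- "static"; task$allowed[[k]] <<- rt$resname[k] },
      NATAA = { task$label[k] <<- "repackable"; task$allowed[[k]] <<- rt$resname[k] },
      ALLAA = { task$label[k] <<- "designable"; task$allowed[[k]] <<- setdiff(.AA3, "CYS") },
      PIKAA = {
        task$label[k] <<- "designable"
        task$allowed[[k]] <<- unname(.AA1TO3[strsplit(toupper(spec), "")[[1]]])
      },
      AUTO = NULL)
  }
  if (resfile$default != "AUTO") {
    for (k in seq_len(nrow(task))) apply_cmd(k, resfile$default, NA)
  }
  cm <- resfile$commands
  for (i in seq_len(nrow(cm))) {
    k <- which(rt$resno == cm$resno[i] & (is.na(cm$chain[i]) | rt$chain == cm$chain[i]))
    if (!length(k)) stop("resfile references absent residue ", cm$resno[i])
    apply_cmd(k[1], cm$command[i], cm$spec[i])
  }
  task
}

# --- stage logging -----------------------------------------------------------

.log_stage <- function(s, stage, weights, extra = list()) {
  log <- attr(s, "stage_log")
  if (is.null(log)) log <- list()
  log[[length(log) + 1]] <- c(list(stage = stage, weights = weights), extra)
  attr(s, "stage_log") <- log
  s
}

#' Stage log of a designed structure
#' @param s structure that passed through design stages.
#' @return list of per-stage records (stage name, term weights, details).
#' @export
stage_log <- function(s) attr(s, "stage_log")

# --- minimization ------------------------------------------------------------

# ligand atoms carrying distance restraints to the protein (their centroid
# is the predock rotation center)
.restrained_lig_atoms <- function(s, theo) {
  nm <- character(0)
  for (b in theo$blocks) {
    if (is.null(b$params[["distanceAB"]])) next
    lside <- .ligand_side(b, s$ligand_name)
    if (is.na(lside)) next
    for (tr in resolve_atom_triples(b[[lside]], s$ligand)) nm <- c(nm, tr[1])
  }
  unique(nm)
}

.rot_axis <- function(axis, angle_deg) {
  a <- .unit(axis); th <- angle_deg * .deg2rad
  c <- cos(th); s <- sin(th); C <- 1 - c
  matrix(c(a[1]^2 * C + c, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
           a[1] * a[2] * C + a[3] * s, a[2]^2 * C + c, a[2] * a[3] * C - a[1] * s,
           a[1] * a[3] * C - a[2] * s, a[2] * a[3] * C + a[1] * s, a[3]^2 * C + c),
         3, 3, byrow = TRUE)
}

# apply a DOF vector: ligand rigid body (first 6 when lig_rb), then chi
# angles of the listed residues, then (bb_min) a rigid translation of each
# listed residue's local backbone unit
.apply_dofs <- function(s, par, lig_rb, chi_resis, chi_counts, center,
                        bb_resis = integer(0)) {
  k <- 0
  if (lig_rb) {
    lc <- ligand_coords(s)
    R <- .rot_axis(c(1, 0, 0), par[4]) %*% .rot_axis(c(0, 1, 0), par[5]) %*%
      .rot_axis(c(0, 0, 1), par[6])
    moved <- sweep(sweep(lc, 2, center) %*% t(R), 2, center + par[1:3], "+")
    s <- set_ligand_coords(s, moved)
    k <- 6
  }
  rt <- res_table(s)
  for (r in bb_resis) {
    rows <- .res_rows(s, r)
    s$atoms[rows, c("x", "y", "z")] <-
      sweep(as.matrix(s$atoms[rows, c("x", "y", "z")]), 2, par[(k + 1):(k + 3)], "+")
    k <- k + 3
  }
  for (i in seq_along(chi_resis)) {
    nc <- chi_counts[i]
    if (nc == 0) next
    chi <- par[(k + 1):(k + nc)]
    k <- k + nc
    s <- mutate_residue(s, chi_resis[i], rt$resname[match(chi_resis[i], rt$resi)], chi)
  }
  s
}

# flat-bottom CA positional restraint (tol 0.5 A) plus peptide-bond
# continuity penalties for translated backbone units
.bb_penalty <- function(s, s0, bb_resis) {
  if (!length(bb_resis)) return(0)
  pen <- 0
  for (r in bb_resis) {
    d <- sqrt(sum((res_atoms(s, r)["CA", ] - res_atoms(s0, r)["CA", ])^2))
    pen <- pen + 10 * max(0, d - 0.5)^2
    for (q in c(r - 1L, r + 1L)) {
      mq <- tryCatch(res_atoms(s, q), error = function(e) NULL)
      if (is.null(mq)) next
      bond <- if (q < r) sqrt(sum((mq["C", ] - res_atoms(s, r)["N", ])^2))
              else sqrt(sum((res_atoms(s, r)["C", ] - mq["N", ])^2))
      pen <- pen + 50 * (bond - .BB$d_c_n)^2
    }
  }
  pen
}

# precomputed evaluation context: fixed-region atom properties are built
# once; each objective evaluation only transforms the ligand and rebuilds
# the catalytic side chains
.fast_ctx <- function(s, theo, em, chi_resis) {
  rt <- res_table(s)
  lrows <- .lig_rows(s)
  sc_rows <- unlist(lapply(chi_resis, function(r) {
    rr <- .res_rows(s, r)
    rr[!s$atoms$name[rr] %in% c("N", "CA", "C", "O")]
  }))
  fixed_rows <- setdiff(seq_len(nrow(s$atoms)), c(lrows, sc_rows))
  fixedP <- .atom_props(s, fixed_rows)
  sc_info <- lapply(seq_along(chi_resis), function(i) {
    r <- chi_resis[i]
    m <- res_atoms(s, r)
    ty <- rt$resname[match(r, rt$resi)]
    # intra-residue pairs are excluded: the rigid rotamer model carries no
    # internal strain, and bonded 1-2/1-3 pairs would swamp the repulsion
    own <- .res_rows(s, r)
    fx <- .atom_props(s, setdiff(fixed_rows, own))
    skel <- .rot_props(m, ty)
    scn <- res_topology(ty)$name  # side-chain atom order
    pmap <- .res_parent_map(ty)
    bn <- ifelse(is.na(pmap[scn]), "CA", pmap[scn])
    list(resi = r, restype = ty, bb = m[c("N", "CA", "C"), , drop = FALSE],
         full0 = m, fixedP = fx, skel = skel, scn = scn, bn = bn)
  })
  catal <- catalytic_residues(s)
  binfo <- lapply(seq_along(theo$blocks), function(bi) {
    b <- theo$blocks[[bi]]
    lside <- .ligand_side(b, s$ligand_name)
    resi <- catal$resi[catal$block == bi][1]
    ty <- rt$resname[match(resi, rt$resi)]
    pm <- b[[if (identical(lside, "map1")) "map2" else "map1"]]
    list(b = b, lside = lside, resi = resi,
         lig_triples = if (!is.na(lside)) resolve_atom_triples(b[[lside]], s$ligand),
         prot_triples = resolve_atom_triples(pm, ty))
  })
  list(s = s, em = em, fixedP = fixedP,
       ligP = if (length(lrows)) .atom_props(s, lrows),
       lig_all = if (length(lrows)) ligand_coords(s),
       chi_resis = chi_resis, sc_info = sc_info, binfo = binfo)
}

# energy + restraint score for a rigid ligand transform and a set of
# catalytic chi vectors, evaluated against the precomputed context
.ctx_eval <- function(ctx, R, tvec, center, chi_list, em = ctx$em) {
  tx <- function(m) sweep(sweep(m, 2, center) %*% t(R), 2, center + tvec, "+")
  groups <- list()
  fixed_of <- list()
  if (!is.null(ctx$ligP)) {
    groups[[1]] <- list(xyz = tx(ctx$ligP$xyz), rad = ctx$ligP$rad,
                        don = ctx$ligP$don, acc = ctx$ligP$acc,
                        base = tx(ctx$ligP$base))
    fixed_of[[1]] <- ctx$fixedP
  }
  sc_full <- list()
  for (i in seq_along(ctx$sc_info)) {
    si <- ctx$sc_info[[i]]
    sc <- build_sidechain(si$bb, si$restype, chi_list[[i]])
    bbn <- intersect(c("N", "CA", "C", "O"), rownames(si$full0))
    full <- rbind(si$full0[bbn, , drop = FALSE], sc)
    sc_full[[i]] <- full
    groups[[length(groups) + 1]] <-
      list(xyz = full[si$scn, , drop = FALSE], rad = si$skel$rad,
           don = si$skel$don, acc = si$skel$acc,
           base = full[si$bn, , drop = FALSE])
    fixed_of[[length(groups)]] <- si$fixedP
  }
  tot <- 0
  for (g in seq_along(groups)) tot <- tot + .pair_e(groups[[g]], fixed_of[[g]], em)
  if (length(groups) > 1) {
    for (i in seq_len(length(groups) - 1))
      for (j in (i + 1):length(groups))
        tot <- tot + .pair_e(groups[[i]], groups[[j]], em)
  }
  lig_coords <- if (!is.null(ctx$lig_all)) tx(ctx$lig_all)
  cst <- 0
  for (bi in ctx$binfo) {
    get_prot <- function(tr) {
      k <- match(bi$resi, ctx$chi_resis)
      src <- if (!is.na(k)) sc_full[[k]] else res_atoms(ctx$s, bi$resi)
      if (!all(tr %in% rownames(src))) return(NULL)
      src[tr, , drop = FALSE]
    }
    pt <- Filter(Negate(is.null), lapply(bi$prot_triples, get_prot))
    lt <- lapply(bi$lig_triples, function(tr) lig_coords[tr, , drop = FALSE])
    bs <- if (identical(bi$lside, "map1")) block_score_triples(lt, pt, bi$b)
          else block_score_triples(pt, lt, bi$b)
    cst <- cst + bs$score
  }
  list(energy = tot, cst = cst)
}

# restrained quasi-Newton minimization of the movable DOFs (ligand rigid
# body + catalytic chi angles; bb_min adds local backbone-unit shifts)
.minimize <- function(s, theo, em, cfg, include_atr = TRUE, cst_weight = em$w_cst,
                      maxit = 60, lig_rb = TRUE) {
  catal <- catalytic_residues(s)
  chi_resis <- if (cfg$chi_min) unique(catal$resi) else integer(0)
  rt <- res_table(s)
  chi_counts <- vapply(chi_resis, function(r)
    n_chi(rt$resname[match(r, rt$resi)]), numeric(1))
  bb_resis <- if (isTRUE(cfg$bb_min)) unique(catal$resi) else integer(0)
  center <- colMeans(ligand_coords(s)[.restrained_lig_atoms(s, theo), , drop = FALSE])
  chi0 <- lapply(seq_along(chi_resis), function(i)
    measure_chis(res_atoms(s, chi_resis[i]), rt$resname[match(chi_resis[i], rt$resi)]))
  nlig <- if (lig_rb) 6 else 0
  p0 <- c(rep(0, nlig), rep(0, 3 * length(bb_resis)), unlist(chi0))
  emx <- em
  if (!include_atr) emx$w_atr <- 0
  nb <- length(bb_resis)
  if (nb == 0) {
    ctx <- .fast_ctx(s, theo, emx, chi_resis)
    split_chis <- function(par) {
      k <- nlig
      lapply(seq_along(chi_resis), function(i) {
        v <- par[(k + 1):(k + chi_counts[i])]
        k <<- k + chi_counts[i]
        v
      })
    }
    obj <- function(par) {
      R <- if (lig_rb)
        .rot_axis(c(1, 0, 0), par[4]) %*% .rot_axis(c(0, 1, 0), par[5]) %*%
          .rot_axis(c(0, 0, 1), par[6]) else diag(3)
      tv <- if (lig_rb) par[1:3] else c(0, 0, 0)
      e <- .ctx_eval(ctx, R, tv, center, split_chis(par))
      e$energy + cst_weight * e$cst
    }
  } else {
    # slower general path used when backbone units may move
    s0 <- s
    obj <- function(par) {
      sx <- .apply_dofs(s, par, TRUE, chi_resis, chi_counts, center, bb_resis)
      ctx <- .fast_ctx(sx, theo, emx, chi_resis)
      e <- .ctx_eval(ctx, diag(3), c(0, 0, 0), center,
                     lapply(seq_along(chi_resis), function(i)
                       measure_chis(res_atoms(sx, chi_resis[i]),
                                    res_table(sx)$resname[match(chi_resis[i],
                                                                res_table(sx)$resi)])))
      e$energy + cst_weight * e$cst + .bb_penalty(sx, s0, bb_resis)
    }
  }
  o0 <- obj(p0)
  fit <- optim(p0, obj, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-8))
  par <- if (fit$value <= o0) fit$par else p0
  if (!lig_rb) par <- c(rep(0, 6), par)
  out <- .apply_dofs(s, par, TRUE, chi_resis, chi_counts, center, bb_resis)
  attr(out, "min_obj") <- c(initial = o0, final = min(fit$value, o0))
  out
}

#' Restrained optimization of the catalytic geometry (cst_opt)
#'
#' Non-catalytic designable/repackable residues are mutated to alanine (the
#' active site is reduced to substrate plus catalytic residues), then the
#' ligand rigid-body placement (plus catalytic chi angles when `chi_min`)
#' is minimized under a reduced energy containing no attractive term, with
#' the restraint score on. Static-region coordinates never move.
#'
#' @param s matched structure (ligand + catalytic annotations).
#' @param theo the theozyme.
#' @param cfg design configuration.
#' @param task optional packer task (defaults to shell detection).
#' @param em energy model.
#' @return optimized structure (with `stage_log` entry).
#' @export
cst_opt <- function(s, theo, cfg = design_config(), task = NULL,
                    em = energy_model()) {
  if (is.null(task)) task <- detect_design_shell(s, cfg)
  for (k in seq_len(nrow(task))) {
    if (task$label[k] %in% c("designable", "repackable"))
      s <- mutate_residue(s, task$resi[k], "ALA")
  }
  out <- .minimize(s, theo, em, cfg, include_atr = FALSE)
  .log_stage(out, "cst_opt",
             c(rep = em$w_rep, atr = 0, hb = em$w_hb, cst = em$w_cst),
             list(objective = attr(out, "min_obj")))
}

#' Monte-Carlo rigid-body predock of the ligand
#'
#' Gaussian rigid-body perturbations (zero mean, one standard deviation
#' scaled by `trans_magnitude` / `rot_magnitude`) about the centroid of the
#' ligand atoms that carry distance restraints, with Metropolis acceptance
#' on the reduced energy plus restraints. Designable residues are mutated
#' to alanine first so the ligand can sample the whole site.
#'
#' @inheritParams cst_opt
#' @return structure with the accepted ligand pose.
#' @export
cst_predock <- function(s, theo, cfg = design_config(), task = NULL,
                        em = energy_model()) {
  if (cfg$dock_trials <= 0) return(s)
  if (is.null(task)) task <- detect_design_shell(s, cfg)
  for (k in seq_len(nrow(task)))
    if (task$label[k] == "designable") s <- mutate_residue(s, task$resi[k], "ALA")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  center_names <- .restrained_lig_atoms(s, theo)
  ctx <- .fast_ctx(s, theo, em, integer(0))
  lc0 <- ligand_coords(s)
  eval_pose <- function(R, tvec, center) {
    e <- .ctx_eval(ctx, R, tvec, center, list())
    e$energy + em$w_cst * e$cst
  }
  # current pose expressed as cumulative transform of the input coordinates
  cur <- list(R = diag(3), t = c(0, 0, 0))
  pose_coords <- function(tr, center0) {
    sweep(sweep(lc0, 2, center0) %*% t(tr$R), 2, center0 + tr$t, "+")
  }
  center0 <- colMeans(lc0[center_names, , drop = FALSE])
  ecur <- eval_pose(cur$R, cur$t, center0)
  best <- cur; ebest <- ecur
  kT <- 1
  for (t in seq_len(cfg$dock_trials)) {
    # perturb about the current restrained-atom centroid
    cc <- colMeans(pose_coords(cur, center0)[center_names, , drop = FALSE])
    shift <- cfg$trans_magnitude * rnorm(3)
    Rm <- .rot_axis(rnorm(3), cfg$rot_magnitude * rnorm(1))
    # compose: new = shift+rotate-about-cc applied after current
    cand <- list(R = Rm %*% cur$R,
                 t = as.numeric(Rm %*% (center0 + cur$t - cc)) + cc + shift - center0)
    e <- eval_pose(cand$R, cand$t, center0)
    if (e <= ecur || runif(1) < exp(-(e - ecur) / kT)) {
      cur <- cand; ecur <- e
      if (e < ebest) { best <- cur; ebest <- e }
    }
  }
  s <- set_ligand_coords(s, pose_coords(best, center0))
  .log_stage(s, "cst_predock",
             c(rep = em$w_rep, atr = em$w_atr, hb = em$w_hb, cst = em$w_cst),
             list(energy = ebest, trials = cfg$dock_trials))
}

# --- packing -----------------------------------------------------------------

# physical properties of a candidate rotamer's side-chain atoms
.rot_props <- function(coords, restype) {
  sc <- coords[setdiff(rownames(coords), c("N", "CA", "C", "O")), , drop = FALSE]
  nm <- rownames(sc)
  ty <- .res_atom_types(restype)[nm]
  pmap <- .res_parent_map(restype)
  base <- coords[ifelse(is.na(pmap[nm]), "CA", pmap[nm]), , drop = FALSE]
  list(xyz = sc, rad = .element_radius(.element_from_name(nm)),
       don = unname(.type_is_donor(ty)), acc = unname(.type_is_acceptor(ty)),
       base = base)
}

.pair_e <- function(A, B, em) {
  if (!nrow(A$xyz) || !nrow(B$xyz)) return(0)
  e <- cpp_pair_energy(A$xyz, A$rad, A$don, A$acc, A$base,
                       B$xyz, B$rad, B$don, B$acc, B$base,
                       .sigma_scale(em), matrix(0L, 0, 2))
  .weighted(e, em)
}

# restraint score of a candidate rotamer at a catalytic position against
# the (fixed) ligand
.cand_cst <- function(coords, restype, resi, s, theo) {
  catal <- catalytic_residues(s)
  blocks <- catal$block[catal$resi == resi]
  tot <- 0
  for (bi in blocks) {
    b <- theo$blocks[[bi]]
    lside <- .ligand_side(b, s$ligand_name)
    if (is.na(lside)) next
    pm <- b[[if (lside == "map1") "map2" else "map1"]]
    trs <- resolve_atom_triples(pm, restype)
    t_res <- list()
    for (tr in trs) if (all(tr %in% rownames(coords)))
      t_res[[length(t_res) + 1]] <- coords[tr, , drop = FALSE]
    lt <- list()
    lc <- ligand_coords(s)
    for (tr in resolve_atom_triples(b[[lside]], s$ligand))
      lt[[length(lt) + 1]] <- lc[tr, , drop = FALSE]
    bs <- if (lside == "map1") block_score_triples(lt, t_res, b)
          else block_score_triples(t_res, lt, b)
    tot <- tot + bs$score
  }
  tot
}

#' Simulated-annealing rotamer/sequence packing
#'
#' Metropolis optimization over per-position rotamer (and, at designable
#' positions, identity) choices under the simplified energy model:
#' protein-ligand pair terms are multiplied by `lig_weight`, the native
#' identity at designable positions is credited `native_bonus`, and the
#' catalytic restraint contribution of catalytic rotamers is included when
#' a theozyme is supplied. A geometric cooling schedule is used; with the
#' temperature at its final (near-zero) value only energy-nonincreasing
#' moves are accepted.
#'
#' @param s structure.
#' @param task packer task (labels + allowed identities).
#' @param theo theozyme (or NULL to pack without restraints).
#' @param cfg design configuration (ex flags, seed).
#' @param em energy model.
#' @param lig_weight protein-ligand upweighting factor.
#' @param native_bonus REU credit for native identities.
#' @param fixed_identity restrict every position to its current identity
#'   (repack-only mode).
#' @param with_ligand include ligand interactions (FALSE after ligand
#'   removal).
#' @return repacked structure.
#' @export
pack_rotamers <- function(s, task, theo = NULL, cfg = design_config(),
                          em = energy_model(), lig_weight = 1,
                          native_bonus = 0, fixed_identity = FALSE,
                          with_ligand = TRUE) {
  rt <- res_table(s)
  movable <- task$resi[task$label %in% c("designable", "repackable", "catalytic")]
  movable <- movable[vapply(movable, function(r) {
    ty <- rt$resname[match(r, rt$resi)]
    nrow(res_topology(ty)) > 0 || !fixed_identity
  }, logical(1))]
  if (!length(movable)) return(s)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  catal <- catalytic_residues(s)
  # candidate rotamers per movable position
  cands <- list()
  for (i in seq_along(movable)) {
    r <- movable[i]
    k <- match(r, task$resi)
    native <- rt$resname[match(r, rt$resi)]
    types <- if (fixed_identity || task$label[k] %in% c("repackable", "catalytic"))
      native else unique(c(task$allowed[[k]], native))
    rot <- build_rotamers(s, r, types, cfg$ex1, cfg$ex2, use_input = TRUE)
    if (!length(rot)) {  # GLY/ALA-only position: keep as is
      cur <- res_atoms(s, r)
      rot <- list(list(resi = r, restype = native,
                       chi = numeric(0), coords = cur))
    }
    cands[[i]] <- lapply(rot, function(x) {
      cst <- if (!is.null(theo) && r %in% catal$resi && with_ligand)
        .cand_cst(x$coords, x$restype, r, s, theo) else 0
      list(restype = x$restype, chi = x$chi,
           props = .rot_props(x$coords, x$restype), cst = cst,
           native = x$restype == native)
    })
  }
  # fixed background: per-residue props for non-movable residues, ligand
  bg <- list()
  for (r in rt$resi) {
    if (r %in% movable) next
    bg[[as.character(r)]] <- .atom_props(s, .res_rows(s, r))
  }
  ligp <- if (with_ligand && any(s$atoms$het)) .atom_props(s, .lig_rows(s)) else NULL
  ca <- t(vapply(rt$resi, function(r) res_atoms(s, r)["CA", ], numeric(3)))
  near <- function(a, b) sum((ca[match(a, rt$resi), ] - ca[match(b, rt$resi), ])^2) < 121
  nb_static <- lapply(movable, function(r)
    Filter(function(q) near(r, q), as.integer(names(bg))))
  nb_mov <- lapply(movable, function(r)
    which(vapply(movable, function(q) q != r && near(r, q), logical(1))))
  state <- vapply(seq_along(movable), function(i) {
    nat <- which(vapply(cands[[i]], function(cc)
      cc$native && length(cc$chi) == 0, logical(1)))
    if (length(nat)) nat[1] else length(cands[[i]])  # use_input rotamer is last
  }, integer(1))
  e_local <- function(i, ki) {
    cc <- cands[[i]][[ki]]
    e <- em$ref[[cc$restype]] %||% 0
    if (cc$native) e <- e - native_bonus
    for (q in nb_static[[i]]) e <- e + .pair_e(cc$props, bg[[as.character(q)]], em)
    for (j in nb_mov[[i]]) e <- e + .pair_e(cc$props, cands[[j]][[state[j]]]$props, em)
    if (!is.null(ligp)) e <- e + lig_weight * .pair_e(cc$props, ligp, em)
    e + em$w_cst * cc$cst
  }
  temps <- 3 * 0.45^(0:7)
  nmove <- min(60L * length(movable), 1500L)
  best_state <- state
  ecur <- sum(vapply(seq_along(movable), function(i) e_local(i, state[i]), numeric(1)))
  ebest <- ecur
  for (kT in temps) {
    for (mv in seq_len(ceiling(nmove / length(temps)))) {
      i <- sample.int(length(movable), 1)
      ki <- sample.int(length(cands[[i]]), 1)
      if (ki == state[i]) next
      d <- e_local(i, ki) - e_local(i, state[i])
      if (d <= 0 || runif(1) < exp(-d / kT)) {
        state[i] <- ki
        ecur <- ecur + d
        if (ecur < ebest - 1e-12) { ebest <- ecur; best_state <- state }
      }
    }
  }
  state <- best_state
  for (i in seq_along(movable)) {
    cc <- cands[[i]][[state[i]]]
    s <- mutate_residue(s, movable[i], cc$restype, cc$chi)
  }
  s
}

#' One or more cycles of restrained sequence design and minimization
#'
#' Each cycle runs simulated-annealing packing (protein-ligand terms
#' upweighted by `lig_packer_weight`, native identities credited
#' `native_bonus`, restraints on throughout) followed, when `cst_min`, by
#' restrained minimization of the ligand rigid body and catalytic chis.
#'
#' @inheritParams cst_opt
#' @param task packer task.
#' @return designed structure.
#' @export
design_cycle <- function(s, task, theo, cfg = design_config(),
                         em = energy_model()) {
  emd <- em
  emd$soft_rep <- emd$soft_rep || cfg$soft_rep_design
  for (cyc in seq_len(cfg$design_min_cycles)) {
    s <- pack_rotamers(s, task, theo, cfg, emd,
                       lig_weight = cfg$lig_packer_weight,
                       native_bonus = cfg$native_bonus)
    if (cfg$cst_min) s <- .minimize(s, theo, em, cfg, include_atr = TRUE)
  }
  .log_stage(s, "design_cycle",
             c(rep = em$w_rep, atr = em$w_atr, hb = em$w_hb, cst = em$w_cst),
             list(cycles = cfg$design_min_cycles,
                  lig_packer_weight = cfg$lig_packer_weight,
                  native_bonus = cfg$native_bonus))
}

#' Final unrestrained fixed-sequence repack/minimization
#'
#' Repacks (and, when `cst_min`, minimizes) with the restraint weight set
#' to zero and the sequence fixed, to test whether the designed sequence
#' holds the catalytic residues in place without artificial restraints.
#' Skipped entirely under `no_unconstrained_repack`.
#'
#' @inheritParams design_cycle
#' @export
unconstrained_repack <- function(s, task, theo, cfg = design_config(),
                                 em = energy_model()) {
  if (cfg$no_unconstrained_repack) return(s)
  s <- pack_rotamers(s, task, theo = NULL, cfg, em, fixed_identity = TRUE)
  if (cfg$cst_min) s <- .minimize(s, theo, em, cfg, cst_weight = 0, lig_rb = FALSE)
  .log_stage(s, "unconstrained_repack",
             c(rep = em$w_rep, atr = em$w_atr, hb = em$w_hb, cst = 0),
             list())
}

#' Repack the apo structure and report catalytic side-chain RMSDs
#'
#' Removes the ligand, repacks with fixed sequence, and reports the
#' side-chain heavy-atom RMSD of each catalytic residue against the
#' liganded model (the preorganization measure).
#'
#' @inheritParams design_cycle
#' @return list with `structure` (apo, repacked) and `rmsd` (named by
#'   catalytic block).
#' @export
repack_without_ligand <- function(s, task, theo, cfg = design_config(),
                                  em = energy_model()) {
  if (!any(s$atoms$het)) stop("structure has no ligand to remove")
  apo <- s
  apo$atoms <- apo$atoms[!apo$atoms$het, ]
  apo <- pack_rotamers(apo, task, theo = NULL, cfg, em, fixed_identity = TRUE,
                       with_ligand = FALSE)
  catal <- catalytic_residues(s)
  rmsd <- vapply(seq_len(nrow(catal)), function(k) {
    a <- res_atoms(s, catal$resi[k]); b <- res_atoms(apo, catal$resi[k])
    sc <- setdiff(rownames(a), c("N", "CA", "C", "O"))
    sc <- sc[.element_from_name(sc) != "H"]
    if (!length(sc)) return(0)
    sqrt(mean(rowSums((a[sc, , drop = FALSE] - b[sc, , drop = FALSE])^2)))
  }, numeric(1))
  list(structure = apo, rmsd = setNames(rmsd, paste0("SR", catal$block)))
}

#' Run the full design protocol on a matched structure
#'
#' Shell detection (+ optional resfile), cst_opt, optional predock, the
#' design/minimization cycles, the unrestrained repack, and optionally the
#' apo repack.
#'
#' @param s matched structure (with ligand + catalytic annotations and an
#'   attached ligand topology).
#' @param theo theozyme.
#' @param cfg design configuration.
#' @param em energy model.
#' @param resfile optional resfile (path or parsed).
#' @return list with `structure`, `task`, and `apo_rmsd` (when requested).
#' @export
run_design <- function(s, theo, cfg = design_config(), em = energy_model(),
                       resfile = NULL) {
  task <- merge_resfile(resfile, detect_design_shell(s, cfg), s)
  if (cfg$cst_opt) s <- cst_opt(s, theo, cfg, task, em)
  if (cfg$cst_predock) s <- cst_predock(s, theo, cfg, task, em)
  if (cfg$cst_design) s <- design_cycle(s, task, theo, cfg, em)
  s <- unconstrained_repack(s, task, theo, cfg, em)
  apo <- NULL
  if (cfg$final_repack_without_ligand)
    apo <- repack_without_ligand(s, task, theo, cfg, em)
  list(structure = s, task = task,
       apo_rmsd = if (!is.null(apo)) apo$rmsd else NULL)
}

#' Per-position packer energy breakdown of the current rotamer state
#'
#' Decomposes, for each movable position, the one-body energy the packer
#' sees: protein-protein pair terms, the protein-ligand pair term (after
#' multiplication by `lig_weight`), the restraint contribution, the
#' reference energy and the native-identity credit. Useful for auditing
#' how `lig_packer_weight` and `native_bonus` enter the optimization.
#'
#' @inheritParams pack_rotamers
#' @return data.frame with one row per movable position.
#' @export
packer_energy_breakdown <- function(s, task, theo = NULL, cfg = design_config(),
                                    em = energy_model(), lig_weight = 1,
                                    native_bonus = 0) {
  rt <- res_table(s)
  movable <- task$resi[task$label %in% c("designable", "repackable", "catalytic")]
  catal <- catalytic_residues(s)
  ligp <- if (any(s$atoms$het)) .atom_props(s, .lig_rows(s)) else NULL
  out <- list()
  for (r in movable) {
    ty <- rt$resname[match(r, rt$resi)]
    m <- res_atoms(s, r)
    pr <- .rot_props(m, ty)
    pp <- 0
    for (q in rt$resi) {
      if (q == r) next
      if (sum((res_atoms(s, q)["CA", ] - m["CA", ])^2) > 121) next
      pp <- pp + .pair_e(pr, .atom_props(s, .res_rows(s, q)), em)
    }
    lig <- if (!is.null(ligp)) lig_weight * .pair_e(pr, ligp, em) else 0
    cst <- if (!is.null(theo) && r %in% catal$resi)
      em$w_cst * .cand_cst(m, ty, r, s, theo) else 0
    k <- match(r, task$resi)
    out[[length(out) + 1]] <- data.frame(
      resi = r, restype = ty, protein_pair = pp, ligand_pair = lig,
      cst = cst, ref = em$ref[[ty]] %||% 0,
      native_credit = -native_bonus * (task$label[k] == "designable"))
  }
  do.call(rbind, out)
}
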