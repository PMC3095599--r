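# Shell detection, resfile merging, and the design-stage contracts.

test_that("shell detection applies the four distance rules in order", {
  # synthetic: ligand atom at the origin, residues at controlled distances
  lig <- make_ligand_dhap()
  res_at <- function(d, cb_toward) {
    ca <- c(d, 0, 0)
    cb <- ca + if (cb_toward) c(-0.8, 0.4, 0) else c(0.8, 0.4, 0)
    list(resname = "ALA",
         coords = rbind(N = ca + c(0, 1.4, 0), CA = ca, C = ca + c(1.2, -0.8, 0),
                        O = ca + c(1.2, -2, 0), CB = cb))
  }
  s <- build_structure(list(res_at(5, FALSE),    # rule i
                            res_at(7, TRUE),     # rule ii
                            res_at(7, FALSE),    # CB farther: falls to rule iii
                            res_at(9.5, FALSE),  # rule iii
                            res_at(11, TRUE),    # rule iv
                            res_at(11, FALSE),   # nothing: static
                            res_at(13, TRUE)),   # beyond cut4: static
                       ligand_atoms = matrix(0, 1, 3, dimnames = list("C1")),
                       ligand = lig)
  task <- detect_design_shell(s, design_config(cut1 = 6, cut2 = 8,
                                               cut3 = 10, cut4 = 12))
  expect_equal(task$label,
               c("designable", "designable", "repackable", "repackable",
                 "repackable", "static", "static"))
  expect_setequal(task$allowed[[1]], setdiff(enzdes:::.AA3, "CYS"))
  expect_false("CYS" %in% unlist(task$allowed))
})

test_that("catalytic residues stay repackable unless explicitly fixed", {
  ps <- fixture_planted(1)
  task <- detect_design_shell(ps$planted, design_config())
  catal <- catalytic_residues(ps$planted)
  expect_true(all(task$label[task$resi %in% catal$resi] == "catalytic"))
  task_fix <- detect_design_shell(ps$planted, design_config(fix_catalytic_aa = TRUE))
  expect_true(all(task_fix$label[task_fix$resi %in% catal$resi] == "static"))
  expect_error(design_config(cut1 = 8, cut2 = 6), "must increase")
})

test_that("resfile commands override the detected shell", {
  ps <- fixture_planted(1)
  s <- ps$planted
  shell <- detect_design_shell(s, design_config())
  expect_identical(merge_resfile(NULL, shell, s), shell)
  des <- shell$resi[shell$label == "designable"]
  tf <- tempfile()
  writeLines(c("AUTO", "start",
               sprintf("%d A NATRO", des[1]),
               sprintf("%d A PIKAA ST", des[2])), tf)
  task <- merge_resfile(tf, shell, s)
  expect_equal(task$label[task$resi == des[1]], "static")
  expect_setequal(task$allowed[[which(task$resi == des[2])]], c("SER", "THR"))
  # untouched residues keep the shell assignment
  rest <- setdiff(shell$resi, des[1:2])
  expect_equal(task$label[task$resi %in% rest], shell$label[shell$resi %in% rest])
  writeLines(c("AUTO", "start", "999 A NATRO"), tf)
  expect_error(merge_resfile(tf, shell, s), "absent residue")
})

test_that("cst_opt reduces the restrained objective and freezes the static region", {
  ps <- fixture_planted(2)
  m <- ps$planted
  # perturb the ligand slightly off the planted optimum
  pert <- set_ligand_coords(m, sweep(ligand_coords(m), 2, c(0.8, 0.5, 0), "+"))
  cfg <- design_config(seed = 5)
  task <- detect_design_shell(pert, cfg)
  cst0 <- all_cst(pert, ps$theozyme)$total
  expect_gt(cst0, 0)
  out <- cst_opt(pert, ps$theozyme, cfg, task)
  obj <- attr(out, "min_obj")
  expect_lte(obj[["final"]], obj[["initial"]])
  expect_lte(all_cst(out, ps$theozyme)$total, cst0)
  st <- task$resi[task$label == "static"]
  expect_true(all(vapply(st, function(r)
    identical(res_atoms(pert, r), res_atoms(out, r)), logical(1))))
  # non-catalytic shell residues are reduced to alanine
  rt <- res_table(out)
  shell_res <- task$resi[task$label %in% c("designable", "repackable")]
  expect_true(all(rt$resname[match(shell_res, rt$resi)] == "ALA"))
  # the attractive term is disabled in this stage
  w <- stage_log(out)[[length(stage_log(out))]]$weights
  expect_equal(unname(w["atr"]), 0)
  expect_gt(unname(w["cst"]), 0)
})

test_that("with only restraints active, cst_opt drives the penalty toward zero", {
  ps <- fixture_planted(3)
  pert <- set_ligand_coords(ps$planted,
                            sweep(ligand_coords(ps$planted), 2, c(0.8, 0.5, 0.2), "+"))
  em0 <- energy_model(w_rep = 0, w_atr = 0, w_hb = 0, w_cst = 1)
  cfg <- design_config(seed = 2)
  cst0 <- all_cst(pert, ps$theozyme)$total
  out <- cst_opt(pert, ps$theozyme, cfg, em = em0)
  cst1 <- all_cst(out, ps$theozyme)$total
  expect_gt(cst0, 1)
  expect_lte(cst1, cst0)
  expect_lt(cst1, 0.1)
})

test_that("predock is seeded, reproducible and centered on the restrained atoms", {
  ps <- fixture_planted(1)
  m <- ps$planted
  cfg0 <- design_config(dock_trials = 0)
  expect_identical(cst_predock(m, ps$theozyme, cfg0)$atoms, m$atoms)
  cfg1 <- design_config(dock_trials = 15, seed = 3)
  a <- cst_predock(m, ps$theozyme, cfg1)
  b <- cst_predock(m, ps$theozyme, cfg1)
  expect_identical(a$atoms, b$atoms)
  cfg2 <- design_config(dock_trials = 15, seed = 4)
  c2 <- cst_predock(m, ps$theozyme, cfg2)
  expect_false(identical(a$atoms, c2$atoms))
  # the rotation operator leaves the pivot fixed
  lc <- ligand_coords(m)
  ctr <- colMeans(lc[c("C1", "O2"), ])
  R <- enzdes:::.rot_axis(c(1, 2, 3), 37)
  rot <- sweep(sweep(lc, 2, ctr) %*% t(R), 2, ctr, "+")
  ctr2 <- colMeans(rot[c("C1", "O2"), ])
  expect_lt(max(abs(ctr2 - ctr)), 1e-9)
})

test_that("an overwhelming native bonus freezes the designed sequence", {
  ps <- fixture_planted(1)
  cfg <- design_config(seed = 11, design_min_cycles = 1, cst_min = FALSE)
  task <- detect_design_shell(ps$planted, cfg)
  seq0 <- res_table(ps$planted)$resname
  out <- pack_rotamers(ps$planted, task, ps$theozyme, cfg,
                       lig_weight = cfg$lig_packer_weight, native_bonus = 1e6)
  expect_equal(res_table(out)$resname, seq0)
})

test_that("doubling the ligand weight exactly doubles the ligand column", {
  ps <- fixture_planted(1)
  cfg <- design_config()
  task <- detect_design_shell(ps$planted, cfg)
  b1 <- packer_energy_breakdown(ps$planted, task, ps$theozyme, cfg,
                                lig_weight = 1.6)
  b2 <- packer_energy_breakdown(ps$planted, task, ps$theozyme, cfg,
                                lig_weight = 3.2)
  expect_equal(b2$ligand_pair, 2 * b1$ligand_pair)
  expect_equal(b2$protein_pair, b1$protein_pair)
})

test_that("repacking without designable positions keeps the sequence", {
  ps <- fixture_planted(2)
  cfg <- design_config(seed = 8)
  task <- detect_design_shell(ps$planted, cfg)
  task$label[task$label == "designable"] <- "repackable"
  task$allowed <- lapply(seq_len(nrow(task)), function(k)
    res_table(ps$planted)$resname[k])
  out <- design_cycle(ps$planted, task, ps$theozyme,
                      design_config(seed = 8, design_min_cycles = 1,
                                    cst_min = FALSE))
  expect_equal(res_table(out)$resname, res_table(ps$planted)$resname)
})

test_that("repacking from a clashing rotamer lowers the energy", {
  ps <- fixture_planted(1)
  cfg <- design_config(seed = 6)
  task <- detect_design_shell(ps$planted, cfg)
  rp <- task$resi[task$label == "repackable"][1]
  bad <- mutate_residue(ps$planted, rp, "TRP", c(-60, 90))
  e0 <- score_structure(bad, ps$theozyme)
  out <- pack_rotamers(bad, task, ps$theozyme, cfg, fixed_identity = TRUE)
  e1 <- score_structure(out, ps$theozyme)
  expect_lte(e1$total + e1$all_cst, e0$total + e0$all_cst)
})

test_that("the unrestrained stage really runs without the restraint term", {
  ps <- fixture_planted(1)
  cfg <- design_config(seed = 9, no_unconstrained_repack = TRUE)
  task <- detect_design_shell(ps$planted, cfg)
  expect_identical(unconstrained_repack(ps$planted, task, ps$theozyme, cfg),
                   ps$planted)
  cfg2 <- design_config(seed = 9)
  out <- unconstrained_repack(ps$planted, task, ps$theozyme, cfg2)
  w <- stage_log(out)[[length(stage_log(out))]]$weights
  expect_equal(unname(w["cst"]), 0)
  # while the design stage keeps restraints on
  outd <- design_cycle(ps$planted, task, ps$theozyme,
                       design_config(seed = 9, design_min_cycles = 1,
                                     cst_min = FALSE))
  wd <- stage_log(outd)[[length(stage_log(outd))]]$weights
  expect_gt(unname(wd["cst"]), 0)
})

test_that("apo-repack RMSD is zero for a rigid site and tracks real movement", {
  ps <- fixture_planted(1)
  cfg <- design_config(seed = 13)
  task <- detect_design_shell(ps$planted, cfg)
  # rigid site: every position frozen -> repack changes nothing
  task_static <- task
  task_static$label[] <- "static"
  rw <- repack_without_ligand(ps$planted, task_static, ps$theozyme, cfg)
  expect_equal(unname(rw$rmsd), rep(0, 3))
  expect_false(any(rw$structure$atoms$het))
  # a hand-made chi flip yields the RMSD of the displaced atoms
  catal <- catalytic_residues(ps$planted)
  r <- catal$resi[1]
  ty <- catal$resname[1]
  chi <- measure_chis(res_atoms(ps$planted, r), ty)
  chi2 <- chi; chi2[length(chi2)] <- chi2[length(chi2)] + 120
  flip <- mutate_residue(ps$planted, r, ty, chi2)
  a <- res_atoms(ps$planted, r); b <- res_atoms(flip, r)
  sc <- setdiff(rownames(a), c("N", "CA", "C", "O"))
  manual <- sqrt(mean(rowSums((a[sc, ] - b[sc, ])^2)))
  expect_gt(manual, 0)
  # the same displacement computed through a rigid motion of both models
  set.seed(3)
  R <- random_rotation(); tv <- rnorm(3)
  a2 <- sweep(a[sc, ] %*% t(R), 2, tv, "+")
  b2 <- sweep(b[sc, ] %*% t(R), 2, tv, "+")
  expect_equal(sqrt(mean(rowSums((a2 - b2)^2))), manual, tolerance = 1e-9)
})
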