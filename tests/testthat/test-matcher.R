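# Rotamer building, classic/secondary matching, 6D hashing, match extraction.

test_that("the reduced rotamer library has the documented sizes", {
  s <- fixture_scaffold(1)
  expect_length(build_rotamers(s, 5, "ASP"), 9)
  expect_length(build_rotamers(s, 5, "ASP", ex1 = TRUE), 27)
  expect_length(build_rotamers(s, 5, "ASP", ex1 = TRUE, ex2 = TRUE), 81)
  expect_length(build_rotamers(s, 5, "GLY"), 0)
  expect_length(build_rotamers(s, 5, "LYS"), 81)
  expect_error(build_rotamers(s, 5, "XXX"), "unknown residue")
  # rebuild consistency: stored chis reproduce the built atoms (mod 360)
  for (r in build_rotamers(s, 5, "HIS")) {
    expect_lt(max(abs(((measure_chis(r$coords, "HIS") - r$chi + 180) %% 360) - 180)),
              1e-6)
  }
})

test_that("classic matching recovers a planted interaction with zero penalty", {
  ps <- fixture_planted(1)
  s <- ps$scaffold
  pos <- attr(s, "pocket_positions")
  hits <- classic_match_interaction(s, ps$theozyme$blocks[[1]], pos,
                                    ps$ligand, match_config(), 1L)
  expect_gt(n_hits(hits), 0)
  # the planted position/type appears among the hits
  expect_true(any(hits$meta$resi == ps$truth$positions[1] &
                    hits$meta$restype == ps$truth$restypes[1]))
  # every emitted hit re-scores to zero penalty
  idx <- sample(n_hits(hits), min(200, n_hits(hits)))
  b <- ps$theozyme$blocks[[1]]
  rt <- res_table(s)
  worst <- 0
  for (h in idx) {
    lp <- matrix(hits$coords[h, ], ncol = 3, byrow = TRUE,
                 dimnames = list(hits$lig_names))
    rot_ty <- hits$meta$restype[h]
    # rebuild the hit's rotamer and take the best triple pair
    chi <- hits$chi[h, seq_len(n_chi(rot_ty))]
    bb <- res_atoms(s, hits$meta$resi[h])[c("N", "CA", "C"), ]
    coords <- rbind(bb, build_sidechain(bb, rot_ty, chi))
    t2 <- lapply(resolve_atom_triples(b$map2, rot_ty), function(tr)
      coords[tr, , drop = FALSE])
    t1 <- lapply(resolve_atom_triples(b$map1, ps$ligand), function(tr)
      lp[tr, , drop = FALSE])
    worst <- max(worst, block_score_triples(t1, t2, b)$score)
  }
  expect_lt(worst, 1e-9)
  expect_equal(n_hits(classic_match_interaction(s, b, integer(0), ps$ligand)), 0)
})

test_that("classic matching hit counts are invariant under rigid motion", {
  ps <- fixture_planted(2)
  s <- ps$scaffold
  pos <- attr(s, "pocket_positions")[1:3]
  h0 <- classic_match_interaction(s, ps$theozyme$blocks[[1]], pos, ps$ligand)
  set.seed(99)
  s2 <- transform_structure(s, random_rotation(), rnorm(3, sd = 5))
  h1 <- classic_match_interaction(s2, ps$theozyme$blocks[[1]], pos, ps$ligand)
  expect_equal(n_hits(h1), n_hits(h0))
})

test_that("a wall of backbone atoms occludes every ligand placement", {
  ps <- fixture_planted(1)
  s <- ps$scaffold
  pos1 <- ps$truth$positions[1]
  ca <- res_atoms(s, pos1)["CA", ]
  # fill the reachable ball with pseudo-backbone carbon atoms dense enough
  # that any placement must collide
  g <- expand.grid(x = seq(-13, 13, 2.2), y = seq(-13, 13, 2.2),
                   z = seq(-13, 13, 2.2))
  g <- g[sqrt(rowSums(g^2)) < 13.5, ]
  wall <- data.frame(resi = max(res_table(s)$resi) + seq_len(nrow(g)),
                     chain = "A", resno = 500L + seq_len(nrow(g)),
                     resname = "ALA", name = "CA", element = "C",
                     x = g$x + ca[1], y = g$y + ca[2], z = g$z + ca[3],
                     het = FALSE)
  # keep only the wall grid plus the match position's own residue
  keep <- s$atoms[s$atoms$resi == pos1 & !s$atoms$het, names(wall)]
  sw <- new_structure(rbind(keep, wall))
  hits <- classic_match_interaction(sw, ps$theozyme$blocks[[1]], pos1, ps$ligand)
  expect_equal(n_hits(hits), 0)
  expect_gt(hits$rejected, 0)
})

test_that("secondary matching screens only the defined parameters", {
  ps <- fixture_planted(1)
  s <- ps$scaffold
  pos <- attr(s, "pocket_positions")
  b1 <- ps$theozyme$blocks[[1]]
  prior <- classic_match_interaction(s, b1, pos, ps$ligand, interaction = 1L)
  b3 <- ps$theozyme$blocks[[3]]
  h3 <- secondary_match_interaction(s, b3, prior, pos, ps$ligand, interaction = 3L)
  expect_gt(n_hits(h3), 0)
  # accepted hits copy the pose (hence the bin) from the prior hits
  k0 <- hash_hits(prior)
  k3 <- hash_hits(h3)
  expect_true(all(k3 %in% k0))
  # dropping constraints can only admit more (rotamer, hit) pairs
  b3_dist <- cst_block(b3$map1, b3$map2, b3$params["distanceAB"],
                       algorithm = "secondary")
  h_dist <- secondary_match_interaction(s, b3_dist, prior, pos, ps$ligand,
                                        interaction = 3L)
  expect_gte(n_hits(h_dist), n_hits(h3))
  # no prior hits: warning and empty result
  expect_warning(
    empty <- secondary_match_interaction(s, b3, enzdes:::.empty_hits(prior$lig_names),
                                         pos, ps$ligand),
    "no prior hits")
  expect_equal(n_hits(empty), 0)
})

test_that("secondary acceptance is equivalent to a zero flat-bottom penalty", {
  ps <- fixture_planted(3)
  s <- ps$scaffold
  pos <- attr(s, "pocket_positions")
  b1 <- ps$theozyme$blocks[[1]]
  b3 <- ps$theozyme$blocks[[3]]
  prior <- classic_match_interaction(s, b1, pos, ps$ligand, interaction = 1L)
  # subsample prior hits for speed
  keep <- seq(1, n_hits(prior), length.out = min(40, n_hits(prior)))
  sub <- prior
  sub$meta <- sub$meta[keep, ]; sub$chi <- sub$chi[keep, , drop = FALSE]
  sub$coords <- sub$coords[keep, , drop = FALSE]
  sub$pose <- sub$pose[keep, , drop = FALSE]
  h3 <- secondary_match_interaction(s, b3, sub, pos[1:3], ps$ligand,
                                    interaction = 3L)
  # oracle: enumerate all (rotamer, prior hit) pairs and accept iff the
  # block penalty of the realized geometry is exactly zero
  accepted_oracle <- 0
  for (p in pos[1:3]) {
    for (r in build_rotamers(s, p, "LYS")) {
      t2 <- lapply(resolve_atom_triples(b3$map2, "LYS"), function(tr)
        r$coords[tr, , drop = FALSE])
      for (h in seq_len(n_hits(sub))) {
        lp <- matrix(sub$coords[h, ], ncol = 3, byrow = TRUE,
                     dimnames = list(sub$lig_names))
        t1 <- lapply(resolve_atom_triples(b3$map1, ps$ligand), function(tr)
          lp[tr, , drop = FALSE])
        if (block_score_triples(t1, t2, b3)$score == 0)
          accepted_oracle <- accepted_oracle + 1
      }
    }
  }
  expect_equal(n_hits(h3), accepted_oracle)
})

test_that("6D hashing bins by floor division with wrapped Euler angles", {
  lig <- make_ligand_dhap()
  mkhits <- function(poses) {
    h <- enzdes:::.empty_hits(rownames(lig$conformer))
    h$meta <- data.frame(interaction = 1L, resi = seq_len(nrow(poses)),
                         restype = "GLU", score = 0)
    h$chi <- matrix(NA_real_, nrow(poses), 4)
    h$coords <- matrix(0, nrow(poses), 18)
    h$pose <- poses
    h
  }
  p <- rbind(c(1.2, 0.4, -0.7, 10, 20, 30),
             c(1.2, 0.4, -0.7, 10, 20, 30),
             c(2.7, 0.4, -0.7, 10, 20, 30),   # 1.5 bins away along x
             c(1.2, 0.4, -0.7, 359.9, 20, 30),
             c(1.2, 0.4, -0.7, 0.1, 20, 30))
  keys <- hash_hits(mkhits(p), match_config(euclid_bin = 1, euler_bin = 15))
  expect_equal(keys[1], keys[2])
  expect_false(keys[3] == keys[1])
  expect_false(keys[4] == keys[5])  # no neighbor merging across 0/360
})

test_that("match extraction requires one hit per interaction at distinct positions", {
  lig <- make_ligand_dhap()
  base <- enzdes:::.empty_hits(rownames(lig$conformer))
  add <- function(h, interaction, resi, pose) {
    h$meta <- rbind(h$meta, data.frame(interaction = interaction, resi = resi,
                                       restype = "GLU", score = 0))
    h$chi <- rbind(h$chi, rep(NA_real_, 4))
    h$coords <- rbind(h$coords, rep(0, 18))
    h$pose <- rbind(h$pose, pose)
    h
  }
  pose <- c(1, 1, 1, 10, 20, 30)
  h <- add(base, 1L, 5L, pose)
  h <- add(h, 1L, 6L, pose)
  h <- add(h, 2L, 7L, pose)
  h <- add(h, 3L, 8L, pose)
  m <- find_matches(h, 3, match_config())
  expect_length(m, 2)  # Cartesian 2 x 1 x 1
  # a bin missing one interaction yields nothing
  h12 <- add(add(base, 1L, 5L, pose), 2L, 7L, pose)
  expect_length(find_matches(h12, 3, match_config()), 0)
  # hits at the same scaffold position cannot form a match
  hsame <- add(add(add(base, 1L, 5L, pose), 2L, 5L, pose), 3L, 8L, pose)
  expect_length(find_matches(hsame, 3, match_config()), 0)
})

test_that("the matcher recovers a planted site end to end", {
  ps <- fixture_planted(1)
  s <- ps$scaffold
  cfg <- match_config()
  outdir <- tempfile()
  res <- suppressMessages(run_matcher(s, ps$theozyme, ps$ligand,
                                      attr(s, "pocket_positions"), cfg, outdir))
  expect_gt(length(res$matches), 0)
  tb <- paste(c(floor(ps$truth$pose[1:3] / cfg$euclid_bin),
                floor((ps$truth$pose[4:6] %% 360) / cfg$euler_bin)),
              collapse = "/")
  hit <- vapply(res$matches, function(m)
    m$bin == tb && all(m$positions == ps$truth$positions) &&
      all(m$restypes == ps$truth$restypes), logical(1))
  expect_true(any(hit))
  # perturbing the pose by 2 A moves it out of every recovered bin
  shifted <- ps$truth$pose + c(2, 0, 0, 0, 0, 0)
  sb <- paste(c(floor(shifted[1:3] / cfg$euclid_bin),
                floor((shifted[4:6] %% 360) / cfg$euler_bin)), collapse = "/")
  expect_false(sb %in% vapply(res$matches, `[[`, "", "bin"))
  # output files carry the grafted site and annotations
  expect_true(file.exists(file.path(outdir, "matches.tsv")))
  m1 <- read_pdb(file.path(outdir, "match_0001.pdb"), "DHL", ps$ligand)
  expect_equal(nrow(m1$catalytic), 3)
  expect_true(any(m1$atoms$het))
})

test_that("matcher configuration errors are caught", {
  ps <- fixture_planted(1)
  theo_bad <- ps$theozyme
  theo_bad$blocks[[1]]$algorithm <- "secondary"
  expect_error(suppressMessages(
    run_matcher(ps$scaffold, theo_bad, ps$ligand, 1:3)),
    "classic matching must be used for the first")
  # empty position list: clean zero-match exit (secondary stage warns)
  res <- suppressMessages(suppressWarnings(
    run_matcher(ps$scaffold, ps$theozyme, ps$ligand, integer(0))))
  expect_length(res$matches, 0)
})
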