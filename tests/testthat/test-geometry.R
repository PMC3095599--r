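# Internal-coordinate measurement/construction and the periodic penalty.

wrapdiff <- function(a, b) abs(((a - b + 180) %% 360) - 180)

test_that("placing an atom and re-measuring recovers the internal coordinates", {
  set.seed(11)
  worst <- 0
  for (i in 1:1000) {
    p1 <- rnorm(3); p2 <- p1 + rnorm(3); p3 <- p2 + rnorm(3)
    d <- runif(1, 0.8, 4); th <- runif(1, 5, 175); ph <- runif(1, -180, 180)
    q <- place_atom(p1, p2, p3, d, th, ph)
    worst <- max(worst,
                 abs(sqrt(sum((q - p3)^2)) - d),
                 abs(angle_deg(p2, p3, q) - th),
                 wrapdiff(dihedral_deg(p1, p2, p3, q), ph))
  }
  expect_lt(worst, 1e-9)
})

test_that("the six constraint parameters follow their atom definitions", {
  # axis-aligned construction: both angles are right angles
  t1 <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))   # Res1 atoms 1..3
  t2 <- rbind(c(3, 0, 0), c(3, 0, 1), c(3, 1, 1))   # Res2 atoms 1..3
  p <- measure_params(t1, t2)
  expect_equal(unname(p["distanceAB"]), 3.0)
  expect_equal(unname(p["angle_A"]), 90)
  expect_equal(unname(p["angle_B"]), 90)
  # coplanar trans arrangement (|180| in the [-180, 180) convention)
  expect_equal(abs(dihedral_deg(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))), 180)
  # degenerate input
  expect_error(measure_params(rbind(t1[1, ], t1[1, ], t1[3, ]), t2), "degenerate")
  expect_error(place_atom(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), 1.5, 109, 0),
               "degenerate")
  expect_error(place_atom(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), 1.5, 109, 0),
               "collinear")
})

test_that("a placement built from a tuple measures back to the same tuple", {
  lig <- make_ligand_dhap()
  anchor <- rbind(c(0.3, 0.1, -0.2), c(1.6, 0.4, 0.3), c(2.2, 1.7, 0.1))
  set.seed(21)
  for (i in 1:25) {
    tup <- c(distanceAB = runif(1, 2.5, 4), angle_A = runif(1, 60, 150),
             angle_B = runif(1, 60, 150), torsion_A = runif(1, -180, 180),
             torsion_AB = runif(1, -180, 180), torsion_B = runif(1, -180, 180))
    lp <- build_ligand_placement(anchor, tup, lig, c("C1", "C2", "O2"))
    meas <- measure_params(anchor, lp[c("C1", "C2", "O2"), ])
    expect_lt(max(abs(meas["distanceAB"] - tup["distanceAB"]),
                  wrapdiff(meas[-1], tup[-1])), 1e-6)
  }
  # identity: re-anchoring the ligand onto its own triple moves nothing
  conf <- lig$conformer
  tr <- enzdes:::.rigid_from_triples(conf[c("C1", "C2", "O2"), ],
                                     conf[c("C1", "C2", "O2"), ])
  moved <- sweep(conf %*% t(tr$R), 2, tr$t, "+")
  expect_lt(max(abs(moved - conf)), 1e-9)
})

test_that("two torsion_AB samples differ by a rotation about the A1-B1 axis", {
  lig <- make_ligand_dhap()
  anchor <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2, 1.4, 0))
  tup <- c(distanceAB = 3, angle_A = 120, angle_B = 115, torsion_A = 40,
           torsion_AB = 30, torsion_B = 170)
  tup2 <- tup; tup2["torsion_AB"] <- 90
  a <- build_ligand_placement(anchor, tup, lig, c("C1", "C2", "O2"))
  b <- build_ligand_placement(anchor, tup2, lig, c("C1", "C2", "O2"))
  # the constrained ligand atom C1 stays on the axis; every atom keeps its
  # distance both to C1 and to the anchor atom defining the axis
  expect_lt(max(abs(a["C1", ] - b["C1", ])), 1e-9)
  da <- sqrt(rowSums(sweep(a, 2, anchor[1, ])^2))
  db <- sqrt(rowSums(sweep(b, 2, anchor[1, ])^2))
  expect_lt(max(abs(da - db)), 1e-9)
})

test_that("periodic deviation picks the nearest periodic copy", {
  expect_equal(periodic_delta(120, 120, 360), 0)
  expect_equal(periodic_delta(300, 120, 180), 0)
  # brute force over explicit copies
  brute <- min(abs(359 - (1 + (-2:2) * 360)))
  expect_equal(periodic_delta(359, 1, 360), brute)
  expect_equal(periodic_delta(359, 1, 360), 2)
  expect_error(periodic_delta(10, 0, -5), "positive")
})

test_that("the flat-bottomed penalty is zero inside and harmonic outside", {
  p <- cst_param("angle_A", 100, 10, 80, 360, 0)
  xs <- seq(90, 110, by = 0.5)
  expect_true(all(cst_penalty(xs, p) == 0))
  expect_equal(cst_penalty(100 + 10 + 0.5, p), 80 * 0.25)
  # continuity at the boundary (numerical scan; steps stay infinitesimal)
  grid <- seq(109.9, 110.1, by = 1e-4)
  vals <- cst_penalty(grid, p)
  expect_lt(max(abs(diff(vals))), 5e-3)
  expect_true(all(vals >= 0))
  # periodic invariance
  expect_equal(cst_penalty(137, p), cst_penalty(137 + 360, p))
  tor <- cst_param("torsion_A", 120, 5, 60, 120, 0)
  expect_equal(cst_penalty(55, tor), cst_penalty(55 + 120, tor))
})

test_that("penalty minima sit at the periodic copies of the ideal value", {
  m3 <- penalty_minima(cst_param("angle_A", 120, 4, 80, 120, 0))
  expect_length(m3, 3)
  expect_equal(m3, c(0, 120, 240), tolerance = 0.05)
  m2 <- penalty_minima(cst_param("angle_A", 120, 4, 80, 180, 0))
  expect_length(m2, 2)
  expect_equal(max(m2), 300, tolerance = 0.05)
})

test_that("block scores resolve by-type ambiguity to the lowest penalty", {
  blk <- example_block()
  lig <- make_ligand_dhap()
  anchor <- rbind(c(0, 0, 0), c(1.52, 0, 0), c(2.1, 1.4, 0))  # OD1, CG, CB
  tup <- vapply(blk$params[enzdes:::.PORDER], function(p) p$x0, numeric(1))
  names(tup) <- enzdes:::.PORDER
  lp <- build_ligand_placement(anchor, enzdes:::.swap_params(tup), lig,
                               c("C1", "C2", "O2"))
  t_lig <- list(lp[c("C1", "C2", "O2"), ])
  good <- list(anchor)
  bs <- block_score_triples(t_lig, good, blk)
  expect_equal(bs$score, 0)
  # a second, violating candidate triple must not raise the score
  bad <- list(anchor + 5, anchor)
  expect_equal(block_score_triples(t_lig, bad, blk)$score, 0)
  # a k=0 parameter contributes nothing however far it deviates
  expect_equal(unname(bs$breakdown["torsion_AB"]), 0)
  only_bad <- block_score_triples(t_lig, list(anchor + 5), blk)
  expect_gt(only_bad$score, 0)
})

test_that("6D poses respond correctly to rigid motions", {
  lig <- make_ligand_dhap()
  conf <- lig$conformer
  p0 <- pose6d_of(conf, lig)
  expect_identical(p0, pose6d_of(conf, lig))
  shifted <- sweep(conf, 2, c(1, 0, 0), "+")
  p1 <- pose6d_of(shifted, lig)
  expect_equal(unname(p1["tx"] - p0["tx"]), 1.0)
  expect_equal(p1[4:6], p0[4:6])
  # frame z of the conformer is world z (C1/C2/O2 lie in the xy-plane),
  # so rotating about it shifts the first Euler angle
  Rz <- enzdes:::.rot_axis(c(0, 0, 1), 90)
  p2 <- pose6d_of(conf %*% t(Rz), lig)
  expect_equal((p2[["e1"]] - p0[["e1"]]) %% 360, 90, tolerance = 1e-6)
  # equivariance: the rotation part of the transformed pose frame equals
  # the motion composed with the original frame
  set.seed(5)
  R <- random_rotation(); tv <- rnorm(3)
  moved <- sweep(conf %*% t(R), 2, tv, "+")
  F0 <- enzdes:::.frame_from_triple(conf["C1", ], conf["C2", ], conf["O2", ])
  F1 <- enzdes:::.frame_from_triple(moved["C1", ], moved["C2", ], moved["O2", ])
  expect_lt(max(abs(F1 - R %*% F0)), 1e-9)
})
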