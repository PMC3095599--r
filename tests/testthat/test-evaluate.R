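# Metrics, scorefile round trips and cutoff filtering.

test_that("the hydrogen-bond criterion accepts ideal geometry only", {
  # donor backbone N of one residue at 2.9 A from an acceptor O, with a
  # wide (165 degree) angle at the donor
  don <- make_residue("ALA")
  acc_O <- don["N", ] + c(0, 2.9, 0)
  # place the donor base so the base-N-O angle is 165 degrees
  th <- (180 - 165) * pi / 180
  base <- don["N", ] + 1.46 * c(sin(th), -cos(th), 0)
  don2 <- don; don2["CA", ] <- base
  acc <- rbind(N = acc_O + c(0, 1.4, 0), CA = acc_O + c(1.2, 0.8, 0),
               C = acc_O + c(2.2, 0, 0.4), O = acc_O)
  s <- build_structure(list(list(resname = "ALA", coords = don2),
                            list(resname = "ALA", coords = acc, resno = 10)))
  expect_equal(count_hbonds(s)$total, 1)
  # apolar-only fixture
  apolar <- build_structure(list(
    list(resname = "ALA", coords = make_residue("ALA")[c("N", "CA", "C", "CB"), ][c("CA", "CB"), , drop = FALSE])))
  expect_equal(count_hbonds(apolar)$total, 0)
  # count is invariant under rigid motion
  ps <- fixture_planted(1)
  h0 <- count_hbonds(ps$planted)
  set.seed(17)
  s2 <- transform_structure(ps$planted, random_rotation(), rnorm(3, sd = 8))
  expect_identical(count_hbonds(s2), h0)
})

test_that("buried unsatisfied polar atoms respond to added donors", {
  # a carbonyl O buried inside a cage of carbon atoms
  set.seed(4)
  cage <- expand.grid(x = c(-4, -2, 2, 4), y = c(-4, -2, 2, 4), z = c(-3, 0, 3))
  res <- list(list(resname = "ALA",
                   coords = rbind(N = c(20, 0, 0), CA = c(21.4, 0, 0),
                                  C = c(22, 1.3, 0), O = c(0, 0, 0))))
  for (i in seq_len(nrow(cage))) {
    p <- as.numeric(cage[i, ])
    res[[i + 1]] <- list(resname = "ALA", resno = i + 1,
                         coords = matrix(p, 1, 3, dimnames = list("CB")))
  }
  s <- build_structure(res)
  expect_equal(count_buried_unsat(s), 1)
  # satisfy it with one donor placed at hydrogen-bond geometry
  res2 <- c(res, list(list(resname = "LYS", resno = 99,
                           coords = matrix(c(0, 2.9, 0), 1, 3,
                                           dimnames = list("NZ")))))
  s2 <- build_structure(res2)
  expect_equal(count_buried_unsat(s2), count_buried_unsat(s) - 1)
  # a fully exposed polar atom is never counted
  lone <- build_structure(list(list(resname = "ALA",
                                    coords = make_residue("ALA"))))
  expect_equal(count_buried_unsat(lone), 0)
})

test_that("non-local contacts need both sequence separation and proximity", {
  # extended arrangement: consecutive residues 4 A apart along x
  ext <- lapply(1:12, function(i)
    list(resname = "ALA", resno = i,
         coords = matrix(c(4 * i, 0, 0), 1, 3, dimnames = list("CA"))))
  expect_equal(count_nonlocal_contacts(build_structure(ext)), 0)
  # hairpin: residues 2 and 11 brought within contact range
  hp <- ext
  hp[[11]]$coords <- matrix(c(8, 3.5, 0), 1, 3, dimnames = list("CA"))
  s <- build_structure(hp)
  expect_equal(count_nonlocal_contacts(s), 1)
  expect_equal(count_nonlocal_contacts(s, subset = 2), 1)
  expect_equal(count_nonlocal_contacts(s, subset = 5), 0)
})

test_that("the packing proxy is bounded and rewards tighter clusters", {
  lone <- build_structure(list(list(resname = "ALA",
                                    coords = matrix(0, 1, 3, dimnames = list("CB")))))
  expect_equal(packing_metric(lone), 0)
  grid <- as.matrix(expand.grid(x = seq(0, 8, 2), y = seq(0, 8, 2), z = seq(0, 8, 2)))
  res <- lapply(seq_len(nrow(grid)), function(i)
    list(resname = "ALA", resno = i,
         coords = matrix(grid[i, ], 1, 3, dimnames = list("CB"))))
  full <- build_structure(res)
  # delete an interior atom: packing around the hole drops
  interior <- which(apply(grid, 1, function(p) all(p == c(4, 4, 4))))
  pruned <- build_structure(res[-interior])
  expect_gt(packing_metric(full), packing_metric(pruned))
  expect_gte(packing_metric(full), 0); expect_lte(packing_metric(full), 1)
  ps <- fixture_planted(1)
  expect_gte(packing_metric(ps$planted), 0)
  expect_lte(packing_metric(ps$planted), 1)
})

test_that("the interface score is the protein-ligand part of the total", {
  ps <- fixture_planted(1)
  s <- ps$planted
  i0 <- interface_score(s)
  expect_identical(i0, interface_score(s))  # deterministic
  # decomposition identity for a pairwise model: complex = protein + interface
  prot <- s; prot$atoms <- prot$atoms[!prot$atoms$het, ]
  expect_equal(score_structure(s)$total,
               score_structure(prot)$total + i0, tolerance = 1e-9)
  # ligand moved far away: no interface left
  far <- set_ligand_coords(s, sweep(ligand_coords(s), 2, c(50, 0, 0), "+"))
  expect_equal(interface_score(far), 0)
})

test_that("score records are self-consistent and survive the scorefile", {
  ps <- fixture_planted(1)
  rec <- score_design(ps$planted, ps$theozyme, id = "planted")
  sr_cols <- grep("^SR[0-9]+$", names(rec), value = TRUE)
  expect_length(sr_cols, 4)  # 3 catalytic residues + the ligand column
  expect_equal(rec$all_cst, sum(unlist(rec[sr_cols])), tolerance = 1e-9)
  # independent recomputation of the restraint total from coordinates
  expect_equal(rec$all_cst, all_cst(ps$planted, ps$theozyme)$total)
  # with a single catalytic residue the ligand is SR2
  one <- theozyme(ps$theozyme$blocks[1], "DHL")
  s1 <- ps$planted
  s1$catalytic <- s1$catalytic[1, , drop = FALSE]
  rec1 <- score_design(s1, one, id = "single")
  expect_true(all(c("SR1", "SR2") %in% names(rec1)))
  expect_false("SR3" %in% names(rec1))
  # scorefile round trip
  recs <- rbind(rec, rec)
  recs$description <- c("d1", "d2")
  tf <- tempfile()
  write_scorefile(recs, tf)
  expect_length(readLines(tf), 3)
  back <- read_scorefile(tf)
  expect_equal(back$all_cst, recs$all_cst, tolerance = 1e-4)
  expect_equal(back$description, recs$description)
})

test_that("metrics are invariant under rigid motion of the whole model", {
  ps <- fixture_planted(2)
  s <- ps$planted
  set.seed(23)
  s2 <- transform_structure(s, random_rotation(), rnorm(3, sd = 10))
  expect_equal(count_buried_unsat(s2), count_buried_unsat(s))
  expect_equal(count_nonlocal_contacts(s2), count_nonlocal_contacts(s))
  expect_equal(packing_metric(s2), packing_metric(s), tolerance = 1e-9)
  expect_equal(all_cst(s2, ps$theozyme)$total, all_cst(s, ps$theozyme)$total,
               tolerance = 1e-6)
})

test_that("cutoff filtering matches a brute-force recount", {
  set.seed(9)
  recs <- data.frame(description = paste0("d", 1:10),
                     all_cst = runif(10, 0, 12),
                     total_score = rnorm(10),
                     tot_burunsat_pm = sample(0:8, 10, TRUE))
  cuts <- cutoff_spec(c("all_cst", "total_score", "tot_burunsat_pm"),
                      c("<", "<", "<"),
                      c(median(recs$all_cst), median(recs$total_score),
                        median(recs$tot_burunsat_pm)))
  out <- filter_designs(recs, cuts)
  brute <- recs[recs$all_cst < cuts$threshold[1] &
                  recs$total_score < cuts$threshold[2] &
                  recs$tot_burunsat_pm < cuts$threshold[3], ]
  expect_equal(out$passing$description, brute$description)
  expect_equal(unname(out$counts),
               c(sum(recs$all_cst < cuts$threshold[1]),
                 sum(recs$total_score < cuts$threshold[2]),
                 sum(recs$tot_burunsat_pm < cuts$threshold[3])))
  # boundary semantics and degenerate inputs
  expect_equal(nrow(filter_designs(data.frame(all_cst = 5),
                                   cutoff_spec("all_cst", "<", 6.5))$passing), 1)
  expect_equal(nrow(filter_designs(recs[0, ], cuts)$passing), 0)
  expect_equal(nrow(filter_designs(recs, cuts[0, ])$passing), nrow(recs))
  expect_error(filter_designs(recs, cutoff_spec("no_such", "<", 1)), "unknown metric")
  # cutoff file round trip
  tf <- tempfile()
  writeLines(c("# selection", "all_cst < 6.5", "tot_pstat_pm > 0.5"), tf)
  cf <- read_cutoff_file(tf)
  expect_equal(cf$metric, c("all_cst", "tot_pstat_pm"))
  expect_equal(cf$cmp, c("<", ">"))
})

test_that("a reference structure scores cleanly under the design conditions", {
  ps <- fixture_planted(1)
  cfg <- design_config(seed = 21)
  rec <- score_reference(ps$planted, ps$theozyme, cfg)
  expect_lt(rec$all_cst, 0.5)
  expect_true(all(c("SR1_rmsd", "SR2_rmsd", "SR3_rmsd") %in% names(rec)))
  # repeated runs with the same seed give identical metrics
  rec2 <- score_reference(ps$planted, ps$theozyme, cfg)
  expect_equal(rec2, rec)
  # annotations for every block are required
  bare <- ps$planted
  bare$catalytic <- bare$catalytic[0, ]
  expect_error(score_reference(bare, ps$theozyme, cfg), "annotations")
})
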