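# cstfile parsing, writing, sample enumeration and atom-map resolution.

test_that("the worked example block parses field by field", {
  theo <- parse_cstfile(example_cst_text)
  expect_length(theo$blocks, 1)
  b <- theo$blocks[[1]]
  expect_equal(theo$ligand_name, "1n1")
  expect_equal(b$map1$mode, "by_name")
  expect_equal(b$map1$names, c("C1", "C2", "O2"))
  expect_equal(b$map2$mode, "by_type")
  expect_equal(b$map2$type_symbol, "OOC")
  expect_setequal(b$map2$allowed_residues, c("ASP", "GLU"))
  d <- b$params$distanceAB
  expect_equal(c(d$x0, d$xtol, d$k, d$fourth, d$n_samples), c(3.06, 0.2, 100, 0, 0))
  a <- b$params$angle_A
  expect_equal(c(a$x0, a$xtol, a$k, a$fourth, a$n_samples), c(73.6, 10, 80, 360, 1))
  expect_equal(b$params$torsion_AB$n_samples, 3)
  expect_equal(b$params$torsion_A$x0, -101.2)
})

test_that("malformed cstfiles are rejected with line numbers", {
  expect_length(parse_cstfile(character(0))$blocks, 0)
  expect_error(validate_theozyme(parse_cstfile(character(0))), "at least one")
  expect_error(parse_cstfile(c("CST::BEGIN",
                               "  TEMPLATE::   ATOM_MAP: 1 atom_name: A B C")),
               "no CST::END")
  expect_error(parse_cstfile(c("CST::BEGIN",
                               "  CONSTRAINT:: bond_AB: 1 2 3 4", "CST::END")),
               "line 2.*unknown")
  expect_error(parse_cstfile(c("CST::BEGIN",
                               "  CONSTRAINT:: distanceAB: 1 x 3 0", "CST::END")),
               "line 2.*non-numeric")
  expect_error(parse_cstfile(c(
    "CST::BEGIN",
    "  TEMPLATE::   ATOM_MAP: 1 atom_name: A B C",
    "  TEMPLATE::   ATOM_MAP: 1 atom_type: OH",
    "CST::END")), "both atom_name and atom_type")
  expect_error(parse_cstfile(c("CST::BEGIN",
                               "  TEMPLATE::   ATOM_MAP: 1 residue1: EDX",
                               "CST::END")), "unknown 1-letter")
  # comments are permitted and ignored
  theo <- parse_cstfile(c("# a theozyme", example_cst_text))
  expect_length(theo$blocks, 1)
})

test_that("writing and re-parsing a theozyme is the identity", {
  t0 <- parse_cstfile(example_cst_text)
  t1 <- parse_cstfile(write_cstfile(t0))
  expect_equal(t1$blocks, t0$blocks)
  # property: random theozymes round-trip field for field
  set.seed(31)
  for (i in 1:20) {
    nm <- sample(c("atom", "type"), 1)
    map1 <- atom_map_spec(1, "by_name",
                          names = paste0("X", 1:3), allowed_residues = "lg1")
    map2 <- if (nm == "atom") {
      atom_map_spec(2, "by_name", names = c("OG", "CB", "CA"),
                    allowed_residues = c("SER", "THR"))
    } else {
      atom_map_spec(2, "by_type", type_symbol = "OH",
                    allowed_residues = c("SER", "THR", "TYR"))
    }
    params <- list(
      cst_param("distanceAB", round(runif(1, 1, 5), 2), round(runif(1, 0, 1), 2),
                round(runif(1, 0, 200), 2), sample(0:1, 1), sample(0:3, 1)),
      cst_param("angle_A", round(runif(1, 0, 180), 2), round(runif(1, 0, 30), 1),
                round(runif(1, 0, 100), 1), sample(c(90, 120, 180, 360), 1),
                sample(0:3, 1)),
      cst_param("torsion_B", round(runif(1, -180, 180), 2), 15, 60.5,
                sample(c(120, 180, 360), 1), sample(0:2, 1)))
    t0 <- theozyme(list(cst_block(map1, map2, params)), "lg1")
    t1 <- parse_cstfile(write_cstfile(t0))
    expect_equal(t1$blocks, t0$blocks)
  }
})

test_that("sample enumeration matches the documented grid", {
  expect_equal(enumerate_samples(cst_param("angle_A", 73.60, 10, 80, 360, 1)),
               c(63.6, 73.6, 83.6))
  expect_equal(enumerate_samples(cst_param("torsion_A", 120, 15, 60, 180, 1)),
               c(105, 120, 135, 285, 300, 315))
  expect_length(enumerate_samples(cst_param("torsion_AB", 180, 90, 0, 360, 3)), 7)
  expect_equal(enumerate_samples(cst_param("distanceAB", 3.06, 0.2, 100, 0, 0)), 3.06)
  # n = 0: exactly the periodic copies of x0
  expect_equal(enumerate_samples(cst_param("angle_B", 120, 15, 80, 120, 0)),
               c(0, 120, 240))
  # odd count per copy, copy center always included
  set.seed(7)
  for (i in 1:30) {
    p <- cst_param("torsion_A", runif(1, -180, 180), runif(1, 1, 20),
                   10, sample(c(90, 120, 180, 360), 1), sample(0:4, 1))
    s <- enumerate_samples(p)
    copies <- sort(unique(round((p$x0 + (0:3) * p$fourth) %% 360, 6)))
    copies <- copies[copies < 360 - 1e-6 | length(copies) == 1]
    expect_equal(length(s) %% (2 * p$n_samples + 1), 0)
    for (cc in copies) expect_true(any(abs(s - cc) < 1e-6))
  }
  expect_error(cst_param("angle_A", 10, 5, 10, 0), "periodicity")
})

test_that("placement counts multiply the per-parameter sample counts", {
  expect_equal(placement_count(example_block()), 567)
  all0 <- lapply(enzdes:::.PORDER, function(n)
    cst_param(n, if (n == "distanceAB") 3 else 100, 5, 10,
              if (n == "distanceAB") 0 else 360, 0))
  b <- cst_block(atom_map_spec(1, "by_name", names = c("A", "B", "C"),
                               allowed_residues = "lg1"),
                 atom_map_spec(2, "by_type", type_symbol = "OH",
                               allowed_residues = "SER"), all0)
  expect_equal(placement_count(b), 1)
  p2 <- all0
  p2[[2]] <- cst_param("angle_A", 100, 5, 10, 360, 2)
  b2 <- cst_block(b$map1, b$map2, p2)
  expect_equal(placement_count(b2), 5)
  # brute-force cross-check: length of the Cartesian product
  brute <- prod(vapply(example_block()$params,
                       function(p) length(enumerate_samples(p)), numeric(1)))
  expect_equal(placement_count(example_block()), brute)
  incomplete <- cst_block(b$map1, b$map2, all0[1:3])
  expect_error(placement_count(incomplete), "lacks")
})

test_that("atom maps resolve to the documented triples", {
  lig <- make_ligand_dhap()
  m1 <- atom_map_spec(1, "by_name", names = c("C1", "C2", "O2"),
                      allowed_residues = "DHL")
  expect_equal(resolve_atom_triples(m1, lig), list(c("C1", "C2", "O2")))
  m2 <- atom_map_spec(2, "by_type", type_symbol = "OOC",
                      allowed_residues = c("ASP", "GLU"))
  trs <- resolve_atom_triples(m2, "ASP")
  expect_setequal(vapply(trs, paste, "", collapse = "-"),
                  c("OD1-CG-CB", "OD2-CG-CB"))
  # no atom of the requested type: empty result
  expect_length(resolve_atom_triples(m2, "SER"), 0)
  bad <- atom_map_spec(1, "by_name", names = c("C1", "C9", "O2"),
                       allowed_residues = "DHL")
  expect_error(resolve_atom_triples(bad, lig), "not in topology")
})
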