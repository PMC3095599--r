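# Internal-coordinate geometry: measurement and construction of the six
# constraint parameters (one distance, two angles, three dihedrals), the
# periodic flat-bottomed penalty, and 6D pose extraction for hashing.
# Angles are in degrees everywhere; torsions live in [-180, 180).

.deg2rad <- pi / 180
.rad2deg <- 180 / pi
.COLLINEAR_EPS <- 1e-8   # sin(angle) below this => degenerate

.vnorm <- function(v) sqrt(sum(v * v))

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

.wrap360 <- function(x) x %% 360

.wrap180 <- function(x) ((x + 180) %% 360) - 180

#' Bond angle at a vertex
#'
#' @param p1,p2,p3 numeric xyz vectors; the angle is measured at `p2`.
#' @return angle in degrees in \[0, 180\].
#' @export
angle_deg <- function(p1, p2, p3) {
  u <- .unit(p1 - p2)
  v <- .unit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * .rad2deg
}

#' Dihedral angle of four points
#'
#' Returns NA (a flagged undefined value) when either inner triple is
#' collinear, which leaves the torsion geometrically undefined.
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @return torsion in degrees in \[-180, 180), or NA if undefined.
#' @export
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  if (.vnorm(n1) < .COLLINEAR_EPS * .vnorm(b1) * .vnorm(b2) ||
      .vnorm(n2) < .COLLINEAR_EPS * .vnorm(b2) * .vnorm(b3)) {
    return(NA_real_)
  }
  m1 <- .vcross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  .wrap180(atan2(y, x) * .rad2deg)
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Builds the position `q` bonded to `p3` with bond length `d`, bond angle
#' `angle_deg(p2, p3, q) == theta` and dihedral
#' `dihedral_deg(p1, p2, p3, q) == phi`.
#'
#' @param p1,p2,p3 reference positions (must not be collinear).
#' @param d bond length in Angstrom (> 0).
#' @param theta bond angle in degrees.
#' @param phi dihedral in degrees.
#' @return xyz vector of the placed atom.
#' @export
place_atom <- function(p1, p2, p3, d, theta, phi) {
  bc <- p3 - p2
  if (.vnorm(bc) < 1e-9 || .vnorm(p2 - p1) < 1e-9)
    stop("degenerate geometry: coincident reference atoms")
  bcu <- .unit(bc)
  ab <- p2 - p1
  n <- .vcross(ab, bcu)
  if (.vnorm(n) < .COLLINEAR_EPS * .vnorm(ab))
    stop("degenerate geometry: collinear reference atoms")
  nu <- .unit(n)
  mu <- .vcross(nu, bcu)
  th <- theta * .deg2rad
  ph <- phi * .deg2rad
  # local displacement in the (bc, m, n) frame
  d2 <- c(-d * cos(th), d * sin(th) * cos(ph), -d * sin(th) * sin(ph))
  p3 + d2[1] * bcu + d2[2] * mu + d2[3] * nu
}

#' Measure the six constraint parameters between two atom triples
#'
#' The parameters follow the cstfile conventions: `distanceAB` is
#' Res1:Atom1 - Res2:Atom1, `angle_A` the angle Res1:Atom2 - Res1:Atom1 -
#' Res2:Atom1, `angle_B` the angle Res1:Atom1 - Res2:Atom1 - Res2:Atom2,
#' `torsion_A` the dihedral Res1:Atom3 - Res1:Atom2 - Res1:Atom1 - Res2:Atom1,
#' `torsion_AB` Res1:Atom2 - Res1:Atom1 - Res2:Atom1 - Res2:Atom2 and
#' `torsion_B` Res1:Atom1 - Res2:Atom1 - Res2:Atom2 - Res2:Atom3.
#'
#' @param t1 3x3 matrix, rows are Res1 atoms 1..3.
#' @param t2 3x3 matrix, rows are Res2 atoms 1..3.
#' @return named numeric vector of the six parameters; undefined torsions
#'   (collinear triples) are flagged NA.
#' @export
measure_params <- function(t1, t2) {
  t1 <- as.matrix(t1); t2 <- as.matrix(t2)
  if (.vnorm(t1[1, ] - t1[2, ]) < 1e-9 || .vnorm(t1[2, ] - t1[3, ]) < 1e-9 ||
      .vnorm(t2[1, ] - t2[2, ]) < 1e-9 || .vnorm(t2[2, ] - t2[3, ]) < 1e-9 ||
      .vnorm(t1[1, ] - t2[1, ]) < 1e-9)
    stop("degenerate geometry: coincident atoms in constraint triple")
  c(distanceAB = .vnorm(t1[1, ] - t2[1, ]),
    angle_A    = angle_deg(t1[2, ], t1[1, ], t2[1, ]),
    angle_B    = angle_deg(t1[1, ], t2[1, ], t2[2, ]),
    torsion_A  = dihedral_deg(t1[3, ], t1[2, ], t1[1, ], t2[1, ]),
    torsion_AB = dihedral_deg(t1[2, ], t1[1, ], t2[1, ], t2[2, ]),
    torsion_B  = dihedral_deg(t1[1, ], t2[1, ], t2[2, ], t2[3, ]))
}

# Swap the roles of Res1/Res2 in a parameter tuple. distanceAB and torsion_AB
# are symmetric; the A/B angles and torsions exchange.
.swap_params <- function(p) {
  c(distanceAB = unname(p["distanceAB"]),
    angle_A    = unname(p["angle_B"]),
    angle_B    = unname(p["angle_A"]),
    torsion_A  = unname(p["torsion_B"]),
    torsion_AB = unname(p["torsion_AB"]),
    torsion_B  = unname(p["torsion_A"]))
}

#' Minimal periodic deviation
#'
#' Smallest absolute difference between `x` and any periodic copy
#' `x0 + m * per` of the ideal value.
#'
#' @param x observed value(s), degrees.
#' @param x0 ideal value, degrees.
#' @param per periodicity in degrees (> 0).
#' @return deviation(s) in \[0, per/2\].
#' @export
periodic_delta <- function(x, x0, per) {
  if (per <= 0) stop("periodicity must be positive")
  d <- (x - x0) %% per
  pmin(d, per - d)
}

#' Flat-bottomed (periodic) restraint penalty
#'
#' Zero while the deviation from the nearest periodic copy of `x0` is within
#' the tolerance `xtol`, and harmonic with force constant `k` beyond it:
#' `k * max(0, delta - xtol)^2`. For `distanceAB` the deviation is plain
#' `|x - x0|`; for the angular parameters it is the minimal periodic
#' deviation with period given by the parameter's fourth column.
#'
#' @param x observed value(s).
#' @param param a `cst_param` (see [cst_param()]).
#' @return penalty score(s) (REU-like units).
#' @export
cst_penalty <- function(x, param) {
  delta <- if (param$name == "distanceAB") abs(x - param$x0)
           else periodic_delta(x, param$x0, param$fourth)
  param$k * pmax(0, delta - param$xtol)^2
}

#' Locate the minima of the periodic penalty over one full turn
#'
#' Evaluates the penalty on a regular grid over \[0, 360) and returns the
#' centers (in degrees) of the disjoint circular regions attaining the global
#' minimum. The domain is treated as circular, so a flat region spanning the
#' 0/360 boundary counts once.
#'
#' @param param an angular `cst_param`.
#' @param step grid spacing in degrees.
#' @return sorted numeric vector of region centers in \[0, 360).
#' @export
penalty_minima <- function(param, step = 0.1) {
  if (param$name == "distanceAB") stop("penalty_minima applies to angular parameters")
  x <- seq(0, 360 - step, by = step)
  p <- cst_penalty(x, param)
  lo <- p <= min(p) + 1e-9
  if (all(lo)) return(numeric(0))  # constant penalty: no distinct minima
  runs <- rle(lo)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  idx <- which(runs$values)
  regions <- cbind(starts[idx], ends[idx])
  # merge a run touching the end of the grid with one at the start (circular)
  wrapped <- FALSE
  if (nrow(regions) > 1 && regions[1, 1] == 1L && regions[nrow(regions), 2] == length(x)) {
    wrapped <- TRUE
  }
  centers <- apply(regions, 1, function(r) mean(x[r[1]:r[2]]))
  if (wrapped) {
    r1 <- regions[1, ]; rn <- regions[nrow(regions), ]
    vals <- c(x[rn[1]:rn[2]], x[r1[1]:r1[2]] + 360)
    centers <- c(.wrap360(mean(vals)), centers[-c(1, length(centers))])
  }
  sort(.wrap360(centers))
}

#' Build a ligand placement from an anchor triple and a parameter tuple
#'
#' Given the three anchor atoms of the catalytic side chain (Res1) and a
#' sampled parameter tuple, constructs the three ligand anchor atoms by
#' internal-coordinate placement and rigidly transforms the full ligand
#' conformer onto them. Measuring the parameters of the result reproduces
#' the tuple.
#'
#' @param res1_triple 3x3 matrix of the side-chain anchor atoms (rows 1..3).
#' @param sample named tuple with entries distanceAB, angle_A, angle_B,
#'   torsion_A, torsion_AB, torsion_B, expressed with Res1 = the anchor
#'   triple and Res2 = the ligand.
#' @param ligand a ligand topology (see [read_ligand_params()]).
#' @param map2_names character(3): the ligand anchor atom names.
#' @return matrix of ligand coordinates (rows named by atom).
#' @export
build_ligand_placement <- function(res1_triple, sample, ligand, map2_names) {
  conf <- ligand$conformer
  if (!all(map2_names %in% rownames(conf)))
    stop("ligand anchor atoms not in topology: ",
         paste(setdiff(map2_names, rownames(conf)), collapse = ", "))
  c1 <- conf[map2_names[1], ]; c2 <- conf[map2_names[2], ]; c3 <- conf[map2_names[3], ]
  q1 <- place_atom(res1_triple[3, ], res1_triple[2, ], res1_triple[1, ],
                   sample[["distanceAB"]], sample[["angle_A"]], sample[["torsion_A"]])
  q2 <- place_atom(res1_triple[2, ], res1_triple[1, ], q1,
                   .vnorm(c2 - c1), sample[["angle_B"]], sample[["torsion_AB"]])
  q3 <- place_atom(res1_triple[1, ], q1, q2,
                   .vnorm(c3 - c2), angle_deg(c1, c2, c3), sample[["torsion_B"]])
  tr <- .rigid_from_triples(rbind(c1, c2, c3), rbind(q1, q2, q3))
  out <- conf %*% t(tr$R)
  out <- sweep(out, 2, tr$t, "+")
  rownames(out) <- rownames(conf)
  out
}

# Orthonormal frame from an atom triple: origin at a1, x toward a2, a3 fixes
# the xy-plane. Errors on collinear triples.
.frame_from_triple <- function(a1, a2, a3) {
  ex <- .unit(a2 - a1)
  w <- a3 - a1
  wz <- .vcross(ex, w)
  if (.vnorm(wz) < .COLLINEAR_EPS * .vnorm(w))
    stop("degenerate geometry: collinear frame atoms")
  ez <- .unit(wz)
  ey <- .vcross(ez, ex)
  cbind(ex, ey, ez)
}

# Exact rigid transform mapping one triple onto a congruent one.
.rigid_from_triples <- function(from3, to3) {
  Ff <- .frame_from_triple(from3[1, ], from3[2, ], from3[3, ])
  Ft <- .frame_from_triple(to3[1, ], to3[2, ], to3[3, ])
  R <- Ft %*% t(Ff)
  list(R = R, t = as.numeric(to3[1, ] - R %*% from3[1, ]))
}

# z-x-z Euler angles (degrees, wrapped to [0,360)) of a rotation matrix.
.euler_zxz <- function(R) {
  b <- acos(max(-1, min(1, R[3, 3]))) * .rad2deg
  if (sin(b * .deg2rad) > 1e-9) {
    a <- atan2(R[1, 3], -R[2, 3]) * .rad2deg
    g <- atan2(R[3, 1], R[3, 2]) * .rad2deg
  } else {
    # gimbal-degenerate: fold everything into the first angle
    a <- atan2(R[2, 1], R[1, 1]) * .rad2deg
    g <- 0
  }
  .wrap360(c(a, b, g))
}

#' Extract the 6D pose of a placed ligand
#'
#' The pose is the position of the ligand reference frame (3 Euclidean
#' coordinates, Angstrom) plus its orientation as z-x-z Euler angles
#' (degrees in \[0, 360)). The frame is built from the ligand's three frame
#' atoms (by default the first theozyme block's ligand atom map).
#'
#' @param coords ligand coordinate matrix with atom-name rownames.
#' @param ligand ligand topology; its `frame` field names the frame atoms.
#' @return named numeric vector (tx, ty, tz, e1, e2, e3).
#' @export
pose6d_of <- function(coords, ligand) {
  fr <- ligand$frame
  if (is.null(fr)) fr <- rownames(ligand$conformer)[1:3]
  if (!all(fr %in% rownames(coords))) stop("frame atoms missing from coordinates")
  Fm <- .frame_from_triple(coords[fr[1], ], coords[fr[2], ], coords[fr[3], ])
  e <- .euler_zxz(Fm)
  setNames(c(as.numeric(coords[fr[1], ]), e),
           c("tx", "ty", "tz", "e1", "e2", "e3"))
}

#' Score one constraint block on resolved atom triples
#'
#' Sums the flat-bottom penalties of the block's defined parameters. When a
#' by-type atom map resolves to several candidate triples, the minimum total
#' over all triple combinations is taken (ambiguity resolution).
#'
#' @param triples1 list of 3x3 matrices for Res1 candidates.
#' @param triples2 list of 3x3 matrices for Res2 candidates.
#' @param block a `cst_block`.
#' @return list with `score` (total), `breakdown` (per parameter, for the
#'   winning combination) and `params` (the measured tuple).
#' @export
block_score_triples <- function(triples1, triples2, block) {
  if (length(triples1) == 0 || length(triples2) == 0)
    return(list(score = Inf, breakdown = NULL, params = NULL,
                note = "unresolvable atom triple"))
  best <- NULL
  for (t1 in triples1) for (t2 in triples2) {
    meas <- measure_params(t1, t2)
    br <- vapply(block$params, function(p) {
      v <- meas[[p$name]]
      if (is.na(v)) return(if (p$k > 0) Inf else 0)
      cst_penalty(v, p)
    }, numeric(1))
    tot <- sum(br)
    if (is.null(best) || tot < best$score)
      best <- list(score = tot, breakdown = br, params = meas)
  }
  best
}
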