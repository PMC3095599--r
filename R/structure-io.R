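# Structure container and readers/writers: PDB (through bio3d, plus the
# catalytic-annotation REMARK dialect), the params-style ligand topology
# format, and position files. Internally residues are indexed 0-based-free:
# `resi` is a 1-based sequential index over protein residues; PDB residue
# numbers/chains only exist at the reader/writer boundary.

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with columns resi, chain, resno, resname, name,
#'   element, x, y, z, het (logical).
#' @param catalytic data.frame with columns block, chain, resno, resname
#'   (zero rows when no annotations).
#' @param ligand_name residue name of the ligand, or NA.
#' @param ligand optional attached ligand topology (`enz_ligand`).
#' @return an `enz_structure`.
#' @export
new_structure <- function(atoms, catalytic = NULL, ligand_name = NA_character_,
                          ligand = NULL) {
  if (is.null(catalytic))
    catalytic <- data.frame(block = integer(0), chain = character(0),
                            resno = integer(0), resname = character(0))
  atoms$backbone <- atoms$name %in% c("N", "CA", "C", "O") & !atoms$het
  structure(list(atoms = atoms, catalytic = catalytic,
                 ligand_name = ligand_name, ligand = ligand),
            class = "enz_structure")
}

#' @export
print.enz_structure <- function(x, ...) {
  rt <- res_table(x)
  cat("structure:", nrow(rt), "residues,",
      sum(x$atoms$het), "ligand atom(s)",
      if (nrow(x$catalytic)) sprintf(", %d catalytic annotation(s)", nrow(x$catalytic)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Residue table of a structure (protein residues only)
#' @param s an `enz_structure`.
#' @return data.frame resi, chain, resno, resname.
#' @export
res_table <- function(s) {
  a <- s$atoms[!s$atoms$het, ]
  unique(a[, c("resi", "chain", "resno", "resname")])
}

#' Coordinates of one residue
#' @param s structure; @param resi residue index.
#' @return coordinate matrix with atom-name rownames.
#' @export
res_atoms <- function(s, resi) {
  a <- s$atoms[!s$atoms$het & s$atoms$resi == resi, ]
  if (!nrow(a)) stop("no residue with index ", resi)
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$name
  m
}

#' Ligand coordinates of a structure
#' @param s structure.
#' @return coordinate matrix with atom-name rownames (error if no ligand).
#' @export
ligand_coords <- function(s) {
  a <- s$atoms[s$atoms$het, ]
  if (!nrow(a)) stop("structure has no ligand")
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$name
  m
}

# heavy ligand atom coordinates only
.ligand_heavy <- function(s) {
  m <- ligand_coords(s)
  a <- s$atoms[s$atoms$het, ]
  m[a$element != "H", , drop = FALSE]
}

#' Replace the ligand coordinates of a structure
#' @param s structure; @param coords matrix with rownames matching the
#'   current ligand atoms.
#' @export
set_ligand_coords <- function(s, coords) {
  idx <- which(s$atoms$het)
  ord <- match(s$atoms$name[idx], rownames(coords))
  if (anyNA(ord)) stop("ligand coordinate names do not match structure")
  s$atoms[idx, c("x", "y", "z")] <- coords[ord, , drop = FALSE]
  s
}

#' Map catalytic annotations to residue indices
#' @param s structure.
#' @return data.frame block, resi, resname (one row per annotation).
#' @export
catalytic_residues <- function(s) {
  if (!nrow(s$catalytic))
    return(data.frame(block = integer(0), resi = integer(0), resname = character(0)))
  rt <- res_table(s)
  key <- paste(rt$chain, rt$resno)
  resi <- rt$resi[match(paste(s$catalytic$chain, s$catalytic$resno), key)]
  if (anyNA(resi)) stop("catalytic annotation references a residue not in the structure")
  data.frame(block = s$catalytic$block, resi = resi, resname = s$catalytic$resname)
}

#' Mutate a residue, rebuilding its side chain from ideal geometry
#'
#' Backbone atoms (N, CA, C, O) are kept; the side chain is rebuilt by
#' internal-coordinate construction with the given chi angles.
#'
#' @param s structure; @param resi residue index; @param restype new
#'   3-letter type; @param chi chi angles (degrees), default all -60.
#' @export
mutate_residue <- function(s, resi, restype, chi = NULL) {
  restype <- toupper(restype)
  if (is.null(chi)) chi <- rep(-60, n_chi(restype))
  bb <- res_atoms(s, resi)
  if (!all(c("N", "CA", "C") %in% rownames(bb)))
    stop("residue ", resi, " lacks backbone atoms")
  sc <- build_sidechain(bb[c("N", "CA", "C"), ], restype, chi)
  keep <- s$atoms$het | s$atoms$resi != resi |
    (s$atoms$resi == resi & s$atoms$name %in% c("N", "CA", "C", "O") & !s$atoms$het)
  a <- s$atoms[keep, ]
  a$resname[!a$het & a$resi == resi] <- restype
  meta <- a[!a$het & a$resi == resi, ][1, ]
  if (nrow(sc)) {
    newrows <- data.frame(resi = resi, chain = meta$chain, resno = meta$resno,
                          resname = restype, name = rownames(sc),
                          element = .element_from_name(rownames(sc)),
                          x = sc[, 1], y = sc[, 2], z = sc[, 3], het = FALSE,
                          backbone = FALSE)
    a <- rbind(a, newrows)
  }
  a <- a[order(a$het, a$resi, match(a$name, c("N", "CA", "C", "O", "CB"), nomatch = 99)), ]
  rownames(a) <- NULL
  s$atoms <- a
  s$atoms$backbone <- s$atoms$name %in% c("N", "CA", "C", "O") & !s$atoms$het
  s
}

#' Read a PDB file into a structure
#'
#' ATOM/HETATM records are parsed with bio3d; HETATM residues matching
#' `ligand_name` (or the first HETATM residue when NULL) become the ligand.
#' `REMARK CATALYTIC <block> <chain> <resno> <restype>` lines populate the
#' catalytic annotations.
#'
#' @param path PDB file.
#' @param ligand_name 3-letter ligand code, or NULL to autodetect.
#' @param ligand optional ligand topology to attach.
#' @return an `enz_structure`.
#' @export
read_pdb <- function(path, ligand_name = NULL, ligand = NULL) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  if (is.null(ligand_name)) {
    hets <- unique(at$resid[at$type == "HETATM" & at$resid != "HOH"])
    ligand_name <- if (length(hets)) hets[1] else NA_character_
  }
  het <- at$type == "HETATM" & !is.na(ligand_name) & at$resid == ligand_name
  prot <- at[!het & at$type == "ATOM", ]
  key <- paste(prot$chain, prot$insert, prot$resno)
  resi <- match(key, unique(key))
  elem <- ifelse(is.na(prot$elesy) | prot$elesy == "",
                 .element_from_name(prot$elety), prot$elesy)
  atoms <- data.frame(resi = resi, chain = prot$chain, resno = prot$resno,
                      resname = prot$resid, name = prot$elety, element = elem,
                      x = prot$x, y = prot$y, z = prot$z, het = FALSE)
  lig <- at[het, ]
  if (nrow(lig)) {
    lelem <- ifelse(is.na(lig$elesy) | lig$elesy == "",
                    .element_from_name(lig$elety), lig$elesy)
    atoms <- rbind(atoms,
                   data.frame(resi = NA_integer_, chain = lig$chain,
                              resno = lig$resno, resname = lig$resid,
                              name = lig$elety, element = lelem,
                              x = lig$x, y = lig$y, z = lig$z, het = TRUE))
  }
  lines <- readLines(path, warn = FALSE)
  cat_lines <- grep("^REMARK CATALYTIC ", lines, value = TRUE)
  catal <- NULL
  if (length(cat_lines)) {
    parts <- strsplit(trimws(sub("^REMARK CATALYTIC", "", cat_lines)), "[[:space:]]+")
    bad <- vapply(parts, length, integer(1)) != 4
    if (any(bad)) stop("malformed REMARK CATALYTIC line in ", path)
    catal <- data.frame(block = as.integer(vapply(parts, `[`, "", 1)),
                        chain = vapply(parts, `[`, "", 2),
                        resno = as.integer(vapply(parts, `[`, "", 3)),
                        resname = vapply(parts, `[`, "", 4))
  }
  new_structure(atoms, catal, ligand_name = ligand_name, ligand = ligand)
}

#' Write a structure to a PDB file
#'
#' Catalytic annotations are emitted as `REMARK CATALYTIC` lines ahead of
#' the coordinate records written by bio3d.
#'
#' @param s structure; @param path output file.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  resno_out <- ifelse(a$het, max(c(0, a$resno[!a$het])) + 1L, a$resno)
  suppressWarnings(bio3d::write.pdb(
    file = tmp, xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = resno_out, resid = a$resname, eleno = seq_len(nrow(a)),
    elety = a$name, chain = ifelse(is.na(a$chain), "A", a$chain),
    elesy = a$element))
  body <- readLines(tmp, warn = FALSE)
  remarks <- character(0)
  if (nrow(s$catalytic)) {
    remarks <- sprintf("REMARK CATALYTIC %d %s %d %s", s$catalytic$block,
                       s$catalytic$chain, s$catalytic$resno, s$catalytic$resname)
  }
  writeLines(c(remarks, body), path)
  invisible(path)
}

# --- ligand params -----------------------------------------------------------

#' Read a params-style ligand topology
#'
#' The dialect has one record per line:
#' \preformatted{
#' NAME <res3>
#' ATOM <name> <element> <type>
#' BOND <atom1> <atom2>
#' ICOOR <atom> <d> <theta> <phi> <parent> <angle_ref> <torsion_ref>
#' FRAME <a1> <a2> <a3>        # optional 6D-pose frame atoms
#' XYZ <atom> <x> <y> <z>      # optional stored conformer
#' }
#' The first three ICOOR records seed the frame (the first atom sits at the
#' origin, the second along x, the third in the xy-plane); later atoms are
#' placed by NeRF from their three reference atoms. A stored conformer, when
#' present, must match the rebuilt one to 1e-4 Angstrom.
#'
#' @param path params file.
#' @return an `enz_ligand` topology.
#' @export
read_ligand_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name3 <- NA_character_
  atoms <- list(); bonds <- list(); icoor <- list(); xyz <- list()
  frame <- NULL
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    if (!nzchar(trimws(line))) next
    t <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (t[1] == "NAME") { name3 <- t[2]; next }
    if (t[1] == "ATOM") {
      if (length(t) < 4) stop("params line ", ln, ": ATOM needs name, element, type")
      atoms[[length(atoms) + 1]] <- data.frame(name = t[2], element = t[3], type = t[4])
      next
    }
    if (t[1] == "BOND") { bonds[[length(bonds) + 1]] <- t[2:3]; next }
    if (t[1] == "ICOOR") {
      nums <- suppressWarnings(as.numeric(t[3:5]))
      if (anyNA(nums)) stop("params line ", ln, ": non-numeric ICOOR column")
      icoor[[length(icoor) + 1]] <-
        data.frame(name = t[2], d = nums[1], theta = nums[2], phi = nums[3],
                   parent = t[6], aref = t[7], tref = t[8])
      next
    }
    if (t[1] == "FRAME") { frame <- t[2:4]; next }
    if (t[1] == "XYZ") {
      xyz[[length(xyz) + 1]] <- data.frame(name = t[2], x = as.numeric(t[3]),
                                           y = as.numeric(t[4]), z = as.numeric(t[5]))
      next
    }
    stop("params line ", ln, ": unknown record: ", t[1])
  }
  atoms <- do.call(rbind, atoms)
  icoor <- do.call(rbind, icoor)
  if (is.null(atoms) || is.null(icoor)) stop("params file lacks ATOM/ICOOR records")
  if (anyDuplicated(atoms$name)) stop("duplicate ligand atom name")
  bonds <- if (length(bonds)) do.call(rbind, lapply(bonds, function(b)
    data.frame(a1 = b[1], a2 = b[2]))) else data.frame(a1 = character(0), a2 = character(0))
  bad <- setdiff(c(bonds$a1, bonds$a2), atoms$name)
  if (length(bad)) stop("bond references undeclared atom: ", paste(bad, collapse = ", "))
  if (!setequal(icoor$name, atoms$name)) stop("ICOOR tree does not span all atoms")
  conformer <- .build_ligand_conformer(icoor)
  if (length(xyz)) {
    xyz <- do.call(rbind, xyz)
    stored <- as.matrix(xyz[, c("x", "y", "z")]); rownames(stored) <- xyz$name
    tr <- .rigid_from_triples(conformer[icoor$name[1:3], ], stored[icoor$name[1:3], ])
    rebuilt <- sweep(conformer %*% t(tr$R), 2, tr$t, "+")
    dev <- max(sqrt(rowSums((rebuilt[rownames(stored), ] - stored)^2)))
    if (dev > 1e-4)
      stop(sprintf("stored conformer deviates %.3g A from icoor rebuild", dev))
    conformer <- stored[rownames(conformer), , drop = FALSE]
  }
  parent <- setNames(icoor$parent, icoor$name)
  parent[icoor$name[1]] <- NA_character_
  if (is.null(frame)) frame <- icoor$name[1:3]
  structure(list(name = name3, atoms = atoms, bonds = bonds, icoor = icoor,
                 parent = parent, conformer = conformer, frame = frame),
            class = "enz_ligand")
}

.build_ligand_conformer <- function(icoor) {
  n <- nrow(icoor)
  if (n < 3) stop("ligand needs at least 3 atoms")
  coords <- matrix(NA_real_, n, 3, dimnames = list(icoor$name))
  coords[1, ] <- c(0, 0, 0)
  coords[2, ] <- c(icoor$d[2], 0, 0)
  th <- icoor$theta[3] * .deg2rad
  p <- icoor$parent[3]
  if (!p %in% icoor$name[1:2]) stop("third ICOOR atom must reference the first two")
  base <- coords[p, ]
  dirx <- if (p == icoor$name[1]) c(1, 0, 0) else c(-1, 0, 0)
  coords[3, ] <- base + icoor$d[3] * (cos(pi - th) * -dirx + sin(pi - th) * c(0, 1, 0))
  if (n > 3) for (i in 4:n) {
    refs <- c(icoor$tref[i], icoor$aref[i], icoor$parent[i])
    if (anyNA(match(refs, icoor$name[seq_len(i - 1)])))
      stop("ICOOR atom ", icoor$name[i], " references a later atom (cyclic tree)")
    coords[i, ] <- place_atom(coords[refs[1], ], coords[refs[2], ], coords[refs[3], ],
                              icoor$d[i], icoor$theta[i], icoor$phi[i])
  }
  coords
}

#' Write a ligand topology as a params-style file
#' @param lig an `enz_ligand`; @param path output file.
#' @export
write_ligand_params <- function(lig, path) {
  out <- c(paste("NAME", lig$name),
           sprintf("ATOM %s %s %s", lig$atoms$name, lig$atoms$element, lig$atoms$type),
           if (nrow(lig$bonds)) sprintf("BOND %s %s", lig$bonds$a1, lig$bonds$a2),
           sprintf("ICOOR %s %s %s %s %s %s %s", lig$icoor$name,
                   .fmt_num(lig$icoor$d), .fmt_num(lig$icoor$theta),
                   .fmt_num(lig$icoor$phi), lig$icoor$parent, lig$icoor$aref,
                   lig$icoor$tref),
           paste("FRAME", paste(lig$frame, collapse = " ")))
  writeLines(out, path)
  invisible(path)
}

# donor/acceptor/radius vectors for the ligand's heavy atoms
.ligand_props <- function(lig) {
  heavy <- lig$atoms$element != "H"
  at <- lig$atoms[heavy, ]
  data.frame(name = at$name,
             radius = .element_radius(at$element),
             don = .type_is_donor(at$type),
             acc = .type_is_acceptor(at$type))
}

#' Read a position file (scaffold residues to match at)
#'
#' Whitespace/newline-separated residue numbers, optionally chain-qualified
#' as `A:17`. Duplicates collapse, order of first appearance is kept.
#'
#' @param path posfile.
#' @return data.frame chain (NA when unqualified), resno.
#' @export
read_posfile <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (!length(toks)) return(data.frame(chain = character(0), resno = integer(0)))
  chain <- ifelse(grepl(":", toks), sub(":.*$", "", toks), NA_character_)
  num <- sub("^.*:", "", toks)
  if (any(!grepl("^[0-9]+$", num)))
    stop("posfile: non-numeric residue token: ",
         paste(toks[!grepl("^[0-9]+$", num)], collapse = ", "))
  df <- unique(data.frame(chain = chain, resno = as.integer(num)))
  rownames(df) <- NULL
  df
}

# resolve posfile selectors to residue indices; unknown selectors are
# skipped with a warning
.positions_to_resi <- function(s, pos) {
  rt <- res_table(s)
  resi <- integer(0)
  for (i in seq_len(nrow(pos))) {
    hit <- rt$resi[rt$resno == pos$resno[i] &
                     (is.na(pos$chain[i]) | rt$chain == pos$chain[i])]
    if (!length(hit)) {
      warning("position ", pos$resno[i], " not in scaffold; skipped")
    } else resi <- c(resi, hit[1])
  }
  unique(resi)
}
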