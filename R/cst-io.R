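# The geometric-constraint file ("cstfile") expresses a theozyme as one block
# per catalytic interaction: two atom maps (which atoms on each partner) and
# up to six parameter records (distanceAB, angle_A, angle_B, torsion_A,
# torsion_AB, torsion_B), each with ideal value, tolerance, force constant,
# covalent flag or periodicity, and an optional sample count for matching.

.PARAM_NAMES <- c("distanceAB", "angle_A", "angle_B",
                  "torsion_A", "torsion_AB", "torsion_B")

#' Constraint parameter record
#'
#' @param name one of distanceAB, angle_A, angle_B, torsion_A, torsion_AB,
#'   torsion_B.
#' @param x0 ideal value (Angstrom or degrees).
#' @param xtol flat-bottom tolerance (same units, >= 0).
#' @param k force constant (score units per squared deviation, >= 0).
#' @param fourth for distanceAB the covalent flag (0/1); for angular
#'   parameters the periodicity in degrees (> 0).
#' @param n_samples matcher sample count n; 2n+1 points are sampled across
#'   the tolerance range around each periodic copy of x0.
#' @return a `cst_param` list.
#' @export
cst_param <- function(name, x0, xtol, k, fourth, n_samples = 0L) {
  if (!name %in% .PARAM_NAMES) stop("unknown constraint parameter: ", name)
  if (!is.finite(x0)) stop(name, ": x0 must be finite")
  if (xtol < 0) stop(name, ": tolerance must be >= 0")
  if (k < 0) stop(name, ": force constant must be >= 0")
  if (name == "distanceAB") {
    if (!fourth %in% c(0, 1)) stop("distanceAB covalent flag must be 0 or 1")
  } else if (fourth <= 0) {
    stop(name, ": periodicity must be > 0")
  }
  if (n_samples < 0 || n_samples != round(n_samples))
    stop(name, ": sample count must be a non-negative integer")
  structure(list(name = name, x0 = x0, xtol = xtol, k = k,
                 fourth = fourth, n_samples = as.integer(n_samples)),
            class = "cst_param")
}

#' Atom map of one constraint partner
#'
#' Either names the three constrained atoms exactly (`atom_name` mode) or
#' gives a single atom type (`atom_type` mode), in which case atoms 2 and 3
#' are the base atom and its base atom in the residue tree and type
#' ambiguity (e.g. the two carboxylate oxygens of Asp) is resolved by taking
#' the lowest-scoring candidate.
#'
#' @param which catalytic partner index, 1 or 2.
#' @param mode "by_name" or "by_type".
#' @param names character(3) atom names (by_name mode).
#' @param type_symbol atom-type token (by_type mode).
#' @param allowed_residues residue type names that may carry this partner.
#' @param residue_tag how the residues were declared ("residue1"/"residue3");
#'   used to round-trip the file faithfully.
#' @return an `atom_map_spec` list.
#' @export
atom_map_spec <- function(which, mode, names = NULL, type_symbol = NULL,
                          allowed_residues, residue_tag = NULL) {
  if (!which %in% c(1L, 2L)) stop("atom map partner index must be 1 or 2")
  if (mode == "by_name") {
    if (length(names) != 3) stop("atom_name mode needs exactly 3 atom names")
    if (!is.null(type_symbol)) stop("atom map cannot give both atom_name and atom_type")
  } else if (mode == "by_type") {
    if (length(type_symbol) != 1) stop("atom_type mode needs exactly 1 type symbol")
    if (!is.null(names)) stop("atom map cannot give both atom_name and atom_type")
  } else stop("atom map mode must be by_name or by_type")
  if (length(allowed_residues) < 1) stop("atom map needs at least one allowed residue type")
  if (is.null(residue_tag))
    residue_tag <- if (all(allowed_residues %in% .AA3)) "residue1" else "residue3"
  structure(list(which = as.integer(which), mode = mode, names = names,
                 type_symbol = type_symbol,
                 allowed_residues = allowed_residues, residue_tag = residue_tag),
            class = "atom_map_spec")
}

#' One theozyme interaction (constraint block)
#'
#' @param map1,map2 `atom_map_spec` for partners 1 and 2.
#' @param params list of `cst_param`, at most one per parameter name.
#' @param algorithm matcher algorithm for this interaction ("classic" or
#'   "secondary"); an assignment made in matcher configuration, not part of
#'   the cstfile grammar.
#' @return a `cst_block` list.
#' @export
cst_block <- function(map1, map2, params, algorithm = "classic") {
  stopifnot(inherits(map1, "atom_map_spec"), inherits(map2, "atom_map_spec"))
  if (map1$which != 1L || map2$which != 2L)
    stop("block maps must have partner indices 1 and 2")
  nm <- vapply(params, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate constraint parameter: ", nm[duplicated(nm)][1])
  names(params) <- nm
  if (!algorithm %in% c("classic", "secondary")) stop("unknown matching algorithm")
  structure(list(map1 = map1, map2 = map2, params = params, algorithm = algorithm),
            class = "cst_block")
}

#' A theozyme: an ordered list of constraint blocks plus the ligand name
#'
#' @param blocks list of `cst_block`.
#' @param ligand_name 3-letter (or params-style) ligand residue code, or NA.
#' @export
theozyme <- function(blocks, ligand_name = NA_character_) {
  structure(list(blocks = blocks, ligand_name = ligand_name), class = "theozyme")
}

#' Validate a theozyme against its structural invariants
#'
#' At least one block is required, the first block must be assigned classic
#' matching, and classic blocks must define all six parameters.
#'
#' @param theo a `theozyme`.
#' @return the theozyme, invisibly; errors on violation.
#' @export
validate_theozyme <- function(theo) {
  if (length(theo$blocks) < 1) stop("theozyme must contain at least one constraint block")
  if (theo$blocks[[1]]$algorithm != "classic")
    stop("classic matching must be used for the first theozyme interaction")
  for (i in seq_along(theo$blocks)) {
    b <- theo$blocks[[i]]
    if (b$algorithm == "classic" && !all(.PARAM_NAMES %in% names(b$params)))
      stop("classic-matched block ", i, " must define sample values for all 6 parameters")
  }
  invisible(theo)
}

#' @export
print.theozyme <- function(x, ...) {
  cat("theozyme:", length(x$blocks), "interaction block(s), ligand",
      x$ligand_name, "\n")
  for (i in seq_along(x$blocks)) {
    b <- x$blocks[[i]]
    cat(sprintf("  block %d [%s]: %s\n", i, b$algorithm,
                paste(names(b$params), collapse = ", ")))
  }
  invisible(x)
}

.expand_residue1 <- function(code, line = NA) {
  letters1 <- strsplit(code, "")[[1]]
  bad <- setdiff(toupper(letters1), names(.AA1TO3))
  if (length(bad))
    stop("cstfile line ", line, ": unknown 1-letter residue code(s): ",
         paste(bad, collapse = ""))
  unname(.AA1TO3[toupper(letters1)])
}

#' Parse a cstfile
#'
#' Reads the block-structured geometric-constraint dialect: records
#' `TEMPLATE:: ATOM_MAP:` and `CONSTRAINT::` between `CST::BEGIN` /
#' `CST::END`. `residue1` strings expand per-letter (e.g. "ED" allows Asp
#' and Glu); a missing optional 5th parameter column means 0 samples; lines
#' starting with '#' are comments.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @return a `theozyme` (unvalidated; see [validate_theozyme()]).
#' @export
parse_cstfile <- function(text) {
  if (length(text) == 1 && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  blocks <- list()
  in_block <- FALSE
  cur <- NULL
  ligand_name <- NA_character_
  begin_line <- NA
  for (ln in seq_along(text)) {
    line <- sub("#.*$", "", text[ln])
    if (!nzchar(trimws(line))) next
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    toks <- sub(",$", "", toks)
    if (toks[1] == "CST::BEGIN") {
      if (in_block) stop("cstfile line ", ln, ": CST::BEGIN inside an open block")
      in_block <- TRUE; begin_line <- ln
      cur <- list(maps = list(`1` = list(), `2` = list()), params = list())
      next
    }
    if (toks[1] == "CST::END") {
      if (!in_block) stop("cstfile line ", ln, ": CST::END without CST::BEGIN")
      blocks[[length(blocks) + 1]] <- .finish_block(cur, begin_line)
      in_block <- FALSE; cur <- NULL
      next
    }
    if (!in_block)
      stop("cstfile line ", ln, ": record outside CST::BEGIN/CST::END block")
    if (toks[1] == "TEMPLATE::" && toks[2] == "ATOM_MAP:") {
      which <- suppressWarnings(as.integer(toks[3]))
      if (is.na(which) || !which %in% 1:2)
        stop("cstfile line ", ln, ": ATOM_MAP partner index must be 1 or 2")
      tag <- sub(":$", "", toks[4])
      val <- toks[-(1:4)]
      w <- as.character(which)
      if (tag == "atom_name") {
        if (length(val) != 3) stop("cstfile line ", ln, ": atom_name needs 3 atom names")
        if (!is.null(cur$maps[[w]]$type_symbol))
          stop("cstfile line ", ln, ": both atom_name and atom_type given for partner ", w)
        cur$maps[[w]]$names <- val
      } else if (tag == "atom_type") {
        if (length(val) != 1) stop("cstfile line ", ln, ": atom_type needs 1 type symbol")
        if (!is.null(cur$maps[[w]]$names))
          stop("cstfile line ", ln, ": both atom_name and atom_type given for partner ", w)
        cur$maps[[w]]$type_symbol <- val
      } else if (tag == "residue3") {
        cur$maps[[w]]$allowed <- val
        cur$maps[[w]]$tag <- "residue3"
        if (!all(val %in% .AA3) && is.na(ligand_name)) ligand_name <- val[1]
      } else if (tag == "residue1") {
        cur$maps[[w]]$allowed <- .expand_residue1(paste(val, collapse = ""), ln)
        cur$maps[[w]]$tag <- "residue1"
      } else stop("cstfile line ", ln, ": unknown ATOM_MAP tag: ", tag)
      next
    }
    if (toks[1] == "CONSTRAINT::") {
      pname <- sub(":$", "", toks[2])
      if (!pname %in% .PARAM_NAMES)
        stop("cstfile line ", ln, ": unknown constraint parameter: ", pname)
      nums <- suppressWarnings(as.numeric(toks[-(1:2)]))
      if (length(nums) < 4 || length(nums) > 5)
        stop("cstfile line ", ln, ": constraint records take 4 or 5 numeric columns")
      if (anyNA(nums))
        stop("cstfile line ", ln, ": non-numeric constraint column")
      n_samp <- if (length(nums) == 5) nums[5] else 0
      cur$params[[length(cur$params) + 1]] <-
        tryCatch(cst_param(pname, nums[1], nums[2], nums[3], nums[4], n_samp),
                 error = function(e) stop("cstfile line ", ln, ": ", conditionMessage(e)))
      next
    }
    stop("cstfile line ", ln, ": unrecognized record: ", toks[1])
  }
  if (in_block)
    stop("cstfile: block opened at line ", begin_line, " has no CST::END")
  theozyme(blocks, ligand_name)
}

.finish_block <- function(cur, begin_line) {
  mk <- function(w) {
    m <- cur$maps[[as.character(w)]]
    if (is.null(m$allowed))
      stop("cstfile: block at line ", begin_line,
           ": ATOM_MAP ", w, " lacks a residue declaration")
    if (is.null(m$names) && is.null(m$type_symbol))
      stop("cstfile: block at line ", begin_line,
           ": ATOM_MAP ", w, " lacks atom_name or atom_type")
    atom_map_spec(w, mode = if (is.null(m$names)) "by_type" else "by_name",
                  names = m$names, type_symbol = m$type_symbol,
                  allowed_residues = m$allowed, residue_tag = m$tag)
  }
  cst_block(mk(1), mk(2), cur$params)
}

#' Read a cstfile from disk
#' @param path file path.
#' @return a `theozyme`.
#' @export
read_cstfile <- function(path) parse_cstfile(readLines(path, warn = FALSE))

.fmt_num <- function(x) {
  vapply(x, function(v) {
    if (v == 0) return("0.0")
    s <- formatC(v, format = "fg", digits = 8, flag = "#")
    sub("\\.$", ".0", sub("0+$", "", s))
  }, character(1))
}

#' Write a theozyme as a cstfile
#'
#' Emits the block dialect accepted by [parse_cstfile()]; the round trip
#' `parse_cstfile(write_cstfile(t))` reproduces the theozyme field for field
#' (the matcher algorithm assignment lives outside the file).
#'
#' @param theo a `theozyme`.
#' @param path optional output file.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
write_cstfile <- function(theo, path = NULL) {
  out <- character(0)
  for (b in theo$blocks) {
    out <- c(out, "CST::BEGIN")
    for (m in list(b$map1, b$map2)) {
      w <- m$which
      if (m$mode == "by_name") {
        out <- c(out, sprintf("  TEMPLATE::   ATOM_MAP: %d atom_name: %s",
                              w, paste(m$names, collapse = " ")))
      } else {
        out <- c(out, sprintf("  TEMPLATE::   ATOM_MAP: %d atom_type: %s",
                              w, m$type_symbol))
      }
      if (identical(m$residue_tag, "residue1")) {
        out <- c(out, sprintf("  TEMPLATE::   ATOM_MAP: %d residue1: %s", w,
                              paste(.AA3TO1[m$allowed_residues], collapse = "")))
      } else {
        out <- c(out, sprintf("  TEMPLATE::   ATOM_MAP: %d residue3: %s", w,
                              paste(m$allowed_residues, collapse = " ")))
      }
    }
    for (p in b$params) {
      out <- c(out, sprintf("  CONSTRAINT:: %s: %s %s %s %s %d",
                            p$name, .fmt_num(p$x0), .fmt_num(p$xtol),
                            .fmt_num(p$k), .fmt_num(p$fourth), p$n_samples))
    }
    out <- c(out, "CST::END")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Enumerate the matcher sample values of a constraint parameter
#'
#' For each periodic copy of x0 within one full 360-degree turn (angular
#' parameters; the single x0 for distanceAB), returns 2n+1 equally spaced
#' values spanning \[copy - xtol, copy + xtol\]. Copies are wrapped to
#' \[0, 360) and deduplicated.
#'
#' @param param a `cst_param`.
#' @return sorted numeric vector of sample values.
#' @export
enumerate_samples <- function(param) {
  n <- param$n_samples
  if (param$name == "distanceAB") {
    copies <- param$x0
  } else {
    per <- param$fourth
    if (per <= 0) stop("periodicity must be positive")
    m <- 0:ceiling(360 / per)
    copies <- sort(unique(round(.wrap360(param$x0 + m * per), 6)))
    # dedupe copies that wrap onto each other within 1e-6 degrees
    if (length(copies) > 1 && (copies[length(copies)] - copies[1]) %% 360 < 1e-6)
      copies <- copies[-length(copies)]
  }
  vals <- unlist(lapply(copies, function(cc) {
    if (n == 0) cc else seq(cc - param$xtol, cc + param$xtol, length.out = 2 * n + 1)
  }))
  sort(vals)
}

#' Number of ligand placements attempted per rotamer for a classic block
#'
#' The product over the six parameters of their sample counts.
#'
#' @param block a `cst_block` defining all six parameters.
#' @return integer placement count.
#' @export
placement_count <- function(block) {
  missing <- setdiff(.PARAM_NAMES, names(block$params))
  if (length(missing))
    stop("classic block lacks parameter(s): ", paste(missing, collapse = ", "))
  prod(vapply(block$params[.PARAM_NAMES],
              function(p) length(enumerate_samples(p)), numeric(1)))
}

#' Resolve an atom map to concrete atom-name triples on a topology
#'
#' In by_name mode the single given triple is returned. In by_type mode one
#' triple (atom, base atom, base of base) is returned for every atom of the
#' requested type; downstream scoring takes the minimum penalty over the
#' candidates.
#'
#' @param map an `atom_map_spec`.
#' @param topology either a ligand topology (from [read_ligand_params()]) or
#'   a 3-letter protein residue type.
#' @return list of character(3) triples (possibly empty in by_type mode when
#'   no atom matches).
#' @export
resolve_atom_triples <- function(map, topology) {
  if (inherits(topology, "enz_ligand")) {
    atom_names <- topology$atoms$name
    types <- setNames(topology$atoms$type, atom_names)
    parent <- topology$parent
  } else {
    restype <- toupper(topology)
    topo <- res_topology(restype)
    atom_names <- c("N", "CA", "C", "O", topo$name)
    types <- .res_atom_types(restype)
    parent <- .res_parent_map(restype)
  }
  if (map$mode == "by_name") {
    missing <- setdiff(map$names, atom_names)
    if (length(missing))
      stop("atom(s) not in topology: ", paste(missing, collapse = ", "))
    return(list(map$names))
  }
  hits <- atom_names[types[atom_names] == map$type_symbol]
  out <- list()
  for (a in hits) {
    p <- parent[[a]]
    if (is.null(p) || is.na(p)) stop("typed atom ", a, " has fewer than 2 ancestors")
    g <- parent[[p]]
    if (is.null(g) || is.na(g)) stop("typed atom ", a, " has fewer than 2 ancestors")
    out[[length(out) + 1]] <- c(a, p, g)
  }
  out
}

# which side of a block is the ligand (by allowed residue types); returns
# "map1", "map2" or NA for side-chain/side-chain blocks
.ligand_side <- function(block, ligand_name) {
  if (!is.na(ligand_name)) {
    if (ligand_name %in% block$map1$allowed_residues) return("map1")
    if (ligand_name %in% block$map2$allowed_residues) return("map2")
  }
  if (!all(block$map1$allowed_residues %in% .AA3)) return("map1")
  if (!all(block$map2$allowed_residues %in% .AA3)) return("map2")
  NA_character_
}
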