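# Stage 4 - per-design metrics, the scorefile, and cutoff-based filtering.
# Metrics are geometric and invariant under rigid motion: hydrogen-bond
# counts, buried unsatisfied polar atoms, non-local contacts, a packing
# proxy in [0,1], and the protein-ligand interface score.

# heavy-atom table of a structure with ids and polarity
.heavy_table <- function(s, with_ligand = TRUE) {
  a <- s$atoms
  keep <- a$element != "H" & (with_ligand | !a$het)
  rows <- which(keep)
  pr <- .atom_props(s, rows)
  list(rows = rows, xyz = pr$xyz, rad = pr$rad, don = pr$don, acc = pr$acc,
       base = pr$base, resid = ifelse(a$het[rows], 0L, a$resi[rows]),
       het = a$het[rows])
}

# logical matrix of qualifying donor->acceptor geometries
.hbond_pairs <- function(ht, dist_max = 3.3, angle_min = 120) {
  nd <- which(ht$don); na_ <- which(ht$acc)
  out <- matrix(FALSE, length(ht$don), length(ht$don))
  if (!length(nd) || !length(na_)) return(out)
  for (i in nd) {
    dv <- sqrt(colSums((t(ht$xyz[na_, , drop = FALSE]) - ht$xyz[i, ])^2))
    cand <- na_[dv <= dist_max & ht$resid[na_] != ht$resid[i]]
    for (j in cand) {
      if (j == i) next
      # donors with no resolvable base atom pass on distance alone
      ang <- if (sum((ht$base[i, ] - ht$xyz[i, ])^2) < 1e-12) 180
             else angle_deg(ht$base[i, ], ht$xyz[i, ], ht$xyz[j, ])
      if (ang >= angle_min) out[i, j] <- TRUE
    }
  }
  out
}

#' Count hydrogen bonds
#'
#' Geometric criterion: donor and acceptor heavy atoms within 3.3 Angstrom
#' with the angle at the donor (through its base atom) at least 120
#' degrees. Each atom pair counts once.
#'
#' @param s structure.
#' @param dist_max,angle_min criterion thresholds.
#' @return list with `total` and `catalytic` (bonds involving catalytic
#'   residues or the ligand).
#' @export
count_hbonds <- function(s, dist_max = 3.3, angle_min = 120) {
  ht <- .heavy_table(s)
  hb <- .hbond_pairs(ht, dist_max, angle_min)
  pair <- hb | t(hb)
  idx <- which(pair & upper.tri(pair), arr.ind = TRUE)
  catal <- catalytic_residues(s)$resi
  is_cat <- ht$resid %in% c(catal, 0L)
  list(total = nrow(idx),
       catalytic = sum(is_cat[idx[, 1]] | is_cat[idx[, 2]]))
}

#' Count buried unsatisfied polar atoms
#'
#' A polar (donor or acceptor) heavy atom is buried when it has at least
#' `burial_neighbors` heavy-atom neighbors within `shell` Angstrom; it is
#' counted when buried and forming no hydrogen bond under the
#' [count_hbonds()] criterion.
#'
#' @param s structure.
#' @param burial_neighbors neighbor-count burial threshold.
#' @param shell neighbor shell radius (Angstrom).
#' @return integer count.
#' @export
count_buried_unsat <- function(s, burial_neighbors = 12, shell = 5.2) {
  ht <- .heavy_table(s)
  hb <- .hbond_pairs(ht)
  sat <- apply(hb | t(hb), 1, any)
  d2 <- as.matrix(dist(ht$xyz))^2
  nn <- rowSums(d2 <= shell^2) - 1L
  polar <- ht$don | ht$acc
  sum(polar & nn >= burial_neighbors & !sat)
}

#' Count non-local residue contacts
#'
#' Residue pairs at least `min_sep` apart in sequence with any heavy-atom
#' pair within `dist` Angstrom, counted once per pair.
#'
#' @param s structure.
#' @param min_sep minimum sequence separation.
#' @param dist contact distance (Angstrom).
#' @param subset optional residue indices; only pairs involving the subset
#'   are counted.
#' @return integer count.
#' @export
count_nonlocal_contacts <- function(s, min_sep = 6, dist = 4.5, subset = NULL) {
  rt <- res_table(s)
  rows <- lapply(rt$resi, function(r) {
    m <- res_atoms(s, r)
    m[.element_from_name(rownames(m)) != "H", , drop = FALSE]
  })
  n <- nrow(rt)
  cnt <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(rt$resi[j] - rt$resi[i]) < min_sep) next
    if (!is.null(subset) && !(rt$resi[i] %in% subset || rt$resi[j] %in% subset)) next
    A <- rows[[i]]; B <- rows[[j]]
    dmin2 <- min(vapply(seq_len(nrow(A)), function(k)
      min(colSums((t(B) - A[k, ])^2)), numeric(1)))
    if (dmin2 <= dist^2) cnt <- cnt + 1L
  }
  cnt
}

#' Packing proxy in \[0, 1\]
#'
#' For every buried heavy atom (at least `burial_neighbors` neighbors
#' within `shell`), the occupied fraction of its neighbor shell is the
#' summed volume of neighbor atoms over the shell volume (capped at 1);
#' the metric is the mean over buried atoms (0 when nothing is buried).
#' Reported as `tot_pstat_pm` and, with the ligand removed,
#' `total_nlpstat_pm`.
#'
#' @param s structure.
#' @param with_ligand include the ligand's atoms.
#' @param burial_neighbors,shell burial definition.
#' @return numeric in \[0, 1\].
#' @export
packing_metric <- function(s, with_ligand = TRUE, burial_neighbors = 12,
                           shell = 5.2) {
  ht <- .heavy_table(s, with_ligand = with_ligand)
  n <- nrow(ht$xyz)
  if (n < 2) return(0)
  d2 <- as.matrix(dist(ht$xyz))^2
  nbr <- d2 <= shell^2
  diag(nbr) <- FALSE
  buried <- rowSums(nbr) >= burial_neighbors
  if (!any(buried)) return(0)
  vol <- (4 / 3) * pi * ht$rad^3
  occ <- vapply(which(buried), function(i) {
    vshell <- (4 / 3) * pi * (shell^3 - ht$rad[i]^3)
    min(1, sum(vol[nbr[i, ]]) / vshell)
  }, numeric(1))
  mean(occ)
}

#' Compute the full metric vector of a design
#'
#' @param s designed structure (ligand + catalytic annotations + topology).
#' @param theo theozyme.
#' @param em energy model.
#' @param id design identifier for the scorefile.
#' @param apo_rmsd optional named per-catalytic-residue repack RMSDs (from
#'   [repack_without_ligand()]).
#' @return one-row data.frame (a score record); restraint totals satisfy
#'   `all_cst == sum(SR columns)` and `total_score` excludes `all_cst`.
#' @export
score_design <- function(s, theo, em = energy_model(), id = "design",
                         apo_rmsd = NULL) {
  sc <- score_structure(s, theo, em)
  hb <- count_hbonds(s)
  catal <- catalytic_residues(s)
  rec <- data.frame(description = id,
                    total_score = sc$total,
                    fa_rep = sc$fa_rep,
                    hbond_sc = sc$hbond_sc,
                    all_cst = sc$all_cst)
  for (nm in names(sc$sr)) rec[[nm]] <- sc$sr[[nm]]
  rec$lig_score <- interface_score(s, em, theo)
  rec$tot_pstat_pm <- packing_metric(s, with_ligand = TRUE)
  rec$total_nlpstat_pm <- packing_metric(s, with_ligand = FALSE)
  rec$tot_burunsat_pm <- count_buried_unsat(s)
  rec$tot_nlcontacts_pm <- count_nonlocal_contacts(s)
  rec$cat_nlcontacts_pm <- count_nonlocal_contacts(s, subset = catal$resi)
  rec$hbond_pm <- hb$total
  rec$cat_hbond_pm <- hb$catalytic
  if (!is.null(apo_rmsd))
    for (nm in names(apo_rmsd)) rec[[paste0(nm, "_rmsd")]] <- apo_rmsd[[nm]]
  rec
}

#' Write a scorefile
#'
#' Whitespace-delimited table, one header line and one line per design.
#'
#' @param records data.frame of score records (rows share columns).
#' @param path output file.
#' @export
write_scorefile <- function(records, path) {
  write.table(format(records, digits = 6), path, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a scorefile written by [write_scorefile()]
#' @param path scorefile path.
#' @return data.frame.
#' @export
read_scorefile <- function(path) {
  read.table(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Cutoff specifications for design selection
#'
#' @param metric score-record column names.
#' @param cmp "<" or ">" per metric.
#' @param threshold numeric thresholds.
#' @return data.frame cutoff table.
#' @export
cutoff_spec <- function(metric, cmp, threshold) {
  stopifnot(all(cmp %in% c("<", ">")), length(metric) == length(cmp),
            length(cmp) == length(threshold))
  data.frame(metric = metric, cmp = cmp, threshold = threshold)
}

#' Read a cutoff file (lines of `metric < value` / `metric > value`)
#' @param path cutoff file.
#' @export
read_cutoff_file <- function(path) {
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- trimws(lines[nzchar(trimws(lines))])
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- vapply(parts, length, integer(1)) != 3
  if (any(bad)) stop("malformed cutoff line: ", lines[bad][1])
  cutoff_spec(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2),
              as.numeric(vapply(parts, `[`, "", 3)))
}

#' Default selection cutoffs
#'
#' Absolute-scale defaults for the restraint, burial and score metrics
#' (scaffold-relative comparisons, where wanted, should be computed as
#' differences to a reference record before filtering).
#'
#' @return cutoff data.frame.
#' @export
default_cutoffs <- function() {
  cutoff_spec(c("all_cst", "SR1", "SR2", "SR3", "total_score", "tot_burunsat_pm"),
              rep("<", 6), c(6.5, 1.2, 1.0, 2.3, 0, 5))
}

#' Filter score records by cutoffs
#'
#' A record passes when every cutoff holds; per-cutoff pass counts are
#' reported alongside. An empty cutoff table passes everything.
#'
#' @param records score-record data.frame.
#' @param cutoffs cutoff data.frame (see [cutoff_spec()]).
#' @return list with `passing` (subset of records) and `counts` (named
#'   per-cutoff pass counts).
#' @export
filter_designs <- function(records, cutoffs) {
  if (!nrow(records)) return(list(passing = records, counts = integer(0)))
  if (is.null(cutoffs) || nrow(cutoffs) == 0)
    return(list(passing = records, counts = integer(0)))
  missing <- setdiff(cutoffs$metric, names(records))
  if (length(missing)) stop("unknown metric(s): ", paste(missing, collapse = ", "))
  pass <- matrix(FALSE, nrow(records), nrow(cutoffs))
  for (k in seq_len(nrow(cutoffs))) {
    v <- records[[cutoffs$metric[k]]]
    pass[, k] <- if (cutoffs$cmp[k] == "<") v < cutoffs$threshold[k]
                 else v > cutoffs$threshold[k]
  }
  counts <- setNames(colSums(pass),
                     paste(cutoffs$metric, cutoffs$cmp, cutoffs$threshold))
  list(passing = records[rowSums(pass) == nrow(cutoffs), , drop = FALSE],
       counts = counts)
}

#' Score a reference structure under the design conditions
#'
#' Repacks and minimizes the given (e.g. native or planted) structure with
#' the same restraints used for the designs, then computes the full metric
#' suite including the apo-repack RMSDs - the benchmark records against
#' which designs are compared.
#'
#' @param s reference structure with catalytic annotations and ligand.
#' @param theo theozyme.
#' @param cfg design configuration.
#' @param em energy model.
#' @return one-row score record.
#' @export
score_reference <- function(s, theo, cfg = design_config(), em = energy_model()) {
  catal <- catalytic_residues(s)
  if (!all(seq_along(theo$blocks) %in% catal$block))
    stop("structure lacks catalytic annotations for some theozyme blocks")
  task <- detect_design_shell(s, cfg)
  s <- pack_rotamers(s, task, theo, cfg, em, fixed_identity = TRUE)
  if (cfg$cst_min) s <- .minimize(s, theo, em, cfg)
  apo <- repack_without_ligand(s, task, theo, cfg, em)
  score_design(s, theo, em, id = "reference", apo_rmsd = apo$rmsd)
}
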