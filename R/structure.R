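## Compactness metrics from coordinate files: PDB import (via bio3d) and
## the radius of gyration over protein atoms.

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

.mass_table <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                 S = 32.06, P = 30.974, SE = 78.971)

.atomic_mass <- function(element) {
  m <- .mass_table[toupper(element)]
  names(m) <- NULL
  m
}

#' Load an atom set from a PDB file
#'
#' Reads one model of a PDB-format coordinate file (parsing by
#' `bio3d::read.pdb`), resolves alternate locations, assigns element
#' masses, and flags protein atoms (ATOM records of the 20 standard amino
#' acids). For NMR bundles, `model` selects the conformer.
#'
#' @param path PDB file.
#' @param model model number (default 1).
#' @param altloc policy for alternate locations: `"occupancy"` keeps the
#'   highest-occupancy location per atom site (ties: first), `"first"`
#'   keeps the first encountered, `"all"` keeps everything.
#' @return an `atom_set` data.frame: `element`, `name`, `resno`, `aa`,
#'   `chain`, `x`, `y`, `z`, `occupancy`, `mass`, `is_protein`.
#' @export
load_structure <- function(path, model = 1,
                           altloc = c("occupancy", "first", "all")) {
  altloc <- match.arg(altloc)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  n_model <- nrow(pdb$xyz)
  if (model > n_model) {
    stop("model ", model, " requested but file has ", n_model)
  }
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  if (altloc != "all" && any(nzchar(at$alt) & !is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    keep <- logical(nrow(at))
    occ <- ifelse(is.finite(at$o), at$o, 1)
    for (g in split(seq_len(nrow(at)), key)) {
      keep[if (altloc == "occupancy") g[which.max(occ[g])] else g[1]] <- TRUE
    }
    at <- at[keep, ]
  }

  element <- at$elesy
  bad <- is.na(element) | !nzchar(trimws(element))
  if (any(bad)) element[bad] <- bio3d::atom2ele(at$elety[bad])
  element <- trimws(element)
  mass <- .atomic_mass(element)
  if (anyNA(mass)) {
    warning("unknown element(s): ",
            paste(unique(element[is.na(mass)]), collapse = ", "),
            "; affected atoms get NA mass")
  }
  out <- data.frame(element = element, name = at$elety, resno = at$resno,
                    aa = at$resid, chain = at$chain,
                    x = at$x, y = at$y, z = at$z,
                    occupancy = ifelse(is.finite(at$o), at$o, 1),
                    mass = mass,
                    is_protein = at$type == "ATOM" & at$resid %in% .standard_aa,
                    stringsAsFactors = FALSE)
  class(out) <- c("atom_set", "data.frame")
  out
}

#' Radius of gyration
#'
#' `Rg = sqrt(sum_i w_i |r_i - rbar|^2 / sum_i w_i)` with `w_i` the atomic
#' mass (or 1 when unweighted) and `rbar` the weighted centroid. With
#' `protein_only = TRUE` (default) heteroatoms, waters and ligands are
#' excluded; hydrogens, when present, are included. Rg is invariant under
#' rigid rotation and translation.
#'
#' @param atoms an `atom_set` (from [load_structure()] or
#'   [gen_globular_atoms()]), or any data.frame with `x`, `y`, `z` and
#'   optionally `mass`, `is_protein`.
#' @param mass_weighted weight by atomic mass (default) or uniformly.
#' @param protein_only restrict to protein atoms (default TRUE).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(atoms, mass_weighted = TRUE,
                               protein_only = TRUE) {
  a <- atoms
  if (protein_only && !is.null(a$is_protein)) a <- a[a$is_protein, ]
  if (nrow(a) == 0) stop("no atoms left after protein filtering")
  if (nrow(a) < 2) stop("at least 2 atoms are required")
  w <- if (mass_weighted) {
    if (is.null(a$mass) || anyNA(a$mass)) {
      stop("mass weighting requested but masses are missing")
    }
    a$mass
  } else rep(1, nrow(a))
  cx <- sum(w * a$x) / sum(w)
  cy <- sum(w * a$y) / sum(w)
  cz <- sum(w * a$z) / sum(w)
  sqrt(sum(w * ((a$x - cx)^2 + (a$y - cy)^2 + (a$z - cz)^2)) / sum(w))
}

#' Radius-of-gyration report for one or more PDB files
#'
#' Computes mass-weighted and unweighted Rg for every model of every file.
#'
#' @param paths PDB file paths.
#' @return data.frame (`file`, `model`, `n_atoms`, `rg_mass`,
#'   `rg_unweighted`).
#' @export
rg_report <- function(paths) {
  rows <- list()
  for (p in paths) {
    pdb <- bio3d::read.pdb(p, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    for (m in seq_len(nrow(pdb$xyz))) {
      a <- load_structure(p, model = m)
      rows[[length(rows) + 1]] <- data.frame(
        file = basename(p), model = m, n_atoms = sum(a$is_protein),
        rg_mass = radius_of_gyration(a, TRUE),
        rg_unweighted = radius_of_gyration(a, FALSE))
    }
  }
  do.call(rbind, rows)
}
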