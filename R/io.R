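# ---------------------------------------------------------------------------
# File formats. SDF parsing goes through ChemmineR, SMILES embedding through
# ChemmineOB (OpenBabel), PDB through bio3d; the V2000 writer is a plain
# formatter. All three heavy dependencies are Suggests: only the functions
# that need them require them.
# ---------------------------------------------------------------------------

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    abort_pharm(sprintf("package '%s' is required for this operation", pkg),
                "missing_dependency")
}

# SDF charge field codes (V2000 atom block column 6)
SDF_CHARGE <- c("0" = 0L, "1" = 3L, "2" = 2L, "3" = 1L, "5" = -1L,
                "6" = -2L, "7" = -3L)

#' Read a (multi-record) SDF file into molecules
#'
#' @param path SDF file path.
#' @return list of `molecule3d`.
#' @export
read_sdf <- function(path) {
  need_pkg("ChemmineR")
  sdfset <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdfset)
  lapply(seq_along(sdfset), function(k) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elem <- sub("_[0-9]+$", "", rownames(ab))
    atoms <- data.frame(elem = elem, x = ab[, 1], y = ab[, 2], z = ab[, 3])
    if (ncol(ab) >= 5) {
      chg <- SDF_CHARGE[as.character(ab[, 5])]
      chg[is.na(chg)] <- 0L
      atoms$charge <- as.integer(chg)
    }
    bonds <- if (!is.null(bb) && nrow(bb))
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    else NULL
    # M CHG property lines override the atom-block field
    hdr <- ChemmineR::header(sdf)
    id <- if (length(ids) >= k && nzchar(ids[k])) ids[k] else
      (hdr[["Molecule_Name"]] %||% paste0("mol", k))
    molecule3d(id, atoms, bonds)
  })
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols a `molecule3d` or list of them.
#' @param path output path.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule3d")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  inv_chg <- c("3" = 1L, "2" = 2L, "1" = 3L, "-1" = 5L, "-2" = 6L, "-3" = 7L)
  for (mol in mols) {
    writeLines(c(mol$id, "  pharmscreen", ""), con)
    na <- n_atoms(mol); nb <- nrow(mol$bonds)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb), con)
    for (i in seq_len(na)) {
      chg <- inv_chg[as.character(mol$atoms$charge[i])]
      if (is.na(chg)) chg <- 0L
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                         mol$atoms$x[i], mol$atoms$y[i], mol$atoms$z[i],
                         mol$atoms$elem[i], chg), con)
    }
    if (nb) for (k in seq_len(nb))
      writeLines(sprintf("%3d%3d%3d  0", mol$bonds$i[k], mol$bonds$j[k],
                         min(mol$bonds$order[k], 4L)), con)
    chgd <- which(mol$atoms$charge != 0L)
    if (length(chgd))
      writeLines(paste0("M  CHG", sprintf("%3d", length(chgd)),
                        paste0(sprintf("%4d%4d", chgd, mol$atoms$charge[chgd]),
                               collapse = "")), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read SMILES strings and embed 3D coordinates
#'
#' Uses OpenBabel (through ChemmineOB) to add hydrogens and generate a 3D
#' conformer; pass-through of provided conformers in SDF is preferred when
#' geometry matters.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional identifiers (defaults to the SMILES strings).
#' @return list of `molecule3d`.
#' @export
read_smiles <- function(smiles, ids = smiles) {
  need_pkg("ChemmineOB")
  stopifnot(length(smiles) == length(ids))
  out <- vector("list", length(smiles))
  for (k in seq_along(smiles)) {
    sdf_txt <- ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles[k], "\n"),
      options = data.frame(names = "gen3d", args = ""))
    tf <- tempfile(fileext = ".sdf")
    writeLines(sdf_txt, tf)
    mol <- read_sdf(tf)[[1]]
    unlink(tf)
    mol$id <- ids[k]
    out[[k]] <- mol
  }
  out
}

# covalent radii (Angstrom) for distance-based bond inference on PDB input
COVALENT_RADIUS <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, Na = 1.66, Mg = 1.41, Si = 1.11, P = 1.07,
                     S = 1.05, Cl = 1.02, K = 2.03, Ca = 1.76, Se = 1.20,
                     Br = 1.20, I = 1.39)

#' Infer bonds from interatomic distances
#'
#' Pairs closer than the sum of covalent radii plus `slack` are bonded
#' (order 1). Intended for PDB-derived structures without CONECT records.
#'
#' @param mol a `molecule3d` without (complete) bonds.
#' @param slack additive tolerance in Angstrom (default 0.45).
#' @return `molecule3d` with inferred bonds.
#' @export
infer_bonds <- function(mol, slack = 0.45) {
  xyz <- mol_xyz(mol)
  n <- n_atoms(mol)
  rad <- COVALENT_RADIUS[mol$atoms$elem]
  rad[is.na(rad)] <- 0.9
  d <- coord_dist(xyz)
  thr <- outer(rad, rad, "+") + slack
  sel <- which(d > 1e-6 & d <= thr & upper.tri(d), arr.ind = TRUE)
  bonds <- if (nrow(sel)) data.frame(i = sel[, 1], j = sel[, 2], order = 1L)
           else NULL
  molecule3d(mol$id, mol$atoms, bonds, mol$partial_charges,
             perceive_aromaticity = FALSE)
}

#' Read a receptor-ligand complex from a PDB file
#'
#' The receptor is the protein (ATOM records); the ligand is selected among
#' HETATM records by residue name. Bonds are inferred by covalent distance.
#'
#' @param path PDB file.
#' @param ligand_resname HETATM residue name of the ligand.
#' @return list with elements `receptor` and `ligand` (both `molecule3d`).
#' @export
read_pdb_complex <- function(path, ligand_resname) {
  need_pkg("bio3d")
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem_of <- function(rows) {
    e <- at$elesy[rows]
    miss <- is.na(e) | !nzchar(e)
    e[miss] <- substr(gsub("[0-9']", "", at$elety[rows][miss]), 1, 1)
    e <- paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, 10)))
    e
  }
  mk <- function(rows, id) {
    if (!length(rows)) abort_pharm(sprintf("no atoms for %s", id), "invalid_input")
    atoms <- data.frame(elem = elem_of(rows),
                        x = at$x[rows], y = at$y[rows], z = at$z[rows],
                        charge = 0L, aromatic = FALSE,
                        resid = at$resno[rows], resname = at$resid[rows])
    infer_bonds(molecule3d(id, atoms, NULL, perceive_aromaticity = FALSE))
  }
  prot_rows <- which(at$type == "ATOM")
  lig_rows <- which(at$type == "HETATM" & at$resid == ligand_resname)
  list(receptor = mk(prot_rows, "receptor"),
       ligand = mk(lig_rows, ligand_resname))
}
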