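#' Construct a 3D molecule
#'
#' The basic container for small molecules and receptor structures: an atom
#' table (element, coordinates in Angstrom, formal charge, aromatic flag,
#' optional residue labels), a bond table (atom index pair, order), and
#' optional per-atom partial charges in units of the elementary charge.
#'
#' @param id character identifier.
#' @param atoms data.frame with columns `elem`, `x`, `y`, `z` and optionally
#'   `charge` (formal, integer), `aromatic` (logical), `resid` (integer
#'   residue index), `resname` (character). Missing optional columns are
#'   filled with defaults.
#' @param bonds data.frame with columns `i`, `j`, `order` (1, 2, 3; 4 is
#'   accepted as an aromatic-bond marker). May have zero rows.
#' @param partial_charges optional numeric vector, one value per atom, in e.
#' @param perceive_aromaticity when TRUE (default) and no atom is flagged
#'   aromatic, rings of alternating single/double bonds (and 5-rings with one
#'   lone-pair heteroatom) are marked aromatic from the Kekule structure.
#' @return an object of class `molecule3d`.
#' @export
molecule3d <- function(id, atoms, bonds = NULL, partial_charges = NULL,
                       perceive_aromaticity = TRUE) {
  stopifnot(is.character(id), length(id) == 1L)
  atoms <- as.data.frame(atoms)
  need <- c("elem", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    abort_pharm("atoms must have columns elem, x, y, z", "invalid_molecule")
  n <- nrow(atoms)
  if (n < 1L) abort_pharm("molecule needs at least one atom", "invalid_molecule")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  if (!all(is.finite(xyz)))
    abort_pharm("all coordinates must be finite", "invalid_molecule")
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$resid)) atoms$resid <- NA_integer_
  if (is.null(atoms$resname)) atoms$resname <- NA_character_
  atoms$elem <- as.character(atoms$elem)

  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(),
                                          order = integer())
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    if (!all(c("i", "j") %in% names(bonds)))
      abort_pharm("bonds must have columns i, j", "invalid_molecule")
    if (is.null(bonds$order)) bonds$order <- 1L
    ij <- cbind(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (any(ij < 1L) || any(ij > n) || any(ij[, 1] == ij[, 2]))
      abort_pharm("bond indices must reference distinct existing atoms",
                  "invalid_molecule")
    if (anyDuplicated(ij))
      abort_pharm("duplicate bonds are not allowed", "invalid_molecule")
    bonds$i <- ij[, 1]; bonds$j <- ij[, 2]
  }

  mol <- structure(list(id = id, atoms = atoms, bonds = bonds,
                        partial_charges = partial_charges),
                   class = "molecule3d")
  if (perceive_aromaticity && !any(atoms$aromatic))
    mol <- perceive_aromatic_rings(mol)
  mol <- annotate_graph(mol)
  mol
}

#' @export
print.molecule3d <- function(x, ...) {
  cat(sprintf("<molecule3d> %s: %d atoms (%d heavy), %d bonds\n",
              x$id, nrow(x$atoms), sum(x$atoms$elem != "H"), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

mol_xyz <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  storage.mode(m) <- "double"
  m
}

# adjacency list + derived per-atom properties used by the matcher
annotate_graph <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  bord <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
      bord[[i]] <- c(bord[[i]], o); bord[[j]] <- c(bord[[j]], o)
    }
  }
  elem <- mol$atoms$elem
  nH <- vapply(seq_len(n), function(i) sum(elem[adj[[i]]] == "H"), integer(1))
  mol$graph <- list(adj = adj, bond_order = bord, nH = nH,
                    degree = lengths(adj))
  mol
}

mol_rings <- function(mol, max_size = 8L) {
  ring_basis(mol$graph$adj, n_atoms(mol), max_size)
}

# Minimum-cycle-basis style ring perception: for every bond, the smallest
# ring through it (BFS on the graph with that bond removed), deduplicated.
# Equivalent to SSSR for the fused systems met in drug-like molecules.
ring_basis <- function(adj, n, max_size = 8L) {
  rings <- list()
  seen <- character()
  for (i in seq_len(n)) for (j in adj[[i]]) {
    if (j <= i) next
    # shortest path i -> j avoiding the direct edge
    prev <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[i] <- 0L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(dist[j]) && dist[v] >= dist[j]) break
      for (w in adj[[v]]) {
        if (v == i && w == j) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L; prev[w] <- v; queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[j]) || dist[j] + 1L > max_size) next
    path <- j
    while (path[1] != i) path <- c(prev[path[1]], path)
    key <- paste(sort(path), collapse = "-")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- path }
  }
  rings
}

# Kekule-based aromaticity: a ring is aromatic when (a) every ring bond is
# marked order 4, or (b) the ring has 5 or 6 members and every ring atom
# either carries a double bond to a ring neighbour or is a lone-pair donor
# heteroatom (N, O, S with only single ring bonds). A deliberately simple
# model, documented in the methods vignette; flags supplied on input win.
perceive_aromatic_rings <- function(mol) {
  mol <- annotate_graph(mol)
  if (!nrow(mol$bonds)) return(mol)
  rings <- mol_rings(mol, max_size = 7L)
  if (!length(rings)) return(mol)
  bkey <- paste(mol$bonds$i, mol$bonds$j)
  border <- mol$bonds$order
  bond_order_of <- function(a, b) border[match(paste(min(a, b), max(a, b)), bkey)]
  arom_atoms <- rep(FALSE, n_atoms(mol))
  arom_bonds <- rep(FALSE, nrow(mol$bonds))
  for (r in rings) {
    k <- length(r)
    if (k < 5L || k > 6L) next
    nxt <- c(r[-1], r[1])
    ords <- mapply(bond_order_of, r, nxt)
    ok <- if (all(ords == 4L)) TRUE else {
      elem <- mol$atoms$elem[r]
      per_atom_ok <- vapply(seq_len(k), function(t) {
        o_in <- ords[if (t == 1L) k else t - 1L]; o_out <- ords[t]
        if (o_in == 2L || o_out == 2L) return(TRUE)
        elem[t] %in% c("N", "O", "S") && o_in == 1L && o_out == 1L
      }, logical(1))
      n_pi <- sum(ords == 2L) * 2L +
        sum(elem %in% c("N", "O", "S") &
              !vapply(seq_len(k), function(t) {
                o_in <- ords[if (t == 1L) k else t - 1L]
                o_in == 2L || ords[t] == 2L
              }, logical(1))) * 2L
      all(per_atom_ok) && (n_pi %% 4L) == 2L   # Hueckel 4n+2 on ring atoms
    }
    if (ok) {
      arom_atoms[r] <- TRUE
      arom_bonds[match(paste(pmin(r, nxt), pmax(r, nxt)), bkey)] <- TRUE
    }
  }
  mol$atoms$aromatic <- mol$atoms$aromatic | arom_atoms
  mol$bonds$aromatic <- arom_bonds
  mol
}

bond_is_aromatic <- function(mol, i, j) {
  if (!nrow(mol$bonds)) return(FALSE)
  ar <- mol$bonds$aromatic
  if (is.null(ar)) ar <- mol$bonds$order == 4L
  k <- match(paste(min(i, j), max(i, j)), paste(mol$bonds$i, mol$bonds$j))
  !is.na(k) && isTRUE(ar[k] | mol$bonds$order[k] == 4L)
}

# standard atomic weights (IUPAC 2021, abridged)
ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Na = 22.990, Mg = 24.305, Si = 28.085,
                 P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
                 Ca = 40.078, Se = 78.971, Br = 79.904, I = 126.904)

# default valences used when adding missing hydrogens
DEFAULT_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                     F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L)

#' Add missing hydrogens with idealized geometry
#'
#' Feature perception operates on explicit-hydrogen structures (donor
#' detection needs the H). Heavy atoms whose bond-order sum falls short of
#' the default valence receive hydrogens at a standard 1.0 Angstrom bond
#' length, placed opposite the mean direction of existing bonds (or along a
#' fixed axis for isolated atoms). Positions are idealized, not minimized.
#'
#' @param mol a `molecule3d`.
#' @return a `molecule3d` with explicit hydrogens.
#' @export
add_hydrogens <- function(mol) {
  elem <- mol$atoms$elem
  xyz <- mol_xyz(mol)
  new_atoms <- mol$atoms
  new_bonds <- mol$bonds
  n0 <- nrow(new_atoms)
  for (i in seq_len(n0)) {
    e <- elem[i]
    if (e == "H" || !(e %in% names(DEFAULT_VALENCE))) next
    val <- DEFAULT_VALENCE[[e]]
    bo <- unlist(mol$graph$bond_order[[i]])
    if (length(bo)) bo[bo == 4L] <- 1.5       # aromatic marker counts 1.5
    used <- if (length(bo)) sum(bo) else 0
    miss <- val - used
    if (e == "N" && mol$atoms$charge[i] > 0) miss <- miss + 1
    if (e == "O" && mol$atoms$charge[i] < 0) miss <- miss - 1
    miss <- max(0L, round(miss))
    if (miss == 0L) next
    nb <- mol$graph$adj[[i]]
    base <- xyz[i, ]
    dir0 <- if (length(nb)) {
      d <- -colSums(matrix(xyz[nb, ] - matrix(base, length(nb), 3, byrow = TRUE),
                           ncol = 3))
      if (vnorm(d) < 1e-8) c(0, 0, 1) else d / vnorm(d)
    } else c(0, 0, 1)
    # distribute multiple H on a small cone around dir0
    ortho <- if (abs(dir0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ortho - sum(ortho * dir0) * dir0; u <- u / vnorm(u)
    v <- c(dir0[2] * u[3] - dir0[3] * u[2],
           dir0[3] * u[1] - dir0[1] * u[3],
           dir0[1] * u[2] - dir0[2] * u[1])
    for (k in seq_len(miss)) {
      ang <- 2 * pi * (k - 1) / max(1L, miss)
      d <- 0.94 * dir0 + 0.34 * (cos(ang) * u + sin(ang) * v)
      d <- d / vnorm(d)
      pos <- base + 1.0 * d
      new_atoms <- rbind(new_atoms, data.frame(
        elem = "H", x = pos[1], y = pos[2], z = pos[3], charge = 0L,
        aromatic = FALSE, resid = new_atoms$resid[i],
        resname = new_atoms$resname[i]))
      new_bonds <- rbind(new_bonds, data.frame(
        i = i, j = nrow(new_atoms), order = 1L,
        aromatic = if ("aromatic" %in% names(new_bonds)) FALSE else NULL))
    }
  }
  m2 <- molecule3d(mol$id, new_atoms, new_bonds, perceive_aromaticity = FALSE)
  m2$atoms$aromatic <- new_atoms$aromatic
  m2$bonds$aromatic <- if ("aromatic" %in% names(new_bonds)) new_bonds$aromatic
                       else rep(FALSE, nrow(new_bonds))
  annotate_graph(m2)
}

#' Molecular weight from standard atomic masses
#' @param mol a `molecule3d` (hydrogens should be explicit for exact weights).
#' @return weight in Dalton.
#' @export
molecular_weight <- function(mol) {
  e <- mol$atoms$elem
  unknown <- setdiff(unique(e), names(ATOMIC_MASS))
  if (length(unknown))
    abort_pharm(paste("unknown element(s):", paste(unknown, collapse = ", ")),
                "unknown_element")
  sum(ATOMIC_MASS[e])
}

# apolar carbon: non-aromatic carbon not bonded to any N/O/P/S (aromatic
# rings are handled as RA features, mirroring the perception rules)
apolar_carbons <- function(mol) {
  polar <- c("N", "O", "P", "S")
  vapply(seq_len(n_atoms(mol)), function(i) {
    if (mol$atoms$elem[i] != "C" || mol$atoms$aromatic[i]) return(FALSE)
    nb <- mol$graph$adj[[i]]
    !any(mol$atoms$elem[nb] %in% polar)
  }, logical(1))
}

#' Apply a rigid-body transform to a molecule
#' @param mol a `molecule3d`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric vector.
#' @return transformed `molecule3d`.
#' @export
transform_molecule <- function(mol, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- mol_xyz(mol) %*% t(rotation) +
    matrix(translation, n_atoms(mol), 3, byrow = TRUE)
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}
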