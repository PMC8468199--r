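# ---------------------------------------------------------------------------
# Hypothesis generation: common-feature (HipHop-like) enumeration from a
# training set of actives, and interaction-geometry derivation from a
# receptor-ligand complex.
# ---------------------------------------------------------------------------

#' Training-set specification for common-feature generation
#'
#' @param members list; each member is a list with elements
#'   `conformers` (a `feature_set` or list of conformer feature sets, or a
#'   `molecule3d`), `principal` (0, 1 or 2) and `max_omit` (>= 0). Principal
#'   value 2 marks reference actives whose features define the candidate
#'   configurations; `max_omit` is how many hypothesis features that member
#'   may miss ("all but one feature must map" corresponds to 1).
#' @param rules perception rules for raw molecules.
#' @return object of class `training_set`.
#' @export
training_set <- function(members, rules = default_feature_rules()) {
  stopifnot(is.list(members), length(members) >= 1)
  members <- lapply(seq_along(members), function(k) {
    m <- members[[k]]
    stopifnot(!is.null(m$conformers))
    m$principal <- as.integer(m$principal %||% 2L)
    m$max_omit <- as.integer(m$max_omit %||% 0L)
    if (!(m$principal %in% 0:2))
      abort_pharm("principal must be 0, 1 or 2", "invalid_training_set")
    if (m$max_omit < 0)
      abort_pharm("max_omit must be >= 0", "invalid_training_set")
    m$conformers <- compound_conformers(m$conformers, rules)
    if (!all(vapply(m$conformers, length, integer(1)) > 0))
      abort_pharm(sprintf("training member %d has a conformer with no features (perception misconfigured?)", k),
                  "degenerate_member")
    m$id <- m$id %||% compound_id(m$conformers[[1]], paste0("train", k))
    m
  })
  if (!any(vapply(members, `[[`, integer(1), "principal") == 2L))
    abort_pharm("at least one member must have principal = 2",
                "no_principal_member")
  structure(list(members = members), class = "training_set")
}

#' Generation configuration
#'
#' @param max_conformers maximum conformers considered per molecule
#'   (default 255).
#' @param energy_window conformer energy window in kcal/mol (default 20;
#'   only consulted when conformers carry energies).
#' @param match_tolerance Angstrom distance-compatibility window (default 1.0).
#' @param min_features,max_features feature-count bounds per hypothesis
#'   (defaults 4 and 7).
#' @param max_hypotheses maximum hypotheses reported (default 10).
#' @return list of class `generation_config`.
#' @export
generation_config <- function(max_conformers = 255L, energy_window = 20,
                              match_tolerance = 1.0, min_features = 4L,
                              max_features = 7L, max_hypotheses = 10L) {
  stopifnot(max_conformers > 0, energy_window > 0, match_tolerance > 0,
            min_features > 0, max_features >= min_features,
            max_hypotheses > 0)
  structure(list(max_conformers = as.integer(max_conformers),
                 energy_window = energy_window,
                 match_tolerance = match_tolerance,
                 min_features = as.integer(min_features),
                 max_features = as.integer(max_features),
                 max_hypotheses = as.integer(max_hypotheses)),
            class = "generation_config")
}

# best fit of a member (over conformers) onto h at the member's max_omit;
# 0 when the member cannot map at all
member_best_fit <- function(h, member, match_tolerance) {
  allow <- min(member$max_omit, h$max_fit - 1L)
  best <- NULL
  for (fs in member$conformers) {
    m <- map_conformer(h, fs, allow, match_tolerance)
    if (!is.null(m) && (is.null(best) || m$fit > best$fit)) best <- m
  }
  best
}

#' Ranking score of a hypothesis over a training set
#'
#' Sum over training members of the best fit value (0 for a member that
#' cannot map). This score is the package's own, defined here because the
#' commercial tools' ranking formulas are undisclosed; a perfect self-map of
#' k features on m members gives m*k.
#'
#' @param h a `pharm_hypothesis`.
#' @param ts a `training_set`.
#' @param cfg a `generation_config`.
#' @return numeric score (deterministic).
#' @export
rank_score <- function(h, ts, cfg = generation_config()) {
  sum(vapply(ts$members, function(m) {
    b <- member_best_fit(h, m, cfg$match_tolerance)
    if (is.null(b)) 0 else b$fit
  }, numeric(1)))
}

#' Enumerate common-feature pharmacophore hypotheses
#'
#' Candidate feature configurations are subsets (within the configured size
#' bounds) of a principal (= 2) member's perceived features. A configuration
#' is retained only when every training member maps it within its own
#' `max_omit` omissions, matching done by clique search on pairwise-distance
#' compatibility within `cfg$match_tolerance`. Retained hypotheses are
#' ranked by [rank_score()], ties broken by more features, then by the
#' lexicographic feature-kind string; at most `cfg$max_hypotheses` are
#' returned.
#'
#' @param ts a `training_set`.
#' @param cfg a `generation_config`.
#' @return list of results, each with `hypothesis` (a `pharm_hypothesis`
#'   with rank_score filled) and `mapping_report` (per member: id,
#'   direct_hit, partial_hit flags and best fit; direct/partial are mutually
#'   exclusive, "mapped all" vs "mapped all but one").
#' @export
enumerate_common_pharmacophores <- function(ts, cfg = generation_config()) {
  stopifnot(inherits(ts, "training_set"), inherits(cfg, "generation_config"))
  prins <- which(vapply(ts$members, `[[`, integer(1), "principal") == 2L)
  seen_cfg <- character()
  results <- list()
  for (pm in prins) {
    confs <- ts$members[[pm]]$conformers
    confs <- confs[seq_len(min(length(confs), cfg$max_conformers))]
    for (fs in confs) {
      feats <- unclass(fs)
      nf <- length(feats)
      lo <- cfg$min_features; hi <- min(cfg$max_features, nf)
      if (nf < lo) next
      for (k in lo:hi) {
        for (sel in utils::combn(nf, k, simplify = FALSE)) {
          kinds <- feature_kinds(feats[sel])
          ckey <- paste(pm, paste(sel, collapse = ","))
          if (ckey %in% seen_cfg) next
          seen_cfg <- c(seen_cfg, ckey)
          h <- pharm_hypothesis(sprintf("cand_%d_%s", pm,
                                        paste(sel, collapse = "_")),
                                feats[sel], "ligand_based")
          fits <- lapply(ts$members, member_best_fit, h = h,
                         match_tolerance = cfg$match_tolerance)
          if (any(vapply(fits, is.null, logical(1)))) next
          omit_ok <- vapply(seq_along(fits), function(i)
            fits[[i]]$omitted_count <= ts$members[[i]]$max_omit, logical(1))
          if (!all(omit_ok)) next
          h$rank_score <- sum(vapply(fits, `[[`, numeric(1), "fit"))
          report <- data.frame(
            id = vapply(ts$members, `[[`, "", "id"),
            direct_hit = vapply(fits, function(f) f$omitted_count == 0L,
                                logical(1)),
            partial_hit = vapply(fits, function(f) f$omitted_count == 1L,
                                 logical(1)),
            fit = vapply(fits, `[[`, numeric(1), "fit"))
          results[[length(results) + 1L]] <-
            list(hypothesis = h, mapping_report = report)
        }
      }
    }
  }
  if (!length(results)) return(list())
  scores <- vapply(results, function(r) r$hypothesis$rank_score, numeric(1))
  sizes <- vapply(results, function(r) r$hypothesis$max_fit, integer(1))
  kindstr <- vapply(results, function(r)
    paste(feature_kinds(r$hypothesis$features), collapse = ","), character(1))
  ord <- order(-scores, -sizes, kindstr)
  results <- results[ord][seq_len(min(length(results), cfg$max_hypotheses))]
  for (i in seq_along(results))
    results[[i]]$hypothesis$id <- sprintf("Hypo%d", i)
  results
}

#' Interaction-geometry rules
#'
#' @param hbond_dist heavy-atom donor-acceptor cutoff in Angstrom
#'   (default 3.5).
#' @param hbond_angle minimum donor-H...acceptor angle in degrees
#'   (default 120).
#' @param hydrophobic_dist apolar-contact cutoff in Angstrom (default 4.5).
#' @param min_cluster minimum apolar-atom cluster size for a HYP feature
#'   (default 3).
#' @param stack_dist aromatic ring-centroid cutoff in Angstrom (default 5.5).
#' @param vdw_dist residual van der Waals contact cutoff (default 4.0).
#' @return list of class `interaction_rules`.
#' @export
interaction_rules <- function(hbond_dist = 3.5, hbond_angle = 120,
                              hydrophobic_dist = 4.5, min_cluster = 3L,
                              stack_dist = 5.5, vdw_dist = 4.0) {
  vals <- c(hbond_dist, hbond_angle, hydrophobic_dist, min_cluster,
            stack_dist, vdw_dist)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort_pharm("all cutoffs must be positive", "invalid_rules")
  structure(list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 hydrophobic_dist = hydrophobic_dist,
                 min_cluster = as.integer(min_cluster),
                 stack_dist = stack_dist, vdw_dist = vdw_dist),
            class = "interaction_rules")
}

# donor heavy atoms (N/O/S with attached H); acceptors via the default HBA
# rules; when a structure carries no hydrogens at all (typical PDB), any
# N/O is treated as a potential donor and angle checks are skipped
donor_atoms <- function(mol) {
  has_h <- any(mol$atoms$elem == "H")
  if (has_h)
    which(mol$atoms$elem %in% c("N", "O", "S") & mol$graph$nH > 0)
  else which(mol$atoms$elem %in% c("N", "O"))
}
acceptor_atoms <- function(mol) {
  o <- which(mol$atoms$elem == "O")
  n <- which(mol$atoms$elem == "N" & mol$graph$nH == 0)
  ok_n <- n[vapply(n, function(i) {
    nb <- mol$graph$adj[[i]]
    bo <- unlist(mol$graph$bond_order[[i]])
    # exclude amide and aniline-type N (single bond to C=O or aromatic C)
    !any(vapply(seq_along(nb), function(t) {
      j <- nb[t]
      if (mol$atoms$elem[j] != "C" || bo[t] != 1L) return(FALSE)
      if (mol$atoms$aromatic[j]) return(TRUE)
      jb <- mol$graph$adj[[j]]; jo <- unlist(mol$graph$bond_order[[j]])
      any(mol$atoms$elem[jb] == "O" & jo == 2L)
    }, logical(1)))
  }, logical(1))]
  sort(c(o, ok_n))
}

hbond_geometry_ok <- function(don_mol, d_idx, don_xyz, acc_xyz, rules) {
  # distance already checked; verify the D-H...A angle over any H on donor
  hs <- don_mol$graph$adj[[d_idx]]
  hs <- hs[don_mol$atoms$elem[hs] == "H"]
  if (!length(hs)) return(TRUE)   # no explicit H: distance-only criterion
  hxyz <- mol_xyz(don_mol)[hs, , drop = FALSE]
  for (r in seq_len(nrow(hxyz))) {
    v1 <- don_xyz - hxyz[r, ]; v2 <- acc_xyz - hxyz[r, ]
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) *
      180 / pi
    if (ang >= rules$hbond_angle) return(TRUE)
  }
  FALSE
}

aromatic_ring_centroids <- function(mol) {
  rings <- mol_rings(mol)
  rings <- Filter(function(r) all(mol$atoms$aromatic[r]), rings)
  xyz <- mol_xyz(mol)
  list(rings = rings,
       centroids = if (length(rings))
         do.call(rbind, lapply(rings, function(r)
           colMeans(xyz[r, , drop = FALSE])))
       else matrix(numeric(), 0, 3))
}

#' Derive a structure-based pharmacophore from a receptor-ligand complex
#'
#' For each ligand donor with a receptor acceptor inside the hydrogen-bond
#' cutoffs, an HBD feature is placed on the ligand donor atom; ligand
#' acceptors facing receptor donors give HBA features; contiguous clusters
#' of at least `min_cluster` apolar ligand atoms within the hydrophobic
#' cutoff of apolar receptor atoms give HYP features at the cluster
#' centroid; a ligand aromatic ring whose centroid lies within the stacking
#' cutoff of a receptor ring centroid gives an RA feature. All features sit
#' on ligand coordinates; provenance is "structure_based" and the
#' selectivity slot is NA ("not computed").
#'
#' @param receptor,ligand `molecule3d` structures with coordinates.
#' @param rules an `interaction_rules` object.
#' @param id hypothesis identifier.
#' @return a `pharm_hypothesis` (possibly with zero features when no
#'   contacts fall within the cutoffs).
#' @export
derive_receptor_hypothesis <- function(receptor, ligand,
                                       rules = interaction_rules(),
                                       id = "receptor_hypo") {
  stopifnot(inherits(receptor, "molecule3d"), inherits(ligand, "molecule3d"))
  rxyz <- mol_xyz(receptor); lxyz <- mol_xyz(ligand)
  feats <- list()
  # HBD: ligand donor vs receptor acceptor
  racc <- acceptor_atoms(receptor)
  for (d in donor_atoms(ligand)) {
    for (a in racc) {
      dd <- vnorm(lxyz[d, ] - rxyz[a, ])
      if (dd <= rules$hbond_dist &&
          hbond_geometry_ok(ligand, d, lxyz[d, ], rxyz[a, ], rules)) {
        feats[[length(feats) + 1L]] <-
          pharm_feature("HBD", lxyz[d, ], source_atoms = d)
        break
      }
    }
  }
  # HBA: ligand acceptor vs receptor donor
  rdon <- donor_atoms(receptor)
  for (a in acceptor_atoms(ligand)) {
    for (d in rdon) {
      dd <- vnorm(lxyz[a, ] - rxyz[d, ])
      if (dd <= rules$hbond_dist &&
          hbond_geometry_ok(receptor, d, rxyz[d, ], lxyz[a, ], rules)) {
        feats[[length(feats) + 1L]] <-
          pharm_feature("HBA", lxyz[a, ], source_atoms = a)
        break
      }
    }
  }
  # HYP: apolar ligand clusters near apolar receptor atoms
  lap <- which(apolar_carbons(ligand))
  rap <- which(apolar_carbons(receptor))
  if (length(lap) && length(rap)) {
    near <- lap[vapply(lap, function(i)
      min(sqrt(colSums((t(rxyz[rap, , drop = FALSE]) - lxyz[i, ])^2))) <=
        rules$hydrophobic_dist, logical(1))]
    for (grp in connected_components(near, ligand$graph$adj)) {
      if (length(grp) >= rules$min_cluster)
        feats[[length(feats) + 1L]] <-
          pharm_feature("HYP", colMeans(lxyz[grp, , drop = FALSE]),
                        source_atoms = grp)
    }
  }
  # RA: ligand ring centroid near receptor ring centroid
  lar <- aromatic_ring_centroids(ligand)
  rar <- aromatic_ring_centroids(receptor)
  if (length(lar$rings) && length(rar$rings)) {
    for (i in seq_along(lar$rings)) {
      dmin <- min(sqrt(colSums((t(rar$centroids) - lar$centroids[i, ])^2)))
      if (dmin <= rules$stack_dist)
        feats[[length(feats) + 1L]] <-
          pharm_feature("RA", lar$centroids[i, ],
                        source_atoms = lar$rings[[i]])
    }
  }
  # deterministic order: kind, then first source atom
  if (length(feats)) {
    ord <- order(match(feature_kinds(feats), FEATURE_KINDS),
                 vapply(feats, function(f)
                   if (length(f$source_atoms)) f$source_atoms[1] else 0L,
                   integer(1)))
    feats <- feats[ord]
  }
  pharm_hypothesis(id, feats, "structure_based")
}

#' Classify receptor-ligand atomic contacts
#'
#' Each (ligand heavy atom, receptor heavy atom) pair is assigned at most
#' one class with priority hydrogen_bond > aromatic_stack > hydrophobic >
#' van_der_waals: hydrogen bonds per the donor/acceptor distance + angle
#' rule; aromatic stacks for aromatic-atom pairs whose ring centroids lie
#' within the stacking cutoff; hydrophobic for apolar carbon pairs within
#' the hydrophobic cutoff; van der Waals for any remaining heavy-atom pair
#' within `vdw_dist`.
#'
#' @inheritParams derive_receptor_hypothesis
#' @return data.frame: `ligand_atom`, `receptor_atom`, `receptor_resid`,
#'   `receptor_resname`, `distance`, `class`.
#' @export
classify_contacts <- function(receptor, ligand, rules = interaction_rules()) {
  rxyz <- mol_xyz(receptor); lxyz <- mol_xyz(ligand)
  lheavy <- which(ligand$atoms$elem != "H")
  rheavy <- which(receptor$atoms$elem != "H")
  ldon <- donor_atoms(ligand); lacc <- acceptor_atoms(ligand)
  rdon <- donor_atoms(receptor); racc <- acceptor_atoms(receptor)
  lap <- which(apolar_carbons(ligand)); rap <- which(apolar_carbons(receptor))
  lar <- aromatic_ring_centroids(ligand); rar <- aromatic_ring_centroids(receptor)
  stack_ring_pairs <- list()
  if (length(lar$rings) && length(rar$rings))
    for (i in seq_along(lar$rings)) for (j in seq_along(rar$rings))
      if (vnorm(lar$centroids[i, ] - rar$centroids[j, ]) <= rules$stack_dist)
        stack_ring_pairs[[length(stack_ring_pairs) + 1L]] <-
          list(l = lar$rings[[i]], r = rar$rings[[j]])
  rows <- list()
  maxcut <- max(rules$hbond_dist, rules$hydrophobic_dist, rules$vdw_dist)
  for (i in lheavy) for (j in rheavy) {
    d <- vnorm(lxyz[i, ] - rxyz[j, ])
    if (d > maxcut) next
    cls <- NULL
    if (d <= rules$hbond_dist) {
      if (i %in% ldon && j %in% racc &&
          hbond_geometry_ok(ligand, i, lxyz[i, ], rxyz[j, ], rules))
        cls <- "hydrogen_bond"
      else if (i %in% lacc && j %in% rdon &&
               hbond_geometry_ok(receptor, j, rxyz[j, ], lxyz[i, ], rules))
        cls <- "hydrogen_bond"
    }
    if (is.null(cls) && length(stack_ring_pairs) && d <= rules$vdw_dist) {
      for (pr in stack_ring_pairs)
        if (i %in% pr$l && j %in% pr$r) { cls <- "aromatic_stack"; break }
    }
    if (is.null(cls) && d <= rules$hydrophobic_dist &&
        i %in% lap && j %in% rap)
      cls <- "hydrophobic"
    if (is.null(cls) && d <= rules$vdw_dist)
      cls <- "van_der_waals"
    if (!is.null(cls))
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_atom = i, receptor_atom = j,
        receptor_resid = receptor$atoms$resid[j],
        receptor_resname = receptor$atoms$resname[j],
        distance = d, class = cls)
  }
  if (!length(rows))
    return(data.frame(ligand_atom = integer(), receptor_atom = integer(),
                      receptor_resid = integer(),
                      receptor_resname = character(),
                      distance = numeric(), class = character()))
  do.call(rbind, rows)
}

#' Tabular report of generated hypotheses
#'
#' A human-readable table with one row per hypothesis: features, rank or
#' selectivity score, direct-hit and partial-hit strings ("1"/"0" per
#' training member) and max fit.
#'
#' @param results output of [enumerate_common_pharmacophores()], or a list
#'   of bare `pharm_hypothesis` objects.
#' @param path optional TSV output path.
#' @return data.frame.
#' @export
hypothesis_report <- function(results, path = NULL) {
  rows <- lapply(results, function(r) {
    h <- if (inherits(r, "pharm_hypothesis")) r else r$hypothesis
    rep <- if (is.list(r) && !is.null(r$mapping_report)) r$mapping_report
    data.frame(
      id = h$id,
      features = paste(feature_kinds(h$features), collapse = ", "),
      rank = h$rank_score,
      selectivity = h$selectivity,
      direct_hit = if (!is.null(rep))
        paste(as.integer(rep$direct_hit), collapse = "") else NA_character_,
      partial_hit = if (!is.null(rep))
        paste(as.integer(rep$partial_hit), collapse = "") else NA_character_,
      max_fit = h$max_fit)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
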