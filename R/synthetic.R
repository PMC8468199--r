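# ---------------------------------------------------------------------------
# Seeded synthetic-data generators. Every generator is a pure function of
# (spec, seed): identical inputs give identical outputs, so all pipeline
# stages are testable without commercial tools or proprietary libraries.
# The confusion-table generator plants mappable/unmappable feature clouds
# rather than fake scores, so validation exercises the real mapping path.
# ---------------------------------------------------------------------------

# default planted arrangement: four features of distinct kinds on a
# well-separated 3D scaffold (distances 4-8 Angstrom, pharmacophore-like)
default_planted_geometry <- function(k = 4L) {
  base <- rbind(c(0, 0, 0), c(5.2, 0, 0), c(2.4, 4.6, 0),
                c(2.8, 1.8, 4.2), c(-2.5, 2.7, 1.5), c(6.5, 3.1, 2.2),
                c(0.8, -3.9, 2.6))
  base[seq_len(k), , drop = FALSE]
}

#' Planted-pharmacophore library specification
#'
#' @param kinds feature kinds of the planted arrangement (>= 3).
#' @param geometry k x 3 matrix of planted centroids in Angstrom (default: a
#'   fixed well-separated scaffold).
#' @param jitter_sd per-coordinate Gaussian jitter in Angstrom (>= 0).
#' @param n_actives,n_decoys library composition.
#' @param decoy_strategy "missing_kind" (decoys lack one planted kind) or
#'   "scrambled" (same kinds, randomized geometry).
#' @param extra_features number of unshared decoy features appended to every
#'   active (random kind/position).
#' @param tolerance mapping tolerance the actives must survive; when
#'   `guarantee` is TRUE a spec with jitter_sd > tolerance/2 is rejected as
#'   infeasible.
#' @param guarantee require the all-actives-map guarantee (default TRUE).
#' @return list of class `planted_spec`.
#' @export
planted_spec <- function(kinds = c("HBD", "HBA", "RA", "HYP"),
                         geometry = NULL, jitter_sd = 0.2,
                         n_actives = 4L, n_decoys = 0L,
                         decoy_strategy = c("missing_kind", "scrambled"),
                         extra_features = 0L, tolerance = 1.6,
                         guarantee = TRUE) {
  kinds <- parse_feature_kind(kinds)
  if (length(kinds) < 3)
    abort_pharm("need >= 3 planted features", "invalid_spec")
  if (jitter_sd < 0) abort_pharm("jitter must be >= 0", "invalid_spec")
  if (is.null(geometry)) geometry <- default_planted_geometry(length(kinds))
  geometry <- as.matrix(geometry)
  stopifnot(nrow(geometry) == length(kinds), ncol(geometry) == 3)
  if (guarantee && jitter_sd > tolerance / 2)
    abort_pharm("infeasible spec: jitter_sd exceeds tolerance/2 while the all-actives-map guarantee is requested",
                "infeasible_spec")
  structure(list(kinds = kinds, geometry = geometry, jitter_sd = jitter_sd,
                 n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 decoy_strategy = match.arg(decoy_strategy),
                 extra_features = as.integer(extra_features),
                 tolerance = tolerance),
            class = "planted_spec")
}

jittered_cloud <- function(spec, id) {
  xyz <- spec$geometry +
    matrix(stats::rnorm(3 * nrow(spec$geometry), sd = spec$jitter_sd),
           ncol = 3)
  feats <- lapply(seq_along(spec$kinds), function(i)
    pharm_feature(spec$kinds[i], xyz[i, ], tolerance = spec$tolerance))
  if (spec$extra_features > 0) {
    for (e in seq_len(spec$extra_features)) {
      k <- sample(FEATURE_KINDS, 1)
      pos <- colMeans(spec$geometry) +
        stats::runif(3, min = 8, max = 14) * sample(c(-1, 1), 3, replace = TRUE)
      feats[[length(feats) + 1L]] <-
        pharm_feature(k, pos, tolerance = spec$tolerance)
    }
  }
  structure(feats, class = "feature_set", id = id)
}

decoy_cloud <- function(spec, id) {
  if (spec$decoy_strategy == "missing_kind") {
    drop_kind <- spec$kinds[1]
    keep <- which(spec$kinds != drop_kind)
    feats <- lapply(keep, function(i)
      pharm_feature(spec$kinds[i],
                    spec$geometry[i, ] + stats::rnorm(3, sd = spec$jitter_sd),
                    tolerance = spec$tolerance))
  } else {
    # same kinds, scrambled geometry: large random displacements break the
    # pairwise-distance pattern
    feats <- lapply(seq_along(spec$kinds), function(i)
      pharm_feature(spec$kinds[i],
                    stats::runif(3, -20, 20), tolerance = spec$tolerance))
  }
  structure(feats, class = "feature_set", id = id)
}

#' Generate a labeled library around a planted pharmacophore
#'
#' Actives are jittered copies of the planted feature arrangement (plus
#' optional unshared features); decoys are constructed to fail mapping by
#' the chosen strategy. With jitter_sd <= tolerance/2 every active maps the
#' planted hypothesis at allow_omit 0.
#'
#' @param spec a `planted_spec`.
#' @param seed integer seed.
#' @return list: `library` (feature sets), `labels` (TRUE = active),
#'   `hypothesis` (the planted `pharm_hypothesis`).
#' @export
gen_planted_library <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "planted_spec"))
  with_seed(seed, {
    actives <- lapply(seq_len(spec$n_actives), function(k)
      jittered_cloud(spec, sprintf("active%03d", k)))
    decoys <- lapply(seq_len(spec$n_decoys), function(k)
      decoy_cloud(spec, sprintf("decoy%03d", k)))
    planted <- lapply(seq_along(spec$kinds), function(i)
      pharm_feature(spec$kinds[i], spec$geometry[i, ],
                    tolerance = spec$tolerance))
    list(library = c(actives, decoys),
         labels = c(rep(TRUE, spec$n_actives), rep(FALSE, spec$n_decoys)),
         hypothesis = pharm_hypothesis("planted", planted, "ligand_based"))
  })
}

#' Decoy-set specification realizing a target confusion table
#'
#' @param D total compounds (default 110).
#' @param A actives (default 6).
#' @param Ht,Ha the hit counts the generated set must realize exactly.
#' @return list of class `decoy_set_spec`.
#' @export
decoy_set_spec <- function(D = 110L, A = 6L, Ht, Ha) {
  if (!(D > A && A > 0) || Ht > D || Ha > min(A, Ht) || Ha < 0)
    abort_pharm("inconsistent decoy-set counts", "invalid_spec")
  structure(list(D = as.integer(D), A = as.integer(A),
                 Ht = as.integer(Ht), Ha = as.integer(Ha)),
            class = "decoy_set_spec")
}

#' Generate a labeled decoy set with an exact confusion table
#'
#' Ha actives and Ht - Ha inactives are mappable feature clouds (small
#' jitter around the planted hypothesis); the rest are unmappable
#' (missing-kind strategy). Screening the output against the returned
#' hypothesis at allow_omit 0 reproduces (D, A, Ht, Ha) exactly, through
#' the real mapping path.
#'
#' @param spec a `decoy_set_spec`.
#' @param seed integer seed.
#' @return list: `hypothesis`, `library`, `labels`.
#' @export
gen_decoy_set <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "decoy_set_spec"))
  base <- planted_spec(jitter_sd = 0.15, n_actives = 1L)
  with_seed(seed, {
    mk <- function(mappable, id)
      if (mappable) jittered_cloud(base, id) else decoy_cloud(base, id)
    lib <- vector("list", spec$D)
    labels <- c(rep(TRUE, spec$A), rep(FALSE, spec$D - spec$A))
    map_flag <- c(rep(TRUE, spec$Ha), rep(FALSE, spec$A - spec$Ha),
                  rep(TRUE, spec$Ht - spec$Ha),
                  rep(FALSE, spec$D - spec$A - (spec$Ht - spec$Ha)))
    for (k in seq_len(spec$D))
      lib[[k]] <- mk(map_flag[k],
                     sprintf("%s%03d", if (labels[k]) "act" else "dec", k))
    planted <- lapply(seq_along(base$kinds), function(i)
      pharm_feature(base$kinds[i], base$geometry[i, ],
                    tolerance = base$tolerance))
    list(hypothesis = pharm_hypothesis("decoy_query", planted, "ligand_based"),
         library = lib, labels = labels)
  })
}

#' Snapshot-series specification
#'
#' @param mean named numeric: per-component means in kJ/mol (vdw, elec,
#'   polar_solv, nonpolar_sasa).
#' @param sd matching SDs (>= 0).
#' @param n snapshots (default 40).
#' @param t_start,t_end time window in ps (defaults 40000-50000, the final
#'   10 ns of a 50 ns run).
#' @return list of class `snapshot_spec`.
#' @export
snapshot_spec <- function(mean = c(vdw = -191.19, elec = -309.22,
                                   polar_solv = 355.74,
                                   nonpolar_sasa = -25.34),
                          sd = c(vdw = 14.45, elec = 30.04,
                                 polar_solv = 44.97, nonpolar_sasa = 1.40),
                          n = 40L, t_start = 40000, t_end = 50000) {
  stopifnot(all(ENERGY_COMPONENTS %in% names(mean)),
            all(ENERGY_COMPONENTS %in% names(sd)))
  if (any(sd < 0) || n < 2)
    abort_pharm("need sd >= 0 and n >= 2", "invalid_spec")
  structure(list(mean = mean[ENERGY_COMPONENTS], sd = sd[ENERGY_COMPONENTS],
                 n = as.integer(n), t_start = t_start, t_end = t_end),
            class = "snapshot_spec")
}

#' Generate a pre-differenced snapshot energy series
#'
#' Independent Gaussian components per snapshot at the configured moments;
#' bit-for-bit reproducible for a given seed.
#'
#' @param spec a `snapshot_spec`.
#' @param seed integer seed.
#' @return list of `snapshot_energies` (pre-differenced representation).
#' @export
gen_snapshots <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "snapshot_spec"))
  times <- seq(spec$t_start, spec$t_end, length.out = spec$n)
  with_seed(seed, {
    lapply(seq_len(spec$n), function(k) {
      v <- stats::rnorm(4, mean = spec$mean, sd = spec$sd)
      snapshot_energies(times[k],
                        interaction = energy_components(v[1], v[2], v[3], v[4]))
    })
  })
}

#' Trajectory specification
#'
#' @param n_residues residues (one backbone atom each by default).
#' @param n_frames frames (>= 2).
#' @param jitter_profile per-residue positional jitter SD in nm (recycled).
#' @param drift global rigid rotation amplitude in radians applied
#'   progressively across frames (0 = none).
#' @param dt_ps frame spacing in ps.
#' @return list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_residues = 50L, n_frames = 50L,
                            jitter_profile = 0.15, drift = 0,
                            dt_ps = 1000) {
  if (n_frames < 2) abort_pharm("need >= 2 frames", "invalid_spec")
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 jitter_profile = rep_len(jitter_profile, n_residues),
                 drift = drift, dt_ps = dt_ps),
            class = "trajectory_spec")
}

#' Generate a synthetic trajectory
#'
#' Frames are an optional progressive rigid rotation of a fixed extended
#' backbone plus independent per-residue Gaussian jitter (nm). Rigid motion
#' is removed by superposition, so the expected RMSD is governed by the
#' jitter profile alone.
#'
#' @param spec a `trajectory_spec`.
#' @param seed integer seed.
#' @return `trajectory3d` (nm).
#' @export
gen_trajectory <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "trajectory_spec"))
  n <- spec$n_residues
  # loose helix, nm scale
  t0 <- seq_len(n) * 0.38
  base <- cbind(cos(t0 / 0.6) * 0.8, sin(t0 / 0.6) * 0.8, t0 * 0.4)
  with_seed(seed, {
    frames <- lapply(seq_len(spec$n_frames), function(f) {
      ang <- spec$drift * (f - 1) / max(1L, spec$n_frames - 1L)
      R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                  3, 3, byrow = TRUE)
      jitter <- matrix(stats::rnorm(3 * n, sd = rep(spec$jitter_profile, 3)),
                       ncol = 3)
      if (f == 1L) base else base %*% t(R) + jitter
    })
    trajectory3d(frames, times = (seq_len(spec$n_frames) - 1) * spec$dt_ps,
                 labels = data.frame(name = "CA", backbone = TRUE,
                                     resid = seq_len(n)),
                 unit = "nm")
  })
}

# -- toy receptor-ligand complexes ------------------------------------------

toy_site_hbd <- function(x) {
  # ligand N-H pointing at a receptor carbonyl O (2.9 A, angle 180)
  lig <- list(atoms = data.frame(
    elem = c("N", "H", "C"),
    x = c(x, x, x), y = c(0, 1.0, -1.45), z = 0),
    bonds = data.frame(i = c(1, 1), j = c(2, 3), order = 1L))
  rec <- list(atoms = data.frame(
    elem = c("O", "C"), x = c(x, x), y = c(2.9, 4.12), z = 0),
    bonds = data.frame(i = 1, j = 2, order = 2L))
  list(lig = lig, rec = rec)
}

toy_site_hba <- function(x) {
  # ligand ether O facing a receptor N-H donor
  lig <- list(atoms = data.frame(
    elem = c("O", "C", "C"),
    x = c(x, x - 1.4, x + 1.4), y = c(0, -1.0, -1.0), z = 0),
    bonds = data.frame(i = c(1, 1), j = c(2, 3), order = 1L))
  rec <- list(atoms = data.frame(
    elem = c("N", "H", "C"),
    x = c(x, x, x), y = c(2.9, 1.9, 4.35), z = 0),
    bonds = data.frame(i = c(1, 1), j = c(2, 3), order = 1L))
  list(lig = lig, rec = rec)
}

toy_site_hyp <- function(x) {
  # three-carbon apolar ligand cluster facing an apolar receptor pair
  lig <- list(atoms = data.frame(
    elem = c("C", "C", "C"),
    x = c(x - 1.3, x, x + 1.3), y = c(0, 0.5, 0), z = 0),
    bonds = data.frame(i = c(1, 2), j = c(2, 3), order = 1L))
  rec <- list(atoms = data.frame(
    elem = c("C", "C"), x = c(x - 0.7, x + 0.7), y = c(3.6, 3.6), z = 0),
    bonds = data.frame(i = 1, j = 2, order = 1L))
  list(lig = lig, rec = rec)
}

toy_site_ra <- function(x) {
  hexagon <- function(cx, cz) data.frame(
    elem = "C",
    x = cx + 1.39 * cos(seq(0, 5) * pi / 3),
    y = 1.39 * sin(seq(0, 5) * pi / 3),
    z = cz)
  ring_bonds <- data.frame(i = 1:6, j = c(2:6, 1),
                           order = rep(c(2L, 1L), 3))
  list(lig = list(atoms = hexagon(x, 0), bonds = ring_bonds),
       rec = list(atoms = hexagon(x, 3.5), bonds = ring_bonds))
}

#' Construct a toy receptor-ligand complex with planted contacts
#'
#' Contact sites (hydrogen-bond donor/acceptor, hydrophobic cluster,
#' aromatic stack) are placed 12 Angstrom apart along the x axis so no
#' unrequested contact falls within any rule window; each requested contact
#' satisfies its default geometric rule by construction.
#'
#' @param n_hbd ligand donor contacts (ligand N-H to receptor C=O, 2.9 A).
#' @param n_hba ligand acceptor contacts (ligand ether O to receptor N-H).
#' @param n_hyp hydrophobic clusters (3 apolar ligand C within 4.5 A of
#'   apolar receptor atoms).
#' @param n_ra stacked aromatic ring pairs (centroids 3.5 A apart).
#' @return list with `receptor` and `ligand` (`molecule3d`); receptor atoms
#'   carry one residue per site.
#' @export
gen_toy_complex <- function(n_hbd = 0L, n_hba = 0L, n_hyp = 0L, n_ra = 0L) {
  counts <- c(hbd = n_hbd, hba = n_hba, hyp = n_hyp, ra = n_ra)
  if (all(counts == 0)) {
    # far-apart inert pair: single carbons 50 A apart
    rec <- molecule3d("receptor", data.frame(elem = "C", x = 0, y = 50, z = 0))
    lig <- molecule3d("ligand", data.frame(elem = "C", x = 0, y = 0, z = 0))
    return(list(receptor = rec, ligand = lig))
  }
  makers <- c(rep(list(toy_site_hbd), n_hbd), rep(list(toy_site_hba), n_hba),
              rep(list(toy_site_hyp), n_hyp), rep(list(toy_site_ra), n_ra))
  lig_atoms <- NULL; lig_bonds <- NULL
  rec_atoms <- NULL; rec_bonds <- NULL
  for (s in seq_along(makers)) {
    site <- makers[[s]]((s - 1) * 12)
    off_l <- nrow(lig_atoms %||% data.frame())
    off_r <- nrow(rec_atoms %||% data.frame())
    la <- site$lig$atoms; ra <- site$rec$atoms
    ra$resid <- s; ra$resname <- sprintf("R%02d", s)
    lig_atoms <- rbind(lig_atoms, la)
    rec_atoms <- rbind(rec_atoms, ra)
    lb <- site$lig$bonds; rb <- site$rec$bonds
    lb$i <- lb$i + off_l; lb$j <- lb$j + off_l
    rb$i <- rb$i + off_r; rb$j <- rb$j + off_r
    lig_bonds <- rbind(lig_bonds, lb)
    rec_bonds <- rbind(rec_bonds, rb)
  }
  list(receptor = molecule3d("receptor", rec_atoms, rec_bonds),
       ligand = molecule3d("ligand", lig_atoms, lig_bonds))
}
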