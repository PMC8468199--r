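# ---------------------------------------------------------------------------
# MM-PBSA-style binding-energy aggregation. Units are kJ/mol throughout
# (kcal/mol accepted on input with explicit conversion); coordinates in
# Angstrom; the Coulomb constant is 138.935458 kJ nm / (mol e^2).
# ---------------------------------------------------------------------------

KJ_PER_KCAL <- 4.184
COULOMB_KJ_NM <- 138.935458
ENERGY_COMPONENTS <- c("vdw", "elec", "polar_solv", "nonpolar_sasa")

#' Energy components of one entity at one snapshot
#' @param vdw,elec,polar_solv,nonpolar_sasa energies in kJ/mol (finite).
#' @param unit "kJ/mol" (default) or "kcal/mol" (converted).
#' @return named numeric vector of class `energy_components`.
#' @export
energy_components <- function(vdw, elec, polar_solv, nonpolar_sasa,
                              unit = c("kJ/mol", "kcal/mol")) {
  unit <- match.arg(unit)
  v <- c(vdw = vdw, elec = elec, polar_solv = polar_solv,
         nonpolar_sasa = nonpolar_sasa)
  if (!all(is.finite(v))) abort_pharm("all components must be finite",
                                      "invalid_energy")
  if (unit == "kcal/mol") v <- v * KJ_PER_KCAL
  structure(v, class = "energy_components")
}

#' One snapshot of complex / protein / ligand energies
#'
#' Either the three entity totals, or pre-differenced interaction components
#' (pass `interaction` only); the representation is flagged and must stay
#' consistent across a series.
#'
#' @param time_ps snapshot time in ps (>= 0).
#' @param complex,protein,ligand `energy_components` of each entity.
#' @param interaction pre-differenced `energy_components`.
#' @return object of class `snapshot_energies`.
#' @export
snapshot_energies <- function(time_ps, complex = NULL, protein = NULL,
                              ligand = NULL, interaction = NULL) {
  if (time_ps < 0) abort_pharm("time must be non-negative", "invalid_snapshot")
  pre <- !is.null(interaction)
  if (pre && (!is.null(complex) || !is.null(protein) || !is.null(ligand)))
    abort_pharm("give either entity energies or pre-differenced interaction, not both",
                "mixed_representation")
  if (!pre && (is.null(complex) || is.null(protein) || is.null(ligand)))
    abort_pharm("need complex, protein and ligand energies", "invalid_snapshot")
  structure(list(time_ps = time_ps, complex = complex, protein = protein,
                 ligand = ligand, interaction = interaction,
                 differenced = pre),
            class = "snapshot_energies")
}

snapshot_components <- function(s) {
  if (s$differenced) unclass(s$interaction)
  else unclass(s$complex) - (unclass(s$protein) + unclass(s$ligand))
}

#' Binding free energy of one snapshot
#'
#' `G_complex - (G_protein + G_ligand)`, summed over the four components
#' (van der Waals, electrostatic, polar solvation, nonpolar/SASA).
#'
#' @param s a `snapshot_energies`.
#' @return kJ/mol.
#' @export
delta_g <- function(s) {
  stopifnot(inherits(s, "snapshot_energies"))
  sum(snapshot_components(s))
}

#' Row sum of component means
#' @param means an `energy_components` (or named numeric with the four
#'   components).
#' @return kJ/mol: vdw + elec + polar_solv + nonpolar_sasa.
#' @export
sum_components <- function(means) {
  v <- unclass(means)[ENERGY_COMPONENTS]
  if (anyNA(v)) abort_pharm("need all four components", "invalid_energy")
  sum(v)
}

#' Aggregate a snapshot series into a binding summary
#'
#' Means and standard deviations per component and for the per-snapshot
#' binding energy, over the snapshots whose time falls inside `window`.
#' The default window is the final 10 ns (10000 ps) of the series, the
#' conventional stable-tail protocol.
#'
#' @param series list of `snapshot_energies` (one representation).
#' @param window length-2 numeric (start, end) in ps, or NULL for the
#'   default tail window.
#' @param id label for reports.
#' @return object of class `binding_summary`: `component_mean`,
#'   `component_sd`, `dg_mean`, `dg_sd`, `n`.
#' @export
summarize_snapshots <- function(series, window = NULL, id = "system") {
  stopifnot(length(series) >= 1)
  if (length(unique(vapply(series, `[[`, logical(1), "differenced"))) != 1L)
    abort_pharm("snapshots mix representations", "mixed_representation")
  times <- vapply(series, `[[`, numeric(1), "time_ps")
  if (is.null(window)) window <- c(max(times) - 10000, max(times))
  keep <- times >= window[1] & times <= window[2]
  if (sum(keep) < 2)
    abort_pharm("need >= 2 snapshots inside the window", "empty_window")
  comp <- t(vapply(series[keep], snapshot_components,
                   numeric(length(ENERGY_COMPONENTS))))
  colnames(comp) <- ENERGY_COMPONENTS
  dg <- rowSums(comp)
  structure(list(id = id,
                 component_mean = colMeans(comp),
                 component_sd = apply(comp, 2, stats::sd),
                 dg_mean = mean(dg), dg_sd = stats::sd(dg),
                 n = sum(keep)),
            class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, ...) {
  cat(sprintf("<binding_summary> %s (n=%d): dG = %.2f +/- %.2f kJ/mol\n",
              x$id, x$n, x$dg_mean, x$dg_sd))
  m <- x$component_mean; s <- x$component_sd
  for (k in ENERGY_COMPONENTS)
    cat(sprintf("  %-14s %9.2f +/- %.2f\n", k, m[[k]], s[[k]]))
  invisible(x)
}

#' Pairwise Lennard-Jones and Coulomb energies
#'
#' 12-6 Lennard-Jones and Coulomb sums over atom pairs within the cutoff,
#' with Lorentz-Berthelot combination (arithmetic sigma, geometric epsilon).
#' Pairs separated by one or two bonds (1-2 and 1-3) are excluded.
#'
#' @param xyz n x 3 coordinates in Angstrom.
#' @param charge per-atom partial charges in e.
#' @param sigma per-atom LJ sigma in Angstrom.
#' @param epsilon per-atom LJ epsilon in kJ/mol.
#' @param cutoff pair cutoff in Angstrom (default Inf).
#' @param bonds optional data.frame (i, j) defining the exclusion topology.
#' @return list with `vdw` and `elec` in kJ/mol.
#' @export
lj_coulomb_energy <- function(xyz, charge, sigma, epsilon, cutoff = Inf,
                              bonds = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(charge) != n || length(sigma) != n || length(epsilon) != n)
    abort_pharm("charge/sigma/epsilon must cover all atoms", "missing_params")
  if (any(sigma < 0) || any(epsilon < 0))
    abort_pharm("sigma and epsilon must be >= 0", "invalid_params")
  if (n < 2) return(list(vdw = 0, elec = 0))
  excl <- matrix(FALSE, n, n)
  if (!is.null(bonds) && nrow(bonds)) {
    adj <- vector("list", n)
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      excl[i, j] <- excl[j, i] <- TRUE            # 1-2
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    for (m in seq_len(n)) {
      nb <- adj[[m]]
      if (length(nb) > 1) for (a in nb) for (b in nb)
        if (a != b) excl[a, b] <- excl[b, a] <- TRUE   # 1-3
    }
  }
  vdw <- 0; elec <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (excl[i, j]) next
    r <- vnorm(xyz[i, ] - xyz[j, ])
    if (r > cutoff) next
    sij <- (sigma[i] + sigma[j]) / 2
    eij <- sqrt(epsilon[i] * epsilon[j])
    if (eij > 0 && sij > 0) {
      sr6 <- (sij / r)^6
      vdw <- vdw + 4 * eij * (sr6^2 - sr6)
    }
    elec <- elec + COULOMB_KJ_NM * charge[i] * charge[j] / (r / 10)
  }
  list(vdw = vdw, elec = elec)
}

#' Nonpolar solvation model parameters
#' @param gamma surface tension in kJ/mol/A^2 (default 0.0226778, the
#'   common g_mmpbsa-style convention).
#' @param offset constant b in kJ/mol (default 3.84928).
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points quadrature points per atom (>= 100; default 960).
#' @return list of class `nonpolar_model`.
#' @export
nonpolar_model <- function(gamma = 0.0226778, offset = 3.84928,
                           probe = 1.4, n_points = 960L) {
  if (n_points < 100) abort_pharm("need >= 100 quadrature points",
                                  "invalid_model")
  structure(list(gamma = gamma, offset = offset, probe = probe,
                 n_points = as.integer(n_points)),
            class = "nonpolar_model")
}

# deterministic Fibonacci-spiral unit sphere points
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley quadrature)
#'
#' Per-atom and total SASA with a deterministic Fibonacci point set, plus
#' the nonpolar energy gamma * SASA + b.
#'
#' @param xyz n x 3 coordinates in Angstrom.
#' @param radii per-atom radii in Angstrom (> 0).
#' @param model a `nonpolar_model`.
#' @return list: `per_atom` (A^2), `total` (A^2), `nonpolar_energy` (kJ/mol).
#' @export
sasa <- function(xyz, radii, model = nonpolar_model()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(radii) != n || any(radii <= 0))
    abort_pharm("positive radius needed per atom", "invalid_params")
  pts <- fibonacci_sphere(model$n_points)
  ext <- radii + model$probe
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    p <- pts * ext[i] + matrix(xyz[i, ], model$n_points, 3, byrow = TRUE)
    acc <- rep(TRUE, model$n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- vnorm(xyz[i, ] - xyz[j, ])
      if (dij >= ext[i] + ext[j]) next
      d2 <- colSums((t(p) - xyz[j, ])^2)
      acc <- acc & d2 > ext[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * ext[i]^2 * mean(acc)
  }
  total <- sum(per_atom)
  list(per_atom = per_atom, total = total,
       nonpolar_energy = model$gamma * total + model$offset)
}

#' Rank candidates against reference inhibitors
#'
#' Sorted ascending by mean binding energy (more negative = better), stable
#' input-order tie-break. Every candidate is flagged better/worse than each
#' reference; the headline `selected` flag marks candidates better than the
#' primary (first) reference, reported alongside the per-reference flags so
#' borderline cases (better than one reference, worse than another) stay
#' visible.
#'
#' @param summaries list of `binding_summary`.
#' @param reference_ids character ids of the reference systems; the first is
#'   the primary selection gate.
#' @return data.frame: id, dg_mean, dg_sd, n, is_reference, one
#'   `better_than_<ref>` column per reference, `selected`.
#' @export
rank_candidates <- function(summaries, reference_ids) {
  ids <- vapply(summaries, `[[`, "", "id")
  missing <- setdiff(reference_ids, ids)
  if (length(missing))
    abort_pharm(paste("missing reference(s):", paste(missing, collapse = ", ")),
                "missing_reference")
  dg <- vapply(summaries, `[[`, numeric(1), "dg_mean")
  out <- data.frame(id = ids, dg_mean = dg,
                    dg_sd = vapply(summaries, `[[`, numeric(1), "dg_sd"),
                    n = vapply(summaries, `[[`, numeric(1), "n"),
                    is_reference = ids %in% reference_ids)
  for (r in reference_ids)
    out[[paste0("better_than_", r)]] <- dg < dg[match(r, ids)]
  out$selected <- !out$is_reference &
    out[[paste0("better_than_", reference_ids[1])]]
  out[order(out$dg_mean), ]
}

#' Read a snapshot energy table (TSV)
#'
#' Columns: `time_ps`, `entity` (complex/protein/ligand, or "interaction"
#' for pre-differenced tables), `vdw`, `elec`, `polar_solv`,
#' `nonpolar_sasa`.
#'
#' @param path TSV path.
#' @param unit input energy unit.
#' @return list of `snapshot_energies`.
#' @export
read_snapshot_table <- function(path, unit = "kJ/mol") {
  tb <- utils::read.delim(path)
  mk <- function(row) energy_components(row$vdw, row$elec, row$polar_solv,
                                        row$nonpolar_sasa, unit = unit)
  out <- lapply(split(tb, tb$time_ps), function(g) {
    if ("interaction" %in% g$entity)
      snapshot_energies(g$time_ps[1],
                        interaction = mk(g[g$entity == "interaction", ]))
    else
      snapshot_energies(g$time_ps[1],
                        complex = mk(g[g$entity == "complex", ]),
                        protein = mk(g[g$entity == "protein", ]),
                        ligand = mk(g[g$entity == "ligand", ]))
  })
  out[order(vapply(out, `[[`, numeric(1), "time_ps"))]
}

#' Write binding summaries as a component table (TSV)
#'
#' One row per system: component means +/- SDs and the binding energy, in
#' kJ/mol.
#' @param summaries list of `binding_summary`.
#' @param path optional output path.
#' @return data.frame.
#' @export
binding_report <- function(summaries, path = NULL) {
  fmt <- function(m, s) sprintf("%.2f +/- %.2f", m, s)
  rows <- lapply(summaries, function(x) data.frame(
    id = x$id,
    vdw = fmt(x$component_mean[["vdw"]], x$component_sd[["vdw"]]),
    elec = fmt(x$component_mean[["elec"]], x$component_sd[["elec"]]),
    polar_solv = fmt(x$component_mean[["polar_solv"]],
                     x$component_sd[["polar_solv"]]),
    nonpolar_sasa = fmt(x$component_mean[["nonpolar_sasa"]],
                        x$component_sd[["nonpolar_sasa"]]),
    dg_bind = fmt(x$dg_mean, x$dg_sd)))
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
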