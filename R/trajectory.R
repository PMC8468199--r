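# ---------------------------------------------------------------------------
# Rigid-body superposition and ensemble stability analysis. Internal length
# unit is nm (the reporting convention for MD observables); Angstrom input
# is converted on construction.
# ---------------------------------------------------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation minimizing the RMSD of `P` onto
#' `Q`. Reflections are corrected: the returned rotation always has
#' determinant +1, even for mirror-image point sets.
#'
#' @param P,Q n x 3 coordinate matrices (same n >= 3).
#' @return object of class `superposition`: `rotation` (3x3), `translation`
#'   (so that `P %*% t(rotation) + translation` approximates `Q`), `rmsd`,
#'   and `degenerate` (TRUE when the point set is collinear so the in-plane
#'   rotation is not unique).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3)
    abort_pharm("kabsch needs two equal-size n x 3 matrices", "invalid_input")
  n <- nrow(P)
  if (n < 1) abort_pharm("empty point sets", "invalid_input")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(sum((moved - Qc)^2) / n)
  degenerate <- n >= 3 && sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp),
                 rmsd = rmsd, degenerate = degenerate),
            class = "superposition")
}

apply_superposition <- function(sp, P)
  sweep(as.matrix(P) %*% t(sp$rotation), 2, -sp$translation)

#' Construct a trajectory
#'
#' @param frames list of n x 3 coordinate matrices (constant atom count), or
#'   a 3-d array (frames x atoms x 3).
#' @param times frame times in ps, strictly increasing.
#' @param labels data.frame with one row per atom; optional columns
#'   `name` (atom name), `backbone` (logical), `resid` (integer).
#' @param unit "nm" or "angstrom" (converted to nm).
#' @return object of class `trajectory3d`.
#' @export
trajectory3d <- function(frames, times = NULL, labels = NULL,
                         unit = c("nm", "angstrom")) {
  unit <- match.arg(unit)
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[1]), function(i) frames[i, , ])
  stopifnot(is.list(frames), length(frames) >= 1)
  nat <- nrow(frames[[1]])
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != nat || ncol(f) != 3)
      abort_pharm("constant atom count (n x 3) required across frames",
                  "invalid_trajectory")
    if (unit == "angstrom") f / 10 else f
  })
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames) || any(diff(times) <= 0))
    abort_pharm("frame times must be strictly increasing, one per frame",
                "invalid_trajectory")
  if (is.null(labels)) labels <- data.frame(name = rep("CA", nat),
                                            backbone = TRUE,
                                            resid = seq_len(nat))
  if (is.null(labels$backbone))
    labels$backbone <- labels$name %in% c("N", "CA", "C")
  if (is.null(labels$resid)) labels$resid <- seq_len(nat)
  structure(list(frames = frames, times = as.numeric(times), labels = labels),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("<trajectory3d> %d frames x %d atoms, t = %g..%g ps\n",
              length(x$frames), nrow(x$frames[[1]]),
              min(x$times), max(x$times)))
  invisible(x)
}

select_atoms <- function(traj, selection) {
  idx <- switch(selection,
    backbone = which(traj$labels$backbone),
    all = seq_len(nrow(traj$labels)),
    if (is.numeric(selection)) as.integer(selection)
    else abort_pharm("unknown selection", "invalid_selection"))
  if (!length(idx)) abort_pharm("empty atom selection", "empty_selection")
  idx
}

#' Per-frame RMSD series after superposition
#'
#' Each frame's selected atoms are rigidly superposed onto the reference
#' frame's selection before the RMSD is taken.
#'
#' @param traj a `trajectory3d`.
#' @param reference reference frame index (default 1).
#' @param selection "backbone" (default), "all", or atom indices.
#' @return data.frame with columns `time_ps`, `rmsd_nm`.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = "backbone") {
  idx <- select_atoms(traj, selection)
  ref <- traj$frames[[reference]][idx, , drop = FALSE]
  vals <- vapply(traj$frames, function(f)
    kabsch(f[idx, , drop = FALSE], ref)$rmsd, numeric(1))
  data.frame(time_ps = traj$times, rmsd_nm = vals)
}

#' Tail average of an RMSD series
#'
#' @param series data.frame from [rmsd_series()] (or numeric vector).
#' @param from_time include frames with time >= `from_time` (ps); default 0.
#' @return mean RMSD in nm over the tail.
#' @export
average_rmsd <- function(series, from_time = 0) {
  if (is.numeric(series)) return(mean(series))
  keep <- series$time_ps >= from_time
  if (!any(keep)) abort_pharm("no frames at/after from_time", "empty_window")
  mean(series$rmsd_nm[keep])
}

#' Per-residue RMSF about the time-mean structure
#'
#' All frames are superposed (two passes: first onto the reference frame,
#' then onto the resulting mean structure) and the per-atom root-mean-square
#' fluctuation about the time mean is aggregated per residue by averaging
#' over that residue's selected atoms.
#'
#' @param traj a `trajectory3d` with >= 2 frames.
#' @param selection as in [rmsd_series()].
#' @return data.frame with columns `resid`, `rmsf_nm`; per-atom values are
#'   kept in attribute `per_atom`.
#' @export
rmsf <- function(traj, selection = "backbone") {
  if (length(traj$frames) < 2)
    abort_pharm("rmsf needs >= 2 frames", "too_few_frames")
  idx <- select_atoms(traj, selection)
  coords <- lapply(traj$frames, function(f) f[idx, , drop = FALSE])
  ref <- coords[[1]]
  for (pass in 1:2) {
    aligned <- lapply(coords, function(f) apply_superposition(kabsch(f, ref), f))
    ref <- Reduce(`+`, aligned) / length(aligned)
  }
  mean_xyz <- ref
  dev2 <- Reduce(`+`, lapply(aligned, function(f) rowSums((f - mean_xyz)^2)))
  per_atom <- sqrt(dev2 / length(aligned))
  resid <- traj$labels$resid[idx]
  agg <- tapply(per_atom, resid, mean)
  out <- data.frame(resid = as.integer(names(agg)), rmsf_nm = as.numeric(agg))
  attr(out, "per_atom") <- per_atom
  out
}

#' Assess trajectory stability against a threshold
#'
#' A system counts as stable when the tail-average RMSD and every residue
#' RMSF are strictly below the threshold (the conventional 0.3 nm criterion).
#'
#' @param rmsd_series data.frame from [rmsd_series()].
#' @param rmsf_values data.frame from [rmsf()].
#' @param threshold nm, default 0.3.
#' @param from_time tail start for the RMSD average (ps).
#' @return list with `stable` (logical), `tail_rmsd_nm`, and
#'   `offending_residues` (resid with RMSF >= threshold).
#' @export
stability_assess <- function(rmsd_series, rmsf_values, threshold = 0.3,
                             from_time = 0) {
  if (!nrow(rmsd_series)) abort_pharm("empty RMSD series", "empty_input")
  tail_rmsd <- average_rmsd(rmsd_series, from_time)
  bad <- rmsf_values$resid[rmsf_values$rmsf_nm >= threshold]
  list(stable = tail_rmsd < threshold && length(bad) == 0L,
       tail_rmsd_nm = tail_rmsd,
       offending_residues = as.integer(bad))
}

#' Read a plain XYZ trajectory
#'
#' Multi-frame XYZ: each frame is "n / comment / n atom lines". Coordinates
#' are taken as Angstrom unless `unit` says otherwise.
#' @param path file path.
#' @param times optional frame times in ps.
#' @param unit input unit.
#' @return `trajectory3d`.
#' @export
read_xyz_trajectory <- function(path, times = NULL, unit = "angstrom") {
  lines <- readLines(path)
  frames <- list(); pos <- 1L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- as.integer(trimws(lines[pos]))
    block <- lines[(pos + 2L):(pos + 1L + n)]
    tok <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(tok[, 2:4]), ncol = 3)
    pos <- pos + 2L + n
  }
  trajectory3d(frames, times = times, unit = unit)
}

#' Write an RMSD/RMSF series as TSV
#' @param x data.frame (e.g. from [rmsd_series()] or [rmsf()]).
#' @param path output file.
#' @export
write_series_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#' @param path PDB with MODEL records.
#' @param times optional times (ps).
#' @return `trajectory3d` (coordinates converted from Angstrom to nm);
#'   backbone flags derived from atom names N, CA, C.
#' @export
read_pdb_trajectory <- function(path, times = NULL) {
  need_pkg("bio3d")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  nat <- nrow(pdb$atom)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  labels <- data.frame(name = pdb$atom$elety,
                       backbone = pdb$atom$elety %in% c("N", "CA", "C"),
                       resid = pdb$atom$resno)
  trajectory3d(frames, times = times, labels = labels, unit = "angstrom")
}
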