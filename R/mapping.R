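# ---------------------------------------------------------------------------
# Ligand-to-hypothesis mapping: kind-respecting correspondences found as
# cliques on a distance-compatibility graph, scored after least-squares
# superposition with fit = sum over matched features of max(0, 1-(d/t)^2).
# ---------------------------------------------------------------------------

# All cliques (not only maximal) of size >= min_size on the correspondence
# graph, with deterministic node ordering. Node count is small (product of
# per-kind feature counts), so exhaustive extension is fine.
all_cliques <- function(adj_mat, min_size) {
  n <- nrow(adj_mat)
  out <- list()
  extend <- function(clique, candidates) {
    if (length(clique) >= min_size)
      out[[length(out) + 1L]] <<- clique
    for (v in candidates) {
      if (all(adj_mat[v, clique]))
        extend(c(clique, v), candidates[candidates > v])
    }
  }
  for (v in seq_len(n)) extend(v, seq_len(n)[seq_len(n) > v])
  out
}

#' Map ligand features onto a hypothesis
#'
#' Finds the kind-respecting feature correspondence maximizing the fit value
#' after least-squares rigid superposition of the matched centroids. A
#' correspondence is admissible when every matched pair shares its feature
#' kind and all pairwise centroid distances agree within `match_tolerance`
#' (clique condition); at least `max_fit - allow_omit` features must match.
#'
#' Fit of a correspondence: sum over matched hypothesis features of
#' `max(0, 1 - (d_i / t_i)^2)` where `d_i` is the post-superposition
#' deviation and `t_i` the feature's tolerance radius.
#'
#' @param h a `pharm_hypothesis` with >= 1 feature.
#' @param ligand_features a `feature_set` (or list of `pharm_feature`).
#' @param allow_omit number of hypothesis features that may stay unmatched
#'   (must be < max_fit).
#' @param match_tolerance Angstrom; pairwise-distance compatibility window
#'   used during correspondence search (default 1.0).
#' @return a `mapping_result` (pairs, omitted_count, deviations, fit,
#'   rotation, translation) or NULL when no admissible correspondence exists.
#' @export
map_conformer <- function(h, ligand_features, allow_omit = 0L,
                          match_tolerance = 1.0) {
  stopifnot(inherits(h, "pharm_hypothesis"))
  if (h$max_fit == 0L)
    abort_pharm("cannot map onto an empty hypothesis", "empty_hypothesis")
  if (allow_omit >= h$max_fit)
    abort_pharm("allow_omit must be < max_fit", "invalid_input")
  lf <- unclass(ligand_features)
  if (!length(lf)) return(NULL)
  hk <- feature_kinds(h$features); lk <- feature_kinds(lf)
  hxy <- feature_coords(h$features); lxy <- feature_coords(lf)
  tol_r <- feature_tolerances(h$features)
  nodes <- which(outer(hk, lk, "=="), arr.ind = TRUE)   # (hyp idx, lig idx)
  if (!nrow(nodes)) return(NULL)
  ord <- order(nodes[, 1], nodes[, 2])
  nodes <- nodes[ord, , drop = FALSE]
  nn <- nrow(nodes)
  min_size <- h$max_fit - allow_omit
  if (nn < min_size) return(NULL)
  dh <- coord_dist(hxy); dl <- coord_dist(lxy)
  adj <- matrix(FALSE, nn, nn)
  for (a in seq_len(nn)) for (b in seq_len(nn)) {
    if (a >= b) next
    ha <- nodes[a, 1]; la <- nodes[a, 2]
    hb <- nodes[b, 1]; lb <- nodes[b, 2]
    if (ha == hb || la == lb) next
    adj[a, b] <- adj[b, a] <-
      abs(dh[ha, hb] - dl[la, lb]) <= match_tolerance
  }
  cliques <- all_cliques(adj, min_size)
  if (h$max_fit == 1L && allow_omit == 0L)  # single-feature hypothesis
    cliques <- c(cliques, as.list(seq_len(nn)))
  if (!length(cliques)) return(NULL)
  best <- NULL
  for (cl in cliques) {
    hp <- nodes[cl, 1]; lp <- nodes[cl, 2]
    if (length(cl) == 1L && min_size > 1L) next
    sp <- kabsch(lxy[lp, , drop = FALSE], hxy[hp, , drop = FALSE])
    moved <- apply_superposition(sp, lxy[lp, , drop = FALSE])
    dev <- sqrt(rowSums((moved - hxy[hp, , drop = FALSE])^2))
    fit <- sum(pmax(0, 1 - (dev / tol_r[hp])^2))
    omitted <- h$max_fit - length(cl)
    key <- paste(sprintf("%03d-%03d", hp, lp), collapse = ";")
    cand <- list(pairs = cbind(hypothesis = hp, ligand = lp),
                 omitted_count = omitted, deviations = dev, fit = fit,
                 rotation = sp$rotation, translation = sp$translation,
                 key = key)
    if (is.null(best) ||
        fit > best$fit + 1e-12 ||
        (abs(fit - best$fit) <= 1e-12 &&
         (omitted < best$omitted_count ||
          (omitted == best$omitted_count && key < best$key))))
      best <- cand
  }
  if (is.null(best)) return(NULL)
  best$key <- NULL
  best$hypothesis_id <- h$id
  class(best) <- "mapping_result"
  best
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("<mapping_result> %d matched, %d omitted, fit = %.3f\n",
              nrow(x$pairs), x$omitted_count, x$fit))
  invisible(x)
}

# a library compound is a molecule3d, a feature_set, or a list of
# feature_set conformers; normalize to a list of feature sets
compound_conformers <- function(cmpd, rules) {
  if (inherits(cmpd, "molecule3d")) list(perceive_features(cmpd, rules))
  else if (inherits(cmpd, "feature_set")) list(cmpd)
  else if (is.list(cmpd)) cmpd
  else abort_pharm("unsupported library entry", "invalid_input")
}

compound_id <- function(cmpd, fallback) {
  if (inherits(cmpd, "molecule3d")) cmpd$id
  else attr(if (inherits(cmpd, "feature_set")) cmpd else cmpd[[1]], "id") %||%
    fallback
}

#' Screen a compound library against a hypothesis
#'
#' One record per compound, best fit over its conformers; a compound passes
#' when any mapping exists at the configured `allow_omit` (no fit threshold
#' by default).
#'
#' @param h a `pharm_hypothesis`.
#' @param library list of compounds (`molecule3d`, `feature_set`, or lists
#'   of conformer feature sets).
#' @param allow_omit,match_tolerance as in [map_conformer()].
#' @param rules perception rules for raw molecules.
#' @param min_fit optional fit threshold (default none).
#' @return data.frame (class `screen_records`): `id`, `fit`, `hypothesis_id`,
#'   `passed`, in input order.
#' @export
screen_library <- function(h, library, allow_omit = 0L, match_tolerance = 1.0,
                           rules = default_feature_rules(), min_fit = NULL) {
  if (!length(library)) abort_pharm("empty library", "empty_input")
  rows <- lapply(seq_along(library), function(k) {
    confs <- compound_conformers(library[[k]], rules)
    best <- NULL
    for (fs in confs) {
      m <- map_conformer(h, fs, allow_omit, match_tolerance)
      if (!is.null(m) && (is.null(best) || m$fit > best$fit)) best <- m
    }
    passed <- !is.null(best) &&
      (is.null(min_fit) || best$fit >= min_fit)
    data.frame(id = compound_id(library[[k]], paste0("cmpd", k)),
               fit = if (is.null(best)) NA_real_ else best$fit,
               hypothesis_id = h$id, passed = passed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("screen_records", class(out))
  out
}
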