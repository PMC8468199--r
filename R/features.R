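#' Pharmacophore feature kinds
#'
#' Closed vocabulary: HBD (hydrogen-bond donor), HBA (acceptor), HYP
#' (hydrophobic), RA (ring aromatic), PI (positive ionizable), NI (negative
#' ionizable).
#' @export
FEATURE_KINDS <- c("HBD", "HBA", "HYP", "RA", "PI", "NI")

# default tolerance radii (Angstrom): common pharmacophore-tool defaults,
# configurable per rule or per call
DEFAULT_TOLERANCE <- c(HBD = 1.6, HBA = 1.6, HYP = 1.7, RA = 1.6,
                       PI = 1.6, NI = 1.6)

#' Parse a feature-kind token
#'
#' The legacy token "HYA" (seen in some published feature tables) is accepted
#' as hydrogen-bond acceptor with a warning rather than silently normalized.
#'
#' @param x character vector of tokens.
#' @return character vector of canonical kinds.
#' @export
parse_feature_kind <- function(x) {
  x <- toupper(trimws(x))
  hya <- x == "HYA"
  if (any(hya)) {
    warning("token 'HYA' interpreted as hydrogen-bond acceptor 'HBA'")
    x[hya] <- "HBA"
  }
  bad <- setdiff(unique(x), FEATURE_KINDS)
  if (length(bad))
    abort_pharm(paste0("unknown feature kind(s): ", paste(bad, collapse = ", "),
                       " (vocabulary: ", paste(FEATURE_KINDS, collapse = ", "), ")"),
                "unknown_feature_kind")
  x
}

#' Construct a pharmacophore feature
#'
#' @param kind one of [FEATURE_KINDS].
#' @param centroid length-3 numeric, Angstrom.
#' @param tolerance sphere radius in Angstrom (> 0).
#' @param direction optional unit vector.
#' @param source_atoms integer indices into the originating molecule (may be
#'   empty for receptor-derived features).
#' @return object of class `pharm_feature`.
#' @export
pharm_feature <- function(kind, centroid, tolerance = DEFAULT_TOLERANCE[[kind]],
                          direction = NULL, source_atoms = integer()) {
  kind <- parse_feature_kind(kind)
  stopifnot(length(centroid) == 3, all(is.finite(centroid)))
  if (!is.finite(tolerance) || tolerance <= 0)
    abort_pharm("feature tolerance must be > 0", "invalid_feature")
  if (!is.null(direction)) {
    if (abs(vnorm(direction) - 1) > 1e-6)
      abort_pharm("feature direction must have unit norm (1e-6)", "invalid_feature")
  }
  structure(list(kind = kind, centroid = as.numeric(centroid),
                 tolerance = tolerance, direction = direction,
                 source_atoms = as.integer(source_atoms)),
            class = "pharm_feature")
}

feature_kinds <- function(features) vapply(features, `[[`, "", "kind")
feature_coords <- function(features)
  do.call(rbind, lapply(features, `[[`, "centroid"))
feature_tolerances <- function(features)
  vapply(features, `[[`, numeric(1), "tolerance")

#' Default feature-perception rule set
#'
#' Explicit, overridable SMARTS rules (the classic tools keep theirs
#' undisclosed): donors are O-H/N-H/S-H heavy atoms; acceptors are oxygens
#' and hydrogen-free nitrogens excluding amide and aniline-type N;
#' hydrophobes are contiguous groups of >= 3 apolar carbons plus halogens on
#' aromatic rings; ring-aromatic features sit at aromatic ring centroids;
#' positive ionizable covers protonatable amines, amidines/guanidines and
#' cationic nitrogens; negative ionizable covers carboxylic acids/
#' carboxylates and phosphates.
#'
#' @return data.frame with columns `pattern`, `kind`, `centroid_rule`
#'   (atom / ring-centroid / group-centroid), `min_group`, `tolerance`.
#' @export
default_feature_rules <- function() {
  r <- rbind(
    c("[#8]-[#1]",  "HBD", "atom", 1, NA),
    c("[#7]-[#1]",  "HBD", "atom", 1, NA),
    c("[#16]-[#1]", "HBD", "atom", 1, NA),
    c("[#8]",       "HBA", "atom", 1, NA),
    c("[#7;H0;!X4;!$([#7]-[#6]=[#8]);!$([#7]-c)]", "HBA", "atom", 1, NA),
    c("[C;!$([#6]~[#7,#8,#15,#16])]", "HYP", "group-centroid", 3, NA),
    c("[F,Cl,Br,I]c", "HYP", "atom", 1, NA),
    c("[a]",        "RA",  "ring-centroid", 1, NA),
    c("[#7;+]",     "PI",  "atom", 1, NA),
    c("[N;X3;!$([#7]-[#6]=[#8]);!$([#7]-c);!$([#7]~[#6]~[#7])]", "PI", "atom", 1, NA),
    c("[#6](=[#7])-[#7]", "PI", "group-centroid", 1, NA),
    c("[#6](=[#8])-[#8;H1,-]", "NI", "group-centroid", 1, NA),
    c("[#15](=[#8])-[#8]",     "NI", "group-centroid", 1, NA))
  rules <- data.frame(pattern = r[, 1], kind = r[, 2], centroid_rule = r[, 3],
                      min_group = as.integer(r[, 4]),
                      tolerance = as.numeric(r[, 5]))
  validate_feature_rules(rules)
}

validate_feature_rules <- function(rules) {
  stopifnot(is.data.frame(rules),
            all(c("pattern", "kind", "centroid_rule") %in% names(rules)))
  if (!nrow(rules)) abort_pharm("rule set is empty", "invalid_rules")
  rules$kind <- parse_feature_kind(rules$kind)
  if (is.null(rules$min_group)) rules$min_group <- 1L
  if (is.null(rules$tolerance)) rules$tolerance <- NA_real_
  bad <- setdiff(unique(rules$centroid_rule),
                 c("atom", "ring-centroid", "group-centroid"))
  if (length(bad))
    abort_pharm(paste("unknown centroid rule:", paste(bad, collapse = ", ")),
                "invalid_rules")
  # every pattern must parse; a failure is a rule error, not a silent skip
  for (p in rules$pattern) {
    ok <- tryCatch({ parse_smarts(p); TRUE }, error = function(e) e)
    if (!isTRUE(ok))
      abort_pharm(sprintf("rule pattern '%s' does not parse: %s",
                          p, conditionMessage(ok)), "rule_error")
  }
  attr(rules, "compiled") <- lapply(rules$pattern, parse_smarts)
  rules
}

#' Read a feature-rules file
#'
#' Plain-text TSV with columns `pattern`, `kind`, `centroid_rule` and
#' optionally `min_group`, `tolerance`.
#' @param path file path.
#' @return validated rules data.frame.
#' @export
read_feature_rules <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rules <- utils::read.delim(text = paste(lines, collapse = "\n"),
                             stringsAsFactors = FALSE)
  validate_feature_rules(rules)
}

#' Perceive pharmacophore features of a 3D molecule
#'
#' Applies the perception rule set to an explicit-hydrogen structure (missing
#' hydrogens are added with idealized geometry first). Features are
#' deduplicated on (kind, heavy source atoms); each feature's centroid is the
#' aggregate required by its rule: the first matched atom, the centroid of an
#' aromatic ring, or the centroid of a contiguous matched-atom group of at
#' least `min_group` atoms.
#'
#' @param mol a `molecule3d` with 3D coordinates.
#' @param rules a validated rules data.frame (default [default_feature_rules()]).
#' @param tolerances named numeric vector of per-kind tolerance radii in
#'   Angstrom (defaults 1.6, HYP 1.7).
#' @return list of `pharm_feature` (class `feature_set`), ordered by rule
#'   then by source atom indices (deterministic).
#' @export
perceive_features <- function(mol, rules = default_feature_rules(),
                              tolerances = DEFAULT_TOLERANCE) {
  if (!inherits(mol, "molecule3d"))
    abort_pharm("perceive_features needs a molecule3d", "invalid_molecule")
  xyz <- mol_xyz(mol)
  if (n_atoms(mol) > 1 && max(abs(xyz)) < 1e-9)
    abort_pharm("molecule has no 3D coordinates (all atoms at origin)",
                "coordinates_missing")
  if (is.null(attr(rules, "compiled"))) rules <- validate_feature_rules(rules)
  if (!any(mol$atoms$elem == "H") &&
      any(mol$atoms$elem %in% c("O", "N", "S", "C")))
    mol <- add_hydrogens(mol)
  xyz <- mol_xyz(mol)
  heavy <- mol$atoms$elem != "H"

  feats <- list()
  seen <- character()
  push <- function(kind, atoms_in_feature, centroid, tol) {
    src <- sort(unique(atoms_in_feature[heavy[atoms_in_feature]]))
    key <- paste(kind, paste(src, collapse = ","))
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    feats[[length(feats) + 1L]] <<-
      pharm_feature(kind, centroid, tol, source_atoms = src)
  }

  rings <- NULL
  compiled <- attr(rules, "compiled")
  for (k in seq_len(nrow(rules))) {
    kind <- rules$kind[k]
    tol <- if (is.finite(rules$tolerance[k])) rules$tolerance[k]
           else tolerances[[kind]]
    m <- smarts_match(mol, compiled[[k]])
    if (!nrow(m)) next
    cr <- rules$centroid_rule[k]
    if (cr == "atom") {
      for (r in seq_len(nrow(m)))
        push(kind, m[r, ], xyz[m[r, 1], ], tol)
    } else if (cr == "ring-centroid") {
      if (is.null(rings)) rings <- mol_rings(mol)
      matched <- unique(as.vector(m))
      for (ring in rings) {
        if (all(ring %in% matched) && all(mol$atoms$aromatic[ring]))
          push(kind, ring, colMeans(xyz[ring, , drop = FALSE]), tol)
      }
    } else {  # group-centroid: contiguous components of the matched-atom set
      matched <- sort(unique(as.vector(m)))
      matched <- matched[heavy[matched]]
      comp <- connected_components(matched, mol$graph$adj)
      for (grp in comp) {
        if (length(grp) < rules$min_group[k]) next
        push(kind, grp, colMeans(xyz[grp, , drop = FALSE]), tol)
      }
    }
  }
  structure(feats, class = "feature_set", id = mol$id)
}

connected_components <- function(nodes, adj) {
  nodes <- sort(nodes)
  remaining <- nodes
  comps <- list()
  inset <- logical(max(c(nodes, 1L)))
  inset[nodes] <- TRUE
  while (length(remaining)) {
    seed <- remaining[1]
    comp <- seed; frontier <- seed
    while (length(frontier)) {
      nb <- unique(unlist(adj[frontier]))
      nb <- nb[nb <= length(inset)]
      nb <- nb[inset[nb] & !(nb %in% comp)]
      comp <- c(comp, nb); frontier <- nb
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s: %d feature(s)\n", attr(x, "id") %||% "?",
              length(x)))
  if (length(x)) {
    tab <- table(factor(feature_kinds(x), levels = FEATURE_KINDS))
    cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Per-kind feature census over a set of molecules
#'
#' @param mols list of `molecule3d` (or ready `feature_set` objects).
#' @param rules perception rules.
#' @return data.frame of per-kind counts (one row per molecule) with
#'   attribute `common`: kinds present (count >= 1) in every molecule.
#' @export
feature_census <- function(mols, rules = default_feature_rules()) {
  if (!length(mols)) abort_pharm("feature_census needs >= 1 molecule",
                                 "empty_input")
  fsets <- lapply(mols, function(m)
    if (inherits(m, "feature_set")) m else perceive_features(m, rules))
  counts <- t(vapply(fsets, function(fs)
    as.integer(table(factor(feature_kinds(fs), levels = FEATURE_KINDS))),
    integer(length(FEATURE_KINDS))))
  colnames(counts) <- FEATURE_KINDS
  out <- as.data.frame(counts)
  out$id <- vapply(seq_along(fsets), function(i)
    attr(fsets[[i]], "id") %||% as.character(i), character(1))
  out <- out[, c("id", FEATURE_KINDS)]
  attr(out, "common") <- FEATURE_KINDS[colSums(counts >= 1L) == length(fsets)]
  out
}

#' Construct a pharmacophore hypothesis
#'
#' A typed, ordered set of features with a pairwise centroid distance table.
#' `max_fit` equals the number of features; the distance table is validated
#' to be symmetric, zero-diagonal and metric (triangle inequality to 1e-6).
#'
#' @param id character identifier.
#' @param features list of `pharm_feature`.
#' @param provenance "ligand_based" or "structure_based".
#' @param rank_score optional score (see [rank_score()]).
#' @param selectivity optional; NA means "not computed".
#' @return object of class `pharm_hypothesis`.
#' @export
pharm_hypothesis <- function(id, features, provenance = c("ligand_based",
                                                          "structure_based"),
                             rank_score = NA_real_, selectivity = NA_real_) {
  provenance <- match.arg(provenance)
  stopifnot(is.list(features))
  if (!all(vapply(features, inherits, logical(1), "pharm_feature")))
    abort_pharm("features must be pharm_feature objects", "invalid_hypothesis")
  dt <- if (length(features) >= 2) coord_dist(feature_coords(features))
        else matrix(0, length(features), length(features))
  h <- structure(list(id = id, features = features, distance_table = dt,
                      provenance = provenance, rank_score = rank_score,
                      selectivity = selectivity,
                      max_fit = length(features)),
                 class = "pharm_hypothesis")
  validate_hypothesis(h)
  h
}

validate_hypothesis <- function(h) {
  dt <- h$distance_table
  if (h$max_fit != length(h$features))
    abort_pharm("max_fit must equal feature count", "invalid_hypothesis")
  if (nrow(dt) >= 2) {
    if (max(abs(dt - t(dt))) > 1e-9 || any(abs(diag(dt)) > 1e-9))
      abort_pharm("distance table must be symmetric with zero diagonal",
                  "invalid_hypothesis")
    n <- nrow(dt)
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
      if (dt[i, j] > dt[i, k] + dt[k, j] + 1e-6)
        abort_pharm("distance table violates the triangle inequality",
                    "invalid_hypothesis")
  }
  invisible(h)
}

#' @export
print.pharm_hypothesis <- function(x, ...) {
  cat(sprintf("<pharm_hypothesis> %s (%s): %s; max_fit=%d, rank=%s\n",
              x$id, x$provenance,
              paste(feature_kinds(x$features), collapse = ", "),
              x$max_fit,
              ifelse(is.na(x$rank_score), "NA", format(x$rank_score))))
  invisible(x)
}

#' Interfeature distance table of a hypothesis
#'
#' @param h a `pharm_hypothesis` with >= 2 features.
#' @return symmetric matrix of pairwise centroid distances in Angstrom.
#' @export
interfeature_distance_table <- function(h) {
  stopifnot(inherits(h, "pharm_hypothesis"))
  if (length(h$features) < 2)
    abort_pharm("need >= 2 features for a distance table", "too_few_features")
  d <- coord_dist(feature_coords(h$features))
  dimnames(d) <- list(feature_kinds(h$features), feature_kinds(h$features))
  d
}

#' Serialize features or a hypothesis to JSON
#'
#' The schema carries kinds, centroids, tolerances, directions, source atoms,
#' provenance and the distance table; round-trips are lossless to 1e-6 A.
#' @param x a `feature_set` or `pharm_hypothesis`.
#' @param path output file.
#' @export
write_pharm_json <- function(x, path) {
  enc_feats <- function(fl) lapply(fl, function(f) list(
    kind = f$kind, centroid = f$centroid, tolerance = f$tolerance,
    direction = f$direction, source_atoms = f$source_atoms))
  obj <- if (inherits(x, "pharm_hypothesis")) {
    list(type = "hypothesis", id = x$id, provenance = x$provenance,
         rank_score = x$rank_score, selectivity = x$selectivity,
         max_fit = x$max_fit, features = enc_feats(x$features),
         distance_table = x$distance_table)
  } else if (inherits(x, "feature_set")) {
    list(type = "feature_set", id = attr(x, "id"),
         features = enc_feats(unclass(x)))
  } else abort_pharm("cannot serialize this object", "invalid_input")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read features or a hypothesis from JSON
#' @param path file written by [write_pharm_json()].
#' @return a `feature_set` or `pharm_hypothesis`.
#' @export
read_pharm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  dec_feats <- function(fl) lapply(fl, function(f)
    pharm_feature(f$kind, unlist(f$centroid), f$tolerance,
                  direction = if (!is.null(f$direction)) unlist(f$direction),
                  source_atoms = unlist(f$source_atoms) %||% integer()))
  if (identical(obj$type, "hypothesis")) {
    pharm_hypothesis(obj$id, dec_feats(obj$features), obj$provenance,
                     rank_score = obj$rank_score %||% NA_real_,
                     selectivity = obj$selectivity %||% NA_real_)
  } else {
    structure(dec_feats(obj$features), class = "feature_set", id = obj$id)
  }
}
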