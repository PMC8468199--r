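# ---------------------------------------------------------------------------
# Drug-likeness gating: rule-of-five properties, an atom-additive AlogP
# estimate (contribution table shipped under extdata for reproducibility),
# and a rule-based ADMET surrogate with user-override.
# ---------------------------------------------------------------------------

# fallback copy of inst/extdata/alogp_contributions.tsv (single source of
# truth is the shipped file; this keeps compute_properties usable on a
# source checkout)
ALOGP_FALLBACK <- c(
  C_ali = 0.1441, C_het = -0.2035, C_aro = 0.1581,
  N_amine = -1.0190, N_amide = -0.6027, N_aro = -0.3239, N_other = -0.5188,
  O_hydroxyl = -0.2893, O_carbonyl = -0.1526, O_ether = -0.2893,
  O_aro = 0.1552, O_anion = -0.3339,
  S_any = 0.6482, P_any = 0.8612,
  F_any = 0.4202, Cl_any = 0.6895, Br_any = 0.8456, I_any = 0.8857,
  H_on_C = 0.1230, H_on_het = -0.2677, other = 0.0)

alogp_table <- function() {
  path <- system.file("extdata", "alogp_contributions.tsv",
                      package = "pharmscreen")
  if (nzchar(path)) {
    tb <- utils::read.delim(path, comment.char = "#")
    stats::setNames(tb$contribution, tb$class)
  } else ALOGP_FALLBACK
}

alogp_class <- function(mol, i) {
  e <- mol$atoms$elem[i]
  nb <- mol$graph$adj[[i]]
  bo <- unlist(mol$graph$bond_order[[i]])
  nb_elem <- mol$atoms$elem[nb]
  switch(e,
    C = if (mol$atoms$aromatic[i]) "C_aro"
        else if (any(nb_elem %in% c("N", "O", "S", "P", "F", "Cl", "Br", "I")))
          "C_het" else "C_ali",
    N = if (mol$atoms$aromatic[i]) "N_aro"
        else if (any(vapply(seq_along(nb), function(t) {
            j <- nb[t]
            if (nb_elem[t] != "C" || bo[t] != 1L) return(FALSE)
            jb <- mol$graph$adj[[j]]; jo <- unlist(mol$graph$bond_order[[j]])
            any(mol$atoms$elem[jb] == "O" & jo == 2L)
          }, logical(1)))) "N_amide"
        else if (all(nb_elem %in% c("C", "H"))) "N_amine" else "N_other",
    O = if (mol$atoms$aromatic[i]) "O_aro"
        else if (mol$atoms$charge[i] < 0) "O_anion"
        else if (mol$graph$nH[i] > 0) "O_hydroxyl"
        else if (any(bo == 2L)) "O_carbonyl" else "O_ether",
    S = "S_any", P = "P_any",
    F = "F_any", Cl = "Cl_any", Br = "Br_any", I = "I_any",
    H = if ((if (length(nb)) nb_elem[1] else "C") == "C") "H_on_C"
        else "H_on_het",
    "other")
}

#' Atom-additive AlogP estimate
#'
#' Sum of per-atom contributions over a small class scheme (aliphatic /
#' aromatic / hetero-substituted carbon, nitrogen and oxygen environments,
#' halogens, hydrogens on carbon vs heteroatoms). The contribution table is
#' shipped as plain text under `extdata/alogp_contributions.tsv`.
#'
#' @param mol a `molecule3d` (hydrogens added if missing).
#' @return dimensionless AlogP estimate.
#' @export
alogp <- function(mol) {
  if (!any(mol$atoms$elem == "H")) mol <- add_hydrogens(mol)
  tab <- alogp_table()
  cls <- vapply(seq_len(n_atoms(mol)), alogp_class, "", mol = mol)
  contrib <- tab[cls]
  contrib[is.na(contrib)] <- tab[["other"]]
  sum(contrib)
}

#' Molecular properties used by the rule-of-five gate
#'
#' Weight from standard atomic masses (hydrogens made explicit first), HBD
#' and HBA counted with the same donor/acceptor atom rules feature
#' perception uses, and the atom-additive [alogp()] estimate.
#'
#' @param mol a `molecule3d`.
#' @return object of class `molecular_properties`: `weight` (Da), `alogp`,
#'   `hbd`, `hba`.
#' @export
compute_properties <- function(mol) {
  stopifnot(inherits(mol, "molecule3d"))
  if (!any(mol$atoms$elem == "H") &&
      any(mol$atoms$elem %in% c("C", "N", "O", "S")))
    mol <- add_hydrogens(mol)
  structure(list(weight = molecular_weight(mol), alogp = alogp(mol),
                 hbd = length(donor_atoms(mol)),
                 hba = length(acceptor_atoms(mol)),
                 id = mol$id),
            class = "molecular_properties")
}

filter_verdict <- function(failed) {
  structure(list(pass = nrow(failed) == 0L, failed_rules = failed),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  if (x$pass) cat("<filter_verdict> PASS\n")
  else {
    cat("<filter_verdict> FAIL:\n")
    print(x$failed_rules, row.names = FALSE)
  }
  invisible(x)
}

#' Rule-of-five filter (extended weight bound)
#'
#' Pass requires AlogP <= 5, HBD <= 5, HBA <= 10, and weight <= `mw_max`;
#' all boundaries inclusive. The weight bound defaults to 600 Da, the
#' extended cutoff used when screening natural-product libraries.
#'
#' @param p a `molecular_properties` (or a `molecule3d`).
#' @param mw_max weight bound in Da (default 600).
#' @return `filter_verdict` with failed rules and observed vs threshold.
#' @export
ro5_filter <- function(p, mw_max = 600) {
  if (inherits(p, "molecule3d")) p <- compute_properties(p)
  checks <- data.frame(
    rule = c("AlogP <= 5", "HBD <= 5", "HBA <= 10",
             sprintf("weight <= %g Da", mw_max)),
    observed = c(p$alogp, p$hbd, p$hba, p$weight),
    threshold = c(5, 5, 10, mw_max))
  filter_verdict(checks[checks$observed > checks$threshold, ])
}

#' ADMET level container
#'
#' Level semantics follow the convention of the screening tools this
#' surrogate replaces: absorption 0 = good; solubility and BBB level 3 =
#' good / undefined-low, the values required by the gate.
#'
#' @param absorption,solubility,bbb small non-negative integer levels.
#' @param cyp2d6,hepatotoxicity logical flags (TRUE = predicted liability).
#' @return object of class `admet_levels`.
#' @export
admet_levels <- function(absorption, solubility, bbb, cyp2d6,
                         hepatotoxicity) {
  vals <- list(absorption = absorption, solubility = solubility, bbb = bbb)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (is.null(v) || is.na(v) || v < 0 || v != round(v) || v > 10)
      abort_pharm(sprintf("ADMET level '%s' must be a small non-negative integer", nm),
                  "invalid_admet")
  }
  if (is.null(cyp2d6) || is.null(hepatotoxicity) ||
      is.na(cyp2d6) || is.na(hepatotoxicity))
    abort_pharm("CYP2D6 and hepatotoxicity flags are required", "invalid_admet")
  structure(list(absorption = as.integer(absorption),
                 solubility = as.integer(solubility), bbb = as.integer(bbb),
                 cyp2d6 = as.logical(cyp2d6),
                 hepatotoxicity = as.logical(hepatotoxicity)),
            class = "admet_levels")
}

#' ADMET gate
#'
#' Pass requires absorption level 0, solubility level 3, BBB level 3, and
#' FALSE for both the CYP2D6 and hepatotoxicity flags.
#'
#' @param levels an `admet_levels`.
#' @return `filter_verdict`.
#' @export
admet_gate <- function(levels) {
  if (!inherits(levels, "admet_levels"))
    abort_pharm("admet_gate needs an admet_levels object", "invalid_admet")
  checks <- data.frame(
    rule = c("absorption = 0", "solubility = 3", "BBB = 3",
             "CYP2D6 = false", "hepatotoxicity = false"),
    observed = c(levels$absorption, levels$solubility, levels$bbb,
                 as.integer(levels$cyp2d6), as.integer(levels$hepatotoxicity)),
    threshold = c(0, 3, 3, 0, 0))
  filter_verdict(checks[checks$observed != checks$threshold, ])
}

#' Rule-based surrogate ADMET predictor
#'
#' A deterministic stand-in for external ADMET predictors, mapping the
#' rule-of-five descriptors to levels: absorption worsens with rule
#' violations; solubility level comes from AlogP bands (3 = good for
#' moderately polar molecules); BBB is set to the low/undefined level 3 for
#' polar or heavy molecules; the CYP2D6 flag fires for lipophilic basic
#' amines, hepatotoxicity for extreme lipophilicity or weight. User-supplied
#' levels (a data.frame with column `id` and the five level columns) take
#' precedence verbatim.
#'
#' @param p a `molecular_properties` (or `molecule3d`).
#' @param has_basic_amine optional logical descriptor (default FALSE) used
#'   by the CYP2D6 rule.
#' @param overrides optional data.frame of user-supplied levels keyed by
#'   `id` (e.g. read from a TSV).
#' @return `admet_levels`.
#' @export
surrogate_admet <- function(p, has_basic_amine = FALSE, overrides = NULL) {
  if (inherits(p, "molecule3d")) {
    has_basic_amine <- any(feature_kinds(perceive_features(p)) == "PI")
    p <- compute_properties(p)
  }
  if (!is.null(overrides) && !is.null(p$id) && p$id %in% overrides$id) {
    r <- overrides[match(p$id, overrides$id), ]
    return(admet_levels(r$absorption, r$solubility, r$bbb,
                        as.logical(r$cyp2d6), as.logical(r$hepatotoxicity)))
  }
  viol <- sum(p$alogp > 5, p$hbd > 5, p$hba > 10, p$weight > 600)
  absorption <- min(viol, 3L)
  solubility <- if (p$alogp < -1) 4L else if (p$alogp <= 3.5) 3L
                else if (p$alogp <= 5) 2L else 1L
  bbb <- if (p$hbd + p$hba >= 3 || p$weight > 500 || p$alogp < 2) 3L
         else if (p$alogp <= 4) 2L else 1L
  cyp2d6 <- isTRUE(has_basic_amine) && p$alogp > 3
  hepato <- p$alogp > 5.5 || p$weight > 700
  admet_levels(absorption, solubility, bbb, cyp2d6, hepato)
}

#' Apply the drug-likeness funnel to a library
#'
#' Runs the rule-of-five filter then the ADMET gate and reports per-stage
#' counts (the funnel shape) plus the surviving compounds. The two filters
#' are pure functions of each compound, so their composition is
#' order-independent.
#'
#' @param mols list of `molecule3d`.
#' @param mw_max rule-of-five weight bound (default 600 Da).
#' @param admet_overrides optional user-level table for [surrogate_admet()].
#' @return list: `funnel` (data.frame stage/count), `verdicts` (per
#'   compound), `passed` (surviving molecules).
#' @export
druglike_funnel <- function(mols, mw_max = 600, admet_overrides = NULL) {
  props <- lapply(mols, compute_properties)
  ro5 <- lapply(props, ro5_filter, mw_max = mw_max)
  adm <- lapply(seq_along(mols), function(k)
    admet_gate(surrogate_admet(mols[[k]], overrides = admet_overrides)))
  keep <- vapply(ro5, `[[`, logical(1), "pass") &
          vapply(adm, `[[`, logical(1), "pass")
  after_ro5 <- sum(vapply(ro5, `[[`, logical(1), "pass"))
  list(funnel = data.frame(stage = c("input", "ro5", "ro5+admet"),
                           count = c(length(mols), after_ro5, sum(keep))),
       verdicts = data.frame(
         id = vapply(props, function(x) x$id %||% NA_character_, ""),
         ro5 = vapply(ro5, `[[`, logical(1), "pass"),
         admet = vapply(adm, `[[`, logical(1), "pass"),
         pass = keep),
       passed = mols[keep])
}
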