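# ---------------------------------------------------------------------------
# Hypothesis validation against labeled decoy sets: Guner-Henry enrichment
# statistics and ROC analysis.
# ---------------------------------------------------------------------------

#' Guner-Henry decoy-set statistics
#'
#' From the confusion counts of a decoy-set screen -- D compounds of which A
#' are active, Ht retrieved of which Ha are active -- derives the percentage
#' yield of actives (100*Ha/Ht), percentage ratio of actives (100*Ha/A),
#' false negatives (A-Ha), false positives (Ht-Ha), and the goodness-of-fit
#' score
#'
#'   GF = (Ha (3A + Ht) / (4 Ht A)) * (1 - (Ht - Ha)/(D - A)),
#'
#' which is 1 exactly when retrieval is perfect (Ha = Ht = A). GF and the
#' percentages are additionally reported truncated (not rounded) to two
#' decimals, the convention used in published validation tables; the
#' full-precision values are always retained.
#'
#' @param D total compounds in the decoy set.
#' @param A total actives (0 < A < D).
#' @param Ht total hits retrieved (> 0).
#' @param Ha actives among the hits (0 <= Ha <= min(A, Ht)).
#' @return object of class `decoy_evaluation`.
#' @examples
#' gh_statistics(110, 6, 2, 2)$GF_2dec   # 0.83
#' gh_statistics(110, 6, 5, 4)$GF_2dec   # 0.75
#' @export
gh_statistics <- function(D, A, Ht, Ha) {
  for (v in list(D, A, Ht, Ha))
    stopifnot(length(v) == 1L, is.finite(v), v == round(v))
  if (!(D > A && A > 0))
    abort_pharm("need D > A > 0", "invalid_counts")
  if (Ht > D) abort_pharm("Ht cannot exceed D", "inconsistent_counts")
  if (Ht == 0) abort_pharm("GF is undefined for Ht = 0", "undefined_gf")
  if (Ha < 0 || Ha > Ht || Ha > A)
    abort_pharm("need 0 <= Ha <= min(A, Ht)", "inconsistent_counts")
  gf <- (Ha * (3 * A + Ht) / (4 * Ht * A)) * (1 - (Ht - Ha) / (D - A))
  yield <- 100 * Ha / Ht
  ratio <- 100 * Ha / A
  structure(list(D = D, A = A, Ht = Ht, Ha = Ha,
                 yield_pct = yield, yield_pct_2dec = trunc_dec(yield),
                 ratio_pct = ratio, ratio_pct_2dec = trunc_dec(ratio),
                 false_negatives = A - Ha, false_positives = Ht - Ha,
                 GF = gf, GF_2dec = trunc_dec(gf)),
            class = "decoy_evaluation")
}

#' @export
print.decoy_evaluation <- function(x, ...) {
  cat(sprintf(paste0("<decoy_evaluation> D=%d A=%d Ht=%d Ha=%d | yield %.2f%%",
                     " ratio %.2f%% FN=%d FP=%d GF=%.4f (%.2f)\n"),
              x$D, x$A, x$Ht, x$Ha, x$yield_pct, x$ratio_pct,
              x$false_negatives, x$false_positives, x$GF, x$GF_2dec))
  invisible(x)
}

#' Screen a labeled decoy set and compute Guner-Henry statistics
#'
#' @param h a `pharm_hypothesis`.
#' @param library compound list as in [screen_library()].
#' @param labels logical (or 0/1) vector, one per compound: TRUE = active.
#' @param allow_omit,match_tolerance,rules as in [screen_library()].
#' @return `decoy_evaluation`; the per-compound screen is kept in attribute
#'   `records`.
#' @export
evaluate_decoy_set <- function(h, library, labels, allow_omit = 0L,
                               match_tolerance = 1.0,
                               rules = default_feature_rules()) {
  labels <- as.logical(labels)
  if (length(labels) != length(library) || anyNA(labels))
    abort_pharm("labels must cover all compounds", "invalid_labels")
  rec <- screen_library(h, library, allow_omit, match_tolerance, rules)
  ev <- gh_statistics(D = length(library), A = sum(labels),
                      Ht = sum(rec$passed), Ha = sum(rec$passed & labels))
  attr(ev, "records") <- rec
  ev
}

#' ROC curve and AUC for a scored, labeled compound set
#'
#' AUC is the probability that a randomly chosen active outscores a randomly
#' chosen inactive, with ties counted one half (Mann-Whitney convention).
#'
#' @param scores numeric scores (higher = more active-like).
#' @param labels logical / 0-1 vector, TRUE = active.
#' @param threshold optional score threshold at which sensitivity and
#'   specificity are reported (compounds with score >= threshold are called
#'   active).
#' @return object of class `roc_result`: `curve` (data.frame fpr, tpr,
#'   monotone non-decreasing), `auc`, and optional `sensitivity`,
#'   `specificity`.
#' @export
roc_curve <- function(scores, labels, threshold = NULL) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    abort_pharm("both classes must be present", "single_class")
  # rank-based AUC (ties = 1/2)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    fpr = vapply(cuts, function(ct) sum(scores >= ct & !labels) / nneg,
                 numeric(1)),
    tpr = vapply(cuts, function(ct) sum(scores >= ct & labels) / npos,
                 numeric(1)))
  out <- list(curve = curve, auc = auc)
  if (!is.null(threshold)) {
    out$sensitivity <- sum(scores >= threshold & labels) / npos
    out$specificity <- sum(scores < threshold & !labels) / nneg
  }
  structure(out, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d curve points)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}

#' Validation-table report for a set of hypotheses
#'
#' Emits a decoy-set validation table (one column block per hypothesis:
#' D, A, Ht, Ha, %yield, %ratio, FN, FP, GF truncated to two decimals) as a
#' data.frame, optionally written as TSV.
#'
#' @param evaluations named list of `decoy_evaluation`.
#' @param path optional TSV output path.
#' @return data.frame, rows = parameters, columns = hypotheses.
#' @export
gh_report <- function(evaluations, path = NULL) {
  stopifnot(length(evaluations) > 0)
  cols <- lapply(evaluations, function(ev) c(
    D = ev$D, A = ev$A, Ht = ev$Ht, Ha = ev$Ha,
    yield_pct = ev$yield_pct_2dec, ratio_pct = ev$ratio_pct_2dec,
    false_negatives = ev$false_negatives,
    false_positives = ev$false_positives, GF = ev$GF_2dec))
  out <- as.data.frame(cols)
  names(out) <- names(evaluations) %||% paste0("hypo", seq_along(evaluations))
  out <- cbind(parameter = rownames(out), out)
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
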