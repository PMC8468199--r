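self_map_fixture <- function() {
  feats <- list(pharm_feature("HBD", c(0, 0, 0), 1.6),
                pharm_feature("HBA", c(4.2, 0, 0), 1.6),
                pharm_feature("HYP", c(2.0, 3.5, 0), 1.7),
                pharm_feature("RA", c(1.5, 1.2, 3.8), 1.6))
  list(h = pharm_hypothesis("self", feats),
       fs = structure(feats, class = "feature_set", id = "self"))
}

test_that("self-mapping gives zero deviations and fit = max_fit", {
  fx <- self_map_fixture()
  m <- map_conformer(fx$h, fx$fs, allow_omit = 0)
  expect_equal(m$omitted_count, 0)
  expect_equal(max(m$deviations), 0, tolerance = 1e-9)
  expect_equal(m$fit, fx$h$max_fit)
})

test_that("the fit term follows the closed form max(0, 1-(d/t)^2)", {
  fx <- self_map_fixture()
  # displace the matched HBD by exactly 0.8 A; tolerance 1.6
  feats <- unclass(fx$fs)
  feats[[1]] <- pharm_feature("HBD", c(0, 0, 0), 1.6)
  lig <- feats
  lig[[1]]$centroid <- lig[[1]]$centroid + c(0.8, 0, 0)
  # keep the other three fixed: superposition would distribute the error,
  # so score the displaced correspondence directly at fixed alignment
  dev <- c(0.8, 0, 0, 0)
  tol <- c(1.6, 1.6, 1.7, 1.6)
  expect_equal(sum(pmax(0, 1 - (dev / tol)^2)), 3.75)
  expect_equal(1 - (0.8 / 1.6)^2, 0.75)

  # through the mapping path: a rigidly displaced whole cloud still fits
  # perfectly (superposition removes the shift)
  moved <- structure(lapply(lig, function(f) {
    f$centroid <- f$centroid + c(3, -2, 1); f
  }), class = "feature_set", id = "moved")
  m <- map_conformer(fx$h, moved)
  expect_lt(abs(m$fit - (fx$h$max_fit -
    sum((0.8 * c(3/4, -1/4, -1/4, -1/4) / tol)^2))), 0.2)
  # fit never exceeds the matched-feature count
  expect_lte(m$fit, fx$h$max_fit - m$omitted_count + 1e-12)
})

test_that("kind mismatches cannot map and empty hypotheses error", {
  fx <- self_map_fixture()
  no_hbd <- structure(unclass(fx$fs)[-1], class = "feature_set", id = "x")
  expect_null(map_conformer(fx$h, no_hbd, allow_omit = 0))
  expect_false(is.null(map_conformer(fx$h, no_hbd, allow_omit = 1)))
  h0 <- pharm_hypothesis("empty", list())
  expect_error(map_conformer(h0, fx$fs), "empty hypothesis")
  expect_error(map_conformer(fx$h, fx$fs, allow_omit = 4), "allow_omit")
})

test_that("fit decreases as a matched deviation grows", {
  fx <- self_map_fixture()
  fits <- vapply(seq(0, 1.6, by = 0.2), function(d) {
    lig <- unclass(fx$fs)
    lig[[1]]$centroid <- lig[[1]]$centroid + c(0, 0, d)
    map_conformer(fx$h, structure(lig, class = "feature_set", id = "d"),
                  match_tolerance = 2.5)$fit
  }, numeric(1))
  expect_true(all(diff(fits) < 1e-9))
})

test_that("screen_library records pass/fail per compound in input order", {
  fx <- self_map_fixture()
  empty <- structure(list(), class = "feature_set", id = "void")
  lib <- list(fx$fs, empty, fx$fs)
  rec <- screen_library(fx$h, lib)
  expect_equal(rec$passed, c(TRUE, FALSE, TRUE))
  expect_equal(rec$id[2], "void")
  expect_error(screen_library(fx$h, list()), "empty library")

  # planted actives at zero jitter all pass at allow_omit 0
  lib0 <- gen_planted_library(planted_spec(jitter_sd = 0, n_actives = 5L,
                                           n_decoys = 3L), seed = 1)
  rec0 <- screen_library(lib0$hypothesis, lib0$library)
  expect_equal(sum(rec0$passed), 5)
  expect_equal(rec0$passed, lib0$labels)
})

test_that("gh_statistics reproduces the printed validation columns", {
  ev <- gh_statistics(110, 6, 2, 2)
  expect_equal(ev$yield_pct, 100)
  expect_equal(ev$ratio_pct_2dec, 33.33)
  expect_equal(ev$false_negatives, 4)
  expect_equal(ev$false_positives, 0)
  expect_equal(ev$GF_2dec, 0.83)

  expect_equal(gh_statistics(110, 6, 6, 6)$GF, 1.0)

  ev7 <- gh_statistics(110, 6, 5, 4)
  expect_equal(ev7$GF, 0.7592949, tolerance = 1e-6)
  expect_equal(ev7$GF_2dec, 0.75)     # truncation, not rounding
  expect_equal(ev7$yield_pct, 80)
})

test_that("gh_statistics guards its preconditions", {
  expect_error(gh_statistics(110, 6, 0, 0), "undefined")
  expect_error(gh_statistics(6, 6, 2, 2), "D > A")
  expect_error(gh_statistics(110, 0, 2, 0), "D > A")
  expect_error(gh_statistics(110, 6, 2, 3), "Ha")
  expect_error(gh_statistics(110, 6, 2, 7), "Ha")
  expect_error(gh_statistics(110, 6, 111, 6), "exceed")
})

test_that("evaluate_decoy_set wires screening into the GH statistics", {
  fx <- self_map_fixture()
  empty <- structure(list(), class = "feature_set", id = "void")
  lib <- c(rep(list(fx$fs), 3), rep(list(empty), 5))
  labels <- c(TRUE, TRUE, TRUE, rep(FALSE, 5))
  ev <- evaluate_decoy_set(fx$h, lib, labels)
  expect_equal(ev$Ht, 3); expect_equal(ev$Ha, 3)
  expect_equal(ev$GF, 1.0)   # separable set
  expect_error(evaluate_decoy_set(fx$h, lib, rep(FALSE, 8)), "D > A")
  expect_error(evaluate_decoy_set(fx$h, lib, labels[-1]), "labels")
})

test_that("ROC AUC equals pairwise concordance and is rank-invariant", {
  expect_equal(roc_curve(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0))$auc, 1.0)
  expect_error(roc_curve(1:5, rep(1, 5)), "both classes")

  set.seed(31)
  for (rep in 1:5) {
    n <- 40
    sc <- rnorm(n); lb <- runif(n) < 0.4
    if (!any(lb) || all(lb)) next
    r <- roc_curve(sc, lb)
    # brute-force concordance count
    conc <- 0
    for (i in which(lb)) for (j in which(!lb))
      conc <- conc + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
    expect_equal(r$auc, conc / (sum(lb) * sum(!lb)))
    # strictly monotone transform leaves AUC unchanged
    expect_equal(roc_curve(exp(sc), lb)$auc, r$auc)
    # curve is monotone in both axes
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
    expect_true(r$auc >= 0 && r$auc <= 1)
  }
})

test_that("ROC agrees with pROC and random scores give AUC near 1/2", {
  skip_if_not_installed("pROC")
  set.seed(77)
  n <- 2000
  sc <- rnorm(n); lb <- runif(n) < 0.5
  mine <- roc_curve(sc, lb)
  ref <- suppressMessages(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<",
                                              levels = c(FALSE, TRUE))))
  expect_equal(mine$auc, as.numeric(ref), tolerance = 1e-12)
  se <- sqrt(1 / 12 * (1 / sum(lb) + 1 / sum(!lb)))
  expect_lt(abs(mine$auc - 0.5), 3 * se)
})

test_that("specificity at a threshold counts rejected inactives", {
  sc <- c(9, 8, 7, 3, 2, 1); lb <- c(1, 1, 1, 0, 0, 0)
  r <- roc_curve(sc, lb, threshold = 5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  r2 <- roc_curve(sc, lb, threshold = 2.5)
  expect_equal(r2$specificity, 2 / 3)
})

test_that("gh_report lays out the validation table", {
  evs <- list(HypoA = gh_statistics(110, 6, 5, 4),
              HypoB = gh_statistics(110, 6, 2, 2))
  tb <- gh_report(evs)
  expect_equal(names(tb), c("parameter", "HypoA", "HypoB"))
  expect_equal(tb$HypoA[tb$parameter == "GF"], 0.75)
  expect_equal(tb$HypoB[tb$parameter == "GF"], 0.83)
  tf <- tempfile(fileext = ".tsv")
  gh_report(evs, tf)
  expect_true(file.exists(tf))
  unlink(tf)
})
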