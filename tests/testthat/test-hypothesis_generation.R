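planted_features <- function(jitter = 0, seed = NULL,
                             kinds = c("HBD", "HBA", "RA", "HYP"),
                             id = "m") {
  if (!is.null(seed)) set.seed(seed)
  geo <- rbind(c(0, 0, 0), c(5.2, 0, 0), c(2.4, 4.6, 0), c(2.8, 1.8, 4.2))
  feats <- lapply(seq_along(kinds), function(i)
    pharm_feature(kinds[i], geo[i, ] + rnorm(3, sd = jitter),
                  tolerance = 1.0))
  structure(feats, class = "feature_set", id = id)
}

test_that("a single-member training set self-maps with direct hits", {
  fs <- planted_features()
  ts <- training_set(list(list(conformers = fs, principal = 2L,
                               max_omit = 0L)))
  res <- enumerate_common_pharmacophores(ts, generation_config(
    min_features = 4, max_features = 4))
  expect_gt(length(res), 0)
  for (r in res) {
    expect_true(all(r$mapping_report$direct_hit))
    expect_false(any(r$mapping_report$partial_hit))  # mutually exclusive
    expect_equal(r$mapping_report$fit, r$hypothesis$max_fit)
  }
})

test_that("training-set constraints are enforced", {
  fs <- planted_features()
  expect_error(training_set(list(list(conformers = fs, principal = 1L))),
               "principal = 2")
  empty <- structure(list(), class = "feature_set", id = "none")
  expect_error(training_set(list(list(conformers = empty, principal = 2L))),
               "no features")
})

test_that("planted arrangement is recovered over decoy features", {
  # 4 actives share the planted 4-feature arrangement (jitter 0.2 A) plus
  # unshared decoy features; the top hypothesis recovers kinds and geometry
  spec <- planted_spec(jitter_sd = 0.2, n_actives = 4L, extra_features = 2L,
                       tolerance = 1.0)
  lib <- gen_planted_library(spec, seed = 11)
  ts <- training_set(lapply(lib$library, function(fs)
    list(conformers = fs, principal = 2L, max_omit = 0L)))
  res <- enumerate_common_pharmacophores(ts, generation_config(
    min_features = 4, max_features = 4, match_tolerance = 1.0))
  top <- res[[1]]$hypothesis
  expect_setequal(vapply(top$features, `[[`, "", "kind"),
                  c("HBD", "HBA", "RA", "HYP"))
  planted_d <- interfeature_distance_table(lib$hypothesis)
  got_d <- interfeature_distance_table(top)
  ord <- match(rownames(planted_d), rownames(got_d))
  expect_lt(max(abs(got_d[ord, ord] - planted_d)), 0.5)
})

test_that("clique search agrees with brute-force enumeration on small instances", {
  set.seed(5)
  for (rep in 1:8) {
    kinds_h <- sample(c("HBD", "HBA", "HYP", "RA"), 4, replace = TRUE)
    h <- pharm_hypothesis("bf", lapply(seq_along(kinds_h), function(i)
      pharm_feature(kinds_h[i], rnorm(3, sd = 3), tolerance = 1.5)))
    lig <- lapply(1:6, function(i)
      pharm_feature(sample(c("HBD", "HBA", "HYP", "RA"), 1),
                    rnorm(3, sd = 3), tolerance = 1.5))
    for (omit in 0:1) {
      mine <- map_conformer(h, lig, allow_omit = omit, match_tolerance = 1.0)
      oracle <- brute_force_map(h, lig, allow_omit = omit,
                                match_tolerance = 1.0)
      if (is.null(oracle)) expect_null(mine)
      else {
        expect_false(is.null(mine))
        expect_equal(mine$fit, oracle$fit, tolerance = 1e-9)
      }
    }
  }
})

test_that("rank_score is the summed best fit and is monotone in features", {
  fs <- planted_features()
  ts <- training_set(lapply(1:3, function(k)
    list(conformers = fs, principal = 2L, max_omit = 0L)))
  h4 <- pharm_hypothesis("h4", unclass(fs), "ligand_based")
  # perfect self-map of k features on m members -> m * k
  expect_equal(rank_score(h4, ts), 3 * 4)
  h3 <- pharm_hypothesis("h3", unclass(fs)[1:3], "ligand_based")
  expect_equal(rank_score(h3, ts), 3 * 3)
  expect_gt(rank_score(h4, ts), rank_score(h3, ts))
  # hypothesis no member can map scores 0
  far <- pharm_hypothesis("far", list(
    pharm_feature("NI", c(0, 0, 0)), pharm_feature("NI", c(40, 0, 0))),
    "ligand_based")
  expect_equal(rank_score(far, ts), 0)
})

test_that("hypothesis recovery improves as jitter shrinks", {
  err_at <- function(jit) {
    errs <- vapply(1:5, function(s) {
      lib <- gen_planted_library(planted_spec(jitter_sd = jit,
                                              n_actives = 4L,
                                              tolerance = 1.0), seed = s)
      ts <- training_set(lapply(lib$library, function(fs)
        list(conformers = fs, principal = 2L, max_omit = 0L)))
      res <- enumerate_common_pharmacophores(ts, generation_config(
        min_features = 4, max_features = 4, match_tolerance = 1.8))
      pd <- interfeature_distance_table(lib$hypothesis)
      gd <- interfeature_distance_table(res[[1]]$hypothesis)
      ord <- match(rownames(pd), rownames(gd))
      max(abs(gd[ord, ord] - pd))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(0.05), err_at(0.3))
})

test_that("receptor-ligand derivation follows the geometric rules", {
  # far-apart pair: empty hypothesis, no error
  inert <- gen_toy_complex()
  h0 <- derive_receptor_hypothesis(inert$receptor, inert$ligand)
  expect_equal(h0$max_fit, 0)

  # one N-H...O=C contact at 2.9 A, angle 180 -> exactly one HBD on the N
  one <- gen_toy_complex(n_hbd = 1)
  h1 <- derive_receptor_hypothesis(one$receptor, one$ligand)
  expect_equal(vapply(h1$features, `[[`, "", "kind"), "HBD")
  n_idx <- which(one$ligand$atoms$elem == "N")
  expect_equal(h1$features[[1]]$source_atoms, n_idx)
  expect_equal(h1$provenance, "structure_based")
  expect_true(is.na(h1$selectivity))   # selectivity "not computed"

  # two acceptor contacts, one donor, three hydrophobic clusters
  t2 <- gen_toy_complex(n_hbd = 1, n_hba = 2, n_hyp = 3)
  h2 <- derive_receptor_hypothesis(t2$receptor, t2$ligand)
  expect_equal(sort(vapply(h2$features, `[[`, "", "kind")),
               c("HBA", "HBA", "HBD", "HYP", "HYP", "HYP"))

  # aromatic stack
  t3 <- gen_toy_complex(n_ra = 1)
  h3 <- derive_receptor_hypothesis(t3$receptor, t3$ligand)
  expect_equal(vapply(h3$features, `[[`, "", "kind"), "RA")
})

test_that("receptor derivation is invariant under joint rigid motion", {
  cx <- gen_toy_complex(n_hbd = 1, n_hyp = 2)
  h <- derive_receptor_hypothesis(cx$receptor, cx$ligand)
  set.seed(9)
  R <- random_rotation(); tvec <- rnorm(3, sd = 8)
  h2 <- derive_receptor_hypothesis(
    transform_molecule(cx$receptor, R, tvec),
    transform_molecule(cx$ligand, R, tvec))
  expect_equal(vapply(h2$features, `[[`, "", "kind"),
               vapply(h$features, `[[`, "", "kind"))
  expect_equal(unname(h2$distance_table), unname(h$distance_table),
               tolerance = 1e-9)
})

test_that("contact classification assigns one prioritized class per pair", {
  one <- gen_toy_complex(n_hbd = 1)
  tab <- classify_contacts(one$receptor, one$ligand)
  expect_equal(sum(tab$class == "hydrogen_bond"), 1)

  inert <- gen_toy_complex()
  expect_equal(nrow(classify_contacts(inert$receptor, inert$ligand)), 0)

  # lone CH3-like carbon 3.8 A from a receptor carbon: hydrophobic or vdW
  # (cluster size decides), never a hydrogen bond
  lig <- molecule3d("l", data.frame(elem = "C", x = 0, y = 0, z = 0))
  rec <- molecule3d("r", data.frame(elem = "C", x = 0, y = 3.8, z = 0,
                                    resid = 1, resname = "ALA"))
  tab2 <- classify_contacts(rec, lig)
  expect_equal(nrow(tab2), 1)
  expect_true(tab2$class %in% c("hydrophobic", "van_der_waals"))

  # hydrophobic sites give hydrophobic rows, aromatic sites stack rows
  hyp <- gen_toy_complex(n_hyp = 1)
  expect_true(all(classify_contacts(hyp$receptor, hyp$ligand)$class ==
                  "hydrophobic"))
  ra <- gen_toy_complex(n_ra = 1)
  cls <- classify_contacts(ra$receptor, ra$ligand)$class
  expect_true("aromatic_stack" %in% cls)
  expect_false("hydrogen_bond" %in% cls)
})

test_that("generated hypotheses all satisfy the type invariants", {
  lib <- gen_planted_library(planted_spec(jitter_sd = 0.3, n_actives = 3L,
                                          tolerance = 1.0), seed = 2)
  ts <- training_set(lapply(lib$library, function(fs)
    list(conformers = fs, principal = 2L, max_omit = 1L)))
  res <- enumerate_common_pharmacophores(ts, generation_config(
    min_features = 3, max_features = 4))
  for (r in res) {
    h <- r$hypothesis
    expect_equal(h$max_fit, length(h$features))
    expect_equal(h$distance_table, t(h$distance_table))
    expect_true(all(abs(diag(h$distance_table)) < 1e-12))
  }
  # at most max_hypotheses come back
  res10 <- enumerate_common_pharmacophores(ts, generation_config(
    min_features = 3, max_features = 4, max_hypotheses = 2))
  expect_lte(length(res10), 2)
})
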