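test_that("molecule3d enforces its invariants", {
  expect_error(molecule3d("bad", data.frame(elem = "C", x = NA, y = 0, z = 0)),
               "finite")
  expect_error(molecule3d("bad", data.frame(elem = character(), x = numeric(),
                                            y = numeric(), z = numeric())),
               "at least one atom")
  atoms <- data.frame(elem = c("C", "C"), x = c(0, 1.5), y = 0, z = 0)
  expect_error(molecule3d("bad", atoms, data.frame(i = 1, j = 3, order = 1)),
               "existing atoms")
  expect_error(molecule3d("bad", atoms,
                          data.frame(i = c(1, 2), j = c(2, 1), order = 1)),
               "duplicate")
})

test_that("perception matches hand-enumerated features on small molecules", {
  expect_length(perceive_features(mk_methane()), 0)

  fs <- perceive_features(mk_ethanol())
  kinds <- vapply(fs, `[[`, "", "kind")
  expect_equal(sort(kinds), c("HBA", "HBD"))
  # both features sit on the hydroxyl oxygen
  o_xyz <- unlist(mk_ethanol()$atoms[3, c("x", "y", "z")], use.names = FALSE)
  for (f in fs) expect_equal(f$centroid, o_xyz, tolerance = 1e-9)

  bz <- perceive_features(mk_benzene())
  expect_length(bz, 1)
  expect_equal(bz[[1]]$kind, "RA")
  ring_xyz <- colMeans(as.matrix(mk_benzene()$atoms[1:6, c("x", "y", "z")]))
  expect_equal(bz[[1]]$centroid, unname(ring_xyz), tolerance = 1e-9)

  w <- perceive_features(mk_water())
  expect_equal(sort(vapply(w, `[[`, "", "kind")), c("HBA", "HBD"))
})

test_that("acceptor rules exclude amide nitrogen but keep pyridine nitrogen", {
  am <- perceive_features(mk_acetamide())
  kinds <- vapply(am, `[[`, "", "kind")
  # amide N: donor yes (N-H), acceptor no; carbonyl O: acceptor
  expect_equal(sum(kinds == "HBD"), 1)
  hba_atoms <- unlist(lapply(am[kinds == "HBA"], `[[`, "source_atoms"))
  expect_false(4 %in% hba_atoms)   # atom 4 is the amide N
  expect_true(3 %in% hba_atoms)    # atom 3 is the carbonyl O

  py <- perceive_features(mk_pyridine())
  kinds <- vapply(py, `[[`, "", "kind")
  expect_true("RA" %in% kinds)
  expect_true(any(kinds == "HBA"))
  expect_false(any(kinds == "HBD"))
})

test_that("perception is deterministic and rigid-motion covariant", {
  mol <- mk_ethanol()
  f1 <- perceive_features(mol)
  f2 <- perceive_features(mol)
  expect_identical(f1, f2)

  set.seed(42)
  for (rep in 1:5) {
    R <- random_rotation(); tvec <- rnorm(3, sd = 5)
    moved <- transform_molecule(mol, R, tvec)
    fm <- perceive_features(moved)
    expect_equal(vapply(fm, `[[`, "", "kind"), vapply(f1, `[[`, "", "kind"))
    for (i in seq_along(f1))
      expect_equal(fm[[i]]$centroid,
                   as.numeric(R %*% f1[[i]]$centroid + tvec),
                   tolerance = 1e-9)
  }
})

test_that("feature census counts and common kinds behave as specified", {
  expect_error(feature_census(list()), "1 molecule")
  single <- feature_census(list(mk_ethanol()))
  expect_equal(attr(single, "common"), c("HBD", "HBA"))

  both <- feature_census(list(mk_ethanol(), mk_methane()))
  expect_false("HBA" %in% attr(both, "common"))

  # four actives built with >= 3 donors each: census reports HBD >= 3 for all
  actives <- lapply(1:4, function(k) mk_triol(paste0("act", k), shift = k))
  cens <- feature_census(actives)
  expect_true(all(cens$HBD >= 3))
  expect_true("HBD" %in% attr(cens, "common"))
})

test_that("interfeature distances are Euclidean, symmetric and metric", {
  f <- list(pharm_feature("HBD", c(0, 0, 0)),
            pharm_feature("HBA", c(3, 4, 0)))
  h <- pharm_hypothesis("h2", f)
  d <- interfeature_distance_table(h)
  expect_equal(d[1, 2], 5.0)
  expect_equal(d, t(d))

  expect_error(interfeature_distance_table(
    pharm_hypothesis("h1", f[1])), "2 features")

  set.seed(7)
  for (rep in 1:10) {
    feats <- lapply(1:5, function(i)
      pharm_feature(sample(FEATURE_KINDS, 1), rnorm(3, sd = 4)))
    h5 <- pharm_hypothesis(paste0("r", rep), feats)
    d5 <- interfeature_distance_table(h5)
    expect_equal(d5, t(d5))
    expect_true(all(abs(diag(d5)) < 1e-12))
    for (i in 1:5) for (j in 1:5) for (k in 1:5)
      expect_lte(d5[i, j], d5[i, k] + d5[k, j] + 1e-9)
    # recomputable from features
    d_re <- as.matrix(dist(do.call(rbind, lapply(feats, `[[`, "centroid"))))
    expect_lt(max(abs(unname(d5) - unname(d_re))), 1e-9)
  }
})

test_that("feature kind vocabulary is closed; HYA is flagged, not silent", {
  expect_error(parse_feature_kind("XYZ"), "unknown feature kind")
  expect_warning(k <- parse_feature_kind("HYA"), "HBA")
  expect_equal(k, "HBA")
  expect_error(pharm_feature("HBD", c(0, 0, 0), tolerance = 0), "tolerance")
  expect_error(pharm_feature("HBD", c(0, 0, 0), direction = c(1, 1, 0)),
               "unit norm")
})

test_that("JSON serialization round-trips hypotheses losslessly", {
  fs <- perceive_features(mk_ethanol())
  h <- pharm_hypothesis("rt", c(fs, perceive_features(mk_benzene())),
                        "ligand_based", rank_score = 12.5)
  tf <- tempfile(fileext = ".json")
  write_pharm_json(h, tf)
  h2 <- read_pharm_json(tf)
  expect_equal(h2$id, h$id)
  expect_equal(h2$provenance, h$provenance)
  expect_equal(h2$max_fit, h$max_fit)
  expect_equal(h2$rank_score, h$rank_score)
  for (i in seq_along(h$features)) {
    expect_equal(h2$features[[i]]$kind, h$features[[i]]$kind)
    expect_lt(max(abs(h2$features[[i]]$centroid - h$features[[i]]$centroid)),
              1e-6)
  }
  expect_lt(max(abs(h2$distance_table - h$distance_table)), 1e-6)
  unlink(tf)
})

test_that("rules files are validated: bad SMARTS is a rule error", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("pattern\tkind\tcentroid_rule",
               "[#8]-[#1]\tHBD\tatom",
               "[#8](\tHBA\tatom"), tf)
  expect_error(read_feature_rules(tf), "does not parse")
  unlink(tf)
  # shipped default rules file parses and matches the built-in set
  shipped <- read_feature_rules(system.file("extdata", "feature_rules.tsv",
                                            package = "pharmscreen"))
  expect_equal(shipped$pattern, default_feature_rules()$pattern)
})

test_that("SDF round-trip preserves structure and coordinates", {
  skip_if_not_installed("ChemmineR")
  mols <- list(mk_ethanol(), mk_benzene())
  tf <- tempfile(fileext = ".sdf")
  write_sdf(mols, tf)
  back <- read_sdf(tf)
  expect_length(back, 2)
  for (k in 1:2) {
    expect_equal(back[[k]]$atoms$elem, mols[[k]]$atoms$elem)
    expect_equal(mol_xyz <- as.matrix(back[[k]]$atoms[, c("x", "y", "z")]),
                 as.matrix(mols[[k]]$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(nrow(back[[k]]$bonds), nrow(mols[[k]]$bonds))
  }
  unlink(tf)
})
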