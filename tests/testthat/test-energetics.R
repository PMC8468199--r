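ec <- function(...) energy_components(...)

test_that("delta_g is the componentwise entity difference", {
  s0 <- snapshot_energies(0, complex = ec(-5, -3, 4, -1),
                          protein = ec(-3, -2, 3, -1),
                          ligand = ec(-2, -1, 1, 0))
  expect_equal(delta_g(s0), 0)

  s1 <- snapshot_energies(10, complex = ec(-10, -5, 8, -1),
                          protein = ec(-4, -2, 3, 0),
                          ligand = ec(-1, -1, 1, 0))
  expect_equal(delta_g(s1), -4)

  # linearity: scaling all inputs scales delta G
  s3 <- snapshot_energies(10, complex = ec(-30, -15, 24, -3),
                          protein = ec(-12, -6, 9, 0),
                          ligand = ec(-3, -3, 3, 0))
  expect_equal(delta_g(s3), 3 * delta_g(s1))

  expect_error(snapshot_energies(0, complex = ec(1, 1, 1, 1),
                                 interaction = ec(0, 0, 0, 0)),
               "not both")
  expect_error(summarize_snapshots(list(
    s1, snapshot_energies(20, interaction = ec(-5, -2, 4, -1)))),
    "mix")
})

test_that("kcal/mol input is converted explicitly", {
  expect_equal(unclass(ec(1, 0, 0, 0, unit = "kcal/mol"))[["vdw"]], 4.184)
})

test_that("summarize recovers constant series exactly and windows correctly", {
  series <- lapply(seq(0, 900, by = 100), function(t)
    snapshot_energies(t, interaction = ec(-12, -3, 8, -2)))
  s <- summarize_snapshots(series, window = c(0, 900))
  expect_equal(unname(s$component_mean), c(-12, -3, 8, -2))
  expect_equal(unname(s$component_sd), rep(0, 4))
  expect_equal(s$dg_mean, -9)
  expect_equal(s$dg_sd, 0)
  expect_equal(s$n, 10)

  s_tail <- summarize_snapshots(series, window = c(500, 900))
  expect_equal(s_tail$n, 5)
  expect_error(summarize_snapshots(series, window = c(2000, 3000)),
               "window")
})

test_that("mean of per-snapshot dG equals dG of per-component means", {
  set.seed(12)
  series <- lapply(1:40, function(k)
    snapshot_energies(k * 10, interaction = ec(rnorm(1, -150, 10),
                                               rnorm(1, -40, 8),
                                               rnorm(1, 120, 15),
                                               rnorm(1, -20, 2))))
  s <- summarize_snapshots(series, window = c(0, 1e6))
  expect_equal(s$dg_mean, sum_components(s$component_mean), tolerance = 1e-9)
})

test_that("snapshot generation at configured moments recovers the dG mean", {
  sp <- snapshot_spec()   # defaults: the strongest-hit row moments, n = 40
  target <- sum_components(sp$mean)
  expect_equal(target, -170.01, tolerance = 1e-9)
  sdg <- sqrt(sum(sp$sd^2))
  hits <- vapply(1:25, function(seed) {
    s <- summarize_snapshots(gen_snapshots(sp, seed = seed),
                             window = c(sp$t_start, sp$t_end))
    abs(s$dg_mean - target) <= 3 * sdg / sqrt(sp$n)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("LJ and Coulomb closed forms hold", {
  # single atom: zero energies
  e0 <- lj_coulomb_energy(matrix(0, 1, 3), 0, 3, 0.5)
  expect_equal(e0$vdw, 0); expect_equal(e0$elec, 0)

  # two neutral atoms at the LJ minimum: vdw = -epsilon
  sigma <- 3.4
  r <- 2^(1/6) * sigma
  e1 <- lj_coulomb_energy(rbind(c(0, 0, 0), c(r, 0, 0)),
                          charge = c(0, 0), sigma = c(sigma, sigma),
                          epsilon = c(0.5, 0.5))
  expect_equal(e1$vdw, -0.5, tolerance = 1e-12)

  # two unit charges at 1 nm: the Coulomb constant in kJ/mol
  e2 <- lj_coulomb_energy(rbind(c(0, 0, 0), c(10, 0, 0)),
                          charge = c(1, 1), sigma = c(0, 0),
                          epsilon = c(0, 0))
  expect_equal(e2$elec, 138.935458, tolerance = 1e-3)

  expect_error(lj_coulomb_energy(matrix(0, 2, 3), 0, c(1, 1), c(1, 1)),
               "cover all atoms")
})

test_that("pair sums match an independent all-pairs evaluation", {
  set.seed(4)
  n <- 60
  xyz <- matrix(runif(3 * n, 0, 15), ncol = 3)
  q <- runif(n, -0.5, 0.5); sg <- runif(n, 2.5, 3.5); ep <- runif(n, 0.1, 1)
  mine <- lj_coulomb_energy(xyz, q, sg, ep, cutoff = 8)
  vdw <- 0; elec <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r > 8) next
    s <- (sg[i] + sg[j]) / 2; e <- sqrt(ep[i] * ep[j])
    vdw <- vdw + 4 * e * ((s / r)^12 - (s / r)^6)
    elec <- elec + 138.935458 * q[i] * q[j] / (r / 10)
  }
  expect_equal(mine$vdw, vdw, tolerance = 1e-9)
  expect_equal(mine$elec, elec, tolerance = 1e-9)
})

test_that("bonded exclusions drop 1-2 and 1-3 pairs", {
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0), c(10, 0, 0))
  bonds <- data.frame(i = c(1, 2), j = c(2, 3))
  e <- lj_coulomb_energy(xyz, charge = c(1, 1, 1, 1),
                         sigma = rep(0, 4), epsilon = rep(0, 4),
                         bonds = bonds)
  # only pairs (1,4), (2,4), (3,4) remain
  manual <- 138.935458 * (1 / 1.0 + 1 / 0.85 + 1 / 0.7)
  expect_equal(e$elec, manual, tolerance = 1e-9)
})

test_that("SASA matches the analytic sphere and converges", {
  m <- nonpolar_model(n_points = 960L)
  s1 <- sasa(matrix(0, 1, 3), 1.5, m)
  exact <- 4 * pi * 2.9^2
  expect_lt(abs(s1$total - exact) / exact, 0.01)
  expect_equal(s1$nonpolar_energy, m$gamma * s1$total + m$offset)

  # disjoint atoms: additivity
  far <- sasa(rbind(c(0, 0, 0), c(10, 0, 0)), c(1.5, 1.2), m)
  iso <- sasa(matrix(0, 1, 3), 1.2, m)
  expect_equal(far$total, s1$total + iso$total, tolerance = 1e-9)

  # overlap strictly reduces area as separation shrinks
  seps <- c(6, 4, 2.5, 1.5)
  areas <- vapply(seps, function(d)
    sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.5, 1.5), m)$total, numeric(1))
  expect_true(all(diff(areas) < 0))

  # quadrature error at least halves from 960 to 3840 points
  err <- function(np) {
    s <- sasa(matrix(0, 1, 3), 1.5, nonpolar_model(n_points = np))
    abs(s$total - exact)
  }
  expect_lte(err(3840), err(960) / 2 + 1e-9)
  expect_error(nonpolar_model(n_points = 50), "100")
})

test_that("candidate ranking orders by dG and flags reference comparisons", {
  mk_sum <- function(id, dg) structure(
    list(id = id, component_mean = c(vdw = dg, elec = 0, polar_solv = 0,
                                     nonpolar_sasa = 0),
         component_sd = c(vdw = 1, elec = 0, polar_solv = 0,
                          nonpolar_sasa = 0),
         dg_mean = dg, dg_sd = 1, n = 40), class = "binding_summary")
  rows <- list(mk_sum("Hit1", -170.01), mk_sum("Hit2", -103.17),
               mk_sum("Hit3", -94.66), mk_sum("Hit4", -90.59),
               mk_sum("THZ1", -91.48), mk_sum("CT7001", -90.58))
  rk <- rank_candidates(rows, c("CT7001", "THZ1"))
  expect_equal(rk$id[1:3], c("Hit1", "Hit2", "Hit3"))
  h4 <- rk[rk$id == "Hit4", ]
  # better than CT7001 (-90.58), not better than THZ1 (-91.48)
  expect_true(h4$better_than_CT7001)
  expect_false(h4$better_than_THZ1)
  expect_true(h4$selected)
  expect_equal(rk$id[rk$selected], c("Hit1", "Hit2", "Hit3", "Hit4"))

  # equal dG: stable input order
  ties <- list(mk_sum("a", -50), mk_sum("b", -50), mk_sum("ref", -40))
  rt <- rank_candidates(ties, "ref")
  expect_equal(rt$id[1:2], c("a", "b"))
  expect_error(rank_candidates(ties, "nope"), "missing reference")
})

test_that("snapshot tables round-trip through TSV", {
  series <- gen_snapshots(snapshot_spec(n = 5), seed = 3)
  tb <- do.call(rbind, lapply(series, function(s) data.frame(
    time_ps = s$time_ps, entity = "interaction",
    vdw = s$interaction[["vdw"]], elec = s$interaction[["elec"]],
    polar_solv = s$interaction[["polar_solv"]],
    nonpolar_sasa = s$interaction[["nonpolar_sasa"]])))
  tf <- tempfile(fileext = ".tsv")
  write.table(tb, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_snapshot_table(tf)
  expect_length(back, 5)
  expect_equal(unname(vapply(back, delta_g, numeric(1))),
               vapply(series, delta_g, numeric(1)), tolerance = 1e-6)
  unlink(tf)
})
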