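# Small molecules with hand-set 3D coordinates (Angstrom), so perception
# tests are independent of any external embedding tool.

mk_methane <- function() {
  molecule3d("methane", data.frame(
    elem = c("C", "H", "H", "H", "H"),
    x = c(0, 1.09, -0.36, -0.36, -0.36),
    y = c(0, 0, 1.03, -0.51, -0.51),
    z = c(0, 0, 0, 0.89, -0.89)),
    data.frame(i = 1, j = 2:5, order = 1L))
}

mk_water <- function() {
  molecule3d("water", data.frame(
    elem = c("O", "H", "H"),
    x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0),
    data.frame(i = 1, j = 2:3, order = 1L))
}

mk_ethanol <- function() {
  molecule3d("ethanol", data.frame(
    elem = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
    x = c(1.17, -0.01, -1.16, 1.24, 2.08, 1.14, -0.05, -0.08, -1.90),
    y = c(-0.40, 0.44, -0.35, -1.07, 0.21, -1.00, 1.10, 1.06, 0.21),
    z = c(0, 0, 0, 0.88, 0, -0.89, 0.89, -0.88, 0)),
    data.frame(i = c(1, 2, 1, 1, 1, 2, 2, 3),
               j = c(2, 3, 4, 5, 6, 7, 8, 9), order = 1L))
}

mk_benzene <- function() {
  ang <- seq(0, 5) * pi / 3
  molecule3d("benzene", data.frame(
    elem = c(rep("C", 6), rep("H", 6)),
    x = c(1.39 * cos(ang), 2.47 * cos(ang)),
    y = c(1.39 * sin(ang), 2.47 * sin(ang)),
    z = 0),
    data.frame(i = c(1:6, 1:6), j = c(2:6, 1, 7:12),
               order = c(rep(c(2L, 1L), 3), rep(1L, 6))))
}

mk_pyridine <- function() {
  ang <- seq(0, 5) * pi / 3
  elem <- c("N", rep("C", 5), rep("H", 5))
  molecule3d("pyridine", data.frame(
    elem = elem,
    x = c(1.39 * cos(ang), 2.47 * cos(ang[-1])),
    y = c(1.39 * sin(ang), 2.47 * sin(ang[-1])),
    z = 0),
    data.frame(i = c(1:6, 2:6), j = c(2:6, 1, 7:11),
               order = c(rep(c(2L, 1L), 3), rep(1L, 5))))
}

mk_acetamide <- function() {
  # CH3-C(=O)-NH2: amide N must not count as an acceptor
  molecule3d("acetamide", data.frame(
    elem = c("C", "C", "O", "N", "H", "H", "H", "H", "H"),
    x = c(-1.28, 0.17, 0.76, 0.82, -1.65, -1.65, -1.65, 1.82, 0.32),
    y = c(0.04, -0.09, -1.15, 1.05, 1.06, -0.49, -0.49, 0.95, 1.95),
    z = c(0, 0, 0, 0, 0, 0.88, -0.88, 0, 0)),
    data.frame(i = c(1, 2, 2, 1, 1, 1, 4, 4),
               j = c(2, 3, 4, 5, 6, 7, 8, 9),
               order = c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L)))
}

# glycerol-like triol: 3 donors, used for the >= 3 HBD census check
mk_triol <- function(id = "triol", shift = 0) {
  molecule3d(id, data.frame(
    elem = c("C", "C", "C", "O", "O", "O", "H", "H", "H"),
    x = c(0, 1.5, 3.0, 0, 1.5, 3.0, -0.6, 0.9, 2.4) + shift,
    y = c(0, 0.8, 0, -1.4, 2.2, -1.4, -2.1, 2.9, -2.1),
    z = 0),
    data.frame(i = c(1, 2, 1, 2, 3, 4, 5, 6),
               j = c(2, 3, 4, 5, 6, 7, 8, 9), order = 1L))
}

random_rotation <- function() {
  # QR-based uniform-ish random proper rotation
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# independent brute-force correspondence search used as the mapping oracle:
# enumerates every injective kind-respecting assignment directly and scores
# it with its own arithmetic (no clique machinery)
brute_force_map <- function(h, lig, allow_omit = 0L, match_tolerance = 1.0) {
  hk <- vapply(h$features, `[[`, "", "kind")
  lk <- vapply(lig, `[[`, "", "kind")
  hxy <- do.call(rbind, lapply(h$features, `[[`, "centroid"))
  lxy <- do.call(rbind, lapply(lig, `[[`, "centroid"))
  tol_r <- vapply(h$features, `[[`, numeric(1), "tolerance")
  dh <- as.matrix(dist(hxy)); dl <- as.matrix(dist(lxy))
  best <- NULL
  n <- length(hk)
  for (size in seq(n, max(1L, n - allow_omit))) {
    for (hsel in utils::combn(n, size, simplify = FALSE)) {
      # all injective assignments of hsel to ligand features, same kind
      assign_rec <- function(pos, used, cur) {
        if (pos > size) {
          ok <- TRUE
          if (size >= 2) for (a in 1:(size - 1)) for (b in (a + 1):size)
            if (abs(dh[hsel[a], hsel[b]] - dl[cur[a], cur[b]]) >
                match_tolerance) ok <- FALSE
          if (!ok) return(invisible())
          sp <- kabsch(lxy[cur, , drop = FALSE], hxy[hsel, , drop = FALSE])
          moved <- sweep(lxy[cur, , drop = FALSE] %*% t(sp$rotation), 2,
                         -sp$translation)
          dev <- sqrt(rowSums((moved - hxy[hsel, , drop = FALSE])^2))
          fit <- sum(pmax(0, 1 - (dev / tol_r[hsel])^2))
          if (is.null(best) || fit > best$fit + 1e-12)
            best <<- list(fit = fit, size = size)
          return(invisible())
        }
        for (cand in which(lk == hk[hsel[pos]])) {
          if (cand %in% used) next
          assign_rec(pos + 1L, c(used, cand), c(cur, cand))
        }
      }
      assign_rec(1L, integer(), integer())
    }
  }
  best
}
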