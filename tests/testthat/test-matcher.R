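# Matching core: clustering, Kabsch, correspondence search, scoring,
# ranking, and the brute-force oracle.

test_that("peaks cluster by covalent connectivity with height filtering", {
  host <- make_host_fixture()
  # two bonded peaks plus one isolated peak, far from cell edges
  base <- c(0.30, 0.60, 0.30)
  p2 <- base + drop(host$cell$ortho_inv %*% c(1.4, 0, 0))
  p3 <- base + drop(host$cell$ortho_inv %*% c(6, 0, 0))
  qp <- qpeak_set(host, data.frame(
    label = c("Q1", "Q2", "Q3"),
    x = c(base[1], p2[1], p3[1]), y = c(base[2], p2[2], p3[2]),
    z = c(base[3], p2[3], p3[3]), height = c(3, 2.8, 2.5)))
  cls <- filter_and_cluster(qp)
  expect_equal(vapply(cls, function(cl) length(cl$labels), integer(1)),
               c(2L, 1L))
  # a 4-peak zigzag with 1.5 A steps is one cluster
  zig <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.5, 0), c(3.0, 1.5, 0))
  zf <- t(apply(zig, 1, function(r) base + drop(host$cell$ortho_inv %*% r)))
  qp2 <- qpeak_set(host, data.frame(label = paste0("Q", 1:4),
                                    x = zf[, 1], y = zf[, 2], z = zf[, 3],
                                    height = c(3, 2.9, 2.8, 2.7)))
  cls2 <- filter_and_cluster(qp2)
  expect_length(cls2, 1L)
  expect_length(cls2[[1]]$labels, 4L)
  # weak peaks below height_min * max height are dropped
  qp3 <- qpeak_set(host, data.frame(label = c("Q1", "Q2"),
                                    x = c(base[1], p2[1]),
                                    y = c(base[2], p2[2]),
                                    z = c(base[3], p2[3]),
                                    height = c(10, 0.5)))
  cls3 <- filter_and_cluster(qp3)
  expect_equal(sum(vapply(cls3, function(cl) length(cl$labels), integer(1))),
               1L)
  # empty input is not an error
  empty <- qpeak_set(host, data.frame(label = character(0), x = numeric(0),
                                      y = numeric(0), z = numeric(0),
                                      height = numeric(0)))
  expect_equal(filter_and_cluster(empty), list())
})

test_that("clusters reassemble across the cell boundary via lattice images", {
  host <- host_structure(unit_cell(10, 10, 10),
                         list(nanosponge:::symop_identity()),
                         data.frame(label = "C1", element = "C",
                                    x = 0.5, y = 0.5, z = 0.5,
                                    occ = 1, uiso = 0.05), "p1")
  qp <- qpeak_set(host, data.frame(label = c("Q1", "Q2"),
                                   x = c(0.93, 0.07), y = c(0, 0),
                                   z = c(0, 0), height = c(3, 2.5)))
  cls <- filter_and_cluster(qp)
  expect_length(cls, 1L)
  expect_length(cls[[1]]$labels, 2L)
  # unwrapped Cartesian separation equals the brute-force minimum image
  d <- sqrt(sum((cls[[1]]$coords[1, ] - cls[[1]]$coords[2, ])^2))
  expect_equal(d, brute_min_image(host$cell, c(0.93, 0, 0), c(0.07, 0, 0)),
               tolerance = 1e-9)
})

test_that("symmetry-split fragments reassemble into one cluster", {
  # a two-peak fragment recorded as one peak plus the twofold image of the
  # other: expansion must reconnect them
  host <- make_host_fixture()
  a <- c(0.30, 0.60, 0.30)
  b_cart <- frac_to_cart(host$cell, a) + c(1.4, 0, 0)
  b <- cart_to_frac(host$cell, b_cart)
  b_img <- wrap_frac(symop_apply(host$symops[[2]], b))
  qp <- qpeak_set(host, data.frame(label = c("Q1", "Q2"),
                                   x = c(a[1], b_img[1]),
                                   y = c(a[2], b_img[2]),
                                   z = c(a[3], b_img[3]),
                                   height = c(3, 2.5)))
  cls <- filter_and_cluster(qp)
  expect_length(cls[[1]]$labels, 2L)
  d <- sqrt(sum((cls[[1]]$coords[1, ] - cls[[1]]$coords[2, ])^2))
  expect_equal(d, 1.4, tolerance = 1e-9)
})

test_that("Kabsch superposition is exact, proper, and analytic", {
  set.seed(11)
  P <- matrix(rnorm(15), 5, 3)
  fit <- kabsch_superpose(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  # a rigidly moved copy superposes to numerical zero
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- sweep(P %*% t(R), 2, c(1, -2, 3), "+")
  expect_lt(kabsch_superpose(P, Q)$rmsd, 1e-9)
  expect_equal(kabsch_superpose(P, Q)$rotation %*% R, diag(3),
               tolerance = 1e-9)
  # analytic collinear pair: half-length mismatch gives rmsd 0.5
  fit2 <- kabsch_superpose(rbind(c(-1, 0, 0), c(1, 0, 0)),
                           rbind(c(-0.5, 0, 0), c(0.5, 0, 0)))
  expect_equal(fit2$rmsd, 0.5, tolerance = 1e-12)
  expect_error(kabsch_superpose(P, P[1:3, ]), "equal size")
  # proper rotations only: reflections must not sneak in
  Qm <- P; Qm[, 1] <- -Qm[, 1]
  expect_equal(det(kabsch_superpose(P, Qm)$rotation), 1, tolerance = 1e-9)
})

test_that("correspondence search equals exhaustive enumeration", {
  lib <- test_lib()
  params <- matcher_params()
  set.seed(21)
  for (case in 1:5) {
    cd <- lib[[sample(c("urea", "DMF"), 1)]]
    cl <- cluster_from_conformer(cd, seed = 100 + case, sigma = 0.04)
    got <- correspondence_search(cl, cd, 1, params)
    keys <- corr_keys(got)
    Pd <- as.matrix(dist(cl$coords))
    Qd <- pairwise_distances(cd, 1)
    min_size <- ceiling(params$min_coverage * nrow(Qd))
    expected <- oracle_correspondences(Pd, Qd, params$pair_tol, min_size)
    expect_identical(keys, expected)
  }
})

test_that("correspondence search honors the coverage gate", {
  lib <- test_lib()
  cl2 <- make_cluster(rbind(c(0, 0, 0), c(1.4, 0, 0)))
  # 2 peaks cannot cover 60% of a 6-atom ring
  expect_length(correspondence_search(cl2, lib$pyridine, 1,
                                      matcher_params()), 0L)
  # an exact self-cluster always admits the full-size correspondence
  cl <- cluster_from_conformer(lib$urea, seed = 1, sigma = 0)
  got <- correspondence_search(cl, lib$urea, 1, matcher_params())
  expect_true(any(vapply(got, nrow, integer(1)) == 4L))
})

test_that("match_candidate recovers pose and scales with noise", {
  lib <- test_lib()
  cl <- cluster_from_conformer(lib$urea, seed = 2, sigma = 0)
  m <- match_candidate(cl, lib$urea)
  expect_equal(m$coverage, 1.0)
  expect_lt(m$rmsd, 1e-9)
  expect_equal(det(m$rotation), 1, tolerance = 1e-8)
  # jittered self-match lands in the expected rmsd band
  sig <- 0.1
  rmsds <- vapply(1:10, function(s) {
    clj <- cluster_from_conformer(lib$pyridine, seed = 200 + s, sigma = sig)
    match_candidate(clj, lib$pyridine)$rmsd
  }, numeric(1))
  expect_true(all(rmsds >= sig / 2 & rmsds <= 3 * sig))
  # determinism
  cl2 <- cluster_from_conformer(lib$DEF, seed = 9, sigma = 0.05)
  expect_identical(match_candidate(cl2, lib$DEF),
                   match_candidate(cl2, lib$DEF))
})

test_that("rmsd is invariant under a common rigid motion", {
  lib <- test_lib()
  cl <- cluster_from_conformer(lib$DMF, seed = 31, sigma = 0.06)
  m0 <- match_candidate(cl, lib$DMF)
  set.seed(99)
  M <- matrix(rnorm(9), 3, 3); qr_ <- qr(M)
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  cl2 <- cl
  cl2$coords <- sweep(cl$coords %*% t(R), 2, c(3, -1, 2), "+")
  m1 <- match_candidate(cl2, lib$DMF)
  expect_lt(abs(m0$rmsd - m1$rmsd), 1e-8)
})

test_that("clique search agrees with the brute-force oracle on small cases", {
  lib <- test_lib()
  small <- lib[vapply(lib, function(cd) length(cd$elements) <= 7, logical(1))]
  params <- matcher_params()
  for (s in 1:10) {
    cd <- small[[(s %% length(small)) + 1]]
    cl <- cluster_from_conformer(cd, seed = 400 + s, sigma = 0.04)
    m <- match_candidate(cl, cd, params)
    b <- brute_force_match(cl, cd, params)
    expect_equal(m$score, b$score, tolerance = 1e-9)
  }
  # the guard refuses oversized problems
  big <- cluster_from_conformer(lib$`benzoic acid`, seed = 1)
  expect_error(brute_force_match(big, lib$`benzoic acid`), "refuses")
  # no admissible correspondence: both routes return NULL
  cl2 <- make_cluster(rbind(c(0, 0, 0), c(1.4, 0, 0)))
  expect_null(match_candidate(cl2, lib$pyridine, params))
  expect_null(brute_force_match(cl2, lib$pyridine, params))
  # single peak vs single atom superposes exactly
  one <- candidate_from_coords("atom", "C", matrix(0, 1, 3))
  m1 <- brute_force_match(make_cluster(matrix(c(1, 2, 3), 1)), one, params)
  expect_equal(m1$rmsd, 0)
})

test_that("increasing pair_tol never shrinks the largest correspondence", {
  lib <- test_lib()
  cl <- cluster_from_conformer(lib$pyridine, seed = 55, sigma = 0.12)
  sizes <- vapply(c(0.05, 0.15, 0.25, 0.4, 0.6), function(tol) {
    got <- correspondence_search(cl, lib$pyridine, 1,
                                 matcher_params(pair_tol = tol,
                                                min_coverage = 0.3))
    if (!length(got)) 0L else max(vapply(got, nrow, integer(1)))
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("ranking prefers the true guest over its sub-fragment", {
  lib <- test_lib()
  cl <- cluster_from_conformer(lib$DEF, seed = 77, sigma = 0.02)
  rk <- rank_candidates(cl, candidate_set(list(lib$DMF, lib$DEF)))
  # DMF is a geometric substructure of DEF: it matches, but DEF wins
  expect_equal(rk$table$candidate[1], "DEF")
  expect_true(rk$table$matched[rk$table$candidate == "DMF"] >= 3)
  # in paper mode (raw RMSD) the fragment may legitimately outrank
  rk0 <- rank_candidates(cl, candidate_set(list(lib$DMF, lib$DEF)),
                         matcher_params(coverage_weight = 0))
  expect_true(all(is.finite(rk0$table$score)))
})

test_that("a synthetic pyridine cluster tops the full ten-guest ranking", {
  lib <- test_lib()
  cl <- cluster_from_conformer(lib$pyridine, seed = 13, sigma = 0.03)
  rk <- rank_candidates(cl, lib)
  expect_true("pyridine" %in% rk$table$candidate[rk$table$rank == 1])
  # rejected candidates trail with infinite score
  expect_true(all(diff(is.infinite(rk$table$score)) >= 0))
})

test_that("near-equal scores tie and order alphabetically", {
  lib <- test_lib()
  cl <- cluster_from_conformer(lib$pyridine, seed = 13, sigma = 0.03)
  # duplicate the winning candidate under two names differing only in name
  dup <- lib$pyridine; dup$name <- "azine"
  rk <- rank_candidates(cl, candidate_set(list(lib$pyridine, dup)))
  expect_equal(rk$table$rank, c(1L, 1L))
  expect_equal(rk$table$candidate, c("azine", "pyridine"))
})
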