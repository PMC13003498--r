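# Synthetic Q-peak generator: self-consistency, reproducibility, and the
# statistics of the injected corruptions.

test_that("a clean simulation matches its own candidate exactly", {
  lib <- test_lib()
  sim <- simulate_qpeaks("urea", lib, seed = 1, sigma = 0)
  cl <- filter_and_cluster(sim$qpeaks)[[1]]
  m <- match_candidate(cl, lib$urea)
  expect_lt(m$rmsd, 1e-9)
  expect_equal(m$coverage, 1.0)
})

test_that("simulation is byte-identical for a fixed seed", {
  lib <- test_lib()
  a <- simulate_qpeaks("DEF", lib, seed = 99, sigma = 0.08, n_spurious = 2)
  b <- simulate_qpeaks("DEF", lib, seed = 99, sigma = 0.08, n_spurious = 2)
  expect_identical(a, b)
  c <- simulate_qpeaks("DEF", lib, seed = 100, sigma = 0.08, n_spurious = 2)
  expect_false(identical(a$qpeaks$peaks, c$qpeaks$peaks))
})

test_that("the simulator does not disturb the global RNG stream", {
  lib <- test_lib()
  set.seed(5)
  before <- runif(1)
  set.seed(5)
  invisible(simulate_qpeaks("urea", lib, seed = 42))
  expect_identical(runif(1), before)
})

test_that("peak deletion concentrates at the binomial rate", {
  lib <- test_lib()
  n_total <- 0L; n_kept <- 0L
  for (s in 1:125) {
    sim <- simulate_qpeaks("benzaldehyde", lib, seed = s, sigma = 0,
                           p_miss = 0.2)
    n_total <- n_total + 8L
    n_kept <- n_kept + sum(sim$truth$provenance != "spurious")
  }
  deleted_frac <- 1 - n_kept / n_total
  expect_gte(deleted_frac, 0.17)
  expect_lte(deleted_frac, 0.23)
})

test_that("exact-count deletion removes exactly n_miss peaks", {
  lib <- test_lib()
  sim <- simulate_qpeaks("pyridine", lib, seed = 4, n_miss = 2)
  expect_equal(nrow(sim$qpeaks$peaks), 4L)
  expect_error(simulate_qpeaks("urea", lib, seed = 1, n_miss = 4),
               "at least one")
})

test_that("jitter displacement statistics are sigma-consistent", {
  lib <- test_lib()
  host <- make_host_fixture()
  sigma <- 0.1
  sq <- numeric(0)
  for (s in 1:1700) {
    sim <- simulate_qpeaks("cyclohexane", lib, host, seed = 20000 + s,
                           sigma = sigma)
    conf <- lib$cyclohexane$conformers[[sim$truth$conformer]]
    ideal <- sweep(conf %*% t(sim$truth$rotation), 2,
                   sim$truth$translation, "+")
    pk <- sim$qpeaks$peaks
    obs <- frac_to_cart(host$cell, as.matrix(pk[, c("x", "y", "z")]))
    idx <- as.integer(sim$truth$provenance)
    # peaks are wrapped into the cell; compare via minimum image
    for (r in seq_len(nrow(pk))) {
      ifr <- cart_to_frac(host$cell, ideal[idx[r], ])
      sq <- c(sq, min_image_distance(host$cell,
                                     unlist(pk[r, c("x", "y", "z")]),
                                     ifr)^2)
    }
    if (length(sq) >= 10000) break
  }
  # mean squared displacement of an isotropic N(0, sigma^2) jitter: 3 sigma^2
  expect_equal(mean(sq), 3 * sigma^2, tolerance = 0.05)
})

test_that("spurious peaks stay clear of true peaks and rank below them", {
  lib <- test_lib()
  host <- make_host_fixture()
  hs <- numeric(0); ht <- numeric(0)
  for (s in 1:20) {
    sim <- simulate_qpeaks("urea", lib, host, seed = 500 + s, sigma = 0.05,
                           n_spurious = 2)
    pk <- sim$qpeaks$peaks
    spur <- sim$truth$provenance == "spurious"
    dm <- min_image_dist_matrix(host$cell,
                                as.matrix(pk[spur, c("x", "y", "z")]),
                                as.matrix(pk[!spur, c("x", "y", "z")]))
    expect_gte(min(dm), 2.5)
    hs <- c(hs, pk$height[spur]); ht <- c(ht, pk$height[!spur])
  }
  expect_gt(mean(ht), mean(hs))
})

test_that("the packaged host fixture has I2/a symmetry and round-trips", {
  host <- make_host_fixture()
  expect_length(host$symops, 8L)
  expect_equal(host$cell$volume, 3617, tolerance = 0.005)
  # the metal orbit is symmetry-consistent: every operator maps the site
  # into the orbit generated by the full list
  bi <- unlist(host$sites[1, c("x", "y", "z")])
  orb <- expand_equivalents(host$cell, host$symops, bi)
  for (op in host$symops) {
    img <- wrap_frac(symop_apply(op, bi))
    d <- min_image_dist_matrix(host$cell, matrix(img, 1), orb)
    expect_lt(min(d), 1e-6)
  }
  tmp <- tempfile(fileext = ".res")
  write_ins_model(host, NULL, tmp)
  rt <- read_res(tmp)$host
  expect_equal(as.matrix(rt$sites[, c("x", "y", "z")]),
               as.matrix(host$sites[, c("x", "y", "z")]), tolerance = 1e-6)
  expect_length(rt$symops, 8L)
})
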