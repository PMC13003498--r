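# Crystallographic geometry kernel: cells, conversions, periodic
# distances, symmetry operations.

test_that("fractional to Cartesian conversion matches the metric tensor", {
  # axis-aligned cubic cell and the origin fixed point
  cl <- unit_cell(10, 10, 10)
  expect_equal(frac_to_cart(cl, c(0.5, 0.5, 0.5)), c(5, 5, 5))
  expect_equal(frac_to_cart(cl, c(0, 0, 0)), c(0, 0, 0))

  # |r|^2 = p' G p with G built directly from the cell parameters
  cl <- unit_cell(10, 12, 14, 90, 100, 90)
  G <- matrix(0, 3, 3)
  len <- c(10, 12, 14); ang <- c(90, 100, 90) * pi / 180
  G[1, 1] <- len[1]^2; G[2, 2] <- len[2]^2; G[3, 3] <- len[3]^2
  G[1, 2] <- G[2, 1] <- len[1] * len[2] * cos(ang[3])
  G[1, 3] <- G[3, 1] <- len[1] * len[3] * cos(ang[2])
  G[2, 3] <- G[3, 2] <- len[2] * len[3] * cos(ang[1])
  for (p in list(c(1, 0, 0), c(0.3, -0.2, 0.7), c(0.5, 0.5, 0.5))) {
    r <- frac_to_cart(cl, p)
    expect_equal(sum(r^2), drop(t(p) %*% G %*% p), tolerance = 1e-10)
  }
})

test_that("frac/cart roundtrip is exact to 1e-10 for random cells", {
  set.seed(42)
  for (rep in 1:20) {
    cl <- random_cell()
    p <- matrix(runif(150, -2, 3), 50, 3)
    back <- cart_to_frac(cl, frac_to_cart(cl, p))
    expect_lt(max(abs(back - p)), 1e-10)
  }
})

test_that("degenerate cells are rejected", {
  expect_error(unit_cell(-1, 10, 10), "positive")
  expect_error(unit_cell(10, 10, 10, 10, 10, 170), "positive-definite")
  expect_error(unit_cell(10, 10, 10, 0, 90, 90), "angles")
})

test_that("minimum-image distance wraps across cell edges and is a metric", {
  cl <- unit_cell(10, 10, 10)
  expect_equal(min_image_distance(cl, c(0.05, 0, 0), c(0.95, 0, 0)), 1.0)
  p <- c(0.3, 0.7, 0.2)
  expect_equal(min_image_distance(cl, p, p), 0)
  expect_equal(min_image_distance(cl, p, p + c(1, -2, 3)), 0, tolerance = 1e-9)
})

test_that("minimum-image distance equals the 5^3 brute-force oracle", {
  set.seed(7)
  for (rep in 1:10) {
    cl <- random_cell()
    for (i in 1:10) {
      p <- runif(3); q <- runif(3)
      expect_equal(min_image_distance(cl, p, q), brute_min_image(cl, p, q),
                   tolerance = 1e-9)
    }
  }
})

test_that("symmetry strings parse to the documented action", {
  id <- parse_symop("x, y, z")
  expect_equal(id$R, diag(3))
  expect_equal(id$t, c(0, 0, 0))
  inv <- parse_symop("-x, -y, -z")
  expect_equal(inv$R, -diag(3))
  op <- parse_symop("1/2+x, 1/2-y, -z")
  expect_equal(symop_apply(op, c(0.1, 0.2, 0.3)), c(0.6, 0.3, -0.3),
               tolerance = 1e-12)
  # decimal translations and whitespace tolerance
  op2 <- parse_symop(" 0.5+x ,  y, z ")
  expect_equal(op2$t, c(0.5, 0, 0))
})

test_that("malformed symmetry strings name the offending component", {
  expect_error(parse_symop("x, y"), "3 comma-separated")
  expect_error(parse_symop("x, y, q"), "malformed")
  expect_error(parse_symop("1/7+x, y, z"), "non-crystallographic")
})

test_that("symop string round-trip is idempotent", {
  ops <- expand_latt_symm(2L, "1/2-X, Y, -Z")
  for (op in ops) {
    op2 <- parse_symop(symop_to_string(op))
    expect_equal(op2$R, op$R)
    expect_equal(op2$t, op$t, tolerance = 1e-12)
    expect_identical(symop_to_string(op2), symop_to_string(op))
  }
})

test_that("orbits have the expected sizes and divide the group order", {
  cl <- unit_cell(10.85, 15, 22.35, 90, 95.5, 90)
  # identity-only group
  orb <- expand_equivalents(cl, list(nanosponge:::symop_identity()),
                            c(0.1, 0.2, 0.3))
  expect_equal(nrow(orb), 1L)
  # general position of a 2-op group
  two <- list(parse_symop("x, y, z"), parse_symop("-x, y, -z"))
  expect_equal(nrow(expand_equivalents(cl, two, c(0.13, 0.4, 0.21))), 2L)
  # special position on the twofold axis collapses
  expect_equal(nrow(expand_equivalents(cl, two, c(0, 0.37, 0))), 1L)
  # orbit sizes divide the group order for the full I2/a list
  ops <- expand_latt_symm(2L, "1/2-X, Y, -Z")
  set.seed(3)
  for (i in 1:5) {
    n <- nrow(expand_equivalents(cl, ops, runif(3)))
    expect_equal(length(ops) %% n, 0L)
  }
})

test_that("the symmetry set closes into a group under composition", {
  ops <- expand_latt_symm(2L, "1/2-X, Y, -Z")
  expect_length(ops, 8L)
  keys <- vapply(ops, nanosponge:::symop_key, character(1))
  for (a in ops) for (b in ops) {
    ab <- symop_compose(a, b)
    expect_true(nanosponge:::symop_key(ab) %in% keys)
  }
})
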