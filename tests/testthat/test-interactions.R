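# Host-guest contact classification and the symmetry-clash occupancy cap.

# P1 host with one Bi and one water O for controlled-distance tests
p1_host <- function(cell = unit_cell(20, 20, 20)) {
  host_structure(cell, list(nanosponge:::symop_identity()),
                 data.frame(label = c("Bi1", "O1W"),
                            element = c("Bi", "O"),
                            x = c(0.0, 0.5), y = c(0.0, 0.5),
                            z = c(0.0, 0.5), occ = 1,
                            uiso = c(0.02, 0.05)), "p1-probe")
}

test_that("metal-oxygen contacts inside the window are coordination", {
  host <- p1_host()
  g <- single_atom_guest(c(2.75 / 20, 0, 0), "O")
  tab <- classify_contacts(host, g)
  expect_equal(tab$kind[tab$host_atom == "Bi1"], "coordination")
  expect_equal(tab$distance[tab$host_atom == "Bi1"], 2.75, tolerance = 1e-9)
})

test_that("guest N near a host water O is a hydrogen bond", {
  host <- p1_host()
  g <- single_atom_guest(c(0.5 + 2.74 / 20, 0.5, 0.5), "N")
  tab <- classify_contacts(host, g)
  expect_equal(tab$kind, "hydrogen_bond")
  expect_equal(tab$distance, 2.74, tolerance = 1e-9)
})

test_that("a distant nonpolar guest falls back to van der Waals", {
  host <- p1_host()
  g <- single_atom_guest(c(3.9 / 20, 0, 0), "C")
  tab <- classify_contacts(host, g)
  expect_equal(tab$kind, "van_der_waals")
  expect_equal(tab$distance, 3.9, tolerance = 1e-9)
  # exhaustive: every guest gets at least one label
  expect_gte(nrow(tab), 1L)
})

test_that("interaction kinds are mutually exclusive per atom pair", {
  host <- p1_host()
  # O at 2.75 A from Bi: coordination must suppress a duplicate H-bond
  g <- single_atom_guest(c(2.75 / 20, 0, 0), "O")
  tab <- classify_contacts(host, g)
  keys <- paste(tab$guest_atom, tab$host_atom)
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("aromatic rings near framework atoms give pi-stacking", {
  host <- p1_host()
  lib <- test_lib()
  # place the pyridine ring with its centroid 3.4 A from the water O
  conf <- lib$pyridine$conformers[[1]]
  cen <- colMeans(conf)
  target <- frac_to_cart(host$cell, c(0.5, 0.5, 0.5)) + c(3.4, 0, 0)
  cart <- sweep(conf, 2, cen) + matrix(target, nrow(conf), 3, byrow = TRUE)
  g <- guest_from_coords(host$cell, cart, lib$pyridine$elements)
  tab <- classify_contacts(host, g)
  expect_true("pi_stacking" %in% tab$kind)
  pis <- tab[tab$kind == "pi_stacking", ]
  expect_true(any(abs(pis$distance - 3.4) < 0.1))
})

test_that("ring centroids require planarity and non-collinearity", {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  hexa <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  cen <- ring_centroid(hexa)
  expect_equal(cen, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sqrt(sum((hexa[1, ] - cen)^2)), 1.39, tolerance = 1e-9)
  # invariant under relabeling
  expect_equal(ring_centroid(hexa[c(4, 2, 6, 1, 3, 5), ]), cen,
               tolerance = 1e-12)
  expect_error(ring_centroid(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
  bent <- hexa; bent[1, 3] <- 0.8
  expect_error(ring_centroid(bent), "planar")
  expect_error(ring_centroid(hexa[1:2, ]), "at least 3")
})

test_that("a guest clashing with one twofold image is capped at 50%", {
  # twofold along b through the origin; place the atom so its image sits
  # 2.0 A away (too short for simultaneous occupancy)
  cell <- unit_cell(12, 14, 16)
  host <- host_structure(cell, lapply(c("x, y, z", "-x, y, -z"),
                                      parse_symop),
                         data.frame(label = "Bi1", element = "Bi",
                                    x = 0.4, y = 0.1, z = 0.4, occ = 1,
                                    uiso = 0.02), "twofold")
  g <- single_atom_guest(c(1.0 / 12, 0.25, 0), "C")  # image at 2.0 A
  expect_equal(occupancy_cap(host, g), 0.5)
  # an isolated guest is uncapped
  g2 <- single_atom_guest(c(0.25, 0.25, 0.25), "C")
  expect_equal(occupancy_cap(host, g2), 1.0)
})

test_that("mutually clashing fourfold images cap occupancy at 25%", {
  # fourfold axis: orbit of four points all within the clash distance
  cell <- unit_cell(10, 10, 10)
  host <- host_structure(cell, symop_group(list(parse_symop("-y, x, z"))),
                         data.frame(label = "M1", element = "Bi",
                                    x = 0.45, y = 0.25, z = 0.1, occ = 1,
                                    uiso = 0.02), "fourfold")
  g <- single_atom_guest(c(0.08, 0, 0.3), "C")
  # brute-force check of the constructed clash graph: orbit radius 0.8 A,
  # adjacent images 1.13 A, opposite 1.6 A -- all below 2.2
  expect_equal(occupancy_cap(host, g), 0.25)
})

test_that("the occupancy cap is invariant under full lattice translation", {
  host <- make_host_fixture()
  lib <- test_lib()
  sim <- simulate_qpeaks("urea", lib, host, seed = 21, sigma = 0.02)
  cl <- filter_and_cluster(sim$qpeaks)[[1]]
  m <- match_candidate(cl, lib$urea)
  model <- apply_atom_types(place_guest_as_carbons(m, cl, host, lib$urea))
  cap1 <- occupancy_cap(host, model)
  shifted <- model
  shifted$atoms$x <- shifted$atoms$x + 1
  shifted$atoms$z <- shifted$atoms$z - 2
  expect_equal(occupancy_cap(host, shifted), cap1)
})

test_that("refined occupancies above the cap are flagged", {
  expect_false(occupancy_exceeds_cap(0.35, 0.5))
  expect_true(occupancy_exceeds_cap(0.60, 0.5))
  expect_false(occupancy_exceeds_cap(0.50, 0.5))
})
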