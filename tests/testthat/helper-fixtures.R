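# Shared fixtures and independent oracles for the test suite.

.cache <- new.env(parent = emptyenv())

# Ten-guest panel, generated once per test run (deterministic, seed 1).
test_lib <- function() {
  if (is.null(.cache$lib)) .cache$lib <- guest_library(seed = 1L)
  .cache$lib
}

# Random valid cell: edges 6-20 A, angles 70-110 deg (realistic, and far
# from the degenerate regime where the one-shell minimum-image search
# would be insufficient).
random_cell <- function() {
  unit_cell(runif(1, 6, 20), runif(1, 6, 20), runif(1, 6, 20),
            runif(1, 70, 110), runif(1, 70, 110), runif(1, 70, 110))
}

# Independent oracle: minimum-image distance by brute force over the
# 5^3 block of lattice translations.
brute_min_image <- function(cell, p, q) {
  best <- Inf
  for (i in -2:2) for (j in -2:2) for (k in -2:2) {
    r <- cell$ortho %*% (q + c(i, j, k) - p)
    best <- min(best, sqrt(sum(r * r)))
  }
  best
}

# Bare cluster from explicit Cartesian coordinates (no host needed).
make_cluster <- function(coords, labels = paste0("Q", seq_len(nrow(coords)))) {
  coords <- as.matrix(coords)
  list(labels = labels, heights = rev(seq_len(nrow(coords))),
       coords = coords, frac = NULL,
       peak_refs = data.frame(label = labels, symop = 1L),
       context = NULL)
}

# Cluster generated from a candidate conformer under a seeded rigid motion
# plus optional jitter: the self-match ground truth for matcher tests.
cluster_from_conformer <- function(candidate, conformer = 1, seed = 1,
                                   sigma = 0) {
  set.seed(seed)
  conf <- candidate$conformers[[conformer]]
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  t0 <- runif(3, -5, 5)
  pts <- sweep(conf %*% t(R), 2, t0, "+")
  if (sigma > 0) pts <- pts + matrix(rnorm(length(pts), sd = sigma),
                                     nrow(pts), 3)
  make_cluster(pts)
}

# Independent oracle for the correspondence search: every injective
# assignment (peak subset -> atom subset, all orders) that passes the
# pairwise distance test, reduced to the maximal ones.
oracle_correspondences <- function(Pd, Qd, tol, min_size) {
  np <- nrow(Pd); na <- nrow(Qd)
  all_sets <- list()
  for (k in seq(from = max(min_size, 1), to = min(np, na))) {
    for (ps in utils::combn(np, k, simplify = FALSE)) {
      for (as_ in utils::combn(na, k, simplify = FALSE)) {
        for (perm in all_perms(k)) {
          atoms <- as_[perm]
          ok <- TRUE
          if (k >= 2) {
            for (i in 1:(k - 1)) for (j in (i + 1):k) {
              if (abs(Pd[ps[i], ps[j]] - Qd[atoms[i], atoms[j]]) > tol) {
                ok <- FALSE; break
              }
              if (!ok) break
            }
          }
          if (ok) all_sets[[length(all_sets) + 1]] <-
              sort(paste(ps, atoms, sep = ":"))
        }
      }
    }
  }
  if (!length(all_sets)) return(character(0))
  keys <- vapply(all_sets, paste, character(1), collapse = ",")
  uniq <- all_sets[!duplicated(keys)]
  # keep maximal sets only
  maximal <- vapply(seq_along(uniq), function(i) {
    !any(vapply(seq_along(uniq), function(j)
      i != j && all(uniq[[i]] %in% uniq[[j]]), logical(1)))
  }, logical(1))
  sort(vapply(uniq[maximal], paste, character(1), collapse = ","))
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) for (pos in seq_len(k))
    out[[length(out) + 1]] <- append(p, k, after = pos - 1L)
  out
}

# Serialize correspondences from correspondence_search the same way.
corr_keys <- function(corrs) {
  sort(vapply(corrs, function(m)
    paste(sort(paste(m[, "peak"], m[, "atom"], sep = ":")), collapse = ","),
    character(1)))
}

# A host with a single-atom "guest" at given fractional position, for
# interaction and occupancy tests.
single_atom_guest <- function(frac, element = "C") {
  structure(list(atoms = data.frame(
    label = "G1", element = element, x = frac[1], y = frac[2], z = frac[3],
    occ = 1, uiso = 0.05, provenance = "Q1", suggested_element = element),
    candidate = "probe"), class = "guest_model")
}

guest_from_coords <- function(cell, cart, elements) {
  frac <- wrap_frac(cart_to_frac(cell, cart))
  frac <- as.matrix(frac)
  structure(list(atoms = data.frame(
    label = paste0("G", seq_len(nrow(frac))), element = elements,
    x = frac[, 1], y = frac[, 2], z = frac[, 3],
    occ = 1, uiso = 0.05, provenance = "sim",
    suggested_element = elements), candidate = "probe"),
    class = "guest_model")
}
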