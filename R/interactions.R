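# Host-guest interaction classification and the symmetry-clash occupancy
# cap. Hydrogens are unavailable before refinement, so hydrogen bonds are
# detected donor-heavy-atom to acceptor-heavy-atom (N/O...N/O), and offset
# pi-stacking by the guest ring-centroid to nearest framework atom.

#' Interaction classification parameters
#'
#' @param coord_range Metal-to-guest-oxygen coordination window (A).
#' @param hbond_range Donor-acceptor N/O...N/O window (A).
#' @param pistack_max Maximum guest-ring-centroid to framework-atom
#'   distance (A) for offset pi-stacking.
#' @param clash_dist Heavy-atom distance (A) below which simultaneous
#'   occupancy of two symmetry copies is chemically infeasible.
#' @param metals Element symbols treated as coordination centers.
#' @return Object of class `interaction_params`.
#' @export
interaction_params <- function(coord_range = c(2.4, 2.86),
                               hbond_range = c(2.5, 3.1),
                               pistack_max = 3.7, clash_dist = 2.2,
                               metals = "Bi") {
  if (coord_range[1] <= 0 || coord_range[1] >= coord_range[2])
    stop("coord_range must be an increasing positive window")
  if (hbond_range[1] <= 0 || hbond_range[1] >= hbond_range[2])
    stop("hbond_range must be an increasing positive window")
  if (pistack_max <= 0 || clash_dist <= 0)
    stop("pistack_max and clash_dist must be positive")
  structure(list(coord_range = coord_range, hbond_range = hbond_range,
                 pistack_max = pistack_max, clash_dist = clash_dist,
                 metals = metals),
            class = "interaction_params")
}

# minimum-image + symmetry distance from one guest atom (frac) to the
# orbit of one host site; returns distance and the symop index realizing it
symmetry_min_dist <- function(cell, ops, p, q) {
  best <- Inf; best_op <- 1L
  for (i in seq_along(ops)) {
    qi <- wrap_frac(symop_apply(ops[[i]], q))
    d <- min_image_distance(cell, p, qi)
    if (d < best) { best <- d; best_op <- i }
  }
  list(distance = best, symop = best_op)
}

#' Classify host-guest contacts
#'
#' Applies, in priority order: coordination (host metal to guest oxygen
#' within `coord_range`), hydrogen bonding (guest N/O to host N/O within
#' `hbond_range`, excluding pairs already classified as coordination and
#' host metal sites), offset pi-stacking (guest aromatic-ring centroid to
#' any framework atom within `pistack_max`), and, when none of those is
#' found, a residual van der Waals label carrying the closest host
#' contact. All distances are periodic minimum-image distances over the
#' full symmetry orbit of the host sites.
#'
#' @param host A [host_structure()].
#' @param guest A `guest_model` with finalized elements (after
#'   [apply_atom_types()]).
#' @param params An [interaction_params()].
#' @param rings Optional list of integer vectors (guest atom indices) to
#'   use as aromatic rings; by default rings are detected from bonded
#'   5/6-cycles among guest atoms with inferred connectivity.
#' @return Data frame of class `interaction_table`: columns `kind`,
#'   `guest_atom`, `host_atom`, `distance`, `symop`.
#' @export
classify_contacts <- function(host, guest, params = interaction_params(),
                              rings = NULL) {
  stopifnot(inherits(host, "host_structure"), inherits(guest, "guest_model"))
  ga <- guest$atoms
  gfrac <- as.matrix(ga[, c("x", "y", "z")])
  hs <- host$sites
  out <- list()
  coord_pairs <- matrix(FALSE, nrow(ga), nrow(hs))
  for (i in seq_len(nrow(ga))) for (j in seq_len(nrow(hs))) {
    sm <- symmetry_min_dist(host$cell, host$symops, gfrac[i, ],
                            c(hs$x[j], hs$y[j], hs$z[j]))
    d <- sm$distance
    if (hs$element[j] %in% params$metals && ga$element[i] == "O" &&
        d >= params$coord_range[1] && d <= params$coord_range[2]) {
      coord_pairs[i, j] <- TRUE
      out[[length(out) + 1]] <- data.frame(
        kind = "coordination", guest_atom = ga$label[i],
        host_atom = hs$label[j], distance = d, symop = sm$symop)
    } else if (ga$element[i] %in% c("N", "O") &&
               hs$element[j] %in% c("N", "O") &&
               d >= params$hbond_range[1] && d <= params$hbond_range[2]) {
      out[[length(out) + 1]] <- data.frame(
        kind = "hydrogen_bond", guest_atom = ga$label[i],
        host_atom = hs$label[j], distance = d, symop = sm$symop)
    }
  }
  if (is.null(rings)) rings <- detect_rings(host$cell, guest)
  for (ring in rings) {
    cart <- frac_to_cart(host$cell, gfrac[ring, , drop = FALSE])
    cen <- tryCatch(ring_centroid(cart), error = function(e) NULL)
    if (is.null(cen)) next
    cen_frac <- cart_to_frac(host$cell, cen)
    for (j in seq_len(nrow(hs))) {
      sm <- symmetry_min_dist(host$cell, host$symops, cen_frac,
                              c(hs$x[j], hs$y[j], hs$z[j]))
      if (sm$distance <= params$pistack_max) {
        out[[length(out) + 1]] <- data.frame(
          kind = "pi_stacking",
          guest_atom = paste0("ring(", paste(ga$label[ring], collapse = ","),
                              ")"),
          host_atom = hs$label[j], distance = sm$distance, symop = sm$symop)
      }
    }
  }
  if (!length(out)) {
    # residual class: van der Waals stabilization, closest contact reported
    best <- list(d = Inf, i = 1L, j = 1L, op = 1L)
    for (i in seq_len(nrow(ga))) for (j in seq_len(nrow(hs))) {
      sm <- symmetry_min_dist(host$cell, host$symops, gfrac[i, ],
                              c(hs$x[j], hs$y[j], hs$z[j]))
      if (sm$distance < best$d)
        best <- list(d = sm$distance, i = i, j = j, op = sm$symop)
    }
    out[[1]] <- data.frame(
      kind = "van_der_waals", guest_atom = ga$label[best$i],
      host_atom = hs$label[best$j], distance = best$d, symop = best$op)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("interaction_table", class(tab))
  tab
}

# 5- and 6-cycles among guest atoms, connectivity inferred from the
# covalent distance window on minimum-image distances
detect_rings <- function(cell, guest) {
  gfrac <- as.matrix(guest$atoms[, c("x", "y", "z")])
  n <- nrow(gfrac)
  if (n < 5) return(list())
  d <- min_image_dist_matrix(cell, gfrac, gfrac)
  adj <- d >= 1.1 & d <= 1.8
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  rings <- list()
  seen <- character(0)
  for (len in c(5L, 6L)) {
    for (v in seq_len(n)) {
      paths <- find_cycles_from(adj, v, len)
      for (p in paths) {
        key <- paste(sort(p), collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        rings[[length(rings) + 1]] <- p
      }
    }
  }
  rings
}

find_cycles_from <- function(adj, start, len) {
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (length(path) == len) {
      if (adj[v, start] && start == min(path)) out[[length(out) + 1]] <<- path
      return()
    }
    for (w in which(adj[v, ])) {
      if (w %in% path || w < start) next
      walk(c(path, w))
    }
  }
  walk(start)
  out
}

#' Centroid of an approximately planar ring
#'
#' Unweighted mean of the atom positions; rejects sets of fewer than three
#' atoms, collinear sets, and sets deviating more than `planar_tol` from
#' their best plane.
#'
#' @param coords n x 3 Cartesian coordinates (A) of the ring atoms.
#' @param planar_tol Maximum out-of-plane deviation (A, default 0.3).
#' @return Length-3 Cartesian centroid.
#' @export
ring_centroid <- function(coords, planar_tol = 0.3) {
  coords <- as_coord_matrix(coords)
  if (nrow(coords) < 3) stop("a ring needs at least 3 atoms")
  X <- sweep(coords, 2, colMeans(coords))
  sv <- svd(X)
  if (sv$d[2] < 1e-6)
    stop("degenerate ring: atoms are collinear")
  oop <- max(abs(X %*% sv$v[, 3]))
  if (oop > planar_tol)
    stop(sprintf("ring is not planar (max deviation %.2f A > %.2f A)",
                 oop, planar_tol))
  colMeans(coords)
}

#' Symmetry-clash cap on site occupancy
#'
#' Generates the symmetry and lattice images of the guest, keeps the
#' images having any heavy-atom pair within `clash_dist` of the reference
#' copy, builds the mutual-clash graph among reference and images, and
#' returns `1 / k` where `k` is the largest mutually clashing set
#' containing the reference copy. A guest whose images never clash gets
#' 1.0; a guest clashing with exactly one symmetry copy gets 0.5.
#'
#' @param host A [host_structure()].
#' @param guest A `guest_model` (or data frame of fractional coordinates).
#' @param params An [interaction_params()] (supplies `clash_dist`).
#' @return Occupancy cap as a fraction in (0, 1].
#' @export
occupancy_cap <- function(host, guest, params = interaction_params()) {
  gfrac <- if (inherits(guest, "guest_model"))
    as.matrix(guest$atoms[, c("x", "y", "z")]) else as_coord_matrix(guest)
  # atoms are stored wrapped into [0,1)^3; rebuild a contiguous molecule
  # (anchor at atom 1, every other atom at its minimum image) so symmetry
  # copies are rigid molecules, not boundary-split fragments
  if (nrow(gfrac) > 1) {
    for (i in 2:nrow(gfrac)) {
      mi <- min_image_vector(host$cell, gfrac[1, ], gfrac[i, ])
      gfrac[i, ] <- gfrac[1, ] + mi$dfrac
    }
  }
  ref_cart <- frac_to_cart(host$cell, gfrac)
  clash <- params$clash_dist
  # images clashing with the reference copy (only those can share a clique
  # with it); lattice shifts one shell around each symmetry image
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  images <- list()
  ref_cen <- colMeans(gfrac)
  for (oi in seq_along(host$symops)) {
    base <- symop_apply(host$symops[[oi]], gfrac)
    base <- as_coord_matrix(base)
    # recentre the image near the reference before scanning the adjacent
    # shell, so wrapping offsets cannot push a clash out of range
    base <- sweep(base, 2, round(colMeans(base) - ref_cen))
    for (s in seq_len(nrow(shifts))) {
      img_frac <- sweep(base, 2, as.numeric(shifts[s, ]), "+")
      img_cart <- frac_to_cart(host$cell, img_frac)
      dd <- pairwise_cross_dist(ref_cart, img_cart)
      if (min(dd) < 1e-6) next            # the reference copy itself
      if (min(dd) < clash)
        images[[length(images) + 1]] <- img_cart
    }
  }
  if (!length(images)) return(1.0)
  # mutual-clash graph on {reference} + clashing images
  all_copies <- c(list(ref_cart), images)
  k <- length(all_copies)
  amat <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    amat[i, j] <- amat[j, i] <-
      min(pairwise_cross_dist(all_copies[[i]], all_copies[[j]])) < clash
  g <- igraph::graph_from_adjacency_matrix(amat, mode = "undirected")
  cl <- igraph::max_cliques(g)
  sizes <- vapply(cl, function(v) if (1 %in% as.integer(v)) length(v) else 0L,
                  integer(1))
  1 / max(max(sizes), 1L)
}

pairwise_cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Flag a refined occupancy that exceeds the symmetry-clash cap
#'
#' @param occupancy Refined site occupancy (fraction).
#' @param cap Cap from [occupancy_cap()].
#' @return TRUE (flagged, inconsistent) or FALSE.
#' @export
occupancy_exceeds_cap <- function(occupancy, cap) {
  occupancy > cap + 1e-9
}
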