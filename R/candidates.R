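# Candidate guest molecules: element-labelled heavy-atom graphs with one or
# more 3D reference geometries.
#
# 3D geometries are built from SMILES with OpenBabel's rule-based builder
# (via ChemmineOB). Because OpenBabel's rotor sampling is unseeded, the
# package canonicalizes every rotatable-bond torsion (anti, 180 deg) and the
# molecular pose (principal axes) after building, and generates additional
# conformers itself by seeded torsion driving. Conformer generation is
# therefore bit-for-bit reproducible for a fixed seed.

parse_sdf_block <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("SDF block too short")
  na <- as.integer(substr(lines[4], 1, 3))
  nb <- as.integer(substr(lines[4], 4, 6))
  if (is.na(na) || na < 1) stop("unparsable SDF counts line")
  ab <- lines[4 + seq_len(na)]
  xyz <- cbind(as.numeric(substr(ab, 1, 10)),
               as.numeric(substr(ab, 11, 20)),
               as.numeric(substr(ab, 21, 30)))
  elem <- normalize_element(trimws(substr(ab, 32, 34)))
  bonds <- NULL
  if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    bonds <- cbind(as.integer(substr(bl, 1, 3)),
                   as.integer(substr(bl, 4, 6)),
                   as.integer(substr(bl, 7, 9)))
  }
  list(xyz = xyz, elements = elem, bonds = bonds)
}

smiles_to_3d <- function(smiles, name = "mol") {
  sdf <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "SDF", source = paste0(smiles, " ", name),
      options = data.frame(names = "gen3d", args = "1")),
    error = function(e) stop("SMILES embedding failed for '", name, "': ",
                             conditionMessage(e)))
  mol <- tryCatch(parse_sdf_block(sdf),
                  error = function(e) stop("unparsable SMILES for '", name,
                                           "': ", smiles))
  if (all(abs(mol$xyz) < 1e-8))
    stop("3D embedding produced no coordinates for '", name, "' (", smiles, ")")
  mol
}

strip_hydrogens <- function(mol) {
  keep <- which(mol$elements != "H")
  remap <- match(seq_along(mol$elements), keep)
  bonds <- mol$bonds
  if (!is.null(bonds)) {
    bonds <- bonds[bonds[, 1] %in% keep & bonds[, 2] %in% keep, , drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
  }
  list(xyz = mol$xyz[keep, , drop = FALSE],
       elements = mol$elements[keep], bonds = bonds)
}

# --- torsion machinery -------------------------------------------------

rodrigues <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

bond_adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

component_beyond <- function(adj, from, excluding) {
  # atoms reachable from `from` without passing through `excluding`
  seen <- c(excluding, from)
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
  }
  setdiff(seen, c(excluding, from))
}

#' Detect rotatable bonds on a heavy-atom graph
#'
#' A bond is rotatable when it is a single, acyclic (bridge) bond whose
#' rotation moves at least one heavy atom, excluding amide C-N bonds and
#' conjugated sp2-sp2 bonds with a single moving atom (e.g. an aryl
#' aldehyde), which are planar in practice.
#'
#' @param elements Character vector of heavy-atom element symbols.
#' @param bonds Matrix with columns from, to, order.
#' @return Matrix with columns `i`, `j` (bond atoms) or zero rows.
#' @export
rotatable_bonds <- function(elements, bonds) {
  n <- length(elements)
  out <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  if (is.null(bonds) || nrow(bonds) == 0) return(out)
  ord <- if (ncol(bonds) >= 3) bonds[, 3] else rep(1L, nrow(bonds))
  g <- igraph::graph_from_edgelist(bonds[, 1:2, drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  bridge_ids <- igraph::bridges(g)
  bridge_set <- igraph::as_edgelist(g)[bridge_ids, , drop = FALSE]
  is_bridge <- function(i, j) any((bridge_set[, 1] == i & bridge_set[, 2] == j) |
                                  (bridge_set[, 1] == j & bridge_set[, 2] == i))
  sp2 <- rep(FALSE, n)
  for (k in seq_len(nrow(bonds)))
    if (ord[k] >= 2) sp2[bonds[k, 1:2]] <- TRUE
  adj <- bond_adjacency(n, bonds)
  has_carbonyl <- function(a) {
    elements[a] == "C" &&
      any(vapply(seq_len(nrow(bonds)), function(k)
        ord[k] == 2 && a %in% bonds[k, 1:2] &&
          any(elements[bonds[k, 1:2]] == "O"), logical(1)))
  }
  for (k in seq_len(nrow(bonds))) {
    if (ord[k] != 1) next
    i <- bonds[k, 1]; j <- bonds[k, 2]
    if (!is_bridge(i, j)) next
    amide <- (elements[i] == "N" && has_carbonyl(j)) ||
             (elements[j] == "N" && has_carbonyl(i))
    if (amide) next
    mi <- length(component_beyond(adj, i, j))
    mj <- length(component_beyond(adj, j, i))
    moving <- min(mi, mj)
    if (moving < 1) next
    if (sp2[i] && sp2[j] && moving < 2) next
    out <- rbind(out, c(i, j))
  }
  out
}

set_torsion <- function(xyz, adj, i, j, target) {
  # rotate the j-side so the reference dihedral a-i-j-b equals `target`
  a <- setdiff(adj[[i]], j)[1]
  b <- setdiff(adj[[j]], i)[1]
  if (is.na(a) || is.na(b)) return(xyz)
  cur <- dihedral_angle(xyz[a, ], xyz[i, ], xyz[j, ], xyz[b, ])
  theta <- target - cur
  moving <- component_beyond(adj, j, i)
  if (!length(moving)) return(xyz)
  R <- rodrigues(xyz[j, ] - xyz[i, ], theta)
  piv <- xyz[j, ]
  xyz[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, piv) %*% t(R),
                         2, piv, "+")
  xyz
}

canonical_pose <- function(xyz) {
  X <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(X), symmetric = TRUE)
  V <- ev$vectors  # columns ordered by decreasing eigenvalue
  for (k in 1:2) {
    proj <- X %*% V[, k]
    lead <- which.max(abs(proj))
    if (proj[lead] < 0) V[, k] <- -V[, k]
  }
  V[, 3] <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
              V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
              V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  X %*% V
}

min_nonbonded_dist <- function(xyz, bonds) {
  n <- nrow(xyz)
  if (n < 3) return(Inf)
  d <- as.matrix(stats::dist(xyz))
  bonded <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(bonds))) {
    bonded[bonds[k, 1], bonds[k, 2]] <- TRUE
    bonded[bonds[k, 2], bonds[k, 1]] <- TRUE
  }
  # 1-3 neighbours are geometry-constrained, not steric clashes
  bonded13 <- (bonded %*% bonded) > 0
  mask <- !(bonded | bonded13)
  diag(mask) <- FALSE
  if (!any(mask)) return(Inf)
  min(d[mask])
}

# --- constructors ------------------------------------------------------

validate_candidate <- function(cand) {
  if (length(cand$conformers) < 1) stop("candidate needs >= 1 conformer")
  n <- length(cand$elements)
  if (any(cand$elements == "H")) stop("candidate must not contain hydrogens")
  for (cf in cand$conformers) {
    if (!is.matrix(cf) || nrow(cf) != n || ncol(cf) != 3 || !all(is.finite(cf)))
      stop("conformer dimensions do not match the element list")
  }
  if (!is.null(cand$bonds) && nrow(cand$bonds) > 0) {
    for (ci in seq_along(cand$conformers)) {
      cf <- cand$conformers[[ci]]
      for (k in seq_len(nrow(cand$bonds))) {
        i <- cand$bonds[k, 1]; j <- cand$bonds[k, 2]
        d <- sqrt(sum((cf[i, ] - cf[j, ])^2))
        if (d < 1.1 || d > 1.8)
          stop(sprintf(
            "bond %d-%d in conformer %d of '%s' has length %.3f A, outside [1.1, 1.8]",
            i, j, ci, cand$name, d))
      }
    }
  }
  cand
}

new_candidate <- function(name, smiles, elements, conformers, bonds) {
  validate_candidate(structure(
    list(name = name, smiles = smiles, elements = elements,
         conformers = conformers, bonds = bonds),
    class = "candidate"))
}

#' Build a candidate guest from a SMILES string
#'
#' Embeds the molecule in 3D with OpenBabel's rule-based builder, strips
#' hydrogens, canonicalizes all rotatable torsions to anti and the pose to
#' principal axes, then generates up to `n_conformers` distinct conformers
#' by seeded torsion driving over staggered rotamers (gauche-, anti,
#' gauche+), discarding sterically clashed combinations. Deterministic for
#' a fixed seed.
#'
#' @param name Candidate name (unique within a set).
#' @param smiles SMILES string.
#' @param n_conformers Number of conformers to attempt; defaults to 5 when
#'   the molecule has at least one rotatable bond, 1 otherwise.
#' @param seed Integer seed for torsion sampling.
#' @return Object of class `candidate` with fields `name`, `smiles`,
#'   `elements`, `conformers` (list of n x 3 Cartesian matrices, Angstrom),
#'   and `bonds` (heavy-atom index pairs with bond order).
#' @examples
#' \dontrun{
#' urea <- candidate_from_smiles("urea", "NC(N)=O")
#' table(urea$elements)
#' }
#' @export
candidate_from_smiles <- function(name, smiles, n_conformers = NULL,
                                  seed = 1L) {
  mol <- strip_hydrogens(smiles_to_3d(smiles, name))
  n <- length(mol$elements)
  rot <- rotatable_bonds(mol$elements, mol$bonds)
  if (is.null(n_conformers))
    n_conformers <- if (nrow(rot) > 0) 5L else 1L
  if (n_conformers < 1) stop("n_conformers must be >= 1")
  conformers <- build_conformer_ensemble(mol$xyz, mol$elements, mol$bonds,
                                         rot, n_conformers, seed)
  new_candidate(name, smiles, mol$elements, conformers, mol$bonds)
}

# Canonicalize every acyclic single-bond torsion to anti (which also fixes
# the torsions OpenBabel randomizes), then drive the chemically rotatable
# subset through seeded staggered rotamers to build the ensemble.
build_conformer_ensemble <- function(xyz, elements, bonds, rot,
                                     n_conformers, seed) {
  n <- length(elements)
  adj <- bond_adjacency(n, bonds)
  base <- xyz
  ord <- if (!is.null(bonds) && ncol(bonds) >= 3) bonds[, 3] else
    rep(1L, nrow(bonds))
  if (!is.null(bonds)) {
    g <- igraph::graph_from_edgelist(bonds[, 1:2, drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    bridge_rows <- igraph::as_edgelist(g)[igraph::bridges(g), , drop = FALSE]
    for (k in seq_len(nrow(bonds))) {
      if (ord[k] != 1) next
      i <- bonds[k, 1]; j <- bonds[k, 2]
      if (!any((bridge_rows[, 1] == i & bridge_rows[, 2] == j) |
               (bridge_rows[, 1] == j & bridge_rows[, 2] == i))) next
      base <- set_torsion(base, adj, i, j, pi)
    }
  }
  conformers <- list(canonical_pose(base))
  if (nrow(rot) > 0 && n_conformers > 1) {
    angles <- c(pi / 3, pi, -pi / 3)
    seen <- paste(rep(2L, nrow(rot)), collapse = ",")  # all-anti base combo
    rng <- make_rng(seed)
    attempts <- 0L
    while (length(conformers) < n_conformers && attempts < 200L) {
      attempts <- attempts + 1L
      combo <- vapply(seq_len(nrow(rot)), function(k)
        sample_int(rng, 3L), integer(1))
      key <- paste(combo, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      xyz2 <- base
      for (k in seq_len(nrow(rot)))
        xyz2 <- set_torsion(xyz2, adj, rot[k, 1], rot[k, 2], angles[combo[k]])
      if (min_nonbonded_dist(xyz2, bonds) < 2.0) next
      conformers[[length(conformers) + 1]] <- canonical_pose(xyz2)
    }
  }
  conformers
}

# Small deterministic RNG (linear congruential) so candidate generation
# never disturbs R's global RNG stream.
make_rng <- function(seed) {
  state <- new.env(parent = emptyenv())
  state$x <- as.numeric(seed %% 2147483647)
  if (state$x <= 0) state$x <- state$x + 2147483646
  state
}

sample_int <- function(rng, n) {
  rng$x <- (rng$x * 16807) %% 2147483647
  as.integer(rng$x %% n) + 1L
}

#' Build a candidate guest from explicit coordinates
#'
#' Template route for users who already know the reference geometry.
#'
#' @param name Candidate name.
#' @param elements Character vector of heavy-atom element symbols.
#' @param coords n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param bonds Two-column matrix of bonded atom index pairs.
#' @return A single-conformer `candidate`.
#' @export
candidate_from_coords <- function(name, elements, coords, bonds = NULL) {
  coords <- as_coord_matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(bonds))
    bonds <- matrix(integer(0), 0, 3)
  else {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) == 2) bonds <- cbind(bonds, 1L)
  }
  new_candidate(name, NA_character_, normalize_element(elements),
                list(coords), bonds)
}

#' Read a candidate from an XYZ-style template file
#'
#' Plain text: first line atom count, second a title, then `element x y z`
#' rows (Angstrom). Bonds are inferred from the heavy-atom bond-length
#' window 1.1-1.8 Angstrom; hydrogens are dropped.
#'
#' @param name Candidate name.
#' @param path Path to the XYZ file.
#' @return A single-conformer `candidate`.
#' @export
candidate_from_xyz <- function(name, path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[2 + seq_len(n)]), "\\s+")
  el <- normalize_element(vapply(rows, `[`, character(1), 1))
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  keep <- el != "H"
  el <- el[keep]; xyz <- xyz[keep, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  bonds <- which(d >= 1.1 & d <= 1.8, arr.ind = TRUE)
  bonds <- bonds[bonds[, 1] < bonds[, 2], , drop = FALSE]
  candidate_from_coords(name, el, xyz, bonds)
}

#' @export
print.candidate <- function(x, ...) {
  cat(sprintf("Candidate '%s': %d heavy atoms (%s), %d conformer(s)\n",
              x$name, length(x$elements),
              paste(names(table(x$elements)), table(x$elements),
                    sep = "", collapse = " "),
              length(x$conformers)))
  invisible(x)
}

#' Heavy-atom pairwise distance matrix of a conformer
#'
#' @param candidate A `candidate`.
#' @param conformer_index Conformer to use (default 1).
#' @return Symmetric matrix of Euclidean distances (Angstrom).
#' @export
pairwise_distances <- function(candidate, conformer_index = 1) {
  if (conformer_index < 1 || conformer_index > length(candidate$conformers))
    stop("conformer index out of range")
  as.matrix(stats::dist(candidate$conformers[[conformer_index]]))
}

#' Assemble a candidate set
#'
#' @param ... `candidate` objects (or a single list of them).
#' @return Object of class `candidate_set` (named list).
#' @export
candidate_set <- function(...) {
  cands <- list(...)
  if (length(cands) == 1 && !inherits(cands[[1]], "candidate"))
    cands <- cands[[1]]
  nm <- vapply(cands, function(x) x$name, character(1))
  if (anyDuplicated(nm)) stop("candidate names must be unique")
  names(cands) <- nm
  structure(cands, class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set with", length(x), "molecules:\n")
  for (cd in x)
    cat(sprintf("  %-18s %2d heavy atoms, %d conformer(s)\n",
                cd$name, length(cd$elements), length(cd$conformers)))
  invisible(x)
}

#' SMILES strings of the ten reference guest molecules
#'
#' The default screening panel: DMF, DEF, pyridine, cyclohexane, urea,
#' 2-methylimidazole (Hmim), benzoic acid, ethyl acetate, benzaldehyde,
#' and isovaleraldehyde.
#'
#' @return Named character vector of SMILES strings.
#' @export
guest_smiles <- function() {
  c(DMF             = "CN(C)C=O",
    DEF             = "CCN(CC)C=O",
    pyridine        = "c1ccncc1",
    cyclohexane     = "C1CCCCC1",
    urea            = "NC(N)=O",
    Hmim            = "Cc1ncc[nH]1",
    "benzoic acid"  = "OC(=O)c1ccccc1",
    "ethyl acetate" = "CCOC(C)=O",
    benzaldehyde    = "O=Cc1ccccc1",
    isovaleraldehyde = "CC(C)CC=O")
}

#' Build the default ten-guest candidate set
#'
#' Base heavy-atom geometries come from the curated template library shipped
#' with the package (idealized geometries with canonical anti torsions, in
#' SDF text under `extdata/guest_templates.sdf`); conformer ensembles are
#' generated at call time by seeded torsion driving, so the result is
#' bit-for-bit reproducible for a fixed seed. Use [candidate_from_smiles()]
#' for molecules outside the panel.
#'
#' @param seed Seed for conformer torsion sampling.
#' @param n_conformers Optional fixed conformer count for every molecule;
#'   by default flexible molecules get 5 and rigid ones 1.
#' @return A [candidate_set()].
#' @export
guest_library <- function(seed = 1L, n_conformers = NULL) {
  path <- system.file("extdata", "guest_templates.sdf",
                      package = "nanosponge", mustWork = TRUE)
  mols <- read_sdf_library(path)
  smis <- guest_smiles()
  candidate_set(lapply(names(mols), function(nm) {
    mol <- mols[[nm]]
    rot <- rotatable_bonds(mol$elements, mol$bonds)
    nc <- n_conformers
    if (is.null(nc)) nc <- if (nrow(rot) > 0) 5L else 1L
    conformers <- build_conformer_ensemble(mol$xyz, mol$elements, mol$bonds,
                                           rot, nc, seed)
    new_candidate(nm, unname(smis[nm]), mol$elements, conformers, mol$bonds)
  }))
}

# Read a multi-molecule SDF text file into named (xyz, elements, bonds).
read_sdf_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  breaks <- c(0, which(lines == "$$$$"))
  out <- list()
  for (k in seq_len(length(breaks) - 1)) {
    blk <- lines[(breaks[k] + 1):(breaks[k + 1] - 1)]
    if (!length(blk)) next
    mol <- parse_sdf_block(paste(blk, collapse = "\n"))
    out[[trimws(blk[1])]] <- mol
  }
  out
}

write_sdf_library <- function(mols, path) {
  out <- character(0)
  for (nm in names(mols)) {
    m <- mols[[nm]]
    na <- nrow(m$xyz); nb <- if (is.null(m$bonds)) 0 else nrow(m$bonds)
    out <- c(out, nm, "  nanosponge curated guest template", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     m$xyz[, 1], m$xyz[, 2], m$xyz[, 3], m$elements))
    if (nb > 0)
      out <- c(out, sprintf("%3d%3d%3d  0  0  0  0", m$bonds[, 1],
                            m$bonds[, 2], m$bonds[, 3]))
    out <- c(out, "M  END", "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}
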