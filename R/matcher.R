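# Guest matching core: Q-peak filtering and clustering, maximum-clique
# correspondence search, Kabsch superposition, and candidate ranking.

#' Matching parameters
#'
#' @param bond_window Length-2 vector, the peak-peak distance window (A)
#'   treated as a plausible covalent connection when clustering.
#' @param height_min Minimum peak height as a fraction of the strongest
#'   peak; weaker peaks are discarded before clustering.
#' @param pair_tol Distance-compatibility tolerance (A) for the
#'   correspondence search.
#' @param min_coverage Minimum fraction of candidate heavy atoms that must
#'   be matched for a correspondence to be admissible.
#' @param coverage_weight Score penalty lambda in A per unit of unmatched
#'   candidate-atom fraction; `score = rmsd + lambda * (1 - coverage)`.
#'   Zero reproduces ranking on raw RMSD alone.
#' @param tie_tol Scores closer than this (A) are reported as a tie.
#' @return Object of class `matcher_params`.
#' @export
matcher_params <- function(bond_window = c(1.1, 1.8), height_min = 0.15,
                           pair_tol = 0.25, min_coverage = 0.6,
                           coverage_weight = 2.0, tie_tol = 0.01) {
  if (length(bond_window) != 2 || bond_window[1] <= 0 ||
      bond_window[1] >= bond_window[2])
    stop("bond_window must satisfy 0 < d_min < d_max")
  if (pair_tol <= 0 || tie_tol <= 0) stop("tolerances must be positive")
  if (height_min < 0 || height_min > 1) stop("height_min must lie in [0, 1]")
  if (min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must lie in (0, 1]")
  if (coverage_weight < 0) stop("coverage_weight must be >= 0")
  structure(list(bond_window = bond_window, height_min = height_min,
                 pair_tol = pair_tol, min_coverage = min_coverage,
                 coverage_weight = coverage_weight, tie_tol = tie_tol),
            class = "matcher_params")
}

#' Filter and cluster Q-peaks into putative guest skeletons
#'
#' Discards peaks weaker than `height_min` times the strongest peak,
#' expands the survivors under the host's symmetry operations, and
#' partitions all images into connected components under periodic
#' minimum-image adjacency within the covalent `bond_window`. One
#' symmetry-unique representative per cluster orbit is returned, with
#' coordinates unwrapped into a contiguous Cartesian fragment.
#'
#' @param qpeaks A [qpeak_set()].
#' @param params A [matcher_params()].
#' @param expand_symmetry Expand peaks under the host symmetry operators
#'   before clustering (default TRUE), so fragments split across the
#'   asymmetric-unit boundary reassemble.
#' @return List of clusters, sorted by size (descending). Each cluster is a
#'   list with `labels`, `heights`, `coords` (n x 3 Cartesian, A), `frac`
#'   (n x 3 fractional, wrapped), and `peak_refs` (data frame: label,
#'   symop index).
#' @export
filter_and_cluster <- function(qpeaks, params = matcher_params(),
                               expand_symmetry = TRUE) {
  stopifnot(inherits(qpeaks, "qpeak_set"))
  host <- qpeaks$host
  pk <- qpeaks$peaks
  if (nrow(pk) == 0) return(list())
  pk <- pk[pk$height >= params$height_min * max(pk$height), , drop = FALSE]
  if (nrow(pk) == 0) return(list())

  ops <- if (expand_symmetry) host$symops else list(symop_identity())
  img_label <- character(0); img_height <- numeric(0)
  img_op <- integer(0); img_frac <- matrix(0, 0, 3)
  for (r in seq_len(nrow(pk))) {
    orb <- expand_equivalents(host$cell, ops, c(pk$x[r], pk$y[r], pk$z[r]),
                              dedup_tol = 0.05)
    k <- nrow(orb)
    img_frac <- rbind(img_frac, orb)
    img_label <- c(img_label, rep(pk$label[r], k))
    img_height <- c(img_height, rep(pk$height[r], k))
    img_op <- c(img_op, attr(orb, "symop_index"))
  }

  dmat <- min_image_dist_matrix(host$cell, img_frac, img_frac)
  adj <- dmat >= params$bond_window[1] & dmat <= params$bond_window[2]
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  # A component containing the same base peak twice is a symmetry-overlap
  # composite: two or more symmetry copies of one fragment fused through
  # short inter-image contacts (mutually exclusive in occupancy terms).
  # Split such components into label-unique, symmetry-consistent images by
  # deterministic greedy growth.
  comp_members <- split(seq_along(comp), comp)
  groups <- list()
  for (idx in comp_members) {
    while (length(idx) > 0) {
      if (!anyDuplicated(img_label[idx])) {
        # remainder may have fallen apart; keep each connected piece
        sg <- igraph::graph_from_adjacency_matrix(
          adj[idx, idx, drop = FALSE], mode = "undirected")
        for (piece in split(idx, igraph::components(sg)$membership))
          groups <- c(groups, list(piece))
        break
      }
      ord <- idx[order(img_op[idx], img_label[idx])]
      grown <- ord[1]
      used <- img_label[grown]
      repeat {
        nb <- idx[colSums(adj[grown, idx, drop = FALSE]) > 0]
        nb <- setdiff(nb, grown)
        nb <- nb[!(img_label[nb] %in% used)]
        if (!length(nb)) break
        nb <- nb[order(img_op[nb], img_label[nb])]
        grown <- c(grown, nb[1]); used <- c(used, img_label[nb[1]])
      }
      groups <- c(groups, list(sort(grown)))
      idx <- setdiff(idx, grown)
    }
  }

  clusters <- list()
  for (idx in groups) {
    # unwrap into one contiguous Cartesian fragment by BFS over the
    # adjacency, placing each new member at its minimum-image position
    coords <- matrix(NA_real_, length(idx), 3)
    start <- 1L
    coords[start, ] <- frac_to_cart(host$cell, img_frac[idx[start], ])
    placed <- start
    queue <- start
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      nb <- which(adj[idx[a], idx])
      for (b in nb) {
        if (b %in% placed) next
        mi <- min_image_vector(host$cell, img_frac[idx[a], ],
                               img_frac[idx[b], ])
        coords[b, ] <- coords[a, ] + drop(host$cell$ortho %*% mi$dfrac)
        placed <- c(placed, b); queue <- c(queue, b)
      }
    }
    # isolated-by-wrap safety: any unplaced member (shouldn't happen for a
    # connected component) falls back to its direct image
    for (b in which(is.na(coords[, 1])))
      coords[b, ] <- frac_to_cart(host$cell, img_frac[idx[b], ])
    clusters[[length(clusters) + 1]] <- list(
      labels = img_label[idx], heights = img_height[idx],
      coords = coords, frac = img_frac[idx, , drop = FALSE],
      peak_refs = data.frame(label = img_label[idx], symop = img_op[idx]),
      # full filtered peak-image context, so matching can later capture
      # peaks that noise detached from this cluster
      context = list(labels = img_label, frac = img_frac, cell = host$cell))
  }

  # deduplicate symmetry-equivalent clusters: identical label multiset and
  # internal distance spectrum -> keep one deterministic representative
  key_of <- function(cl) {
    dd <- if (nrow(cl$coords) > 1) sort(round(stats::dist(cl$coords), 2)) else 0
    paste(paste(sort(cl$labels), collapse = "|"),
          paste(dd, collapse = ","), sep = "#")
  }
  keys <- vapply(clusters, key_of, character(1))
  rep_of <- function(cl) paste(cl$peak_refs$symop, collapse = ",")
  keep <- integer(0)
  for (k in unique(keys)) {
    cand <- which(keys == k)
    reps <- vapply(clusters[cand], rep_of, character(1))
    keep <- c(keep, cand[order(reps)][1])
  }
  clusters <- clusters[keep]
  clusters[order(-vapply(clusters, function(cl) length(cl$labels), numeric(1)),
                 vapply(clusters, function(cl) cl$labels[1], character(1)))]
}

#' Kabsch rigid-body superposition
#'
#' Least-squares proper rotation and translation superposing `Q` onto `P`
#' (paired by row). Reflections are excluded by the determinant correction,
#' so enantiomeric point sets do not superpose to zero.
#'
#' @param P,Q n x 3 Cartesian coordinate matrices (A), n >= 1.
#' @return List with `rotation` (3x3 proper orthogonal), `translation`
#'   (length 3; the aligned copy is `Q %*% t(rotation) + translation`),
#'   and `rmsd` (A).
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as_coord_matrix(P); Q <- as_coord_matrix(Q)
  if (nrow(P) != nrow(Q)) stop("point sets must have equal size")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Qc, Pc)           # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Pc)^2)))
  list(rotation = R, translation = cp - drop(R %*% cq), rmsd = rmsd)
}

#' Correspondence search between a peak cluster and a candidate conformer
#'
#' Builds the association graph whose vertices are (peak, atom) pairs and
#' whose edges join assignments with compatible internal distances
#' (`|d_peaks - d_atoms| <= pair_tol`), then enumerates maximal cliques of
#' size at least `min_coverage * n_atoms`. Cliques are injective by
#' construction and returned largest first in a deterministic order.
#'
#' @param cluster One cluster from [filter_and_cluster()].
#' @param candidate A `candidate`.
#' @param conformer Conformer index.
#' @param params A [matcher_params()].
#' @return List of correspondences; each is a 2-column matrix with columns
#'   `peak` and `atom` (row-sorted by peak index). Empty list when no
#'   admissible correspondence exists.
#' @export
correspondence_search <- function(cluster, candidate, conformer = 1,
                                  params = matcher_params()) {
  Pd <- as.matrix(stats::dist(cluster$coords))
  Qd <- pairwise_distances(candidate, conformer)
  np <- nrow(Pd); na <- nrow(Qd)
  min_size <- ceiling(params$min_coverage * na)
  if (min(np, na) < min_size) return(list())
  if (np == 1 || na == 1) {
    # single-vertex association graphs: every pairing is a size-1 clique
    if (min_size > 1) return(list())
    out <- list()
    for (i in seq_len(np)) for (a in seq_len(na))
      out[[length(out) + 1]] <- matrix(c(i, a), 1, 2,
                                       dimnames = list(NULL, c("peak", "atom")))
    return(out)
  }
  # association graph vertices: v = (peak i, atom a) -> id (i-1)*na + a
  nv <- np * na
  compat <- abs(outer(c(Pd), c(Qd), "-")) <= params$pair_tol
  dim(compat) <- c(np, np, na, na)
  edges <- integer(0)
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    ok <- which(compat[i, j, , ], arr.ind = TRUE)
    if (!nrow(ok)) next
    ok <- ok[ok[, 1] != ok[, 2], , drop = FALSE]
    if (!nrow(ok)) next
    vi <- (i - 1L) * na + ok[, 1]; vj <- (j - 1L) * na + ok[, 2]
    edges <- c(edges, rbind(vi, vj))
  }
  if (!length(edges)) {
    if (min_size > 1) return(list())
    edges <- NULL
  }
  g <- igraph::make_empty_graph(nv, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, edges)
  cl <- igraph::max_cliques(g, min = min_size)
  if (!length(cl)) return(list())
  out <- lapply(cl, function(vs) {
    vs <- sort(as.integer(vs))
    m <- cbind(peak = (vs - 1L) %/% na + 1L, atom = (vs - 1L) %% na + 1L)
    m[order(m[, 1]), , drop = FALSE]
  })
  sizes <- vapply(out, nrow, integer(1))
  keys <- vapply(out, function(m) paste(t(m), collapse = ","), character(1))
  out[order(-sizes, keys)]
}

#' Match one candidate against one cluster
#'
#' Searches all conformers and all admissible correspondences, superposes
#' each with [kabsch_superpose()], and returns the result minimizing
#' `score = rmsd + lambda * (1 - f)`, where `f` is the symmetric match
#' fraction `matched / max(n_candidate_atoms, n_cluster_peaks)`. The
#' penalty therefore acts both on candidates that explain only part of the
#' cluster (sub-fragments of a larger guest) and on candidates only partly
#' supported by the peaks. The reported `coverage` field remains the
#' matched fraction of candidate heavy atoms; unexplained cluster peaks
#' are listed in `unmatched_peaks`.
#'
#' @param cluster One cluster from [filter_and_cluster()].
#' @param candidate A `candidate`.
#' @param params A [matcher_params()].
#' @return Object of class `match_result`, or `NULL` when no admissible
#'   correspondence exists.
#' @export
match_candidate <- function(cluster, candidate, params = matcher_params()) {
  best <- NULL
  n_atoms <- length(candidate$elements)
  n_peaks <- nrow(cluster$coords)
  score_of <- function(rmsd, k)
    rmsd + params$coverage_weight * (1 - k / max(n_atoms, n_peaks))
  consider <- function(cand_best, res) {
    if (is.null(cand_best) || res$score < cand_best$score - 1e-12 ||
        (abs(res$score - cand_best$score) <= 1e-12 &&
         res$coverage > cand_best$coverage)) res else cand_best
  }
  for (ci in seq_along(candidate$conformers)) {
    conf <- candidate$conformers[[ci]]
    corrs <- correspondence_search(cluster, candidate, ci, params)
    conf_best <- NULL; conf_fit <- NULL
    for (m in corrs) {
      P <- cluster$coords[m[, "peak"], , drop = FALSE]
      Q <- conf[m[, "atom"], , drop = FALSE]
      fit <- kabsch_superpose(P, Q)
      k <- nrow(m)
      res <- structure(list(
        candidate = candidate$name, conformer = ci, correspondence = m,
        rotation = fit$rotation, translation = fit$translation,
        rmsd = fit$rmsd, coverage = k / n_atoms, score = score_of(fit$rmsd, k),
        unmatched_peaks = setdiff(seq_len(n_peaks), m[, "peak"]),
        extra_labels = character(0),
        extra_coords = matrix(0, 0, 3)),
        class = "match_result")
      prev <- conf_best
      conf_best <- consider(conf_best, res)
      if (!identical(prev, conf_best)) conf_fit <- fit
    }
    if (!is.null(conf_best)) {
      best <- consider(best, conf_best)
      ext <- extend_match(cluster, conf, conf_best$correspondence, conf_fit,
                          params, candidate$name, ci, n_atoms, n_peaks,
                          score_of)
      if (!is.null(ext)) best <- consider(best, ext)
    }
  }
  best
}

# Capture pass: peaks that noise pushed outside the clique's distance
# tolerance (or even out of the cluster) are recovered by proximity to the
# predicted positions of unmatched candidate atoms, then the superposition
# is refit. Peak indices beyond the cluster size refer to `extra_coords`.
extend_match <- function(cluster, conf, m, fit, params, cand_name, ci,
                         n_atoms, n_peaks, score_of) {
  ctx <- cluster$context
  if (is.null(ctx)) return(NULL)
  cell <- ctx$cell
  corr <- m
  P <- cluster$coords[m[, "peak"], , drop = FALSE]
  labels_used <- cluster$labels[m[, "peak"]]
  extra_coords <- matrix(0, 0, 3); extra_labels <- character(0)
  changed <- FALSE
  for (pass in 1:3) {
    miss_atoms <- setdiff(seq_len(n_atoms), corr[, "atom"])
    if (!length(miss_atoms)) break
    added <- FALSE
    for (at in miss_atoms) {
      pred <- drop(fit$rotation %*% conf[at, ]) + fit$translation
      pred_frac <- cart_to_frac(cell, pred)
      d <- min_image_dist_matrix(cell, pred_frac, ctx$frac)
      ok <- which(d[1, ] <= params$pair_tol & !(ctx$labels %in% labels_used))
      if (!length(ok)) next
      pick <- ok[order(d[1, ok], ctx$labels[ok])][1]
      mi <- min_image_vector(cell, pred_frac, ctx$frac[pick, ])
      obs <- pred + drop(cell$ortho %*% mi$dfrac)
      extra_coords <- rbind(extra_coords, obs)
      extra_labels <- c(extra_labels, ctx$labels[pick])
      labels_used <- c(labels_used, ctx$labels[pick])
      corr <- rbind(corr, c(n_peaks + length(extra_labels), at))
      P <- rbind(P, obs)
      added <- TRUE; changed <- TRUE
    }
    if (!added) break
    fit <- kabsch_superpose(P, conf[corr[, "atom"], , drop = FALSE])
  }
  if (!changed) return(NULL)
  k <- nrow(corr)
  structure(list(
    candidate = cand_name, conformer = ci, correspondence = corr,
    rotation = fit$rotation, translation = fit$translation,
    rmsd = fit$rmsd, coverage = k / n_atoms, score = score_of(fit$rmsd, k),
    unmatched_peaks = Filter(function(i) !(cluster$labels[i] %in% extra_labels),
                             setdiff(seq_len(n_peaks), corr[, "peak"])),
    extra_labels = extra_labels, extra_coords = extra_coords),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Match: %s  rmsd=%.4f A  coverage=%.2f  score=%.4f (conformer %d, %d peaks matched)\n",
              x$candidate, x$rmsd, x$coverage, x$score, x$conformer,
              nrow(x$correspondence)))
  invisible(x)
}

#' Exhaustive brute-force match (verification oracle)
#'
#' Enumerates every injective assignment of every peak subset meeting the
#' coverage requirement, superposes each, and returns the score-minimal
#' result. Intended as an independent check of [match_candidate()] on
#' small problems; refuses clusters or candidates larger than `max_n`.
#'
#' @inheritParams match_candidate
#' @param max_n Combinatorial guard (default 8).
#' @return A `match_result` or `NULL`.
#' @export
brute_force_match <- function(cluster, candidate, params = matcher_params(),
                              max_n = 8) {
  np <- nrow(cluster$coords); na <- length(candidate$elements)
  if (np > max_n || na > max_n)
    stop("brute_force_match refuses problems larger than ", max_n,
         " peaks/atoms")
  min_size <- ceiling(params$min_coverage * na)
  best <- NULL
  for (ci in seq_along(candidate$conformers)) {
    conf <- candidate$conformers[[ci]]
    res <- cpp_brute_force(cluster$coords, conf, as.integer(min_size),
                           params$coverage_weight)
    if (!isTRUE(res$found)) next
    coverage <- res$k / na
    if (is.null(best) || res$score < best$score - 1e-12 ||
        (abs(res$score - best$score) <= 1e-12 && coverage > best$coverage)) {
      m <- cbind(peak = res$peaks, atom = res$atoms)
      fit <- kabsch_superpose(cluster$coords[res$peaks, , drop = FALSE],
                              conf[res$atoms, , drop = FALSE])
      best <- structure(list(
        candidate = candidate$name, conformer = ci, correspondence = m,
        rotation = fit$rotation, translation = fit$translation,
        rmsd = fit$rmsd, coverage = coverage, score = res$score,
        unmatched_peaks = setdiff(seq_len(np), res$peaks),
        extra_labels = character(0), extra_coords = matrix(0, 0, 3)),
        class = "match_result")
    }
  }
  best
}

#' Rank all candidates against a cluster
#'
#' Matches every candidate with [match_candidate()]; accepted candidates
#' are sorted by ascending score, candidates with no admissible
#' correspondence follow with infinite score. Scores within `tie_tol` of
#' the group leader share a rank and are ordered alphabetically.
#'
#' @param cluster One cluster from [filter_and_cluster()].
#' @param candidates A [candidate_set()].
#' @param params A [matcher_params()].
#' @return Object of class `guest_ranking`: list with `table` (data frame
#'   rank, candidate, rmsd, coverage, score, matched, conformer) and
#'   `results` (named list of `match_result`).
#' @export
rank_candidates <- function(cluster, candidates, params = matcher_params()) {
  if (!length(candidates)) stop("empty candidate set")
  results <- lapply(candidates, function(cd)
    match_candidate(cluster, cd, params))
  names(results) <- names(candidates)
  score <- vapply(results, function(r) if (is.null(r)) Inf else r$score,
                  numeric(1))
  rmsd <- vapply(results, function(r) if (is.null(r)) NA_real_ else r$rmsd,
                 numeric(1))
  coverage <- vapply(results, function(r) if (is.null(r)) NA_real_ else
    r$coverage, numeric(1))
  matched <- vapply(results, function(r) if (is.null(r)) 0L else
    nrow(r$correspondence), integer(1))
  conformer <- vapply(results, function(r) if (is.null(r)) NA_integer_ else
    r$conformer, integer(1))
  ord <- order(score, names(candidates))
  tab <- data.frame(candidate = names(candidates)[ord], rmsd = rmsd[ord],
                    coverage = coverage[ord], score = score[ord],
                    matched = matched[ord], conformer = conformer[ord],
                    stringsAsFactors = FALSE)
  # tie grouping: a new rank starts when the score exceeds the current
  # group leader by tie_tol (infinite scores share the final rank group)
  rank <- integer(nrow(tab))
  if (nrow(tab)) {
    rank[1] <- 1L; lead <- tab$score[1]
    for (i in seq_len(nrow(tab))[-1]) {
      new_group <- if (is.infinite(tab$score[i])) !is.infinite(lead) else
        tab$score[i] - lead >= params$tie_tol
      if (new_group) { rank[i] <- i; lead <- tab$score[i] }
      else rank[i] <- rank[i - 1]
    }
    # alphabetical order inside tie groups (order() above already sorts by
    # score then name; re-sort each group purely by name)
    for (g in unique(rank)) {
      sel <- which(rank == g)
      tab[sel, ] <- tab[sel, , drop = FALSE][order(tab$candidate[sel]), ]
    }
  }
  tab <- cbind(rank = rank, tab)
  rownames(tab) <- NULL
  structure(list(table = tab, results = results, params = params),
            class = "guest_ranking")
}

#' @export
print.guest_ranking <- function(x, digits = 4, ...) {
  cat("Guest ranking (", nrow(x$table), " candidates):\n", sep = "")
  tab <- x$table
  tab$rmsd <- round(tab$rmsd, digits)
  tab$score <- round(tab$score, digits)
  tab$coverage <- round(tab$coverage, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.guest_ranking <- function(object, ...) {
  tab <- object$table
  top <- tab[tab$rank == 1, ]
  cat("Top-ranked candidate(s): ", paste(top$candidate, collapse = ", "),
      sprintf(" (score %.4f)\n", top$score[1]), sep = "")
  n_rej <- sum(is.infinite(tab$score))
  if (n_rej) cat(n_rej, "candidate(s) had no admissible correspondence\n")
  invisible(object)
}
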