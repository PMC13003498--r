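# Seeded synthetic Q-peak generator with known ground truth, plus a
# packaged monoclinic I2/a host fixture. Every stage of the pipeline is
# testable against these without any experimental data.

#' Simulate a Q-peak set from a known guest
#'
#' Places one copy of the named candidate at a seeded uniform-random
#' rotation and translation inside the host cell, adds isotropic Gaussian
#' positional jitter, optionally deletes peaks (at random with probability
#' `p_miss`, or exactly `n_miss` of them), and adds spurious peaks drawn
#' uniformly in the cell but kept at least `spurious_clearance` Angstrom
#' from every true peak so ground-truth labels stay unambiguous. Peak
#' heights are drawn so true peaks stochastically dominate spurious ones.
#' Fully reproducible for a fixed seed.
#'
#' @param candidate_name Name of the guest in `candidates`.
#' @param candidates A [candidate_set()].
#' @param host A [host_structure()]; defaults to [make_host_fixture()].
#' @param seed Integer seed.
#' @param sigma Gaussian positional jitter per coordinate (A).
#' @param p_miss Per-peak deletion probability in [0, 1).
#' @param n_miss Exact number of true peaks to delete (overrides `p_miss`).
#' @param n_spurious Number of spurious peaks to add.
#' @param height_true,height_spurious,height_sd Normal height model
#'   (arbitrary ordinal units).
#' @param spurious_clearance Minimum distance (A) between a spurious peak
#'   and any true peak; set to 0 for "hard mode".
#' @return List of class `simulated_case` with `qpeaks` (a [qpeak_set()])
#'   and `truth` (candidate name, conformer, `rotation`/`translation`
#'   pose, and per-peak provenance: true atom index or `"spurious"`).
#' @export
simulate_qpeaks <- function(candidate_name, candidates,
                            host = make_host_fixture(), seed = 1L,
                            sigma = 0.05, p_miss = 0, n_miss = NULL,
                            n_spurious = 0, height_true = 3.0,
                            height_spurious = 1.2, height_sd = 0.4,
                            spurious_clearance = 2.5) {
  if (!candidate_name %in% names(candidates))
    stop("unknown candidate: ", candidate_name)
  if (sigma < 0) stop("sigma must be >= 0")
  if (p_miss < 0 || p_miss >= 1) stop("p_miss must lie in [0, 1)")
  cand <- candidates[[candidate_name]]
  n <- length(cand$elements)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    ci <- sample.int(length(cand$conformers), 1)
    conf <- cand$conformers[[ci]]
    # uniform random rotation from a QR-decomposed Gaussian matrix
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(M)
    R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
    if (det(R) < 0) R[, 3] <- -R[, 3]
    center_frac <- stats::runif(3)
    center_cart <- frac_to_cart(host$cell, center_frac)
    placed <- sweep(conf %*% t(R), 2, center_cart, "+")
    jitter <- matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
    noisy <- placed + jitter

    keep <- seq_len(n)
    if (!is.null(n_miss)) {
      if (n_miss >= n) stop("n_miss must leave at least one peak")
      if (n_miss > 0) keep <- sort(sample(keep, n - n_miss))
    } else if (p_miss > 0) {
      keep <- which(stats::runif(n) >= p_miss)
      if (!length(keep)) keep <- sample.int(n, 1)  # never delete everything
    }
    true_frac <- wrap_frac(cart_to_frac(host$cell, noisy[keep, , drop = FALSE]))
    true_h <- abs(stats::rnorm(length(keep), height_true, height_sd))

    sp_frac <- matrix(0, 0, 3)
    if (n_spurious > 0) {
      tries <- 0L
      while (nrow(sp_frac) < n_spurious) {
        tries <- tries + 1L
        if (tries > 200L * n_spurious)
          stop("could not place spurious peaks clear of true peaks")
        p <- stats::runif(3)
        dmin <- min(min_image_dist_matrix(host$cell, matrix(p, 1), true_frac))
        if (dmin >= spurious_clearance) sp_frac <- rbind(sp_frac, p)
      }
    }
    sp_h <- abs(stats::rnorm(nrow(sp_frac), height_spurious, height_sd))

    frac <- rbind(true_frac, sp_frac)
    heights <- c(true_h, sp_h)
    provenance <- c(as.character(keep), rep("spurious", nrow(sp_frac)))
    ord <- order(-heights)
    pk <- data.frame(label = paste0("Q", seq_along(ord)),
                     x = frac[ord, 1], y = frac[ord, 2], z = frac[ord, 3],
                     height = heights[ord])
    structure(list(
      qpeaks = qpeak_set(host, pk),
      truth = list(candidate = candidate_name, conformer = ci,
                   rotation = R, translation = center_cart,
                   provenance = provenance[ord])),
      class = "simulated_case")
  })
}

#' @export
print.simulated_case <- function(x, ...) {
  cat(sprintf("Simulated case: %s, %d peaks (%d spurious)\n",
              x$truth$candidate, nrow(x$qpeaks$peaks),
              sum(x$truth$provenance == "spurious")))
  invisible(x)
}

#' Packaged monoclinic I2/a host fixture
#'
#' A synthetic crystalline-sponge host: a monoclinic I-centered cell of
#' roughly 3617 cubic Angstrom with the full eight-operator I2/a symmetry
#' list and a minimal framework motif (one Bi site, its coordinated water
#' oxygen, and two framework O/C sites), suitable for symmetry, distance,
#' and interaction tests. This is a synthetic stand-in, not experimental
#' data.
#'
#' @return A [host_structure()].
#' @export
make_host_fixture <- function() {
  cell <- unit_cell(10.85, 15.00, 22.35, 90, 95.5, 90)
  ops <- expand_latt_symm(2L, "1/2-X, Y, -Z")
  sites <- data.frame(
    label = c("Bi1", "O1W", "O1", "C1"),
    element = c("Bi", "O", "O", "C"),
    x = c(0.3622, 0.1323, 0.4300, 0.4860),
    y = c(0.4671, 0.4163, 0.3113, 0.2250),
    z = c(0.1178, 0.1434, 0.1401, 0.1730),
    occ = c(1, 1, 1, 1), uiso = c(0.02, 0.05, 0.04, 0.04))
  host_structure(cell, ops, sites, name = "synthetic-I2a-sponge")
}
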