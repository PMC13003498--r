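#' Unit cell
#'
#' Construct a crystallographic unit cell from its six lattice parameters.
#' The orthogonalization convention is fixed: \eqn{a} lies along Cartesian
#' \eqn{x} and \eqn{b} lies in the \eqn{xy}-plane. Cartesian coordinates are
#' therefore convention-dependent, while all distances derived from them are
#' not.
#'
#' @param a,b,c Cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `unit_cell` with components `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`, the 3x3 orthogonalization matrix `ortho`,
#'   its inverse `ortho_inv`, and the cell `volume` in cubic Angstrom.
#' @examples
#' cl <- unit_cell(10, 12, 14, 90, 100, 90)
#' cl$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c)
  ang <- c(alpha, beta, gamma)
  if (!all(is.finite(len)) || any(len <= 0))
    stop("cell lengths must be finite and positive")
  if (!all(is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0)
    stop("degenerate cell: metric tensor is not positive-definite")
  v <- sqrt(v2)
  ortho <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * v / sg), nrow = 3, byrow = TRUE)
  out <- list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
              ortho = ortho, ortho_inv = solve(ortho),
              volume = a * b * c * v)
  class(out) <- "unit_cell"
  out
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

as_coord_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3) stop("coordinate matrix must have 3 columns")
    p
  } else {
    if (length(p) != 3) stop("coordinate must have length 3")
    matrix(p, nrow = 1)
  }
}

#' Fractional to Cartesian conversion
#'
#' @param cell A [unit_cell()].
#' @param p A length-3 fractional coordinate or an n x 3 matrix of them.
#' @return Cartesian coordinates in Angstrom, same shape as the input.
#' @export
frac_to_cart <- function(cell, p) {
  stopifnot(inherits(cell, "unit_cell"))
  m <- as_coord_matrix(p)
  out <- m %*% t(cell$ortho)
  if (is.matrix(p)) out else drop(out)
}

#' Cartesian to fractional conversion
#'
#' @inheritParams frac_to_cart
#' @param x Cartesian coordinates (Angstrom), length-3 or n x 3.
#' @return Fractional coordinates, same shape as the input.
#' @export
cart_to_frac <- function(cell, x) {
  stopifnot(inherits(cell, "unit_cell"))
  m <- as_coord_matrix(x)
  out <- m %*% t(cell$ortho_inv)
  if (is.matrix(x)) out else drop(out)
}

#' Wrap fractional coordinates into [0, 1)
#'
#' @param p Fractional coordinates, length-3 or n x 3.
#' @return Wrapped coordinates, same shape.
#' @export
wrap_frac <- function(p) {
  w <- p - floor(p)
  # floating point: 1 - eps wraps of exact integers can return 1
  w[w >= 1] <- w[w >= 1] - 1
  w
}

#' Periodic minimum-image distance
#'
#' Shortest Cartesian distance between two fractional points over all
#' lattice translations. The difference vector is first wrapped into
#' \eqn{[-1/2, 1/2)^3} and the minimum is then searched over the adjacent
#' shell of 27 lattice shifts, which is exact for cells that are not
#' extremely oblique.
#'
#' @param cell A [unit_cell()].
#' @param p,q Fractional coordinates (length-3 vectors).
#' @return Distance in Angstrom.
#' @export
min_image_distance <- function(cell, p, q) {
  min_image_vector(cell, p, q)$distance
}

#' Minimum-image difference vector
#'
#' Like [min_image_distance()] but also returns the lattice shift realizing
#' the minimum and the fractional difference vector `q + shift - p`.
#'
#' @inheritParams min_image_distance
#' @return List with `distance` (Angstrom), `shift` (integer lattice
#'   translation applied to `q`), and `dfrac` (fractional difference).
#' @export
min_image_vector <- function(cell, p, q) {
  stopifnot(inherits(cell, "unit_cell"))
  d0 <- q - p
  base <- round(d0)
  d <- d0 - base
  best <- Inf; bs <- c(0, 0, 0)
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    s <- c(i, j, k)
    r <- cell$ortho %*% (d + s)
    dd <- sum(r * r)
    if (dd < best) { best <- dd; bs <- s }
  }
  shift <- bs - base
  list(distance = sqrt(best), shift = shift, dfrac = d0 + shift)
}

#' All minimum-image distances between two coordinate sets
#'
#' Vectorized periodic distance matrix between rows of `P` and rows of `Q`
#' (fractional coordinates).
#'
#' @param cell A [unit_cell()].
#' @param P,Q n x 3 and m x 3 matrices of fractional coordinates.
#' @return n x m matrix of distances in Angstrom.
#' @export
min_image_dist_matrix <- function(cell, P, Q) {
  P <- as_coord_matrix(P); Q <- as_coord_matrix(Q)
  n <- nrow(P); m <- nrow(Q)
  # pairwise fractional differences wrapped to [-0.5, 0.5)
  out <- matrix(0, n, m)
  shifts <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
  for (a in seq_len(n)) {
    d <- sweep(Q, 2, P[a, ])
    d <- d - round(d)
    best <- rep(Inf, m)
    for (s in seq_len(nrow(shifts))) {
      ds <- sweep(d, 2, shifts[s, ], "+")
      r <- ds %*% t(cell$ortho)
      best <- pmin(best, rowSums(r * r))
    }
    out[a, ] <- sqrt(best)
  }
  out
}
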