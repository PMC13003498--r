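#' Space-group symmetry operation
#'
#' A symmetry operation acting on fractional coordinates as
#' `p' = R p + t`, with an integer-valued 3x3 rotation part of determinant
#' +/-1 and a translation part taken modulo 1. Operations are supplied
#' explicitly (from a CIF symmetry loop, SHELX LATT/SYMM cards, or a config
#' list of xyz triplets); the package deliberately ships no space-group
#' symbol database.
#'
#' @param rotation 3x3 numeric matrix (integer-valued entries).
#' @param translation Length-3 numeric vector; reduced modulo 1.
#' @return Object of class `symop` with components `R` and `t`.
#' @export
symop <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(rotation - round(rotation))) > 1e-9)
    stop("rotation part must be integer-valued")
  rotation <- round(rotation)
  dt <- round(det(rotation))
  if (abs(dt) != 1)
    stop("rotation part must have determinant +1 or -1, got ", dt)
  translation <- wrap_frac(as.numeric(translation))
  structure(list(R = rotation, t = translation), class = "symop")
}

symop_identity <- function() symop(diag(3), c(0, 0, 0))

#' Apply a symmetry operation to fractional coordinates
#'
#' @param op A [symop()].
#' @param p Length-3 fractional coordinate or n x 3 matrix.
#' @return Transformed coordinates (not wrapped), same shape as input.
#' @export
symop_apply <- function(op, p) {
  m <- as_coord_matrix(p)
  out <- m %*% t(op$R) + matrix(op$t, nrow(m), 3, byrow = TRUE)
  if (is.matrix(p)) out else drop(out)
}

#' Compose two symmetry operations
#'
#' Returns the operation equivalent to applying `b` first, then `a`,
#' with the translation reduced modulo 1.
#'
#' @param a,b [symop()] objects.
#' @export
symop_compose <- function(a, b) {
  symop(a$R %*% b$R, a$R %*% b$t + a$t)
}

symop_key <- function(op) {
  paste(c(op$R, round(wrap_frac(op$t) * 24)), collapse = ",")
}

#' Parse an xyz-triplet symmetry string
#'
#' Parses strings in the CIF `_symmetry_equiv_pos_as_xyz` dialect, e.g.
#' `"1/2+x, -y, z"`. Coefficients on x, y, z must be +/-1 (optionally with
#' an explicit integer coefficient); translations may be fractions (`1/2`)
#' or decimals (`0.5`).
#'
#' @param text Comma-separated triplet string.
#' @return A [symop()].
#' @examples
#' parse_symop("1/2+x, 1/2-y, -z")
#' @export
parse_symop <- function(text) {
  comps <- strsplit(text, ",", fixed = TRUE)[[1]]
  if (length(comps) != 3)
    stop("symmetry string must have 3 comma-separated components: ", text)
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (i in 1:3) {
    s <- gsub("[[:space:]]", "", tolower(comps[i]))
    if (!nzchar(s)) stop("empty component ", i, " in symmetry string: ", text)
    terms <- regmatches(s, gregexpr("[+-]?[^+-]+", s))[[1]]
    if (sum(nchar(terms)) != nchar(s))
      stop("malformed token in component ", i, " of symmetry string: ", text)
    for (tm in terms) {
      sign <- 1
      body <- tm
      if (startsWith(body, "+")) body <- substring(body, 2)
      else if (startsWith(body, "-")) { sign <- -1; body <- substring(body, 2) }
      if (grepl("[xyz]$", body)) {
        axis <- match(substring(body, nchar(body)), c("x", "y", "z"))
        coef_s <- substring(body, 1, nchar(body) - 1)
        coef_s <- sub("\\*$", "", coef_s)
        coef <- if (nzchar(coef_s)) suppressWarnings(as.numeric(coef_s)) else 1
        if (is.na(coef))
          stop("malformed coefficient '", tm, "' in symmetry string: ", text)
        R[i, axis] <- R[i, axis] + sign * coef
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        parts <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        t[i] <- t[i] + sign * parts[1] / parts[2]
      } else if (grepl("^[0-9]*\\.?[0-9]+$", body)) {
        t[i] <- t[i] + sign * as.numeric(body)
      } else {
        stop("malformed token '", tm, "' in symmetry string: ", text)
      }
    }
  }
  # crystallographic translations are multiples of 1/12
  tw <- wrap_frac(t)
  if (max(abs(tw * 12 - round(tw * 12))) > 1e-6)
    stop("non-crystallographic translation in symmetry string: ", text)
  symop(R, t)
}

#' Render a symmetry operation as an xyz-triplet string
#'
#' Inverse of [parse_symop()] up to formatting.
#'
#' @param op A [symop()].
#' @return String such as `"1/2+x, -y, z"`.
#' @export
symop_to_string <- function(op) {
  ax <- c("x", "y", "z")
  frac_str <- function(v) {
    v <- wrap_frac(v)
    if (abs(v) < 1e-9) return("")
    num <- round(v * 12); g <- gcd_int(num, 12)
    paste0(num %/% g, "/", 12 %/% g)
  }
  comps <- character(3)
  for (i in 1:3) {
    s <- frac_str(op$t[i])
    for (j in 1:3) {
      cf <- op$R[i, j]
      if (cf == 0) next
      term <- if (abs(cf) == 1) ax[j] else paste0(abs(cf), ax[j])
      s <- paste0(s, if (cf > 0 && nzchar(s)) "+" else if (cf < 0) "-" else "",
                  term)
    }
    if (!nzchar(s)) s <- "0"
    comps[i] <- s
  }
  paste(comps, collapse = ", ")
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  max(a, 1)
}

#' Close a set of symmetry operations into a group
#'
#' Repeatedly composes the supplied operations (adding the identity) until
#' closure modulo lattice translations is reached.
#'
#' @param ops List of [symop()] objects.
#' @param max_order Safety cap on the group order.
#' @return List of `symop` forming a group, identity first.
#' @export
symop_group <- function(ops, max_order = 192) {
  out <- list(symop_identity())
  keys <- symop_key(out[[1]])
  queue <- ops
  while (length(queue) > 0) {
    op <- queue[[1]]; queue <- queue[-1]
    k <- symop_key(op)
    if (k %in% keys) next
    out <- c(out, list(op)); keys <- c(keys, k)
    if (length(out) > max_order) stop("symmetry set does not close (order > ",
                                      max_order, ")")
    for (other in out) {
      queue <- c(queue, list(symop_compose(op, other)),
                 list(symop_compose(other, op)))
    }
  }
  out
}

#' Orbit of a point under a set of symmetry operations
#'
#' Applies every operation to `p`, wraps results into `[0,1)^3`, and merges
#' points closer than `dedup_tol` (periodic minimum-image distance), so
#' special positions collapse to their distinct images.
#'
#' @param cell A [unit_cell()].
#' @param ops List of [symop()]; must contain the identity.
#' @param p Length-3 fractional coordinate.
#' @param dedup_tol Merge tolerance in Angstrom (default 0.1).
#' @return Matrix (k x 3) of distinct fractional images; attribute
#'   `"symop_index"` gives, per row, the index of the op that produced it.
#' @export
expand_equivalents <- function(cell, ops, p, dedup_tol = 0.1) {
  if (length(ops) == 0) stop("empty symmetry operation list")
  pts <- matrix(0, 0, 3); idx <- integer(0)
  for (i in seq_along(ops)) {
    q <- wrap_frac(symop_apply(ops[[i]], p))
    dup <- FALSE
    if (nrow(pts) > 0) {
      d <- min_image_dist_matrix(cell, q, pts)
      dup <- any(d < dedup_tol)
    }
    if (!dup) { pts <- rbind(pts, q); idx <- c(idx, i) }
  }
  attr(pts, "symop_index") <- idx
  pts
}
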