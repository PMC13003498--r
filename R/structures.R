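#' Host structure container
#'
#' @param cell A [unit_cell()].
#' @param symops List of [symop()] (full expanded operator list).
#' @param sites Data frame with columns `label`, `element`, `x`, `y`, `z`
#'   (fractional), `occ`, `uiso`.
#' @param name Structure name.
#' @param header Character vector of SHELX header lines to preserve on
#'   write-out (optional).
#' @return Object of class `host_structure`.
#' @export
host_structure <- function(cell, symops, sites, name = "host",
                           header = NULL) {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(sites))
  need <- c("label", "element", "x", "y", "z", "occ", "uiso")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(sites) == 0) stop("host structure must contain at least one site")
  if (any(sites$occ <= 0 | sites$occ > 1))
    stop("site occupancies must lie in (0, 1]")
  bad <- !sites$element %in% known_elements()
  if (any(bad))
    stop("unrecognized element symbol(s): ",
         paste(unique(sites$element[bad]), collapse = ", "))
  w <- wrap_frac(as.matrix(sites[, c("x", "y", "z")]))
  sites$x <- w[, 1]; sites$y <- w[, 2]; sites$z <- w[, 3]
  if (length(symops) == 0) symops <- list(symop_identity())
  structure(list(cell = cell, symops = symops, sites = sites,
                 name = name, header = header),
            class = "host_structure")
}

#' @export
print.host_structure <- function(x, ...) {
  cat(sprintf("Host structure '%s': %d sites, %d symmetry operations\n",
              x$name, nrow(x$sites), length(x$symops)))
  print(x$cell)
  invisible(x)
}

#' Q-peak set container
#'
#' Residual electrostatic-potential maxima with ordinal heights. Heights
#' carry no absolute calibration; only their relative ordering is used.
#'
#' @param host A [host_structure()] the peaks refer to.
#' @param peaks Data frame with columns `label`, `x`, `y`, `z` (fractional),
#'   `height`.
#' @return Object of class `qpeak_set`, peaks sorted by height descending.
#' @export
qpeak_set <- function(host, peaks) {
  stopifnot(inherits(host, "host_structure"), is.data.frame(peaks))
  need <- c("label", "x", "y", "z", "height")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peaks is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(peaks$label))
    stop("Q-peak labels must be unique")
  peaks <- peaks[order(-peaks$height), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(host = host, peaks = peaks), class = "qpeak_set")
}

#' @export
print.qpeak_set <- function(x, ...) {
  cat(sprintf("Q-peak set: %d peaks (heights %s)\n", nrow(x$peaks),
              if (nrow(x$peaks)) sprintf("%.2f .. %.2f", max(x$peaks$height),
                                         min(x$peaks$height)) else "none"))
  invisible(x)
}

known_elements <- function() {
  c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
    "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
    "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
    "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
    "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
    "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Hf", "Ta",
    "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi")
}

normalize_element <- function(sym) {
  s <- paste0(toupper(substring(sym, 1, 1)), tolower(substring(sym, 2)))
  s
}
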