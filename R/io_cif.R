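# Minimal CIF reader covering the tags needed for a host structure:
# cell parameters, a symmetry-operation loop, and the atom_site loop.

cif_tokenize <- function(lines) {
  toks <- list()
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    if (!nzchar(trimws(ln))) next
    if (grepl("^;", ln)) next  # multi-line text blocks are skipped wholesale
    rest <- trimws(ln)
    while (nzchar(rest)) {
      if (startsWith(rest, "'")) {
        m <- regmatches(rest, regexpr("^'[^']*'", rest))
        toks[[length(toks) + 1]] <- substring(m, 2, nchar(m) - 1)
        rest <- trimws(substring(rest, nchar(m) + 1))
      } else if (startsWith(rest, '"')) {
        m <- regmatches(rest, regexpr('^"[^"]*"', rest))
        toks[[length(toks) + 1]] <- substring(m, 2, nchar(m) - 1)
        rest <- trimws(substring(rest, nchar(m) + 1))
      } else {
        m <- regmatches(rest, regexpr("^[^[:space:]]+", rest))
        toks[[length(toks) + 1]] <- m
        rest <- trimws(substring(rest, nchar(m) + 1))
      }
    }
  }
  unlist(toks)
}

cif_numeric <- function(x) {
  # strip standard uncertainty "1.234(5)" -> 1.234
  as.numeric(sub("\\(.*\\)$", "", x))
}

#' Read a host structure from a CIF file
#'
#' Requires `_cell_length_*` and `_cell_angle_*` tags, an atom-site loop
#' with label and fractional coordinates, and (optionally) a symmetry loop
#' (`_symmetry_equiv_pos_as_xyz` or `_space_group_symop_operation_xyz`);
#' without one, P1 (identity only) is assumed. Missing occupancies default
#' to 1.0; the element is taken from `_atom_site_type_symbol` when present,
#' otherwise inferred from the label.
#'
#' @param path Path to a CIF file.
#' @param name Structure name (defaults to the data block name).
#' @return A [host_structure()].
#' @export
read_cif_structure <- function(path, name = NULL) {
  toks <- cif_tokenize(readLines(path, warn = FALSE))
  if (is.null(name)) {
    db <- grep("^data_", toks, value = TRUE)
    name <- if (length(db)) sub("^data_", "", db[1]) else
      sub("\\.[^.]*$", "", basename(path))
  }
  get_tag <- function(tag) {
    i <- which(toks == tag)
    if (!length(i)) return(NULL)
    toks[i[1] + 1]
  }
  need_num <- function(tag) {
    v <- get_tag(tag)
    if (is.null(v)) stop("CIF is missing mandatory tag ", tag)
    cif_numeric(v)
  }
  cell_a <- need_num("_cell_length_a"); cell_b <- need_num("_cell_length_b")
  cell_c <- need_num("_cell_length_c")
  al <- need_num("_cell_angle_alpha"); be <- need_num("_cell_angle_beta")
  ga <- need_num("_cell_angle_gamma")
  cell <- unit_cell(cell_a, cell_b, cell_c, al, be, ga)

  # locate loops: a loop_ token followed by tag tokens then data tokens
  loops <- list()
  i <- 1
  while (i <= length(toks)) {
    if (toks[i] == "loop_") {
      j <- i + 1
      tags <- character(0)
      while (j <= length(toks) && startsWith(toks[j], "_")) {
        tags <- c(tags, toks[j]); j <- j + 1
      }
      vals <- character(0)
      while (j <= length(toks) && !startsWith(toks[j], "_") &&
             toks[j] != "loop_" && !startsWith(toks[j], "data_")) {
        vals <- c(vals, toks[j]); j <- j + 1
      }
      loops[[length(loops) + 1]] <- list(tags = tags, vals = vals)
      i <- j
    } else i <- i + 1
  }

  find_loop <- function(tag) {
    for (lp in loops) if (tag %in% lp$tags) return(lp)
    NULL
  }
  sym_lp <- find_loop("_symmetry_equiv_pos_as_xyz")
  sym_tag <- "_symmetry_equiv_pos_as_xyz"
  if (is.null(sym_lp)) {
    sym_lp <- find_loop("_space_group_symop_operation_xyz")
    sym_tag <- "_space_group_symop_operation_xyz"
  }
  if (!is.null(sym_lp)) {
    nt <- length(sym_lp$tags)
    col <- match(sym_tag, sym_lp$tags)
    m <- matrix(sym_lp$vals, ncol = nt, byrow = TRUE)
    ops <- symop_group(lapply(m[, col], parse_symop))
  } else ops <- list(symop_identity())

  at_lp <- find_loop("_atom_site_fract_x")
  if (is.null(at_lp)) stop("CIF is missing mandatory tag _atom_site_fract_x")
  nt <- length(at_lp$tags)
  if (length(at_lp$vals) %% nt != 0)
    stop("ragged atom_site loop in ", path)
  m <- matrix(at_lp$vals, ncol = nt, byrow = TRUE)
  colv <- function(tag) {
    k <- match(tag, at_lp$tags)
    if (is.na(k)) NULL else m[, k]
  }
  label <- colv("_atom_site_label")
  if (is.null(label)) stop("CIF is missing mandatory tag _atom_site_label")
  elem <- colv("_atom_site_type_symbol")
  if (is.null(elem)) elem <- sub("[0-9'].*$", "", label)
  elem <- normalize_element(sub("[0-9+-]+$", "", elem))
  occ <- colv("_atom_site_occupancy")
  occ <- if (is.null(occ)) rep(1, nrow(m)) else cif_numeric(occ)
  uiso <- colv("_atom_site_U_iso_or_equiv")
  uiso <- if (is.null(uiso)) rep(0.05, nrow(m)) else cif_numeric(uiso)
  sites <- data.frame(
    label = label, element = elem,
    x = cif_numeric(colv("_atom_site_fract_x")),
    y = cif_numeric(colv("_atom_site_fract_y")),
    z = cif_numeric(colv("_atom_site_fract_z")),
    occ = occ, uiso = uiso)
  host_structure(cell, ops, sites, name = name)
}
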