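# SHELX res/ins reading and writing.
#
# Supported subset: TITL/CELL/ZERR/LATT/SYMM/SFAC/UNIT header cards, atom
# lines (label, sfac index, fractional x y z, sof, Uiso), trailing Q-peak
# lines (extra height field), HKLF/END terminators. The sof field follows
# the SHELX fixed-parameter convention: 10 + occ means a fixed occupancy
# (11.0 = fixed full occupancy).

shelx_keywords <- c(
  "TITL", "CELL", "ZERR", "LATT", "SYMM", "SFAC", "UNIT", "TEMP", "SIZE",
  "L.S.", "CGLS", "PLAN", "BOND", "FMAP", "ACTA", "WGHT", "FVAR", "HKLF",
  "END", "REM", "MORE", "TIME", "OMIT", "SHEL", "BASF", "TWIN", "EXTI",
  "HTAB", "CONF", "LIST", "EQIV", "ANIS", "AFIX", "HFIX", "PART", "DFIX",
  "SADI", "SAME", "SIMU", "DELU", "RIGU", "ISOR", "EADP", "EXYZ", "SUMP",
  "FREE", "BIND", "MERG", "SPEC", "RESI", "MOVE", "ABIN", "ANSC", "ANSR",
  "BLOC", "BUMP", "CHIV", "DAMP", "DANG", "DEFS", "DISP", "EGEN", "FEND",
  "FLAT", "FRAG", "GRID", "LAUE", "MOLE", "MPLA", "NCSY", "NEUT", "PRIG",
  "RTAB", "SLIM", "STIR", "SWAT", "TANG", "WIGL", "WPDB", "XNPD", "ZERR")

#' Read a SHELX res/ins file
#'
#' Parses the cell, the symmetry (LATT centering and inversion plus SYMM
#' cards, expanded to the full operator list), the atom sites, and any
#' trailing Q-peaks.
#'
#' @param path Path to a res/ins file.
#' @param name Structure name (defaults to the TITL card or file name).
#' @return List with components `host` (a [host_structure()]) and
#'   `qpeaks` (a [qpeak_set()], possibly empty).
#' @export
read_res <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  # join continuation lines ending in '='
  joined <- character(0)
  buf <- NULL
  for (ln in lines) {
    if (!is.null(buf)) { ln <- paste(buf, ln); buf <- NULL }
    if (grepl("=\\s*$", ln) && !grepl("^\\s*(TITL|REM)", ln)) {
      buf <- sub("=\\s*$", "", ln)
    } else joined <- c(joined, ln)
  }
  if (!is.null(buf)) joined <- c(joined, buf)
  lines <- joined

  cell <- NULL; latt <- 1L; symm <- character(0); sfac <- character(0)
  sites <- list(); qpeaks <- list(); header <- character(0)
  titl <- NULL
  in_atoms <- FALSE
  for (i in seq_along(lines)) {
    raw <- lines[i]
    ln <- trimws(raw)
    if (!nzchar(ln)) { if (!in_atoms) header <- c(header, raw); next }
    tok <- strsplit(ln, "\\s+")[[1]]
    key <- toupper(tok[1])
    if (key == "TITL") { titl <- trimws(sub("^\\s*TITL", "", raw)); header <- c(header, raw); next }
    if (key == "CELL") {
      if (length(tok) < 8)
        stop("line ", i, ": CELL card needs wavelength + 6 parameters")
      v <- suppressWarnings(as.numeric(tok[2:8]))
      if (any(is.na(v))) stop("line ", i, ": non-numeric CELL field")
      cell <- unit_cell(v[2], v[3], v[4], v[5], v[6], v[7])
      header <- c(header, raw); next
    }
    if (key == "LATT") { latt <- as.integer(tok[2]); header <- c(header, raw); next }
    if (key == "SYMM") {
      symm <- c(symm, sub("^\\s*SYMM\\s*", "", ln, ignore.case = TRUE))
      header <- c(header, raw); next
    }
    if (key == "SFAC") {
      sfac <- c(sfac, normalize_element(tok[-1]))
      header <- c(header, raw); next
    }
    if (key %in% c("HKLF", "END")) break
    if (key %in% shelx_keywords || grepl("^REM", key)) {
      if (!in_atoms) header <- c(header, raw)
      next
    }
    # atom or Q-peak line: label sfac x y z [sof [U [height]]]
    nums <- suppressWarnings(as.numeric(tok[-1]))
    if (length(nums) < 4 || any(is.na(nums[1:4])))
      stop("line ", i, ": atom line '", tok[1],
           "' needs at least sfac index and x y z")
    sfac_i <- as.integer(nums[1])
    if (is.null(cell)) stop("missing CELL card before atom line ", i)
    if (sfac_i < 1 || sfac_i > length(sfac))
      stop("line ", i, ": unknown scattering-factor index ", sfac_i)
    sof <- if (length(nums) >= 5 && !is.na(nums[5])) nums[5] else 11.0
    occ <- if (sof > 5) sof - 10 else sof
    uiso <- if (length(nums) >= 6 && !is.na(nums[6])) nums[6] else 0.05
    if (grepl("^Q[0-9]+$", toupper(tok[1]))) {
      height <- nums[length(nums)]
      qpeaks[[length(qpeaks) + 1]] <-
        data.frame(label = tok[1], x = nums[2], y = nums[3], z = nums[4],
                   height = height)
    } else {
      in_atoms <- TRUE
      sites[[length(sites) + 1]] <-
        data.frame(label = tok[1], element = sfac[sfac_i],
                   x = nums[2], y = nums[3], z = nums[4],
                   occ = occ, uiso = uiso)
    }
  }
  if (is.null(cell)) stop("missing CELL card in ", path)
  if (length(sites) == 0) stop("no atom sites found in ", path)
  ops <- expand_latt_symm(latt, symm)
  if (is.null(name)) name <- if (!is.null(titl) && nzchar(titl)) titl else
    sub("\\.[^.]*$", "", basename(path))
  host <- host_structure(cell, ops, do.call(rbind, sites), name = name,
                         header = header)
  pk <- if (length(qpeaks)) do.call(rbind, qpeaks) else
    data.frame(label = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), height = numeric(0))
  list(host = host, qpeaks = qpeak_set(host, pk))
}

#' Expand SHELX LATT/SYMM cards to a full symmetry operator list
#'
#' `LATT` encodes the lattice centering (1 P, 2 I, 3 R, 4 F, 5 A, 6 B, 7 C)
#' and, when positive, the presence of an inversion center at the origin.
#' `SYMM` cards list the non-identity operations of the point group half.
#'
#' @param latt Integer LATT code (sign = centrosymmetry flag).
#' @param symm Character vector of xyz-triplet strings.
#' @return Full list of [symop()], closed under composition.
#' @export
expand_latt_symm <- function(latt, symm = character(0)) {
  cent <- switch(abs(latt),
    list(),                                                # 1 P
    list(c(0.5, 0.5, 0.5)),                                # 2 I
    list(c(2/3, 1/3, 1/3), c(1/3, 2/3, 2/3)),              # 3 R
    list(c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0)),  # 4 F
    list(c(0, 0.5, 0.5)),                                  # 5 A
    list(c(0.5, 0, 0.5)),                                  # 6 B
    list(c(0.5, 0.5, 0)))                                  # 7 C
  if (is.null(cent)) stop("invalid LATT code: ", latt)
  gens <- lapply(symm, parse_symop)
  if (latt > 0) gens <- c(gens, list(symop(-diag(3))))
  gens <- c(gens, lapply(cent, function(t) symop(diag(3), t)))
  symop_group(gens)
}

format_shelx_atom_line <- function(label, sfac_i, x, y, z, occ, uiso,
                                   height = NULL) {
  base <- sprintf("%-5s %2d %10.6f %10.6f %10.6f %10.5f %10.5f",
                  label, sfac_i, x, y, z, 10 + occ, uiso)
  if (!is.null(height)) base <- sprintf("%s %9.2f", base, height)
  base
}

#' Write a SHELX ins file with appended guest atoms
#'
#' Emits the preserved host header (or a minimal generated one), the host
#' atom block, and the guest atoms with the scattering-factor index of
#' their element, extending the SFAC/UNIT cards when the guest introduces a
#' new element. Re-reading the file with [read_res()] reproduces all sites
#' to 1e-6 fractional units.
#'
#' @param host A [host_structure()].
#' @param guest_atoms Data frame like the `sites` component (columns
#'   `label`, `element`, `x`, `y`, `z`, `occ`, `uiso`), or NULL.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_ins_model <- function(host, guest_atoms = NULL, path) {
  stopifnot(inherits(host, "host_structure"))
  elements <- unique(c(host$sites$element,
                       if (!is.null(guest_atoms)) guest_atoms$element))
  bad <- !elements %in% known_elements()
  if (any(bad)) stop("element not representable: ",
                     paste(elements[bad], collapse = ", "))
  header <- host$header
  if (is.null(header)) {
    header <- c(
      sprintf("TITL %s", host$name),
      sprintf("CELL 0.0251 %9.4f %9.4f %9.4f %8.3f %8.3f %8.3f",
              host$cell$a, host$cell$b, host$cell$c,
              host$cell$alpha, host$cell$beta, host$cell$gamma),
      "LATT -1",
      vapply(host$symops[-1], function(op)
        paste("SYMM", toupper(symop_to_string(op))), character(1)),
      paste(c("SFAC", toupper(elements)), collapse = " "),
      paste(c("UNIT", rep("1", length(elements))), collapse = " "))
    sfac <- elements
  } else {
    # extend the existing SFAC card if new elements appear
    sfac_idx <- grep("^\\s*SFAC", header, ignore.case = TRUE)
    sfac <- normalize_element(
      strsplit(trimws(header[sfac_idx[1]]), "\\s+")[[1]][-1])
    new_el <- setdiff(elements, sfac)
    if (length(new_el)) {
      header[sfac_idx[1]] <- paste(c(trimws(header[sfac_idx[1]]),
                                     toupper(new_el)), collapse = " ")
      unit_idx <- grep("^\\s*UNIT", header, ignore.case = TRUE)
      if (length(unit_idx))
        header[unit_idx[1]] <- paste(c(trimws(header[unit_idx[1]]),
                                       rep("1", length(new_el))),
                                     collapse = " ")
      sfac <- c(sfac, new_el)
    }
  }
  atom_line <- function(s)
    format_shelx_atom_line(s$label, match(s$element, sfac),
                           s$x, s$y, s$z, s$occ, s$uiso)
  out <- header
  for (i in seq_len(nrow(host$sites))) out <- c(out, atom_line(host$sites[i, ]))
  if (!is.null(guest_atoms))
    for (i in seq_len(nrow(guest_atoms))) out <- c(out, atom_line(guest_atoms[i, ]))
  out <- c(out, "HKLF 4", "END")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read a plain TSV Q-peak list
#'
#' Tab- or whitespace-separated dialect with columns `label x y z height`
#' (header line optional), for users without SHELX files.
#'
#' @param path Path to the TSV file.
#' @param host A [host_structure()] the peaks belong to.
#' @return A [qpeak_set()].
#' @export
read_qpeaks_tsv <- function(path, host) {
  first <- readLines(path, n = 1, warn = FALSE)
  has_header <- grepl("label", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(df) != 5) stop("Q-peak TSV must have 5 columns: label x y z height")
    names(df) <- c("label", "x", "y", "z", "height")
  }
  df$label <- as.character(df$label)
  qpeak_set(host, df[, c("label", "x", "y", "z", "height")])
}

#' Write a Q-peak set in the TSV dialect
#'
#' @param qpeaks A [qpeak_set()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_qpeaks_tsv <- function(qpeaks, path) {
  stopifnot(inherits(qpeaks, "qpeak_set"))
  df <- qpeaks$peaks
  lines <- c("label\tx\ty\tz\theight",
             sprintf("%s\t%.6f\t%.6f\t%.6f\t%.4f",
                     df$label, df$x, df$y, df$z, df$height))
  writeLines(lines, path)
  invisible(path)
}
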