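# Turn the best match into a refinement-ready atomic model: matched peaks
# become carbon sites, unmatched candidate atoms are added at their
# transformed positions, and element reassignments are suggested from the
# candidate. Least-squares refinement itself (anisotropic ADPs, restraints,
# hydrogens) is outside this package; a polish checklist documents those
# manual steps.

#' Place a matched guest as an initial carbon skeleton
#'
#' One carbon site per matched peak at the peak's position (occupancy 1.0);
#' unmatched candidate atoms are appended at their candidate-transform
#' positions with provenance `"added"`. Each atom carries the element the
#' candidate suggests for it.
#'
#' @param match A `match_result` from [match_candidate()].
#' @param cluster The cluster the match refers to.
#' @param host The [host_structure()].
#' @param candidate The matched `candidate` (needed for unmatched-atom
#'   positions and suggested elements).
#' @param uiso Initial isotropic displacement parameter (A^2).
#' @return Object of class `guest_model`: list with `atoms` (data frame
#'   label, element, x, y, z, occ, uiso, provenance, suggested_element)
#'   and `candidate` name.
#' @export
place_guest_as_carbons <- function(match, cluster, host, candidate,
                                   uiso = 0.05) {
  if (is.null(match)) stop("empty match: nothing to place")
  m <- match$correspondence
  if (max(m[, "peak"]) > nrow(cluster$coords))
    stop("match does not refer to this cluster")
  if (match$candidate != candidate$name)
    stop("match was computed for candidate '", match$candidate,
         "', not '", candidate$name, "'")
  n_at <- length(candidate$elements)
  n_pk <- nrow(cluster$coords)
  conf <- candidate$conformers[[match$conformer]]
  peak_coord <- function(pk) {
    if (pk <= n_pk) cluster$coords[pk, ] else
      match$extra_coords[pk - n_pk, ]
  }
  peak_label <- function(pk) {
    if (pk <= n_pk) cluster$labels[pk] else match$extra_labels[pk - n_pk]
  }
  rows <- list()
  for (r in seq_len(nrow(m))) {
    pk <- m[r, "peak"]; at <- m[r, "atom"]
    if (pk > n_pk + length(match$extra_labels))
      stop("match does not refer to this cluster")
    fr <- wrap_frac(cart_to_frac(host$cell, peak_coord(pk)))
    rows[[length(rows) + 1]] <- data.frame(
      label = paste0("C", r), element = "C",
      x = fr[1], y = fr[2], z = fr[3], occ = 1.0, uiso = uiso,
      provenance = peak_label(pk),
      suggested_element = candidate$elements[at])
  }
  missing_atoms <- setdiff(seq_len(n_at), m[, "atom"])
  for (at in missing_atoms) {
    pos <- drop(match$rotation %*% conf[at, ]) + match$translation
    fr <- wrap_frac(cart_to_frac(host$cell, pos))
    rows[[length(rows) + 1]] <- data.frame(
      label = paste0("C", length(rows) + 1), element = "C",
      x = fr[1], y = fr[2], z = fr[3], occ = 1.0, uiso = uiso,
      provenance = "added",
      suggested_element = candidate$elements[at])
  }
  structure(list(atoms = do.call(rbind, rows), candidate = candidate$name),
            class = "guest_model")
}

#' @export
print.guest_model <- function(x, ...) {
  cat(sprintf("Guest model (%s): %d atoms (%d added)\n", x$candidate,
              nrow(x$atoms), sum(x$atoms$provenance == "added")))
  invisible(x)
}

#' Suggest atom-type reassignments from the matched candidate
#'
#' For every guest atom whose suggested element differs from the carbon it
#' was placed as, emit a `C -> element` reassignment. The list is empty
#' exactly when the candidate is all-carbon.
#'
#' @param model A [place_guest_as_carbons()] result.
#' @return Data frame with columns `label`, `from`, `to` (zero rows when
#'   no reassignment is needed).
#' @export
suggest_atom_types <- function(model) {
  stopifnot(inherits(model, "guest_model"))
  sel <- model$atoms$suggested_element != model$atoms$element
  data.frame(label = model$atoms$label[sel],
             from = model$atoms$element[sel],
             to = model$atoms$suggested_element[sel],
             stringsAsFactors = FALSE)
}

#' Apply suggested element reassignments
#'
#' @param model A `guest_model`.
#' @return The model with elements replaced by the suggestions.
#' @export
apply_atom_types <- function(model) {
  stopifnot(inherits(model, "guest_model"))
  model$atoms$element <- model$atoms$suggested_element
  model
}

#' Manual polishing checklist for downstream refinement
#'
#' The finishing steps a crystallographer performs after automated guest
#' placement; this package emits the refinement-ready model but does not
#' execute refinement.
#'
#' @param model A `guest_model` (used to flag unexplained peaks).
#' @param cluster Optionally, the source cluster, to list unexplained peaks.
#' @param match Optionally, the `match_result`, to list unmatched peaks.
#' @return Character vector of checklist items.
#' @export
polish_checklist <- function(model, cluster = NULL, match = NULL) {
  items <- c(
    "Review flagged unexplained residual peaks; remove spurious atoms only on chemical grounds",
    "Apply suggested atom-type reassignments (see suggest_atom_types)",
    "Refine non-hydrogen atoms anisotropically",
    "Add hydrogen atoms from chemical knowledge",
    "If needed: geometric restraints (DFIX) and ADP restraints/constraints (SIMU, ISOR, EADP)",
    "If needed: EXTI to partially compensate dynamical effects")
  if (!is.null(match) && length(match$unmatched_peaks) && !is.null(cluster)) {
    items <- c(sprintf(
      "Unexplained peaks not used by the match: %s",
      paste(cluster$labels[match$unmatched_peaks], collapse = ", ")), items)
  }
  n_added <- sum(model$atoms$provenance == "added")
  if (n_added > 0)
    items <- c(sprintf("Verify the %d added (unobserved) atom position(s)",
                       n_added), items)
  items
}
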