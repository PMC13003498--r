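# JSON ranking reports (versioned schema) and YAML pipeline configuration.

REPORT_SCHEMA_VERSION <- "1.0"

#' Write a ranking report as JSON
#'
#' Structured, versioned report with, per candidate: rank, rmsd, coverage,
#' score, matched peak labels, conformer, and the rigid transform of the
#' match. Values are written at full precision so the report round-trips
#' through [read_report()].
#'
#' @param ranking A `guest_ranking` from [rank_candidates()].
#' @param path Output path.
#' @param cluster Optional source cluster; adds matched peak labels.
#' @return Invisibly, the path.
#' @export
write_report <- function(ranking, path, cluster = NULL) {
  stopifnot(inherits(ranking, "guest_ranking"))
  if (!nrow(ranking$table)) stop("empty ranking")
  entries <- lapply(seq_len(nrow(ranking$table)), function(i) {
    row <- ranking$table[i, ]
    res <- ranking$results[[row$candidate]]
    e <- list(rank = row$rank, candidate = row$candidate,
              rmsd = row$rmsd, coverage = row$coverage, score = row$score,
              matched = row$matched, conformer = row$conformer)
    if (!is.null(res)) {
      e$correspondence <- unname(apply(res$correspondence, 1, as.list))
      e$rotation <- unname(apply(res$rotation, 1, as.list))
      e$translation <- res$translation
      e$unmatched_peaks <- res$unmatched_peaks
      e$extra_labels <- res$extra_labels
      e$extra_coords <- unname(apply(res$extra_coords, 1, as.list))
      if (length(res$extra_labels)) e$captured_peak_labels <- res$extra_labels
      if (!is.null(cluster)) {
        pk <- res$correspondence[, "peak"]
        lbl <- ifelse(pk <= length(cluster$labels), cluster$labels[pk],
                      res$extra_labels[pmax(pk - length(cluster$labels), 1)])
        e$matched_peak_labels <- lbl
      }
    }
    e
  })
  payload <- list(schema_version = REPORT_SCHEMA_VERSION,
                  params = unclass(ranking$params),
                  ranking = entries)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a JSON ranking report back into a `guest_ranking`
#'
#' @param path Path written by [write_report()].
#' @return A `guest_ranking` equivalent to the one written.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(payload$schema_version))
    stop("not a ranking report: missing schema_version")
  entries <- payload$ranking
  nm <- vapply(entries, function(e) e$candidate, character(1))
  num <- function(x) {
    if (is.null(x) || identical(x, "NA")) return(NA_real_)
    if (identical(x, "Inf")) return(Inf)
    if (identical(x, "-Inf")) return(-Inf)
    as.numeric(x)
  }
  tab <- data.frame(
    rank = vapply(entries, function(e) as.integer(e$rank), integer(1)),
    candidate = nm,
    rmsd = vapply(entries, function(e) num(e$rmsd), numeric(1)),
    coverage = vapply(entries, function(e) num(e$coverage), numeric(1)),
    score = vapply(entries, function(e) num(e$score), numeric(1)),
    matched = vapply(entries, function(e) as.integer(e$matched), integer(1)),
    conformer = vapply(entries, function(e)
      if (is.null(e$conformer)) NA_integer_ else as.integer(e$conformer),
      integer(1)),
    stringsAsFactors = FALSE)
  results <- lapply(entries, function(e) {
    if (is.null(e$rotation)) return(NULL)
    m <- do.call(rbind, lapply(e$correspondence, function(p)
      c(peak = as.integer(p[[1]]), atom = as.integer(p[[2]]))))
    structure(list(
      candidate = e$candidate, conformer = as.integer(e$conformer),
      correspondence = m,
      rotation = do.call(rbind, lapply(e$rotation, as.numeric)),
      translation = as.numeric(unlist(e$translation)),
      rmsd = num(e$rmsd), coverage = num(e$coverage), score = num(e$score),
      unmatched_peaks = as.integer(unlist(e$unmatched_peaks)),
      extra_labels = as.character(unlist(e$extra_labels)),
      extra_coords = if (length(e$extra_coords))
        do.call(rbind, lapply(e$extra_coords, as.numeric)) else
          matrix(0, 0, 3)),
      class = "match_result")
  })
  names(results) <- nm
  # restore original candidate-set ordering if recoverable; ranking order
  # is what the table carries, results keep report order
  p <- payload$params
  params <- matcher_params(
    bond_window = as.numeric(unlist(p$bond_window)),
    height_min = as.numeric(p$height_min), pair_tol = as.numeric(p$pair_tol),
    min_coverage = as.numeric(p$min_coverage),
    coverage_weight = as.numeric(p$coverage_weight),
    tie_tol = as.numeric(p$tie_tol))
  structure(list(table = tab, results = results, params = params),
            class = "guest_ranking")
}

#' Read a pipeline configuration file
#'
#' YAML with the keys `candidates` (named SMILES map, or the string
#' `"builtin:paper10"` for the packaged ten-guest panel), `matcher`
#' (arguments of [matcher_params()]), `interaction` (arguments of
#' [interaction_params()]), `paper_mode` (logical; rank on raw RMSD),
#' and `seed`. Unknown keys are rejected before any work is done.
#'
#' @param path Path to a YAML config file.
#' @return Validated list of class `pipeline_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("candidates", "matcher", "interaction", "paper_mode", "seed",
             "n_conformers")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  check_args <- function(sub, fn, label) {
    if (is.null(sub)) return(list())
    bad <- setdiff(names(sub), names(formals(fn)))
    if (length(bad))
      stop("unknown ", label, " parameter(s): ", paste(bad, collapse = ", "))
    sub
  }
  cfg$matcher <- check_args(cfg$matcher, matcher_params, "matcher")
  cfg$interaction <- check_args(cfg$interaction, interaction_params,
                                "interaction")
  if (is.null(cfg$candidates)) cfg$candidates <- "builtin:paper10"
  if (is.null(cfg$paper_mode)) cfg$paper_mode <- FALSE
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "pipeline_config")
}

#' Materialize the candidate set named by a configuration
#'
#' @param cfg A [read_config()] result (or compatible list).
#' @return A [candidate_set()].
#' @export
config_candidates <- function(cfg) {
  spec <- cfg$candidates
  seed <- as.integer(cfg$seed %||% 1L)
  if (identical(spec, "builtin:paper10"))
    return(guest_library(seed = seed, n_conformers = cfg$n_conformers))
  if (!is.list(spec) || is.null(names(spec)))
    stop("config candidates must be 'builtin:paper10' or a named SMILES map")
  candidate_set(lapply(names(spec), function(nm)
    candidate_from_smiles(nm, spec[[nm]], n_conformers = cfg$n_conformers,
                          seed = seed)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
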