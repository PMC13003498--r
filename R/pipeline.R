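# End-to-end identification: Q-peaks in, ranked identification + built
# model + interaction report out.

#' Identify the guest in a Q-peak set
#'
#' Runs the full automated path: peak filtering and symmetry-aware
#' clustering, per-cluster candidate ranking, carbon-skeleton placement
#' and atom-type suggestions for the top candidate of the largest cluster,
#' contact classification, and the symmetry-clash occupancy cap. With
#' `out_dir` set, writes the JSON ranking report, the refinement-ready
#' SHELX ins model, a polish checklist, and a parameter log.
#'
#' @param qpeaks A [qpeak_set()] (e.g. from [read_res()],
#'   [read_qpeaks_tsv()], or [simulate_qpeaks()]).
#' @param candidates A [candidate_set()]; defaults to the packaged
#'   ten-guest panel.
#' @param params A [matcher_params()].
#' @param iparams An [interaction_params()].
#' @param paper_mode Rank on raw RMSD alone (coverage weight 0), emulating
#'   ranking purely by geometric agreement.
#' @param out_dir Optional output directory.
#' @param min_cluster_size Smallest cluster worth ranking (default 2).
#' @return Object of class `guest_identification`: list with `clusters`,
#'   `rankings` (one `guest_ranking` per cluster), `best` (cluster index,
#'   candidate), `model` (a `guest_model`, elements applied),
#'   `reassignments`, `interactions`, `occupancy_cap`, `checklist`.
#' @export
identify_guest <- function(qpeaks, candidates = guest_library(),
                           params = matcher_params(),
                           iparams = interaction_params(),
                           paper_mode = FALSE, out_dir = NULL,
                           min_cluster_size = 2L) {
  stopifnot(inherits(qpeaks, "qpeak_set"))
  if (!length(candidates)) stop("empty candidate set")
  if (paper_mode) params$coverage_weight <- 0
  clusters <- filter_and_cluster(qpeaks, params)
  clusters <- Filter(function(cl) length(cl$labels) >= min_cluster_size,
                     clusters)
  if (!length(clusters))
    stop(structure(class = c("nanosponge_no_clusters", "error", "condition"),
                   list(message = "no Q-peak clusters above the minimum size",
                        call = sys.call())))
  rankings <- lapply(clusters, rank_candidates, candidates = candidates,
                     params = params)
  # best = top-ranked accepted candidate of the largest cluster that has one
  best <- NULL
  for (i in seq_along(rankings)) {
    tab <- rankings[[i]]$table
    acc <- tab[!is.infinite(tab$score), , drop = FALSE]
    if (nrow(acc)) { best <- list(cluster = i, candidate = acc$candidate[1]); break }
  }
  if (is.null(best))
    stop(structure(class = c("nanosponge_no_match", "error", "condition"),
                   list(message = "no candidate achieved an admissible match",
                        call = sys.call())))
  cl <- clusters[[best$cluster]]
  match <- rankings[[best$cluster]]$results[[best$candidate]]
  model <- place_guest_as_carbons(match, cl, qpeaks$host,
                                  candidates[[best$candidate]])
  reass <- suggest_atom_types(model)
  finalized <- apply_atom_types(model)
  interactions <- classify_contacts(qpeaks$host, finalized, iparams)
  cap <- occupancy_cap(qpeaks$host, finalized, iparams)
  checklist <- polish_checklist(model, cl, match)
  out <- structure(list(
    clusters = clusters, rankings = rankings, best = best, model = model,
    reassignments = reass, interactions = interactions,
    occupancy_cap = cap, checklist = checklist, host = qpeaks$host,
    params = params, iparams = iparams), class = "guest_identification")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(rankings[[best$cluster]],
                 file.path(out_dir, "ranking.json"), cluster = cl)
    write_ins_model(qpeaks$host, finalized$atoms[, c(
      "label", "element", "x", "y", "z", "occ", "uiso")],
      file.path(out_dir, "model.ins"))
    jsonlite::write_json(
      list(schema_version = REPORT_SCHEMA_VERSION,
           best_candidate = best$candidate,
           occupancy_cap = cap,
           reassignments = reass,
           interactions = as.data.frame(interactions),
           checklist = checklist),
      file.path(out_dir, "identification.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
    writeLines(c(
      paste("nanosponge", as.character(utils::packageVersion("nanosponge"))),
      paste("matcher:", jsonlite::toJSON(unclass(params), auto_unbox = TRUE)),
      paste("interaction:", jsonlite::toJSON(unclass(iparams),
                                             auto_unbox = TRUE)),
      paste("paper_mode:", paper_mode)),
      file.path(out_dir, "run_log.txt"))
  }
  out
}

#' @export
print.guest_identification <- function(x, ...) {
  cat("Guest identification\n")
  cat(sprintf("  clusters ranked: %d (largest: %d peaks)\n",
              length(x$clusters), length(x$clusters[[1]]$labels)))
  cat(sprintf("  best candidate: %s (cluster %d)\n", x$best$candidate,
              x$best$cluster))
  res <- x$rankings[[x$best$cluster]]$results[[x$best$candidate]]
  cat(sprintf("  rmsd %.4f A, coverage %.2f, score %.4f\n",
              res$rmsd, res$coverage, res$score))
  cat(sprintf("  atom-type reassignments: %d\n", nrow(x$reassignments)))
  cat(sprintf("  occupancy cap: %.0f%%\n", 100 * x$occupancy_cap))
  cat(sprintf("  interactions: %s\n",
              paste(unique(x$interactions$kind), collapse = ", ")))
  invisible(x)
}
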