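#' Run configuration
#'
#' Bundles the analysis constants shared across pipeline stages.
#'
#' @param max_distance Maximum inter-individual distance in metres; the
#'   greatest distance two animals can be seen apart given the enclosure,
#'   used both as the cross-room proximity value and as the reversal
#'   constant for the DSI. Default 6.
#' @param mastication_mask AU codes treated as feeding-related and dropped
#'   when they occur during an `AD50a` (feeding) interval. Default
#'   `c("AU25", "AU26")`.
#' @param min_context_seconds Minimum per-context true observation time for
#'   the robustness re-analysis; contexts with less data are excluded there.
#'   Default 60.
#' @param elo_start,elo_k,elo_scale Classical Elo parameters: start rating,
#'   k factor and logistic scale. Defaults 1000, 100, 400.
#' @param walktrap_steps Random-walk length for walktrap community
#'   detection. Default 4.
#' @param kmeans_restarts Number of random restarts for k-means. Default 50.
#' @param kmeans_seed Seed fixed for the k-means scan so cluster labels are
#'   reproducible. Default 42.
#' @param contexts Context label set.
#' @param allow_missing_dyads If `TRUE`, dyads with no joint scan
#'   denominator are returned as `NA` instead of raising an error.
#' @return A list of class `maqsoc_config`.
#' @export
run_config <- function(max_distance = 6,
                       mastication_mask = c("AU25", "AU26"),
                       min_context_seconds = 60,
                       elo_start = 1000, elo_k = 100, elo_scale = 400,
                       walktrap_steps = 4,
                       kmeans_restarts = 50, kmeans_seed = 42,
                       contexts = default_contexts(),
                       allow_missing_dyads = FALSE) {
  stopifnot(max_distance > 0, min_context_seconds >= 0,
            elo_k > 0, elo_scale > 0, walktrap_steps >= 1)
  vocab <- maqfacs_vocabulary()$code
  bad <- setdiff(mastication_mask, c(vocab, "AU43"))
  if (length(bad))
    stop("mastication_mask codes outside the vocabulary: ",
         paste(bad, collapse = ", "))
  structure(list(
    max_distance = max_distance,
    mastication_mask = mastication_mask,
    min_context_seconds = min_context_seconds,
    elo_start = elo_start, elo_k = elo_k, elo_scale = elo_scale,
    walktrap_steps = walktrap_steps,
    kmeans_restarts = kmeans_restarts, kmeans_seed = kmeans_seed,
    contexts = contexts,
    allow_missing_dyads = allow_missing_dyads
  ), class = "maqsoc_config")
}

#' Read a run configuration from YAML
#'
#' Any field of [run_config()] may be set in the file; unset fields keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `maqsoc_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config fields: ", paste(extra, collapse = ", "))
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#'
#' @param config A `maqsoc_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
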