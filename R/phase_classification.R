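# Cluster -> developmental-phase classification. Clusters are assigned a
# phase from the stage at which their centroid peaks, checked against the
# per-species stage configuration; genes inherit the phase of their hard
# cluster.

#' Stage index of a profile's maximum
#'
#' @param profile Numeric stage profile (e.g. a cluster centroid).
#' @return 1-based index of the maximal value; ties break to the earliest
#'   stage.
#' @export
peak_stage <- function(profile) {
  if (length(profile) == 0L) stop("empty profile")
  which.max(profile)
}

#' Classify clusters into developmental phases by their expression maxima
#'
#' Each cluster's centroid peak stage is looked up in the species stage
#' configuration: peaks in `early_stages` give phase `early`, in
#' `late_stages` give `late`, in `excluded_stages` give `excluded`
#' (e.g. adult-peaking clusters dropped from comparisons), anything else is
#' `transitional`. When `larva_stage` is configured, late clusters are
#' sub-classified: peak before the larva stage is `pre_larval`, at or after
#' it `post_larval`. The peak is taken on the centroid of standardized
#' profiles; `peaks` can be supplied to use a different summary.
#'
#' @param clustering A `SoftClustering` (see [fuzzy_cmeans()]).
#' @param config A [stage_config()].
#' @param peaks Optional integer vector of per-cluster peak stages
#'   overriding the centroid maxima.
#' @return A `ClusterPhaseMap` data frame: cluster, peak_stage, phase,
#'   sub_phase.
#' @export
classify_clusters <- function(clustering, config, peaks = NULL) {
  stopifnot(inherits(clustering, "SoftClustering"),
            inherits(config, "SpeciesStageConfig"))
  n_stages <- ncol(clustering$centroids)
  idx <- c(config$early_stages, config$late_stages, config$excluded_stages)
  if (any(idx > n_stages)) stop("stage configuration references stage beyond the matrix")
  if (is.null(peaks)) {
    peaks <- apply(clustering$centroids, 1L, peak_stage)
  }
  stopifnot(length(peaks) == clustering$k)
  phase <- vapply(peaks, function(p) {
    if (p %in% config$early_stages) "early"
    else if (p %in% config$late_stages) "late"
    else if (p %in% config$excluded_stages) "excluded"
    else "transitional"
  }, character(1))
  sub_phase <- rep("none", clustering$k)
  if (!is.null(config$larva_stage)) {
    late <- phase == "late"
    sub_phase[late] <- ifelse(peaks[late] < config$larva_stage,
                              "pre_larval", "post_larval")
  }
  out <- data.frame(cluster = seq_len(clustering$k),
                    peak_stage = as.integer(peaks),
                    phase = phase, sub_phase = sub_phase,
                    stringsAsFactors = FALSE)
  class(out) <- c("ClusterPhaseMap", "data.frame")
  attr(out, "species_id") <- config$species_id
  out
}

#' Propagate cluster phases to genes
#'
#' Every gene inherits the phase and sub-phase of its hard-assigned cluster.
#' Genes in excluded clusters are flagged (`phase == "excluded"`) so
#' downstream comparisons can drop them.
#'
#' @param clustering A `SoftClustering`.
#' @param phase_map A `ClusterPhaseMap` covering all clusters.
#' @return A `GenePhaseTable` data frame: gene_id, cluster, phase, sub_phase.
#' @export
gene_phases <- function(clustering, phase_map) {
  stopifnot(inherits(clustering, "SoftClustering"),
            inherits(phase_map, "ClusterPhaseMap"))
  if (!all(seq_len(clustering$k) %in% phase_map$cluster)) {
    stop("phase map must cover all clusters")
  }
  idx <- match(clustering$hard_labels, phase_map$cluster)
  out <- data.frame(gene_id = names(clustering$hard_labels),
                    cluster = as.integer(clustering$hard_labels),
                    phase = phase_map$phase[idx],
                    sub_phase = phase_map$sub_phase[idx],
                    stringsAsFactors = FALSE)
  class(out) <- c("GenePhaseTable", "data.frame")
  attr(out, "species_id") <- attr(phase_map, "species_id")
  out
}
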