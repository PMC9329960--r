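#' Clinical-cohort bookkeeping tables
#'
#' The package ships two small plain-text tables describing the clinical
#' development cohort of the video-based FOG study this pipeline
#' re-implements: per-patient FOG episode counts by motion stage, and the
#' cohort-level video accounting (subject counts and per-stage video
#' minutes). They feed the episode-count and dataset-arithmetic summaries.
#'
#' @return \code{cohort_episode_counts()}: data frame with one row per
#'   FOG-affected patient and columns \code{patient}, \code{walking},
#'   \code{turning}. \code{cohort_summary()}: named list of cohort-level
#'   quantities.
#' @export
cohort_episode_counts <- function() {
  utils::read.table(system.file("extdata", "cohort_episode_counts.tsv",
                                package = "fogvision", mustWork = TRUE),
                    header = TRUE, sep = "\t")
}

#' @rdname cohort_episode_counts
#' @export
cohort_summary <- function() {
  df <- utils::read.table(system.file("extdata", "cohort_summary.tsv",
                                      package = "fogvision", mustWork = TRUE),
                          header = TRUE, sep = "\t")
  stats::setNames(as.list(df$value), df$quantity)
}

#' @rdname cohort_episode_counts
#' @export
cohort_model_rates <- function() {
  utils::read.table(system.file("extdata", "cohort_model_rates.tsv",
                                package = "fogvision", mustWork = TRUE),
                    header = TRUE, sep = "\t")
}

#' Episode-count accounting over the per-patient table
#'
#' Sums the per-patient FOG episode counts by stage and overall.
#'
#' @param counts Per-patient count table
#'   (default \code{\link{cohort_episode_counts}()}).
#' @return Named list: \code{n_patients}, \code{walking}, \code{turning},
#'   \code{total}, and \code{per_patient_total} (vector).
#' @export
episode_count_totals <- function(counts = cohort_episode_counts()) {
  per_patient <- counts$walking + counts$turning
  list(n_patients = nrow(counts), walking = sum(counts$walking),
       turning = sum(counts$turning), total = sum(per_patient),
       per_patient_total = stats::setNames(per_patient, counts$patient))
}
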