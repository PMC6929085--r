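#' Bundled reference benchmark tables
#'
#' Per-posture recognition counts (frame and instance granularity) and
#' per-subject inter-segment angle summaries reported for an 11-subject,
#' 18-posture wearable-IMU benchmark database.  The counts feed
#' [accuracy_table()] to reproduce the benchmark's aggregate accuracies;
#' the angle means quantify the inter-subject shape variability that the
#' synthetic generator's subject-offset layer emulates.
#'
#' @param which `"frame_counts"`, `"instance_counts"` or `"angle_means"`.
#' @return a data.frame.
#' @examples
#' counts <- reference_table("instance_counts")
#' accuracy_table(counts$correct, counts$total, counts$posture)
#' @export
reference_table <- function(which = c("frame_counts", "instance_counts",
                                      "angle_means")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_", which, ".csv"),
                      package = "imupose", mustWork = TRUE)
  utils::read.csv(path)
}
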