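#' Bundled three-subject reference summary table
#'
#' Per-subject hydrodynamic summary measures for one healthy control (Con1)
#' and two Chiari I patients (P1, P2): peak systolic velocities at the
#' cervical SAS, aqueduct and foramen magnum; pressure-drop extrema between
#' the pontine cistern and cervical SAS and between the aqueduct and pontine
#' cistern; systolic/diastolic resistances; phase differences; probe-station
#' heights; and cycle-timing statistics (heart rate, caudal-flow fraction,
#' systolic-peak time, aqueduct delay). Used by the worked examples, e.g. to
#' recompute axial pressure gradients from the drops and station separations,
#' and across-subject max/min ratios via [subject_ratio_stats()]. These are
#' also the calibration anchors of the [waveform_presets()].
#'
#' @return A data.frame, one row per subject.
#' @export
example_subjects <- function() {
  path <- system.file("extdata", "example_subjects.csv", package = "csfflow")
  if (path == "") path <- file.path("inst", "extdata", "example_subjects.csv")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
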