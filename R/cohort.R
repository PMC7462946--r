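#' Published five-patient angioplasty cohort values
#'
#' Bundled worked example: per-ROI transit-time, blood-flow and blood-volume
#' values measured before and after infrapopliteal angioplasty in a
#' five-patient critical-limb-ischemia feasibility cohort, as printed
#' (rounded) in the study report, together with the percent rise the report
#' printed for each row. 15 analysis ROIs (2-4 per patient, anterior tibial
#' and posterior tibial artery territories) times 3 metrics.
#'
#' Some printed rises are not reproducible from the printed (rounded) pre
#' and post values — the report carried them at full internal precision —
#' so the printed rise is kept as its own column (`rise_printed`) rather
#' than recomputed.
#'
#' @return data frame with columns `patient`, `metric` (MTT/PBF/PBV),
#'   `artery` (ATA/PA), `roi_id`, `pre_value`, `post_value`, `rise_printed`.
#' @export
angioplasty_cohort <- function() {
  path <- system.file("extdata", "angioplasty_cohort.csv",
                      package = "perfdsa", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
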