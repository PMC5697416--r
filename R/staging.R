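.stage <- function(category, grade, criterion) {
  structure(list(category = category, grade = grade,
                 criterion_text = criterion),
            class = "disease_stage")
}

#' @export
print.disease_stage <- function(x, ...) {
  cat(sprintf("<disease_stage> %s: %s  (%s)\n",
              x$category, x$grade, x$criterion_text))
  invisible(x)
}

#' Stage hypertension from systolic and diastolic pressure
#'
#' Guideline bands, with the overall stage taken as the higher of the stages
#' implied by the systolic and diastolic readings independently (either
#' criterion suffices): normal below 140/90; Stage 1 at SBP 140-159 or
#' DBP 90-99; Stage 2 at SBP >= 160 or DBP >= 100; Accelerated at
#' SBP >= 180 or DBP >= 120.  Printed band edges such as "140-159" then
#' ">160" are closed at the upper edge (159-160 belongs to Stage 2 from
#' 160 upward), the standard guideline convention.
#'
#' @param SBP,DBP Systolic and diastolic arterial pressure, mmHg;
#'   `SBP > DBP > 0` required.
#' @return A `disease_stage` with category `"hypertension"` (grade `"N/A"`
#'   and category `"normal"` below all bands).
#' @examples
#' classifyHypertension(140, 80)   # Stage 1 on the systolic criterion
#' classifyHypertension(120, 80)   # normal
#' @export
classifyHypertension <- function(SBP, DBP) {
  if (!is.finite(SBP) || !is.finite(DBP) || DBP <= 0 || SBP <= DBP)
    stop("require SBP > DBP > 0")
  s <- findInterval(SBP, c(140, 160, 180))
  d <- findInterval(DBP, c(90, 100, 120))
  level <- max(s, d)
  switch(level + 1L,
         .stage("normal", "N/A", "SBP < 140 and DBP < 90 mmHg"),
         .stage("hypertension", "Stage 1", "140-159/90-99 mmHg"),
         .stage("hypertension", "Stage 2", ">160/>100 mmHg"),
         .stage("hypertension", "Accelerated", ">180/>120 mmHg"))
}

#' Stage systolic heart failure from ejection fraction
#'
#' Severity bands on left-ventricular ejection fraction: Severe below 30
#' percent, Moderate below 40, Mild below 50, otherwise normal.
#'
#' @param LVEF Ejection fraction as a fraction in `(0, 1]`.
#' @return A `disease_stage` with category `"heart_failure"` (or `"normal"`).
#' @examples
#' classifyHeartFailure(0.45)  # Mild
#' classifyHeartFailure(0.25)  # Severe
#' @export
classifyHeartFailure <- function(LVEF) {
  if (!is.finite(LVEF) || LVEF <= 0 || LVEF > 1)
    stop("LVEF must lie in (0, 1]")
  if (LVEF < 0.30) .stage("heart_failure", "Severe", "LVEF <30%")
  else if (LVEF < 0.40) .stage("heart_failure", "Moderate", "LVEF <40%")
  else if (LVEF < 0.50) .stage("heart_failure", "Mild", "LVEF <50%")
  else .stage("normal", "N/A", "LVEF >=50%")
}

#' Stage haemorrhage from fractional blood-volume loss
#'
#' Volume-loss classes: Stage I below 15 percent, Stage II from 15 to below
#' 30, Stage III from 30 to 40, Stage IV above 40 (closing the gap left by
#' bands printed as "30-40%" followed by "50%").
#'
#' @param volume_loss_fraction Fraction of circulating volume lost, in
#'   `[0, 1)`.
#' @return A `disease_stage` with category `"haemorrhage"`.
#' @examples
#' classifyHaemorrhage(0.50)             # Stage IV
#' classifyHaemorrhage(1 - 5200 / 5700)  # Stage I
#' @export
classifyHaemorrhage <- function(volume_loss_fraction) {
  f <- volume_loss_fraction
  if (!is.finite(f) || f < 0 || f >= 1)
    stop("volume_loss_fraction must lie in [0, 1)")
  if (f < 0.15) .stage("haemorrhage", "Stage I", "<15% volume loss")
  else if (f < 0.30) .stage("haemorrhage", "Stage II", "15-30% volume loss")
  else if (f <= 0.40) .stage("haemorrhage", "Stage III", "30-40% volume loss")
  else .stage("haemorrhage", "Stage IV", ">40% volume loss")
}

#' Stage a simulated preset by its own disease category
#'
#' Dispatches on the preset's category: hypertension is staged from the
#' simulated systolic/diastolic pressures, heart failure from the simulated
#' ejection fraction, haemorrhage from the analytic volume-loss fraction
#' relative to the normal circulating volume, and the normal preset maps to
#' the normal stage.
#'
#' @param preset_name A preset identifier.
#' @param metrics A `haemodynamics` object from a converged run of that
#'   preset.
#' @param reference_volume Circulating volume of the normal preset, ml, used
#'   as the haemorrhage denominator.
#' @return A `disease_stage`.
#' @export
stagePreset <- function(preset_name, metrics,
                        reference_volume = loadPreset("normal")$V_total) {
  info <- presetInfo(preset_name)
  switch(info$category,
         normal = .stage("normal", "N/A", "baseline physiology"),
         hypertension = classifyHypertension(metrics$SBP, metrics$DBP),
         heart_failure = classifyHeartFailure(metrics$LVEF),
         haemorrhage = {
           v <- loadPreset(preset_name)$V_total
           classifyHaemorrhage(1 - v / reference_volume)
         })
}
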