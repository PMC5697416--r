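#' Baseline-comparison table
#'
#' One row per haemodynamic quantity (SBP, DBP, MAP, HR, SV, CO, LVEF) with
#' the baseline value, the case value and the percent change from baseline
#' rounded to one decimal.  A zero baseline flags the row undefined instead
#' of failing the table.
#'
#' @param baseline,case `haemodynamics` objects.
#' @return A data frame with columns `quantity`, `baseline`, `case`,
#'   `percent_change` and `unit`.
#' @examples
#' \donttest{
#' b <- extractMetrics(runToSteadyState(loadPreset("normal")))
#' h <- extractMetrics(runToSteadyState(loadPreset("hf_severe")))
#' compareToBaseline(b, h)
#' }
#' @export
compareToBaseline <- function(baseline, case) {
  stopifnot(inherits(baseline, "haemodynamics"),
            inherits(case, "haemodynamics"))
  quantities <- c("SBP", "DBP", "MAP", "HR", "SV", "CO", "LVEF")
  units <- c(SBP = "mmHg", DBP = "mmHg", MAP = "mmHg", HR = "bpm",
             SV = "ml", CO = "l/min", LVEF = "fraction")
  b <- unlist(baseline[quantities])
  v <- unlist(case[quantities])
  pc <- ifelse(b == 0, NA_real_, round(100 * (v - b) / b, 1))
  data.frame(quantity = quantities,
             baseline = unname(b),
             case = unname(v),
             percent_change = unname(pc),
             unit = unname(units[quantities]),
             stringsAsFactors = FALSE)
}

.series_header <- c("t", "P_la", "P_lv", "P_art", "P_ven",
                    "V_la", "V_lv", "V_art", "V_ven",
                    "Q_mi", "Q_ao", "Q_sys", "Q_ven", "cycle")

#' Write / read a cycle time series as CSV
#'
#' Fixed column order
#' `t,P_la,P_lv,P_art,P_ven,V_la,V_lv,V_art,V_ven,Q_mi,Q_ao,Q_sys,Q_ven,cycle`,
#' comma separator, `.` decimal, LF line endings.
#'
#' @param series A `cycle_series`.
#' @param path Output file path.
#' @return `path`, invisibly (`writeSeries`); a data frame (`readSeries`).
#' @export
writeSeries <- function(series, path) {
  df <- as.data.frame(series)[, .series_header]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname writeSeries
#' @export
readSeries <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df), .series_header))
    stop("unexpected series header in ", path)
  df
}

#' Write / read haemodynamic metrics as flat JSON
#'
#' A single flat JSON object with unit-suffixed keys
#' (`SBP_mmHg`, ..., `CO_l_min`, `LVEF_frac`), numbers at full precision,
#' deterministic key order.  An optional disease stage adds
#' `stage_category` and `stage_grade` fields.
#'
#' @param metrics A `haemodynamics` object.
#' @param path Output file path.
#' @param stage Optional `disease_stage` to embed.
#' @return `path`, invisibly (`writeMetrics`); a `haemodynamics` object with
#'   a `stage` attribute if present (`readMetrics`).
#' @export
writeMetrics <- function(metrics, path, stage = NULL) {
  stopifnot(inherits(metrics, "haemodynamics"))
  out <- list(SBP_mmHg = metrics$SBP, DBP_mmHg = metrics$DBP,
              MAP_mmHg = metrics$MAP, HR_bpm = metrics$HR,
              HR_exact_bpm = metrics$HR_exact,
              SV_ml = metrics$SV, EDV_ml = metrics$EDV, ESV_ml = metrics$ESV,
              CO_l_min = metrics$CO, LVEF_frac = metrics$LVEF)
  if (!is.null(stage)) {
    out$stage_category <- stage$category
    out$stage_grade <- stage$grade
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMetrics
#' @export
readMetrics <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- list(SBP = raw$SBP_mmHg, DBP = raw$DBP_mmHg, MAP = raw$MAP_mmHg,
            HR = raw$HR_bpm, HR_exact = raw$HR_exact_bpm,
            SV = raw$SV_ml, EDV = raw$EDV_ml, ESV = raw$ESV_ml,
            CO = raw$CO_l_min, LVEF = raw$LVEF_frac)
  class(m) <- "haemodynamics"
  if (!is.null(raw$stage_category))
    attr(m, "stage") <- .stage(raw$stage_category, raw$stage_grade, "")
  m
}

#' Write / read a pressure-volume loop as two-column CSV
#'
#' Columns `V_lv,P_lv`; the closed loop's first row equals its last.
#'
#' @param loop A `pv_loop` data frame.
#' @param path Output file path.
#' @return `path`, invisibly (`writeLoop`); a data frame (`readLoop`).
#' @export
writeLoop <- function(loop, path) {
  utils::write.csv(as.data.frame(loop)[, c("V_lv", "P_lv")], path,
                   row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname writeLoop
#' @export
readLoop <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df), c("V_lv", "P_lv")))
    stop("unexpected loop header in ", path)
  df
}
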