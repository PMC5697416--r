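.registry_env <- new.env(parent = emptyenv())

.registry_path <- function() {
  system.file("extdata", "presets.tsv", package = "cardiolpm", mustWork = TRUE)
}

.constants_path <- function() {
  system.file("extdata", "constants.conf", package = "cardiolpm",
              mustWork = TRUE)
}

#' Read a key-value constants file
#'
#' Parses the shipped `constants.conf` format: one `key = value` pair per
#' line, `#` comments (inline or whole-line) ignored, blank lines allowed.
#'
#' @param path File path; defaults to the calibrated constants shipped with
#'   the package.
#' @return Named numeric vector of constants.
#' @export
readConstants <- function(path = .constants_path()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed constants line: ", lines[bad][1L])
  vals <- vapply(kv, function(x) as.numeric(trimws(x[2L])), numeric(1))
  names(vals) <- vapply(kv, function(x) trimws(x[1L]), character(1))
  if (any(is.na(vals))) stop("non-numeric constant value in ", path)
  vals
}

#' Table of shipped disease presets
#'
#' The registry of parameter presets: normal physiology plus graded
#' hypertension (resistance up, arterial compliance down), heart failure
#' (contractility down) and haemorrhagic shock (blood volume down, heart
#' rate up).  Each row carries the five tunable inputs; the fixed internal
#' constants come from the calibrated constants file and are shared by all
#' presets.
#'
#' @return A data frame with columns `name`, `category`, `grade`,
#'   `E_lv_max`, `R_sys`, `C_art`, `V_total`, `T` and `note`.
#' @export
presetTable <- function() {
  if (is.null(.registry_env$table)) {
    tab <- utils::read.delim(.registry_path(), stringsAsFactors = FALSE,
                             na.strings = NULL)
    stopifnot(!anyDuplicated(tab$name),
              all(tab$category %in% c("normal", "hypertension",
                                      "heart_failure", "haemorrhage")))
    .registry_env$table <- tab
  }
  .registry_env$table
}

#' Names of the shipped presets
#' @return Character vector of preset identifiers.
#' @export
presetNames <- function() presetTable()$name

#' Load a preset as a full parameter set
#'
#' Merges the preset's five tunable inputs with the calibrated fixed
#' constants, then applies any user overrides.
#'
#' @param name A preset identifier (see [presetNames()]).
#' @param overrides Optional named list of parameter overrides, applied via
#'   [applyOverrides()].
#' @return A validated `cardio_params` object.
#' @examples
#' loadPreset("hf_severe")
#' loadPreset("normal", overrides = list(R_sys = 1.614))
#' @export
loadPreset <- function(name, overrides = list()) {
  tab <- presetTable()
  i <- match(name, tab$name)
  if (length(name) != 1L || is.na(i))
    stop("unknown preset '", name, "'; valid names: ",
         paste(tab$name, collapse = ", "))
  const <- as.list(readConstants())
  p <- do.call(cardioParams,
               c(list(E_lv_max = tab$E_lv_max[i], R_sys = tab$R_sys[i],
                      C_art = tab$C_art[i], V_total = tab$V_total[i],
                      T = tab$T[i]),
                 const))
  applyOverrides(p, overrides)
}

#' Category and grade of a preset
#' @param name A preset identifier.
#' @return A list with `category`, `grade` and `note`.
#' @export
presetInfo <- function(name) {
  tab <- presetTable()
  i <- match(name, tab$name)
  if (length(name) != 1L || is.na(i))
    stop("unknown preset '", name, "'; valid names: ",
         paste(tab$name, collapse = ", "))
  list(name = name, category = tab$category[i], grade = tab$grade[i],
       note = tab$note[i])
}

#' One-time baseline calibration of the fixed constants
#'
#' Tunes a chosen subset of the fixed internal constants so that the normal
#' preset reproduces target haemodynamics (by default systolic/diastolic
#' pressure 120/80 mmHg and cardiac output 5 l/min), minimising the
#' equal-weight sum of squared relative errors with a bounded Nelder-Mead
#' search.  The five tunable inputs of the normal preset are held fixed;
#' only fixed constants from the allowed set (`E_lv_min`, `E_la_min`,
#' `E_la_max`, `C_ven`, `R_ven`, `V0_ven`, `f_peak`, `f_end`) may be freed.
#'
#' The shipped constants file is the frozen result of one such run; the
#' function is retained so the calibration is reproducible and auditable.
#' The search is deterministic: identical starts and bounds give identical
#' constants.
#'
#' @param targets Named list with `SBP`, `DBP` (mmHg) and `CO` (l/min).
#' @param free Named numeric vector of starting values for the constants to
#'   calibrate; names must come from the allowed set.
#' @param lower,upper Named bounds for the free constants (same names as
#'   `free`).
#' @param base Parameter set providing the anchored inputs and the remaining
#'   constants; defaults to the normal preset.
#' @param config Simulation configuration used inside the objective.
#' @param maxit Maximum Nelder-Mead iterations.
#' @return A list with `constants` (the calibrated values), `achieved`
#'   (haemodynamics of the calibrated model), `value` (final objective),
#'   `within_5pct` (logical: every target matched within 5 percent) and
#'   `params` (the calibrated parameter set).
#' @export
calibrateBaseline <- function(targets = list(SBP = 120, DBP = 80, CO = 5),
                              free,
                              lower,
                              upper,
                              base = loadPreset("normal"),
                              config = simConfig(ss_rel_tol = 3e-4),
                              maxit = 500) {
  allowed <- c("E_lv_min", "E_la_min", "E_la_max", "C_ven", "R_ven",
               "V0_ven", "f_peak", "f_end")
  if (is.null(names(free)) || !all(names(free) %in% allowed))
    stop("free constants must be named and drawn from: ",
         paste(allowed, collapse = ", "))
  if (!all(c("SBP", "DBP", "CO") %in% names(targets)))
    stop("targets must name SBP, DBP and CO")
  nm <- names(free)
  lower <- lower[nm]; upper <- upper[nm]
  if (any(is.na(lower)) || any(is.na(upper)) || any(lower >= upper))
    stop("lower/upper must bound every free constant")
  tgt <- unlist(targets[c("SBP", "DBP", "CO")])
  objective <- function(x) {
    if (any(x < lower) || any(x > upper)) return(1e6)
    p <- try(applyOverrides(base, as.list(stats::setNames(x, nm))),
             silent = TRUE)
    if (inherits(p, "try-error")) return(1e6)
    r <- try(runToSteadyState(p, config), silent = TRUE)
    if (inherits(r, "try-error")) return(1e6)
    m <- extractMetrics(r)
    sum(((c(m$SBP, m$DBP, m$CO) - tgt) / tgt)^2)
  }
  fit <- stats::optim(unname(free), objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10,
                                     parscale = upper - lower))
  if (!is.finite(fit$value) || fit$value >= 1e6)
    stop("calibration failed; best objective ", fit$value)
  constants <- stats::setNames(fit$par, nm)
  params <- applyOverrides(base, as.list(constants))
  achieved <- extractMetrics(runToSteadyState(params, config))
  dev <- abs(c(achieved$SBP, achieved$DBP, achieved$CO) - tgt) / tgt
  list(constants = constants, achieved = achieved, value = fit$value,
       within_5pct = all(dev < 0.05), params = params)
}
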