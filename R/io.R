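# File formats: the patient CSV dialect and YAML design/scenario configs.

#' Read and write the patient CSV dialect
#'
#' One row per randomised patient with header
#' `patient_id,arm,recruit_week,outcome`: `arm` is `control` or `treatment`,
#' `recruit_week` a non-negative decimal in ascending order, and `outcome`
#' `0` (alive at follow-up), `1` (dead) or `NA` (dropout). The round trip
#' write-read reproduces the records exactly.
#'
#' @param path File path.
#' @param patients Patient tibble.
#' @return `read_patients()` returns the validated patient tibble;
#'   `write_patients()` returns `path` invisibly.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) abort(sprintf("Patient file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expected <- c("patient_id", "arm", "recruit_week", "outcome")
  if (!identical(trimws(header), expected)) {
    abort(sprintf("Patient CSV header must be '%s' (line 1 of %s).",
                  paste(expected, collapse = ","), path))
  }
  df <- utils::read.csv(path, colClasses = c("character", "character", "numeric", "integer"))
  df <- tibble::as_tibble(df)
  tryCatch(validate_patients(df), error = function(e) {
    abort(sprintf("%s (%s; data rows are offset by the header line)",
                  conditionMessage(e), path))
  })
  df
}

#' @rdname read_patients
#' @export
write_patients <- function(patients, path) {
  validate_patients(patients)
  readr::write_csv(patients, path, na = "NA")
  invisible(path)
}

design_to_list <- function(design) {
  list(
    name = design$name,
    n_max = design$n_max,
    interims = lapply(seq_len(nrow(design$interims)), function(i) {
      list(n = design$interims$n[i],
           S = design$interims$success[i],
           F = design$interims$futility[i])
    }),
    final_threshold = design$final_threshold,
    prior = design$prior,
    allocation = design$allocation
  )
}

#' Read and write design configurations
#'
#' YAML serialisation of a [design_spec()] with keys `name`, `n_max`,
#' `interims` (list of `{n, S, F}`; `S: NA` disables success stopping at
#' that interim), `final_threshold`, `prior` and `allocation`. The
#' load-dump-load round trip is exact.
#'
#' @param path File path.
#' @param design A [design_spec()].
#' @return `read_design()` returns a [design_spec()]; `write_design()`
#'   returns `path` invisibly.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort(sprintf("Design config not found: %s", path))
  x <- yaml::read_yaml(path)
  for (key in c("name", "n_max")) {
    if (is.null(x[[key]])) abort(sprintf("Design config %s: missing field '%s'.", path, key))
  }
  interims <- if (length(x$interims)) {
    tibble::tibble(
      n = vapply(x$interims, function(i) as.integer(i$n), integer(1)),
      success = vapply(x$interims, function(i) {
        if (is.null(i$S) || is.na(i$S)) NA_real_ else as.numeric(i$S)
      }, double(1)),
      futility = vapply(x$interims, function(i) as.numeric(i$F), double(1))
    )
  }
  design_spec(
    name = x$name, n_max = x$n_max, interims = interims,
    final_threshold = x$final_threshold %||% 0.975,
    prior = x$prior %||% c(1, 1),
    allocation = unlist(x$allocation %||% c(1, 1))
  )
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_spec"))
  yaml::write_yaml(design_to_list(design), path, precision = 15)
  invisible(path)
}

#' Read and write scenario configurations
#'
#' YAML serialisation of a [scenario_spec()] with keys `p_control`,
#' `p_treatment`, `accrual_rate`, `dropout`, `followup_days`, `label`.
#'
#' @param path File path.
#' @param scenario A [scenario_spec()].
#' @return `read_scenario()` returns a [scenario_spec()];
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(sprintf("Scenario config not found: %s", path))
  x <- yaml::read_yaml(path)
  for (key in c("p_control", "p_treatment")) {
    if (is.null(x[[key]])) abort(sprintf("Scenario config %s: missing field '%s'.", path, key))
  }
  scenario_spec(
    p_control = x$p_control, p_treatment = x$p_treatment,
    accrual_rate = x$accrual_rate %||% 5.5,
    dropout = x$dropout %||% 0.03,
    followup_days = x$followup_days %||% 30,
    label = x$label
  )
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario_spec"))
  yaml::write_yaml(unclass(scenario), path, precision = 15)
  invisible(path)
}
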