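# Interim snapshots: per-arm randomised / complete / death counts at an
# interim analysis trigger.

#' Construct an interim snapshot
#'
#' Per-arm counts at an interim analysis: patients randomised, patients with
#' a complete primary outcome, and deaths among the complete. Patients
#' randomised but without a complete outcome are "in transit" and are
#' handled by predictive imputation; dropouts are randomised but never
#' complete.
#'
#' @param randomised_control,randomised_treatment Randomised per arm.
#' @param complete_control,complete_treatment Complete outcomes per arm.
#' @param deaths_control,deaths_treatment Deaths among the complete.
#' @return An object of class `interim_snapshot`.
#' @examples
#' interim_snapshot(129, 121, 118, 113, 49, 44)
#' @export
interim_snapshot <- function(randomised_control, randomised_treatment,
                             complete_control, complete_treatment,
                             deaths_control, deaths_treatment) {
  randomised <- c(control = check_count(randomised_control, "randomised_control"),
                  treatment = check_count(randomised_treatment, "randomised_treatment"))
  complete <- c(control = check_count(complete_control, "complete_control"),
                treatment = check_count(complete_treatment, "complete_treatment"))
  deaths <- c(control = check_count(deaths_control, "deaths_control"),
              treatment = check_count(deaths_treatment, "deaths_treatment"))
  for (arm in c("control", "treatment")) {
    if (deaths[[arm]] > complete[[arm]] || complete[[arm]] > randomised[[arm]]) {
      abort(sprintf(
        "Snapshot invariant violated for %s arm: need deaths (%d) <= complete (%d) <= randomised (%d).",
        arm, deaths[[arm]], complete[[arm]], randomised[[arm]]))
    }
  }
  structure(list(randomised = randomised, complete = complete, deaths = deaths),
            class = "interim_snapshot")
}

#' @export
print.interim_snapshot <- function(x, ...) {
  cat(sprintf(
    "Interim snapshot (%d randomised)\n  control:   %d randomised, %d/%d deaths among complete\n  treatment: %d randomised, %d/%d deaths among complete\n",
    sum(x$randomised),
    x$randomised[["control"]], x$deaths[["control"]], x$complete[["control"]],
    x$randomised[["treatment"]], x$deaths[["treatment"]], x$complete[["treatment"]]))
  invisible(x)
}

#' @export
as.data.frame.interim_snapshot <- function(x, ...) {
  as.data.frame(tibble::as_tibble(x))
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.interim_snapshot <- function(x, ...) {
  tibble::tibble(
    arm = c("control", "treatment"),
    randomised = as.integer(x$randomised),
    complete = as.integer(x$complete),
    deaths = as.integer(x$deaths)
  )
}

#' Snapshot of a patient stream at an interim trigger
#'
#' Computes the [interim_snapshot()] seen at the moment the `at_n`-th patient
#' is randomised: all `at_n` patients count as randomised; a patient's
#' outcome is complete when they were recruited at least the follow-up
#' length before the trigger patient's recruitment time and their outcome is
#' not missing. Missing outcomes (dropouts) count as randomised but are
#' never complete.
#'
#' @param patients Patient tibble with columns `patient_id`, `arm`
#'   (`"control"`/`"treatment"`), `recruit_week`, `outcome` (0 alive, 1 dead,
#'   `NA` dropout), sorted by `recruit_week`.
#' @param at_n Trigger recruit count.
#' @param followup_days Follow-up length in days (default 30).
#' @return An `interim_snapshot`.
#' @export
stream_snapshot <- function(patients, at_n, followup_days = 30) {
  validate_patients(patients)
  at_n <- check_count(at_n, "at_n", min = 1L)
  if (at_n > nrow(patients)) {
    abort(sprintf("Trigger count %d exceeds stream length %d.", at_n, nrow(patients)))
  }
  sub <- patients[seq_len(at_n), ]
  trigger_time <- sub$recruit_week[[at_n]]
  lag <- followup_weeks(followup_days)
  is_complete <- sub$recruit_week <= trigger_time - lag + 1e-9 & !is.na(sub$outcome)
  ctrl <- sub$arm == "control"
  interim_snapshot(
    randomised_control = sum(ctrl),
    randomised_treatment = sum(!ctrl),
    complete_control = sum(is_complete & ctrl),
    complete_treatment = sum(is_complete & !ctrl),
    deaths_control = sum(sub$outcome[is_complete & ctrl] == 1),
    deaths_treatment = sum(sub$outcome[is_complete & !ctrl] == 1)
  )
}

validate_patients <- function(patients) {
  required <- c("patient_id", "arm", "recruit_week", "outcome")
  if (!is.data.frame(patients) || !all(required %in% names(patients))) {
    abort(sprintf("`patients` must have columns %s.", paste(required, collapse = ", ")))
  }
  bad_arm <- which(!patients$arm %in% c("control", "treatment"))
  if (length(bad_arm)) {
    abort(sprintf("Row %d: `arm` must be 'control' or 'treatment' (got '%s').",
                  bad_arm[1], patients$arm[bad_arm[1]]))
  }
  bad_week <- which(is.na(patients$recruit_week) | patients$recruit_week < 0)
  if (length(bad_week)) {
    abort(sprintf("Row %d: `recruit_week` must be a non-negative number.", bad_week[1]))
  }
  if (is.unsorted(patients$recruit_week)) {
    abort("`patients` must be sorted by `recruit_week` (recruitment order).")
  }
  bad_out <- which(!(is.na(patients$outcome) | patients$outcome %in% c(0, 1)))
  if (length(bad_out)) {
    abort(sprintf("Row %d: `outcome` must be 0, 1 or NA.", bad_out[1]))
  }
  invisible(patients)
}
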