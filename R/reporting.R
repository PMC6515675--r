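# Pipeline runners: configuration handling, manifests, and table rendering
# in the shapes used for reporting sequential-trial results. Probabilities
# are rendered to 4 decimal places and relative risks to 2 in the CSV
# views; the JSON twins always carry full precision.

run_manifest <- function(command, config_paths, seed, n_sims = NA, n_draws = NA) {
  list(
    command = command,
    config_paths = as.list(config_paths),
    master_seed = seed,
    n_sims = n_sims,
    n_draws = n_draws,
    package_version = as.character(utils::packageVersion("seqbayes")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

write_outputs <- function(tbl_render, tbl_full, manifest, out_dir, stem,
                          format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (format == "csv") {
    p <- file.path(out_dir, paste0(stem, ".csv"))
    readr::write_csv(tbl_render, p, na = "NA")
    paths <- c(paths, p)
  }
  pj <- file.path(out_dir, paste0(stem, ".json"))
  jsonlite::write_json(tbl_full, pj, auto_unbox = TRUE, digits = NA, na = "null")
  pm <- file.path(out_dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paths, pj, pm))
}

round_probs <- function(tbl, prob_cols, digits = 4) {
  for (cl in intersect(prob_cols, names(tbl))) tbl[[cl]] <- round(tbl[[cl]], digits)
  tbl
}

#' Simulate operating characteristics for designs x scenarios
#'
#' Runs [operating_characteristics()] for every design-scenario pair and
#' writes one OC row per pair (CSV rendered to 4 decimal places, JSON at
#' full precision, plus a run manifest recording seeds and sizes).
#'
#' @param designs A [design_spec()], a list of them, or paths to YAML
#'   configs.
#' @param scenarios A [scenario_spec()], a list of them, or paths to YAML
#'   configs.
#' @param n_sims Simulated trials per pair.
#' @param seed Master seed.
#' @param n_draws Imputation draws per interim predictive probability.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param format `"csv"` (plus JSON) or `"json"` only.
#' @return The combined OC tibble, invisibly when writing.
#' @export
run_simulate <- function(designs, scenarios, n_sims, seed, n_draws = 10000,
                         out_dir = NULL, format = c("csv", "json")) {
  config_paths <- c(
    if (is.character(designs)) designs else character(),
    if (is.character(scenarios)) scenarios else character()
  )
  designs <- as_spec_list(designs, read_design, "design_spec")
  scenarios <- as_spec_list(scenarios, read_scenario, "scenario_spec")
  grid <- expand.grid(d = seq_along(designs), s = seq_along(scenarios))
  oc <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    message(sprintf("simulating %s under %s (n_sims = %d)",
                    designs[[grid$d[i]]]$name, scenarios[[grid$s[i]]]$label, n_sims))
    tibble::as_tibble(operating_characteristics(
      designs[[grid$d[i]]], scenarios[[grid$s[i]]],
      n_sims = n_sims, seed = seed, n_draws = n_draws))
  })
  if (!is.null(out_dir)) {
    rendered <- round_probs(oc, c("prop_stop_success", "prop_stop_futility",
                                  "prop_successful", "mcse_prop_stop_success",
                                  "mcse_prop_stop_futility", "mcse_prop_successful"))
    manifest <- run_manifest("simulate", config_paths, seed, n_sims, n_draws)
    write_outputs(rendered, oc, manifest, out_dir, "oc", match.arg(format))
    return(invisible(oc))
  }
  oc
}

as_spec_list <- function(x, reader, cls) {
  if (inherits(x, cls)) return(list(x))
  if (is.character(x)) return(lapply(x, reader))
  if (is.list(x) && all(vapply(x, inherits, logical(1), cls))) return(x)
  abort(sprintf("Expected %s objects or config paths.", cls))
}

#' Re-execute a design over a patient stream and write the reports
#'
#' Runs [reexecute()] and writes the interim decision trail (one row per
#' interim: allocation, complete outcomes, posterior probability of
#' superiority, `P_curr` where defined, `P_max`, decision) and the final
#' analysis block (final counts, relative risk with interval, posterior
#' probability, deaths, number randomised, accrual duration, and the
#' recruitment savings `n_max - n_randomised`).
#'
#' @param patients Patient tibble or path to a patient CSV.
#' @param design A [design_spec()] or path to a YAML config.
#' @param seed Master seed for the interim imputations.
#' @param n_draws Imputation draws per predictive probability.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param format `"csv"` (plus JSON) or `"json"` only.
#' @return The `reexecution` object, invisibly when writing.
#' @export
run_reexecute <- function(patients, design, seed, n_draws = 10000,
                          out_dir = NULL, format = c("csv", "json")) {
  config_paths <- c(
    if (is.character(patients)) patients else character(),
    if (is.character(design)) design else character()
  )
  if (is.character(patients)) patients <- read_patients(patients)
  if (is.character(design)) design <- read_design(design)
  res <- reexecute(patients, design, n_draws = n_draws, seed = seed)
  if (!is.null(out_dir)) {
    manifest <- run_manifest("reexecute", config_paths, seed, NA, n_draws)
    trail <- tidy(res)
    trail_r <- round_probs(trail, c("p_superior", "p_curr", "p_max"))
    write_outputs(trail_r, trail, manifest, out_dir, "decision_trail", match.arg(format))
    fin <- glance(res)
    fin_r <- round_probs(fin, c("final_prob_superior"))
    fin_r$rr <- round(fin_r$rr, 2)
    fin_r$rr_ci_low <- round(fin_r$rr_ci_low, 2)
    fin_r$rr_ci_high <- round(fin_r$rr_ci_high, 2)
    write_outputs(fin_r, fin, manifest, out_dir, "final_analysis", match.arg(format))
    return(invisible(res))
  }
  res
}

#' Planned sample size report
#'
#' Thin wrapper over [sample_size_two_proportions()] that also logs the
#' result.
#'
#' @inheritParams sample_size_two_proportions
#' @return The one-row sample-size tibble.
#' @export
run_sample_size <- function(p_control, absolute_reduction, alpha = 0.05,
                            power = 0.80, dropout = 0) {
  out <- sample_size_two_proportions(p_control, absolute_reduction,
                                     alpha = alpha, power = power, dropout = dropout)
  message(sprintf("%d per arm (%d total) for %g%% vs %g%% at two-sided alpha %g, power %g, dropout %g%%",
                  out$n_per_arm, out$n_total, 100 * p_control,
                  100 * (p_control - absolute_reduction), alpha, power, 100 * dropout))
  out
}
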