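#' Configuration for a desk-scale replication study
#'
#' Bundles every setting of the end-to-end pipeline (design, simulation,
#' fitting, analysis) with a single master seed, so a whole study is
#' reproducible from its config. Defaults generate the study conditions:
#' three conditions of 110 trials, twenty subjects, and generating
#' parameters equal to the group-mean fits the models are anchored to
#' (categorical observer for the cued condition, basic observer for the
#' no-cue conditions).
#'
#' @param seed Master seed; all other seeds are derived from it.
#' @param n_subjects Cohort size (default 20).
#' @param noise_sd Log-scale measurement noise SD of the synthetic subjects.
#' @param response_noise_sd Log-scale response noise SD (default 0).
#' @param sigma_s,d0 Scale constants shared by simulation and fitting.
#' @param generating Named list of generating `observer_params`, keys
#'   `"BR-NC"`, `"IR-NC"`, `"IR-C"`.
#' @param starts Multi-start setting for the per-subject fits (`"small"`
#'   keeps the full study tractable; group-mean fits always use the full
#'   grid).
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1, n_subjects = 20, noise_sd = 0.15,
                         response_noise_sd = 0, sigma_s = 0.15, d0 = 0.01,
                         generating = NULL, starts = "small") {
  if (is.null(generating)) {
    generating <- list(
      "BR-NC" = basic_params(rho = gain_to_rho(0.34), delta_x = -0.04,
                             d0 = d0, sigma_s = sigma_s),
      "IR-NC" = basic_params(rho = gain_to_rho(0.33), delta_x = -0.05,
                             d0 = d0, sigma_s = sigma_s),
      "IR-C" = categorical_params(p_c = 0.74, rho = gain_to_rho(0.33),
                                  delta_x = -0.04, d0 = d0,
                                  sigma_s = sigma_s)
    )
  }
  stopifnot(all(CONDITIONS %in% names(generating)))
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 noise_sd = noise_sd,
                 response_noise_sd = response_noise_sd,
                 sigma_s = sigma_s, d0 = d0, generating = generating,
                 starts = starts),
            class = "study_config")
}

#' Run the full desk-scale study pipeline
#'
#' Composes the package end to end: generates the three condition
#' sequences, simulates a cohort per condition from the configured
#' generating observers, fits the basic model to the no-cue conditions and
#' both cued models (categorical and cue-combination) to every subject and
#' to the group mean of the cued condition, compares the cued models'
#' per-subject R-squared by paired Wilcoxon signed-rank test, and computes
#' the behavioral summary tables (per-distance errors, overlapping-samples
#' comparison, condition differences).
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, sequences, response
#'   tables, fit results, and summaries are written there (CSV/JSON) with
#'   provenance metadata.
#' @return A list with elements `sequences`, `cohorts`, `group_means`,
#'   `fits` (per condition: group fit(s) and per-subject fits),
#'   `model_comparison`, `summaries`, `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  opts_subject <- fit_options(sigma_s = config$sigma_s, d0 = config$d0,
                              starts = config$starts)
  opts_group <- fit_options(sigma_s = config$sigma_s, d0 = config$d0,
                            starts = "full")

  sequences <- setNames(
    lapply(CONDITIONS, generate_condition_sequence, seed = config$seed),
    CONDITIONS)

  cohorts <- setNames(lapply(CONDITIONS, function(cond) {
    simulate_cohort(config$n_subjects, config$generating[[cond]],
                    sequences[[cond]], noise_sd = config$noise_sd,
                    response_noise_sd = config$response_noise_sd,
                    seed = config$seed + match(cond, CONDITIONS))
  }), CONDITIONS)

  group_means <- lapply(cohorts, group_mean_responses)

  fits <- list(
    "BR-NC" = list(
      group = fit_observer("basic", sequences[["BR-NC"]],
                           group_means[["BR-NC"]], opts_group),
      subjects = lapply(cohorts[["BR-NC"]], function(tab) {
        fit_observer("basic", sequences[["BR-NC"]], tab, opts_subject)
      })),
    "IR-NC" = list(
      group = fit_observer("basic", sequences[["IR-NC"]],
                           group_means[["IR-NC"]], opts_group),
      subjects = lapply(cohorts[["IR-NC"]], function(tab) {
        fit_observer("basic", sequences[["IR-NC"]], tab, opts_subject)
      })),
    "IR-C" = list(
      group_categorical = fit_observer("categorical", sequences[["IR-C"]],
                                       group_means[["IR-C"]], opts_group),
      group_cuecomb = fit_observer("cuecomb", sequences[["IR-C"]],
                                   group_means[["IR-C"]], opts_group),
      subjects_categorical = lapply(cohorts[["IR-C"]], function(tab) {
        fit_observer("categorical", sequences[["IR-C"]], tab, opts_subject)
      }),
      subjects_cuecomb = lapply(cohorts[["IR-C"]], function(tab) {
        fit_observer("cuecomb", sequences[["IR-C"]], tab, opts_subject)
      }))
  )

  r2_cat <- vapply(fits[["IR-C"]]$subjects_categorical,
                   function(f) f$r_squared, numeric(1))
  r2_cc <- vapply(fits[["IR-C"]]$subjects_cuecomb,
                  function(f) f$r_squared, numeric(1))
  comparison <- if (length(r2_cat) >= 5) {
    compare_fits(r2_cat, r2_cc)
  } else {
    list(statistic = NA_real_, p_value = NA_real_, n_nonzero = NA_integer_)
  }
  model_comparison <- c(comparison,
                        list(r2_categorical = r2_cat, r2_cuecomb = r2_cc))

  summaries <- list(
    per_distance = lapply(group_means, per_distance_errors),
    overlapping = lapply(group_means, overlapping_samples_comparison),
    difference_irnc_minus_irc = condition_difference(
      group_means[["IR-NC"]], group_means[["IR-C"]]),
    difference_irnc_minus_brnc = condition_difference(
      group_means[["IR-NC"]], group_means[["BR-NC"]])
  )

  result <- list(sequences = sequences, cohorts = cohorts,
                 group_means = group_means, fits = fits,
                 model_comparison = model_comparison,
                 summaries = summaries, config = config)
  if (!is.null(out_dir)) write_study_outputs(result, out_dir)
  result
}

fit_to_list <- function(fit) {
  list(model = fit$model, par = as.list(fit$par),
       rho = as.list(fit$rho),
       ci95 = list(lower = as.list(fit$ci95[, "lower"]),
                   upper = as.list(fit$ci95[, "upper"])),
       r_squared = fit$r_squared, ss = fit$ss,
       converged = fit$converged, n_evals = fit$n_evals)
}

write_study_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  provenance <- list(
    master_seed = cfg$seed,
    n_subjects = cfg$n_subjects,
    noise_sd = cfg$noise_sd,
    response_noise_sd = cfg$response_noise_sd,
    sigma_s = cfg$sigma_s, d0 = cfg$d0,
    package_version = as.character(utils::packageVersion("itercue"))
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  for (cond in names(result$sequences)) {
    tag <- tolower(gsub("-", "_", cond))
    write_sequence_csv(result$sequences[[cond]],
                       file.path(out_dir, paste0("sequence_", tag, ".csv")))
    write_responses_csv(result$group_means[[cond]],
                        file.path(out_dir,
                                  paste0("group_mean_", tag, ".csv")))
    for (i in seq_along(result$cohorts[[cond]])) {
      write_responses_csv(result$cohorts[[cond]][[i]],
                          file.path(out_dir,
                                    sprintf("responses_%s_s%02d.csv",
                                            tag, i)))
    }
    pd <- result$summaries$per_distance[[cond]]
    write.csv(pd, file.path(out_dir, paste0("per_distance_", tag, ".csv")),
              row.names = FALSE)
  }
  fits_json <- list(
    br_nc_group = fit_to_list(result$fits[["BR-NC"]]$group),
    ir_nc_group = fit_to_list(result$fits[["IR-NC"]]$group),
    ir_c_group_categorical = fit_to_list(
      result$fits[["IR-C"]]$group_categorical),
    ir_c_group_cuecomb = fit_to_list(result$fits[["IR-C"]]$group_cuecomb),
    model_comparison = result$model_comparison[c("statistic", "p_value",
                                                 "n_nonzero")]
  )
  jsonlite::write_json(fits_json, file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
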