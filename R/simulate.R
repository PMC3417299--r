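#' Simulate a synthetic subject
#'
#' A synthetic subject reproduces each sample distance with the observer
#' model's estimate: the log-scale measurement is the true log distance plus
#' Gaussian measurement noise (`noise_sd`), and the back-transformed response
#' can optionally be perturbed by multiplicative log-normal response noise
#' (`reproduced * exp(eta)`, `eta ~ N(0, response_noise_sd^2)`), mimicking
#' motor/decision variability on top of the estimate. Both noise sources are
#' derived deterministically from `seed`.
#'
#' @param params An `observer_params` object (selects the generating model).
#' @param sequence A `trial_sequence`.
#' @param noise_sd Log-scale measurement noise SD (`>= 0`).
#' @param response_noise_sd Log-scale response noise SD (`>= 0`, default 0).
#' @param seed Integer seed (required if any noise SD is positive).
#' @param subject_id Identifier stored in the table's metadata.
#' @return A `response_table` (see [run_sequence()]) with attributes
#'   `subject_id`, `noise_sd`, `response_noise_sd`, `seed`.
#' @export
simulate_subject <- function(params, sequence, noise_sd = 0,
                             response_noise_sd = 0, seed = NULL,
                             subject_id = "s1") {
  stopifnot(noise_sd >= 0, response_noise_sd >= 0)
  if ((noise_sd > 0 || response_noise_sd > 0) && is.null(seed)) {
    stop("seed required when simulating with noise")
  }
  tab <- run_sequence(params, sequence, noise_sd = noise_sd,
                      seed = if (noise_sd > 0) seed else NULL)
  if (response_noise_sd > 0) {
    eta <- withr::with_seed(as.integer(seed) + 1L,
                            rnorm(nrow(tab), 0, response_noise_sd))
    tab$reproduced_distance_m <- tab$reproduced_distance_m * exp(eta)
  }
  attr(tab, "subject_id") <- subject_id
  attr(tab, "response_noise_sd") <- response_noise_sd
  attr(tab, "seed") <- seed
  tab
}

#' Simulate a cohort of synthetic subjects
#'
#' Simulates `n_subjects` independent subjects over the *same* trial
#' sequence, with per-subject seeds derived deterministically from the
#' master seed.
#'
#' @param n_subjects Number of subjects (`>= 1`); the original study tested
#'   twenty volunteers.
#' @param params Generating `observer_params`.
#' @param sequence A `trial_sequence`.
#' @param noise_sd,response_noise_sd Noise SDs passed to
#'   [simulate_subject()].
#' @param seed Master seed.
#' @return List of `response_table`s, one per subject.
#' @export
simulate_cohort <- function(n_subjects, params, sequence, noise_sd = 0,
                            response_noise_sd = 0, seed = 1) {
  stopifnot(n_subjects >= 1)
  subj_seeds <- as.integer(seed) + 1000L * seq_len(n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    simulate_subject(params, sequence, noise_sd = noise_sd,
                     response_noise_sd = response_noise_sd,
                     seed = subj_seeds[i],
                     subject_id = sprintf("s%02d", i))
  })
}

#' Group-mean response table of a cohort
#'
#' Averages the reproduced distances of a cohort trial by trial (the "group
#' mean" series that is fitted as if it were a single subject).
#'
#' @param cohort List of `response_table`s over the same sequence.
#' @return A `response_table` with the per-trial mean reproduced distance.
#' @export
group_mean_responses <- function(cohort) {
  stopifnot(is.list(cohort), length(cohort) >= 1)
  ref <- cohort[[1]]
  for (tab in cohort[-1]) {
    if (!identical(tab$index, ref$index) ||
        !identical(tab$sample_distance_m, ref$sample_distance_m)) {
      stop("all cohort tables must share the same trial sequence")
    }
  }
  mat <- vapply(cohort, function(tab) tab$reproduced_distance_m,
                numeric(nrow(ref)))
  out <- ref
  out$reproduced_distance_m <- rowMeans(mat)
  attr(out, "subject_id") <- "group_mean"
  out
}

#' Read/write response tables as CSV
#'
#' Plain comma-separated files with header
#' `index,condition,cue_label,range_label,sample_distance_m,reproduced_distance_m`.
#' Metadata (model, noise settings, seed) is written to a JSON sidecar when
#' `sidecar = TRUE`.
#'
#' @param responses A `response_table`.
#' @param path CSV file path.
#' @param sidecar Write `<path>.json` with the table's metadata.
#' @return `write_responses_csv()` returns `path` invisibly;
#'   `read_responses_csv()` a `response_table`.
#' @export
write_responses_csv <- function(responses, path, sidecar = FALSE) {
  df <- as.data.frame(responses)[, c("index", "condition", "cue_label",
                                     "range_label", "sample_distance_m",
                                     "reproduced_distance_m")]
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (sidecar) {
    meta <- list(
      subject_id = attr(responses, "subject_id"),
      model = attr(responses, "model"),
      noise_sd = attr(responses, "noise_sd"),
      response_noise_sd = attr(responses, "response_noise_sd"),
      seed = attr(responses, "seed"),
      package_version = as.character(utils::packageVersion("itercue"))
    )
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null", digits = NA)
  }
  invisible(path)
}

#' @rdname write_responses_csv
#' @export
read_responses_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("index", "condition", "cue_label", "range_label",
            "sample_distance_m", "reproduced_distance_m")
  if (!all(need %in% names(df))) {
    stop("response file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(!is.finite(df$reproduced_distance_m)) ||
      any(df$reproduced_distance_m <= 0)) {
    stop("reproduced distances must be positive and finite")
  }
  out <- tibble::as_tibble(df[need])
  structure(out, class = c("response_table", class(out)))
}
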