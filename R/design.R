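#' Generate the trial sequence of one experimental condition
#'
#' Builds the ordered trial list for one of the three conditions of the
#' distance production-reproduction design:
#'
#' * `"BR-NC"` (blocked ranges, no cue): 100 test trials in two blocks of 50.
#'   The first block draws from the "short" range (5, 7, 9, 11, 13 m), the
#'   second from the "long" range (11, 13, 15, 17, 19 m); within each block
#'   every distance occurs exactly 10 times in shuffled order.
#' * `"IR-NC"` (interleaved ranges, no cue): the same 100 distances in one
#'   fully interleaved shuffled order (5, 7, 9, 15, 17, 19 m ten times each;
#'   11 and 13 m twenty times each).
#' * `"IR-C"` (interleaved ranges, cue): the *identical* distance order as
#'   `"IR-NC"` for the same seed, but every trial carries a symbolic cue:
#'   distances 5-9 m are cued "short", 15-19 m are cued "long", and the 20
#'   repetitions of 11 m (and of 13 m) are split exactly 10/10 between the
#'   two cue labels.
#'
#' Each condition is preceded by 10 training trials (distances drawn from the
#' same distance set; excluded from all analyses). The `range_label` column
#' carries the analysis split: first/second block for BR-NC, and the IR-C cue
#' assignment for both interleaved conditions, so that the same trials can be
#' compared with and without the cue.
#'
#' @param condition One of `"BR-NC"`, `"IR-NC"`, `"IR-C"`.
#' @param seed Integer seed controlling the (otherwise uniform) shuffles. The
#'   original study used one fixed order for all participants; the seed plays
#'   that role here, and `IR-NC`/`IR-C` share their order for equal seeds.
#' @return A `trial_sequence` object: a tibble with columns `index`,
#'   `condition`, `phase` (`"training"`/`"test"`), `sample_distance_m`,
#'   `cue_label` (`"short"`/`"long"`/`"none"`), `range_label`
#'   (`"short"`/`"long"`, `NA` for training trials), with attributes
#'   `condition` and `seed`.
#' @examples
#' seq_irc <- generate_condition_sequence("IR-C", seed = 1)
#' table(test_trials(seq_irc)$cue_label)
#' @seealso [split_by_range()], [run_sequence()]
#' @export
generate_condition_sequence <- function(condition, seed) {
  condition <- match.arg(condition, CONDITIONS)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  seed <- as.integer(seed)

  test <- withr::with_seed(seed, {
    training_d <- sample(DISTANCES_ALL, 10, replace = TRUE)
    if (condition == "BR-NC") {
      short_block <- sample(rep(DISTANCES_SHORT, each = 10))
      long_block <- sample(rep(DISTANCES_LONG, each = 10))
      list(
        training_d = training_d,
        d = c(short_block, long_block),
        assignment = rep(CUE_LEVELS, each = 50)
      )
    } else {
      # One draw shared by IR-NC and IR-C: shuffle (distance, assignment)
      # pairs so both conditions agree trial by trial for a given seed.
      pool_d <- c(rep(c(5, 7, 9), each = 10), rep(c(11, 13), each = 20),
                  rep(c(15, 17, 19), each = 10))
      pool_a <- c(rep("short", 30), rep(c("short", "long"), times = 2, each = 10),
                  rep("long", 30))
      ord <- sample(length(pool_d))
      # training cue labels for IR-C follow the same distance rule
      train_a <- ifelse(training_d <= 9, "short",
                        ifelse(training_d >= 15, "long",
                               sample(CUE_LEVELS, 10, replace = TRUE)))
      list(
        training_d = training_d,
        d = pool_d[ord],
        assignment = pool_a[ord],
        train_a = train_a
      )
    }
  })

  has_cue <- condition == "IR-C"
  trials <- tibble::tibble(
    index = seq_len(110L),
    condition = condition,
    phase = rep(c("training", "test"), c(10L, 100L)),
    sample_distance_m = c(test$training_d, test$d),
    cue_label = if (has_cue) {
      c(test$train_a, test$assignment)
    } else {
      "none"
    },
    range_label = c(rep(NA_character_, 10L), test$assignment)
  )
  structure(trials, class = c("trial_sequence", class(trials)),
            condition = condition, seed = seed)
}

#' Extract the test trials of a sequence
#'
#' @param sequence A `trial_sequence`.
#' @return The test-phase rows (training trials dropped), as a tibble.
#' @export
test_trials <- function(sequence) {
  stopifnot(inherits(sequence, "trial_sequence") || is.data.frame(sequence))
  sequence[sequence$phase == "test", , drop = FALSE]
}

#' Split the test trials of a condition into "short" and "long" ranges
#'
#' Implements the range split used throughout the analysis: for BR-NC the
#' first 50 test trials form the "short" group and the last 50 the "long"
#' group; for IR-C the split follows the symbolic cue; for IR-NC it follows
#' the cue assignment the *matching-seed* IR-C condition would have shown, so
#' that identical trials can be compared with and without the cue.
#'
#' @param sequence A `trial_sequence`.
#' @return A named list `list(short =, long =)` of test-trial positions
#'   (1-based within the 100 test trials).
#' @export
split_by_range <- function(sequence) {
  tt <- test_trials(sequence)
  if (nrow(tt) == 0) stop("sequence has no test trials")
  lab <- tt$range_label
  if (anyNA(lab)) stop("range_label must be defined for every test trial")
  list(short = which(lab == "short"), long = which(lab == "long"))
}

#' Read/write trial sequences as CSV
#'
#' The on-disk dialect is a plain comma-separated file with header
#' `index,condition,phase,sample_distance_m,cue_label,range_label`.
#'
#' @param sequence A `trial_sequence`.
#' @param path File path.
#' @return `write_sequence_csv()` returns `path` invisibly;
#'   `read_sequence_csv()` returns a `trial_sequence` (seed attribute `NA`,
#'   since the order on disk is authoritative).
#' @export
write_sequence_csv <- function(sequence, path) {
  df <- as.data.frame(sequence)[, c("index", "condition", "phase",
                                    "sample_distance_m", "cue_label",
                                    "range_label")]
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_sequence_csv
#' @export
read_sequence_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("index", "condition", "phase", "sample_distance_m",
            "cue_label", "range_label")
  if (!all(need %in% names(df))) {
    stop("sequence file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  trials <- tibble::as_tibble(df[need])
  structure(trials, class = c("trial_sequence", class(trials)),
            condition = df$condition[1], seed = NA_integer_)
}
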