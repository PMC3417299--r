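#' Per-distance reproduction summary
#'
#' Summarizes a response table by range and sample distance: mean and SD of
#' the reproduced distance, mean reproduction error
#' (`reproduced - sample`), and trial count. This is the long-format table a
#' repeated-measures ANOVA over conditions/distances would consume.
#'
#' @param table A `response_table` (must carry `range_label`).
#' @return Tibble `condition, range_label, sample_distance_m, mean_repro_m,
#'   sd_m, mean_error_m, n`, ordered by range and distance.
#' @export
per_distance_errors <- function(table) {
  stopifnot(is.data.frame(table))
  table |>
    dplyr::mutate(error_m = reproduced_distance_m - sample_distance_m) |>
    dplyr::group_by(condition, range_label, sample_distance_m) |>
    dplyr::summarise(
      mean_repro_m = mean(reproduced_distance_m),
      sd_m = sd(reproduced_distance_m),
      mean_error_m = mean(error_m),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(range_label, sample_distance_m)
}

#' Overlapping-samples comparison
#'
#' The 11 m and 13 m distances occur in both the "short" and the "long"
#' range. Comparing their reproductions between ranges isolates
#' range-dependent (prior- or cue-driven) biases: for each overlapping
#' distance the difference `mean(long-range reproductions) -
#' mean(short-range reproductions)` is reported.
#'
#' @param table A `response_table` with both ranges present at 11 and 13 m.
#' @return Tibble `sample_distance_m, mean_short_m, mean_long_m,
#'   difference_m`.
#' @export
overlapping_samples_comparison <- function(table) {
  stopifnot(is.data.frame(table))
  out <- lapply(c(11, 13), function(d) {
    sub <- table[table$sample_distance_m == d, ]
    m_short <- sub$reproduced_distance_m[sub$range_label == "short"]
    m_long <- sub$reproduced_distance_m[sub$range_label == "long"]
    if (length(m_short) == 0 || length(m_long) == 0) {
      stop("distance ", d, " m missing from one of the ranges")
    }
    tibble::tibble(sample_distance_m = d,
                   mean_short_m = mean(m_short),
                   mean_long_m = mean(m_long),
                   difference_m = mean(m_long) - mean(m_short))
  })
  dplyr::bind_rows(out)
}

#' Per-distance mean differences between two conditions
#'
#' For every (range, distance) cell present in both tables, the difference
#' of mean reproduced distances `mean(a) - mean(b)`. Used to contrast the
#' cued and uncued interleaved conditions (and the blocked condition), whose
#' characteristic signature is overshoot in the short range and undershoot
#' in the long range when the ranges are separated by time or cue.
#'
#' @param table_a,table_b `response_table`s covering the same distances.
#' @return Tibble `range_label, sample_distance_m, mean_a, mean_b,
#'   difference_m`.
#' @export
condition_difference <- function(table_a, table_b) {
  summarize_means <- function(tab) {
    tab |>
      dplyr::group_by(range_label, sample_distance_m) |>
      dplyr::summarise(mean_repro_m = mean(reproduced_distance_m),
                       .groups = "drop")
  }
  a <- summarize_means(table_a)
  b <- summarize_means(table_b)
  merged <- dplyr::inner_join(a, b, by = c("range_label",
                                           "sample_distance_m"),
                              suffix = c("_a", "_b"))
  tibble::tibble(
    range_label = merged$range_label,
    sample_distance_m = merged$sample_distance_m,
    mean_a = merged$mean_repro_m_a,
    mean_b = merged$mean_repro_m_b,
    difference_m = merged$mean_repro_m_a - merged$mean_repro_m_b
  ) |>
    dplyr::arrange(range_label, sample_distance_m)
}
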