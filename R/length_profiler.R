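# Read-length distribution over the ultra-short 8-30 nt window and
# per-length dominant-sequence statistics.

#' Length histogram of a collapsed library
#'
#' Tabulates reads, RPM and distinct sequences per insert length over the
#' full 8-30 nt window (lengths with no reads are reported with zeros).
#'
#' @param uniques A collapsed, RPM-normalized library: a data frame with
#'   columns `sequence`, `count` and optionally `rpm` (see
#'   [collapse_reads()] and [rpm_normalize()]).
#' @param min_len,max_len Profiled window bounds (defaults 8 and 30).
#' @return A tibble of class `dorna_length_profile` with columns `length`,
#'   `reads`, `rpm` and `n_unique`, and a `total_reads` attribute.
#' @export
#' @examples
#' u <- rpm_normalize(collapse_reads(c("GACTCTTAGCGG", "GACTCTTAGCGG")))
#' length_histogram(u)
length_histogram <- function(uniques, min_len = 8L, max_len = 30L) {
  uniques <- as_tibble(uniques)
  if (!"rpm" %in% names(uniques)) uniques$rpm <- NA_real_
  len <- nchar(uniques$sequence)
  if (any(len < min_len | len > max_len)) {
    abort(sprintf("sequences outside the %d-%d nt window", min_len, max_len),
          class = "dorna_error_input")
  }
  prof <- uniques |>
    dplyr::mutate(length = nchar(.data$sequence)) |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(
      reads = sum(.data$count),
      rpm = sum(.data$rpm),
      n_unique = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(
      length = seq.int(min_len, max_len),
      fill = list(reads = 0L, rpm = 0, n_unique = 0L)
    ) |>
    dplyr::arrange(.data$length)
  structure(
    prof,
    total_reads = sum(prof$reads),
    class = c("dorna_length_profile", class(prof))
  )
}

#' Fraction of reads at selected lengths
#'
#' The share of all profiled reads falling at the requested insert
#' lengths, e.g. the 12+13 nt doRNA window.
#'
#' @param profile A [length_histogram()] result.
#' @param lengths Integer lengths inside the profiled window; the empty
#'   set yields 0.
#' @return A single number in \[0, 1\].
#' @export
window_fraction <- function(profile, lengths = c(12L, 13L)) {
  total <- attr(profile, "total_reads") %||% sum(profile$reads)
  if (total == 0) {
    abort("empty profile: no reads", class = "dorna_error_input")
  }
  if (length(lengths) == 0L) return(0)
  if (!all(lengths %in% profile$length)) {
    abort("requested lengths outside the profiled window",
          class = "dorna_error_input")
  }
  sum(profile$reads[profile$length %in% lengths]) / total
}

#' Most abundant sequences of one length class
#'
#' Ranks the unique sequences of a given insert length by count
#' (lexicographic tie-break) and reports each one's fraction of that
#' length class.
#'
#' @param uniques A collapsed library (columns `sequence`, `count`).
#' @param length Insert length to interrogate (8-30).
#' @param k Number of top records to return.
#' @return A tibble with columns `length`, `rank`, `sequence`, `count` and
#'   `fraction`; empty when no reads have that length.
#' @export
dominant_sequences <- function(uniques, length, k = 1L) {
  stopifnot(length >= 8L, length <= 30L, k >= 1L)
  uniques <- as_tibble(uniques)
  cls <- uniques[nchar(uniques$sequence) == length, , drop = FALSE]
  if (nrow(cls) == 0L) {
    return(tibble(length = integer(), rank = integer(), sequence = character(),
                  count = integer(), fraction = double()))
  }
  cls |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence) |>
    head(k) |>
    dplyr::transmute(
      length = !!as.integer(length),
      rank = dplyr::row_number(),
      sequence = .data$sequence,
      count = .data$count,
      fraction = .data$count / sum(cls$count)
    )
}

#' Combined share of the top sequence of each of several length classes
#'
#' Computes, for the given lengths, the summed count of each class's single
#' most abundant sequence, as a fraction of (a) the union of those length
#' classes and (b) the whole profiled library. This is the "two sequences"
#' statistic for the 12+13 nt doRNA window, with both candidate
#' denominators reported because either reading is defensible.
#'
#' @param uniques A collapsed library.
#' @param lengths Length classes whose top-1 sequences are combined.
#' @return A one-row tibble with columns `top_count`,
#'   `fraction_of_classes` and `fraction_of_library`.
#' @export
combined_top_fraction <- function(uniques, lengths = c(12L, 13L)) {
  uniques <- as_tibble(uniques)
  tops <- purrr::map_dfr(lengths, function(l) dominant_sequences(uniques, l, 1L))
  class_total <- sum(uniques$count[nchar(uniques$sequence) %in% lengths])
  lib_total <- sum(uniques$count)
  tibble(
    top_count = sum(tops$count),
    fraction_of_classes = if (class_total > 0) sum(tops$count) / class_total else NA_real_,
    fraction_of_library = if (lib_total > 0) sum(tops$count) / lib_total else NA_real_
  )
}
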