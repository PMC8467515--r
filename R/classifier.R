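# doRNA family classification. The family is defined by sequence identity
# to reference windows that all end at the invariant G13 of the 5.8S rRNA:
# the 12-nt core (doRNA), the 13-nt +1 variant (C-doRNA in human/mouse),
# and single-nucleotide 5' extensions reaching into ITS1 up to a maximum
# total length (default 18 nt). Nothing extended 3' of position 13 is ever
# a family member.

#' Derive the doRNA anchor from a 5.8S-bearing reference record
#'
#' Extracts the 12-nt core (5.8S positions 2..13), the 13-nt +1 variant
#' (positions 1..13) and the 5'-extension ladder windows ending at 5.8S
#' position 13, and validates the biological signature of the anchor: the
#' base at position 13 must be G and the base at position 14 must be U/T
#' (the 2'-O-methylated U14 adjacent to the cleavage site).
#'
#' @param refs A [reference_feature_set()].
#' @param accession Record to anchor on; defaults to the only record.
#' @param max_total_length Longest family member (default 18 nt, i.e. up
#'   to 6 extra 5' bases, reaching the 3' end of ITS1).
#' @return An object of class `dorna_anchor` with elements
#'   `core_sequence`, `c_variant_sequence`, `five_prime_base`,
#'   `family_windows` (named by 5' offset `0`, `-1`, ... ),
#'   `three_prime_ref_pos` (0-based coordinate of 5.8S position 13),
#'   `upstream_context` and `methylation_note`.
#' @export
#' @examples
#' derive_anchor(synthetic_reference("human"))
derive_anchor <- function(refs, accession = NULL, max_total_length = 18L) {
  stopifnot(inherits(refs, "dorna_refset"))
  if (is.null(accession)) {
    if (nrow(refs$records) != 1L) {
      abort("`accession` must be given for multi-record references",
            class = "dorna_error_input")
    }
    accession <- refs$records$accession[1]
  }
  rec <- refs$records[refs$records$accession == accession, ]
  if (nrow(rec) == 0L) {
    abort(sprintf("no record '%s'", accession), class = "dorna_error_input")
  }
  f58 <- refs$features[refs$features$accession == accession &
                         refs$features$name == "5.8S", ]
  if (nrow(f58) == 0L) {
    abort(sprintf("record '%s' has no 5.8S feature", accession),
          class = "dorna_error_no_58s")
  }
  if (max_total_length < 13L) {
    abort("`max_total_length` must be >= 13", class = "dorna_error_config")
  }
  seq <- rec$sequence
  s <- f58$start  # 0-based start of 5.8S => 1-based position 1 is s + 1
  max_ext <- max_total_length - 12L  # extra 5' bases beyond the core
  if (s < max_ext - 1L) {
    abort("insufficient upstream (ITS1) context for the extension ladder",
          class = "dorna_error_insufficient_upstream")
  }
  if (f58$end - s < 14L) {
    abort("5.8S feature shorter than 14 nt", class = "dorna_error_anchor_validation")
  }
  pos <- function(p) substr(seq, s + p, s + p)  # 1-based 5.8S position
  if (pos(13L) != "G") {
    abort("anchor validation failed: 5.8S position 13 is not G",
          class = "dorna_error_anchor_validation")
  }
  if (pos(14L) != "T") {
    abort("anchor validation failed: 5.8S position 14 is not U/T",
          class = "dorna_error_anchor_validation")
  }
  three_prime_ref_pos <- s + 12L  # 0-based coordinate of position 13
  # Window with k extra 5' bases beyond the 12-nt core (k = 0 is the core,
  # which spans 1-based string positions s+2 .. s+13, i.e. 5.8S 2..13).
  window <- function(k) substr(seq, s + 2L - k, s + 13L)
  offsets <- 0L:(-max_ext)
  windows <- setNames(
    vapply(0L:max_ext, window, character(1)),
    as.character(offsets)
  )
  structure(
    list(
      accession = accession,
      core_sequence = windows[["0"]],
      c_variant_sequence = windows[["-1"]],
      five_prime_base = substr(windows[["-1"]], 1L, 1L),
      family_windows = windows,
      three_prime_ref_pos = three_prime_ref_pos,
      max_total_length = as.integer(max_total_length),
      upstream_context = substr(seq, s - max_ext + 1L, s),
      methylation_note = "5.8S position 14 is a 2'-O-methylated U"
    ),
    class = "dorna_anchor"
  )
}

#' @export
print.dorna_anchor <- function(x, ...) {
  cat("<dorna_anchor> on ", x$accession, "\n",
      "  core (doRNA, 5.8S 2..13): ", x$core_sequence, "\n",
      "  +1 variant (1..13):       ", x$c_variant_sequence,
      " (5' base ", x$five_prime_base, ")\n",
      "  ladder up to ", x$max_total_length, " nt; ",
      x$methylation_note, "\n", sep = "")
  invisible(x)
}

#' Classify reads into the doRNA family ladder
#'
#' Assigns each sequence to exactly one of `dorna` (identical to the
#' 12-nt core), `c_dorna` (the 13-nt +1 variant; 5' C in human and mouse,
#' 5' A in fly -- see the anchor's `five_prime_base`), `extended_variant`
#' (14 nt up to the anchor's maximum length, ending exactly at 5.8S
#' position 13) or `non_dorna` (everything else, including any sequence
#' extended 3' of position 13). With `allow_mismatches = 1`, one internal
#' substitution is tolerated but the 3' terminal base must remain G.
#'
#' @param reads A data frame with a `sequence` column (e.g. a collapsed
#'   library), or a character vector of sequences, each 8-30 nt.
#' @param anchor A [derive_anchor()] object.
#' @param allow_mismatches 0 (strict, default) or 1.
#' @return The input as a tibble with added columns `category`,
#'   `five_prime_offset` (0 for doRNA, -1 for the +1 variant, -k for k-nt
#'   extensions; NA for non-family) and `mismatches`.
#' @export
#' @examples
#' anchor <- derive_anchor(synthetic_reference("human"))
#' classify_reads(c("GACTCTTAGCGG", "CGACTCTTAGCGG", "ACGTACGTACGT"), anchor)
classify_reads <- function(reads, anchor, allow_mismatches = 0L) {
  stopifnot(inherits(anchor, "dorna_anchor"),
            allow_mismatches %in% c(0L, 1L))
  if (is.character(reads)) reads <- tibble(sequence = reads)
  out <- as_tibble(reads)
  seqs <- canonicalize_seq(out$sequence)
  lens <- nchar(seqs)
  if (any(lens < 8L | lens > 30L)) {
    abort("sequences outside the 8-30 nt window", class = "dorna_error_input")
  }
  windows <- anchor$family_windows
  wlens <- nchar(windows)
  category <- rep("non_dorna", length(seqs))
  offset <- rep(NA_integer_, length(seqs))
  mism <- rep(NA_integer_, length(seqs))

  for (i in seq_along(windows)) {
    w <- windows[[i]]
    off <- as.integer(names(windows)[i])
    sel <- which(lens == wlens[i] & category == "non_dorna")
    if (length(sel) == 0L) next
    if (allow_mismatches == 0L) {
      hit <- sel[seqs[sel] == w]
      d <- rep(0L, length(hit))
    } else {
      d_all <- vapply(seqs[sel], hamming, integer(1), w, USE.NAMES = FALSE)
      keep <- d_all <= 1L & substr(seqs[sel], wlens[i], wlens[i]) == "G"
      hit <- sel[keep]
      d <- d_all[keep]
    }
    category[hit] <- dplyr::case_when(off == 0L ~ "dorna",
                                      off == -1L ~ "c_dorna",
                                      TRUE ~ "extended_variant")
    offset[hit] <- off
    mism[hit] <- d
  }
  out$category <- category
  out$five_prime_offset <- offset
  out$mismatches <- mism
  out
}

#' Tabulate the doRNA 5'-extension ladder
#'
#' Aggregates a collapsed library into one row per family offset (0 down
#' to the anchor's maximum extension), whether observed or not, plus a
#' single `non_dorna` aggregate row. Counts are conserved: the column sum
#' equals the library total.
#'
#' @param uniques A collapsed (optionally RPM-normalized) library.
#' @param anchor A [derive_anchor()] object.
#' @param allow_mismatches Passed to [classify_reads()].
#' @return A tibble of class `dorna_ladder` with columns `category`,
#'   `offset`, `length`, `sequence`, `count` and `rpm`.
#' @export
tabulate_ladder <- function(uniques, anchor, allow_mismatches = 0L) {
  uniques <- as_tibble(uniques)
  if (!"rpm" %in% names(uniques)) uniques$rpm <- NA_real_
  calls <- classify_reads(uniques, anchor, allow_mismatches)
  windows <- anchor$family_windows
  scaffold <- tibble(
    offset = as.integer(names(windows)),
    category = dplyr::case_when(
      as.integer(names(windows)) == 0L ~ "dorna",
      as.integer(names(windows)) == -1L ~ "c_dorna",
      TRUE ~ "extended_variant"
    ),
    length = nchar(unname(windows)),
    sequence = unname(windows)
  )
  fam <- calls |>
    dplyr::filter(.data$category != "non_dorna") |>
    dplyr::group_by(offset = .data$five_prime_offset) |>
    dplyr::summarise(count = sum(.data$count), rpm = sum(.data$rpm),
                     .groups = "drop")
  non <- calls |>
    dplyr::filter(.data$category == "non_dorna") |>
    dplyr::summarise(count = sum(.data$count), rpm = sum(.data$rpm))
  ladder <- scaffold |>
    dplyr::left_join(fam, by = "offset") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  rpm = ifelse(is.na(.data$rpm) & .data$count == 0L,
                               0, .data$rpm)) |>
    dplyr::bind_rows(tibble(
      category = "non_dorna", offset = NA_integer_, length = NA_integer_,
      sequence = NA_character_, count = non$count,
      rpm = non$rpm
    ))
  structure(ladder,
            total_reads = sum(calls$count),
            class = c("dorna_ladder", class(ladder)))
}

#' Estimate the C-doRNA/doRNA ratio with a bootstrap confidence interval
#'
#' The point estimate is the plain count ratio. Uncertainty comes from a
#' seeded percentile bootstrap: the two counts are resampled as a binomial
#' split of their total, and the 2.5/97.5 percentiles of the resampled
#' ratios form the interval.
#'
#' @param c_count,d_count Non-negative integer read counts of the 13-nt
#'   variant and the 12-nt core; `d_count` must be >= 1.
#' @param n_bootstrap Number of bootstrap resamples (default 2000).
#' @param seed Integer seed for reproducible intervals; `NULL` uses the
#'   current RNG state.
#' @param conf_level Interval coverage (default 0.95).
#' @return An object of class `dorna_ratio`; see [tidy()] / [glance()].
#' @export
#' @examples
#' estimate_ratio(500, 100, seed = 1)
estimate_ratio <- function(c_count, d_count, n_bootstrap = 2000L,
                           seed = NULL, conf_level = 0.95) {
  if (c_count < 0 || d_count < 0) {
    abort("counts must be non-negative", class = "dorna_error_input")
  }
  if (d_count == 0) {
    abort("ratio undefined: core (doRNA) count is zero",
          class = "dorna_error_zero_denominator")
  }
  n <- c_count + d_count
  boot <- with_local_seed(seed, {
    x <- rbinom(n_bootstrap, n, c_count / n)
    x / (n - x)
  })
  ci <- unname(quantile(boot, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        na.rm = TRUE, names = FALSE))
  structure(
    list(c_count = c_count, d_count = d_count, ratio = c_count / d_count,
         ci_low = ci[1], ci_high = ci[2], n_bootstrap = n_bootstrap,
         seed = seed, conf_level = conf_level, boot = boot),
    class = "dorna_ratio"
  )
}

#' @export
print.dorna_ratio <- function(x, ...) {
  cat(sprintf(
    "<dorna_ratio> C-doRNA/doRNA = %.4g (%d/%d), %g%% CI [%.4g, %.4g], %d bootstraps\n",
    x$ratio, x$c_count, x$d_count, 100 * x$conf_level,
    x$ci_low, x$ci_high, x$n_bootstrap
  ))
  invisible(x)
}

#' Compare two C-doRNA/doRNA ratio estimates
#'
#' Bootstrap test on the difference of log ratios: both ratios are
#' resampled as in [estimate_ratio()], the percentile interval of
#' `log(ratio_a) - log(ratio_b)` is reported and a two-sided p-value is
#' obtained from the bootstrap tail probabilities (add-one corrected, so
#' the smallest attainable p is `2/(n_bootstrap + 1)`).
#'
#' @param sample_a,sample_b `dorna_ratio` objects (or lists with
#'   `c_count`/`d_count`).
#' @param n_bootstrap Number of resamples (default 2000).
#' @param seed Integer seed.
#' @param conf_level Interval coverage (default 0.95).
#' @return An object of class `dorna_ratio_comparison`.
#' @export
compare_ratios <- function(sample_a, sample_b, n_bootstrap = 2000L,
                           seed = NULL, conf_level = 0.95) {
  for (s in list(sample_a, sample_b)) {
    if (s$d_count == 0) {
      abort("ratio undefined: core (doRNA) count is zero",
            class = "dorna_error_zero_denominator")
    }
  }
  boot_one <- function(s) {
    n <- s$c_count + s$d_count
    x <- rbinom(n_bootstrap, n, s$c_count / n)
    log(x / (n - x))
  }
  delta <- with_local_seed(seed, boot_one(sample_a) - boot_one(sample_b))
  delta_ok <- delta[is.finite(delta)]
  ci <- unname(quantile(delta_ok,
                        c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                        names = FALSE))
  p <- 2 * min((sum(delta_ok <= 0) + 1) / (length(delta_ok) + 1),
               (sum(delta_ok >= 0) + 1) / (length(delta_ok) + 1))
  structure(
    list(
      log_ratio_diff = log(sample_a$ratio %||%
                             (sample_a$c_count / sample_a$d_count)) -
        log(sample_b$ratio %||% (sample_b$c_count / sample_b$d_count)),
      ci_low = ci[1], ci_high = ci[2], p_value = min(p, 1),
      n_bootstrap = n_bootstrap, seed = seed, conf_level = conf_level
    ),
    class = "dorna_ratio_comparison"
  )
}

#' @export
print.dorna_ratio_comparison <- function(x, ...) {
  cat(sprintf(
    "<dorna_ratio_comparison> log ratio difference %.4g, %g%% CI [%.4g, %.4g], p = %.3g\n",
    x$log_ratio_diff, 100 * x$conf_level, x$ci_low, x$ci_high, x$p_value
  ))
  invisible(x)
}

#' Compare per-replicate ratios with a two-sample t-test
#'
#' Plain plumbing for replicate-level comparisons (e.g. independent
#' cultures): a Welch t-test on per-replicate ratio values.
#'
#' @param ratios_a,ratios_b Numeric vectors of per-replicate ratios.
#' @param ... Passed to [stats::t.test()].
#' @return A one-row tibble (estimate difference, statistic, p.value,
#'   conf.low, conf.high).
#' @export
compare_ratio_replicates <- function(ratios_a, ratios_b, ...) {
  tt <- t.test(ratios_a, ratios_b, ...)
  tibble(
    estimate_a = mean(ratios_a), estimate_b = mean(ratios_b),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
    method = tt$method
  )
}
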