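# End-to-end orchestration: trim -> collapse -> RPM -> profile -> map ->
# classify -> ratio, with a reproducible run manifest.

#' Run the full doRNA discovery pipeline
#'
#' Executes every stage on a FASTQ file or an in-memory read tibble and
#' returns a report (length profile, dominance and window statistics,
#' ladder table, ratio estimate, anchor mapping) together with a manifest
#' recording the configuration, seeds, package version and the checksums
#' of any files written. Reruns with the same inputs and seed are
#' deterministic.
#'
#' @param reads A tibble with a `sequence` column, or `NULL` if `fastq`
#'   is given.
#' @param fastq Optional path to a FASTQ file.
#' @param reference A [reference_feature_set()]; default human synthetic
#'   record.
#' @param adapter3 3' adapter for trimming.
#' @param min_insert,max_insert Insert window (defaults 8, 30).
#' @param dominance_lengths Length classes for the dominance table.
#' @param n_bootstrap,seed Bootstrap settings for the ratio estimate.
#' @param allow_mismatches Passed to the classifier.
#' @param out_dir Optional directory; when given, TSV/JSON outputs are
#'   written there and checksummed into the manifest.
#' @return A list of class `dorna_run` with elements `report` and
#'   `manifest`.
#' @export
#' @examples
#' sim <- simulate_library(library_sim_config("human", n_reads = 2000, seed = 1))
#' run <- run_pipeline(sim$reads, seed = 1)
#' tidy(run$report$ratio)
run_pipeline <- function(reads = NULL, fastq = NULL,
                         reference = synthetic_reference("human"),
                         adapter3 = default_adapter3(),
                         min_insert = 8L, max_insert = 30L,
                         dominance_lengths = c(12L, 13L),
                         n_bootstrap = 2000L, seed = 1L,
                         allow_mismatches = 0L, out_dir = NULL) {
  log_lines <- character()
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }

  if (is.null(reads) && is.null(fastq)) {
    abort("supply `reads` or `fastq`", class = "dorna_error_input")
  }
  if (!is.null(fastq)) {
    if (!file.exists(fastq)) {
      abort(sprintf("missing input: %s", fastq), class = "dorna_error_input")
    }
    reads <- read_fastq(fastq)
    note("load", sprintf("%d reads from %s", nrow(reads), fastq))
  } else {
    reads <- if (is.character(reads)) tibble(sequence = reads) else as_tibble(reads)
    note("load", sprintf("%d in-memory reads", nrow(reads)))
  }

  empty_report <- function() {
    list(uniques = tibble(sequence = character(), count = integer(),
                          rpm = double()),
         profile = NULL, window_fraction_1213 = NA_real_,
         dominance = NULL, combined_top = NULL, ladder = NULL, ratio = NULL,
         anchor = NULL, anchor_hits = NULL, trim_summary = NULL)
  }

  if (nrow(reads) == 0L) {
    warn("empty input; returning an empty report")
    note("trim", "no reads")
    report <- empty_report()
  } else {
    trimmed <- trim_adapters(reads, adapter3 = adapter3,
                             min_insert = min_insert, max_insert = max_insert)
    trim_summary <- dplyr::count(trimmed, .data$status, name = "reads")
    note("trim", sprintf("%d/%d reads kept",
                         sum(trimmed$status == "kept"), nrow(trimmed)))
    kept <- trimmed[trimmed$status == "kept", ]
    if (nrow(kept) == 0L) {
      warn("no reads survived trimming; returning an empty report")
      report <- empty_report()
      report$trim_summary <- trim_summary
    } else {
      uniques <- rpm_normalize(collapse_reads(kept, column = "insert"))
      note("collapse", sprintf("%d unique sequences", nrow(uniques)))
      profile <- length_histogram(uniques, min_insert, max_insert)
      wf <- window_fraction(profile, c(12L, 13L))
      dominance <- purrr::map_dfr(dominance_lengths,
                                  function(l) dominant_sequences(uniques, l, 3L))
      combined_top <- combined_top_fraction(uniques, dominance_lengths)
      note("profile", sprintf("12+13 nt fraction %.3f", wf))

      anchor <- derive_anchor(reference)
      idx <- build_reference_index(reference)
      anchor_hits <- annotate_hit_position(
        dplyr::bind_rows(map_query(anchor$core_sequence, idx),
                         map_query(anchor$c_variant_sequence, idx)),
        reference
      )
      ladder <- tabulate_ladder(uniques, anchor, allow_mismatches)
      d_count <- ladder$count[!is.na(ladder$offset) & ladder$offset == 0L]
      c_count <- ladder$count[!is.na(ladder$offset) & ladder$offset == -1L]
      ratio <- if (d_count >= 1L) {
        estimate_ratio(c_count, d_count, n_bootstrap = n_bootstrap, seed = seed)
      } else {
        note("ratio", "core count is zero; ratio not estimated")
        NULL
      }
      if (!is.null(ratio)) {
        note("ratio", sprintf("C-doRNA/doRNA = %.3f [%.3f, %.3f]",
                              ratio$ratio, ratio$ci_low, ratio$ci_high))
      }
      report <- list(uniques = uniques, profile = profile,
                     window_fraction_1213 = wf, dominance = dominance,
                     combined_top = combined_top, ladder = ladder,
                     ratio = ratio, anchor = anchor,
                     anchor_hits = anchor_hits, trim_summary = trim_summary)
    }
  }

  outputs <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv <- function(df, name) {
      if (is.null(df)) return(NULL)
      path <- file.path(out_dir, name)
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, path)
    }
    write_tsv(report$uniques, "collapsed.tsv")
    write_tsv(report$profile, "length_profile.tsv")
    write_tsv(report$dominance, "dominance.tsv")
    if (!is.null(report$ladder)) {
      write_tsv(dplyr::select(report$ladder, !dplyr::any_of("feature_overlap")),
                "ladder.tsv")
    }
    if (!is.null(report$ratio)) {
      path <- file.path(out_dir, "ratio.json")
      jsonlite::write_json(tidy(report$ratio), path, auto_unbox = TRUE,
                           digits = NA)
      outputs <- c(outputs, path)
    }
    note("write", sprintf("%d files under %s", length(outputs), out_dir))
  }

  manifest <- list(
    tool = "dornaseq",
    version = as.character(utils::packageVersion("dornaseq")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = list(adapter3 = adapter3, min_insert = min_insert,
                  max_insert = max_insert, n_bootstrap = n_bootstrap,
                  seed = seed, allow_mismatches = allow_mismatches,
                  reference = reference$records$accession),
    inputs = if (!is.null(fastq)) {
      list(fastq = fastq, md5 = unname(tools::md5sum(fastq)))
    } else {
      list(n_reads = nrow(reads))
    },
    outputs = if (length(outputs)) {
      tibble(path = outputs, md5 = unname(tools::md5sum(outputs)))
    } else NULL,
    log = log_lines
  )
  if (!is.null(out_dir)) {
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  structure(list(report = report, manifest = manifest), class = "dorna_run")
}

#' @export
print.dorna_run <- function(x, ...) {
  cat("<dorna_run>\n")
  for (l in x$manifest$log) cat("  ", l, "\n", sep = "")
  invisible(x)
}
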