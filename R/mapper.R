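# Exact / near-exact exhaustive mapping of ultra-short (8-30 nt) queries.
# Seeded aligners behave unreliably for 12-mers, so hits are enumerated by
# ungapped scanning of every offset on both strands; the published
# evidence for doRNAs is 100%-identity, 100%-coverage matches, which this
# reproduces exactly.

#' Build an index over a reference set for ultra-short queries
#'
#' Precomputes byte representations of every record so that
#' [map_query()] can enumerate all ungapped occurrences of a query (both
#' strands) with at most a small number of mismatches.
#'
#' @param refs A [reference_feature_set()].
#' @param min_len,max_len Accepted query length bounds (defaults 8, 30).
#' @return An object of class `dorna_ref_index`.
#' @export
build_reference_index <- function(refs, min_len = 8L, max_len = 30L) {
  stopifnot(inherits(refs, "dorna_refset"))
  if (nrow(refs$records) == 0L) {
    abort("empty reference set", class = "dorna_error_input")
  }
  structure(
    list(
      refs = refs,
      raw = lapply(setNames(refs$records$sequence, refs$records$accession),
                   charToRaw),
      min_len = as.integer(min_len),
      max_len = as.integer(max_len)
    ),
    class = "dorna_ref_index"
  )
}

#' @export
print.dorna_ref_index <- function(x, ...) {
  cat("<dorna_ref_index> ", length(x$raw), " record(s), query length ",
      x$min_len, "-", x$max_len, " nt\n", sep = "")
  invisible(x)
}

# All 1-based start offsets of `q_raw` within `ref_raw` with <= max_mm
# mismatches; N never matches. Vectorized over offsets (one pass per query
# base), so runtime is O(n * m) with small constants.
scan_offsets <- function(ref_raw, q_raw, max_mm) {
  n <- length(ref_raw)
  m <- length(q_raw)
  if (m > n) return(list(starts = integer(), mm = integer()))
  k <- n - m + 1L
  n_byte <- charToRaw("N")
  mm <- integer(k)
  for (j in seq_len(m)) {
    seg <- ref_raw[j:(j + k - 1L)]
    mm <- mm + as.integer(seg != q_raw[j] | seg == n_byte | q_raw[j] == n_byte)
  }
  keep <- which(mm <= max_mm)
  list(starts = keep, mm = mm[keep])
}

#' Map an ultra-short query against an indexed reference
#'
#' Enumerates every ungapped occurrence of the query on both strands of
#' every record with at most `max_mismatches` substitutions. A minus-strand
#' hit means the reverse complement of the query occurs at the reported
#' forward-strand interval. Hits are annotated with the overlapping
#' reference features and ordered by accession, start, strand.
#'
#' @param query A nucleotide string with length within the index bounds.
#' @param index A [build_reference_index()] object.
#' @param max_mismatches Maximum substitutions tolerated (default 0).
#' @return A tibble with columns `query`, `accession`, `start`, `end`
#'   (0-based half-open), `strand`, `mismatches`, `identity_pct`,
#'   `query_coverage_pct` and `feature_overlap` (list column of feature
#'   names).
#' @export
#' @examples
#' idx <- build_reference_index(synthetic_reference("human"))
#' map_query("GACTCTTAGCGG", idx)
map_query <- function(query, index, max_mismatches = 0L) {
  stopifnot(inherits(index, "dorna_ref_index"))
  query <- canonicalize_seq(query, what = "query")
  m <- nchar(query)
  if (m < index$min_len || m > index$max_len) {
    abort(sprintf("query length %d outside [%d, %d]",
                  m, index$min_len, index$max_len),
          class = "dorna_error_input")
  }
  q_fwd <- charToRaw(query)
  q_rev <- charToRaw(revcomp(query))
  hits <- purrr::imap_dfr(index$raw, function(ref_raw, acc) {
    fwd <- scan_offsets(ref_raw, q_fwd, max_mismatches)
    rev <- scan_offsets(ref_raw, q_rev, max_mismatches)
    tibble(
      accession = acc,
      start = c(fwd$starts, rev$starts) - 1L,
      mismatches = c(fwd$mm, rev$mm),
      strand = rep(c("+", "-"), c(length(fwd$starts), length(rev$starts)))
    )
  })
  if (nrow(hits) == 0L) {
    return(tibble(
      query = character(), accession = character(), start = integer(),
      end = integer(), strand = character(), mismatches = integer(),
      identity_pct = double(), query_coverage_pct = double(),
      feature_overlap = list()
    ))
  }
  feats <- index$refs$features
  hits |>
    dplyr::mutate(
      query = query,
      end = .data$start + m,
      identity_pct = 100 * (m - .data$mismatches) / m,
      query_coverage_pct = 100,
      feature_overlap = purrr::map2(.data$accession, .data$start, function(a, s) {
        f <- feats[feats$accession == a & feats$start < s + m & feats$end > s, ]
        f$name
      })
    ) |>
    dplyr::arrange(.data$accession, .data$start, .data$strand) |>
    dplyr::select("query", "accession", "start", "end", "strand",
                  "mismatches", "identity_pct", "query_coverage_pct",
                  "feature_overlap")
}

#' Annotate hits with 5.8S-relative coordinates
#'
#' Adds signed coordinates relative to the 5' end of the 5.8S feature
#' (position 1 is the first 5.8S base; upstream ITS1 positions are
#' negative, with no position 0) and a human-readable label such as
#' `"5.8S:1..13"` or the ladder coordinate `"-5..13"` for hits straddling
#' the ITS1/5.8S boundary. Records lacking a 5.8S feature fall back to raw
#' 1-based coordinates.
#'
#' @param hits A [map_query()] result.
#' @param refs The [reference_feature_set()] the hits were mapped to.
#' @return `hits` with added columns `rel_start`, `rel_end` and
#'   `position_label`.
#' @export
annotate_hit_position <- function(hits, refs) {
  stopifnot(inherits(refs, "dorna_refset"))
  f58 <- refs$features[refs$features$name == "5.8S", ]
  rel <- function(pos0, acc) {
    # signed 1-based coordinate of a 0-based position, skipping 0
    i <- match(acc, f58$accession)
    if (is.na(i)) return(NA_integer_)
    d <- pos0 - f58$start[i]
    if (d >= 0L) d + 1L else d
  }
  hits <- as_tibble(hits)
  hits$rel_start <- purrr::map2_int(hits$start, hits$accession, rel)
  hits$rel_end <- purrr::map2_int(hits$end - 1L, hits$accession, rel)
  hits$position_label <- purrr::pmap_chr(
    list(hits$rel_start, hits$rel_end, hits$start, hits$end, hits$accession),
    function(rs, re, s, e, acc) {
      if (is.na(rs)) return(sprintf("%s:%d..%d", acc, s + 1L, e))
      if (rs >= 1L) sprintf("5.8S:%d..%d", rs, re)
      else if (re >= 1L) sprintf("%d..%d", rs, re)
      else sprintf("%s:%d..%d", acc, s + 1L, e)
    }
  )
  hits
}
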