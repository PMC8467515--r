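# Reading, trimming, collapsing and contaminant screening of ultra-short
# sRNA-seq reads. All sequences are canonicalized to DNA letters (U -> T)
# on ingest.

#' Read a FASTQ file into a tibble
#'
#' Reads a (optionally gzipped) 4-line FASTQ file and returns one row per
#' read. Sequences are canonicalized to DNA letters (U is converted to T,
#' case folded to upper).
#'
#' @param path Path to a FASTQ file (plain or gzipped).
#' @return A tibble with columns `id`, `sequence` and `quality`.
#' @export
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "GACTCTTAGCGG", "+", "IIIIIIIIIIII"), fq)
#' read_fastq(fq)
read_fastq <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    id = names(x),
    sequence = unname(canonicalize_seq(as.character(x))),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  tibble(id = names(x), sequence = unname(canonicalize_seq(as.character(x))))
}

#' Write reads to FASTQ
#'
#' @param reads A data frame with columns `id`, `sequence` and optionally
#'   `quality` (defaults to the maximum Phred+33 score "I").
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  qual <- if ("quality" %in% names(reads)) reads$quality else
    strrep("I", nchar(reads$sequence))
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$id
  Biostrings::writeXStringSet(
    seqs, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Write collapsed unique reads to FASTA
#'
#' Headers follow the widespread collapsed-read convention
#' `>seq<rank>_x<count>`.
#'
#' @param uniques A data frame with columns `sequence` and `count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(uniques, path) {
  seqs <- Biostrings::DNAStringSet(uniques$sequence)
  names(seqs) <- sprintf("seq%d_x%d", seq_len(nrow(uniques)), uniques$count)
  Biostrings::writeXStringSet(seqs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Trim 3' adapters into the ultra-short insert window
#'
#' Locates the 3' sequencing adapter in each read by seed-and-extend: the
#' first `min_overlap` bases of the adapter must occur exactly; the leftmost
#' seed whose full-adapter extension stays at or below `max_mismatch_rate`
#' mismatches over the aligned span wins. The insert is the read prefix
#' before that position. Inserts outside `[min_insert, max_insert]` or with
#' more than `max_n` ambiguous bases are rejected with a reason.
#'
#' @param reads A data frame with a `sequence` column (a bare character
#'   vector is also accepted); other columns are carried through.
#' @param adapter3 The 3' adapter sequence; must be at least `min_overlap`
#'   long.
#' @param min_overlap Exact adapter prefix length required (>= 5).
#' @param max_mismatch_rate Maximum mismatch fraction over the aligned
#'   adapter span beyond the seed.
#' @param min_insert,max_insert Accepted insert length window (defaults 8
#'   and 30 nt).
#' @param max_n Maximum number of N bases tolerated in a kept insert.
#' @return The input tibble with added columns `insert` (NA when rejected),
#'   `insert_length` and `status` (one of `"kept"`, `"no_adapter"`,
#'   `"length_out_of_window"`, `"too_many_N"`).
#' @export
#' @examples
#' trim_adapters(
#'   tibble::tibble(sequence = paste0("GACTCTTAGCGG", default_adapter3())),
#'   adapter3 = default_adapter3()
#' )
trim_adapters <- function(reads, adapter3 = default_adapter3(),
                          min_overlap = 5L, max_mismatch_rate = 0.1,
                          min_insert = 8L, max_insert = 30L, max_n = 1L) {
  if (is.character(reads)) reads <- tibble(sequence = reads)
  stopifnot("sequence" %in% names(reads))
  if (min_overlap < 5L) {
    abort("`min_overlap` must be >= 5", class = "dorna_error_config")
  }
  if (min_insert < 0L || min_insert > max_insert) {
    abort("need 0 <= min_insert <= max_insert", class = "dorna_error_config")
  }
  adapter3 <- canonicalize_seq(adapter3, what = "adapter3")
  if (nchar(adapter3) < min_overlap) {
    abort("`adapter3` is shorter than `min_overlap`",
          class = "dorna_error_config")
  }
  seqs <- canonicalize_seq(reads$sequence)
  if (any(nchar(seqs) == 0L)) {
    abort("empty read sequence", class = "dorna_error_input")
  }

  # Work on distinct sequences only; ultra-short libraries are highly
  # redundant, so this is the difference between O(reads) and O(uniques).
  distinct_seqs <- unique(seqs)
  ins_len <- vapply(distinct_seqs, locate_adapter,
                    integer(1), adapter3, min_overlap, max_mismatch_rate,
                    USE.NAMES = FALSE)
  insert <- ifelse(ins_len >= 0L, substr(distinct_seqs, 1L, ins_len), NA)
  n_count <- ifelse(is.na(insert), NA_integer_,
                    nchar(insert) - nchar(gsub("N", "", insert)))
  status <- dplyr::case_when(
    ins_len < 0L ~ "no_adapter",
    ins_len < min_insert | ins_len > max_insert ~ "length_out_of_window",
    n_count > max_n ~ "too_many_N",
    TRUE ~ "kept"
  )
  insert[status != "kept"] <- NA

  idx <- match(seqs, distinct_seqs)
  out <- as_tibble(reads)
  out$sequence <- seqs
  out$insert <- insert[idx]
  out$insert_length <- ifelse(ins_len[idx] >= 0L, ins_len[idx], NA_integer_)
  out$status <- status[idx]
  out
}

# 0-based... actually returns the insert length (bases before the adapter)
# or -1L when no acceptable adapter occurrence exists.
locate_adapter <- function(seq, adapter, min_overlap, max_mismatch_rate) {
  seed <- substr(adapter, 1L, min_overlap)
  n <- nchar(seq)
  hits <- gregexpr(seed, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(-1L)
  for (s in as.integer(hits)) {
    span <- min(nchar(adapter), n - s + 1L)
    mm <- hamming(substr(seq, s, s + span - 1L), substr(adapter, 1L, span))
    if (mm <= max_mismatch_rate * span) return(s - 1L)
  }
  -1L
}

#' Default 3' adapter
#'
#' The classic small-RNA TruSeq 3' adapter, used as an overridable default
#' by the trimmer and simulator.
#'
#' @return A character scalar.
#' @export
default_adapter3 <- function() "TGGAATTCTCGGGTGCCAAGG"

#' Collapse reads to unique sequences
#'
#' Reads identical in both length and sequence are collapsed into a single
#' record carrying the read count. Ordering is deterministic: decreasing
#' count, then lexicographic sequence.
#'
#' @param reads A data frame with a `sequence` column (e.g. the kept rows
#'   of [trim_adapters()], using the `insert` column), or a character
#'   vector of sequences.
#' @param column Which column holds the sequence to collapse (default
#'   `"sequence"`).
#' @return A tibble with columns `sequence` and `count`; the sum of
#'   `count` equals the number of input reads.
#' @export
#' @examples
#' collapse_reads(c("AAA", "AAA", "CCC"))
collapse_reads <- function(reads, column = "sequence") {
  seqs <- if (is.character(reads)) reads else reads[[column]]
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0L) {
    return(tibble(sequence = character(), count = integer()))
  }
  tibble(sequence = canonicalize_seq(seqs)) |>
    dplyr::count(.data$sequence, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
}

#' Normalize unique-read counts to reads per million
#'
#' @param uniques A data frame with columns `sequence` and `count`.
#' @param total Library size used as the RPM denominator; defaults to the
#'   sum of `count` (in which case the RPM column sums to exactly 1e6).
#' @return `uniques` with an added `rpm` column.
#' @export
rpm_normalize <- function(uniques, total = sum(uniques$count)) {
  assert_scalar_number(total, "total", positive = TRUE)
  if (total < sum(uniques$count)) {
    abort("`total` is smaller than the sum of counts",
          class = "dorna_error_input")
  }
  dplyr::mutate(as_tibble(uniques), rpm = .data$count / total * 1e6)
}

#' Screen a query sequence against a contaminant set
#'
#' Exact substring search of the query (and its reverse complement) in a
#' set of named vector/adapter/linker/primer sequences, T/U-normalized.
#' An empty result means the query is clean.
#'
#' @param query A nucleotide string of at least 8 nt.
#' @param contaminants A data frame with columns `name` and `sequence`;
#'   defaults to [default_contaminants()].
#' @return A tibble with columns `name`, `offset` (0-based start of the
#'   query occurrence within the contaminant) and `strand`.
#' @export
#' @examples
#' screen_contaminants("GACTCTTAGCGG")
screen_contaminants <- function(query, contaminants = default_contaminants()) {
  query <- canonicalize_seq(query, what = "query")
  if (nchar(query) < 8L) {
    abort("`query` must be at least 8 nt for a reliable screen",
          class = "dorna_error_input")
  }
  stopifnot(all(c("name", "sequence") %in% names(contaminants)))
  subject <- canonicalize_seq(contaminants$sequence, what = "contaminant")
  one_strand <- function(q, strand) {
    purrr::map2_dfr(contaminants$name, subject, function(nm, s) {
      hits <- gregexpr(q, s, fixed = TRUE)[[1]]
      if (hits[1] == -1L) return(NULL)
      tibble(name = nm, offset = as.integer(hits) - 1L, strand = strand)
    })
  }
  out <- dplyr::bind_rows(
    one_strand(query, "+"),
    one_strand(revcomp(query), "-")
  )
  if (nrow(out) == 0L) {
    return(tibble(name = character(), offset = integer(), strand = character()))
  }
  dplyr::arrange(out, .data$name, .data$offset)
}

#' Bundled contaminant sequences
#'
#' A small built-in set of widely used small-RNA library adapter, linker,
#' RT and PCR primer sequences for the contamination screen. Users with a
#' specific kit should supply their own set.
#'
#' @return A tibble with columns `name` and `sequence`.
#' @export
default_contaminants <- function() {
  tibble(
    name = c(
      "truseq_smallrna_3p_adapter",
      "truseq_smallrna_5p_adapter",
      "illumina_smallrna_v1_3p_adapter",
      "universal_pcr_primer",
      "smallrna_rt_primer",
      "cloning_linker_1"
    ),
    sequence = c(
      "TGGAATTCTCGGGTGCCAAGG",
      "GTTCAGAGTTCTACAGTCCGACGATC",
      "TCGTATGCCGTCTTCTGCTTG",
      "AATGATACGGCGACCACCGAGATCTACAC",
      "GCCTTGGCACCCGAGAATTCCA",
      "CTGTAGGCACCATCAAT"
    )
  )
}
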