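# Independent brute-force oracles and small fixtures, deliberately naive
# and separate from the package's implementations.

# Leftmost adapter position by scanning every offset: the seed must match
# exactly and the full-adapter extension must stay under the mismatch
# rate. Returns the insert length or -1.
oracle_find_adapter <- function(seq, adapter, min_overlap = 5L,
                                max_mismatch_rate = 0.1) {
  sc <- strsplit(seq, "")[[1]]
  ac <- strsplit(adapter, "")[[1]]
  n <- length(sc)
  for (s in seq_len(n)) {
    span <- min(length(ac), n - s + 1L)
    if (span < min_overlap) break
    seg <- sc[s:(s + span - 1L)]
    if (!all(seg[1:min_overlap] == ac[1:min_overlap])) next
    if (sum(seg != ac[1:span]) <= max_mismatch_rate * span) return(s - 1L)
  }
  -1L
}

# All occurrences of a query in a reference set by checking every offset
# on both strands, one offset at a time (byte comparison; any N counts as
# a mismatch). Returns a data frame (accession, start [0-based], strand,
# mismatches).
oracle_map <- function(refs, query, max_mm = 0L) {
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }
  n_byte <- charToRaw("N")
  acc_out <- character(); start_out <- integer()
  strand_out <- character(); mm_out <- integer()
  for (i in seq_len(nrow(refs$records))) {
    acc <- refs$records$accession[i]
    sc <- charToRaw(refs$records$sequence[i])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else rc(query)
      qc <- charToRaw(q)
      m <- length(qc)
      if (m > length(sc)) next
      any_n <- any(qc == n_byte)
      for (s in seq_len(length(sc) - m + 1L)) {
        seg <- sc[s:(s + m - 1L)]
        mm <- if (any_n) {
          sum(seg != qc | seg == n_byte | qc == n_byte)
        } else {
          sum(seg != qc | seg == n_byte)
        }
        if (mm <= max_mm) {
          acc_out <- c(acc_out, acc)
          start_out <- c(start_out, s - 1L)
          strand_out <- c(strand_out, strand)
          mm_out <- c(mm_out, mm)
        }
      }
    }
  }
  data.frame(accession = acc_out, start = start_out, strand = strand_out,
             mismatches = mm_out)
}

hamming_chr <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Tiny handmade reference: 20 nt ITS1 + a 30 nt "5.8S" whose 5' end is
# the mammalian anchor region, 0-based half-open features.
tiny_refset <- function() {
  its1 <- "AACCGGTTACAACCGGTTAC"
  s58 <- "CGACTCTTAGCGGTGGATCACTCGGCTCGT"
  reference_feature_set(
    records = tibble::tibble(accession = "TINY",
                             sequence = paste0(its1, s58)),
    features = tibble::tibble(
      accession = "TINY",
      name = c("ITS1", "5.8S"),
      start = c(0L, 20L),
      end = c(20L, 50L)
    )
  )
}

expected_ladder_from_truth <- function(truth, anchor) {
  windows <- anchor$family_windows
  vapply(windows, function(w) sum(truth$count[truth$sequence == w]),
         numeric(1))
}
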