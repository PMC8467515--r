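# Internal helpers shared across modules.

# Canonical internal alphabet is DNA letters: U -> T, lower -> upper.
canonicalize_seq <- function(x, allow_n = TRUE, what = "sequence") {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), x)
  if (any(bad)) {
    abort(
      sprintf(
        "%s contains non-nucleotide characters (first offender: '%s')",
        what, x[which(bad)[1]]
      ),
      class = "dorna_error_alphabet"
    )
  }
  x
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings; N never matches.
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  n_raw <- charToRaw("N")
  sum(ra != rb | ra == n_raw | rb == n_raw)
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name),
          class = "dorna_error_input")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0", name), class = "dorna_error_input")
  }
  invisible(x)
}

# One random DNA string per element of `lengths`.
random_dna <- function(lengths) {
  vapply(
    lengths,
    function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""),
    character(1)
  )
}
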