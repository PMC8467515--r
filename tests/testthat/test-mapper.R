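test_that("the index reports planted occurrences on both strands", {
  withr::with_seed(31, base <- rand_seq(100))
  refs <- reference_feature_set(
    tibble::tibble(accession = "R1", sequence = base),
    tibble::tibble(accession = "R1", name = "18S", start = 0L, end = 100L)
  )
  idx <- build_reference_index(refs)

  # the record's own 12-nt prefix maps at offset 0
  hit <- map_query(substr(base, 1, 12), idx)
  expect_true(any(hit$start == 0L & hit$strand == "+"))
  expect_equal(unique(unlist(hit$feature_overlap)), "18S")

  # a query planted at two offsets is returned at both
  withr::with_seed(32, probe <- rand_seq(15))
  double_seq <- paste0(probe, rand_seq(20), probe, rand_seq(20))
  refs2 <- reference_feature_set(
    tibble::tibble(accession = "R2", sequence = double_seq),
    tibble::tibble(accession = "R2", name = "18S", start = 0L,
                   end = nchar(double_seq))
  )
  got <- map_query(probe, build_reference_index(refs2))
  fwd <- got[got$strand == "+", ]
  expect_equal(fwd$start, c(0L, 35L))

  # reverse-complement query returns a minus-strand hit at the same locus
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(probe)))
  rev_hit <- map_query(rc, build_reference_index(refs2))
  expect_equal(rev_hit$start[rev_hit$strand == "-"], c(0L, 35L))
})

test_that("mapping reproduces published-style 100% identity hits", {
  refs <- synthetic_reference("human")
  idx <- build_reference_index(refs)
  anchor <- derive_anchor(refs)
  hit <- map_query(anchor$c_variant_sequence, idx)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$identity_pct, 100)
  expect_equal(hit$query_coverage_pct, 100)
  expect_true("5.8S" %in% hit$feature_overlap[[1]])

  expect_equal(nrow(map_query(strrep("ACGT", 5), idx)), 0L)

  # one planted mismatch: found only when tolerated, identity 11/12
  q <- anchor$core_sequence
  substr(q, 6, 6) <- setdiff(c("A", "C", "G", "T"), substr(q, 6, 6))[1]
  expect_equal(nrow(map_query(q, idx, max_mismatches = 0)), 0L)
  mm <- map_query(q, idx, max_mismatches = 1)
  expect_equal(mm$mismatches, 1L)
  expect_equal(mm$identity_pct, 100 * 11 / 12)

  expect_error(map_query("ACGTACG", idx), class = "dorna_error_input")
  expect_error(map_query(strrep("A", 31), idx), class = "dorna_error_input")
  expect_error(
    reference_feature_set(tibble::tibble(accession = "X", sequence = "ACGX"),
                          tibble::tibble(accession = "X", name = "18S",
                                         start = 0L, end = 4L)),
    class = "dorna_error_alphabet"
  )
})

test_that("hit sets equal brute-force scanning on random pairs", {
  withr::with_seed(77, {
    for (i in 1:100) {
      refs <- reference_feature_set(
        tibble::tibble(accession = "R", sequence = rand_seq(sample(80:200, 1))),
        tibble::tibble(accession = "R", name = "18S", start = 0L, end = 10L)
      )
      idx <- build_reference_index(refs)
      m <- sample(8:30, 1)
      query <- if (runif(1) < 0.5) {
        rand_seq(m)
      } else {
        # plant the query to guarantee hits
        s <- sample(nchar(refs$records$sequence) - m + 1, 1)
        substr(refs$records$sequence, s, s + m - 1)
      }
      for (mm in 0:1) {
        got <- map_query(query, idx, max_mismatches = mm)
        want <- oracle_map(refs, query, mm)
        got_key <- sort(paste(got$accession, got$start, got$strand,
                              got$mismatches))
        want_key <- sort(paste(want$accession, want$start, want$strand,
                               want$mismatches))
        expect_identical(got_key, want_key)
      }
    }
  })
})

test_that("mapping the reverse complement only swaps strand labels", {
  withr::with_seed(78, {
    refs <- reference_feature_set(
      tibble::tibble(accession = "R", sequence = rand_seq(300)),
      tibble::tibble(accession = "R", name = "18S", start = 0L, end = 300L)
    )
    idx <- build_reference_index(refs)
    q <- substr(refs$records$sequence, 40, 51)
    a <- map_query(q, idx, max_mismatches = 1)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
    b <- map_query(rc, idx, max_mismatches = 1)
    flip <- function(x) ifelse(x == "+", "-", "+")
    expect_equal(
      sort(paste(a$start, a$strand)),
      sort(paste(b$start, flip(b$strand)))
    )
  })
})

test_that("positions are annotated relative to the 5.8S 5' end", {
  refs <- tiny_refset()
  idx <- build_reference_index(refs)
  anchor <- derive_anchor(refs)

  h <- annotate_hit_position(map_query(anchor$c_variant_sequence, idx), refs)
  expect_equal(h$position_label, "5.8S:1..13")
  expect_equal(h$rel_start, 1L)

  # the 18-nt ladder window straddles ITS1: signed ladder coordinate
  h <- annotate_hit_position(map_query(anchor$family_windows[["-6"]], idx), refs)
  expect_equal(h$position_label, "-5..13")

  # record without a 5.8S feature falls back to raw 1-based coordinates
  refs2 <- reference_feature_set(
    tibble::tibble(accession = "R", sequence = strrep("ACGT", 20)),
    tibble::tibble(accession = "R", name = "18S", start = 0L, end = 80L)
  )
  h <- annotate_hit_position(
    map_query("ACGTACGTACGT", build_reference_index(refs2))[1, ], refs2
  )
  expect_match(h$position_label, "^R:1\\.\\.12$")
})
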