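adapter <- default_adapter3()

test_that("adapter trimming recovers planted inserts and rejects by rule", {
  insert <- "GACTCTTAGCGG"
  res <- trim_adapters(paste0(insert, adapter), adapter3 = adapter)
  expect_equal(res$status, "kept")
  expect_equal(res$insert, insert)
  expect_equal(res$insert_length,
               oracle_find_adapter(paste0(insert, adapter), adapter))

  # read that is the adapter itself: empty insert, below the window
  expect_equal(trim_adapters(adapter, adapter3 = adapter)$status,
               "length_out_of_window")

  # 31-nt insert: outside the window
  withr::with_seed(11, long31 <- rand_seq(31))
  expect_equal(trim_adapters(paste0(long31, adapter), adapter3 = adapter)$status,
               "length_out_of_window")

  # an already-trimmed insert has no adapter seed: rejected, never shortened
  res <- trim_adapters(insert, adapter3 = adapter)
  expect_equal(res$status, "no_adapter")
  expect_true(is.na(res$insert))

  # at most one N tolerated in the insert
  one_n <- trim_adapters(paste0("GACTCTTAGCNG", adapter), adapter3 = adapter)
  two_n <- trim_adapters(paste0("GACTCTTAGNNG", adapter), adapter3 = adapter)
  expect_equal(one_n$status, "kept")
  expect_equal(two_n$status, "too_many_N")
})

test_that("trimming rejects invalid configuration and inputs", {
  expect_error(trim_adapters("ACGTACGTACGT", adapter3 = "ACG"),
               class = "dorna_error_config")
  expect_error(trim_adapters("ACGT", adapter3 = adapter, min_overlap = 3),
               class = "dorna_error_config")
  expect_error(trim_adapters("", adapter3 = adapter),
               class = "dorna_error_input")
})

test_that("adapter localization agrees with the brute-force oracle", {
  withr::with_seed(101, {
    for (i in 1:300) {
      insert <- rand_seq(sample(5:32, 1))
      # sometimes corrupt the adapter copy to exercise the mismatch path
      acopy <- adapter
      if (runif(1) < 0.3) {
        p <- sample(nchar(acopy), 1)
        substr(acopy, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      read <- paste0(insert, acopy, rand_seq(sample(0:5, 1)))
      got <- trim_adapters(read, adapter3 = adapter)
      want <- oracle_find_adapter(read, adapter)
      if (want < 0) {
        expect_equal(got$status, "no_adapter")
      } else {
        expect_equal(got$insert_length, want,
                     label = sprintf("read %s", read))
      }
    }
  })
})

test_that("collapsing conserves counts with deterministic ordering", {
  expect_equal(collapse_reads(c("AAA", "AAA", "CCC")),
               tibble::tibble(sequence = c("AAA", "CCC"), count = c(2L, 1L)))
  expect_equal(nrow(collapse_reads(character())), 0L)

  # ties break lexicographically
  out <- collapse_reads(c("TTT", "AAA", "CCC", "TTT", "AAA", "CCC"))
  expect_equal(out$sequence, c("AAA", "CCC", "TTT"))

  # counts equal the simulator's planted counts at error rate 0
  cfg <- library_sim_config("human", n_reads = 10000, error_rate = 0,
                            seed = 5)
  sim <- simulate_library(cfg)
  tr <- trim_adapters(sim$reads, adapter3 = cfg$adapter3)
  u <- collapse_reads(tr[tr$status == "kept", ], column = "insert")
  expect_equal(sum(u$count), nrow(sim$reads))
  truth <- sim$truth |>
    dplyr::group_by(sequence) |>
    dplyr::summarise(count = sum(count)) |>
    dplyr::arrange(dplyr::desc(count), sequence)
  expect_equal(dplyr::arrange(u, dplyr::desc(count), sequence), truth)
})

test_that("RPM normalization satisfies its arithmetic identities", {
  u <- tibble::tibble(sequence = c("AAAAAAAA", "CCCCCCCC"),
                      count = c(5L, 999995L))
  out <- rpm_normalize(u, total = 1e6)
  expect_equal(out$rpm[1], 5)
  expect_equal(rpm_normalize(tibble::tibble(sequence = "A", count = 7L),
                             total = 7)$rpm, 1e6)
  withr::with_seed(42, {
    u <- tibble::tibble(sequence = replicate(50, rand_seq(10)),
                        count = sample(1:1000, 50))
    expect_equal(sum(rpm_normalize(u)$rpm), 1e6, tolerance = 1e-6)
  })
  expect_error(rpm_normalize(u, total = 0), class = "dorna_error_input")
  expect_error(rpm_normalize(u, total = 10), class = "dorna_error_input")
})

test_that("contaminant screen finds exactly the planted occurrences", {
  # the doRNA core is clean against the bundled vector/adapter set
  expect_equal(nrow(screen_contaminants("GACTCTTAGCGG")), 0L)

  cont <- default_contaminants()
  first12 <- substr(cont$sequence[1], 1, 12)
  hit <- screen_contaminants(first12)
  expect_true(any(hit$name == cont$name[1] & hit$offset == 0L &
                    hit$strand == "+"))

  withr::with_seed(7, {
    host <- rand_seq(60)
    probe <- rand_seq(14)
    off <- sample(0:(60 - 14), 1)
    planted <- paste0(substr(host, 1, off), probe,
                      substr(host, off + 15, 60))
    custom <- tibble::tibble(name = "vec1", sequence = planted)
    got <- screen_contaminants(probe, custom)
    expect_true(nrow(got) >= 1)
    expect_true(any(got$offset == off & got$strand == "+"))
  })

  expect_error(screen_contaminants("ACGTACG"), class = "dorna_error_input")
})

test_that("FASTQ and collapsed FASTA round-trip through files", {
  reads <- tibble::tibble(id = c("r1", "r2"),
                          sequence = c("GACTCTTAGCGG", "ACGTACGTAC"),
                          quality = c(strrep("I", 12), strrep("F", 10)))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  expect_equal(read_fastq(fq), reads)

  # U is canonicalized to T on ingest
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "GACUCUUAGCGG", "+", "IIIIIIIIIIII"), fq2)
  expect_equal(read_fastq(fq2)$sequence, "GACTCTTAGCGG")

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_collapsed_fasta(tibble::tibble(sequence = c("AAAA", "CCCC"),
                                       count = c(3L, 1L)), fa)
  out <- read_fasta(fa)
  expect_equal(out$id, c("seq1_x3", "seq2_x1"))
})
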