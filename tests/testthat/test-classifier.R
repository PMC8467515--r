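test_that("anchors are derived from the reference and validated", {
  anchor <- derive_anchor(synthetic_reference("human"))
  expect_equal(anchor$core_sequence, "GACTCTTAGCGG")
  expect_equal(anchor$c_variant_sequence, "CGACTCTTAGCGG")
  expect_equal(anchor$five_prime_base, "C")
  expect_equal(substr(anchor$core_sequence, 12, 12), "G")
  expect_equal(nchar(anchor$family_windows),
               stats::setNames(12:18, as.character(0:-6)))
  # every window is a suffix-extension of the core
  expect_true(all(vapply(anchor$family_windows, endsWith, logical(1),
                         anchor$core_sequence)))

  # mouse anchor is identical in sequence, fly differs by 2 nt and has a 5' A
  mouse <- derive_anchor(synthetic_reference("mouse"))
  expect_equal(mouse$core_sequence, anchor$core_sequence)
  fly <- derive_anchor(synthetic_reference("fly"))
  expect_equal(fly$five_prime_base, "A")
  expect_equal(hamming_chr(fly$core_sequence, anchor$core_sequence), 2L)
  expect_equal(substr(fly$core_sequence, 12, 12), "G")
})

test_that("anchor derivation fails with distinct error classes", {
  # position 13 not G
  bad13 <- reference_feature_set(
    tibble::tibble(accession = "B",
                   sequence = paste0(strrep("AC", 10), "CGACTCTTAGCGA",
                                     "T", strrep("GT", 20))),
    tibble::tibble(accession = "B", name = "5.8S", start = 20L, end = 54L)
  )
  expect_error(derive_anchor(bad13), class = "dorna_error_anchor_validation")

  # position 14 not U/T
  bad14 <- reference_feature_set(
    tibble::tibble(accession = "B",
                   sequence = paste0(strrep("AC", 10), "CGACTCTTAGCGG",
                                     "A", strrep("GT", 20))),
    tibble::tibble(accession = "B", name = "5.8S", start = 20L, end = 54L)
  )
  expect_error(derive_anchor(bad14), class = "dorna_error_anchor_validation")

  # no 5.8S feature
  no58 <- reference_feature_set(
    tibble::tibble(accession = "B", sequence = strrep("ACGT", 30)),
    tibble::tibble(accession = "B", name = "18S", start = 0L, end = 120L)
  )
  expect_error(derive_anchor(no58), class = "dorna_error_no_58s")

  # not enough ITS1 upstream for the 18-nt ladder
  shallow <- reference_feature_set(
    tibble::tibble(accession = "B",
                   sequence = paste0("ACG", "CGACTCTTAGCGG", "T",
                                     strrep("GT", 20))),
    tibble::tibble(accession = "B", name = "5.8S", start = 3L, end = 57L)
  )
  expect_error(derive_anchor(shallow),
               class = "dorna_error_insufficient_upstream")
})

test_that("reads are classified into the ladder by the 3'-anchored rules", {
  anchor <- derive_anchor(synthetic_reference("human"))
  calls <- classify_reads(
    c(anchor$core_sequence,                      # doRNA
      anchor$c_variant_sequence,                 # +1 variant
      paste0(anchor$core_sequence, "T"),         # 3' extension: excluded
      anchor$family_windows[["-6"]],             # 18-nt ladder window
      "ACGTACGTACGTACGT"),                       # unrelated
    anchor
  )
  expect_equal(calls$category,
               c("dorna", "c_dorna", "non_dorna", "extended_variant",
                 "non_dorna"))
  expect_equal(calls$five_prime_offset,
               c(0L, -1L, NA_integer_, -6L, NA_integer_))

  expect_error(classify_reads("ACGT", anchor), class = "dorna_error_input")
  expect_error(classify_reads(strrep("A", 31), anchor),
               class = "dorna_error_input")
})

test_that("one internal substitution is tolerated only with a 3' G", {
  anchor <- derive_anchor(synthetic_reference("human"))
  internal <- anchor$core_sequence
  substr(internal, 5, 5) <- "A"  # reference has C at core position 5
  three_prime <- anchor$core_sequence
  substr(three_prime, 12, 12) <- "T"

  strict <- classify_reads(c(internal, three_prime), anchor)
  expect_equal(strict$category, c("non_dorna", "non_dorna"))

  loose <- classify_reads(c(internal, three_prime), anchor,
                          allow_mismatches = 1)
  expect_equal(loose$category, c("dorna", "non_dorna"))
  expect_equal(loose$mismatches[1], 1L)
})

test_that("allowing mismatches never shrinks the family", {
  anchor <- derive_anchor(synthetic_reference("human"))
  withr::with_seed(55, {
    cfg <- library_sim_config("human", n_reads = 20000, error_rate = 0.01,
                              seed = 13)
    sim <- simulate_library(cfg)
    tr <- trim_adapters(sim$reads, adapter3 = cfg$adapter3)
    u <- collapse_reads(tr[tr$status == "kept", ], "insert")
    strict <- classify_reads(u, anchor)
    loose <- classify_reads(u, anchor, allow_mismatches = 1)
    n_fam <- function(x) sum(x$count[x$category != "non_dorna"])
    expect_gte(n_fam(loose), n_fam(strict))
    # each sequence gets exactly one category
    expect_equal(nrow(strict), nrow(u))
    expect_true(all(strict$category %in%
                      c("dorna", "c_dorna", "extended_variant", "non_dorna")))
  })
})

test_that("the ladder table recovers planted counts and conserves totals", {
  cfg <- library_sim_config("human", n_reads = 20000, error_rate = 0, seed = 8)
  sim <- simulate_library(cfg)
  tr <- trim_adapters(sim$reads, adapter3 = cfg$adapter3)
  u <- rpm_normalize(collapse_reads(tr[tr$status == "kept", ], "insert"))
  ladder <- tabulate_ladder(u, sim$anchor)

  want <- expected_ladder_from_truth(sim$truth, sim$anchor)
  fam <- ladder[!is.na(ladder$offset), ]
  expect_equal(stats::setNames(as.numeric(fam$count),
                               as.character(fam$offset)), want)
  expect_equal(sum(ladder$count), sum(u$count))
  expect_equal(attr(ladder, "total_reads"), sum(u$count))

  # a library without family reads yields all-zero family rows
  bg <- collapse_reads(c("ACGTACGTAC", "TTTTAAAACCCCG"))
  empty <- tabulate_ladder(bg, sim$anchor)
  expect_true(all(empty$count[!is.na(empty$offset)] == 0L))
  expect_equal(sum(empty$count), sum(bg$count))
})

test_that("ratio estimation is exact in its point estimate and seeded", {
  r <- estimate_ratio(500, 100, seed = 1)
  expect_equal(r$ratio, 5.0)
  expect_lte(r$ci_low, r$ratio)
  expect_gte(r$ci_high, r$ratio)

  r1 <- estimate_ratio(4000, 800, seed = 42)
  r2 <- estimate_ratio(4000, 800, seed = 42)
  expect_identical(tidy(r1), tidy(r2))

  req <- estimate_ratio(1000, 1000, seed = 2)
  expect_equal(req$ratio, 1.0)
  expect_lte(req$ci_low, 1.0)
  expect_gte(req$ci_high, 1.0)

  expect_error(estimate_ratio(10, 0), class = "dorna_error_zero_denominator")
  expect_error(estimate_ratio(-1, 10), class = "dorna_error_input")
})

test_that("ratio comparison separates planted ratios and not equal ones", {
  a <- estimate_ratio(5000, 1000, seed = 1)
  same <- compare_ratios(a, a, seed = 3)
  expect_equal(same$log_ratio_diff, 0)
  expect_gt(same$p_value, 0.5)

  b <- estimate_ratio(5000, 5000, seed = 1)
  diff <- compare_ratios(a, b, seed = 3)
  expect_lt(diff$p_value, 0.01)
  expect_gt(diff$ci_low, 0)

  tt <- compare_ratio_replicates(c(5.1, 4.9, 5.2), c(1.0, 1.1, 0.9))
  expect_lt(tt$p_value, 0.01)
})

test_that("the bootstrap ratio test has power and near-nominal size", {
  # count-level replicates: n family reads split binomially by the ratio
  draw <- function(ratio, n = 10000L) {
    c_count <- rbinom(1, n, ratio / (1 + ratio))
    estimate_ratio(c_count, n - c_count, n_bootstrap = 500L)
  }
  withr::with_seed(1313, {
    # planted 5 vs 1: detected at p < 0.01 in almost every replicate
    p_alt <- vapply(1:40, function(i) {
      compare_ratios(draw(5), draw(1), n_bootstrap = 500L)$p_value
    }, numeric(1))
    expect_gte(mean(p_alt < 0.01), 0.90)

    # planted equal ratios: rejection rate stays near the nominal 5%
    p_null <- vapply(1:200, function(i) {
      compare_ratios(draw(2), draw(2), n_bootstrap = 500L)$p_value
    }, numeric(1))
    expect_gte(mean(p_null < 0.05), 0.01)
    expect_lte(mean(p_null < 0.05), 0.10)
  })
})
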