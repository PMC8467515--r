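# Seeded synthetic-data generators. Each generator returns both the data
# and the planted truth so every downstream stage can be checked exactly.

#' Simulation configuration for an ultra-short sRNA-seq library
#'
#' Species presets fix the planted C-doRNA/doRNA ratio (human 5.0,
#' mouse 1.0, fly 0.25) and the share of family reads in the 8-30 nt
#' window; within the family, the 12-nt core has weight 1, the 13-nt +1
#' variant has weight `true_ratio` and the 5'-extension ladder follows
#' `ladder_weights`. The remainder of the library is background: reads
#' sampled from a fixed panel of random 19-24 nt miRNA-like sequences and
#' a `degradation_fraction` of random reference fragments (8-30 nt).
#' Sequencing is emulated as insert + 3' adapter with independent
#' per-base substitution errors.
#'
#' @param species_preset `"human"`, `"mouse"`, `"fly"` or `"custom"`.
#' @param true_ratio Planted C-variant/core ratio; preset default by
#'   species (custom default 1).
#' @param family_fraction Share of family (core + variant + ladder) reads;
#'   preset defaults human 0.60, mouse 0.74, fly 0.50 (the observed
#'   12+13 nt window shares span roughly 0.22-0.74 across real samples).
#' @param ladder_weights Named numeric weights for offsets `-2` .. `-6`,
#'   relative to the core's weight of 1.
#' @param n_reads Library size.
#' @param error_rate Per-base substitution error rate.
#' @param adapter3 3' adapter appended to every insert.
#' @param n_mirnas Number of background miRNA-like species.
#' @param degradation_fraction Share of the library that is random
#'   reference degradation fragments.
#' @param seed Integer seed; fixed seeds give byte-identical libraries.
#' @return An object of class `dorna_sim_config`.
#' @export
#' @examples
#' library_sim_config("human", n_reads = 1000, seed = 1)
library_sim_config <- function(species_preset = c("human", "mouse", "fly", "custom"),
                               true_ratio = NULL, family_fraction = NULL,
                               ladder_weights = c(`-2` = 0.12, `-3` = 0.06,
                                                  `-4` = 0.03, `-5` = 0.015,
                                                  `-6` = 0.0075),
                               n_reads = 100000L, error_rate = 0.001,
                               adapter3 = default_adapter3(),
                               n_mirnas = 20L, degradation_fraction = 0.10,
                               seed = 1L) {
  species_preset <- match.arg(species_preset)
  presets <- list(
    human = list(true_ratio = 5.0, family_fraction = 0.60),
    mouse = list(true_ratio = 1.0, family_fraction = 0.74),
    fly = list(true_ratio = 0.25, family_fraction = 0.50),
    custom = list(true_ratio = 1.0, family_fraction = 0.50)
  )
  p <- presets[[species_preset]]
  true_ratio <- true_ratio %||% p$true_ratio
  family_fraction <- family_fraction %||% p$family_fraction
  assert_scalar_number(true_ratio, "true_ratio", positive = TRUE)
  if (family_fraction < 0 || family_fraction > 1) {
    abort("`family_fraction` must be in [0, 1]", class = "dorna_error_config")
  }
  if (any(ladder_weights < 0)) {
    abort("ladder weights must be >= 0", class = "dorna_error_config")
  }
  if (family_fraction + degradation_fraction > 1) {
    abort("family_fraction + degradation_fraction exceeds 1",
          class = "dorna_error_config")
  }
  structure(
    list(species_preset = species_preset, true_ratio = true_ratio,
         family_fraction = family_fraction, ladder_weights = ladder_weights,
         n_reads = as.integer(n_reads), error_rate = error_rate,
         adapter3 = canonicalize_seq(adapter3, what = "adapter3"),
         n_mirnas = as.integer(n_mirnas),
         degradation_fraction = degradation_fraction,
         seed = as.integer(seed)),
    class = "dorna_sim_config"
  )
}

#' Simulate an ultra-short sRNA-seq library with a planted truth table
#'
#' Draws reads according to the configured composition, appends the 3'
#' adapter and applies substitution errors. The returned truth table
#' records every planted insert with its category, 5' offset and count,
#' so exact recovery can be asserted at error rate 0.
#'
#' @param cfg A [library_sim_config()].
#' @param reference A [reference_feature_set()]; defaults to the species'
#'   [synthetic_reference()] (`"custom"` uses the human record).
#' @return A list of class `dorna_sim_library`: `reads` (tibble `id`,
#'   `sequence`, `quality`), `truth` (tibble `sequence`, `category`,
#'   `offset`, `count`), `anchor`, `config`.
#' @export
#' @examples
#' sim <- simulate_library(library_sim_config("human", n_reads = 500, seed = 7))
#' head(sim$truth)
simulate_library <- function(cfg, reference = NULL) {
  stopifnot(inherits(cfg, "dorna_sim_config"))
  reference <- reference %||% synthetic_reference(
    if (cfg$species_preset == "custom") "human" else cfg$species_preset
  )
  anchor <- derive_anchor(reference)
  windows <- anchor$family_windows
  ref_seq <- reference$records$sequence[
    reference$records$accession == anchor$accession]

  # Family composition: core weight 1, +1 variant weight true_ratio,
  # deeper ladder rungs as configured.
  fam_w <- c(`0` = 1, `-1` = cfg$true_ratio)
  lw <- cfg$ladder_weights[names(cfg$ladder_weights) %in% names(windows)]
  fam_w <- c(fam_w, lw)
  fam_p <- cfg$family_fraction * fam_w / sum(fam_w)

  with_local_seed(cfg$seed, {
    mirna_fraction <- 1 - cfg$family_fraction - cfg$degradation_fraction
    mirnas <- if (cfg$n_mirnas > 0L) {
      random_dna(sample(19:24, cfg$n_mirnas, replace = TRUE))
    } else character()
    mirna_w <- if (cfg$n_mirnas > 0L) 1 / seq_len(cfg$n_mirnas) else numeric()
    mirna_p <- if (cfg$n_mirnas > 0L) {
      mirna_fraction * mirna_w / sum(mirna_w)
    } else numeric()

    labels <- c(names(fam_p),
                if (length(mirnas)) paste0("mirna_", seq_along(mirnas)),
                "degradation")
    probs <- c(fam_p, mirna_p, cfg$degradation_fraction)
    if (mirna_fraction > 0 && length(mirnas) == 0L) {
      abort("background miRNA fraction is positive but n_mirnas is 0",
            class = "dorna_error_config")
    }
    draw <- sample(seq_along(labels), cfg$n_reads, replace = TRUE, prob = probs)
    lab <- labels[draw]

    insert <- character(cfg$n_reads)
    fam_idx <- match(lab, names(windows))
    is_fam <- !is.na(fam_idx)
    insert[is_fam] <- unname(windows)[fam_idx[is_fam]]
    is_mir <- startsWith(lab, "mirna_")
    if (any(is_mir)) {
      insert[is_mir] <- mirnas[as.integer(sub("mirna_", "", lab[is_mir]))]
    }
    is_deg <- lab == "degradation"
    if (any(is_deg)) {
      dl <- sample(8:30, sum(is_deg), replace = TRUE)
      ds <- vapply(dl, function(l) {
        sample.int(nchar(ref_seq) - l + 1L, 1L)
      }, integer(1))
      insert[is_deg] <- substr(rep(ref_seq, sum(is_deg)), ds, ds + dl - 1L)
    }

    truth <- tibble(insert = insert, label = lab) |>
      dplyr::count(.data$insert, .data$label, name = "count") |>
      dplyr::transmute(
        sequence = .data$insert,
        category = dplyr::case_when(
          .data$label == "0" ~ "dorna",
          .data$label == "-1" ~ "c_dorna",
          .data$label %in% names(windows) ~ "extended_variant",
          startsWith(.data$label, "mirna_") ~ "mirna",
          TRUE ~ "degradation"
        ),
        offset = ifelse(.data$label %in% names(windows),
                        suppressWarnings(as.integer(.data$label)), NA_integer_),
        count = .data$count
      ) |>
      dplyr::arrange(dplyr::desc(.data$count), .data$sequence)

    reads <- paste0(insert, cfg$adapter3)
    if (cfg$error_rate > 0) {
      reads <- mutate_reads(reads, cfg$error_rate)
    }
    out <- list(
      reads = tibble(
        id = sprintf("read%07d", seq_len(cfg$n_reads)),
        sequence = reads,
        quality = strrep("I", nchar(reads))
      ),
      truth = truth,
      anchor = anchor,
      config = cfg
    )
    class(out) <- "dorna_sim_library"
    out
  })
}

#' @export
print.dorna_sim_library <- function(x, ...) {
  cat("<dorna_sim_library> ", nrow(x$reads), " reads (",
      x$config$species_preset, " preset, planted ratio ",
      x$config$true_ratio, ", seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

# Apply independent per-base substitution errors; only reads drawn to
# carry at least one error are touched, so the common case stays cheap.
mutate_reads <- function(reads, error_rate) {
  n_err <- rbinom(length(reads), nchar(reads), error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(chars), n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate an LC/MS-MS peptide-count table with a planted Venn partition
#'
#' Plants proteins exclusive to each bait, shared proteins, decoys that
#' are contaminated in the negative pull-down (and must be filtered out)
#' and sub-threshold decoys (<= `min` peptides). Applying
#' [filter_partners()] + [venn_partition()] recovers the planted
#' partition exactly.
#'
#' @param n_a_only,n_b_only,n_shared Planted counts of doRNA-exclusive,
#'   C-doRNA-exclusive and shared partners.
#' @param n_negative_contaminated Decoys with high bait counts but >= 1
#'   peptide in the negative sample.
#' @param n_subthreshold Decoys with 1-3 bait peptides.
#' @param seed Integer seed.
#' @param min_peptides Threshold the planted proteins must strictly
#'   exceed (default 3).
#' @return A tibble with columns `protein_id`, `bait`, `peptide_count`,
#'   `coverage_pct`, plus a `truth` attribute naming the planted sets.
#' @export
#' @examples
#' pep <- simulate_peptides(25, 23, 37, 5, 5, seed = 1)
#' glance(partner_venn(pep))
simulate_peptides <- function(n_a_only, n_b_only, n_shared,
                              n_negative_contaminated = 0L,
                              n_subthreshold = 0L, seed = 1L,
                              min_peptides = 3) {
  stopifnot(n_a_only >= 0, n_b_only >= 0, n_shared >= 0,
            n_negative_contaminated >= 0, n_subthreshold >= 0)
  with_local_seed(seed, {
    ids <- function(prefix, n) {
      if (n == 0L) character() else sprintf("%s%03d", prefix, seq_len(n))
    }
    a_only <- ids("DORNA_ONLY_", n_a_only)
    b_only <- ids("CDORNA_ONLY_", n_b_only)
    shared <- ids("SHARED_", n_shared)
    contam <- ids("CONTAM_", n_negative_contaminated)
    subthr <- ids("WEAK_", n_subthreshold)
    high <- function(n) sample((min_peptides + 1):(min_peptides + 40), n,
                               replace = TRUE)
    low <- function(n) sample(seq_len(min_peptides), n, replace = TRUE)
    rows <- list(
      tibble(protein_id = a_only, bait = "doRNA", peptide_count = high(n_a_only)),
      tibble(protein_id = b_only, bait = "C-doRNA", peptide_count = high(n_b_only)),
      tibble(protein_id = shared, bait = "doRNA", peptide_count = high(n_shared)),
      tibble(protein_id = shared, bait = "C-doRNA", peptide_count = high(n_shared)),
      tibble(protein_id = contam, bait = "doRNA", peptide_count = high(n_negative_contaminated)),
      tibble(protein_id = contam, bait = "negative",
             peptide_count = if (n_negative_contaminated) sample(1:5, n_negative_contaminated, replace = TRUE) else integer()),
      tibble(protein_id = subthr, bait = sample(c("doRNA", "C-doRNA"), n_subthreshold, replace = TRUE),
             peptide_count = low(n_subthreshold))
    )
    out <- dplyr::bind_rows(rows)
    out$coverage_pct <- round(pmin(95, 10 + out$peptide_count * 2.3 +
                                     runif(nrow(out), 0, 10)), 1)
    attr(out, "truth") <- list(a_only = a_only, b_only = b_only, shared = shared)
    out
  })
}

#' Simulate a qPCR run: serial dilution plus unknown samples
#'
#' Cq values follow `intercept + slope * log10(copies)` with
#' `slope = -1/log10(1 + efficiency)` and additive Gaussian noise.
#'
#' @param true_copies Named numeric vector of unknown-sample copy numbers.
#' @param efficiency Amplification efficiency fraction in (0.5, 1.2].
#' @param noise_sd Gaussian Cq noise standard deviation.
#' @param seed Integer seed.
#' @param dilution_copies Copies of the standard-curve points.
#' @param intercept Cq at 1 copy (default 35).
#' @return A list with tibbles `dilutions` (copies, cq) and `unknowns`
#'   (target, true_copies, cq), plus `slope` and `intercept`.
#' @export
#' @examples
#' simulate_qpcr(c(doRNA = 1e4, `C-doRNA` = 5e4), seed = 1)
simulate_qpcr <- function(true_copies, efficiency = 1, noise_sd = 0,
                          seed = 1L, dilution_copies = 10^(2:7),
                          intercept = 35) {
  if (efficiency <= 0.5 || efficiency > 1.2) {
    abort("`efficiency` must be in (0.5, 1.2]", class = "dorna_error_config")
  }
  if (any(true_copies <= 0) || any(dilution_copies <= 0)) {
    abort("copy numbers must be > 0", class = "dorna_error_input")
  }
  slope <- -1 / log10(1 + efficiency)
  with_local_seed(seed, {
    dil <- tibble(
      copies = dilution_copies,
      cq = intercept + slope * log10(dilution_copies) +
        stats::rnorm(length(dilution_copies), 0, noise_sd)
    )
    unk <- tibble(
      target = names(true_copies) %||% paste0("target", seq_along(true_copies)),
      true_copies = unname(true_copies),
      cq = intercept + slope * log10(unname(true_copies)) +
        stats::rnorm(length(true_copies), 0, noise_sd)
    )
    list(dilutions = dil, unknowns = unk, slope = slope, intercept = intercept)
  })
}
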