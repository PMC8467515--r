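# Pull-down proteomics candidate filtering and Venn partition of doRNA /
# C-doRNA protein partners, plus IP fold enrichment.

PEPTIDE_BAITS <- c("doRNA", "C-doRNA", "negative")

#' Filter pull-down protein candidates by peptide count
#'
#' A protein is kept for a bait (doRNA or C-doRNA) iff its peptide count
#' for that bait strictly exceeds `min_peptides_exclusive` and it was not
#' detected at all (zero peptides) in the negative-RNA pull-down. A
#' protein absent from a bait's table counts as zero peptides.
#'
#' @param records A data frame with columns `protein_id`, `bait` (one of
#'   `"doRNA"`, `"C-doRNA"`, `"negative"`) and `peptide_count`; an
#'   optional `coverage_pct` column is ignored by the filter.
#' @param min_peptides_exclusive Strict lower bound on peptide count
#'   (default 3, i.e. "more than 3 peptides" keeps counts >= 4).
#' @return A tibble with columns `bait` and `protein_id` of the kept
#'   candidates.
#' @export
#' @examples
#' filter_partners(tibble::tibble(
#'   protein_id = c("P1", "P1", "P2"),
#'   bait = c("doRNA", "negative", "doRNA"),
#'   peptide_count = c(10, 0, 2)
#' ))
filter_partners <- function(records, min_peptides_exclusive = 3) {
  records <- as_tibble(records)
  stopifnot(all(c("protein_id", "bait", "peptide_count") %in% names(records)))
  bad <- setdiff(unique(records$bait), PEPTIDE_BAITS)
  if (length(bad) > 0L) {
    abort(sprintf("unknown bait label(s): %s", paste(bad, collapse = ", ")),
          class = "dorna_error_input")
  }
  if (any(records$peptide_count < 0)) {
    abort("negative peptide count", class = "dorna_error_input")
  }
  wide <- records |>
    dplyr::group_by(.data$protein_id, .data$bait) |>
    dplyr::summarise(peptide_count = max(.data$peptide_count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "bait", values_from = "peptide_count",
                       values_fill = 0)
  for (b in PEPTIDE_BAITS) if (!b %in% names(wide)) wide[[b]] <- 0
  purrr::map_dfr(c("doRNA", "C-doRNA"), function(b) {
    keep <- wide[[b]] > min_peptides_exclusive & wide[["negative"]] == 0
    tibble(bait = b, protein_id = sort(wide$protein_id[keep]))
  })
}

#' Venn partition of two candidate sets
#'
#' Exact set algebra: exclusive and shared members of two protein sets.
#'
#' @param set_a,set_b Character vectors of protein ids (duplicates are
#'   dropped).
#' @param names Labels for the two sets.
#' @return An object of class `dorna_venn` with sorted id sets `a_only`,
#'   `b_only`, `shared`; see [tidy()] / [glance()].
#' @export
#' @examples
#' venn_partition(c("P1", "P2"), c("P2", "P3"))
venn_partition <- function(set_a, set_b, names = c("doRNA", "C-doRNA")) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  structure(
    list(
      a_only = sort(setdiff(set_a, set_b)),
      b_only = sort(setdiff(set_b, set_a)),
      shared = sort(intersect(set_a, set_b)),
      names = names
    ),
    class = "dorna_venn"
  )
}

#' @export
print.dorna_venn <- function(x, ...) {
  cat(sprintf(
    "<dorna_venn> %s only: %d | shared: %d | %s only: %d (union %d)\n",
    x$names[1], length(x$a_only), length(x$shared),
    x$names[2], length(x$b_only),
    length(x$a_only) + length(x$b_only) + length(x$shared)
  ))
  invisible(x)
}

#' Filter candidates and partition them in one call
#'
#' @inheritParams filter_partners
#' @return A `dorna_venn` of the doRNA vs C-doRNA kept sets.
#' @export
partner_venn <- function(records, min_peptides_exclusive = 3) {
  kept <- filter_partners(records, min_peptides_exclusive)
  venn_partition(kept$protein_id[kept$bait == "doRNA"],
                 kept$protein_id[kept$bait == "C-doRNA"])
}

#' Immunoprecipitation fold enrichment over the IgG control
#'
#' @param target_quantity_ab Quantity (copies or efficiency-corrected
#'   qPCR quantity) in the antibody IP.
#' @param target_quantity_igg Matching quantity in the control IgG IP;
#'   must be > 0.
#' @return `target_quantity_ab / target_quantity_igg` (vectorized).
#' @export
#' @examples
#' ip_fold_enrichment(8, 1)
ip_fold_enrichment <- function(target_quantity_ab, target_quantity_igg) {
  if (any(target_quantity_igg <= 0) || any(target_quantity_ab <= 0)) {
    abort("IP quantities must be > 0", class = "dorna_error_input")
  }
  target_quantity_ab / target_quantity_igg
}
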