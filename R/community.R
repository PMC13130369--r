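#' Design a tiered mock community
#'
#' Builds a ground-truth community from species ranked by abundance. Under
#' the default design the 15 species fall into three tiers of five: "main"
#' taxa at 15% each (three strain/subspecies variants, 5% apiece), "mid" taxa
#' at 4.5% (one variant) and "rare" taxa at 0.5% (one variant), so abundances
#' sum to exactly 100 and the community probes classifier sensitivity from
#' dominant down to low-density taxa. Alternative tier geometries are allowed
#' through the arguments; the defaults are the reference design.
#'
#' @param species Character vector of species names ordered by decreasing
#'   abundance rank; length must equal `sum(tier_sizes)` and names must be
#'   unique.
#' @param site_id Site label for the community.
#' @param tier_sizes Named integer vector: number of species per tier, in
#'   rank order.
#' @param tier_abundance_pct Per-species abundance (percent) in each tier.
#' @param tier_variants Number of sequence variants per species in each tier.
#' @return A [truth_profile()].
#' @examples
#' design_community(sprintf("species_%02d", 1:15), site_id = "west_bank")
#' @export
design_community <- function(species, site_id = "site",
                             tier_sizes = c(main = 5L, mid = 5L, rare = 5L),
                             tier_abundance_pct = c(main = 15, mid = 4.5, rare = 0.5),
                             tier_variants = c(main = 3L, mid = 1L, rare = 1L)) {
  species <- stringr::str_squish(as.character(species))
  if (length(species) != sum(tier_sizes)) {
    abort(sprintf("expected %d species (one per tier slot), got %d.",
                  sum(tier_sizes), length(species)))
  }
  if (anyDuplicated(species)) abort("species names must be unique.")
  if (!identical(names(tier_sizes), names(tier_abundance_pct)) ||
      !identical(names(tier_sizes), names(tier_variants))) {
    abort("tier_sizes, tier_abundance_pct and tier_variants must share tier names.")
  }
  tier <- rep(names(tier_sizes), times = tier_sizes)
  truth_profile(
    tibble(taxon = species,
           tier = tier,
           abundance_pct = unname(tier_abundance_pct[tier]),
           n_variants = as.integer(unname(tier_variants[tier]))),
    site_id = site_id
  )
}

#' Select representative species from pilot classifications
#'
#' Ranks species by mean relative abundance across replicate pilot profiles
#' of one site (a species absent from a replicate counts as zero there) and
#' returns the top `k`, the selection rule used to pick representative taxa
#' for simulated read sets. Ties are broken lexicographically.
#'
#' @param profiles List of [classification_profile()]s (replicates of one site).
#' @param k Number of species to select.
#' @return A tibble with columns `rank`, `taxon`, `mean_rel_abundance_pct`.
#' @export
select_representatives <- function(profiles, k = 15L) {
  if (!length(profiles)) abort("at least one pilot profile is required.")
  n_rep <- length(profiles)
  rel <- purrr::imap(profiles, function(p, i) {
    r <- to_relative(p, denominator = "mapped")
    tibble(replicate = i, taxon = r$taxon, abundance_pct = r$abundance_pct)
  })
  means <- dplyr::bind_rows(rel) |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(mean_rel_abundance_pct = sum(.data$abundance_pct) / n_rep,
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_rel_abundance_pct), .data$taxon)
  if (nrow(means) < k) {
    abort(sprintf("only %d distinct species across replicates; %d more needed to select %d.",
                  nrow(means), k - nrow(means), k))
  }
  means |>
    utils::head(k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Emit a per-variant abundance configuration
#'
#' Expands a truth profile to one row per sequence variant with its
#' fractional abundance — the community-design input a read simulator such
#' as CAMISIM consumes. Variants are named `<species>|v1..vK` and split their
#' species' abundance equally (main taxa under the default design: three
#' variants at 0.05 each). Fractions sum to the community total (1 for a
#' full design).
#'
#' @param truth A [truth_profile()].
#' @param total_reads Planned read-set size; used for the expected per-variant
#'   read counts.
#' @return A tibble with columns `variant_id`, `taxon`, `tier`, `fraction`,
#'   `expected_reads`.
#' @export
abundance_config <- function(truth, total_reads = 175000L) {
  if (!isTRUE(total_reads > 0)) abort("`total_reads` must be positive.")
  rows <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    k <- truth$n_variants[i]
    tibble(variant_id = sprintf("%s|v%d", truth$taxon[i], seq_len(k)),
           taxon = truth$taxon[i],
           tier = truth$tier[i],
           fraction = truth$abundance_pct[i] / 100 / k)
  })
  rows$expected_reads <- rows$fraction * total_reads
  stopifnot(abs(sum(rows$fraction) - sum(truth$abundance_pct) / 100) < 1e-9)
  rows
}

#' @rdname abundance_config
#' @param config A tibble from `abundance_config()`.
#' @param path Output path for the two-column (variant, fraction) TSV.
#' @export
write_abundance_config <- function(config, path) {
  writeLines(sprintf("%s\t%s", config$variant_id,
                     format(config$fraction, scientific = FALSE, trim = TRUE)),
             path, sep = "\n", useBytes = TRUE)
  invisible(path)
}
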