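#' Taxon-level confusion sets
#'
#' Splits taxa into true positives (detected and truly present), false
#' positives (detected only) and false negatives (present but undetected).
#' Names are canonicalized with [canonicalize_name()] on both sides and
#' sequence variants collapse to their species, so a taxon is "detected" iff
#' at least one read maps to any of its variants.
#'
#' @param profile A [classification_profile()].
#' @param truth A [truth_profile()].
#' @return A list with character vectors `tp`, `fp`, `fn` of canonical names.
#' @export
taxa_confusion <- function(profile, truth) {
  detected <- names(canonical_counts(profile))
  present <- names(canonical_truth(truth))
  list(tp = sort(intersect(detected, present)),
       fp = sort(setdiff(detected, present)),
       fn = sort(setdiff(present, detected)))
}

#' Composite surveillance score
#'
#' The mean of the two sensitivity-times-selectivity products, at taxon and
#' at read level, expressed as a percentage:
#' `(taxa_sens * taxa_sel + read_sens * read_sel) / 200` with all inputs in
#' percent. It is 100 only for a perfect profile and summarizes a pipeline's
#' usefulness for detecting which organisms are present and how much of the
#' signal lands on them.
#'
#' @param taxa_sensitivity,taxa_selectivity,read_sensitivity,read_selectivity
#'   Percentages in `[0, 100]`.
#' @return The score in percent.
#' @examples
#' surveillance_score(57.8, 81.3, 72.5, 85.2)
#' @export
surveillance_score <- function(taxa_sensitivity, taxa_selectivity,
                               read_sensitivity, read_selectivity) {
  (taxa_sensitivity * taxa_selectivity + read_sensitivity * read_selectivity) / 200
}

#' Score a classification against the ground truth
#'
#' Computes the detection-accuracy panel: taxa sensitivity (share of truth
#' taxa detected), taxa selectivity (share of detected taxa that are true),
#' read sensitivity (share of all input reads mapped to true taxa), read
#' selectivity (share of mapped reads mapped to true taxa), the false
#' positivity rate (complement of taxa selectivity), and the composite
#' [surveillance_score()]. When nothing is detected the selectivities and
#' the score are undefined and reported as `NA`, not zero.
#'
#' @inheritParams taxa_confusion
#' @return A one-row tibble of class `"detection_report"`; the confusion
#'   sets are attached as attribute `"confusion"`.
#' @export
detection_report <- function(profile, truth) {
  if (!nrow(truth)) abort("truth profile is empty.")
  conf <- taxa_confusion(profile, truth)
  counts <- canonical_counts(profile)
  n_truth <- length(canonical_truth(truth))
  n_det <- length(counts)
  mapped <- sum(counts)
  reads_tp <- sum(counts[conf$tp])
  total <- total_reads(profile)

  taxa_sens <- 100 * length(conf$tp) / n_truth
  taxa_sel <- if (n_det > 0) 100 * length(conf$tp) / n_det else NA_real_
  read_sens <- if (isTRUE(total > 0)) 100 * reads_tp / total else NA_real_
  read_sel <- if (mapped > 0) 100 * reads_tp / mapped else NA_real_
  fp_rate <- if (n_det > 0) 100 * length(conf$fp) / n_det else NA_real_
  surv <- if (anyNA(c(taxa_sel, read_sens, read_sel))) {
    NA_real_
  } else {
    surveillance_score(taxa_sens, taxa_sel, read_sens, read_sel)
  }

  out <- tibble(
    sample_id = sample_id(profile) %||% NA_character_,
    pipeline = pipeline_label(profile) %||% NA_character_,
    n_truth = n_truth, n_detected = n_det,
    tp = length(conf$tp), fp = length(conf$fp), fn = length(conf$fn),
    taxa_sensitivity = taxa_sens, taxa_selectivity = taxa_sel,
    read_sensitivity = read_sens, read_selectivity = read_sel,
    false_positivity_rate = fp_rate,
    surveillance_score = surv
  )
  structure(out, confusion = conf,
            class = c("detection_report", class(out)))
}

#' @export
tidy.detection_report <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[, c("taxa_sensitivity", "taxa_selectivity",
                                       "read_sensitivity", "read_selectivity",
                                       "false_positivity_rate", "surveillance_score")],
                      dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.detection_report <- function(x, ...) as_tibble(x)

#' Sensitivity stratified by abundance tier
#'
#' @inheritParams taxa_confusion
#' @return A tibble with one row per tier: `tier`, `n_truth`, `n_detected`,
#'   `sensitivity` (percent of the tier's taxa detected).
#' @export
tier_sensitivity <- function(profile, truth) {
  if (!"tier" %in% names(truth)) abort("truth profile carries no tiers.")
  detected <- names(canonical_counts(profile))
  tibble(taxon = canonicalize_name(truth$taxon), tier = truth$tier) |>
    dplyr::group_by(.data$tier) |>
    dplyr::summarise(n_truth = dplyr::n(),
                     n_detected = sum(.data$taxon %in% detected),
                     sensitivity = 100 * .data$n_detected / .data$n_truth,
                     .groups = "drop") |>
    dplyr::arrange(match(.data$tier, unique(truth$tier)))
}

#' Improvement arithmetic
#'
#' Two conventions for comparing a baseline with an optimized value, reported
#' side by side because they answer different questions. `relative_change()`
#' is the signed percent change `100 * (improved - baseline) / baseline`,
#' undefined for a zero baseline. `absolute_error_reduction()` is the drop in
#' error magnitude `|baseline| - |improved|` in percentage points, the right
#' convention when the inputs are themselves signed percent errors.
#'
#' @param baseline,improved Numeric values (percent metrics or percent errors).
#' @return A percentage (`relative_change`) or percentage points
#'   (`absolute_error_reduction`).
#' @examples
#' relative_change(11.1, 37.8)            # sensitivity raised by 240.5%
#' absolute_error_reduction(115.6, -20.0) # richness error cut by 95.6 points
#' @export
relative_change <- function(baseline, improved) {
  if (any(baseline == 0)) abort("relative change is undefined for a zero baseline.")
  100 * (improved - baseline) / baseline
}

#' @rdname relative_change
#' @export
absolute_error_reduction <- function(baseline, improved) {
  abs(baseline) - abs(improved)
}
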