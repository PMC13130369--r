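#' Per-taxon abundance errors
#'
#' Signed differences between observed and true abundance over the union of
#' truth and detected taxa (the absent side counting as zero), the shared
#' substrate of every mapping-error metric. Negative errors on truth taxa
#' are under-detection (false-negative-derived); positive errors anywhere
#' are over-detection (false-positive-derived).
#'
#' @param profile A [classification_profile()].
#' @param truth A [truth_profile()].
#' @param scale `"percent"` computes errors on the relative-abundance scale
#'   (counts / total reads x 100, the read-normalized convention);
#'   `"count"` on the raw read-count scale (true counts are
#'   `true_pct / 100 * total_reads`).
#' @return A tibble with columns `taxon` (canonical), `true`, `observed`,
#'   `error`, `in_truth`, `detected`.
#' @export
abundance_errors <- function(profile, truth, scale = c("percent", "count")) {
  scale <- match.arg(scale)
  total <- total_reads(profile)
  if (!isTRUE(total > 0)) abort("profile has no reads.")
  counts <- canonical_counts(profile)
  tr <- canonical_truth(truth)
  taxa <- union(names(tr), names(counts))
  obs <- stats::setNames(rep(0, length(taxa)), taxa)
  obs[names(counts)] <- counts
  tru <- stats::setNames(rep(0, length(taxa)), taxa)
  tru[names(tr)] <- tr
  if (scale == "percent") {
    obs <- 100 * obs / total
  } else {
    tru <- tru / 100 * total
  }
  tibble(taxon = taxa,
         true = unname(tru), observed = unname(obs),
         error = unname(obs - tru),
         in_truth = taxa %in% names(tr),
         detected = taxa %in% names(counts)) |>
    dplyr::arrange(dplyr::desc(.data$in_truth), dplyr::desc(.data$true), .data$taxon)
}

# core metric evaluation from an error table (also used by the modelling grid,
# whose cells may carry fractional model counts)
eval_mapping_metric <- function(errors, metric, w) {
  e <- errors$error
  fn_terms <- pmax(-e, 0)            # under-detection; only truth taxa can be negative
  fp_terms <- pmax(e, 0)             # over-detection
  weighted <- startsWith(metric, "wn")
  w_eff <- if (weighted) w else 1
  if (metric %in% c("SAE", "nSAE", "wnSAE")) {
    U <- sum(fn_terms)
    O <- sum(fp_terms)
    list(value = w_eff * U + O, fn_component = U, fp_component = O)
  } else {
    N <- length(e)                   # |truth union detected|
    fn2 <- sum(fn_terms^2)
    fp2 <- sum(fp_terms^2)
    list(value = sqrt((w_eff * fn2 + fp2) / N),
         fn_component = sqrt(fn2 / N),
         fp_component = sqrt(fp2 / N))
  }
}

#' Read-mapping error metrics (SAE and RMSE families)
#'
#' The six-variant mapping-error family. The sum-of-absolute-errors side:
#' `SAE` (raw read-count errors), `nSAE` (read-normalized: errors on the
#' percent-abundance scale, invariant under uniform count scaling) and
#' `wnSAE` (the false-negative-derived component multiplied by `w`, so
#' under-detection of taxa truly present is penalized more than
#' over-detection of false positives). The RMSE side mirrors it:
#' `RMSE`, `nRMSE`, `wnRMSE`, each the square root of the mean squared
#' per-taxon error over the union of truth and detected taxa, the weighted
#' variant multiplying squared false-negative-derived terms by `w` before
#' the mean.
#'
#' For the SAE family the decomposition identity
#' `value = weight * fn_component + fp_component` holds exactly; for the
#' RMSE family `value^2 = weight * fn_component^2 + fp_component^2`.
#'
#' @inheritParams abundance_errors
#' @param metric One of `"SAE"`, `"nSAE"`, `"wnSAE"`, `"RMSE"`, `"nRMSE"`,
#'   `"wnRMSE"`.
#' @param w False-negative weight (> 0) for the weighted variants.
#' @return A one-row tibble of class `"mapping_error_report"`: `metric`,
#'   `value`, `fn_component`, `fp_component`, `weight_w`, `scale`.
#' @examples
#' truth <- design_community(sprintf("species_%02d", 1:15))
#' sim <- simulate_classification(truth, 10000, confusion_params(seed = 7))
#' mapping_error(sim, truth, "wnSAE")
#' @export
mapping_error <- function(profile, truth,
                          metric = c("wnSAE", "SAE", "nSAE", "RMSE", "nRMSE", "wnRMSE"),
                          w = 2) {
  metric <- match.arg(metric)
  if (!isTRUE(w > 0)) abort("`w` must be positive.")
  scale <- if (metric %in% c("SAE", "RMSE")) "count" else "percent"
  errs <- abundance_errors(profile, truth, scale = scale)
  res <- eval_mapping_metric(errs, metric, w)
  out <- tibble(metric = metric, value = res$value,
                fn_component = res$fn_component, fp_component = res$fp_component,
                weight_w = if (startsWith(metric, "wn")) w else 1,
                scale = scale)
  structure(out, class = c("mapping_error_report", class(out)))
}

#' @rdname mapping_error
#' @export
mapping_error_all <- function(profile, truth, w = 2) {
  out <- purrr::map_dfr(c("SAE", "nSAE", "wnSAE", "RMSE", "nRMSE", "wnRMSE"),
                        function(m) mapping_error(profile, truth, m, w))
  structure(out, class = c("mapping_error_report", class(out)))
}

#' @export
tidy.mapping_error_report <- function(x, ...) as_tibble(x)

#' Modelling grid for the mapping-error family
#'
#' Evaluates all six metric variants over the full cross of
#' `0, 3, ..., 15` true taxa detected by `0, 3, ..., 15` false-positive taxa
#' detected, against the default 15-taxon tiered truth. Each step of three
#' true taxa adds one main, one mid and one rare taxon. Detected true taxa
#' are observed at their true abundances; false-positive taxa split the
#' unassigned abundance mass (the reads belonging to missed taxa) in equal
#' shares. Count-scale metrics use `total_reads` at the same proportions.
#' The grid exposes how each variant responds to Type I (false positive) and
#' Type II (missed taxon) errors; see [grid_correlations()].
#'
#' @param truth A tiered [truth_profile()]; defaults to the standard
#'   15-taxon design with placeholder names.
#' @param w False-negative weight for the weighted variants.
#' @param total_reads Read-set size backing the count-scale metrics.
#' @return A tibble of class `"modelling_grid"` with columns
#'   `n_true_detected`, `n_false_positive` and the six metric columns.
#' @export
modelling_grid <- function(truth = NULL, w = 2, total_reads = 175000) {
  truth <- truth %||% design_community(sprintf("species_%02d", 1:15))
  tiers <- split(seq_len(nrow(truth)), truth$tier)[unique(truth$tier)]
  sizes <- lengths(tiers)
  if (length(sizes) != 3 || length(unique(sizes)) != 1) {
    abort("modelling_grid expects a three-tier truth with equal tier sizes.")
  }
  per_tier <- sizes[[1]]
  tru_pct <- truth$abundance_pct
  steps <- seq(0, 3 * per_tier, by = 3)
  cells <- tidyr::expand_grid(n_true_detected = steps, n_false_positive = steps)

  metrics <- purrr::pmap_dfr(cells, function(n_true_detected, n_false_positive) {
    k <- n_true_detected / 3
    det <- unlist(lapply(tiers, function(ix) ix[seq_len(k)]), use.names = FALSE)
    obs_pct <- rep(0, nrow(truth))
    obs_pct[det] <- tru_pct[det]
    missed_mass <- 100 - sum(obs_pct)
    fp_pct <- if (n_false_positive > 0) {
      rep(missed_mass / n_false_positive, n_false_positive)
    } else {
      numeric(0)
    }
    pct_errors <- tibble(error = c(obs_pct - tru_pct, fp_pct))
    cnt_errors <- tibble(error = pct_errors$error / 100 * total_reads)
    vals <- purrr::map_dbl(
      stats::setNames(c("SAE", "nSAE", "wnSAE", "RMSE", "nRMSE", "wnRMSE"),
                      c("SAE", "nSAE", "wnSAE", "RMSE", "nRMSE", "wnRMSE")),
      function(m) {
        errs <- if (m %in% c("SAE", "RMSE")) cnt_errors else pct_errors
        eval_mapping_metric(errs, m, w)$value
      })
    as_tibble(as.list(vals))
  })
  out <- dplyr::bind_cols(cells, metrics)
  structure(out, w = w, n_truth = nrow(truth), total_reads = total_reads,
            class = c("modelling_grid", class(out)))
}

#' Correlate grid metrics with Type I and Type II error counts
#'
#' For each metric column of a modelling grid, the Pearson correlation with
#' the number of false-positive taxa (Type I errors) and with the number of
#' missed taxa (Type II errors), plus their mean — a summary of how
#' proportionately a metric reflects both error sources. A constant metric
#' column has no defined correlation and is reported as `NA`.
#'
#' @param grid A [modelling_grid()] result, or any data frame with columns
#'   `n_true_detected` and `n_false_positive` plus numeric metric columns.
#' @param n_truth Community size used to convert detected-true counts into
#'   missed counts; taken from the grid attribute when present.
#' @return A tibble with columns `metric`, `r_type1`, `r_type2`, `r_mean`.
#' @export
grid_correlations <- function(grid, n_truth = NULL) {
  n_truth <- n_truth %||% attr(grid, "n_truth", exact = TRUE) %||%
    max(grid$n_true_detected)
  id <- c("n_true_detected", "n_false_positive")
  if (!all(id %in% names(grid))) {
    abort("grid must have columns n_true_detected and n_false_positive.")
  }
  metric_cols <- setdiff(names(grid)[vapply(grid, is.numeric, logical(1))], id)
  type1 <- grid$n_false_positive
  type2 <- n_truth - grid$n_true_detected
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }
  purrr::map_dfr(metric_cols, function(m) {
    r1 <- safe_cor(grid[[m]], type1)
    r2 <- safe_cor(grid[[m]], type2)
    tibble(metric = m, r_type1 = r1, r_type2 = r2,
           r_mean = mean(c(r1, r2)))
  })
}
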