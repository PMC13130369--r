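#' Run the full evaluation on one or more profiles
#'
#' Composes the whole framework: optionally filters each profile, then
#' scores it against its site's ground truth with the detection panel, the
#' six mapping-error variants and the alpha-diversity report. With at least
#' two sites, mean Bray-Curtis dissimilarity between observed profiles is
#' compared against the truth's, and the four diversity percent errors are
#' combined into the composite [diversity_score()].
#'
#' @param truths A [truth_profile()] or a named list of them (one per site;
#'   names must cover the sites of `profiles`).
#' @param profiles A named list of [classification_profile()]s; each name is
#'   a site id (append `/replicate` labels as you wish — the part before the
#'   first `/` selects the truth).
#' @param filter `"none"`, `"zscore"` or `"fraction"`.
#' @param cutoff Filter cutoff (defaults: z = -0.25, fraction = 0.004).
#' @param w False-negative weight for the weighted mapping-error variants.
#' @return A list of class `"benchmark_report"`: tibbles `detection`,
#'   `mapping_error`, `alpha` (with truth values and percent errors),
#'   optional `beta` and `diversity` (score), `filter_diagnostics`, and
#'   `meta` (package version, configuration hash).
#' @export
run_benchmark <- function(truths, profiles,
                          filter = c("none", "zscore", "fraction"),
                          cutoff = NULL, w = 2) {
  filter <- match.arg(filter)
  if (inherits(truths, "truth_profile")) {
    truths <- stats::setNames(rep(list(truths), length(profiles)),
                              names(profiles))
  }
  if (is.null(names(profiles))) {
    names(profiles) <- paste0("profile_", seq_along(profiles))
  }
  truth_for <- function(nm) {
    site <- sub("/.*$", "", nm)
    tr <- truths[[site]] %||% truths[[nm]]
    if (is.null(tr)) abort(sprintf("no truth profile supplied for '%s'.", nm))
    tr
  }

  diag <- NULL
  if (filter != "none") {
    diag <- purrr::imap(profiles, function(p, nm) {
      filter_diagnostics(p, truth_for(nm), method = filter, cutoff = cutoff)
    }) |> dplyr::bind_rows(.id = "id")
    profiles <- purrr::map(profiles, function(p) {
      switch(filter,
             zscore = zscore_filter(p, cutoff %||% -0.25)$profile,
             fraction = fraction_filter(p, cutoff %||% 0.004)$profile)
    })
  }

  detection <- purrr::imap(profiles, function(p, nm) {
    as_tibble(detection_report(p, truth_for(nm)))
  }) |> dplyr::bind_rows(.id = "id")
  maperr <- purrr::imap(profiles, function(p, nm) {
    as_tibble(mapping_error_all(p, truth_for(nm), w = w))
  }) |> dplyr::bind_rows(.id = "id")
  alpha <- purrr::imap(profiles, function(p, nm) {
    obs <- as_tibble(alpha_report(p))[, c("richness", "chao1", "shannon", "pielou")]
    tr_ab <- truth_for(nm)$abundance_pct
    tibble(id = nm,
           richness = obs$richness, chao1 = obs$chao1,
           shannon = obs$shannon, pielou = obs$pielou,
           true_richness = sum(tr_ab > 0),
           true_shannon = shannon(tr_ab),
           true_pielou = pielou(tr_ab)) |>
      dplyr::mutate(
        pct_error_richness = percent_error(.data$richness, .data$true_richness),
        pct_error_shannon = percent_error(.data$shannon, .data$true_shannon),
        pct_error_pielou = percent_error(.data$pielou, .data$true_pielou))
  }) |> dplyr::bind_rows()

  out <- list(detection = detection, mapping_error = maperr, alpha = alpha,
              filter_diagnostics = diag)

  sites <- sub("/.*$", "", names(profiles))
  if (dplyr::n_distinct(sites) >= 2) {
    site_truths <- truths[unique(sites)]
    obs_bc <- bray_curtis_matrix(profiles)
    true_bc <- bray_curtis_matrix(site_truths)
    mean_off <- function(m) mean(m[upper.tri(m)])
    out$beta <- list(observed = obs_bc, truth = true_bc,
                     mean_observed = mean_off(obs_bc),
                     mean_truth = mean_off(true_bc))
    pct_bc <- if (mean_off(true_bc) > 0) {
      percent_error(mean_off(obs_bc), mean_off(true_bc))
    } else {
      warn("true mean Bray-Curtis is zero (identical site communities); its percent error and the diversity score are undefined.")
      NA_real_
    }
    out$diversity <- tibble(
      pct_error_richness = mean(alpha$pct_error_richness),
      pct_error_pielou = mean(alpha$pct_error_pielou),
      pct_error_shannon = mean(alpha$pct_error_shannon),
      pct_error_braycurtis = pct_bc,
      diversity_score = if (is.na(pct_bc)) NA_real_ else {
        diversity_score(c(.data$pct_error_richness, .data$pct_error_pielou,
                          .data$pct_error_shannon, pct_bc))
      })
  }

  out$meta <- list(
    tool = "ampliconbench",
    version = as.character(utils::packageVersion("ampliconbench")),
    filter = filter, cutoff = cutoff, w = w,
    config_hash = rlang::hash(list(names(profiles), filter, cutoff, w))
  )
  structure(out, class = "benchmark_report")
}

#' Compare baseline and optimized metric panels
#'
#' Lines up two named metric vectors (or one-row reports) and reports both
#' improvement conventions side by side, explicitly labelled because they
#' are easy to conflate: the signed relative change in percent of the
#' baseline, and the absolute reduction in error magnitude in percentage
#' points (meaningful when the metrics are themselves signed percent
#' errors).
#'
#' @param baseline,improved Named numeric vectors over the same metrics, or
#'   one-row data frames of numeric columns.
#' @return A tibble: `metric`, `baseline`, `improved`,
#'   `relative_change_pct`, `abs_error_reduction_points`.
#' @examples
#' improvement_table(c(taxa_sensitivity = 11.1), c(taxa_sensitivity = 37.8))
#' @export
improvement_table <- function(baseline, improved) {
  as_vec <- function(x) {
    if (is.data.frame(x)) {
      x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
      x <- unlist(x[1, , drop = TRUE])
    }
    if (is.null(names(x))) abort("metric values must be named.")
    x
  }
  b <- as_vec(baseline)
  i <- as_vec(improved)
  miss <- union(setdiff(names(b), names(i)), setdiff(names(i), names(b)))
  if (length(miss)) {
    abort(paste0("unmatched metric labels: ", paste(miss, collapse = ", ")))
  }
  i <- i[names(b)]
  tibble(metric = names(b), baseline = unname(b), improved = unname(i),
         relative_change_pct = unname(ifelse(b == 0, NA_real_, 100 * (i - b) / b)),
         abs_error_reduction_points = unname(abs(b) - abs(i)))
}
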