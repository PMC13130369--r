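#' Alpha diversity metrics
#'
#' Shannon entropy in natural-log units (`shannon()`), Pielou's evenness
#' (`pielou()`, Shannon divided by `ln` richness, undefined below two taxa
#' and reported as `NA`), and the bias-corrected Chao1 richness estimator
#' (`chao1()`, `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1`/`F2` the
#' singleton/doubleton counts, which survives the absence of doubletons and
#' collapses to the observed richness when no taxon has a single read).
#' Abundances are renormalized internally, so any scale (counts, percents,
#' proportions) is accepted by `shannon()` and `pielou()`; `chao1()` needs
#' integer read counts, since singletons are taxa carrying exactly one read.
#'
#' The default tiered community (five taxa at 15%, five at 4.5%, five at
#' 0.5%) has Shannon entropy 2.25 and evenness 0.83.
#'
#' @param x Numeric vector of abundances (named or not); zeros are ignored.
#' @return A single numeric value.
#' @examples
#' shannon(c(rep(15, 5), rep(4.5, 5), rep(0.5, 5)))
#' pielou(c(rep(15, 5), rep(4.5, 5), rep(0.5, 5)))
#' chao1(c(1, 1, 2))
#' @export
shannon <- function(x) {
  if (any(x < 0) || !isTRUE(sum(x) > 0)) {
    abort("abundances must be non-negative with a positive sum.")
  }
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' @rdname shannon
#' @export
pielou <- function(x) {
  s <- sum(x > 0)
  if (s < 2) {
    warn("Pielou evenness is undefined for fewer than two taxa; returning NA.")
    return(NA_real_)
  }
  shannon(x) / log(s)
}

#' @rdname shannon
#' @export
chao1 <- function(x) {
  if (any(x < 0) || any(x != round(x))) {
    abort("chao1 needs non-negative integer read counts.")
  }
  x <- x[x > 0]
  if (!length(x)) return(0)
  as.numeric(vegan::estimateR(round(x))["S.chao1"])
}

#' Alpha-diversity report for a profile
#'
#' @param profile A [classification_profile()] (variants are collapsed to
#'   canonical species before counting).
#' @return A one-row tibble of class `"alpha_report"`: `richness`, `chao1`,
#'   `shannon`, `pielou`.
#' @export
alpha_report <- function(profile) {
  counts <- canonical_counts(profile)
  counts <- counts[counts > 0]
  out <- tibble(
    sample_id = sample_id(profile) %||% NA_character_,
    richness = length(counts),
    chao1 = if (length(counts)) chao1(as.numeric(counts)) else 0,
    shannon = if (length(counts)) shannon(as.numeric(counts)) else NA_real_,
    pielou = if (length(counts) >= 2) pielou(as.numeric(counts)) else NA_real_
  )
  structure(out, class = c("alpha_report", class(out)))
}

#' @export
glance.alpha_report <- function(x, ...) as_tibble(x)

#' Bray-Curtis dissimilarity between two profiles
#'
#' `1 - sum(min(p_i, q_i))` over the taxon union after renormalizing both
#' profiles to sum to one: 0 for identical compositions, 1 for disjoint
#' ones.
#'
#' @param a,b [classification_profile()]s (converted with mapped-read
#'   denominators), `rel_abundance` tibbles from [to_relative()],
#'   [truth_profile()]s, or named abundance vectors.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  va <- as_abundance_vector(a)
  vb <- as_abundance_vector(b)
  taxa <- union(names(va), names(vb))
  m <- rbind(ifelse(is.na(va[taxa]), 0, va[taxa]),
             ifelse(is.na(vb[taxa]), 0, vb[taxa]))
  if (any(rowSums(m) <= 0)) abort("cannot compare an empty profile.")
  m <- m / rowSums(m)
  as.numeric(vegan::vegdist(m, method = "bray"))
}

#' @rdname bray_curtis
#' @param profiles Named list of profiles.
#' @return `bray_curtis_matrix()`: a symmetric dissimilarity matrix.
#' @export
bray_curtis_matrix <- function(profiles) {
  n <- length(profiles)
  labs <- names(profiles) %||% as.character(seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) m[i, j] <- m[j, i] <- bray_curtis(profiles[[i]], profiles[[j]])
  }
  m
}

as_abundance_vector <- function(x) {
  if (inherits(x, "classification_profile")) x <- to_relative(x, "mapped")
  if (inherits(x, "truth_profile")) x <- to_relative(x)
  if (is.data.frame(x)) {
    return(stats::setNames(x$abundance_pct, canonicalize_name(x$taxon)))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(stats::setNames(as.numeric(x), canonicalize_name(names(x))))
  }
  abort("cannot interpret input as an abundance profile.")
}

#' Signed percent error
#'
#' `100 * (measured - true) / true`, the signed convention used for the
#' diversity-metric error tables.
#'
#' @param measured,true Numeric; `true` must be nonzero.
#' @return Signed percent error.
#' @export
percent_error <- function(measured, true) {
  if (any(true == 0)) abort("percent error is undefined for a true value of zero.")
  100 * (measured - true) / true
}

#' Composite diversity score
#'
#' One hundred minus the mean absolute percent error across the four
#' diversity estimates (richness, Pielou evenness, Shannon entropy and mean
#' Bray-Curtis dissimilarity), so the score rises with the usefulness of a
#' pipeline for diversity estimation and is invariant to the sign of each
#' input error.
#'
#' @param errors Numeric vector of signed percent errors (conventionally
#'   four: richness, evenness, Shannon, Bray-Curtis).
#' @return The score (percent; can be negative for errors above 100%).
#' @examples
#' diversity_score(c(-20.0, +14.4, +4.9, -3.6))
#' @export
diversity_score <- function(errors) {
  if (!length(errors) || any(!is.finite(errors))) {
    abort("`errors` must be finite and non-empty.")
  }
  100 - mean(abs(errors))
}

#' Replicate-to-site precision ratio
#'
#' The ratio of the mean per-replicate diversity to the mean whole-site
#' diversity, in percent — a precision measure for sequencing replicates of
#' the same sample: identical replicates give 100%, and the more taxa each
#' replicate misses relative to the site-wide union, the lower the ratio.
#' For richness the site value is the size of the union of taxa detected
#' across the site's replicates (see [richness_precision()]).
#'
#' @param replicate_values Per-replicate metric values (all sites pooled).
#' @param site_values Per-site union/total metric values.
#' @return The ratio in percent.
#' @examples
#' replicate_site_ratio(320.0, 611.0)
#' @export
replicate_site_ratio <- function(replicate_values, site_values) {
  ms <- mean(site_values)
  if (!isTRUE(abs(ms) > 0)) abort("mean site value is zero; ratio undefined.")
  100 * mean(replicate_values) / ms
}

#' @rdname replicate_site_ratio
#' @param profiles List of [classification_profile()]s (replicates).
#' @param sites Character vector, one site label per profile.
#' @return `richness_precision()`: a list with the per-replicate richness
#'   table, the per-site union richness table, and `ratio`.
#' @export
richness_precision <- function(profiles, sites) {
  if (length(profiles) != length(sites)) {
    abort("`profiles` and `sites` must have equal length.")
  }
  taxa <- purrr::map(profiles, function(p) names(canonical_counts(p)))
  reps <- tibble(site = sites, richness = lengths(taxa))
  site_union <- tibble(site = sites, taxa = taxa) |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(richness = length(unique(unlist(.data$taxa))), .groups = "drop")
  list(replicates = reps, sites = site_union,
       ratio = replicate_site_ratio(reps$richness, site_union$richness))
}
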