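#' Build a classification profile
#'
#' A classification profile is the species-level output of one taxonomic
#' classifier on one sample: a tibble with columns `taxon` and `count`
#' (mapped reads), carrying the total number of input reads and sample /
#' pipeline labels as attributes. Reads not assigned to any taxon are
#' represented implicitly as `total_reads(x) - sum(x$count)`; they are never a
#' pseudo-taxon row.
#'
#' @param counts A data frame with columns `taxon` and `count`, or a named
#'   numeric vector of read counts.
#' @param total_reads Total reads input to the classifier. Defaults to
#'   `sum(counts)` (i.e., every read mapped).
#' @param sample_id,pipeline_label Optional labels carried through reports.
#' @return A tibble of class `"classification_profile"` with columns `taxon`
#'   and `count`, sorted by decreasing count.
#' @examples
#' classification_profile(c(`Escherichia coli` = 120, `Aeromonas caviae` = 30),
#'                        total_reads = 200)
#' @export
classification_profile <- function(counts, total_reads = NULL,
                                   sample_id = NA_character_,
                                   pipeline_label = NA_character_) {
  if (is.numeric(counts)) {
    if (is.null(names(counts)) && length(counts) > 0) {
      abort("`counts` given as a vector must be named by taxon.")
    }
    counts <- tibble(taxon = names(counts) %||% character(),
                     count = unname(counts))
  }
  counts <- as_tibble(counts)
  if (!all(c("taxon", "count") %in% names(counts))) {
    abort("`counts` must have columns `taxon` and `count`.")
  }
  counts <- counts[, c("taxon", "count")]
  counts$taxon <- stringr::str_squish(as.character(counts$taxon))
  if (any(!nzchar(counts$taxon))) abort("taxon names must be non-empty.")
  if (anyDuplicated(counts$taxon)) {
    abort("taxon names must be unique; aggregate duplicates before building a profile.")
  }
  if (any(is.na(counts$count)) || any(counts$count < 0)) {
    abort("counts must be non-negative and non-missing.")
  }
  if (any(counts$count != round(counts$count))) {
    abort("counts must be whole numbers of reads.")
  }
  counts$count <- as.numeric(counts$count)
  mapped <- sum(counts$count)
  total_reads <- total_reads %||% mapped
  if (length(total_reads) != 1 || is.na(total_reads) || total_reads < 0) {
    abort("`total_reads` must be a single non-negative number.")
  }
  if (mapped > total_reads + 1e-9) {
    abort(sprintf("mapped reads (%s) exceed total_reads (%s).",
                  format(mapped), format(total_reads)))
  }
  out <- dplyr::arrange(counts, dplyr::desc(.data$count), .data$taxon)
  structure(out,
            total_reads = as.numeric(total_reads),
            sample_id = sample_id,
            pipeline_label = pipeline_label,
            class = c("classification_profile", class(out)))
}

#' Profile attribute accessors
#'
#' @param x A `classification_profile` or `truth_profile`.
#' @return The total input reads, sample id, pipeline label, or site id.
#' @export
total_reads <- function(x) attr(x, "total_reads", exact = TRUE)

#' @rdname total_reads
#' @export
sample_id <- function(x) attr(x, "sample_id", exact = TRUE)

#' @rdname total_reads
#' @export
pipeline_label <- function(x) attr(x, "pipeline_label", exact = TRUE)

#' @rdname total_reads
#' @export
site_id <- function(x) attr(x, "site_id", exact = TRUE)

#' Build a ground-truth community profile
#'
#' The ground truth for a mock or simulated community: one row per
#' species-level taxon with its abundance tier (`"main"`, `"mid"`, `"rare"`
#' under the default tiered design), its relative abundance in percent, and
#' the number of strain/subspecies sequence variants it contributes.
#'
#' @param taxa A data frame with columns `taxon`, `tier`, `abundance_pct` and
#'   optionally `n_variants` (default 1).
#' @param site_id Label of the sampling site the community represents.
#' @return A tibble of class `"truth_profile"`.
#' @seealso [design_community()] for the tiered default design.
#' @export
truth_profile <- function(taxa, site_id = NA_character_) {
  taxa <- as_tibble(taxa)
  req <- c("taxon", "tier", "abundance_pct")
  if (!all(req %in% names(taxa))) {
    abort("`taxa` must have columns taxon, tier and abundance_pct.")
  }
  if (!"n_variants" %in% names(taxa)) taxa$n_variants <- 1L
  taxa <- taxa[, c("taxon", "tier", "abundance_pct", "n_variants")]
  taxa$taxon <- stringr::str_squish(as.character(taxa$taxon))
  if (anyDuplicated(taxa$taxon)) abort("truth taxa must be unique.")
  if (any(taxa$abundance_pct < 0)) abort("abundances must be non-negative.")
  if (sum(taxa$abundance_pct) > 100 + 1e-6) {
    abort("truth abundances must sum to at most 100%.")
  }
  if (any(taxa$n_variants < 1)) abort("n_variants must be >= 1.")
  structure(taxa,
            site_id = site_id,
            class = c("truth_profile", class(taxa)))
}

#' Convert a profile to relative abundances
#'
#' @param profile A `classification_profile` or `truth_profile`.
#' @param denominator For classification profiles, `"mapped"` divides by the
#'   sum of mapped reads (abundances sum to 100); `"total"` divides by the
#'   total input reads (abundances sum to 100 x mapped/total, less than 100
#'   when reads were left unmapped).
#' @return A tibble of class `"rel_abundance"` with columns `taxon` and
#'   `abundance_pct`.
#' @export
to_relative <- function(profile, denominator = c("mapped", "total")) {
  denominator <- match.arg(denominator)
  if (inherits(profile, "truth_profile")) {
    out <- tibble(taxon = profile$taxon, abundance_pct = profile$abundance_pct)
  } else {
    den <- switch(denominator,
                  mapped = sum(profile$count),
                  total  = total_reads(profile))
    if (is.null(den) || !isTRUE(den > 0)) {
      abort("cannot compute relative abundances: zero denominator.")
    }
    out <- tibble(taxon = profile$taxon,
                  abundance_pct = 100 * profile$count / den)
  }
  structure(out, class = c("rel_abundance", class(out)))
}

#' Double a read set at the profile level
#'
#' Represents the read-doubling strategy (concatenating forward and reverse
#' read sets onto themselves before denoising) as a profile transformation:
#' every count and the read total are multiplied by two, so every relative
#' abundance is unchanged.
#'
#' @param profile A `classification_profile`.
#' @return A `classification_profile` with doubled counts and total.
#' @export
double_reads <- function(profile) {
  classification_profile(
    tibble(taxon = profile$taxon, count = 2 * profile$count),
    total_reads = 2 * total_reads(profile),
    sample_id = sample_id(profile),
    pipeline_label = pipeline_label(profile)
  )
}

#' Canonicalize a species name
#'
#' Reduces classifier- or database-specific naming to a canonical species
#' binomial for matching detected taxa against the ground truth: trims and
#' collapses whitespace, lowercases, drops a trailing `|v<k>` sequence-variant
#' suffix, and strips strain/subspecies designations after the binomial
#' (tokens such as `strain`, `str.`, `subsp.`, `serovar`, or any
#' numeric/alphanumeric designation like `K-12`). A leading `Candidatus`
#' prefix is preserved as part of the name.
#'
#' @param x Character vector of raw taxon names.
#' @return Character vector of canonical lowercase names.
#' @examples
#' canonicalize_name("Escherichia coli str. K-12")
#' canonicalize_name("Candidatus Accumulibacter phosphatis")
#' @export
canonicalize_name <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    s <- sub("\\|v[0-9]+$", "", trimws(s))
    s <- tolower(stringr::str_squish(s))
    if (!nzchar(s)) abort("taxon name is empty after canonicalization.")
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    base <- if (toks[1] == "candidatus") 3L else 2L
    if (length(toks) > base) {
      extra <- toks[(base + 1L):length(toks)]
      markers <- c("strain", "str", "str.", "subsp", "subsp.", "subspecies",
                   "serovar", "sv.", "pv.", "bv.", "var.", "biovar", "pathovar")
      cut <- which(extra %in% markers | grepl("[^a-z]", extra))
      if (length(cut)) toks <- toks[seq_len(base + cut[1] - 1L)]
    }
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# canonical named count vector of a profile, variants collapsed
canonical_counts <- function(profile) {
  key <- canonicalize_name(profile$taxon)
  tapply(profile$count, key, sum)
}

# canonical truth abundances (named percent vector)
canonical_truth <- function(truth) {
  key <- canonicalize_name(truth$taxon)
  tapply(truth$abundance_pct, key, sum)
}
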