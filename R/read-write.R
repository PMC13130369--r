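#' Read a Kraken 2 taxonomic report
#'
#' Parses the standard six-column Kraken 2 report (percent, clade reads,
#' direct reads, rank code, taxid, indented name) and returns the profile at
#' one taxonomic rank. Counts are the clade reads of each row at the
#' requested rank, so reads resolved below that rank (e.g. at strain level)
#' are included, following the usual report-aggregation convention. Paired
#' reads count as one record, Kraken's own convention. `total_reads` is the
#' clade read count of the root row.
#'
#' @param path Path to the report.
#' @param level Rank code to extract, e.g. `"S"` for species, `"G"` for genus.
#' @param sample_id,pipeline_label Labels for the profile; the sample id
#'   defaults to the file name.
#' @return A [classification_profile()].
#' @export
read_kraken_report <- function(path, level = "S",
                               sample_id = basename(path),
                               pipeline_label = "kraken2") {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 6L)
  if (length(bad)) {
    abort(sprintf("malformed Kraken report line %d in '%s': expected 6 tab-separated fields.",
                  keep[bad[1]], path))
  }
  m <- do.call(rbind, fields)
  clade <- suppressWarnings(as.numeric(m[, 2]))
  direct <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(clade) || anyNA(direct)) {
    bad <- keep[which(is.na(clade) | is.na(direct))[1]]
    abort(sprintf("malformed Kraken report line %d in '%s': unparseable read count.",
                  bad, path))
  }
  rank <- m[, 4]
  name <- trimws(m[, 6])
  root <- which(rank == "R" & name == "root")
  if (length(root)) {
    total <- clade[root[1]]
  } else {
    total <- sum(direct)
    warn("Kraken report has no root row; total_reads set to the sum of direct reads.")
  }
  sel <- which(rank == level)
  if (!length(sel)) {
    warn(sprintf("no rows at rank '%s' in '%s'; returning an empty profile.", level, path))
  }
  classification_profile(tibble(taxon = name[sel], count = clade[sel]),
                         total_reads = total,
                         sample_id = sample_id, pipeline_label = pipeline_label)
}

#' Read a Bracken species-level abundance table
#'
#' Parses Bracken's tab-separated output (`name`, `taxonomy_id`,
#' `taxonomy_lvl`, `kraken_assigned_reads`, `added_reads`, `new_est_reads`,
#' `fraction_total_reads`). Counts are the re-estimated reads
#' (`new_est_reads`); `total_reads` is their sum, since the format carries
#' only assigned reads.
#'
#' @inheritParams read_kraken_report
#' @return A [classification_profile()].
#' @export
read_bracken_report <- function(path, sample_id = basename(path),
                                pipeline_label = "bracken") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("name", "new_est_reads") %in% names(df))) {
    abort(sprintf("'%s' is not a Bracken table: columns 'name' and 'new_est_reads' required.",
                  path))
  }
  if (!is.numeric(df$new_est_reads)) {
    abort(sprintf("malformed Bracken table '%s': non-numeric new_est_reads.", path))
  }
  classification_profile(tibble(taxon = df$name, count = df$new_est_reads),
                         total_reads = sum(df$new_est_reads),
                         sample_id = sample_id, pipeline_label = pipeline_label)
}

#' Read a tabular BLAST hit table as a best-hit profile
#'
#' Each query read contributes one count to the taxon of its single best hit:
#' highest bitscore, ties broken by lower e-value and then by the
#' lexicographically smallest subject name, so the result does not depend on
#' database order. `total_reads` is the number of distinct query ids in the
#' table (queries with zero hits never appear in tabular output; pass
#' `n_queries` to count them in the total).
#'
#' @param path Path to a tab-separated hit table (BLAST `-outfmt 6` layout by
#'   default).
#' @param col_names Column names for the table; must include the three
#'   columns named by `query_col`, `taxon_col`, `bitscore_col` (and
#'   `evalue_col` if present in the data).
#' @param query_col,taxon_col,bitscore_col,evalue_col Which columns hold the
#'   query id, subject taxon, bitscore and e-value.
#' @param n_queries Optional true number of queries searched, used as
#'   `total_reads` when some queries had no hits.
#' @inheritParams read_kraken_report
#' @return A [classification_profile()].
#' @export
read_blast_hits <- function(path,
                            col_names = c("qseqid", "sseqid", "pident", "length",
                                          "mismatch", "gapopen", "qstart", "qend",
                                          "sstart", "send", "evalue", "bitscore"),
                            query_col = "qseqid", taxon_col = "sseqid",
                            bitscore_col = "bitscore", evalue_col = "evalue",
                            n_queries = NULL,
                            sample_id = basename(path),
                            pipeline_label = "blast") {
  df <- readr::read_tsv(path, col_names = col_names,
                        col_types = readr::cols(.default = readr::col_character()),
                        show_col_types = FALSE, progress = FALSE)
  need <- c(query_col, taxon_col, bitscore_col)
  if (!all(need %in% names(df))) {
    abort("hit table is missing the query, taxon or bitscore column.")
  }
  bits <- suppressWarnings(as.numeric(df[[bitscore_col]]))
  if (anyNA(bits)) {
    abort(sprintf("unparseable bitscore on row %d of '%s'.", which(is.na(bits))[1], path))
  }
  ev <- if (evalue_col %in% names(df)) {
    suppressWarnings(as.numeric(df[[evalue_col]]))
  } else {
    rep(0, nrow(df))
  }
  hits <- tibble(query = df[[query_col]], taxon = df[[taxon_col]],
                 bitscore = bits, evalue = ev)
  best <- hits |>
    dplyr::arrange(.data$query, dplyr::desc(.data$bitscore), .data$evalue, .data$taxon) |>
    dplyr::distinct(.data$query, .keep_all = TRUE)
  counts <- dplyr::count(best, .data$taxon, name = "count")
  total <- n_queries %||% dplyr::n_distinct(hits$query)
  if (total < dplyr::n_distinct(hits$query)) {
    abort("`n_queries` is smaller than the number of distinct queries in the table.")
  }
  classification_profile(counts, total_reads = total,
                         sample_id = sample_id, pipeline_label = pipeline_label)
}

#' Read a generic two-column taxon/count table
#'
#' Accepts a tab-separated file of `taxon<TAB>count` rows with an optional
#' header and an optional `#total_reads=N` comment line. Rows repeating a
#' taxon are summed. Without a total-reads line, `total_reads` defaults to
#' the sum of counts.
#'
#' @inheritParams read_kraken_report
#' @return A [classification_profile()].
#' @export
read_taxon_table <- function(path, sample_id = basename(path),
                             pipeline_label = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  total <- NULL
  tl <- grep("^#total_reads=", lines)
  if (length(tl)) total <- as.numeric(sub("^#total_reads=", "", lines[tl[1]]))
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    return(classification_profile(tibble(taxon = character(), count = numeric()),
                                  total_reads = total %||% 0,
                                  sample_id = sample_id, pipeline_label = pipeline_label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    abort(sprintf("malformed taxon table line %d: expected two tab-separated fields.",
                  which(lengths(fields) < 2L)[1]))
  }
  taxon <- vapply(fields, `[[`, character(1), 1L)
  countc <- vapply(fields, `[[`, character(1), 2L)
  n1 <- suppressWarnings(as.numeric(countc[1]))
  if (is.na(n1)) {  # header row
    taxon <- taxon[-1]
    countc <- countc[-1]
  }
  count <- suppressWarnings(as.numeric(countc))
  if (anyNA(count)) abort("unparseable count in taxon table.")
  if (any(count < 0)) abort("negative count in taxon table.")
  agg <- tapply(count, taxon, sum)
  classification_profile(tibble(taxon = names(agg), count = as.numeric(agg)),
                         total_reads = total %||% sum(count),
                         sample_id = sample_id, pipeline_label = pipeline_label)
}

#' Profile and truth writers
#'
#' Writers for the formats the readers consume, used for export and for
#' building fixtures. All emit UTF-8, tab-separated, LF-terminated text.
#' `write_taxon_table()` records `total_reads` in a `#total_reads=` header so
#' the generic format round-trips exactly. `write_kraken_report()` emits an
#' unclassified row, a root row whose clade count equals the profile's total
#' reads, and one species row per taxon; `write_bracken_report()` emits the
#' species table (which carries assigned reads only, so a profile with
#' unmapped reads round-trips its counts but not its read total).
#'
#' @param profile A [classification_profile()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_taxon_table <- function(profile, path) {
  lines <- c(sprintf("#total_reads=%s", format(total_reads(profile), scientific = FALSE)),
             "taxon\tcount",
             sprintf("%s\t%s", profile$taxon,
                     format(profile$count, scientific = FALSE, trim = TRUE)))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_taxon_table
#' @export
write_kraken_report <- function(profile, path) {
  total <- total_reads(profile)
  mapped <- sum(profile$count)
  fmt <- function(pct, clade, direct, rank, taxid, name, indent = 0) {
    sprintf("%6.2f\t%s\t%s\t%s\t%d\t%s%s",
            pct, format(clade, scientific = FALSE, trim = TRUE),
            format(direct, scientific = FALSE, trim = TRUE),
            rank, taxid, strrep("  ", indent), name)
  }
  lines <- c(
    fmt(0, 0, 0, "U", 0L, "unclassified"),
    fmt(100, total, total - mapped, "R", 1L, "root")
  )
  if (nrow(profile)) {
    pct <- if (total > 0) 100 * profile$count / total else rep(0, nrow(profile))
    lines <- c(lines, fmt(pct, profile$count, profile$count, "S",
                          seq_len(nrow(profile)) + 1L, profile$taxon, indent = 1))
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_taxon_table
#' @export
write_bracken_report <- function(profile, path) {
  mapped <- sum(profile$count)
  frac <- if (mapped > 0) profile$count / mapped else rep(0, nrow(profile))
  lines <- c(
    paste(c("name", "taxonomy_id", "taxonomy_lvl", "kraken_assigned_reads",
            "added_reads", "new_est_reads", "fraction_total_reads"), collapse = "\t"),
    sprintf("%s\t%d\tS\t%s\t0\t%s\t%.5f",
            profile$taxon, seq_len(nrow(profile)),
            format(profile$count, scientific = FALSE, trim = TRUE),
            format(profile$count, scientific = FALSE, trim = TRUE), frac)
  )
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_taxon_table
#' @param truth A [truth_profile()].
#' @export
write_truth_profile <- function(truth, path) {
  lines <- c(sprintf("#site_id=%s", site_id(truth) %||% NA_character_),
             "taxon\ttier\tabundance_pct\tn_variants",
             sprintf("%s\t%s\t%s\t%d", truth$taxon, truth$tier,
                     format(truth$abundance_pct, scientific = FALSE, trim = TRUE),
                     truth$n_variants))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_taxon_table
#' @export
read_truth_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  site <- NA_character_
  sl <- grep("^#site_id=", lines)
  if (length(sl)) site <- sub("^#site_id=", "", lines[sl[1]])
  df <- readr::read_tsv(paste(lines[!startsWith(lines, "#")], collapse = "\n"),
                        show_col_types = FALSE, progress = FALSE)
  truth_profile(df, site_id = site)
}

#' Dispatch a classifier-output reader by format
#'
#' @param path Input file.
#' @param format One of `"kraken"`, `"bracken"`, `"blast"`, `"tsv"`.
#' @param ... Passed to the format-specific reader.
#' @return A [classification_profile()].
#' @export
read_classification <- function(path, format = c("kraken", "bracken", "blast", "tsv"),
                                ...) {
  format <- match.arg(format)
  switch(format,
         kraken = read_kraken_report(path, ...),
         bracken = read_bracken_report(path, ...),
         blast = read_blast_hits(path, ...),
         tsv = read_taxon_table(path, ...))
}

#' Subsample sequence reads without replacement
#'
#' Draws exactly `n` records uniformly at random without replacement from a
#' FASTA or FASTQ file (gzip-transparent), reproducibly for a fixed seed.
#' Records are returned in their original file order.
#'
#' @param path Input FASTA/FASTQ path (`.gz` allowed). Format is detected
#'   from the extension.
#' @param n Number of records to keep; must not exceed the number available.
#' @param seed Integer seed; the draw is bit-reproducible for a fixed seed.
#' @param out Optional path to write the subsample to (same format).
#' @return A `Biostrings::DNAStringSet` of the sampled records.
#' @export
subsample_reads <- function(path, n, seed, out = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("subsample_reads() requires the Biostrings package.")
  }
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  reads <- if (fastq) {
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  } else {
    Biostrings::readDNAStringSet(path, format = "fasta")
  }
  if (n > length(reads)) {
    abort(sprintf("cannot subsample %d reads from a file with only %d records.",
                  n, length(reads)))
  }
  idx <- withr::with_seed(seed, sort(sample.int(length(reads), n)))
  sub <- reads[idx]
  if (!is.null(out)) {
    if (fastq) {
      Biostrings::writeXStringSet(sub, out, format = "fastq",
                                  qualities = S4Vectors::mcols(sub)$qualities)
    } else {
      Biostrings::writeXStringSet(sub, out, format = "fasta")
    }
  }
  sub
}
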