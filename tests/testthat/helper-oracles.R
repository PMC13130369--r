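# Independent oracles and fixture builders. Everything here is deliberately
# naive (loops, regexes, direct formulas) so it cannot share a defect with the
# implementation it checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

default_truth <- function(site = "site1") {
  design_community(sprintf("species_%02d", 1:15), site_id = site)
}

# brute-force name canonicalization: lowercase, squish, drop |v suffix, then
# truncate at the first strain-ish token after the binomial
oracle_canonical <- function(x) {
  vapply(x, function(s) {
    s <- tolower(gsub("\\s+", " ", trimws(sub("\\|v[0-9]+$", "", s))))
    toks <- unlist(strsplit(s, " "))
    base <- if (identical(toks[1], "candidatus")) 3 else 2
    out <- toks[seq_len(min(base, length(toks)))]
    i <- base + 1
    while (i <= length(toks)) {
      t <- toks[i]
      if (t %in% c("strain", "str", "str.", "subsp", "subsp.", "subspecies",
                   "serovar", "sv.", "pv.", "bv.", "var.", "biovar", "pathovar") ||
          grepl("[^a-z]", t)) break
      out <- c(out, t)
      i <- i + 1
    }
    paste(out, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# brute-force best-hit assignment: per query, max bitscore, then min evalue,
# then lexicographically smallest taxon
oracle_best_hits <- function(hits) {
  counts <- list()
  for (q in unique(hits$query)) {
    h <- hits[hits$query == q, ]
    h <- h[h$bitscore == max(h$bitscore), ]
    h <- h[h$evalue == min(h$evalue), ]
    tax <- sort(h$taxon)[1]
    counts[[tax]] <- (counts[[tax]] %||% 0) + 1
  }
  unlist(counts)[sort(names(counts))]
}

random_profile <- function(seed, n_taxa = 12, total = NULL) {
  withr::with_seed(seed, {
    taxa <- sprintf("taxon %02d", sample(1:40, n_taxa))
    counts <- sample(1:500, n_taxa, replace = TRUE)
    total <- total %||% (sum(counts) + sample(0:100, 1))
    classification_profile(tibble::tibble(taxon = taxa, count = counts),
                           total_reads = total)
  })
}

random_truth <- function(seed, n_taxa = 8) {
  withr::with_seed(seed, {
    taxa <- sprintf("taxon %02d", sample(1:40, n_taxa))
    ab <- runif(n_taxa)
    ab <- 100 * ab / sum(ab)
    truth_profile(tibble::tibble(taxon = taxa,
                                 tier = rep_len(c("main", "mid", "rare"), n_taxa),
                                 abundance_pct = ab))
  })
}

# direct per-taxon error scan on the percent scale (absent side = 0)
oracle_errors <- function(profile, truth) {
  obs <- stats::setNames(profile$count, canonicalize_name(profile$taxon))
  obs <- tapply(obs, names(obs), sum)
  tru <- stats::setNames(truth$abundance_pct, canonicalize_name(truth$taxon))
  taxa <- union(names(tru), names(obs))
  e <- numeric(length(taxa)); names(e) <- taxa
  for (t in taxa) {
    o <- if (t %in% names(obs)) 100 * obs[[t]] / attr(profile, "total_reads") else 0
    tr <- if (t %in% names(tru)) tru[[t]] else 0
    e[t] <- o - tr
  }
  e
}
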