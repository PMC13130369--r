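#' Confusion-model parameters for the classifier simulator
#'
#' Defines the stochastic channel through which simulated reads pass. Each
#' read of a (non-dropout) truth taxon is, independently: left unmapped with
#' probability `p_unmapped`, mapped to its taxon of origin with probability
#' `p_correct`, and otherwise misassigned to a false-positive taxon drawn
#' from a Zipf-like allocation (probability of the k-th FP name proportional
#' to `k^-fp_concentration`) over `fp_pool_size` reserved names
#' (`fp_0001`, ...). Each truth taxon independently drops out entirely with
#' probability `p_dropout`, in which case all of its reads are rerouted as
#' misassignments. The heavy-tailed FP allocation reproduces the empirical
#' tendency of real classifiers that false-positive taxa attract far fewer
#' reads than taxa truly present.
#'
#' Defaults describe a mid-performing classifier on a complex community:
#' 85% of reads mapped correctly, 5% unmapped, 10% misassigned across a pool
#' of 30 candidate false positives, and a 10% chance per taxon of total
#' non-detection.
#'
#' @param p_correct Probability a read maps to its taxon of origin.
#' @param p_dropout Per-taxon probability of total non-detection.
#' @param fp_pool_size Number of candidate false-positive taxa (>= 0).
#' @param fp_concentration Zipf shape of the FP allocation (> 0); larger
#'   values concentrate misassigned reads on fewer FP taxa.
#' @param p_unmapped Probability a read maps nowhere. `p_correct + p_unmapped`
#'   must not exceed 1.
#' @param seed Integer seed; one generator governs every sampling stage.
#' @return A list of class `"confusion_params"`.
#' @export
confusion_params <- function(p_correct = 0.85, p_dropout = 0.10,
                             fp_pool_size = 30L, fp_concentration = 1.5,
                             p_unmapped = 0.05, seed = 1L) {
  for (p in list(p_correct = p_correct, p_dropout = p_dropout, p_unmapped = p_unmapped)) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      abort("probabilities must be single values in [0, 1].")
    }
  }
  if (p_correct + p_unmapped > 1 + 1e-12) {
    abort("p_correct + p_unmapped must be at most 1.")
  }
  if (!isTRUE(fp_pool_size >= 0)) abort("fp_pool_size must be >= 0.")
  if (!isTRUE(fp_concentration > 0)) abort("fp_concentration must be > 0.")
  structure(list(p_correct = p_correct, p_dropout = p_dropout,
                 fp_pool_size = as.integer(fp_pool_size),
                 fp_concentration = fp_concentration,
                 p_unmapped = p_unmapped, seed = as.integer(seed)),
            class = "confusion_params")
}

#' Simulate classifier output from a ground-truth community
#'
#' Draws per-taxon read counts from the truth abundances and passes every
#' read through the confusion channel of [confusion_params()], producing a
#' [classification_profile()] as a stand-in for a real pipeline run. Mapped
#' plus unmapped reads always equal `n_reads` exactly, and the run is
#' deterministic for a fixed seed.
#'
#' @param truth A [truth_profile()].
#' @param n_reads Total reads in the simulated set.
#' @param params A [confusion_params()].
#' @param allocation `"multinomial"` draws the per-taxon read totals
#'   multinomially (the default, emulating read sampling); `"expected"`
#'   assigns each taxon its expected read count by largest-remainder
#'   rounding, the noiseless condition used for analytic identity checks.
#' @return A [classification_profile()] with `pipeline_label = "simulated"`.
#' @examples
#' truth <- design_community(sprintf("species_%02d", 1:15))
#' sim <- simulate_classification(truth, n_reads = 10000,
#'                                params = confusion_params(seed = 42))
#' @export
simulate_classification <- function(truth, n_reads = 175000L,
                                    params = confusion_params(),
                                    allocation = c("multinomial", "expected")) {
  allocation <- match.arg(allocation)
  if (!isTRUE(n_reads > 0)) abort("`n_reads` must be positive.")
  if (!inherits(params, "confusion_params")) abort("`params` must come from confusion_params().")
  p <- truth$abundance_pct / sum(truth$abundance_pct)
  nt <- nrow(truth)

  withr::with_seed(params$seed, {
    n_i <- if (allocation == "multinomial") {
      as.numeric(rmultinom(1, n_reads, p))
    } else {
      largest_remainder(n_reads * p)
    }
    dropped <- runif(nt) < params$p_dropout

    unmapped_i <- numeric(nt)
    correct_i <- numeric(nt)
    live <- !dropped
    if (any(live)) {
      unmapped_i[live] <- rbinom(sum(live), size = n_i[live], prob = params$p_unmapped)
      p_cond <- if (params$p_unmapped < 1) {
        params$p_correct / (1 - params$p_unmapped)
      } else {
        0
      }
      correct_i[live] <- rbinom(sum(live), size = n_i[live] - unmapped_i[live],
                                prob = p_cond)
    }
    err_i <- n_i - unmapped_i - correct_i  # dropout taxa: all reads become errors

    n_err <- sum(err_i)
    fp_counts <- numeric(0)
    if (n_err > 0) {
      if (params$fp_pool_size > 0) {
        zipf <- seq_len(params$fp_pool_size)^(-params$fp_concentration)
        fp_counts <- as.numeric(rmultinom(1, n_err, zipf))
        names(fp_counts) <- sprintf("fp_%04d", seq_len(params$fp_pool_size))
      } else {
        # no FP namespace to absorb errors: reads are left unmapped
        unmapped_i <- unmapped_i + err_i
        err_i[] <- 0
      }
    }
  })

  counts <- c(stats::setNames(correct_i, truth$taxon), fp_counts)
  counts <- counts[counts > 0]
  classification_profile(tibble(taxon = names(counts), count = as.numeric(counts)),
                         total_reads = n_reads,
                         sample_id = site_id(truth) %||% NA_character_,
                         pipeline_label = "simulated")
}

# round x to integers summing to sum(x) (largest-remainder method)
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    add <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[add] <- fl[add] + 1
  }
  fl
}
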