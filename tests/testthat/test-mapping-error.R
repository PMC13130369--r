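test_that("per-taxon abundance errors match a direct scan", {
  truth <- default_truth()
  perfect <- classification_profile(
    stats::setNames(truth$abundance_pct * 10, truth$taxon))
  errs <- abundance_errors(perfect, truth)
  expect_true(all(errs$error == 0))

  tr <- truth_profile(tibble::tibble(taxon = "A", tier = "main", abundance_pct = 100))
  prof <- classification_profile(c(B = 100))
  errs <- abundance_errors(prof, tr)
  expect_equal(sum(pmax(-errs$error, 0)), 100)  # under-detection U
  expect_equal(sum(pmax(errs$error, 0)), 100)   # over-detection O

  for (s in 1:10) {
    p <- random_profile(s)
    tr <- random_truth(s + 50)
    errs <- abundance_errors(p, tr)
    want <- oracle_errors(p, tr)
    expect_equal(stats::setNames(errs$error, errs$taxon)[sort(names(want))],
                 want[sort(names(want))])
  }
})

test_that("the SAE decomposition identity and weight semantics hold", {
  truth <- default_truth()
  perfect <- classification_profile(
    stats::setNames(truth$abundance_pct * 10, truth$taxon))
  for (m in c("SAE", "nSAE", "wnSAE", "RMSE", "nRMSE", "wnRMSE")) {
    expect_equal(mapping_error(perfect, truth, m)$value, 0)
  }

  for (s in 1:50) {
    p <- random_profile(s)
    tr <- random_truth(s + 500)
    for (m in c("SAE", "nSAE", "wnSAE")) {
      r <- mapping_error(p, tr, m, w = 2)
      expect_equal(r$value, r$weight_w * r$fn_component + r$fp_component)
    }
    # w = 1 weighted equals unweighted exactly
    expect_equal(mapping_error(p, tr, "wnSAE", w = 1)$value,
                 mapping_error(p, tr, "nSAE")$value)
    expect_equal(mapping_error(p, tr, "wnRMSE", w = 1)$value,
                 mapping_error(p, tr, "nRMSE")$value)
  }
})

test_that("normalization separates the count and percent scales", {
  truth <- default_truth()
  sim <- simulate_classification(truth, 20000, confusion_params(seed = 3))
  doubled <- double_reads(sim)
  # doubling all counts doubles the raw-count SAE but leaves nSAE unchanged
  expect_equal(mapping_error(doubled, truth, "SAE")$value,
               2 * mapping_error(sim, truth, "SAE")$value)
  expect_equal(mapping_error(doubled, truth, "nSAE")$value,
               mapping_error(sim, truth, "nSAE")$value)
  expect_equal(mapping_error(doubled, truth, "nRMSE")$value,
               mapping_error(sim, truth, "nRMSE")$value)
})

test_that("single-term RMSE equals the absolute error", {
  tr <- truth_profile(tibble::tibble(taxon = "A", tier = "main", abundance_pct = 100))
  prof <- classification_profile(c(A = 50), total_reads = 100)
  expect_equal(mapping_error(prof, tr, "nRMSE")$value, 50)
})

test_that("false positives inflate SAE but can deflate unweighted nRMSE", {
  # a pipeline detecting 5 of 15 taxa at their true abundances
  truth <- default_truth()
  base_counts <- stats::setNames(truth$abundance_pct[1:5] * 100, truth$taxon[1:5])
  base <- classification_profile(base_counts, total_reads = 10000)
  with_fps <- function(k) {
    classification_profile(c(base_counts,
                             stats::setNames(rep(1, k), sprintf("fp %02d", 1:k))),
                           total_reads = 10000)
  }
  nrmse <- vapply(c(0, 5, 10, 20), function(k) {
    p <- if (k == 0) base else with_fps(k)
    mapping_error(p, truth, "nRMSE")$value
  }, numeric(1))
  # the documented pathology: more tiny false positives, lower unweighted nRMSE
  expect_true(all(diff(nrmse) < 0))

  # no SAE variant ever decreases when a false positive is added
  for (m in c("SAE", "nSAE", "wnSAE")) {
    sae <- vapply(c(0, 5, 10, 20), function(k) {
      p <- if (k == 0) base else with_fps(k)
      mapping_error(p, truth, m)$value
    }, numeric(1))
    expect_true(all(diff(sae) >= 0))
  }
})

test_that("the modelling grid matches an independent cell-by-cell recomputation", {
  g <- modelling_grid(w = 2, total_reads = 175000)
  expect_equal(nrow(g), 36)

  # perfect-detection cell is exactly zero for every variant
  row <- g[g$n_true_detected == 15 & g$n_false_positive == 0, ]
  expect_true(all(row[, c("SAE", "nSAE", "wnSAE", "RMSE", "nRMSE", "wnRMSE")] == 0))

  # total-miss cells: the FN-derived component is the whole community (100%)
  miss <- g[g$n_true_detected == 0 & g$n_false_positive > 0, ]
  expect_true(all(miss$nSAE == 200))   # U = 100, O = 100
  expect_true(all(miss$wnSAE == 300))  # 2 * 100 + 100

  # loop-based recomputation of every cell
  tru <- c(rep(15, 5), rep(4.5, 5), rep(0.5, 5))
  for (i in seq_len(nrow(g))) {
    t <- g$n_true_detected[i]; f <- g$n_false_positive[i]
    det <- rep(FALSE, 15)
    if (t > 0) det[c(seq_len(t / 3), 5 + seq_len(t / 3), 10 + seq_len(t / 3))] <- TRUE
    obs <- ifelse(det, tru, 0)
    fp <- if (f > 0) rep((100 - sum(obs)) / f, f) else numeric(0)
    e_pct <- c(obs - tru, fp)
    e_cnt <- e_pct / 100 * 175000
    U <- sum(pmax(-e_pct, 0)); O <- sum(pmax(e_pct, 0)); N <- 15 + f
    expect_equal(g$nSAE[i], U + O)
    expect_equal(g$wnSAE[i], 2 * U + O)
    expect_equal(g$SAE[i], sum(pmax(-e_cnt, 0)) + sum(pmax(e_cnt, 0)))
    expect_equal(g$nRMSE[i], sqrt(sum(e_pct^2) / N))
    expect_equal(g$wnRMSE[i],
                 sqrt((2 * sum(pmax(-e_pct, 0)^2) + sum(pmax(e_pct, 0)^2)) / N))
    expect_equal(g$RMSE[i], sqrt(sum(e_cnt^2) / N))
  }
})

test_that("grid correlations recover analytic cases", {
  fake <- tidyr::expand_grid(n_true_detected = seq(0, 15, 3),
                             n_false_positive = seq(0, 15, 3))
  fake$exact_type2 <- 15 - fake$n_true_detected
  fake$flat <- 7
  rc <- grid_correlations(fake, n_truth = 15)
  expect_equal(rc$r_type2[rc$metric == "exact_type2"], 1)
  expect_equal(rc$r_type1[rc$metric == "exact_type2"], 0)
  expect_true(is.na(rc$r_type1[rc$metric == "flat"]))
  expect_true(is.na(rc$r_mean[rc$metric == "flat"]))
})
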