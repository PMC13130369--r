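test_that("confusion sets follow set identities", {
  truth <- default_truth()
  fp_names <- paste("falsum", c("unum", "duo", "tria"))
  prof <- classification_profile(
    stats::setNames(c(rep(100, 5), rep(50, 3)),
                    c(truth$taxon[1:5], fp_names)))
  conf <- taxa_confusion(prof, truth)
  expect_length(conf$tp, 5)
  expect_length(conf$fp, 3)
  expect_length(conf$fn, 10)

  perfect <- classification_profile(stats::setNames(rep(10, 15), truth$taxon))
  conf <- taxa_confusion(perfect, truth)
  expect_length(conf$fp, 0)
  expect_length(conf$fn, 0)

  for (s in 1:10) {
    p <- random_profile(s)
    tr <- random_truth(s + 100)
    conf <- taxa_confusion(p, tr)
    det <- unique(canonicalize_name(p$taxon))
    pres <- unique(canonicalize_name(tr$taxon))
    expect_setequal(conf$tp, det[det %in% pres])
    expect_setequal(conf$fp, det[!det %in% pres])
    expect_setequal(conf$fn, pres[!pres %in% det])
  }
})

test_that("the detection panel matches its defining ratios", {
  truth <- default_truth()
  # 5 true + 3 false detected; true taxa carry 600 of 1000 total reads,
  # 150 reads sit on false positives, 250 reads unmapped
  prof <- classification_profile(
    stats::setNames(c(rep(120, 5), rep(50, 3)),
                    c(truth$taxon[1:5], paste("falsum", c("unum", "duo", "tria")))),
    total_reads = 1000)
  rep <- detection_report(prof, truth)
  expect_equal(rep$taxa_sensitivity, 100 * 5 / 15)
  expect_equal(rep$taxa_selectivity, 100 * 5 / 8)
  expect_equal(rep$read_sensitivity, 100 * 600 / 1000)
  expect_equal(rep$read_selectivity, 100 * 600 / 750)
  expect_equal(rep$false_positivity_rate, 100 * 3 / 8)
  expect_equal(rep$taxa_selectivity + rep$false_positivity_rate, 100)
  expect_equal(rep$surveillance_score,
               (rep$taxa_sensitivity * rep$taxa_selectivity +
                  rep$read_sensitivity * rep$read_selectivity) / 200)

  perfect <- classification_profile(
    stats::setNames(truth$abundance_pct * 10, truth$taxon))
  rp <- detection_report(perfect, truth)
  expect_equal(rp$taxa_sensitivity, 100)
  expect_equal(rp$read_selectivity, 100)
  expect_equal(rp$surveillance_score, 100)

  # nothing detected: selectivities are missing, not zero
  none <- classification_profile(tibble::tibble(taxon = character(), count = numeric()),
                                 total_reads = 100)
  rn <- detection_report(none, truth)
  expect_true(is.na(rn$taxa_selectivity))
  expect_true(is.na(rn$surveillance_score))
  expect_equal(rn$taxa_sensitivity, 0)
})

test_that("the surveillance score reproduces worked table rows", {
  expect_equal(round(surveillance_score(11.1, 100, 0.07, 100), 1), 5.6)
  expect_equal(round(surveillance_score(57.8, 81.3, 72.5, 85.2), 1), 54.4)
  expect_equal(round(surveillance_score(24.4, 78.6, 1.1, 95.4), 1), 10.1)
  expect_equal(surveillance_score(100, 100, 100, 100), 100)
})

test_that("detection scores are invariant under read doubling", {
  truth <- default_truth()
  sim <- simulate_classification(truth, 20000, confusion_params(seed = 9))
  r1 <- detection_report(sim, truth)
  r2 <- detection_report(double_reads(sim), truth)
  for (m in c("taxa_sensitivity", "taxa_selectivity", "read_sensitivity",
              "read_selectivity", "surveillance_score")) {
    expect_equal(r1[[m]], r2[[m]])
  }
})

test_that("tier sensitivity counts detections per abundance tier", {
  truth <- default_truth()
  # all main and 3 mid detected, no rare
  prof <- classification_profile(
    stats::setNames(rep(10, 8), truth$taxon[c(1:5, 6:8)]))
  ts <- tier_sensitivity(prof, truth)
  expect_equal(ts$sensitivity[ts$tier == "main"], 100)
  expect_equal(ts$sensitivity[ts$tier == "mid"], 60)
  expect_equal(ts$sensitivity[ts$tier == "rare"], 0)

  none <- classification_profile(tibble::tibble(taxon = character(), count = numeric()),
                                 total_reads = 10)
  expect_true(all(tier_sensitivity(none, truth)$sensitivity == 0))

  for (s in 1:5) {
    mask <- withr::with_seed(s, runif(15) < 0.5)
    prof <- classification_profile(stats::setNames(rep(5, sum(mask)),
                                                   truth$taxon[mask]))
    ts <- tier_sensitivity(prof, truth)
    for (tier in c("main", "mid", "rare")) {
      in_tier <- truth$tier == tier
      expect_equal(ts$sensitivity[ts$tier == tier],
                   100 * sum(mask & in_tier) / sum(in_tier))
    }
  }
})

test_that("improvement arithmetic follows both conventions", {
  expect_equal(round(relative_change(11.1, 37.8), 1), 240.5)
  expect_equal(round(relative_change(45.4, 81.3), 1), 79.1)
  expect_equal(round(relative_change(56.2, 66.7), 1), 18.7)
  expect_equal(relative_change(33.3, 33.3), 0)
  expect_error(relative_change(0, 10), "zero baseline")

  expect_equal(absolute_error_reduction(+115.6, -20.0), 95.6)
  expect_equal(absolute_error_reduction(174.8, 0.5), 174.3)
  expect_equal(absolute_error_reduction(-7.5, -7.5), 0)
})
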