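test_that("Shannon entropy (natural log) matches the closed form", {
  tier_vec <- c(rep(15, 5), rep(4.5, 5), rep(0.5, 5))
  expect_equal(round(shannon(tier_vec), 2), 2.25)
  expect_equal(shannon(rep(1, 7)), log(7))
  expect_equal(shannon(c(42)), 0)
  expect_error(shannon(c(0, 0)), "positive sum")
  expect_error(shannon(c(-1, 2)), "non-negative")

  # hand-computed -sum(p log p) on random vectors
  for (s in 1:10) {
    x <- withr::with_seed(s, runif(9))
    p <- x / sum(x)
    expect_equal(shannon(x), -sum(p * log(p)))
  }
  # maximal for the uniform vector at fixed richness
  for (s in 1:5) {
    x <- withr::with_seed(s, runif(9))
    expect_lte(shannon(x), shannon(rep(1, 9)))
  }
})

test_that("Pielou evenness is Shannon over log richness", {
  tier_vec <- c(rep(15, 5), rep(4.5, 5), rep(0.5, 5))
  expect_equal(round(pielou(tier_vec), 2), 0.83)
  expect_equal(pielou(rep(3, 12)), 1)
  expect_warning(expect_true(is.na(pielou(c(5)))), "undefined")
  for (s in 1:10) {
    x <- withr::with_seed(s, runif(6, min = 0.01))
    e <- pielou(x)
    expect_gt(e, 0); expect_lte(e, 1)
    expect_equal(e, shannon(x) / log(6))
  }
})

test_that("Chao1 uses the bias-corrected singleton/doubleton form", {
  expect_equal(chao1(c(5, 10, 20)), 3)          # no singletons: observed richness
  expect_equal(chao1(c(1, 1, 2)), 3.5)          # 3 + 2*1/(2*2)
  expect_equal(chao1(c(1, 5, 5)), 3)            # F1=1: 3 + 1*0/(2*1)
  expect_error(chao1(c(1.5, 2)), "integer")
  # selectivity-filtered profiles (all counts > 2) carry no Chao1 benefit
  for (s in 1:5) {
    x <- withr::with_seed(s, sample(3:50, 10))
    expect_equal(chao1(x), 10)
  }
  # direct formula on random count vectors
  for (s in 1:10) {
    x <- withr::with_seed(s + 20, sample(1:6, 12, replace = TRUE))
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    expect_equal(chao1(x), 12 + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
})

test_that("Bray-Curtis dissimilarity is one minus shared abundance", {
  a <- classification_profile(c(A = 50, B = 30, C = 20))
  expect_equal(bray_curtis(a, a), 0)
  b <- classification_profile(c(D = 70, E = 30))
  expect_equal(bray_curtis(a, b), 1)

  for (s in 1:10) {
    p <- random_profile(s); q <- random_profile(s + 30)
    got <- bray_curtis(p, q)
    # brute-force union scan on normalized vectors
    vp <- stats::setNames(p$count / sum(p$count), canonicalize_name(p$taxon))
    vq <- stats::setNames(q$count / sum(q$count), canonicalize_name(q$taxon))
    shared <- sum(vapply(union(names(vp), names(vq)), function(t) {
      min(if (t %in% names(vp)) vp[[t]] else 0,
          if (t %in% names(vq)) vq[[t]] else 0)
    }, numeric(1)))
    expect_equal(got, 1 - shared)
    expect_equal(got, bray_curtis(q, p))        # symmetry
    expect_gte(got, 0); expect_lte(got, 1)
  }

  empty <- classification_profile(tibble::tibble(taxon = character(), count = numeric()),
                                  total_reads = 5)
  expect_error(bray_curtis(a, empty), "empty|denominator")

  m <- bray_curtis_matrix(list(x = a, y = b, z = a))
  expect_equal(m["x", "z"], 0)
  expect_equal(m["x", "y"], 1)
  expect_equal(m, t(m))
})

test_that("the diversity score averages absolute percent errors", {
  expect_equal(round(diversity_score(c(-20.0, +14.4, +4.9, -3.6)), 1), 89.3)
  expect_equal(diversity_score(c(0, 0, 0, 0)), 100)
  expect_equal(diversity_score(c(100, 100, 100, 100)), 0)
  # invariant to the sign of each input error
  errs <- c(-12.5, 30, -7, 2)
  expect_equal(diversity_score(errs), diversity_score(abs(errs)))
  expect_error(diversity_score(c(1, NA)), "finite")
})

test_that("alpha reports collapse variants before counting", {
  prof <- classification_profile(c(`Species a|v1` = 10, `Species a|v2` = 5,
                                   `Species b` = 2, `Species c` = 1))
  a <- alpha_report(prof)
  expect_equal(a$richness, 3)
  expect_equal(a$chao1, 3 + 1 * 0 / (2 * 2))    # one singleton, one doubleton
  expect_equal(a$shannon, shannon(c(15, 2, 1)))
})

test_that("replicate/site precision compares replicate means with site unions", {
  expect_equal(round(replicate_site_ratio(320.0, 611.0), 1), 52.4)
  expect_equal(replicate_site_ratio(c(10, 10, 10), c(10, 10, 10)), 100)
  expect_error(replicate_site_ratio(c(1, 2), c(0, 0)), "zero")

  # synthetic 3-site / 3-replicate design against a loop oracle
  profs <- list(); sites <- character()
  k <- 0
  for (s in 1:3) for (r in 1:3) {
    k <- k + 1
    profs[[k]] <- random_profile(100 * s + r, n_taxa = 10)
    sites[k] <- paste0("site", s)
  }
  rp <- richness_precision(profs, sites)
  rep_vals <- vapply(profs, function(p) length(unique(canonicalize_name(p$taxon))),
                     numeric(1))
  site_vals <- vapply(paste0("site", 1:3), function(s) {
    length(unique(unlist(lapply(profs[sites == s],
                                function(p) canonicalize_name(p$taxon)))))
  }, numeric(1))
  expect_equal(rp$ratio, 100 * mean(rep_vals) / mean(site_vals))
  expect_lte(rp$ratio, 100)
})
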