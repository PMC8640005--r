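test_that("exposure profiles follow the windowed-DDD rules", {
  rec <- data.frame(
    participant_id = "P1",
    age_at_purchase = c(3, 9.5, 11),
    drug_class = "cephalosporin_1_2",
    ddd = c(10, 7, 5))
  samp <- data.frame(participant_id = "P1", sampling_age = 13.0)
  e <- build_exposures(rec, samp)
  expect_equal(e$cephalosporin_1_2_ddd_to_10, 17)
  expect_equal(e$cephalosporin_1_2_ddd_lifetime, 22)
  expect_equal(e$cephalosporin_1_2_courses, 3)
  expect_equal(e$cephalosporin_1_2_time_since_last, 2)

  rec2 <- data.frame(participant_id = "P1", age_at_purchase = 12.2,
                     drug_class = "macrolide", ddd = 4)
  e2 <- build_exposures(rec2, samp)
  expect_equal(e2$macrolide_time_since_last, 0.8)
  # never exposed: zero counts and the +Inf sentinel
  expect_equal(e2$penicillin_courses, 0)
  expect_equal(e2$penicillin_time_since_last, Inf)

  rec3 <- data.frame(participant_id = "P1", age_at_purchase = 13.5,
                     drug_class = "penicillin", ddd = 4)
  expect_warning(e3 <- build_exposures(rec3, samp), "after sampling")
  expect_equal(e3$penicillin_courses, 0)
})

test_that("windowed DDD sums are monotone and bounded by lifetime", {
  set.seed(67)
  cfg <- scenario_config()
  md <- generate_metadata(cfg, sprintf("P%02d", 1:25), "female", 7)
  e <- build_exposures(md$records,
                       data.frame(participant_id = sprintf("P%02d", 1:25),
                                  sampling_age = 13))
  for (cl in DRUG_CLASSES) {
    w2 <- e[[paste0(cl, "_ddd_to_2")]]
    w5 <- e[[paste0(cl, "_ddd_to_5")]]
    w10 <- e[[paste0(cl, "_ddd_to_10")]]
    lt <- e[[paste0(cl, "_ddd_lifetime")]]
    expect_true(all(w2 <= w5 & w5 <= w10 & w10 <= lt))
  }
  # the sentinel is re-coded, never dropped
  cand <- exposure_candidates(e, rep(13, 25))
  expect_true(all(is.finite(as.matrix(cand))))
})

test_that("AIC follows 2k - 2*loglik", {
  expect_equal(aic(-100, 3), 206)
  expect_equal(aic(-100, 4) - aic(-100, 3), 2)
  expect_error(aic(NaN, 2), "finite")
})

test_that("the screen selects the generating candidate and logs a trace", {
  set.seed(71)
  n <- 80
  cand <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 * cand$b + rnorm(n, 0, 0.5)
  s <- screen_exposures(y, cand)
  expect_equal(s$best, "b")
  expect_equal(nrow(s$trace), 3)
  expect_true(all(s$trace$aic[!s$trace$skipped] >= s$aic))

  # constant candidates are skipped; exact AIC ties break by order
  cand2 <- data.frame(k = rep(1, n), dup1 = cand$b, dup2 = cand$b)
  s2 <- screen_exposures(y, cand2)
  expect_true(s2$trace$skipped[1])
  expect_equal(s2$best, "dup1")
})

test_that("stepwise selection finds planted terms and is locally optimal", {
  set.seed(73)
  n <- 120
  pool <- as.data.frame(matrix(rnorm(n * 10), n,
                               dimnames = list(NULL, paste0("v", 1:10))))
  y <- 1.5 * pool$v2 - 1.2 * pool$v7 + rnorm(n, 0, 0.8)
  mv <- multivariate_timing_model(y, pool)
  expect_true(all(c("v2", "v7") %in% mv$terms))

  # local optimum: dropping any selected term raises AIC
  for (tm in mv$terms) {
    reduced <- lm(stats::reformulate(setdiff(mv$terms, tm),
                                     response = "y"),
                  data = cbind(pool, y = y))
    expect_gt(AIC(reduced), mv$aic)
  }
  # trace is replayable: winning moves strictly decrease AIC
  taken <- mv$steps[mv$steps$taken, ]
  expect_true(all(diff(c(Inf, taken$aic)) < 0))
})

test_that("a pure-noise pool yields a small final model", {
  set.seed(79)
  sizes <- replicate(20, {
    n <- 60
    pool <- as.data.frame(matrix(rnorm(n * 8), n,
                                 dimnames = list(NULL, paste0("v", 1:8))))
    length(multivariate_timing_model(rnorm(n), pool)$terms)
  })
  expect_lte(median(sizes), 2)
})

test_that("oversized candidate pools are pre-filtered by univariate AIC", {
  set.seed(83)
  n <- 30
  pool <- as.data.frame(matrix(rnorm(n * 40), n,
                               dimnames = list(NULL, paste0("v", 1:40))))
  mv <- multivariate_timing_model(rnorm(n), pool)
  expect_gt(length(mv$prefiltered), 0)
  expect_lte(40 - length(mv$prefiltered), n / 5)
})
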