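test_that("velocity computation applies the greedy six-month rule", {
  v <- compute_velocities(c(10.0, 10.5), c(140.0, 143.0))
  expect_equal(v$velocity, 6.0)
  expect_equal(v$age, 10.25)

  # a measurement 0.3 y after the previous retained one is skipped
  v2 <- compute_velocities(c(10.0, 10.3, 10.7), c(140.0, 141.0, 143.0))
  expect_equal(nrow(v2), 1L)
  expect_equal(v2$velocity, 3 / 0.7)
  expect_equal(v2$age, 10.35)

  expect_equal(nrow(compute_velocities(10, 140)), 0L)
  expect_equal(nrow(compute_velocities(c(10, 10.2), c(140, 141))), 0L)
  expect_error(compute_velocities(c(10, 10), c(140, 141)),
               "strictly increasing")
})

test_that("every greedy velocity interval spans at least six months", {
  set.seed(11)
  for (rep in 1:20) {
    ages <- sort(runif(sample(3:15, 1), 5, 14))
    ages <- ages[c(TRUE, diff(ages) > 1e-6)]
    if (length(ages) < 2) next
    v <- compute_velocities(ages, 100 + cumsum(runif(length(ages), 0, 3)))
    if (nrow(v) > 0)
      expect_true(all(v$end_age - v$start_age >= 0.5))
  }
})

test_that("take-off requires a crossing followed by sustained acceleration", {
  ref <- flat_reference()  # mean 5, sd 0.5 -> thresholds 6 and 5.5

  flat <- velocity_frame(seq(9, 13, 0.5), rep(5.2, 9))
  expect_true(is.na(detect_takeoff(flat, ref)))

  # isolated spike, then velocities below mean + 1 SD
  spike <- velocity_frame(seq(9, 12, 0.5), c(5, 5, 7.5, 5.2, 5.1, 5.0, 5.0))
  expect_true(is.na(detect_takeoff(spike, ref)))

  # monotone rise crossing 2 SD at 10.5, peaking at 11.5
  rise <- velocity_frame(seq(9, 13, 0.5),
                         c(5.0, 5.2, 5.5, 6.5, 7.0, 8.0, 7.0, 6.0, 5.6))
  expect_equal(detect_takeoff(rise, ref), 10.5)
})

test_that("APHV is the filtered argmax, censored at the record edge", {
  v <- velocity_frame(c(7.5, 10.0, 11.5, 12.5), c(6.0, 5.0, 8.2, 6.1))
  expect_equal(detect_aphv(v, "female"), 11.5)
  expect_equal(detect_aphv(v, "male"), 11.5)

  early <- velocity_frame(c(6, 7, 7.9), c(6, 7, 8))
  expect_true(is.na(detect_aphv(early, "female")))

  # max on the final velocity point: peak not yet observed
  rising <- velocity_frame(c(10, 11, 12), c(5, 6, 7))
  expect_true(is.na(detect_aphv(rising, "female")))
})

test_that("APHV matches a brute-force argmax on random fixtures", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    v <- velocity_frame(sort(runif(n, 6, 13)), runif(n, 3, 9))
    for (sex in c("female", "male")) {
      min_age <- if (sex == "female") 8 else 9
      keep <- v$age > min_age
      expected <- if (!any(keep)) NA_real_ else {
        cand <- v[keep, ]
        best <- cand$age[which.max(cand$velocity)]
        if (best == max(v$age)) NA_real_ else best
      }
      expect_identical(detect_aphv(v, sex), expected)
    }
  }
})

test_that("timing derivation imputes take-off and computes offsets", {
  t1 <- finalize_timing(NA, 12.0, 13.0)
  expect_equal(t1$takeoff_age, 11.5)
  expect_true(t1$takeoff_imputed)

  t2 <- finalize_timing(10.5, 11.5, 13.0)
  expect_equal(t2$time_from_peak, 1.5)
  expect_equal(t2$time_from_takeoff, 2.5)
  expect_false(t2$takeoff_imputed)

  t3 <- finalize_timing(12.6, 13.4, 13.0)
  expect_equal(t3$time_from_peak, -0.4)
  expect_equal(t3$stage_group, "pre_peak")

  expect_error(finalize_timing(11, NA, 13), "undeterminable")
})

test_that("stage groups partition the time axis with stated boundaries", {
  expect_equal(assign_stage(0.3, 1), "peak")
  expect_equal(assign_stage(-0.25, 0.5), "peak")
  expect_equal(assign_stage(0.5, 1), "peak")
  expect_equal(assign_stage(-0.3, 0.2), "pre_peak")
  expect_equal(assign_stage(2.0, 3), "post_peak_lt2y")
  expect_equal(assign_stage(3.0, 4), "post_peak_gt2y")
  expect_equal(assign_stage(-1, -0.5), "pre_takeoff")

  # exactly one stage per point across a dense grid
  tfp <- seq(-3, 4, by = 0.05)
  st <- assign_stage(tfp, tfp + 0.5)  # take-off 0.5 y before peak
  expect_false(anyNA(st))
  expect_true(all(st %in% c("pre_takeoff", "pre_peak", "peak",
                            "post_peak_lt2y", "post_peak_gt2y")))
  # chronological ordering is respected
  expect_true(all(diff(match(st, stage_order(unique(st)))) >= 0))
})

test_that("timing_table assembles cohort timing and excludes undeterminable", {
  cfg <- scenario_config(n_girls = 12L)
  co <- generate_cohort(cfg, "female", 99)
  refs <- list(female = co$reference, male = co$reference)
  tt <- timing_table(co$growth, refs,
                     data.frame(participant_id = co$metadata$participant_id,
                                sex = co$metadata$sex),
                     cfg$sampling_age)
  expect_true(nrow(tt) + length(attr(tt, "excluded")) == 12)
  expect_true(all(tt$takeoff_age <= tt$aphv))
  expect_true(all(tt$takeoff_age[tt$takeoff_imputed] ==
                    tt$aphv[tt$takeoff_imputed] - 0.5))
})
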