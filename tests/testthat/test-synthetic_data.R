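test_that("cohort generation is deterministic per seed", {
  cfg <- scenario_config(n_girls = 10L, n_adults_per_sex = 5L)
  a <- generate_cohort(cfg, "female", 123)
  b <- generate_cohort(cfg, "female", 123)
  expect_identical(a$growth, b$growth)
  expect_identical(a$adolescents$counts, b$adolescents$counts)
  expect_identical(a$records, b$records)
  c <- generate_cohort(cfg, "female", 124)
  expect_false(identical(a$adolescents$counts, c$adolescents$counts))
})

test_that("noiseless growth curves are strictly increasing", {
  cfg <- scenario_config(height_noise_sd = 0)
  gr <- generate_growth(cfg, "female", 10, 3)
  for (p in unique(gr$growth$participant_id)) {
    h <- gr$growth$height[gr$growth$participant_id == p]
    expect_true(all(diff(h) > 0))
  }
  expect_true(all(gr$reference$sd > 0))
  expect_error(generate_growth(scenario_config(visit_ages = 5),
                               "female", 3, 1), "2 visits")
})

test_that("noiseless APHV recovery lands within half the visit spacing", {
  cfg <- scenario_config(height_noise_sd = 0, n_girls = 15L)
  gr <- generate_growth(cfg, "female", 15, 21)
  for (i in 1:15) {
    g <- gr$growth[gr$growth$participant_id ==
                     gr$truth$participant_id[i], ]
    est <- detect_aphv(compute_velocities(g$age, g$height), "female")
    if (!is.na(est))
      expect_lt(abs(est - gr$truth$true_aphv[i]), 0.26)
  }
})

test_that("generated tables pass the validators", {
  cfg <- scenario_config(n_girls = 8L, n_adults_per_sex = 6L)
  co <- generate_cohort(cfg, "male", 5)
  expect_length(co$adolescents$validation$errors, 0)
  expect_length(co$adults$validation$errors, 0)
  expect_true(all(co$adolescents$taxon_ids %in% cfg$taxonomy$taxon_id))
  if (nrow(co$records) > 0) {
    expect_true(all(co$records$ddd > 0))
    expect_true(all(co$records$drug_class %in% DRUG_CLASSES))
  }
})

test_that("theta = Inf reduces to plain multinomial sampling", {
  cfg <- scenario_config(theta = Inf, depth_sdlog = 0,
                         maturation_slope = c(female = 0, male = 0),
                         m_noise_sd = 0)
  tim <- data.frame(participant_id = sprintf("P%04d", 1:1000),
                    time_from_peak = 0)
  mb <- generate_microbiota(cfg, tim, "female", 31)
  depth <- unique(rowSums(mb$adolescents$counts))
  expect_length(depth, 1)  # fixed depth
  p <- colMeans(mb$adolescents$counts) / depth
  v_obs <- apply(mb$adolescents$counts, 2, var)
  v_mult <- depth * p * (1 - p)
  top <- order(p, decreasing = TRUE)[1:4]
  expect_true(all(abs(v_obs[top] / v_mult[top] - 1) < 0.25))

  # finite theta is overdispersed relative to the multinomial
  cfg2 <- scenario_config(theta = 50, depth_sdlog = 0,
                          maturation_slope = c(female = 0, male = 0),
                          m_noise_sd = 0)
  mb2 <- generate_microbiota(cfg2, tim, "female", 31)
  v_obs2 <- apply(mb2$adolescents$counts, 2, var)
  expect_gt(mean(v_obs2[top] / v_mult[top]), 1.5)
})

test_that("expected Clostridia abundance is monotone in pubertal progress", {
  cfg <- scenario_config(theta = Inf, m_noise_sd = 0, depth_sdlog = 0)
  tfp_grid <- seq(-2, 3, by = 0.5)
  tim <- data.frame(participant_id = sprintf("P%03d", seq_along(tfp_grid)),
                    time_from_peak = tfp_grid)
  mb <- generate_microbiota(cfg, tim, "female", 37)
  rel <- relative_abundance(mb$adolescents)
  clo <- cfg$taxonomy$taxon_id[cfg$taxonomy$class == "Clostridia"]
  bac <- cfg$taxonomy$taxon_id[cfg$taxonomy$class == "Bacteroidia"]
  clo_share <- rowSums(rel[, clo])
  bac_share <- rowSums(rel[, bac])
  expect_gt(cor(tfp_grid, clo_share, method = "spearman"), 0.9)
  expect_lt(cor(tfp_grid, bac_share, method = "spearman"), -0.9)
})

test_that("fully matured adolescents are exchangeable with adults", {
  cfg <- scenario_config(n_adults_per_sex = 40L)
  tim <- data.frame(participant_id = sprintf("P%03d", 1:30),
                    time_from_peak = 50)  # logistic saturates at m = 1
  mb <- generate_microbiota(cfg, tim, "female", 41)
  sc <- maturity_index(mb$adolescents, mb$adults,
                       rep("female", 40), "female")
  rel <- relative_abundance(mb$adults)
  lp <- log_profile(rel)
  sims <- cor(t(lp))
  adult_mean <- mean(sims[upper.tri(sims)])
  expect_lt(abs(mean(sc$maturity) - adult_mean), 0.05)
})

test_that("a written cohort reloads through the standard readers", {
  cfg <- scenario_config(n_girls = 6L, n_adults_per_sex = 4L)
  co <- generate_cohort(cfg, "female", 9)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  tab <- read_count_table(file.path(dir, "adolescent_counts.tsv"),
                          file.path(dir, "taxonomy.tsv"))
  expect_identical(tab$counts, co$adolescents$counts)
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(md), 6)
  g <- read_growth_records(file.path(dir, "growth.tsv"))
  expect_equal(sort(unique(g$participant_id)),
               sort(co$metadata$participant_id))
  ref <- read_reference_curve(file.path(dir, "reference_curve.tsv"),
                              "female")
  expect_equal(ref$mean, co$reference$mean)
  gt <- utils::read.delim(file.path(dir, "ground_truth.tsv"))
  expect_true(all(c("true_aphv", "true_takeoff", "true_m",
                    "ceph_ddd_to_10") %in% names(gt)))
})
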