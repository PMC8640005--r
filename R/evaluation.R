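#' Simulation studies of estimator performance
#'
#' These routines run the package's own methods on freshly generated
#' synthetic cohorts with known ground truth and summarize recovery,
#' power and calibration. They back the acceptance checks and are
#' exported so users can rerun them under other scenarios.
#'
#' @name evaluation
NULL

#' APHV recovery error on a synthetic cohort
#'
#' Generates one growth cohort, estimates APHV per participant with the
#' greedy-velocity pipeline, and returns the absolute errors against the
#' generator's true APHV (the argmax of each participant's velocity
#' curve). Excluded as undeterminable, mirroring the upstream exclusion
#' path of every analysis: participants whose detected peak is
#' right-censored ([detect_aphv()] returns `NA`), whose detected maximum
#' never exceeds the reference mean + 1 SD (no observable spurt, the
#' `aphv_weak` flag of [timing_table()]), or whose true APHV lies beyond
#' the last observable velocity midpoint -- no schedule can recover a
#' peak outside its observation window.
#'
#' @param config a `scenario_config`.
#' @param n cohort size.
#' @param seed RNG seed.
#' @param sex cohort sex.
#' @return numeric vector of absolute errors (years), one per
#'   participant with determinable APHV.
#' @export
evaluate_aphv_recovery <- function(config, n = 80L, seed = 1,
                                   sex = "female") {
  gr <- generate_growth(config, sex, n, seed)
  est <- weak <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- gr$growth[gr$growth$participant_id ==
                     gr$truth$participant_id[i], ]
    vel <- compute_velocities(g$age, g$height)
    est[i] <- detect_aphv(vel, sex)
    env <- eval_reference(gr$reference, vel$age)
    weak[i] <- !any(vel$velocity > env$mean + env$sd)
  }
  observable <- gr$truth$true_aphv <= max(config$visit_ages) - 0.25
  ok <- !is.na(est) & !weak & observable
  abs(est[ok] - gr$truth$true_aphv[ok])
}

#' Power / type-I error of the maturity-timing association
#'
#' Replicates full cohort generation plus the maturity index and its OLS
#' association with the true time from peak, and returns the fraction of
#' replicates with a positive association at `alpha` (for a sex with a
#' maturation gradient this is power; with slope 0 it is the type-I
#' error, in which case sign is ignored).
#'
#' @param config a `scenario_config`.
#' @param sex cohort sex.
#' @param n_reps number of replicates.
#' @param seed RNG seed.
#' @param alpha significance level.
#' @return list: `rate`, `n_reps`, per-replicate `p_values` and `slopes`.
#' @export
evaluate_maturity_power <- function(config, sex, n_reps = 50, seed = 1,
                                    alpha = 0.05) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_reps)
  null_world <- config$maturation_slope[[sex]] == 0
  p <- numeric(n_reps); b <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    co <- generate_cohort(config, sex, seeds[r])
    sc <- maturity_index(co$adolescents, co$adults,
                         rep(sex, config$n_adults_per_sex), sex)
    a <- maturity_association(sc$maturity, co$timing_true$time_from_peak)
    p[r] <- a$p_value; b[r] <- a$slope
  }
  hit <- if (null_world) p < alpha else (p < alpha & b > 0)
  list(rate = mean(hit), n_reps = n_reps, p_values = p, slopes = b)
}

#' Calibration of the per-taxon model cascade
#'
#' Simulates negative-binomial taxa with a known timing coefficient and
#' depth offset, runs [fit_cascade()], and summarizes stage-1 acceptance,
#' 95% CI coverage of the true coefficient, and (for `beta = 0`) the raw
#' rejection rate. Coverage uses profile-likelihood intervals for the
#' count models (the `confint` default for GLMs), falling back to Wald
#' intervals when profiling fails. Replicates that cascade past the
#' count models report a relative-abundance coefficient -- a different
#' estimand than the link-scale truth -- and are excluded from the
#' coverage denominator (they still count toward `stage1_rate` and the
#' rejection rate).
#'
#' @param n samples per replicate.
#' @param beta true timing coefficient on the log scale.
#' @param n_reps replicates.
#' @param seed RNG seed.
#' @param theta negative-binomial size of the simulated taxa.
#' @return list: `stage1_rate`, `coverage`, `rejection_rate`,
#'   `none_rate`, `n_reps`.
#' @export
evaluate_cascade_calibration <- function(n = 150L, beta = 0.5,
                                         n_reps = 100, seed = 1,
                                         theta = 5) {
  set.seed(seed)
  stage1 <- cover <- reject <- none <- count_scale <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    tfp <- stats::rnorm(n, 1.5, 1)
    depth <- round(stats::rlnorm(n, log(2e4), 0.3))
    y <- stats::rnbinom(n, size = theta,
                        mu = exp(-5 + beta * tfp + log(depth)))
    f <- fit_cascade(y, depth, tfp)
    stage1[r] <- f$model_used == "negbin"
    none[r] <- f$model_used == "none"
    count_scale[r] <- f$model_used %in% c("negbin", "poisson")
    if (count_scale[r]) {
      ci <- c(f$estimate - stats::qnorm(0.975) * f$se,
              f$estimate + stats::qnorm(0.975) * f$se)
      pci <- tryCatch(
        suppressWarnings(suppressMessages(
          stats::confint(f$fit, "time_from_peak"))),
        error = function(e) NULL)
      if (!is.null(pci) && all(is.finite(pci))) ci <- as.numeric(pci)
      cover[r] <- ci[1] <= beta && beta <= ci[2]
    }
    if (!none[r]) reject[r] <- f$p_value < 0.05
  }
  list(stage1_rate = mean(stage1),
       coverage = mean(cover[count_scale]),
       rejection_rate = mean(reject[!none]),
       none_rate = mean(none), n_reps = n_reps)
}

#' Recovery rate of the AIC exposure screen
#'
#' Replicates the exposure world: antibiotic purchase histories, a
#' cephalosporin DDD-to-age-10 effect of `effect` years of APHV advance
#' per DDD planted on the timing, and the AIC screen over the full
#' candidate grid. Returns how often each candidate wins.
#'
#' @param config a `scenario_config` (its `ceph_effect_per_ddd` is
#'   overridden by `effect`).
#' @param effect planted effect size (0 for the null world).
#' @param n_reps replicates.
#' @param seed RNG seed.
#' @param n participants per replicate.
#' @return list: `target_rate` (fraction of wins for
#'   `cephalosporin_1_2_ddd_to_10`), `wins` (table), `n_reps`.
#' @export
evaluate_exposure_screen <- function(config, effect = 0.15,
                                     n_reps = 100, seed = 1, n = 80L) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_reps)
  wins <- character(n_reps)
  pid <- sprintf("P%03d", seq_len(n))
  samp <- data.frame(participant_id = pid,
                     sampling_age = config$sampling_age)
  for (r in seq_len(n_reps)) {
    md <- generate_metadata(config, pid, "female", seeds[r])
    expo <- build_exposures(md$records, samp)
    set.seed(seeds[r] + 1)
    aphv <- stats::rnorm(n, config$aphv_mean[["female"]],
                         config$aphv_sd) -
      effect * expo$cephalosporin_1_2_ddd_to_10
    tfp <- config$sampling_age - aphv
    wins[r] <- screen_exposures(
      tfp, exposure_candidates(expo, samp$sampling_age))$best
  }
  list(target_rate = mean(wins == "cephalosporin_1_2_ddd_to_10"),
       wins = table(wins), n_reps = n_reps)
}

#' Directional properties of the maturation gradient
#'
#' Pools several girl cohorts, assigns true stage groups, and checks the
#' qualitative pattern: Clostridia relative abundance increases and
#' Bacteroidia decreases across stage-group means (Spearman rank
#' correlation with stage order), and the summed PC1+PC2 ordination
#' score is higher post-peak than pre-peak.
#'
#' @param config a `scenario_config`.
#' @param n_seeds number of cohorts pooled.
#' @param seed RNG seed.
#' @return list: `clostridia_rank_cor`, `bacteroidia_rank_cor`,
#'   `score_diff_post_minus_pre`, `stage_counts`.
#' @export
evaluate_direction_properties <- function(config, n_seeds = 5, seed = 1) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_seeds)
  clo_ids <- config$taxonomy$taxon_id[config$taxonomy$class == "Clostridia"]
  bac_ids <- config$taxonomy$taxon_id[config$taxonomy$class == "Bacteroidia"]
  stage <- character(0); clo <- bac <- score <- numeric(0)
  for (s in seeds) {
    co <- generate_cohort(config, "female", s)
    rel <- relative_abundance(co$adolescents)
    st <- assign_stage(co$timing_true$time_from_peak,
                       co$timing_true$time_from_takeoff)
    joint <- count_table(rbind(co$adolescents$counts, co$adults$counts))
    pc <- pcoa(bray_curtis(relative_abundance(joint)))
    sc <- pc_sum_score(pc, co$adults$sample_ids)
    stage <- c(stage, st)
    clo <- c(clo, rowSums(rel[, clo_ids]))
    bac <- c(bac, rowSums(rel[, bac_ids]))
    score <- c(score, sc[co$adolescents$sample_ids])
  }
  lv <- stage_order(unique(stage))
  gm <- function(x) vapply(lv, function(g) mean(x[stage == g]), 0)
  rank_cor <- function(x) stats::cor(seq_along(lv), gm(x),
                                     method = "spearman")
  pre <- stage %in% c("pre_takeoff", "pre_peak")
  post <- stage %in% c("post_peak_lt2y", "post_peak_gt2y")
  list(clostridia_rank_cor = rank_cor(clo),
       bacteroidia_rank_cor = rank_cor(bac),
       score_diff_post_minus_pre = mean(score[post]) - mean(score[pre]),
       stage_counts = table(factor(stage, levels = lv)))
}
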