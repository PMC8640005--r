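#' Default taxon tree for synthetic communities
#'
#' Sixteen leaf taxa across three groups: the class Clostridia
#' (Ruminococcaceae: Anaerofilum, Anaerotruncus, Subdoligranulum,
#' Faecalibacterium; Lachnospiraceae: Dorea, Syntrophococcus), the class
#' Bacteroidia (Bacteroides, Barnesiella, Paludibacter,
#' Macellibacteroides) and minor taxa (Streptococcus, Lactobacillus,
#' Coriobacteriaceae, Escherichia, Neisseriaceae, Pasteurellaceae).
#' Family-level leaves carry explicit `NA` genus/species ranks.
#'
#' @return taxonomy data.frame (`taxon_id` + seven ranks).
#' @export
default_taxon_tree <- function() {
  L <- function(id, phylum, class, order, family, genus = NA, species = NA)
    data.frame(taxon_id = id, kingdom = "Bacteria", phylum = phylum,
               class = class, order = order, family = family,
               genus = genus, species = species, stringsAsFactors = FALSE)
  rum <- function(g) L(paste0(g, "_sp"), "Firmicutes", "Clostridia",
                       "Clostridiales", "Ruminococcaceae", g,
                       paste0(g, "_sp"))
  lac <- function(g) L(paste0(g, "_sp"), "Firmicutes", "Clostridia",
                       "Clostridiales", "Lachnospiraceae", g,
                       paste0(g, "_sp"))
  bac <- function(g, fam) L(paste0(g, "_sp"), "Bacteroidetes",
                            "Bacteroidia", "Bacteroidales", fam, g,
                            paste0(g, "_sp"))
  rbind(
    rum("Anaerofilum"), rum("Anaerotruncus"), rum("Subdoligranulum"),
    rum("Faecalibacterium"),
    lac("Dorea"), lac("Syntrophococcus"),
    bac("Bacteroides", "Bacteroidaceae"),
    bac("Barnesiella", "Barnesiellaceae"),
    bac("Paludibacter", "Porphyromonadaceae"),
    bac("Macellibacteroides", "Porphyromonadaceae"),
    L("Streptococcus_sp", "Firmicutes", "Bacilli", "Lactobacillales",
      "Streptococcaceae", "Streptococcus", "Streptococcus_sp"),
    L("Lactobacillus_sp", "Firmicutes", "Bacilli", "Lactobacillales",
      "Lactobacillaceae", "Lactobacillus", "Lactobacillus_sp"),
    L("Coriobacteriaceae_unc", "Actinobacteria", "Coriobacteriia",
      "Coriobacteriales", "Coriobacteriaceae"),
    L("Escherichia_sp", "Proteobacteria", "Gammaproteobacteria",
      "Enterobacterales", "Enterobacteriaceae", "Escherichia",
      "Escherichia_sp"),
    L("Neisseriaceae_unc", "Proteobacteria", "Betaproteobacteria",
      "Neisseriales", "Neisseriaceae"),
    L("Pasteurellaceae_unc", "Proteobacteria", "Gammaproteobacteria",
      "Pasteurellales", "Pasteurellaceae")
  )
}

#' Scenario configuration for the synthetic cohort generator
#'
#' Defaults state the emulated world: 80 adolescents per sex sampled near
#' the 13-year follow-up, 100 adults per sex, APHV normally distributed at
#' 11.5 y (girls) / 13.5 y (boys) with SD 1 y, a Gaussian growth spurt of
#' amplitude 5 cm/y and width 0.7 y on an exponentially decaying
#' prepubertal velocity, six-monthly height measurements from age 2 with
#' 0.3 cm noise, a maturation gradient on the microbiota with slope 0.8
#' per year in girls and 0 in boys, Dirichlet-multinomial counts, and a
#' Poisson antibiotic-purchase process. All ground-truth parameters are
#' carried in the returned object.
#'
#' @param ... overrides of any default field.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(...) {
  tax <- default_taxon_tree()
  child <- c(0.01, 0.01, 0.03, 0.10, 0.04, 0.01,          # Clostridia 0.20
             0.30, 0.08, 0.06, 0.06,                       # Bacteroidia 0.50
             0.08, 0.05, 0.05, 0.06, 0.03, 0.03)           # minor 0.30
  adult <- c(0.03, 0.03, 0.06, 0.18, 0.07, 0.03,           # Clostridia 0.40
             0.22, 0.03, 0.02, 0.02,                       # Bacteroidia 0.29
             0.04, 0.03, 0.06, 0.08, 0.05, 0.05)           # minor 0.31
  names(child) <- names(adult) <- tax$taxon_id
  cfg <- list(
    n_girls = 80L, n_boys = 80L, n_adults_per_sex = 100L,
    sampling_age = 13.0,
    # growth
    aphv_mean = c(female = 11.5, male = 13.5), aphv_sd = 1.0,
    spurt_amplitude = 5.0, spurt_width = 0.7,
    v0_mean = 18.0, v0_sd = 1.5, decay_mean = 0.15, decay_sd = 0.015,
    birth_length = 50.0,
    visit_ages = seq(2, 13.5, by = 0.5), height_noise_sd = 0.3,
    # microbiota
    taxonomy = tax, child_composition = child, adult_composition = adult,
    maturation_slope = c(female = 0.8, male = 0.0), m_noise_sd = 0.5,
    theta = 200, depth_meanlog = log(2e4), depth_sdlog = 0.3,
    # metadata / exposures
    bmi_mean = c(female = 19.5, male = 19.8), bmi_sd = 2.5,
    whole_grain_shape = 2, whole_grain_scale = 1,
    flatulence_prob = 0.3, probiotic_prob = 0.5,
    abx_rates = c(cephalosporin_1_2 = 0.06, macrolide = 0.05,
                  penicillin = 0.12, other = 0.05),   # courses / year
    ddd_meanlog = log(8), ddd_sdlog = 0.4,
    ceph_effect_per_ddd = 0.0   # years of APHV advance per DDD-to-age-10
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L)
    stop("unknown scenario fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (abs(sum(cfg$child_composition) - 1) > 1e-8 ||
      abs(sum(cfg$adult_composition) - 1) > 1e-8)
    stop("composition vectors must sum to 1")
  if (is.finite(cfg$theta) && cfg$theta <= 0) stop("theta must be positive")
  structure(cfg, class = "scenario_config")
}

velocity_curve <- function(t, v0, a, A, aphv, sigma) {
  v0 * exp(-a * t) + A * exp(-(t - aphv)^2 / (2 * sigma^2))
}

height_curve <- function(t, v0, a, A, aphv, sigma, birth_length) {
  # closed-form integral of the velocity model from 0 to t
  birth_length + v0 / a * (1 - exp(-a * t)) +
    A * sigma * sqrt(2 * pi) *
      (stats::pnorm((t - aphv) / sigma) - stats::pnorm(-aphv / sigma))
}

#' Generate longitudinal growth data with a parametric pubertal spurt
#'
#' Individual velocity is `v(t) = v0 exp(-a t) + A exp(-(t - APHV)^2 /
#' (2 sigma^2))`; heights follow its exact integral from a birth length,
#' observed on the visit schedule with Gaussian noise. The reference
#' velocity curve is the age-gridded mean and SD of the prepubertal
#' component (`v0 exp(-a t)`) across the simulated population.
#'
#' @param config a `scenario_config`.
#' @param sex `"female"` or `"male"`.
#' @param n number of participants.
#' @param seed RNG seed.
#' @param aphv_override optional vector of true APHVs (used when exposure
#'   effects have shifted them); otherwise drawn from the configured
#'   normal distribution.
#' @return list: `growth` (long data.frame), `reference`
#'   (a `reference_velocity_curve`), `truth` (per-participant true APHV,
#'   true take-off, individual curve parameters).
#' @export
generate_growth <- function(config, sex, n, seed, aphv_override = NULL) {
  if (length(config$visit_ages) < 2L)
    stop("visit schedule must contain at least 2 visits")
  set.seed(seed)
  pid <- sprintf("%s%03d", if (sex == "female") "G" else "B", seq_len(n))
  aphv <- if (is.null(aphv_override))
    stats::rnorm(n, config$aphv_mean[[sex]], config$aphv_sd)
  else aphv_override
  v0 <- stats::rnorm(n, config$v0_mean, config$v0_sd)
  a <- stats::rnorm(n, config$decay_mean, config$decay_sd)
  A <- config$spurt_amplitude; sigma <- config$spurt_width
  grid <- seq(2, 18, by = 0.25)
  pre <- sapply(seq_len(n), function(i) v0[i] * exp(-a[i] * grid))
  ref <- reference_velocity_curve(sex, grid, rowMeans(pre),
                                  apply(pre, 1, stats::sd))
  growth <- do.call(rbind, lapply(seq_len(n), function(i) {
    h <- height_curve(config$visit_ages, v0[i], a[i], A, aphv[i], sigma,
                      config$birth_length) +
      stats::rnorm(length(config$visit_ages), 0, config$height_noise_sd)
    data.frame(participant_id = pid[i], age = config$visit_ages,
               height = h, stringsAsFactors = FALSE)
  }))
  takeoff_true <- vapply(seq_len(n), function(i) {
    tt <- seq(2, aphv[i], by = 0.01)
    v <- velocity_curve(tt, v0[i], a[i], A, aphv[i], sigma)
    env <- eval_reference(ref, tt)
    hit <- which(v > env$mean + 2 * env$sd)
    if (length(hit) == 0L) NA_real_ else tt[hit[1]]
  }, 0)
  # true APHV is the argmax of the total velocity curve; the declining
  # prepubertal baseline pulls it slightly before the spurt center
  aphv_true <- vapply(seq_len(n), function(i) {
    stats::optimize(function(t)
      velocity_curve(t, v0[i], a[i], A, aphv[i], sigma),
      interval = c(aphv[i] - 2, aphv[i] + 2), maximum = TRUE)$maximum
  }, 0)
  list(growth = growth, reference = ref,
       truth = data.frame(participant_id = pid, sex = sex,
                          true_aphv = aphv_true, spurt_center = aphv,
                          true_takeoff = takeoff_true,
                          v0 = v0, decay = a, stringsAsFactors = FALSE))
}

rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

maturation_composition <- function(m, child, adult) {
  lw <- (1 - m) * log(child) + m * log(adult)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Generate adolescent and adult microbiota count tables
#'
#' Each adolescent's maturation is `m = logistic(beta_sex *
#' time_from_peak + eps)`; the community composition interpolates between
#' the child and adult compositions on the log scale (softmax of the
#' convex combination of logs), so the expected Clostridia share is
#' monotone increasing in `m`. Counts are Dirichlet-multinomial with
#' precision `theta` and log-normal depths; `theta = Inf` gives plain
#' multinomial draws. Adults are drawn at `m = 1`.
#'
#' @param config a `scenario_config`.
#' @param timings data.frame with `participant_id` and `time_from_peak`
#'   for the adolescents.
#' @param sex cohort sex.
#' @param seed RNG seed.
#' @return list: `adolescents` and `adults` (`count_table`s), `truth`
#'   (per-participant maturation `m`; per-taxon adult/child log-ratio and
#'   implied effect direction).
#' @export
generate_microbiota <- function(config, timings, sex, seed) {
  set.seed(seed)
  n <- nrow(timings)
  beta <- config$maturation_slope[[sex]]
  eps <- stats::rnorm(n, 0, config$m_noise_sd)
  m <- stats::plogis(beta * timings$time_from_peak + eps)
  child <- config$child_composition; adult <- config$adult_composition
  draw <- function(mi) {
    comp <- maturation_composition(mi, child, adult)
    depth <- max(1000L, round(stats::rlnorm(1, config$depth_meanlog,
                                            config$depth_sdlog)))
    p <- if (is.finite(config$theta)) rdirichlet(config$theta * comp)
         else comp
    as.integer(stats::rmultinom(1, depth, p))
  }
  ado <- t(vapply(m, draw, integer(length(child))))
  dimnames(ado) <- list(timings$participant_id, names(child))
  n_adult <- config$n_adults_per_sex
  adu <- t(vapply(rep(1, n_adult), draw, integer(length(child))))
  dimnames(adu) <- list(sprintf("A%s%03d", if (sex == "female") "F" else "M",
                                seq_len(n_adult)), names(child))
  lr <- log(adult) - log(child)
  list(adolescents = count_table(ado), adults = count_table(adu),
       truth = list(m = stats::setNames(m, timings$participant_id),
                    taxon_log_ratio = lr,
                    taxon_effect_direction = sign(lr) * (beta != 0),
                    beta = beta))
}

#' Generate sample metadata and antibiotic purchase histories
#'
#' BMI is normal per sex, probiotic arm Bernoulli(0.5), whole-grain
#' intake gamma, GI-symptom (flatulence) Bernoulli. Antibiotic purchases
#' follow a homogeneous Poisson process per drug class over \[0,
#' sampling_age\] with log-normal DDD per course. The configured
#' cephalosporin effect (`ceph_effect_per_ddd`, years of APHV advance per
#' cumulative DDD before age 10) is returned as ground truth; the cohort
#' orchestrator applies it to APHV before growth generation.
#'
#' @param config a `scenario_config`.
#' @param pids participant identifiers.
#' @param sex cohort sex.
#' @param seed RNG seed.
#' @return list: `metadata` (sample-level data.frame), `records`
#'   (antibiotic purchase data.frame), `truth` (planted exposure effect).
#' @export
generate_metadata <- function(config, pids, sex, seed) {
  set.seed(seed)
  n <- length(pids)
  metadata <- data.frame(
    sample_id = pids, participant_id = pids, sex = sex,
    cohort = "adolescent",
    age_at_sampling = config$sampling_age,
    bmi = stats::rnorm(n, config$bmi_mean[[sex]], config$bmi_sd),
    probiotic_arm = ifelse(stats::runif(n) < config$probiotic_prob,
                           "active", "placebo"),
    whole_grain_intake = stats::rgamma(n, shape = config$whole_grain_shape,
                                       scale = config$whole_grain_scale),
    flatulence = stats::runif(n) < config$flatulence_prob,
    stringsAsFactors = FALSE
  )
  recs <- list()
  for (i in seq_len(n)) {
    for (cl in names(config$abx_rates)) {
      k <- stats::rpois(1, config$abx_rates[[cl]] * config$sampling_age)
      if (k == 0L) next
      recs[[length(recs) + 1L]] <- data.frame(
        participant_id = pids[i],
        age_at_purchase = sort(stats::runif(k, 0, config$sampling_age)),
        drug_class = cl,
        ddd = stats::rlnorm(k, config$ddd_meanlog, config$ddd_sdlog),
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs) > 0L) do.call(rbind, recs) else
    data.frame(participant_id = character(0), age_at_purchase = numeric(0),
               drug_class = character(0), ddd = numeric(0))
  list(metadata = metadata, records = records,
       truth = list(ceph_effect_per_ddd = config$ceph_effect_per_ddd))
}

#' Generate a complete synthetic cohort for one sex
#'
#' Orchestrates metadata (including the antibiotic process), applies any
#' planted cephalosporin effect to the true APHVs, generates growth data,
#' derives true timing, and generates the microbiota from the true time
#' from peak. Everything needed to score recovery is in `$truth`.
#'
#' @param config a `scenario_config`.
#' @param sex `"female"` or `"male"`.
#' @param seed RNG seed; sub-stage seeds are derived from it.
#' @return list with elements `growth`, `reference`, `metadata`,
#'   `records`, `adolescents`, `adults`, `timing_true`, `truth`, `config`.
#' @export
generate_cohort <- function(config, sex, seed) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, 4)
  n <- if (sex == "female") config$n_girls else config$n_boys
  pid <- sprintf("%s%03d", if (sex == "female") "G" else "B", seq_len(n))
  md <- generate_metadata(config, pid, sex, seeds[1])
  expo <- build_exposures(md$records,
                          data.frame(participant_id = pid,
                                     sampling_age = config$sampling_age))
  set.seed(seeds[2])
  aphv_base <- stats::rnorm(n, config$aphv_mean[[sex]], config$aphv_sd)
  spurt_center <- aphv_base -
    config$ceph_effect_per_ddd * expo$cephalosporin_1_2_ddd_to_10
  gr <- generate_growth(config, sex, n, seeds[3],
                        aphv_override = spurt_center)
  timing_true <- data.frame(
    participant_id = pid,
    time_from_peak = config$sampling_age - gr$truth$true_aphv,
    time_from_takeoff = config$sampling_age - gr$truth$true_takeoff,
    stringsAsFactors = FALSE)
  mb <- generate_microbiota(config, timing_true, sex, seeds[4])
  list(growth = gr$growth, reference = gr$reference,
       metadata = md$metadata, records = md$records,
       adolescents = mb$adolescents, adults = mb$adults,
       timing_true = timing_true,
       truth = list(growth = gr$truth, microbiota = mb$truth,
                    exposure = md$truth,
                    aphv_base = aphv_base,
                    ceph_ddd_to_10 = expo$cephalosporin_1_2_ddd_to_10),
       config = config, sex = sex, seed = seed)
}

#' Write a generated cohort to a directory of TSV files
#'
#' Emits the standard delimited files (counts, taxonomy, metadata, growth,
#' antibiotic records, reference curve) plus `ground_truth.tsv`.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_count_table(cohort$adolescents, p("adolescent_counts.tsv"))
  write_count_table(cohort$adults, p("adult_counts.tsv"))
  write_taxonomy(cohort$config$taxonomy, p("taxonomy.tsv"))
  utils::write.table(cohort$metadata, p("metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$growth, p("growth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$records, p("antibiotics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_reference_curves(list(cohort$reference), p("reference_curve.tsv"))
  gt <- merge(cohort$truth$growth,
              data.frame(participant_id =
                           names(cohort$truth$microbiota$m),
                         true_m = as.numeric(cohort$truth$microbiota$m)),
              by = "participant_id")
  gt$ceph_ddd_to_10 <- cohort$truth$ceph_ddd_to_10[
    match(gt$participant_id,
          cohort$timing_true$participant_id)]
  utils::write.table(gt, p("ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
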