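#' Run the full analysis for one sex-stratified cohort
#'
#' Executes, in dependency order: pubertal-timing estimation from growth
#' records, the microbiota maturity index and its covariate-adjusted
#' association with timing, joint Bray-Curtis PCoA with adults and
#' stage-group contrasts of the summed PC1+PC2 score, the family-level
#' per-taxon model cascade, the AIC exposure screen, and the multivariate
#' timing model. All stages use the estimated (not true) timing.
#'
#' @param adolescents,adults species-level `count_table`s.
#' @param taxonomy taxonomy data.frame covering both tables.
#' @param metadata adolescent sample metadata (see
#'   [read_sample_metadata()]).
#' @param growth long growth data.frame.
#' @param records antibiotic purchase records.
#' @param reference `reference_velocity_curve` for this sex.
#' @param sex `"female"` or `"male"`.
#' @param adult_sex sexes of the adult panel samples (default: all `sex`).
#' @return list of per-stage results (`timing`, `maturity`,
#'   `maturity_association`, `pcoa`, `scores`, `contrasts`, `scan`,
#'   `exposure_screen`, `multivariate`).
#' @export
analyze_cohort <- function(adolescents, adults, taxonomy, metadata,
                           growth, records, reference, sex,
                           adult_sex = NULL) {
  if (is.null(adult_sex)) adult_sex <- rep(sex, length(adults$sample_ids))
  refs <- stats::setNames(list(reference, reference), c("female", "male"))
  sex_map <- data.frame(participant_id = metadata$participant_id,
                        sex = metadata$sex)
  samp <- data.frame(participant_id = metadata$participant_id,
                     sampling_age = metadata$age_at_sampling)
  timing <- timing_table(growth, refs, sex_map, samp)
  keep <- metadata$participant_id %in% timing$participant_id
  md <- metadata[keep, ]
  ord <- match(timing$participant_id, md$participant_id)
  md <- md[ord, ]

  sub <- function(tab, ids) {
    i <- match(ids, tab$sample_ids)
    count_table(tab$counts[i, , drop = FALSE])
  }
  ado <- sub(adolescents, md$sample_id)

  # covariates shared by maturity association and the taxon scan
  expo <- build_exposures(records,
                          data.frame(participant_id = md$participant_id,
                                     sampling_age = md$age_at_sampling))
  tsl <- do.call(pmin, expo[paste0(DRUG_CLASSES, "_time_since_last")])
  covars <- data.frame(
    probiotic = as.numeric(md$probiotic_arm == "active"),
    time_since_abx = ifelse(is.finite(tsl), tsl, md$age_at_sampling),
    bmi = md$bmi,
    whole_grain = md$whole_grain_intake
  )

  mat <- maturity_index(ado, adults, adult_sex, sex)
  mat_assoc <- maturity_association(mat$maturity, timing$time_from_peak,
                                    covars)

  rel_joint <- relative_abundance(
    count_table(rbind(ado$counts,
                      adults$counts[adult_sex == sex, , drop = FALSE])))
  pc <- pcoa(bray_curtis(rel_joint))
  adult_ids <- adults$sample_ids[adult_sex == sex]
  scores <- pc_sum_score(pc, adult_ids)
  ado_scores <- scores[md$sample_id]
  ref_group <- stage_order(unique(timing$stage_group))[1]
  contrasts <- tryCatch(
    stage_score_test(ado_scores, timing$stage_group, ref_group),
    error = function(e) e$message)

  fam <- aggregate_taxa(ado, taxonomy, "family")
  scan <- scan_taxa(fam, timing$time_from_peak, covars)

  screen <- screen_exposures(
    timing$time_from_peak,
    exposure_candidates(expo, md$age_at_sampling))

  fam_rel <- relative_abundance(fam)
  fam_log <- log_profile(fam_rel)
  colnames(fam_log) <- paste0("fam_", colnames(fam_log))
  mv_pool <- cbind(as.data.frame(fam_log),
                   exposure_candidates(expo, md$age_at_sampling),
                   bmi = md$bmi,
                   probiotic = as.numeric(md$probiotic_arm == "active"),
                   flatulence = as.numeric(md$flatulence))
  mv <- multivariate_timing_model(timing$time_from_peak, mv_pool)

  list(timing = timing, maturity = mat, maturity_association = mat_assoc,
       pcoa = pc, scores = ado_scores, contrasts = contrasts,
       scan = scan, exposure_screen = screen, multivariate = mv,
       reference_group = ref_group)
}

#' Run the end-to-end pipeline and write a report
#'
#' For each requested sex: generate (or load) the cohort, run
#' [analyze_cohort()], and write per-stage TSVs plus a consolidated
#' markdown report under `out_dir`. Re-running with the same config and
#' seed reproduces the outputs exactly.
#'
#' @param config a `scenario_config` (synthetic mode) or a list with
#'   element `inputs` naming per-sex TSV paths (`counts`, `adults`,
#'   `taxonomy`, `metadata`, `growth`, `antibiotics`, `reference`).
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param sexes which cohorts to run; a sex whose inputs are missing is
#'   skipped with a logged notice.
#' @return invisibly, the run manifest (config hash, seed, per-stage
#'   wall-times, warnings, output files).
#' @export
run_pipeline <- function(config = scenario_config(), seed = 1,
                         out_dir = tempfile("pubertome_run_"),
                         sexes = c("female", "male")) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(
    config_hash = config_hash(config), seed = seed,
    package_version = as.character(utils::packageVersion("pubertome")),
    stages = list(), warnings = character(0), outputs = character(0))
  report <- c("# pubertome pipeline report", "",
              sprintf("seed: %d; config hash: %s", seed,
                      manifest$config_hash), "")
  for (sx in sexes) {
    t0 <- proc.time()[["elapsed"]]
    cohort <- generate_cohort(config, sx,
                              seed + match(sx, c("female", "male")))
    res <- withCallingHandlers(
      analyze_cohort(cohort$adolescents, cohort$adults,
                     config$taxonomy, cohort$metadata, cohort$growth,
                     cohort$records, cohort$reference, sx),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(sx, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[sx]] <-
      list(wall_time_s = proc.time()[["elapsed"]] - t0,
           n_participants = nrow(res$timing))
    wr <- function(obj, name) {
      f <- file.path(out_dir, paste0(sx, "_", name, ".tsv"))
      utils::write.table(obj, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$outputs <<- c(manifest$outputs, f)
      f
    }
    wr(res$timing, "timing")
    wr(res$maturity, "maturity")
    wr(res$scan, "scan")
    wr(res$exposure_screen$trace, "exposure_trace")
    wr(data.frame(sample_id = names(res$scores), score = res$scores),
       "pc_scores")
    if (is.data.frame(res$contrasts)) wr(res$contrasts, "pcoa_contrasts")
    wr(res$multivariate$steps, "multivariate_steps")

    ma <- res$maturity_association
    report <- c(report, sprintf("## %s cohort (n = %d)", sx,
                                nrow(res$timing)), "",
      sprintf("- maturity ~ time_from_peak: slope %.4f (se %.4f), p = %.4g",
              ma$slope, ma$se, ma$p_value),
      sprintf("- PCoA PC1+PC2 variance: %.1f%%",
              100 * sum(res$pcoa$prop_var[1:2])),
      if (is.data.frame(res$contrasts)) sprintf(
        "- stage contrast %s vs %s: diff %.3f, p = %.4g",
        res$contrasts$group, res$reference_group,
        res$contrasts$difference, res$contrasts$p_value)
      else paste("- stage contrasts skipped:", res$contrasts),
      sprintf("- taxon scan: %d/%d taxa with p < 0.05 (family level)",
              sum(res$scan$p_value < 0.05, na.rm = TRUE),
              nrow(res$scan)),
      sprintf("- exposure screen winner: %s (p = %.4g; post-selection p-values are optimistic)",
              res$exposure_screen$best, res$exposure_screen$p_value),
      sprintf("- multivariate final model: %s (AIC %.2f)",
              if (length(res$multivariate$terms) > 0)
                paste(res$multivariate$terms, collapse = ", ")
              else "(intercept only)", res$multivariate$aic),
      "")
  }
  writeLines(report, file.path(out_dir, "report.md"))
  manifest$outputs <- c(manifest$outputs, file.path(out_dir, "report.md"))
  jsonlite::write_json(
    manifest[c("config_hash", "seed", "package_version", "warnings")],
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- substring(args[i], 3)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        out[[key]] <- args[i + 1L]; i <- i + 2L
      } else {
        out[[key]] <- TRUE; i <- i + 1L
      }
    } else i <- i + 1L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `timing`
#' (growth records to timing TSV), `run` (full pipeline). A YAML config
#' passed via `--config` may override any [scenario_config()] field.
#'
#' ```
#' pubertome simulate --sex female --seed 7 --out dir/
#' pubertome timing --growth growth.tsv --reference ref.tsv \
#'   --sex-map metadata.tsv --sampling-age 13 --out timing.tsv
#' pubertome run --seed 1 --out dir/ [--config run.yaml]
#' ```
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return exit status, invisibly.
#' @export
pubertome_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("--help", "-h")) {
    cat("usage: pubertome <simulate|timing|run|--version> [options]\n")
    return(invisible(0L))
  }
  if (args[1] == "--version") {
    cat(as.character(utils::packageVersion("pubertome")), "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  seed <- as.integer(opt$seed %||% 1)
  cfg <- scenario_config()
  if (!is.null(opt$config)) {
    over <- yaml::read_yaml(opt$config)
    cfg <- do.call(scenario_config, over)
  }
  if (cmd == "simulate") {
    sex <- opt$sex %||% "female"
    cohort <- generate_cohort(cfg, sex, seed)
    write_cohort(cohort, opt$out %||% ".")
  } else if (cmd == "timing") {
    growth <- read_growth_records(opt$growth)
    md <- utils::read.delim(opt[["sex-map"]], stringsAsFactors = FALSE)
    refs <- list(female = tryCatch(read_reference_curve(opt$reference,
                                                        "female"),
                                   error = function(e) NULL),
                 male = tryCatch(read_reference_curve(opt$reference,
                                                      "male"),
                                 error = function(e) NULL))
    samp <- if (!is.null(opt[["sampling-age"]]))
      as.numeric(opt[["sampling-age"]])
    else data.frame(participant_id = md$participant_id,
                    sampling_age = md$age_at_sampling)
    tim <- timing_table(growth, refs, md, samp)
    utils::write.table(tim, opt$out %||% "timing.tsv", sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else if (cmd == "run") {
    run_pipeline(cfg, seed = seed, out_dir = opt$out %||% "pubertome_out")
  } else {
    stop("unknown subcommand '", cmd, "'")
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
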