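#' Compute growth velocities by greedy six-month thinning
#'
#' Only measurements at least six months apart enter the velocity
#' calculation. Starting from the first measurement, the next retained
#' measurement is the earliest one at least 0.5 years later; each retained
#' pair yields one velocity point, velocity = delta height / delta age,
#' stamped at the interval midpoint.
#'
#' @param age numeric vector of measurement ages (years), strictly
#'   increasing.
#' @param height numeric vector of heights (cm), same length.
#' @return data.frame with columns `age` (midpoint), `velocity` (cm/year),
#'   `start_age`, `end_age`; zero rows if fewer than two measurements
#'   survive thinning.
#' @export
compute_velocities <- function(age, height) {
  stopifnot(length(age) == length(height))
  empty <- data.frame(age = numeric(0), velocity = numeric(0),
                      start_age = numeric(0), end_age = numeric(0))
  if (length(age) < 2L) return(empty)
  if (any(diff(age) <= 0)) stop("measurement ages must be strictly increasing")
  keep <- 1L
  last <- age[1]
  for (i in seq_along(age)[-1]) {
    if (age[i] - last >= 0.5) {
      keep <- c(keep, i)
      last <- age[i]
    }
  }
  if (length(keep) < 2L) return(empty)
  a <- age[keep]; h <- height[keep]
  data.frame(
    age = (a[-length(a)] + a[-1]) / 2,
    velocity = diff(h) / diff(a),
    start_age = a[-length(a)],
    end_age = a[-1]
  )
}

#' Construct a sex-specific reference velocity curve
#'
#' Age-gridded mean and SD of prepubertal growth velocity, evaluated by
#' linear interpolation between grid points (constant extrapolation beyond
#' the grid ends).
#'
#' @param sex `"female"` or `"male"`.
#' @param age strictly increasing age grid (years).
#' @param mean,sd mean and SD of velocity (cm/year) at each grid age;
#'   SD must be positive everywhere.
#' @return object of class `reference_velocity_curve`.
#' @export
reference_velocity_curve <- function(sex, age, mean, sd) {
  stopifnot(length(age) == length(mean), length(age) == length(sd))
  if (any(diff(age) <= 0)) stop("age grid must be strictly increasing")
  if (any(sd <= 0)) stop("reference SD must be positive everywhere")
  structure(list(sex = sex, age = age, mean = mean, sd = sd),
            class = "reference_velocity_curve")
}

#' Evaluate a reference curve at arbitrary ages
#' @param ref a `reference_velocity_curve`.
#' @param age ages (years) at which to interpolate.
#' @return data.frame with columns `mean` and `sd`.
#' @export
eval_reference <- function(ref, age) {
  data.frame(
    mean = stats::approx(ref$age, ref$mean, age, rule = 2)$y,
    sd   = stats::approx(ref$age, ref$sd,   age, rule = 2)$y
  )
}

#' Read / write a reference velocity curve as TSV
#'
#' Columns: `sex`, `age`, `mean`, `sd`; one curve per sex in the file.
#'
#' @param path TSV file.
#' @param sex which curve to extract.
#' @return a `reference_velocity_curve`.
#' @export
read_reference_curve <- function(path, sex) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d <- d[d$sex == sex, ]
  if (nrow(d) == 0L) stop("no reference curve for sex '", sex, "'")
  reference_velocity_curve(sex, d$age, d$mean, d$sd)
}

#' @rdname read_reference_curve
#' @param curves list of `reference_velocity_curve` objects.
#' @export
write_reference_curves <- function(curves, path) {
  d <- do.call(rbind, lapply(curves, function(r)
    data.frame(sex = r$sex, age = r$age, mean = r$mean, sd = r$sd)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect the age at pubertal growth take-off
#'
#' Take-off is the first velocity point exceeding the age- and sex-specific
#' reference mean + 2 SD that is followed by a period of sustained
#' acceleration: (a) the maximum subsequent velocity occurs at or after the
#' crossing, and (b) every velocity between the crossing and that maximum
#' stays above mean + 1 SD. Returns `NA` when no crossing qualifies --
#' absence is a valid outcome, not an error.
#'
#' @param velocities data.frame from [compute_velocities()], sorted by age.
#' @param ref the `reference_velocity_curve` for this participant's sex.
#' @return take-off age (years) or `NA_real_`.
#' @export
detect_takeoff <- function(velocities, ref) {
  if (nrow(velocities) == 0L) return(NA_real_)
  env <- eval_reference(ref, velocities$age)
  above2 <- which(velocities$velocity > env$mean + 2 * env$sd)
  n <- nrow(velocities)
  for (i in above2) {
    if (i == n) next  # nothing follows: no accelerated-growth period
    later <- seq(i + 1L, n)
    imax <- later[which.max(velocities$velocity[later])]
    between <- seq(i, imax)
    if (all(velocities$velocity[between] >
            env$mean[between] + env$sd[between]))
      return(velocities$age[i])
  }
  NA_real_
}

#' Detect the age at peak height velocity (APHV)
#'
#' The midpoint age of the maximal velocity among points after 8 years of
#' age for girls and 9 years for boys; ties broken to the earliest age;
#' `NA` if no points pass the age filter. A maximum sitting on the last
#' velocity point of the whole series is right-censored -- the peak has
#' not yet been observed to pass -- and also yields `NA`.
#'
#' @param velocities data.frame from [compute_velocities()], sorted by age.
#' @param sex `"female"` or `"male"`.
#' @return APHV (years) or `NA_real_`.
#' @export
detect_aphv <- function(velocities, sex) {
  min_age <- if (sex == "female") 8.0 else 9.0
  cand <- velocities[velocities$age > min_age, , drop = FALSE]
  if (nrow(cand) == 0L) return(NA_real_)
  best <- which.max(cand$velocity)
  if (cand$age[best] == velocities$age[nrow(velocities)]) return(NA_real_)
  cand$age[best]
}

#' Derive pubertal-timing variables for one participant
#'
#' Participants without a detectable APHV are excluded upstream (error
#' here). A missing take-off is imputed as APHV minus six months, flagged.
#'
#' @param takeoff take-off age or `NA`.
#' @param aphv APHV (years); must be present.
#' @param sampling_age age at fecal sampling (years).
#' @return one-row data.frame: `takeoff_age`, `aphv`, `takeoff_imputed`,
#'   `time_from_takeoff`, `time_from_peak`, `stage_group`.
#' @export
finalize_timing <- function(takeoff, aphv, sampling_age) {
  if (is.na(aphv)) stop("timing undeterminable: APHV absent")
  imputed <- is.na(takeoff)
  if (imputed) takeoff <- aphv - 0.5
  tfp <- sampling_age - aphv
  tft <- sampling_age - takeoff
  data.frame(
    takeoff_age = takeoff, aphv = aphv, takeoff_imputed = imputed,
    time_from_takeoff = tft, time_from_peak = tfp,
    stage_group = assign_stage(tfp, tft),
    stringsAsFactors = FALSE
  )
}

#' Assign the pubertal stage group
#'
#' Stages partition the time axis: `pre_takeoff` (sampling before
#' take-off), `pre_peak` (post take-off, more than three months before
#' peak), `peak` (three months before to six months after peak),
#' `post_peak_lt2y` (six months to two years after peak) and
#' `post_peak_gt2y` (more than two years after). Boundaries: -0.25 and
#' +0.5 inclusive to `peak`, +2.0 inclusive to `post_peak_lt2y`.
#'
#' @param time_from_peak sampling age minus APHV (years); vectorized.
#' @param time_from_takeoff sampling age minus take-off age (years).
#' @return character vector of stage labels.
#' @export
assign_stage <- function(time_from_peak, time_from_takeoff) {
  stopifnot(length(time_from_peak) == length(time_from_takeoff))
  out <- ifelse(time_from_takeoff < 0, "pre_takeoff",
         ifelse(time_from_peak < -0.25, "pre_peak",
         ifelse(time_from_peak <= 0.5, "peak",
         ifelse(time_from_peak <= 2.0, "post_peak_lt2y", "post_peak_gt2y"))))
  out
}

#' Pubertal timing for a cohort of growth series
#'
#' Runs velocity computation, take-off and APHV detection and timing
#' derivation for every participant in a long-format growth table.
#' Participants without a detectable APHV are dropped (reported in the
#' `"excluded"` attribute). APHVs whose velocity never exceeds the
#' reference mean + 1 SD are kept but flagged in `aphv_weak`.
#'
#' @param growth data.frame with `participant_id`, `age`, `height`.
#' @param refs named list of `reference_velocity_curve`s, names `female`
#'   and `male`.
#' @param sex_map data.frame with `participant_id`, `sex`.
#' @param sampling_age data.frame with `participant_id`, `sampling_age`,
#'   or a single number applied to all.
#' @return data.frame, one row per participant with timing variables.
#' @export
timing_table <- function(growth, refs, sex_map, sampling_age) {
  pids <- unique(growth$participant_id)
  if (is.numeric(sampling_age) && length(sampling_age) == 1L)
    sampling_age <- data.frame(participant_id = pids,
                               sampling_age = sampling_age)
  rows <- list(); excluded <- character(0)
  for (pid in pids) {
    g <- growth[growth$participant_id == pid, ]
    sex <- sex_map$sex[match(pid, sex_map$participant_id)]
    samp <- sampling_age$sampling_age[
      match(pid, sampling_age$participant_id)]
    if (is.na(sex) || is.na(samp)) {
      excluded <- c(excluded, pid); next
    }
    vel <- compute_velocities(g$age, g$height)
    aphv <- detect_aphv(vel, sex)
    if (is.na(aphv)) { excluded <- c(excluded, pid); next }
    takeoff <- detect_takeoff(vel, refs[[sex]])
    tim <- finalize_timing(takeoff, aphv, samp)
    env <- eval_reference(refs[[sex]], vel$age)
    tim <- cbind(data.frame(participant_id = pid, sex = sex,
                            sampling_age = samp,
                            stringsAsFactors = FALSE),
                 tim,
                 aphv_weak = !any(vel$velocity > env$mean + env$sd))
    rows[[length(rows) + 1L]] <- tim
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}
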