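#' Antibiotic drug classes tracked in exposure profiles
#' @export
DRUG_CLASSES <- c("cephalosporin_1_2", "macrolide", "penicillin", "other")

#' Summarize antibiotic purchase histories into exposure profiles
#'
#' For each participant and drug class: cumulative defined daily doses
#' (DDD) within each age window `[0, upper)`, lifetime DDD, lifetime
#' course count, and time since the last course at sampling. Records dated
#' after the sampling age are excluded with a warning. Participants never
#' exposed to a class get `Inf` for time since last course; for modelling,
#' [exposure_candidates()] re-codes that sentinel.
#'
#' @param records data.frame of antibiotic records
#'   (see [read_antibiotic_records()]), possibly many participants.
#' @param sampling_age data.frame with `participant_id`, `sampling_age`.
#' @param windows upper bounds (years) of the cumulative-DDD age windows.
#' @return data.frame, one row per participant in `sampling_age`, with
#'   columns `<class>_ddd_to_<w>`, `<class>_ddd_lifetime`,
#'   `<class>_courses`, `<class>_time_since_last`.
#' @export
build_exposures <- function(records, sampling_age,
                            windows = c(2, 5, 10)) {
  pids <- sampling_age$participant_id
  cols <- c(outer(DRUG_CLASSES, windows,
                  function(cl, w) paste0(cl, "_ddd_to_", w)),
            paste0(DRUG_CLASSES, "_ddd_lifetime"),
            paste0(DRUG_CLASSES, "_courses"),
            paste0(DRUG_CLASSES, "_time_since_last"))
  out <- as.data.frame(matrix(0, length(pids), length(cols),
                              dimnames = list(NULL, cols)))
  out <- cbind(data.frame(participant_id = pids,
                          stringsAsFactors = FALSE), out)
  for (cl in DRUG_CLASSES)
    out[[paste0(cl, "_time_since_last")]] <- Inf
  for (i in seq_along(pids)) {
    samp <- sampling_age$sampling_age[i]
    rec <- records[records$participant_id == pids[i], , drop = FALSE]
    late <- rec$age_at_purchase > samp
    if (any(late)) {
      warning("participant ", pids[i], ": ", sum(late),
              " record(s) after sampling age excluded")
      rec <- rec[!late, , drop = FALSE]
    }
    for (cl in DRUG_CLASSES) {
      rc <- rec[rec$drug_class == cl, , drop = FALSE]
      if (nrow(rc) == 0L) next
      for (w in windows)
        out[i, paste0(cl, "_ddd_to_", w)] <-
          sum(rc$ddd[rc$age_at_purchase < w])
      out[i, paste0(cl, "_ddd_lifetime")] <- sum(rc$ddd)
      out[i, paste0(cl, "_courses")] <- nrow(rc)
      out[i, paste0(cl, "_time_since_last")] <-
        samp - max(rc$age_at_purchase)
    }
  }
  out
}

#' Model-ready exposure candidate matrix
#'
#' Expands an exposure profile into the candidate grid used for AIC
#' screening: classes x (windowed DDD, lifetime DDD, lifetime courses,
#' time since last course). The `Inf` never-exposed sentinel in
#' time-since-last is re-coded as the participant's sampling age (the
#' longest possible drug-free interval) plus a `<class>_never` indicator,
#' so unexposed participants are never dropped.
#'
#' @param exposures data.frame from [build_exposures()].
#' @param sampling_age numeric vector parallel to rows, used to cap the
#'   sentinel.
#' @return data.frame of numeric candidate variables (participant_id
#'   removed).
#' @export
exposure_candidates <- function(exposures, sampling_age) {
  x <- exposures[, setdiff(names(exposures), "participant_id"),
                 drop = FALSE]
  for (cl in DRUG_CLASSES) {
    tcol <- paste0(cl, "_time_since_last")
    never <- !is.finite(x[[tcol]])
    x[[tcol]][never] <- sampling_age[never]
    x[[paste0(cl, "_never")]] <- as.numeric(never)
  }
  x
}

#' Akaike information criterion
#'
#' `AIC = 2 * n_params - 2 * loglik`; lower is preferred.
#'
#' @param loglik finite log-likelihood.
#' @param n_params number of estimated parameters.
#' @return AIC value.
#' @export
aic <- function(loglik, n_params) {
  if (!is.finite(loglik)) stop("log-likelihood must be finite")
  2 * n_params - 2 * loglik
}

#' Screen exposure candidates for association with pubertal timing
#'
#' Fits `time_from_peak ~ candidate` by ordinary least squares for every
#' candidate variable and returns the minimal-AIC candidate with its
#' coefficient and p-value, plus the full trace. Constant candidates are
#' skipped (logged in the trace). AIC ties below 1e-9 are broken by
#' candidate declaration order. Post-selection p-values are optimistic;
#' they are reported as the original analysis reported them, uncorrected.
#'
#' @param time_from_peak numeric response, one per participant.
#' @param candidates data.frame of candidate variables
#'   (e.g. [exposure_candidates()]).
#' @return list: `best` (name), `estimate`, `se`, `p_value`, `aic`, and
#'   `trace` (data.frame of every candidate's AIC, skipped ones flagged).
#' @export
screen_exposures <- function(time_from_peak, candidates) {
  stopifnot(nrow(candidates) == length(time_from_peak))
  trace <- data.frame(candidate = names(candidates), aic = NA_real_,
                      estimate = NA_real_, se = NA_real_,
                      p_value = NA_real_, skipped = FALSE,
                      stringsAsFactors = FALSE)
  for (j in seq_along(candidates)) {
    x <- candidates[[j]]
    if (stats::sd(x, na.rm = TRUE) == 0 || anyNA(x)) {
      trace$skipped[j] <- TRUE
      next
    }
    fit <- stats::lm(time_from_peak ~ x)
    co <- summary(fit)$coefficients
    trace$aic[j] <- aic(as.numeric(stats::logLik(fit)),
                        attr(stats::logLik(fit), "df"))
    trace$estimate[j] <- co["x", 1]
    trace$se[j] <- co["x", 2]
    trace$p_value[j] <- co["x", 4]
  }
  ok <- which(!trace$skipped)
  if (length(ok) == 0L) stop("no usable candidates")
  best <- ok[which.min(trace$aic[ok])]  # first minimum: declaration order
  list(best = trace$candidate[best], estimate = trace$estimate[best],
       se = trace$se[best], p_value = trace$p_value[best],
       aic = trace$aic[best], trace = trace)
}

#' Multivariate pubertal-timing model with AIC-based stepwise selection
#'
#' Pools log-transformed family-level relative abundances, detailed
#' antibiotic-exposure variables, probiotic use, BMI and GI-symptom flags
#' as candidate terms for the timing of puberty, then runs bidirectional
#' stepwise selection by AIC starting from the intercept-only model. When
#' the candidate pool is as large as the sample, candidates are
#' pre-filtered to the best `n/5` by univariate AIC (recorded in the
#' trace). The final model is a local AIC optimum: no single add or drop
#' improves it.
#'
#' @param time_from_peak numeric response.
#' @param candidates data.frame of all candidate variables (already
#'   transformed).
#' @return list of class `model_selection_trace`: `terms` (selected),
#'   `coefficients` (data.frame with estimate/se/p), `aic` (final),
#'   `steps` (data.frame of every move considered and taken),
#'   `prefiltered` (dropped candidates, if any).
#' @export
multivariate_timing_model <- function(time_from_peak, candidates) {
  stopifnot(nrow(candidates) == length(time_from_peak))
  usable <- vapply(candidates, function(x)
    !anyNA(x) && stats::sd(x) > 0, TRUE)
  candidates <- candidates[, usable, drop = FALSE]
  n <- length(time_from_peak)
  prefiltered <- character(0)
  if (n <= ncol(candidates)) {
    uaic <- vapply(seq_along(candidates), function(j) {
      fit <- stats::lm(time_from_peak ~ candidates[[j]])
      stats::AIC(fit)
    }, 0)
    keep_n <- max(1L, floor(n / 5))
    keep <- order(uaic)[seq_len(min(keep_n, ncol(candidates)))]
    prefiltered <- setdiff(names(candidates), names(candidates)[keep])
    candidates <- candidates[, keep, drop = FALSE]
  }
  df <- data.frame(.y = time_from_peak, candidates, check.names = FALSE)
  current <- character(0)
  fit_terms <- function(terms) {
    fml <- if (length(terms) == 0L) .y ~ 1 else
      stats::reformulate(sprintf("`%s`", terms), response = ".y")
    stats::lm(fml, data = df)
  }
  cur_aic <- stats::AIC(fit_terms(current))
  steps <- data.frame(step = integer(0), move = character(0),
                      term = character(0), aic = numeric(0),
                      taken = logical(0), stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    moves <- rbind(
      if (length(setdiff(names(candidates), current)) > 0)
        data.frame(move = "add",
                   term = setdiff(names(candidates), current),
                   stringsAsFactors = FALSE),
      if (length(current) > 0)
        data.frame(move = "drop", term = current,
                   stringsAsFactors = FALSE)
    )
    if (is.null(moves) || nrow(moves) == 0L) break
    moves$aic <- vapply(seq_len(nrow(moves)), function(k) {
      terms <- if (moves$move[k] == "add") c(current, moves$term[k])
               else setdiff(current, moves$term[k])
      stats::AIC(fit_terms(terms))
    }, 0)
    moves$taken <- FALSE
    best <- which.min(moves$aic)
    improved <- moves$aic[best] < cur_aic - 1e-9
    if (improved) {
      moves$taken[best] <- TRUE
      current <- if (moves$move[best] == "add")
        c(current, moves$term[best]) else setdiff(current, moves$term[best])
      cur_aic <- moves$aic[best]
    }
    steps <- rbind(steps, cbind(step = step_i, moves))
    if (!improved) break
  }
  fit <- fit_terms(current)
  co <- summary(fit)$coefficients
  sel <- if (length(current) > 0) {
    idx <- match(sprintf("`%s`", current), rownames(co))
    idx[is.na(idx)] <- match(current, rownames(co))[is.na(idx)]
    data.frame(term = current, estimate = co[idx, 1], se = co[idx, 2],
               p_value = co[idx, 4], row.names = NULL,
               stringsAsFactors = FALSE)
  } else data.frame(term = character(0), estimate = numeric(0),
                    se = numeric(0), p_value = numeric(0))
  structure(list(terms = current, coefficients = sel, aic = cur_aic,
                 steps = steps, prefiltered = prefiltered, fit = fit),
            class = "model_selection_trace")
}

#' @export
print.model_selection_trace <- function(x, ...) {
  cat(sprintf("model_selection_trace: %d term(s), AIC %.2f\n",
              length(x$terms), x$aic))
  if (length(x$terms) > 0) print(x$coefficients)
  invisible(x)
}
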