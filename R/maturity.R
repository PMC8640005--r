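#' Log-transform a relative-abundance profile
#'
#' Elementwise `log10(x + pseudocount)` over a shared taxon set; taxa
#' absent from a sample contribute `log10(pseudocount)`, keeping every
#' entry finite. The default pseudocount (1e-6) sits below the smallest
#' nonzero relative abundance observable at typical sequencing depths.
#'
#' @param x numeric vector (or matrix, samples x taxa) of relative
#'   abundances.
#' @param pseudocount positive offset added before the log.
#' @param base logarithm base; the maturity index is invariant to it.
#' @return transformed vector or matrix.
#' @export
log_profile <- function(x, pseudocount = 1e-6, base = 10) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log(x + pseudocount, base = base)
}

#' Similarity between one adolescent and one adult profile
#'
#' Pearson (default) or Spearman correlation of two equal-length
#' log-transformed relative-abundance vectors over the identical taxon
#' order. A zero-variance vector makes the correlation undefined; `NA` is
#' returned and the pair is excluded from downstream averaging.
#'
#' @param a,b numeric vectors of equal length (log-profiles).
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation in \[-1, 1\], or `NA_real_` if undefined.
#' @export
pair_similarity <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = method)
}

#' Microbiota maturity index
#'
#' For each adolescent sample, the mean correlation of its
#' log-transformed species-level relative abundances with those of every
#' same-sex adult in the reference panel. The average similarity to adults
#' is the maturity score. Tables are aligned on the union of their taxon
#' sets (missing taxa filled with zero abundance before the pseudocount).
#'
#' @param adolescents `count_table` of adolescent samples (species level).
#' @param adults `count_table` of the adult reference panel.
#' @param adult_sex character vector of adult sexes, parallel to the adult
#'   panel's samples.
#' @param sex which sex's panel to compare against (`"female"`/`"male"`).
#' @param pseudocount,method,base passed to [log_profile()] /
#'   [pair_similarity()].
#' @param min_prevalence optional minimum fraction of samples (pooled
#'   adolescents + selected adults) in which a taxon must be nonzero to be
#'   retained; default 0 (no filtering).
#' @return data.frame: `sample_id`, `maturity`, `n_adults_compared`, plus
#'   attributes `pseudocount` and `log_base`.
#' @export
maturity_index <- function(adolescents, adults, adult_sex, sex,
                           pseudocount = 1e-6,
                           method = c("pearson", "spearman"),
                           base = 10, min_prevalence = 0) {
  method <- match.arg(method)
  stopifnot(length(adult_sex) == length(adults$sample_ids))
  keep <- adult_sex == sex
  if (!any(keep)) stop("no adults of sex '", sex, "' in the panel")
  taxa <- union(adolescents$taxon_ids, adults$taxon_ids)
  pad <- function(tab) {
    m <- matrix(0L, nrow = length(tab$sample_ids), ncol = length(taxa),
                dimnames = list(tab$sample_ids, taxa))
    m[, tab$taxon_ids] <- tab$counts
    m
  }
  ra_ado <- pad(adolescents); ra_ado <- ra_ado / rowSums(ra_ado)
  ra_adu <- pad(adults)[keep, , drop = FALSE]
  ra_adu <- ra_adu / rowSums(ra_adu)
  if (min_prevalence > 0) {
    pooled <- rbind(ra_ado, ra_adu)
    prev <- colMeans(pooled > 0)
    taxa_keep <- prev >= min_prevalence
    ra_ado <- ra_ado[, taxa_keep, drop = FALSE]
    ra_adu <- ra_adu[, taxa_keep, drop = FALSE]
  }
  la <- log_profile(ra_ado, pseudocount, base)
  lb <- log_profile(ra_adu, pseudocount, base)
  if (method == "spearman") {
    la <- t(apply(la, 1, rank)); lb <- t(apply(lb, 1, rank))
  }
  ok_a <- apply(la, 1, stats::sd) > 0
  ok_b <- apply(lb, 1, stats::sd) > 0
  sim <- matrix(NA_real_, nrow(la), nrow(lb))
  if (any(ok_b))
    sim[ok_a, ok_b] <- stats::cor(t(la[ok_a, , drop = FALSE]),
                                  t(lb[ok_b, , drop = FALSE]))
  out <- data.frame(
    sample_id = adolescents$sample_ids,
    maturity = rowMeans(sim, na.rm = TRUE),
    n_adults_compared = rowSums(!is.na(sim)),
    stringsAsFactors = FALSE
  )
  out$maturity[out$n_adults_compared == 0] <- NA_real_
  attr(out, "pseudocount") <- pseudocount
  attr(out, "log_base") <- base
  out
}

#' Association between microbiota maturity and pubertal timing
#'
#' Ordinary-least-squares fit of the maturity score on time from peak
#' height velocity, optionally adjusted for covariates (probiotic arm,
#' time since last antibiotic course, BMI, whole-grain intake). Run
#' separately per sex by the caller.
#'
#' @param maturity numeric vector of maturity scores.
#' @param time_from_peak numeric vector, same length.
#' @param covariates optional data.frame of adjustment variables.
#' @return list: `slope`, `se`, `p_value`, `n`, and the `lm` `fit`.
#' @export
maturity_association <- function(maturity, time_from_peak,
                                 covariates = NULL) {
  stopifnot(length(maturity) == length(time_from_peak))
  df <- data.frame(maturity = maturity, time_from_peak = time_from_peak)
  k <- 0L
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(maturity))
    df <- cbind(df, covariates)
    k <- ncol(covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < k + 2L)
    stop("too few complete observations (", nrow(df),
         ") for ", k, " covariates")
  fit <- stats::lm(maturity ~ ., data = df)
  co <- summary(fit)$coefficients
  list(slope = co["time_from_peak", 1],
       se = co["time_from_peak", 2],
       p_value = co["time_from_peak", 4],
       n = nrow(df), fit = fit)
}
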