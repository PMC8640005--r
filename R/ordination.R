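#' Bray-Curtis dissimilarity matrix
#'
#' For relative-abundance rows summing to 1, the Bray-Curtis dissimilarity
#' reduces to `d(a, b) = 1 - sum(pmin(a, b))`: symmetric, zero on the
#' diagonal, bounded in \[0, 1\], and 1 exactly for disjoint supports.
#'
#' @param rel numeric matrix of relative abundances (samples x taxa, rows
#'   summing to 1).
#' @return symmetric numeric matrix of dissimilarities with sample
#'   dimnames.
#' @export
bray_curtis <- function(rel) {
  if (any(abs(rowSums(rel) - 1) > 1e-8))
    stop("rows must be relative abundances summing to 1")
  n <- nrow(rel)
  d <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n - 1L)) {
    shared <- colSums(pmin(t(rel[(i + 1L):n, , drop = FALSE]), rel[i, ]))
    d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- 1 - shared
  }
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of the squared distance matrix,
#' `-1/2 * J %*% D^2 %*% J` with `J = I - 11'/n`, followed by
#' eigendecomposition. Axes with eigenvalue below 1e-10 are dropped;
#' negative eigenvalues (non-Euclidean distances) are dropped rather than
#' corrected, and their summed magnitude is recorded. Proportion of
#' variance is eigenvalue over the sum of positive eigenvalues.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return object of class `pcoa_result`: `coordinates` (samples x
#'   retained axes, scaled by sqrt eigenvalue), `eigenvalues`
#'   (non-increasing), `prop_var`, `negative_magnitude`.
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-10))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  keep <- eig$values > 1e-10
  neg <- sum(abs(eig$values[eig$values < 0]))
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), sum(keep))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(
    coordinates = coords,
    eigenvalues = eig$values[keep],
    prop_var = eig$values[keep] / sum(eig$values[keep]),
    negative_magnitude = neg
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d positive axes; PC1+PC2 = %.1f%% of variance\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * sum(x$prop_var[seq_len(min(2, length(x$prop_var)))])))
  invisible(x)
}

#' Summed first-two-coordinates score
#'
#' The ordination is computed jointly on adolescents and same-sex adults;
#' each of the first two axes is sign-oriented so that the adult centroid
#' is non-negative on it (making "towards adults" the positive direction),
#' and the score is oriented PC1 + oriented PC2. Invariant to the
#' eigensolver's arbitrary sign choices.
#'
#' @param result a `pcoa_result` fitted on adolescents plus adults.
#' @param adult_ids sample identifiers of the adult reference samples.
#' @return named numeric vector of scores for every sample in the
#'   ordination.
#' @export
pc_sum_score <- function(result, adult_ids) {
  co <- result$coordinates
  if (ncol(co) < 2L) stop("need at least 2 positive axes")
  adult_ids <- intersect(adult_ids, rownames(co))
  if (length(adult_ids) == 0L) stop("no adult samples in the ordination")
  score <- rep(0, nrow(co))
  for (ax in 1:2) {
    centroid <- mean(co[adult_ids, ax])
    flip <- if (centroid < 0) -1 else 1
    score <- score + flip * co[, ax]
  }
  names(score) <- rownames(co)
  score
}

#' Stage-group contrasts of ordination scores
#'
#' Linear model of the summed PC score on pubertal stage group as a
#' categorical factor; each group is contrasted against the reference
#' (earliest stage present for that sex) with two-sided p-values. With
#' degenerate (zero) variance the contrasts are 0 and p-values `NaN`;
#' this is returned, not an error.
#'
#' @param scores numeric vector of per-sample scores.
#' @param stage_groups character vector of stage labels, same length.
#' @param reference_group stage label used as baseline; must be present.
#' @return data.frame: `group`, `difference`, `se`, `p_value`, `n`.
#' @export
stage_score_test <- function(scores, stage_groups, reference_group) {
  stopifnot(length(scores) == length(stage_groups))
  groups <- stage_order(unique(stage_groups))
  if (!reference_group %in% groups)
    stop("reference group '", reference_group, "' absent")
  f <- factor(stage_groups, levels = c(reference_group,
                                       setdiff(groups, reference_group)))
  tab <- table(f)
  if (sum(tab >= 2) < 2L)
    stop("need at least 2 groups with at least 2 samples each")
  fit <- stats::lm(scores ~ f)
  co <- summary(fit)$coefficients
  others <- levels(f)[-1]
  rows <- paste0("f", others)
  present <- rows %in% rownames(co)
  data.frame(
    group = others[present],
    difference = co[rows[present], 1],
    se = co[rows[present], 2],
    p_value = co[rows[present], 4],
    n = as.integer(tab[others[present]]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Order stage labels chronologically
#' @param stages character vector of stage labels (any subset).
#' @return the input labels in pubertal order.
#' @export
stage_order <- function(stages) {
  all <- c("pre_takeoff", "pre_peak", "peak", "post_peak_lt2y",
           "post_peak_gt2y")
  all[all %in% stages]
}
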