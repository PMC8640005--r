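#' @keywords internal
"_PACKAGE"

#' Taxonomic ranks, coarsest to finest
#'
#' The seven-rank lineage used throughout: kingdom, phylum, class, order,
#' family, genus, species. Species is treated simply as the finest provided
#' rank; missing ranks are explicit `NA`s.
#'
#' @export
TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")

#' Construct a validated count table
#'
#' A count table holds non-negative integer read counts for samples (rows)
#' by taxa (columns). Per-sample sequencing depth is the row sum and is kept
#' in sync automatically. Validation distinguishes hard errors (negative or
#' non-integer counts, duplicated identifiers) from warnings (all-zero taxa
#' or samples), which are collected in a structured report attached to the
#' object.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns, with
#'   dimnames giving sample and taxon identifiers.
#' @return an object of class `count_table` with elements `counts`
#'   (integer matrix), `sample_ids`, `taxon_ids`, `depth` (named integer
#'   vector of row sums) and `validation` (see [validate_counts()]).
#' @export
count_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("T", seq_len(ncol(counts)))
  report <- validate_counts(counts)
  if (length(report$errors) > 0L)
    stop("invalid count table:\n  ", paste(report$errors, collapse = "\n  "))
  storage.mode(counts) <- "integer"
  structure(list(
    counts     = counts,
    sample_ids = rownames(counts),
    taxon_ids  = colnames(counts),
    depth      = rowSums(counts),
    validation = report
  ), class = "count_table")
}

#' Validate a raw count matrix
#'
#' @param counts numeric matrix, samples x taxa.
#' @return list with character vectors `errors` and `warnings`.
#' @export
validate_counts <- function(counts) {
  errors <- character(0)
  warnings <- character(0)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    for (i in seq_len(min(nrow(bad), 10L))) {
      r <- bad[i, 1]; c <- bad[i, 2]
      errors <- c(errors, sprintf(
        "non-integer or negative count %s at sample '%s', taxon '%s'",
        format(counts[r, c]), rownames(counts)[r], colnames(counts)[c]))
    }
  }
  if (anyDuplicated(rownames(counts)))
    errors <- c(errors, "duplicated sample identifiers")
  if (anyDuplicated(colnames(counts)))
    errors <- c(errors, "duplicated taxon identifiers")
  if (length(errors) == 0L) {
    zt <- colnames(counts)[colSums(counts) == 0]
    if (length(zt) > 0L)
      warnings <- c(warnings, sprintf("all-zero taxa retained: %s",
                                      paste(zt, collapse = ", ")))
    zs <- rownames(counts)[rowSums(counts) == 0]
    if (length(zs) > 0L)
      warnings <- c(warnings, sprintf("zero-depth samples: %s",
                                      paste(zs, collapse = ", ")))
  }
  list(errors = errors, warnings = warnings)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa, depth %s-%s\n",
              length(x$sample_ids), length(x$taxon_ids),
              format(min(x$depth)), format(max(x$depth))))
  if (length(x$validation$warnings) > 0L)
    cat("warnings:", paste(x$validation$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read a count table (and optionally its taxonomy) from TSV
#'
#' The file is tab-separated with a header row; the first column holds
#' sample identifiers when `samples_in_rows = TRUE` (the default) or taxon
#' identifiers otherwise. Non-integer cells are hard errors naming the
#' offending sample and taxon. If a taxonomy path is given, every taxon in
#' the table must resolve in it.
#'
#' @param path TSV file of counts.
#' @param taxonomy_path optional TSV file of lineages (see
#'   [read_taxonomy()]).
#' @param samples_in_rows orientation flag; default samples-in-rows.
#' @return a `count_table`, with the taxonomy attached as attribute
#'   `"taxonomy"` when requested.
#' @export
read_count_table <- function(path, taxonomy_path = NULL,
                             samples_in_rows = TRUE) {
  raw <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                           stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  if (!is.numeric(m))
    stop("count table '", path, "' contains non-numeric cells")
  if (!samples_in_rows) m <- t(m)
  tab <- count_table(m)
  if (!is.null(taxonomy_path)) {
    tax <- read_taxonomy(taxonomy_path)
    missing <- setdiff(tab$taxon_ids, tax$taxon_id)
    if (length(missing) > 0L)
      stop("taxa without taxonomy entries: ",
           paste(missing, collapse = ", "))
    attr(tab, "taxonomy") <- tax
  }
  tab
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]: integer counts round-trip bit-exactly.
#'
#' @param table a `count_table`.
#' @param path output file.
#' @param samples_in_rows orientation flag.
#' @export
write_count_table <- function(table, path, samples_in_rows = TRUE) {
  m <- table$counts
  if (!samples_in_rows) m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- if (samples_in_rows) "sample_id" else "taxon_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table from TSV
#'
#' Expected columns: `taxon_id` plus the seven ranks of [TAXONOMIC_RANKS].
#' Missing ranks may be empty strings or `NA`; both are normalized to `NA`.
#'
#' @param path TSV file.
#' @return data.frame with `taxon_id` and one column per rank.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("taxon_id", TAXONOMIC_RANKS)
  miss <- setdiff(need, names(tax))
  if (length(miss) > 0L)
    stop("taxonomy '", path, "' lacks columns: ", paste(miss, collapse = ", "))
  tax <- tax[, need]
  for (r in TAXONOMIC_RANKS) tax[[r]][!nzchar(tax[[r]])] <- NA_character_
  if (anyDuplicated(tax$taxon_id))
    stop("duplicated taxon_id in taxonomy")
  tax
}

#' Write a taxonomy table to TSV
#' @param taxonomy data.frame as returned by [read_taxonomy()].
#' @param path output file.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Mandatory columns: `sample_id`, `participant_id`, `sex`
#' (`female`/`male`), `cohort` (`adolescent`/`adult_reference`). Optional:
#' `age_at_sampling`, `bmi`, `probiotic_arm`, `whole_grain_intake`,
#' `flatulence`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "participant_id", "sex", "cohort")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0L)
    stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (!all(md$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  if (!all(md$cohort %in% c("adolescent", "adult_reference")))
    stop("cohort must be 'adolescent' or 'adult_reference'")
  if ("age_at_sampling" %in% names(md) &&
      any(md$age_at_sampling <= 0, na.rm = TRUE))
    stop("age_at_sampling must be positive")
  md
}

#' Read longitudinal growth records from TSV
#'
#' Columns `participant_id`, `age` (years), `height` (cm). Rows are sorted
#' by participant and age; strictly decreasing heights within a participant
#' are flagged as warnings (attribute `"warnings"`), not errors, since
#' measurement noise can produce small dips.
#'
#' @param path TSV file.
#' @return data.frame sorted by (participant_id, age).
#' @export
read_growth_records <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age", "height")
  miss <- setdiff(need, names(g))
  if (length(miss) > 0L)
    stop("growth records lack columns: ", paste(miss, collapse = ", "))
  if (any(g$height <= 0)) stop("heights must be positive")
  g <- g[order(g$participant_id, g$age), ]
  warnings <- character(0)
  for (pid in unique(g$participant_id)) {
    h <- g$height[g$participant_id == pid]
    a <- g$age[g$participant_id == pid]
    if (anyDuplicated(a))
      stop("duplicated measurement ages for participant ", pid)
    if (any(diff(h) < -1))  # > 1 cm shrink exceeds noise tolerance
      warnings <- c(warnings, sprintf(
        "participant %s: height decreases by more than 1 cm", pid))
  }
  attr(g, "warnings") <- warnings
  g
}

#' Read antibiotic purchase records from TSV
#'
#' Columns `participant_id`, `age_at_purchase` (years, >= 0), `drug_class`
#' (one of cephalosporin_1_2, macrolide, penicillin, other), `ddd`
#' (defined daily doses, > 0).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_antibiotic_records <- function(path) {
  ab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "age_at_purchase", "drug_class", "ddd")
  miss <- setdiff(need, names(ab))
  if (length(miss) > 0L)
    stop("antibiotic records lack columns: ", paste(miss, collapse = ", "))
  if (any(ab$ddd <= 0)) stop("ddd must be positive")
  if (any(ab$age_at_purchase < 0)) stop("age_at_purchase must be >= 0")
  ok <- c("cephalosporin_1_2", "macrolide", "penicillin", "other")
  if (!all(ab$drug_class %in% ok))
    stop("unknown drug_class values: ",
         paste(setdiff(unique(ab$drug_class), ok), collapse = ", "))
  ab
}

#' Aggregate a count table at a taxonomic rank
#'
#' Counts of taxa sharing the same lineage down to `rank` are summed. Taxa
#' whose `rank` is unknown collapse into one `unclassified_<parent>` bucket
#' per nearest known parent, so that per-sample depth is conserved exactly.
#'
#' @param table a `count_table`.
#' @param taxonomy taxonomy data.frame covering every taxon in `table`.
#' @param rank one of [TAXONOMIC_RANKS].
#' @return a `count_table` whose taxon_ids are rank-level labels.
#' @export
aggregate_taxa <- function(table, taxonomy, rank) {
  if (!rank %in% TAXONOMIC_RANKS)
    stop("unknown rank '", rank, "'; must be one of ",
         paste(TAXONOMIC_RANKS, collapse = ", "))
  idx <- match(table$taxon_ids, taxonomy$taxon_id)
  if (anyNA(idx))
    stop("taxa without taxonomy entries: ",
         paste(table$taxon_ids[is.na(idx)], collapse = ", "))
  lab <- taxonomy[[rank]][idx]
  ri <- match(rank, TAXONOMIC_RANKS)
  unk <- is.na(lab)
  if (any(unk)) {
    parent <- rep("root", sum(unk))
    if (ri > 1L) {
      for (j in which(unk)) {
        lin <- as.character(taxonomy[idx[j], TAXONOMIC_RANKS[seq_len(ri - 1L)]])
        known <- lin[!is.na(lin)]
        parent[match(j, which(unk))] <-
          if (length(known) > 0L) known[length(known)] else "root"
      }
    }
    lab[unk] <- paste0("unclassified_", parent)
  }
  groups <- unique(lab)
  agg <- sapply(groups, function(g)
    rowSums(table$counts[, lab == g, drop = FALSE]))
  if (length(table$sample_ids) == 1L)
    agg <- matrix(agg, nrow = 1, dimnames = list(table$sample_ids, groups))
  count_table(agg)
}

#' Convert counts to per-sample relative abundances
#'
#' Each sample's counts are divided by its depth; rows sum to 1 within
#' 1e-12. Zero-depth samples are an error (they carry no compositional
#' information).
#'
#' @param table a `count_table`.
#' @return numeric matrix, samples x taxa, rows summing to 1.
#' @export
relative_abundance <- function(table) {
  zero <- table$sample_ids[table$depth == 0]
  if (length(zero) > 0L)
    stop("zero-depth samples: ", paste(zero, collapse = ", "))
  sweep(table$counts, 1, table$depth, "/")
}
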