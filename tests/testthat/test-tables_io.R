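test_that("count tables round-trip through TSV bit-exactly", {
  tab <- tiny_counts()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, f)
  back <- read_count_table(f)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$depth, tab$depth)

  # taxa-in-columns orientation round-trips too
  write_count_table(tab, f, samples_in_rows = FALSE)
  back2 <- read_count_table(f, samples_in_rows = FALSE)
  expect_identical(back2$counts, tab$counts)
})

test_that("non-integer and negative counts are errors naming the cell", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tTaxA\tTaxB", "S1\t3.5\t2", "S2\t1\t4"), f)
  expect_error(read_count_table(f), "S1.*TaxA|TaxA.*S1")
  expect_error(count_table(matrix(-1, 1, 1)), "negative")
})

test_that("all-zero taxa are retained and flagged, not dropped", {
  m <- matrix(c(5L, 0L, 3L, 0L), 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("TaxA", "TaxZ")))
  tab <- count_table(m)
  expect_equal(ncol(tab$counts), 2L)
  expect_match(tab$validation$warnings, "TaxZ", all = FALSE)
})

test_that("taxa missing from the taxonomy are a hard error", {
  tab <- tiny_counts()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, f)
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tiny_taxonomy()[1, ], ft)
  expect_error(read_count_table(f, taxonomy_path = ft), "TaxB")
})

test_that("aggregation sums lineage groups and conserves depth", {
  tax <- tiny_taxonomy()
  m <- matrix(c(4L, 6L, 2L), 1, dimnames = list("S1", tax$taxon_id))
  tab <- count_table(m)
  fam <- aggregate_taxa(tab, tax, "family")
  expect_equal(fam$counts["S1", "Ruminococcaceae"], 10L)
  expect_equal(fam$counts["S1", "Lachnospiraceae"], 2L)

  # conservation at every rank, random tables
  set.seed(42)
  for (rep in 1:5) {
    big <- count_table(matrix(rpois(5 * 3, 20), 5,
                              dimnames = list(paste0("s", 1:5),
                                              tax$taxon_id)))
    for (rank in TAXONOMIC_RANKS)
      expect_identical(aggregate_taxa(big, tax, rank)$depth, big$depth)
  }
  expect_error(aggregate_taxa(tab, tax, "clade"), "unknown rank")
})

test_that("aggregating an already-aggregated table is the identity", {
  tax <- tiny_taxonomy()
  tab <- count_table(matrix(c(4L, 6L, 2L), 1,
                            dimnames = list("S1", tax$taxon_id)))
  fam <- aggregate_taxa(tab, tax, "family")
  fam_tax <- data.frame(taxon_id = fam$taxon_ids, kingdom = "Bacteria",
                        phylum = "Firmicutes", class = "Clostridia",
                        order = "Clostridiales", family = fam$taxon_ids,
                        genus = NA, species = NA)
  again <- aggregate_taxa(fam, fam_tax, "family")
  expect_identical(again$counts[, sort(colnames(again$counts))],
                   fam$counts[, sort(colnames(fam$counts))])
})

test_that("unknown ranks collapse into parent-scoped unclassified buckets", {
  tax <- tiny_taxonomy()
  tax$genus[2] <- NA
  tax$family[3] <- NA
  tab <- count_table(matrix(c(4L, 6L, 2L), 1,
                            dimnames = list("S1", tax$taxon_id)))
  gen <- aggregate_taxa(tab, tax, "genus")
  expect_true("unclassified_Ruminococcaceae" %in% gen$taxon_ids)
  fam <- aggregate_taxa(tab, tax, "family")
  expect_true("unclassified_Clostridiales" %in% fam$taxon_ids)
  expect_identical(fam$depth, tab$depth)
})

test_that("relative abundance normalizes, is scale-invariant, rejects zero depth", {
  tab <- count_table(matrix(c(2L, 8L), 1,
                            dimnames = list("S1", c("a", "b"))))
  expect_equal(unname(relative_abundance(tab)[1, ]), c(0.2, 0.8))

  set.seed(7)
  m <- matrix(rpois(40, 30) + 1L, 4,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:10)))
  r1 <- relative_abundance(count_table(m))
  expect_true(all(abs(rowSums(r1) - 1) < 1e-12))
  m2 <- m; m2[2, ] <- m2[2, ] * 10L
  r2 <- relative_abundance(count_table(m2))
  expect_equal(r2[2, ], r1[2, ])

  zz <- matrix(c(1L, 0L, 2L, 0L), 2, byrow = TRUE,
               dimnames = list(c("ok", "empty"), c("a", "b")))
  zz["empty", ] <- 0L
  expect_error(relative_abundance(count_table(zz)), "empty")
})

test_that("metadata, growth and antibiotic readers validate their contracts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tparticipant_id\tsex\tcohort",
               "S1\tP1\tfemale\tadolescent"), f)
  md <- read_sample_metadata(f)
  expect_equal(md$sex, "female")
  writeLines(c("sample_id\tparticipant_id\tsex\tcohort",
               "S1\tP1\tgirl\tadolescent"), f)
  expect_error(read_sample_metadata(f), "sex")

  writeLines(c("participant_id\tage\theight", "P1\t10\t140",
               "P1\t11\t120"), f)
  g <- read_growth_records(f)
  expect_match(attr(g, "warnings"), "P1", all = FALSE)

  writeLines(c("participant_id\tage_at_purchase\tdrug_class\tddd",
               "P1\t3\tquinolone\t5"), f)
  expect_error(read_antibiotic_records(f), "drug_class")
  writeLines(c("participant_id\tage_at_purchase\tdrug_class\tddd",
               "P1\t3\tmacrolide\t0"), f)
  expect_error(read_antibiotic_records(f), "ddd")
})
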