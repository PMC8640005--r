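# shared fixture builders; everything is generated in code

tiny_counts <- function() {
  count_table(matrix(c(5L, 0L, 3L, 7L), nrow = 2, byrow = TRUE,
                     dimnames = list(c("S1", "S2"), c("TaxA", "TaxB"))))
}

tiny_taxonomy <- function() {
  data.frame(
    taxon_id = c("TaxA", "TaxB", "TaxC"),
    kingdom = "Bacteria", phylum = "Firmicutes", class = "Clostridia",
    order = "Clostridiales",
    family = c("Ruminococcaceae", "Ruminococcaceae", "Lachnospiraceae"),
    genus = c("Faecalibacterium", "Subdoligranulum", "Dorea"),
    species = c("TaxA", "TaxB", "TaxC"),
    stringsAsFactors = FALSE
  )
}

# flat reference: mean 5 cm/y, SD 0.5 everywhere
flat_reference <- function(mean = 5, sd = 0.5) {
  reference_velocity_curve("female", c(2, 18), rep(mean, 2), rep(sd, 2))
}

velocity_frame <- function(age, velocity) {
  data.frame(age = age, velocity = velocity,
             start_age = age - 0.25, end_age = age + 0.25)
}

random_composition <- function(n_samples, n_taxa) {
  m <- matrix(stats::rgamma(n_samples * n_taxa, 1), n_samples)
  m <- m / rowSums(m)
  dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                      paste0("t", seq_len(n_taxa)))
  m
}
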