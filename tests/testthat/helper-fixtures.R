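# Fixtures built in code: small cohorts with fully controlled calls.

# a bare cohort of n_cases + n_controls samples and no variants
empty_cohort <- function(n_cases = 6, n_controls = 5) {
  samples <- data.frame(
    sample_id = c(sprintf("P%d", seq_len(n_cases)),
                  sprintf("C%d", seq_len(n_controls))),
    status = rep(c("case", "control"), c(n_cases, n_controls)),
    sex = "F", age = 50,
    stringsAsFactors = FALSE
  )
  genotype_matrix(samples, data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), rsid = character(0), gene = character(0),
    consequence = character(0)
  ), matrix(character(0), nrow = n_cases + n_controls, ncol = 0))
}

# helper to describe a variant for plant_signal
mk_variant <- function(chrom, pos, gene, rsid = NA_character_,
                       consequence = "missense_variant", af_1kg = 0.01) {
  list(chrom = as.character(chrom), pos = pos, ref = "A", alt = "G",
       gene = gene, rsid = rsid, consequence = consequence, af_1kg = af_1kg)
}

# random cohort with arbitrary zygosity states, independent of the simulator
random_cohort <- function(n_cases = 4, n_controls = 3, n_variants = 8,
                          genes = c("SLC6A1", "SLC9B1", "TRPM2", "CAT",
                                    "GENE0001")) {
  states <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt", "missing")
  n <- n_cases + n_controls
  samples <- data.frame(
    sample_id = sprintf("S%d", seq_len(n)),
    status = rep(c("case", "control"), c(n_cases, n_controls)),
    sex = sample(c("F", "M"), n, replace = TRUE), age = 50,
    stringsAsFactors = FALSE
  )
  variants <- data.frame(
    chrom = sample(c("1", "2", "X"), n_variants, replace = TRUE),
    pos = sample.int(1e6, n_variants),
    ref = "A", alt = "G",
    rsid = sprintf("rs%d", seq_len(n_variants)),
    gene = sample(genes, n_variants, replace = TRUE),
    consequence = sample(c("missense_variant", "synonymous_variant",
                           "intron_variant", "3_prime_UTR_variant"),
                         n_variants, replace = TRUE),
    af_1kg = round(runif(n_variants, 0.001, 0.04), 5),
    stringsAsFactors = FALSE
  )
  calls <- matrix(sample(states, n * n_variants, replace = TRUE,
                         prob = c(0.6, 0.2, 0.05, 0.05, 0.05, 0.05)),
                  nrow = n)
  genotype_matrix(samples, variants, calls)
}

# cohort reproducing the homozygous SLC carrier pattern of the published
# group-analysis table: one control with one variant, patients with
# [2, 2, 1, 1, 1, 1]
hom_slc_cohort <- function() {
  gm <- empty_cohort(6, 5)
  planting <- list(
    list("SLC35A2", "C1"),
    list("SLC4A2", "P1"), list("SLC6A1", "P1"),
    list("SLC6A14", "P2"), list("SLC9A7", "P2"),
    list("SLC13A3", "P3"), list("SLC13A4", "P4"),
    list("SLC35D2", "P5"), list("SLCO1A2", "P6")
  )
  for (i in seq_along(planting)) {
    gm <- plant_signal(gm, mk_variant("1", 1000 + i, planting[[i]][[1]]),
                       planting[[i]][[2]], "hom_alt")
  }
  gm
}
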