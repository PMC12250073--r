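catl <- load_builtin_catalog()

# cohort reproducing the shared-variant carrier patterns of the published
# report: 8 qualifying variants in 6 SLC genes, plus a decoy carried by one
# control and variants with no population frequency at all
shared_fixture <- function() {
  gm <- empty_cohort(6, 5)
  spec <- list(
    list("2",  "SLC39A10", "rs72913263",  0.015916, sprintf("P%d", 1:3), "het"),
    list("3",  "SLC6A1",   "rs41293373",  0.006309, sprintf("P%d", 1:3), "het"),
    list("4",  "SLC9B1",   "rs201645894", 0.036757, sprintf("P%d", 1:3), "het"),
    list("4",  "SLC9B1",   "rs369692318", 0.029791, sprintf("P%d", 1:4), "het"),
    list("4",  "SLC9B1",   "rs764250836", 0.009533, sprintf("P%d", 1:4), "het"),
    list("11", "SLC22A25", "rs61930188",  0.031116, sprintf("P%d", 1:3), "het"),
    list("14", "SLC38A6",  "rs17097938",  0.049403, sprintf("P%d", 1:3), "het"),
    list("17", "SPNS2",    "rs2144402808", 0,       sprintf("P%d", 1:3), "het")
  )
  pos <- 0
  for (s in spec) {
    pos <- pos + 100
    gm <- plant_signal(gm, mk_variant(s[[1]], pos, s[[2]], rsid = s[[3]],
                                      af_1kg = s[[4]]), s[[5]], s[[6]])
  }
  # the rs41293373 pattern: a fourth patient carries it in homozygosis
  gm$calls[4, which(gm$variants$rsid == "rs41293373")] <- "hom_alt"
  # decoy: carried by 3 patients AND 1 control, so not private to patients
  gm <- plant_signal(gm, mk_variant("11", 900, "SLC1A2", rsid = "rs_decoy",
                                    af_1kg = 0.02),
                     c("P1", "P2", "P3", "C1"), "het")
  # no-frequency variants carried by both arms (not filtered against)
  v <- mk_variant("11", 950, "MTCH2", rsid = "rs_nofreq")
  v$af_1kg <- NULL
  gm <- plant_signal(gm, v, c("P1", "P2", "C1", "C2"), "het")
  gm
}

test_that("carrier counting is presence-based across zygosity states", {
  gm <- shared_fixture()
  expect_equal(unname(carrier_counts(gm, "rs41293373")), c(4, 0))
  expect_equal(unname(carrier_counts(gm, "rs_decoy")), c(3, 1))
  # an all-reference variant has no carriers
  gm2 <- plant_signal(empty_cohort(2, 2), mk_variant("1", 1, "SLC6A1"),
                      "P1", "het")
  gm2$calls[1, 1] <- "hom_ref"
  expect_equal(unname(carrier_counts(gm2, 1)), c(0, 0))
  expect_error(carrier_counts(gm, "rs_not_there"), "unknown variant")
})

test_that("the patients-only criterion flags exactly the private variants", {
  gm <- shared_fixture()
  sh <- find_shared(gm, k = 3, c_max = 0)
  expect_equal(nrow(sh), nrow(gm$variants))  # report keeps every variant
  expect_equal(sum(sh$shared), 8)
  expect_setequal(unique(sh$gene[sh$shared]),
                  c("SLC39A10", "SLC6A1", "SLC9B1", "SLC22A25", "SLC38A6",
                    "SPNS2"))
  expect_false(sh$shared[sh$rsid == "rs_decoy"])
  expect_false(sh$shared[sh$rsid == "rs_nofreq"])  # only 2 patient carriers
  expect_true(sh$any_hom_patient[sh$rsid == "rs41293373"])
  expect_true(is.na(sh$maf[sh$rsid == "rs_nofreq"]))
  expect_equal(sh$maf[sh$rsid == "rs2144402808"], 0)
  # chromosome-ordered output (numeric chromosome order, not lexicographic)
  expect_equal(sh$chrom,
               c("2", "3", "4", "4", "4", "11", "11", "11", "14", "17"))
})

test_that("the shared set is monotone in k and c_max", {
  gm <- shared_fixture()
  sets <- lapply(0:6, function(k) which(find_shared(gm, k, 0)$shared))
  for (k in 1:6) expect_true(all(sets[[k + 1]] %in% sets[[k]]))
  s0 <- which(find_shared(gm, 3, 0)$shared)
  s1 <- which(find_shared(gm, 3, 1)$shared)
  expect_true(all(s0 %in% s1))
  expect_true("rs_decoy" %in% find_shared(gm, 3, 1)$rsid[s1])
  # vacuous criterion flags everything
  expect_true(all(find_shared(gm, k = 0, c_max = 11)$shared))
  expect_warning(find_shared(gm, k = 7), "exceeds")
})

test_that("carrier counts match a brute-force grid scan on random cohorts", {
  set.seed(55)
  ok <- TRUE
  for (rep in 1:200) {
    gm <- random_cohort(n_cases = 3, n_controls = 2, n_variants = 5)
    cc <- carrier_counts(gm)
    is_case <- gm$samples$status == "case"
    for (j in seq_len(nrow(gm$variants))) {
      np <- 0; nc <- 0
      for (i in seq_len(nrow(gm$samples))) {
        if (gm$calls[i, j] %in% c("het", "hom_alt", "hemi_alt")) {
          if (is_case[i]) np <- np + 1 else nc <- nc + 1
        }
      }
      ok <- ok && cc$n_patient_carriers[j] == np &&
        cc$n_control_carriers[j] == nc
    }
  }
  expect_true(ok)
})

test_that("mirrored frequencies are carrier percentages per arm", {
  gm <- plant_signal(empty_cohort(6, 5),
                     mk_variant("1", 10, "SLC6A1", rsid = "rs_a",
                                af_1kg = 0.01),
                     c("P1", "P2", "P3"), "het")
  v_all <- mk_variant("2", 20, "SLC9B1", rsid = "rs_b", af_1kg = 0.01)
  gm <- plant_signal(gm, v_all, c(sprintf("P%d", 1:6), sprintf("C%d", 1:5)),
                     "het")
  # non-SLC variants are excluded from the report
  gm <- plant_signal(gm, mk_variant("3", 30, "TRPM2", rsid = "rs_c",
                                    af_1kg = 0.01), "P1", "het")
  mt <- mirrored_frequency_table(gm, catl)
  expect_equal(nrow(mt), 2)
  expect_equal(mt$pct_controls[mt$rsid == "rs_a"], 0)
  expect_equal(mt$pct_patients[mt$rsid == "rs_a"], 50)
  expect_equal(mt$pct_controls[mt$rsid == "rs_b"], 100)
  expect_equal(mt$pct_patients[mt$rsid == "rs_b"], 100)
})

test_that("mirrored percentages match brute force on random cohorts", {
  set.seed(66)
  for (rep in 1:50) {
    gm <- random_cohort(n_variants = 10)
    mt <- mirrored_frequency_table(gm, catalog = NULL)
    expect_equal(nrow(mt), 10)
    is_case <- gm$samples$status == "case"
    for (j in seq_len(nrow(gm$variants))) {
      row <- which(mt$rsid == gm$variants$rsid[j])
      carriers <- gm$calls[, j] %in% c("het", "hom_alt", "hemi_alt")
      expect_equal(mt$pct_patients[row],
                   100 * sum(carriers & is_case) / sum(is_case))
      expect_equal(mt$pct_controls[row],
                   100 * sum(carriers & !is_case) / sum(!is_case))
    }
  }
})
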