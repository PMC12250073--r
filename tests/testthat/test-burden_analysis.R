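catl <- load_builtin_catalog()

test_that("Welch t reproduces hand-computed and published-count examples", {
  # homozygous SLC counts: controls [1,0,0,0,0] vs patients [2,2,1,1,1,1]
  w <- welch_t(c(1, 0, 0, 0, 0), c(2, 2, 1, 1, 1, 1))
  expect_equal(round(w$t, 2), -3.90)
  expect_equal(round(w$p, 4), 0.0036)
  # hand computation: means 2 and 5, variances 1, se = sqrt(2/3)
  w2 <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w2$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(round(w2$t, 4), -3.6742)
  expect_equal(w2$df, 4, tolerance = 1e-10)
  # identical arms
  w3 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w3$t, 0)
  expect_equal(w3$p, 1)
})

test_that("degenerate zero-variance arms have defined behaviour", {
  eq <- welch_t(c(4, 4, 4), c(4, 4))
  expect_equal(eq$t, 0); expect_equal(eq$p, 1); expect_true(eq$degenerate)
  ne <- welch_t(c(4, 4, 4), c(5, 5))
  expect_equal(ne$t, -Inf); expect_equal(ne$p, 0); expect_true(ne$degenerate)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Welch t agrees with stats::t.test and satisfies its invariants", {
  set.seed(123)
  for (rep in 1:50) {
    x <- rnorm(sample(2:9, 1)); y <- rnorm(sample(2:9, 1), mean = runif(1, -2, 2))
    w <- welch_t(x, y)
    ref <- t.test(x, y)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(w$p, ref$p.value, tolerance = 1e-12)
    # antisymmetry and p invariance under swapping arms
    ws <- welch_t(y, x)
    expect_equal(ws$t, -w$t, tolerance = 1e-12)
    expect_equal(ws$p, w$p, tolerance = 1e-12)
    # Welch-Satterthwaite df bounds
    expect_gte(w$df, min(length(x), length(y)) - 1 - 1e-9)
    expect_lte(w$df, length(x) + length(y) - 2 + 1e-9)
    # sign follows the mean difference
    if (mean(x) != mean(y)) expect_equal(sign(w$t), sign(mean(x) - mean(y)))
  }
})

test_that("Welch equals the pooled t when sizes and variances match", {
  set.seed(9)
  x <- rnorm(6)
  y <- x + 1.7  # same n, identical sample variance
  w <- welch_t(x, y)
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(w$t, unname(pooled$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(pooled$parameter), tolerance = 1e-12)
})

test_that("arm summaries reproduce the printed column-total means", {
  # group-table column totals: total / n gives the per-individual mean
  expect_equal(summarize_counts(c(4, 3, 3, 2, 3))$mean, 15 / 5)   # 3.0
  expect_equal(summarize_counts(rep(8, 6))$mean, 48 / 6)          # 8.0
  s <- summarize_counts(c(4, 4, 4))
  expect_equal(s$mean, 4); expect_equal(s$sem, 0)
  expect_error(summarize_counts(numeric(0)), "empty")
})

test_that("homozygous SLC burden reconstructs the published carrier pattern", {
  gm <- hom_slc_cohort()
  tab <- per_individual_burden(gm, "C", "hom", catl)
  expect_equal(unname(sort(tab$counts_controls, decreasing = TRUE)),
               c(1, 0, 0, 0, 0))
  expect_equal(unname(sort(tab$counts_cases, decreasing = TRUE)),
               c(2, 2, 1, 1, 1, 1))
  fit <- burden_test(gm, "C", "hom", catl)
  expect_equal(round(fit$test$t, 2), -3.90)
  expect_equal(round(fit$test$p, 4), 0.0036)
  # group A has no homozygous variants in this cohort
  tabA <- per_individual_burden(gm, "A", "hom", catl)
  expect_true(all(c(tabA$counts_cases, tabA$counts_controls) == 0))
})

test_that("empty cohorts give all-zero burden vectors", {
  tab <- per_individual_burden(empty_cohort(3, 2), "C", "hom", catl)
  expect_equal(unname(tab$counts_cases), c(0, 0, 0))
  expect_equal(unname(tab$counts_controls), c(0, 0))
})

test_that("burden counts equal a naive grid-scan oracle", {
  set.seed(31)
  cfg <- filter_config()
  for (rep in 1:25) {
    gm <- random_cohort(n_variants = 12)
    for (zyg in c("hom", "het")) {
      states <- if (zyg == "hom") c("hom_alt", "hemi_alt") else "het"
      tab <- per_individual_burden(gm, "C", zyg, catl, cfg)
      # oracle: scan every (sample, variant) cell
      pass <- passes_frequency(gm$variants, cfg)
      slc <- !is.na(parse_slc_family(gm$variants$gene, catl))
      for (i in seq_len(nrow(gm$samples))) {
        expected <- sum(pass & slc & gm$calls[i, ] %in% states)
        got <- c(tab$counts_cases, tab$counts_controls)[gm$samples$sample_id[i]]
        expect_equal(unname(got), expected)
      }
    }
  }
})

test_that("hemizygous-alternate calls follow the configured policy", {
  gm <- empty_cohort(2, 2)
  gm$samples$sex <- c("M", "F", "M", "F")
  v <- mk_variant("X", 500, "SLC6A14", af_1kg = 0.01)
  gm <- plant_signal(gm, v, "P1", "hemi_alt")
  hom_default <- per_individual_burden(gm, "C", "hom", catl)
  expect_equal(unname(hom_default$counts_cases), c(1, 0))
  hom_off <- per_individual_burden(gm, "C", "hom", catl,
                                   filter_config(hemi_as_hom = FALSE))
  expect_equal(unname(hom_off$counts_cases), c(0, 0))
  het_off <- per_individual_burden(gm, "C", "het", catl,
                                   filter_config(hemi_as_hom = FALSE))
  expect_equal(unname(het_off$counts_cases), c(1, 0))
})

test_that("location breakdown reproduces the published percentage rows", {
  # occurrence design: controls 31 R / 14 SC / 9 NSC, patients 32/34/27
  gm <- empty_cohort(6, 5)
  terms <- c(R = "3_prime_UTR_variant", SC = "synonymous_variant",
             NSC = "missense_variant")
  pos <- 0
  plant_occurrences <- function(gm, n, term, who) {
    for (i in seq_len(n)) {
      pos <<- pos + 1
      gm <- plant_signal(gm, mk_variant("3", pos, "SLC6A1",
                                        consequence = term, af_1kg = 0.01),
                         who[(i - 1) %% length(who) + 1], "het")
    }
    gm
  }
  ctrls <- sprintf("C%d", 1:5); cases <- sprintf("P%d", 1:6)
  gm <- plant_occurrences(gm, 31, terms["R"], ctrls)
  gm <- plant_occurrences(gm, 14, terms["SC"], ctrls)
  gm <- plant_occurrences(gm, 9, terms["NSC"], ctrls)
  gm <- plant_occurrences(gm, 32, terms["R"], cases)
  gm <- plant_occurrences(gm, 34, terms["SC"], cases)
  gm <- plant_occurrences(gm, 27, terms["NSC"], cases)
  lb <- location_breakdown(gm, "C_restricted", "het", catl)
  expect_equal(unname(lb$counts[, "control"]), c(31, 14, 9))
  expect_equal(unname(lb$counts[, "case"]), c(32, 34, 27))
  expect_equal(unname(round(lb$percents[, "control"])), c(57, 26, 17))
  expect_equal(unname(round(lb$percents[, "case"])), c(34, 37, 29))
})

test_that("single-category breakdown yields 100/0/0", {
  gm <- plant_signal(empty_cohort(2, 2),
                     mk_variant("3", 1, "SLC6A1",
                                consequence = "3_prime_UTR_variant",
                                af_1kg = 0.01), "P1", "het")
  lb <- location_breakdown(gm, "C_restricted", "het", catl)
  expect_equal(unname(lb$percents[, "case"]), c(100, 0, 0))
})

test_that("scenario counts recount exactly and nest per individual", {
  set.seed(77)
  for (rep in 1:10) {
    gm <- random_cohort(n_variants = 15)
    sc <- exome_scenario_counts(gm)
    # oracle for scenario a: every non-reference call counts
    carrier <- gm$calls %in% c("het", "hom_alt", "hemi_alt")
    dim(carrier) <- dim(gm$calls)
    expect_equal(unname(sc$scenarios$a$counts), rowSums(carrier))
    expect_true(all(sc$scenarios$b$counts <= sc$scenarios$c$counts))
    expect_true(all(sc$scenarios$c$counts <= sc$scenarios$a$counts))
  }
})
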