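# Per-individual burden counts by gene group and zygosity, arm summaries,
# Welch comparison, the R/SC/NSC location breakdown and the whole-exome
# scenario counts.

.zygosity_states_for <- function(zygosity, config) {
  switch(zygosity,
    hom = if (config$hemi_as_hom) c("hom_alt", "hemi_alt") else "hom_alt",
    het = if (config$hemi_as_hom) "het" else c("het", "hemi_alt"),
    stop("zygosity must be 'hom' or 'het'")
  )
}

#' Per-individual rare-variant burden for one gene group
#'
#' Counts, for every individual, the filtered variants in the group's genes
#' at which that individual carries the requested zygosity. Hemizygous-
#' alternate calls count as homozygous under the default policy (single-copy
#' X variants in males are functionally equivalent to two-copy dosage); each
#' variant contributes at most once per individual.
#'
#' @param gm A [genotype_matrix].
#' @param group One of `"A"`, `"B"`, `"C"`, `"C_restricted"`, `"D"`,
#'   `"D_risk"`, `"D_protective"`.
#' @param zygosity `"hom"` or `"het"`.
#' @param catalog A [load_builtin_catalog()] gene catalog.
#' @param config A [filter_config()]; the default is the gene-group filter
#'   (MAF < 0.05, missing frequencies pass).
#' @return A list of class `burden_table` with per-individual count vectors
#'   `counts_cases` and `counts_controls` (named by sample id).
#' @export
per_individual_burden <- function(gm, group, zygosity = c("hom", "het"),
                                  catalog = load_builtin_catalog(),
                                  config = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  zygosity <- match.arg(zygosity)
  fgm <- apply_scenario(gm, config)
  in_group <- if (nrow(fgm$variants) > 0)
    gene_in_group(fgm$variants$gene, group, catalog) else logical(0)
  fgm <- subset_variants(fgm, which(in_group))
  states <- .zygosity_states_for(zygosity, config)
  counts <- if (ncol(fgm$calls) > 0)
    rowSums(matrix(fgm$calls %in% states, nrow = nrow(fgm$calls)))
  else rep(0L, nrow(fgm$samples))
  names(counts) <- fgm$samples$sample_id
  is_case <- fgm$samples$status == "case"
  structure(list(group = group, zygosity = zygosity,
                 counts_cases = counts[is_case],
                 counts_controls = counts[!is_case]),
            class = "burden_table")
}

#' Burden comparison between arms for one gene group
#'
#' The central analysis: per-individual qualifying-variant counts in a gene
#' group at a given zygosity, summarized per arm (mean +/- SEM) and compared
#' with the Welch unequal-variance t-test. Control arm first, so a negative
#' statistic means a higher burden in patients.
#'
#' @inheritParams per_individual_burden
#' @return An object of class `burden_test` with the `burden_table`, per-arm
#'   summaries, and the [welch_t()] result.
#' @examples
#' \dontrun{
#' fit <- burden_test(gm, group = "C", zygosity = "hom")
#' print(fit)
#' }
#' @export
burden_test <- function(gm, group, zygosity = c("hom", "het"),
                        catalog = load_builtin_catalog(),
                        config = filter_config()) {
  zygosity <- match.arg(zygosity)
  tab <- per_individual_burden(gm, group, zygosity, catalog, config)
  test <- welch_t(tab$counts_controls, tab$counts_cases)
  structure(list(group = group, zygosity = zygosity, table = tab,
                 controls = summarize_counts(tab$counts_controls),
                 cases = summarize_counts(tab$counts_cases),
                 test = test),
            class = "burden_test")
}

#' @export
print.burden_test <- function(x, digits = 3, ...) {
  cat(sprintf("Rare-variant burden: group %s, %szygous\n", x$group,
              if (x$zygosity == "hom") "homo" else "hetero"))
  cat(sprintf("  controls (n=%d): mean %s +/- %s SEM\n", x$controls$n,
              format(x$controls$mean, digits = digits),
              format(x$controls$sem, digits = digits)))
  cat(sprintf("  patients (n=%d): mean %s +/- %s SEM\n", x$cases$n,
              format(x$cases$mean, digits = digits),
              format(x$cases$sem, digits = digits)))
  cat(sprintf("  Welch t = %s, df = %s, p = %s %s\n",
              format(x$test$t, digits = digits),
              format(x$test$df, digits = digits),
              format(x$test$p, digits = digits), sig_mark(x$test$p)))
  invisible(x)
}

#' @export
summary.burden_test <- function(object, ...) {
  data.frame(
    group = object$group, zygosity = object$zygosity,
    arm = c("control", "case"),
    n = c(object$controls$n, object$cases$n),
    total = c(sum(object$table$counts_controls),
              sum(object$table$counts_cases)),
    mean = c(object$controls$mean, object$cases$mean),
    sem = c(object$controls$sem, object$cases$sem),
    t = object$test$t, df = object$test$df, p = object$test$p,
    sig = sig_mark(object$test$p),
    stringsAsFactors = FALSE
  )
}

#' Burden table as a tidy data frame
#'
#' @param x A `burden_table` or `burden_test`.
#' @export
as.data.frame.burden_table <- function(x, ...) {
  data.frame(
    sample_id = c(names(x$counts_controls), names(x$counts_cases)),
    arm = rep(c("control", "case"),
              c(length(x$counts_controls), length(x$counts_cases))),
    group = x$group, zygosity = x$zygosity,
    count = c(unname(x$counts_controls), unname(x$counts_cases)),
    stringsAsFactors = FALSE
  )
}

#' Variant-location (R / SC / NSC) breakdown for a gene group
#'
#' Occurrence counts are carrier-variant pairs: a variant carried by three
#' individuals of an arm contributes three occurrences. Percentages are per
#' arm over the three-category total (rounded to integers for display).
#' A Welch comparison of the per-individual counts is attached per category.
#'
#' @inheritParams per_individual_burden
#' @return An object of class `location_breakdown` with `counts`, `percents`
#'   and per-category `tests`.
#' @export
location_breakdown <- function(gm, group = "C_restricted", zygosity = "het",
                               catalog = load_builtin_catalog(),
                               config = filter_config()) {
  fgm <- apply_scenario(gm, config)
  in_group <- if (nrow(fgm$variants) > 0)
    gene_in_group(fgm$variants$gene, group, catalog) else logical(0)
  fgm <- subset_variants(fgm, which(in_group))
  states <- .zygosity_states_for(zygosity, config)
  cls <- classify_consequence(fgm$variants$consequence,
                              splice_as_nsc = config$splice_as_nsc)
  is_case <- fgm$samples$status == "case"
  cats <- c("R", "SC", "NSC")
  counts <- matrix(0L, nrow = 3, ncol = 2,
                   dimnames = list(cats, c("control", "case")))
  tests <- list()
  carried <- fgm$calls %in% states
  dim(carried) <- dim(fgm$calls)
  for (cat_i in cats) {
    sel <- cls == cat_i
    per_ind <- if (any(sel))
      rowSums(carried[, sel, drop = FALSE]) else rep(0L, nrow(fgm$samples))
    counts[cat_i, "control"] <- sum(per_ind[!is_case])
    counts[cat_i, "case"] <- sum(per_ind[is_case])
    tests[[cat_i]] <- welch_t(per_ind[!is_case], per_ind[is_case])
  }
  totals <- colSums(counts)
  percents <- sweep(counts, 2, pmax(totals, 1), "/") * 100
  structure(list(group = group, zygosity = zygosity, counts = counts,
                 percents = percents, tests = tests),
            class = "location_breakdown")
}

#' @export
print.location_breakdown <- function(x, ...) {
  cat(sprintf("Variant location breakdown (group %s, %s)\n",
              x$group, x$zygosity))
  for (cat_i in rownames(x$counts)) {
    tt <- x$tests[[cat_i]]
    cat(sprintf("  %-4s controls %3d (%d%%)  patients %3d (%d%%)   t = %s (p = %s %s)\n",
                cat_i,
                x$counts[cat_i, "control"], round(x$percents[cat_i, "control"]),
                x$counts[cat_i, "case"], round(x$percents[cat_i, "case"]),
                format(tt$t, digits = 3), format(tt$p, digits = 2),
                sig_mark(tt$p)))
  }
  invisible(x)
}

#' Whole-exome per-individual variant counts under the three filter scenarios
#'
#' For scenarios `a` (quality only), `b` (rare coding) and `c` (rare
#' non-intronic), counts the passing variants each individual carries (any
#' non-reference call) and compares arms with the Welch test. Survivor sets
#' nest (b within c within a), so per-individual counts are ordered
#' accordingly.
#'
#' @param gm A [genotype_matrix].
#' @param scenarios Character vector of scenarios to run.
#' @param ... Passed to [filter_config()] (e.g. quality gates).
#' @return An object of class `scenario_counts`: per-scenario per-individual
#'   counts plus Welch results.
#' @export
exome_scenario_counts <- function(gm, scenarios = c("a", "b", "c"), ...) {
  is_case <- gm$samples$status == "case"
  out <- list()
  for (sc in scenarios) {
    fgm <- apply_scenario(gm, filter_config(scenario = sc, ...))
    carried <- fgm$calls %in% CARRIER_STATES
    dim(carried) <- dim(fgm$calls)
    counts <- rowSums(carried)
    names(counts) <- gm$samples$sample_id
    out[[sc]] <- list(counts = counts,
                      test = welch_t(counts[!is_case], counts[is_case]))
  }
  structure(list(scenarios = out,
                 samples = gm$samples[, c("sample_id", "status")]),
            class = "scenario_counts")
}

#' @export
print.scenario_counts <- function(x, ...) {
  cat("Whole-exome variant counts per filter scenario\n")
  for (sc in names(x$scenarios)) {
    s <- x$scenarios[[sc]]
    is_case <- x$samples$status == "case"
    cat(sprintf("  (%s) controls mean %.2f, patients mean %.2f, t = %s (p = %s %s)\n",
                sc, mean(s$counts[!is_case]), mean(s$counts[is_case]),
                format(s$test$t, digits = 3), format(s$test$p, digits = 2),
                sig_mark(s$test$p)))
  }
  invisible(x)
}
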