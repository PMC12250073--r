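# End-to-end driver: (simulate |) read -> filter -> burden -> shared ->
# enrichment, with a machine-readable JSON summary and a run log. The
# pipeline is a pure function of (inputs, parameters, seed); reruns with the
# same arguments produce byte-identical summaries.

#' Run the full case-control rare-variant pipeline
#'
#' Either reads an annotated cohort (`vcf` + `sample_sheet`) or simulates
#' one (`sim`), then produces: whole-exome scenario counts, burden tables
#' with Welch statistics and significance marks for every requested gene
#' group and zygosity, the variant-location breakdown for the restricted
#' SLC list, the shared-variant report, the mirrored carrier-frequency
#' table, and (when an annotation is supplied) the over-representation
#' table for the shared/homozygous candidate genes. All tables are written
#' as TSV under `out_dir` together with `summary.json` and `run.log`.
#'
#' @param out_dir Output directory (created if needed).
#' @param vcf,sample_sheet Paths to the input cohort; ignored when `sim` is
#'   given.
#' @param sim Optional [sim_config()]; when supplied the cohort is simulated
#'   and its VCF/sample sheet are written into `out_dir`.
#' @param catalog Gene catalog.
#' @param groups Gene groups to run burden tests for.
#' @param maf_threshold,missing_af Passed to [filter_config()] for the
#'   group analyses.
#' @param k,c_max Shared-variant criterion.
#' @param annotation Optional gene-to-term annotation (path or data frame)
#'   for enrichment.
#' @param query Optional gene list for enrichment; defaults to the genes of
#'   homozygous patient variants plus shared-variant genes found in the run.
#' @return Invisibly, a list with every result object and the output paths.
#' @export
run_pipeline <- function(out_dir,
                         vcf = NULL, sample_sheet = NULL, sim = NULL,
                         catalog = load_builtin_catalog(),
                         groups = c("A", "B", "C", "C_restricted",
                                    "D_risk", "D_protective"),
                         maf_threshold = 0.05,
                         missing_af = "pass",
                         k = 3, c_max = 0,
                         annotation = NULL, query = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- c(
    sprintf("rvburden %s | R %s.%s",
            as.character(utils::packageVersion("rvburden")),
            R.version$major, R.version$minor),
    sprintf("parameters: maf_threshold=%g missing_af=%s k=%d c_max=%d",
            maf_threshold, missing_af, k, c_max)
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  gm <- stage("input", {
    if (!is.null(sim)) {
      log_lines <- c(log_lines, sprintf("simulated cohort, seed=%d", sim$seed))
      res <- simulate_cohort(sim, file.path(out_dir, "cohort.vcf"),
                             file.path(out_dir, "sample_sheet.tsv"), catalog)
      res$matrix
    } else {
      if (is.null(vcf) || is.null(sample_sheet)) {
        stop("either (vcf, sample_sheet) or sim must be given")
      }
      read_cohort(vcf, sample_sheet)
    }
  })
  cfg <- filter_config(scenario = "group", maf_threshold = maf_threshold,
                       missing_af = missing_af)

  scen <- stage("scenario_counts", exome_scenario_counts(gm))
  scen_df <- do.call(rbind, lapply(names(scen$scenarios), function(s) {
    st <- scen$scenarios[[s]]
    data.frame(scenario = s, sample_id = names(st$counts),
               count = unname(st$counts), t = st$test$t, p = st$test$p,
               stringsAsFactors = FALSE)
  }))
  write_report(scen_df, file.path(out_dir, "scenario_counts.tsv"))

  burdens <- list()
  for (g in groups) {
    for (z in c("hom", "het")) {
      fit <- stage(paste0("burden_", g, "_", z),
                   burden_test(gm, g, z, catalog, cfg))
      burdens[[paste(g, z, sep = "_")]] <- fit
    }
  }
  burden_df <- do.call(rbind, lapply(burdens, summary))
  rownames(burden_df) <- NULL
  write_report(burden_df, file.path(out_dir, "burden_tables.tsv"))

  loc <- stage("location_breakdown",
               location_breakdown(gm, "C_restricted", "het", catalog, cfg))
  loc_df <- data.frame(
    location = rownames(loc$counts),
    controls = loc$counts[, "control"],
    controls_pct = round(loc$percents[, "control"]),
    patients = loc$counts[, "case"],
    patients_pct = round(loc$percents[, "case"]),
    t = vapply(loc$tests, function(t) t$t, numeric(1)),
    p = vapply(loc$tests, function(t) t$p, numeric(1)),
    stringsAsFactors = FALSE
  )
  write_report(loc_df, file.path(out_dir, "location_breakdown.tsv"))

  filtered <- apply_scenario(gm, cfg)
  shared <- stage("shared_variants", find_shared(filtered, k, c_max))
  write_report(as.data.frame(shared), file.path(out_dir, "shared_variants.tsv"))
  mirrored <- stage("mirrored_frequencies",
                    mirrored_frequency_table(filtered, catalog))
  write_report(as.data.frame(mirrored),
               file.path(out_dir, "mirrored_frequencies.tsv"))

  enr <- NULL
  if (!is.null(annotation)) {
    if (is.null(query)) {
      hom_states <- c("hom_alt", "hemi_alt")
      is_case <- gm$samples$status == "case"
      hom_any <- colSums(matrix(filtered$calls[is_case, , drop = FALSE] %in%
                                  hom_states, nrow = sum(is_case))) > 0
      slc <- gene_in_group(filtered$variants$gene, "C", catalog)
      query <- unique(stats::na.omit(c(
        filtered$variants$gene[hom_any & slc],
        shared$gene[shared$shared]
      )))
    }
    enr <- stage("enrichment", enrich_terms(query, annotation))
    write_report(enr$results, file.path(out_dir, "enrichment.tsv"))
  }

  summary_list <- list(
    schema_version = "1.0",
    n_cases = sum(gm$samples$status == "case"),
    n_controls = sum(gm$samples$status == "control"),
    n_variants = nrow(gm$variants),
    scenario_tests = lapply(scen$scenarios, function(s)
      list(t = s$test$t, p = s$test$p)),
    burden = lapply(burdens, function(b)
      list(t = b$test$t, df = b$test$df, p = b$test$p,
           sig = sig_mark(b$test$p),
           mean_controls = b$controls$mean, mean_cases = b$cases$mean)),
    shared_variants = sum(shared$shared),
    enrichment_terms = if (is.null(enr)) NULL else nrow(enr$report)
  )
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)

  invisible(list(matrix = gm, scenarios = scen, burdens = burdens,
                 location = loc, shared = shared, mirrored = mirrored,
                 enrichment = enr, out_dir = out_dir))
}
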