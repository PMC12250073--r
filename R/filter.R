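# Frequency filtering and consequence classification.
#
# The "MAF" used throughout is the MAXIMUM alternate-allele frequency across
# the population databases annotating a variant (1000 Genomes, ExAC, ESP,
# gnomAD v2 exomes/genomes, gnomAD v3); a variant passes when that maximum is
# strictly below the threshold, and a variant with no frequency in any
# database passes by default (it cannot be filtered against).

# database columns of the variant table, in fixed order
AF_DB_COLS <- c("af_1kg", "af_exac", "af_esp", "af_gne", "af_gng", "af_gn3")
AF_INFO_KEYS <- c("AF_1KG", "AF_EXAC", "AF_ESP", "AF_GNE", "AF_GNG", "AF_GN3")

ZYGOSITY_STATES <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt",
                     "missing")
CARRIER_STATES <- c("het", "hom_alt", "hemi_alt")

#' Filtering configuration
#'
#' @param scenario One of `"a"` (quality gates only), `"b"` (rare coding:
#'   MAF < 0.01 and a synonymous or non-synonymous coding change), `"c"`
#'   (rare non-intronic: MAF < 0.01 and any consequence class except
#'   intronic), or `"group"` (the gene-group analyses: MAF < 0.05, all
#'   consequence classes).
#' @param maf_threshold Frequency threshold; variants pass strictly below it.
#'   Defaults to 0.01 for scenarios b/c and 0.05 for the group analysis.
#' @param missing_af `"pass"` (default) lets variants with no database
#'   frequency through; `"fail"` drops them.
#' @param hemi_as_hom Count hemizygous-alternate calls (X in males) as
#'   homozygous in burden counts (default `TRUE`).
#' @param splice_as_nsc Classify splice-affecting terms as non-synonymous
#'   coding (default `TRUE`); set `FALSE` to reroute them to `other`.
#' @param min_gq,min_dp Optional per-call quality gates; calls below either
#'   gate are recoded to missing when the genotype matrix carries GQ/DP.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(scenario = c("group", "a", "b", "c"),
                          maf_threshold = NULL,
                          missing_af = c("pass", "fail"),
                          hemi_as_hom = TRUE,
                          splice_as_nsc = TRUE,
                          min_gq = NULL, min_dp = NULL) {
  scenario <- match.arg(scenario)
  missing_af <- match.arg(missing_af)
  if (is.null(maf_threshold)) {
    maf_threshold <- switch(scenario, a = NA_real_, b = 0.01, c = 0.01,
                            group = 0.05)
  }
  if (!is.na(maf_threshold) &&
      (maf_threshold < 0 || maf_threshold > 1)) {
    stop("maf_threshold must lie in [0, 1]")
  }
  structure(list(scenario = scenario, maf_threshold = maf_threshold,
                 missing_af = missing_af, hemi_as_hom = hemi_as_hom,
                 splice_as_nsc = splice_as_nsc,
                 min_gq = min_gq, min_dp = min_dp),
            class = "filter_config")
}

#' Effective (maximum-across-databases) allele frequency
#'
#' @param variants A variant table (the `$variants` data frame of a
#'   [genotype_matrix]) or a whole `genotype_matrix`.
#' @return Numeric vector: the maximum frequency over the reporting
#'   databases per variant, `NA` when no database reports one.
#' @examples
#' v <- data.frame(af_1kg = 0.002, af_gne = 0.006309)
#' effective_maf(v)  # 0.006309
#' @export
effective_maf <- function(variants) {
  if (inherits(variants, "genotype_matrix")) variants <- variants$variants
  cols <- intersect(AF_DB_COLS, names(variants))
  if (length(cols) == 0 || nrow(variants) == 0) {
    return(rep(NA_real_, nrow(variants)))
  }
  m <- as.matrix(variants[, cols, drop = FALSE])
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("allele frequency outside [0, 1]")
  }
  out <- apply(m, 1L, function(r) if (all(is.na(r))) NA_real_
               else max(r, na.rm = TRUE))
  as.numeric(out)
}

#' Frequency filter predicate
#'
#' A variant passes when its effective MAF is strictly below the threshold,
#' or when it has no database frequency at all and the missing-frequency
#' policy is `"pass"`.
#'
#' @inheritParams effective_maf
#' @param config A [filter_config()].
#' @return Logical vector, one entry per variant.
#' @export
passes_frequency <- function(variants, config = filter_config()) {
  maf <- effective_maf(variants)
  if (is.na(config$maf_threshold)) {
    return(rep(TRUE, length(maf)))
  }
  ifelse(is.na(maf), config$missing_af == "pass", maf < config$maf_threshold)
}

.R_TERMS <- c("5_prime_UTR_variant", "3_prime_UTR_variant",
              "upstream_gene_variant", "downstream_gene_variant",
              "regulatory_region_variant", "promoter_variant",
              "TF_binding_site_variant",
              "non_coding_transcript_exon_variant")
.SC_TERMS <- c("synonymous_variant", "stop_retained_variant")
.NSC_TERMS <- c("missense_variant", "stop_gained", "stop_lost", "start_lost",
                "inframe_insertion", "inframe_deletion", "frameshift_variant",
                "protein_altering_variant")
.SPLICE_TERMS <- c("splice_donor_variant", "splice_acceptor_variant",
                   "splice_region_variant")
.INTRON_TERMS <- c("intron_variant")

#' Classify a consequence term into the R / SC / NSC / intronic scheme
#'
#' The scheme follows the variant-location classes used in the burden
#' tables: `R` — change in a regulatory region (UTRs, up/downstream,
#' promoter/regulatory region, non-coding exon); `SC` — synonymous coding
#' change; `NSC` — non-synonymous coding change (amino-acid altering,
#' including splice-affecting terms by default); `intronic`; anything else
#' maps to `other`. Total and deterministic; never raises.
#'
#' @param term Character vector of Sequence Ontology-style consequence terms.
#' @param splice_as_nsc Count splice donor/acceptor/region terms as NSC
#'   (default) rather than `other`.
#' @return Character vector over `c("R", "SC", "NSC", "intronic", "other")`.
#' @examples
#' classify_consequence(c("3_prime_UTR_variant", "synonymous_variant",
#'                        "splice_acceptor_variant", "intron_variant"))
#' @export
classify_consequence <- function(term, splice_as_nsc = TRUE) {
  t <- tolower(trimws(as.character(term)))
  out <- rep("other", length(t))
  out[t %in% tolower(.R_TERMS)] <- "R"
  out[t %in% tolower(.SC_TERMS)] <- "SC"
  out[t %in% tolower(.NSC_TERMS)] <- "NSC"
  if (splice_as_nsc) out[t %in% tolower(.SPLICE_TERMS)] <- "NSC"
  out[t %in% tolower(.INTRON_TERMS)] <- "intronic"
  # labels are fixed points, so classification is idempotent
  out[t %in% c("r", "sc", "nsc")] <- toupper(t[t %in% c("r", "sc", "nsc")])
  out[t == "intronic"] <- "intronic"
  out
}

#' Restrict a genotype matrix to the variants passing a filter scenario
#'
#' Applies the configured scenario: quality gates only (`a`); rare coding
#' changes (`b`: MAF < 0.01, consequence class SC or NSC); rare non-intronic
#' changes (`c`: MAF < 0.01, any class but intronic); or the gene-group
#' filter (`group`: MAF < 0.05). Variant order is preserved, so survivor
#' sets nest: b within c within a.
#'
#' @param gm A [genotype_matrix].
#' @param config A [filter_config()].
#' @return The genotype matrix restricted to passing variants.
#' @export
apply_scenario <- function(gm, config = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm <- .apply_quality_gates(gm, config)
  if (nrow(gm$variants) == 0) return(gm)
  keep <- passes_frequency(gm$variants, config)
  cls <- classify_consequence(gm$variants$consequence,
                              splice_as_nsc = config$splice_as_nsc)
  keep <- switch(config$scenario,
    a = rep(TRUE, nrow(gm$variants)),
    b = keep & cls %in% c("SC", "NSC"),
    c = keep & cls != "intronic",
    group = keep,
    stop("unknown scenario: ", config$scenario)
  )
  subset_variants(gm, which(keep))
}

.apply_quality_gates <- function(gm, config) {
  if (!is.null(config$min_gq) && !is.null(gm$gq)) {
    gm$calls[!is.na(gm$gq) & gm$gq < config$min_gq] <- "missing"
  }
  if (!is.null(config$min_dp) && !is.null(gm$dp)) {
    gm$calls[!is.na(gm$dp) & gm$dp < config$min_dp] <- "missing"
  }
  gm
}
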