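# Cohort container and VCF / sample-sheet I/O.
#
# A genotype_matrix holds the whole cohort: a sample sheet (id, case/control
# status, sex, age), a normalized biallelic variant table (chrom, pos, ref,
# alt, rsid, gene, consequence term, per-database allele frequencies) and a
# samples x variants call matrix over the six zygosity states hom_ref, het,
# hom_alt, hemi_ref, hemi_alt, missing.

#' Construct a genotype matrix
#'
#' Low-level constructor; most users get one from [read_cohort()] or
#' [simulate_cohort()].
#'
#' @param samples Data frame with columns `sample_id`, `status`
#'   (`"case"`/`"control"`), `sex` (`"F"`/`"M"`), `age`.
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `rsid`, `gene`, `consequence` and the six database-frequency columns
#'   `af_1kg`, `af_exac`, `af_esp`, `af_gne`, `af_gng`, `af_gn3` (`NA` =
#'   the database reports no frequency).
#' @param calls Character matrix, `nrow(samples)` x `nrow(variants)`, over
#'   the six zygosity states.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, variants, calls) {
  samples <- as.data.frame(samples)
  variants <- as.data.frame(variants)
  stopifnot(
    all(c("sample_id", "status", "sex") %in% names(samples)),
    !anyDuplicated(samples$sample_id),
    all(samples$status %in% c("case", "control"))
  )
  for (col in AF_DB_COLS) {
    if (!col %in% names(variants)) {
      variants[[col]] <- rep(NA_real_, nrow(variants))
    }
  }
  calls <- matrix(as.character(calls), nrow = nrow(samples),
                  ncol = nrow(variants),
                  dimnames = list(samples$sample_id, NULL))
  bad <- !(calls %in% ZYGOSITY_STATES)
  if (any(bad)) {
    stop("invalid zygosity state(s): ",
         paste(unique(calls[bad]), collapse = ", "))
  }
  if (nrow(variants) > 0 && any(variants$pos < 1)) stop("pos must be >= 1")
  structure(list(samples = samples, variants = variants, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_case <- sum(x$samples$status == "case")
  n_ctrl <- sum(x$samples$status == "control")
  cat(sprintf("Genotype matrix: %d samples (%d cases, %d controls) x %d variants\n",
              nrow(x$samples), n_case, n_ctrl, nrow(x$variants)))
  if (nrow(x$variants) > 0) {
    tab <- table(factor(x$calls, levels = ZYGOSITY_STATES))
    cat("  calls:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Restrict a genotype matrix to a subset of variants
#'
#' @param gm A `genotype_matrix`.
#' @param idx Integer indices of the variants to keep (order preserved).
#' @export
subset_variants <- function(gm, idx) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm$variants <- gm$variants[idx, , drop = FALSE]
  rownames(gm$variants) <- NULL
  gm$calls <- gm$calls[, idx, drop = FALSE]
  if (!is.null(gm$gq)) gm$gq <- gm$gq[, idx, drop = FALSE]
  if (!is.null(gm$dp)) gm$dp <- gm$dp[, idx, drop = FALSE]
  gm
}

#' Read an annotated multi-sample VCF and its sample sheet
#'
#' Multi-allelic records are split into one biallelic record per alternate
#' allele, with the genotype recoded per allele. Diploid genotypes map
#' `0/0 -> hom_ref`, `0/1` or `1/0 -> het`, `1/1 -> hom_alt`, any missing
#' allele `-> missing`; haploid genotypes (X/Y in males) map to
#' `hemi_ref`/`hemi_alt`. Phase separators are ignored. Per-variant
#' annotations are taken from the INFO column; a missing key leaves the
#' field absent (`NA`), which is what drives the missing-frequency
#' pass-through in filtering.
#'
#' @param vcf_path Path to a VCF 4.x file with GT in FORMAT.
#' @param sheet_path Path to a TSV sample sheet with columns `sample_id`,
#'   `status` (`case`/`control`), `sex` (`F`/`M`), `age`.
#' @param info_keys Named list mapping the internal fields `gene`,
#'   `consequence`, `rsid` and the six frequency slots to INFO key names;
#'   override to read VCFs annotated with a different dialect.
#' @return A [genotype_matrix].
#' @export
read_cohort <- function(vcf_path, sheet_path,
                        info_keys = list(gene = "GENE", consequence = "CSQTERM",
                                         rsid = "RSID", af = AF_INFO_KEYS)) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  if (!file.exists(sheet_path)) stop("sample sheet not found: ", sheet_path)
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "status", "sex")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns sample_id, status, sex")
  }
  bad_status <- setdiff(unique(sheet$status), c("case", "control"))
  if (length(bad_status) > 0) {
    stop("unknown status value(s): ", paste(bad_status, collapse = ", "))
  }

  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcf@gt
  vcf_samples <- colnames(gt_raw)[-1]
  missing_samples <- setdiff(vcf_samples, sheet$sample_id)
  if (length(missing_samples) > 0) {
    stop("VCF sample(s) absent from sample sheet: ",
         paste(missing_samples, collapse = ", "))
  }
  sheet <- sheet[match(vcf_samples, sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL

  if (nrow(fix) == 0) {
    return(genotype_matrix(sheet, .empty_variant_table(),
                           matrix(character(0), nrow = nrow(sheet), ncol = 0)))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  info <- list(
    gene = vcfR::extract.info(vcf, info_keys$gene),
    consequence = vcfR::extract.info(vcf, info_keys$consequence),
    rsid = vcfR::extract.info(vcf, info_keys$rsid)
  )
  afs <- lapply(info_keys$af, function(k)
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, k))))

  var_rows <- list(); call_cols <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    rsid <- if (!is.na(fix$ID[i]) && fix$ID[i] != ".") fix$ID[i]
            else info$rsid[i]
    for (j in seq_along(alts)) {
      row <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j],
        rsid = if (is.na(rsid)) NA_character_ else rsid,
        gene = info$gene[i], consequence = info$consequence[i],
        stringsAsFactors = FALSE
      )
      for (d in seq_along(AF_DB_COLS)) row[[AF_DB_COLS[d]]] <- afs[[d]][i]
      var_rows[[length(var_rows) + 1L]] <- row
      call_cols[[length(call_cols) + 1L]] <-
        vapply(gt[i, vcf_samples], .recode_gt, character(1), alt_index = j)
    }
  }
  variants <- do.call(rbind, var_rows)
  calls <- do.call(cbind, call_cols)
  genotype_matrix(sheet, variants, calls)
}

# map one GT string onto the zygosity state for alternate allele alt_index
.recode_gt <- function(gt, alt_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return("missing")
  if (!all(grepl("^[0-9]+$", alleles))) stop("malformed GT: ", gt)
  n_alt <- sum(alleles == as.character(alt_index))
  if (length(alleles) == 1L) {
    return(if (n_alt == 1L) "hemi_alt" else "hemi_ref")
  }
  c("hom_ref", "het", "hom_alt")[n_alt + 1L]
}

.empty_variant_table <- function() {
  v <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), rsid = character(0), gene = character(0),
                  consequence = character(0), stringsAsFactors = FALSE)
  for (col in AF_DB_COLS) v[[col]] <- numeric(0)
  v
}

#' Write / read a tabular report
#'
#' Reports are plain TSV; `read_report()` of a `write_report()` output
#' reproduces the table cell for cell.
#'
#' @param table A data frame (may have zero rows; the header is still
#'   written).
#' @param path Output path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   data frame.
#' @export
write_report <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
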