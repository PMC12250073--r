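# Carrier counting per variant and arm, the shared-variant criterion
# (>= k patients, <= c_max controls), and the mirrored-frequency report.

# chromosome labels ordered 1..22, X, Y, MT, then anything else
.chrom_order <- function(chrom) {
  c0 <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  rank <- suppressWarnings(as.numeric(c0))
  rank[toupper(c0) == "X"] <- 23
  rank[toupper(c0) == "Y"] <- 24
  rank[toupper(c0) %in% c("MT", "M")] <- 25
  rank[is.na(rank)] <- 26
  rank
}

#' Carrier counts per variant and arm
#'
#' A carrier is any sample with a heterozygous, homozygous-alternate or
#' hemizygous-alternate call; presence, not dosage, so a homozygote counts
#' once.
#'
#' @param gm A [genotype_matrix].
#' @param variant Optional: a variant index, or an rsid, to count a single
#'   variant; by default counts all.
#' @return With `variant`: a named integer vector `c(n_patients, n_controls)`.
#'   Without: a data frame with `n_patient_carriers`, `n_control_carriers`
#'   and `any_hom_patient` per variant.
#' @export
carrier_counts <- function(gm, variant = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  is_case <- gm$samples$status == "case"
  carried <- gm$calls %in% CARRIER_STATES
  dim(carried) <- dim(gm$calls)
  hom <- gm$calls %in% c("hom_alt", "hemi_alt")
  dim(hom) <- dim(gm$calls)
  res <- data.frame(
    n_patient_carriers = colSums(carried[is_case, , drop = FALSE]),
    n_control_carriers = colSums(carried[!is_case, , drop = FALSE]),
    any_hom_patient = colSums(hom[is_case, , drop = FALSE]) > 0
  )
  if (is.null(variant)) return(res)
  idx <- if (is.character(variant)) match(variant, gm$variants$rsid)
         else as.integer(variant)
  if (is.na(idx) || idx < 1 || idx > nrow(res)) {
    stop("unknown variant: ", variant)
  }
  c(n_patients = res$n_patient_carriers[idx],
    n_controls = res$n_control_carriers[idx])
}

#' Flag variants shared by patients and absent in controls
#'
#' Builds a per-variant report (one row per variant, chromosome-ordered)
#' with carrier counts per arm, effective MAF, and a `shared` flag set when
#' at least `k` patients and at most `c_max` controls carry the variant.
#' The defaults, k = 3 (half the patient arm) and c_max = 0, are the
#' criterion under which a rare variant is a plausible disease-associated
#' candidate in a pilot cohort.
#'
#' @param gm A [genotype_matrix].
#' @param k Minimum number of patient carriers.
#' @param c_max Maximum number of control carriers.
#' @return An object of class `shared_report`: a data frame with columns
#'   `rsid`, `gene`, `chrom`, `pos`, `maf`, `n_patient_carriers`,
#'   `n_control_carriers`, `any_hom_patient`, `shared`.
#' @export
find_shared <- function(gm, k = 3, c_max = 0) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_cases <- sum(gm$samples$status == "case")
  n_ctrls <- sum(gm$samples$status == "control")
  if (n_cases == 0 || n_ctrls == 0) stop("both cohort arms must be present")
  if (k > n_cases) {
    warning("k = ", k, " exceeds the patient arm size (", n_cases,
            "); no variant can be flagged")
  }
  cc <- carrier_counts(gm)
  rep_df <- data.frame(
    rsid = gm$variants$rsid, gene = gm$variants$gene,
    chrom = gm$variants$chrom, pos = gm$variants$pos,
    maf = effective_maf(gm$variants),
    cc,
    stringsAsFactors = FALSE
  )
  rep_df$shared <- rep_df$n_patient_carriers >= k &
    rep_df$n_control_carriers <= c_max
  ord <- order(.chrom_order(rep_df$chrom), rep_df$pos)
  rep_df <- rep_df[ord, , drop = FALSE]
  rownames(rep_df) <- NULL
  structure(rep_df, class = c("shared_report", "data.frame"),
            k = k, c_max = c_max,
            n_cases = n_cases, n_controls = n_ctrls)
}

#' @export
print.shared_report <- function(x, ...) {
  k <- attr(x, "k"); c_max <- attr(x, "c_max")
  sh <- x[x$shared, , drop = FALSE]
  cat(sprintf("Shared-variant report: %d variants, %d shared by >= %d patients and <= %d controls\n",
              nrow(x), nrow(sh), k, c_max))
  if (nrow(sh) > 0) {
    sh$maf <- ifelse(is.na(sh$maf), "no frequency data",
                     format(sh$maf, digits = 4))
    print.data.frame(sh[, c("chrom", "gene", "rsid", "maf",
                            "n_patient_carriers", "any_hom_patient")],
                     row.names = FALSE)
  }
  invisible(x)
}

#' Mirrored carrier-frequency table for SLC-superfamily variants
#'
#' For every solute-carrier variant, the percentage of controls and of
#' patients carrying it, chromosome-ordered — the numeric content of a
#' mirrored bar chart in which control frequencies extend left of the axis
#' and patient frequencies right.
#'
#' @param gm A [genotype_matrix].
#' @param catalog Gene catalog used to restrict to SLC (group C) variants;
#'   pass `NULL` to keep all variants.
#' @return An object of class `mirrored_freq`: data frame with
#'   `pct_controls` and `pct_patients` per variant.
#' @export
mirrored_frequency_table <- function(gm, catalog = load_builtin_catalog()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(catalog) && nrow(gm$variants) > 0) {
    gm <- subset_variants(gm, which(gene_in_group(gm$variants$gene, "C",
                                                  catalog)))
  }
  n_cases <- sum(gm$samples$status == "case")
  n_ctrls <- sum(gm$samples$status == "control")
  cc <- carrier_counts(gm)
  out <- data.frame(
    rsid = gm$variants$rsid, gene = gm$variants$gene,
    chrom = gm$variants$chrom, pos = gm$variants$pos,
    pct_controls = cc$n_control_carriers / n_ctrls * 100,
    pct_patients = cc$n_patient_carriers / n_cases * 100,
    stringsAsFactors = FALSE
  )
  ord <- order(.chrom_order(out$chrom), out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mirrored_freq", "data.frame"))
}

#' @export
plot.mirrored_freq <- function(x, ...) {
  if (nrow(x) == 0) {
    graphics::plot.new()
    graphics::title("No SLC variants to plot")
    return(invisible(x))
  }
  y <- rev(seq_len(nrow(x)))
  graphics::plot(NULL, xlim = c(-100, 100), ylim = range(y),
                 xlab = "% of arm carrying (controls | patients)",
                 ylab = "variants (chromosome order)", yaxt = "n", ...)
  graphics::segments(-x$pct_controls, y, 0, y, col = "steelblue", lwd = 2)
  graphics::segments(0, y, x$pct_patients, y, col = "darkorange", lwd = 2)
  graphics::abline(v = 0)
  invisible(x)
}
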