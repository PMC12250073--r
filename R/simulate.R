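# Seeded synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# small case-control exome cohort in which every individual carries a
# Poisson-distributed background of rare heterozygous variants across all
# gene groups, and cases additionally carry planted rare homozygous variants
# concentrated in a target gene set. Variants get synthetic loci, rs-style
# ids, consequence terms drawn from a configurable mix, and 0-6 per-database
# allele frequencies (occasionally none at all, so the missing-frequency
# pass-through is exercised). X-linked genes yield hemizygous calls in
# males. Identical configuration and seed give byte-identical output files.

#' Simulation configuration
#'
#' Defaults describe a small pilot cohort: 6 cases and 5 controls, per-
#' individual background heterozygous rates per gene group taken from the
#' control-arm column totals of the group analyses (A: 3.0, B: 7.6, C: 48,
#' D: 4.8 variants per individual) plus an exome-wide remainder, and planted
#' homozygous rates of 4/3 per case versus 0.2 per control in the solute
#' carrier superfamily — the observed case-control imbalance the burden test
#' is designed to detect.
#'
#' @param n_cases,n_controls Cohort arm sizes (must be positive).
#' @param background_het_rate Named vector: expected heterozygous rare
#'   variants per individual for gene pools `A`, `B`, `C`, `D` and `other`
#'   (exome-wide remainder).
#' @param planted_hom_cases,planted_hom_controls Expected homozygous rare
#'   variants per case (resp. control) in the target gene set.
#' @param target_set Gene-set name receiving the planted homozygous signal.
#' @param maf_range Two frequencies in (0, 0.5]: true minor-allele
#'   frequencies are drawn uniformly in this range and reported database
#'   values stay inside it.
#' @param p_missing_af Probability that a variant carries no frequency in
#'   any database.
#' @param consequence_mix Probabilities over the consequence classes
#'   `R`, `SC`, `NSC`, `intronic`; must sum to 1.
#' @param seed Integer seed; the generator is a pure function of the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 6, n_controls = 5,
                       background_het_rate = c(A = 3.0, B = 7.6, C = 48,
                                               D = 4.8, other = 40),
                       planted_hom_cases = 4 / 3,
                       planted_hom_controls = 0.2,
                       target_set = "C",
                       maf_range = c(5e-4, 0.049),
                       p_missing_af = 0.05,
                       consequence_mix = c(R = 0.25, SC = 0.2, NSC = 0.3,
                                           intronic = 0.25),
                       seed = 1L) {
  if (n_cases < 1 || n_controls < 1) stop("cohort arm sizes must be positive")
  if (any(background_het_rate < 0) || planted_hom_cases < 0 ||
      planted_hom_controls < 0) stop("rates must be non-negative")
  if (abs(sum(consequence_mix) - 1) > 1e-9) {
    stop("consequence_mix probabilities must sum to 1")
  }
  if (!all(names(consequence_mix) %in% c("R", "SC", "NSC", "intronic"))) {
    stop("consequence_mix must be named over R, SC, NSC, intronic")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must satisfy 0 < low <= high <= 0.5")
  }
  if (!nzchar(target_set)) stop("target set must be non-empty")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 background_het_rate = background_het_rate,
                 planted_hom_cases = planted_hom_cases,
                 planted_hom_controls = planted_hom_controls,
                 target_set = target_set, maf_range = maf_range,
                 p_missing_af = p_missing_af,
                 consequence_mix = consequence_mix,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' The file mirrors the [sim_config()] field names; absent fields keep their
#' defaults.
#' @param path Path to a YAML file.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$background_het_rate)) {
    raw$background_het_rate <- unlist(raw$background_het_rate)
  }
  if (!is.null(raw$consequence_mix)) {
    raw$consequence_mix <- unlist(raw$consequence_mix)
  }
  if (!is.null(raw$maf_range)) raw$maf_range <- as.numeric(raw$maf_range)
  do.call(sim_config, raw)
}

# gene pools backing the simulator: curated groups plus a synthetic SLC
# superfamily roster (4 typical members per family, plus atypically named
# members) and an exome-wide remainder of anonymous genes
.sim_gene_pools <- function(catalog) {
  slc_typ <- unlist(lapply(1:66, function(f) sprintf("SLC%dA%d", f, 1:4)))
  slc_extra <- c("SLC6A14", "SLC9A7", "SLC9B1", "SLC22A25", "SLC35D2",
                 "SLC38A6", "SLC39A10", "SLCO1A2", "SPNS2", "MTCH2", "UCP1",
                 "LETM1", "SFXN1", "NIPA1", "MAGT1", "ANKH", "CTNS", "MPDU1",
                 "NPC1", "XPR1", "FLVCR1", "RHAG", "TMEM165", "MFSD2A")
  list(A = catalog$groups$A,
       B = catalog$groups$B,
       C = sort(unique(c(slc_typ, slc_extra))),
       D = sort(unique(c(catalog$groups$D_risk, catalog$groups$D_protective))),
       other = sprintf("GENE%04d", 1:300))
}

# deterministic synthetic loci: X-linked genes on chrX, everything else
# cycled over chromosomes 1-22 in alphabetical order; each gene owns a
# 20 kb window and hands out sequential positions
.gene_loci <- function(pools, catalog) {
  genes <- sort(unique(unlist(pools)))
  chrom <- ifelse(genes %in% catalog$xlinked, "X",
                  as.character(1 + (seq_along(genes) - 1) %% 22))
  base <- integer(length(genes))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    base[idx] <- 1000000L + 20000L * (seq_along(idx) - 1L)
  }
  data.frame(gene = genes, chrom = chrom, base = base,
             stringsAsFactors = FALSE)
}

.CSQ_TERMS <- list(
  R = c("5_prime_UTR_variant", "3_prime_UTR_variant",
        "upstream_gene_variant", "downstream_gene_variant",
        "non_coding_transcript_exon_variant"),
  SC = c("synonymous_variant", "stop_retained_variant"),
  NSC = c("missense_variant", "stop_gained", "frameshift_variant",
          "inframe_deletion", "splice_donor_variant",
          "splice_acceptor_variant"),
  intronic = "intron_variant"
)

# pick the pool of genes eligible for the planted signal
.target_pool <- function(target_set, pools, catalog) {
  pool <- switch(target_set,
    A = pools$A, B = pools$B, C = pools$C, D = pools$D,
    C_restricted = {
      fams <- vapply(pools$C, .parse_one_slc, integer(1), catalog = catalog,
                     USE.NAMES = FALSE)
      pools$C[!is.na(fams) & fams %in% catalog$restricted_families]
    },
    D_risk = catalog$groups$D_risk,
    D_protective = catalog$groups$D_protective,
    stop("unknown target set: ", target_set)
  )
  if (length(pool) == 0) stop("empty target set: ", target_set)
  pool
}

#' Simulate a synthetic case-control cohort in memory
#'
#' The generative model: each individual draws, per gene pool, a Poisson
#' number of background rare variants (each a new singleton variant carried
#' heterozygously by that individual); each case additionally draws a
#' Poisson number of planted homozygous variants in the target gene set
#' (controls likewise at their own, typically much lower, rate). True minor
#' allele frequencies are uniform on `maf_range`; each variant reports
#' 1-6 database frequencies (the true value jittered by up to 20% relative
#' and kept inside `maf_range`) or, with probability `p_missing_af`, none.
#' Planted homozygous variants are constrained to an effective (maximum
#' database) frequency below 0.05. Males carry hemizygous calls at X-linked
#' genes.
#'
#' @param config A [sim_config()].
#' @param catalog Gene catalog (drives SLC membership and X-linkage).
#' @return A [genotype_matrix].
#' @export
simulate_cohort_data <- function(config = sim_config(),
                                 catalog = load_builtin_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_cases + config$n_controls
  sex_cases <- if (config$n_cases >= 2)
    c(rep("F", config$n_cases - 1), "M") else rep("F", config$n_cases)
  n_f_ctrl <- ceiling(config$n_controls * 0.4)
  sex_ctrls <- c(rep("F", n_f_ctrl), rep("M", config$n_controls - n_f_ctrl))
  samples <- data.frame(
    sample_id = c(sprintf("P%d", seq_len(config$n_cases)),
                  sprintf("C%d", seq_len(config$n_controls))),
    status = rep(c("case", "control"),
                 c(config$n_cases, config$n_controls)),
    sex = c(sex_cases, sex_ctrls),
    age = c(sample(52:70, config$n_cases, replace = TRUE),
            sample(48:68, config$n_controls, replace = TRUE)),
    stringsAsFactors = FALSE
  )

  pools <- .sim_gene_pools(catalog)
  loci <- .gene_loci(pools, catalog)

  # draw every event (one event = one new singleton variant) vectorized:
  # background het events per pool and individual, then the planted
  # homozygous signal in the target set
  ev_gene <- character(0); ev_sample <- integer(0); ev_kind <- character(0)
  for (pool_name in names(config$background_het_rate)) {
    pool <- pools[[pool_name]]
    if (is.null(pool)) stop("no gene pool named ", pool_name)
    rate <- config$background_het_rate[[pool_name]]
    if (rate <= 0) next
    k <- stats::rpois(n, rate)
    if (sum(k) == 0) next
    ev_gene <- c(ev_gene, sample(pool, sum(k), replace = TRUE))
    ev_sample <- c(ev_sample, rep(seq_len(n), k))
    ev_kind <- c(ev_kind, rep("het", sum(k)))
  }
  # Planted homozygous counts are a fixed dose, not Poisson: the integer
  # part of the rate is given to every individual of the arm and the
  # fractional part as a Bernoulli extra. This emulates the designed
  # case-control signal — every case carries it (at rate 4/3: each case
  # gets one, a third of cases two) — whereas Poisson planting would leave
  # about a quarter of cases carrier-free at that mean, which is not the
  # cohort structure the analysis is meant to detect. The configured rate
  # is recovered exactly in expectation either way.
  target <- .target_pool(config$target_set, pools, catalog)
  plant_rate <- ifelse(samples$status == "case",
                       config$planted_hom_cases, config$planted_hom_controls)
  k <- floor(plant_rate) + stats::rbinom(n, 1L, plant_rate - floor(plant_rate))
  if (sum(k) > 0) {
    ev_gene <- c(ev_gene, sample(target, sum(k), replace = TRUE))
    ev_sample <- c(ev_sample, rep(seq_len(n), k))
    ev_kind <- c(ev_kind, rep("hom", sum(k)))
  }
  m <- length(ev_gene)
  if (m == 0) {
    return(genotype_matrix(samples, .empty_variant_table(),
                           matrix(character(0), nrow = n, ncol = 0)))
  }

  # loci: each gene owns a window and hands out sequential offsets
  li <- match(ev_gene, loci$gene)
  off <- stats::ave(seq_len(m), ev_gene, FUN = seq_along)
  # alleles
  acgt <- c("A", "C", "G", "T")
  r_idx <- sample.int(4L, m, replace = TRUE)
  a_shift <- sample.int(3L, m, replace = TRUE)
  # consequence class, then a term within the class
  cls <- sample(names(config$consequence_mix), m, replace = TRUE,
                prob = config$consequence_mix)
  term <- character(m)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    term[idx] <- sample(.CSQ_TERMS[[cl]], length(idx), replace = TRUE)
  }
  # true MAF: planted homozygous variants are capped at 0.04 so a +20%
  # database jitter cannot reach the 0.05 threshold
  cap <- ifelse(ev_kind == "hom", pmin(config$maf_range[2], 0.04),
                config$maf_range[2])
  lo <- pmin(config$maf_range[1], cap)
  maf <- stats::runif(m, lo, cap)
  # database frequencies: with prob p_missing_af none at all, else a
  # uniform 1..6 of the databases report the true MAF jittered by up to
  # 20% relative, kept inside maf_range (and below 0.05 for planted)
  af <- matrix(NA_real_, nrow = m, ncol = 6L)
  has_af <- stats::runif(m) >= config$p_missing_af
  n_db <- sample.int(6L, m, replace = TRUE)
  db_rank <- matrix(stats::runif(6L * m), nrow = m)
  rk <- t(apply(db_rank, 1L, rank))
  db_sel <- rk <= n_db  # n_db recycles down columns, i.e. per variant
  db_sel[!has_af, ] <- FALSE
  vals <- maf * stats::runif(m * 6L, 0.8, 1.2)
  vals <- pmin(pmax(vals, config$maf_range[1]),
               pmin(config$maf_range[2], rep(cap * 1.2, 6L), 0.5))
  af[db_sel] <- vals[db_sel]

  variants <- data.frame(
    chrom = loci$chrom[li], pos = loci$base[li] + off,
    ref = acgt[r_idx], alt = acgt[(r_idx - 1L + a_shift) %% 4L + 1L],
    rsid = sprintf("rs%07d", seq_len(m)),
    gene = ev_gene, consequence = term,
    stringsAsFactors = FALSE
  )
  for (d in seq_along(AF_DB_COLS)) variants[[AF_DB_COLS[d]]] <- af[, d]
  # default background call: hemi_ref for males at X-linked genes
  calls <- matrix("hom_ref", nrow = n, ncol = nrow(variants))
  xl_var <- toupper(variants$gene) %in% catalog$xlinked
  calls[samples$sex == "M", xl_var] <- "hemi_ref"
  hemi <- xl_var & samples$sex[ev_sample] == "M"
  carrier_call <- ifelse(hemi, "hemi_alt",
                         ifelse(ev_kind == "het", "het", "hom_alt"))
  calls[cbind(ev_sample, seq_len(m))] <- carrier_call

  ord <- order(.chrom_order(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  calls <- calls[, ord, drop = FALSE]
  genotype_matrix(samples, variants, calls)
}

#' Simulate a cohort and write it as VCF plus sample sheet
#'
#' @inheritParams simulate_cohort_data
#' @param vcf_path,sheet_path Output paths for the VCF 4.2 file and the TSV
#'   sample sheet.
#' @return Invisibly, a list with the two paths and the in-memory
#'   [genotype_matrix].
#' @export
simulate_cohort <- function(config = sim_config(),
                            vcf_path, sheet_path,
                            catalog = load_builtin_catalog()) {
  gm <- simulate_cohort_data(config, catalog)
  write_cohort_vcf(gm, vcf_path)
  utils::write.table(gm$samples, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(vcf = vcf_path, sample_sheet = sheet_path, matrix = gm))
}

.GT_STRINGS <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                 hemi_ref = "0", hemi_alt = "1", missing = "./.")

#' Write a genotype matrix as an annotated VCF 4.2 file
#'
#' One sample column per individual (GT only); INFO carries the gene symbol
#' (`GENE`), consequence term (`CSQTERM`), rs identifier (`RSID`) and the
#' per-database allele frequencies (`AF_1KG`, `AF_EXAC`, `AF_ESP`,
#' `AF_GNE`, `AF_GNG`, `AF_GN3`), each key present only when annotated.
#'
#' @param gm A [genotype_matrix].
#' @param path Output path.
#' @export
write_cohort_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rvburden_synthetic_cohort",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQTERM,Number=1,Type=String,Description=\"Consequence term\">",
    "##INFO=<ID=RSID,Number=1,Type=String,Description=\"rs identifier\">",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Alternate allele frequency (%s)\">",
            AF_INFO_KEYS,
            c("1000 Genomes", "ExAC", "ESP", "gnomAD v2 exomes",
              "gnomAD v2 genomes", "gnomAD v3")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t")
  )
  v <- gm$variants
  lines <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    info <- character(0)
    if (!is.na(v$gene[i])) info <- c(info, paste0("GENE=", v$gene[i]))
    if (!is.na(v$consequence[i])) {
      info <- c(info, paste0("CSQTERM=", v$consequence[i]))
    }
    if (!is.na(v$rsid[i])) info <- c(info, paste0("RSID=", v$rsid[i]))
    for (d in seq_along(AF_DB_COLS)) {
      val <- v[[AF_DB_COLS[d]]][i]
      if (!is.na(val)) {
        info <- c(info, sprintf("%s=%.6g", AF_INFO_KEYS[d], val))
      }
    }
    lines[i] <- paste(
      v$chrom[i], v$pos[i],
      if (is.na(v$rsid[i])) "." else v$rsid[i],
      v$ref[i], v$alt[i], ".", "PASS",
      if (length(info) > 0) paste(info, collapse = ";") else ".",
      "GT", paste(.GT_STRINGS[gm$calls[, i]], collapse = "\t"),
      sep = "\t"
    )
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Plant a genotype call at a variant for named samples
#'
#' Sets the requested zygosity for the named samples at the given variant;
#' all other calls are untouched. The variant is matched on
#' (chrom, pos, ref, alt) and appended to the matrix (reference calls
#' everywhere) when absent — the mechanism tests use to construct carrier
#' patterns exactly.
#'
#' @param gm A [genotype_matrix].
#' @param variant A one-row data frame or named list with at least `chrom`,
#'   `pos`, `ref`, `alt` (optionally `rsid`, `gene`, `consequence` and
#'   `af_*` frequency fields).
#' @param samples Character vector of sample ids to receive the call.
#' @param zygosity One of `"het"`, `"hom_alt"`, `"hemi_alt"`.
#' @return The modified genotype matrix.
#' @export
plant_signal <- function(gm, variant, samples,
                         zygosity = c("het", "hom_alt", "hemi_alt")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  zygosity <- match.arg(zygosity)
  variant <- as.list(variant)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variant))) {
    stop("variant needs fields chrom, pos, ref, alt")
  }
  unknown <- setdiff(samples, gm$samples$sample_id)
  if (length(unknown) > 0) {
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  }
  idx <- which(gm$variants$chrom == variant$chrom &
               gm$variants$pos == variant$pos &
               gm$variants$ref == variant$ref &
               gm$variants$alt == variant$alt)
  if (length(idx) == 0) {
    row <- .empty_variant_table()[0, ]
    row[1, "chrom"] <- as.character(variant$chrom)
    row[1, "pos"] <- as.integer(variant$pos)
    row[1, "ref"] <- variant$ref
    row[1, "alt"] <- variant$alt
    for (f in c("rsid", "gene", "consequence", AF_DB_COLS)) {
      if (!is.null(variant[[f]])) row[1, f] <- variant[[f]]
    }
    gm$variants <- rbind(gm$variants, row)
    rownames(gm$variants) <- NULL
    gm$calls <- cbind(gm$calls, rep("hom_ref", nrow(gm$samples)))
    idx <- nrow(gm$variants)
  }
  rows <- match(samples, gm$samples$sample_id)
  existing <- gm$calls[rows, idx]
  conflict <- !(existing %in% c("hom_ref", "hemi_ref", "missing")) &
    existing != zygosity
  if (any(conflict)) {
    stop("conflicting non-reference call(s) already present for: ",
         paste(samples[conflict], collapse = ", "))
  }
  gm$calls[rows, idx] <- zygosity
  gm
}
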