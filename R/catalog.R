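#' Load the built-in gene catalog
#'
#' The catalog bundles the four curated case-control gene groups (A:
#' detoxification/oxidative stress, 17 genes; B: TRP ion channels, 29 genes;
#' D: GWAS risk and protective genes, 11 + 8) together with the nomenclature
#' rules of the solute carrier (SLC) superfamily: how typical `SLC<family>`
#' symbols and atypically named members (SLCO, UCP, MTCH, SPNS, ...) resolve
#' to one of the 66 SLC families, which 12 families form the
#' neurotransmitter-related restricted list, and which symbols are X-linked.
#'
#' @param path Optional path to a YAML file with the same schema as the
#'   packaged catalog, to override the built-in lists.
#' @return An object of class `gene_catalog`.
#' @examples
#' cat <- load_builtin_catalog()
#' length(cat$groups$A)
#' @export
load_builtin_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gene_catalog.yaml", package = "rvburden")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("catalog file not found: ", path)
  }
  raw <- yaml::read_yaml(path)
  needed <- c("groups", "slc_alias_prefixes", "restricted_families",
              "tmem_family64", "xlinked")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("corrupt catalog: missing fields ", paste(missing, collapse = ", "))
  }
  cat <- structure(
    list(
      groups = lapply(raw$groups, function(g) toupper(unlist(g))),
      synonyms = vapply(raw$symbol_synonyms, toupper, character(1)),
      alias_prefixes = unlist(raw$slc_alias_prefixes),
      tmem_family64 = toupper(unlist(raw$tmem_family64)),
      restricted_families = as.integer(unlist(raw$restricted_families)),
      xlinked = toupper(unlist(raw$xlinked))
    ),
    class = "gene_catalog"
  )
  stopifnot(
    length(cat$groups$A) == 17, length(cat$groups$B) == 29,
    length(cat$groups$D_risk) == 11, length(cat$groups$D_protective) == 8,
    length(cat$restricted_families) == 12
  )
  cat
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("Gene catalog\n")
  for (g in names(x$groups)) {
    cat(sprintf("  group %-13s %3d genes\n", g, length(x$groups[[g]])))
  }
  cat(sprintf("  SLC alias prefixes   %3d\n", length(x$alias_prefixes)))
  cat(sprintf("  restricted families  %3d (%s)\n",
              length(x$restricted_families),
              paste(x$restricted_families, collapse = ", ")))
  invisible(x)
}

#' Resolve a gene symbol to its SLC family number
#'
#' Typical symbols of the form `SLC<family><subfamily letters><member>`
#' (e.g. `SLC6A1`) resolve directly; atypically named members resolve through
#' the catalog's alias table (`SLCO* -> 21`, `MTCH* -> 25`, `SPNS* -> 63`,
#' ...). Alias matching is whole-prefix with a boundary check (a prefix
#' ending in a letter must be followed by a digit or nothing; one ending in a
#' digit must not be followed by another digit), so unrelated symbols such as
#' `CAT` or `MFSD20` can never match. `TMEM` symbols map to family 64 only
#' for the catalog's explicit member list. The function is total and
#' case-insensitive; non-SLC symbols return `NA`.
#'
#' @param symbol Character vector of gene symbols.
#' @param catalog A `gene_catalog`, by default the built-in one.
#' @return Integer vector of family numbers (1-66), `NA` where the symbol is
#'   not an SLC-superfamily member.
#' @examples
#' parse_slc_family(c("SLC6A1", "SLCO1A2", "MTCH2", "TRPM2"))
#' @export
parse_slc_family <- function(symbol, catalog = load_builtin_catalog()) {
  vapply(symbol, function(s) .parse_one_slc(s, catalog), integer(1),
         USE.NAMES = FALSE)
}

.parse_one_slc <- function(symbol, catalog) {
  if (is.na(symbol) || !nzchar(symbol)) return(NA_integer_)
  s <- toupper(trimws(symbol))
  if (!is.null(catalog$synonyms) && s %in% names(catalog$synonyms)) {
    s <- catalog$synonyms[[s]]
  }
  # typical symbols: literal "SLC" then the family number
  m <- regmatches(s, regexec("^SLC([0-9]{1,2})([A-Z][A-Z0-9]*)?$", s))[[1]]
  if (length(m) > 0) {
    fam <- as.integer(m[2])
    if (fam >= 1 && fam <= 66) return(fam)
    return(NA_integer_)
  }
  if (s %in% catalog$tmem_family64) return(64L)
  # atypical members: alias prefix with digit/letter boundary
  for (pfx in names(catalog$alias_prefixes)) {
    if (!startsWith(s, pfx)) next
    rest <- substring(s, nchar(pfx) + 1L)
    last <- substring(pfx, nchar(pfx))
    ok <- if (grepl("[0-9]", last)) {
      # prefix ends in a digit: full-symbol match or a letter next
      !nzchar(rest) || grepl("^[A-Z]", rest)
    } else {
      # prefix ends in a letter: full-symbol match or a digit next
      !nzchar(rest) || grepl("^[0-9]", rest)
    }
    if (ok) return(as.integer(catalog$alias_prefixes[[pfx]]))
  }
  NA_integer_
}

#' Assign a gene symbol to its catalog groups
#'
#' Returns every group a symbol belongs to. Groups A, B, D_risk and
#' D_protective are explicit lists; membership in C follows from
#' [parse_slc_family()] succeeding, and in C_restricted from the family being
#' one of the 12 neurotransmitter-related families. A symbol may belong to
#' several groups (SLC25A38 sits in both C and D_risk).
#'
#' @inheritParams parse_slc_family
#' @param symbol A single gene symbol.
#' @return Character vector of group names (possibly empty), a subset of
#'   `c("A", "B", "C", "C_restricted", "D_risk", "D_protective")`.
#' @examples
#' assign_groups("SLC25A38")
#' assign_groups("SLC6A14")
#' @export
assign_groups <- function(symbol, catalog = load_builtin_catalog()) {
  stopifnot(length(symbol) == 1L)
  s <- toupper(trimws(symbol))
  if (!is.null(catalog$synonyms) && s %in% names(catalog$synonyms)) {
    s <- catalog$synonyms[[s]]
  }
  out <- character(0)
  for (g in c("A", "B", "D_risk", "D_protective")) {
    if (s %in% catalog$groups[[g]]) out <- c(out, g)
  }
  fam <- .parse_one_slc(s, catalog)
  if (!is.na(fam)) {
    out <- c(out, "C")
    if (fam %in% catalog$restricted_families) out <- c(out, "C_restricted")
  }
  sort(out)
}

# vectorised group-membership test used by the burden counters
gene_in_group <- function(symbols, group, catalog) {
  symbols <- toupper(ifelse(is.na(symbols), "", symbols))
  syn <- catalog$synonyms
  if (length(syn) > 0) {
    hit <- symbols %in% names(syn)
    symbols[hit] <- unname(syn[symbols[hit]])
  }
  if (group %in% c("A", "B", "D_risk", "D_protective")) {
    return(symbols %in% catalog$groups[[group]])
  }
  if (group == "D") {
    return(symbols %in% c(catalog$groups$D_risk, catalog$groups$D_protective))
  }
  u <- unique(symbols)  # parse each distinct symbol once
  fams_u <- vapply(u, .parse_one_slc, integer(1),
                   catalog = catalog, USE.NAMES = FALSE)
  fams <- fams_u[match(symbols, u)]
  if (group == "C") return(!is.na(fams))
  if (group == "C_restricted") {
    return(!is.na(fams) & fams %in% catalog$restricted_families)
  }
  stop("unknown group: ", group)
}
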