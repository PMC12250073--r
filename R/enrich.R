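# Over-representation analysis from first principles: hypergeometric
# upper-tail probabilities in log space and Benjamini-Hochberg step-up
# adjustment, applied to a gene -> term annotation table.

#' Hypergeometric upper-tail probability
#'
#' `P[X >= k]` for X ~ hypergeometric: `n` draws without replacement from a
#' universe of `N` objects of which `K` are marked. Point masses are
#' accumulated in log space via `lchoose`, so large annotation tables do not
#' underflow.
#'
#' @param k Observed number of marked draws (query genes annotated to the
#'   term).
#' @param K Marked objects in the universe (universe genes with the term).
#' @param n Number of draws (query size).
#' @param N Universe size.
#' @return The tail probability, in \[0, 1\].
#' @examples
#' hypergeom_tail(3, 5, 3, 10)  # C(5,3)/C(10,3) = 10/120
#' @export
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (k < 0 || K < 0 || n < 0 || K > N || n > N || k > min(n, K)) {
    stop("inconsistent counts: need 0 <= k <= min(n, K), K <= N, n <= N")
  }
  if (k == 0) return(1)
  i <- seq.int(k, min(n, K))
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logp)
  min(1, exp(m + log(sum(exp(logp - m)))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_i = min_{j >= i} (p_j * m / j)`, capped at 1 and returned in the input
#' order.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Over-representation analysis of a gene list
#'
#' Tests every annotation term carrying at least one query gene for
#' over-representation of the query within the universe, using the
#' hypergeometric upper tail, then adjusts across terms with
#' Benjamini-Hochberg. The reported table keeps terms with `p <= p_cutoff`
#' and `p_adj <= q_cutoff`, ranked by adjusted then raw p, truncated to
#' `top_n` rows; the full per-term table is retained alongside.
#'
#' @param query Character vector of gene symbols (case-insensitive).
#' @param annotation Data frame with columns `gene` and `term` (optionally
#'   `term_name`), or a path to a 2-3 column TSV of that shape.
#' @param universe Gene universe; defaults to all genes in the annotation
#'   table. Query genes outside the universe are dropped (an error if none
#'   remain).
#' @param p_cutoff,q_cutoff Raw and adjusted p-value cutoffs for the report.
#' @param top_n Maximum rows in the report.
#' @return An object of class `enrichment` with `$results` (all tested
#'   terms) and `$report` (the filtered, ranked table).
#' @export
enrich_terms <- function(query, annotation, universe = NULL,
                         p_cutoff = 0.05, q_cutoff = 0.2, top_n = 10) {
  if (is.character(annotation) && length(annotation) == 1) {
    annotation <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(annotation),
            all(c("gene", "term") %in% names(annotation)))
  annotation$gene <- toupper(annotation$gene)
  query <- unique(toupper(query))
  if (is.null(universe)) universe <- unique(annotation$gene)
  else universe <- unique(toupper(universe))
  annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
  query <- intersect(query, universe)
  if (length(query) == 0) {
    stop("no query gene is present in the universe after normalization")
  }
  N <- length(universe)
  n <- length(query)
  terms <- unique(annotation$term)
  rows <- lapply(terms, function(tm) {
    genes_tm <- unique(annotation$gene[annotation$term == tm])
    k <- length(intersect(genes_tm, query))
    if (k == 0) return(NULL)
    name <- if ("term_name" %in% names(annotation))
      annotation$term_name[annotation$term == tm][1] else NA_character_
    data.frame(term = tm, term_name = name, k = k, K = length(genes_tm),
               n = n, N = N,
               p = hypergeom_tail(k, length(genes_tm), n, N),
               genes = paste(sort(intersect(genes_tm, query)),
                             collapse = "/"),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  if (is.null(results)) {
    results <- data.frame(term = character(0), term_name = character(0),
                          k = integer(0), K = integer(0), n = integer(0),
                          N = integer(0), p = numeric(0),
                          genes = character(0), p_adj = numeric(0))
  } else {
    results$p_adj <- bh_adjust(results$p)
    results <- results[order(results$p_adj, results$p), , drop = FALSE]
    rownames(results) <- NULL
  }
  report <- results[results$p <= p_cutoff & results$p_adj <= q_cutoff, ,
                    drop = FALSE]
  if (nrow(report) > top_n) report <- report[seq_len(top_n), , drop = FALSE]
  structure(list(results = results, report = report, query = query,
                 n_universe = N),
            class = "enrichment")
}

#' @export
print.enrichment <- function(x, digits = 3, ...) {
  cat(sprintf("Over-representation analysis: %d query genes, universe %d, %d terms tested\n",
              length(x$query), x$n_universe, nrow(x$results)))
  if (nrow(x$report) == 0) {
    cat("  no term passes the cutoffs\n")
  } else {
    df <- x$report
    df$p <- signif(df$p, digits); df$p_adj <- signif(df$p_adj, digits)
    print.data.frame(df[, c("term", "term_name", "k", "K", "p", "p_adj")],
                     row.names = FALSE)
  }
  invisible(x)
}
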