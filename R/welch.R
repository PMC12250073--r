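#' Welch unequal-variance two-sample t-test
#'
#' Computes `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with sample
#' variances (n-1 denominator), Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value. Written out explicitly rather than delegated so the
#' degenerate case of two zero-variance arms has defined behaviour: equal
#' means give `t = 0, p = 1`; unequal means give a signed infinite statistic
#' with `p = 0`, flagged as degenerate.
#'
#' @param x,y Numeric vectors, each of length at least 2 (per-individual
#'   variant counts of the two cohort arms).
#' @return An object of class `welch_t` with fields `t`, `df`, `p`,
#'   `estimate` (the two means), `n`, and `degenerate`.
#' @examples
#' welch_t(c(1, 0, 0, 0, 0), c(2, 2, 1, 1, 1, 1))  # t ~ -3.90
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each arm needs at least 2 observations")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  degenerate <- FALSE
  if (vx == 0 && vy == 0) {
    degenerate <- TRUE
    if (mx == my) {
      t <- 0; df <- nx + ny - 2; p <- 1
    } else {
      t <- sign(mx - my) * Inf; df <- nx + ny - 2; p <- 0
    }
  } else {
    se2 <- vx / nx + vy / ny
    t <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p = p, estimate = c(mean_x = mx, mean_y = my),
                 n = c(nx = nx, ny = ny), degenerate = degenerate),
            class = "welch_t")
}

# significance marks used throughout the reports
sig_mark <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}

#' @export
print.welch_t <- function(x, digits = 4, ...) {
  cat("Welch two-sample t-test (unequal variances)\n")
  cat(sprintf("  t = %s, df = %s, p = %s %s\n",
              format(x$t, digits = digits), format(x$df, digits = digits),
              format(x$p, digits = digits), sig_mark(x$p)))
  cat(sprintf("  means: %s vs %s (n = %d, %d)%s\n",
              format(x$estimate[1], digits = digits),
              format(x$estimate[2], digits = digits),
              x$n[1], x$n[2],
              if (x$degenerate) "  [degenerate: zero variance in both arms]"
              else ""))
  invisible(x)
}

#' Per-arm summary statistics (mean and standard error of the mean)
#'
#' @param counts Numeric vector of per-individual counts.
#' @return List with `mean`, `sem` (sample SD / sqrt(n)) and `n`.
#' @examples
#' summarize_counts(c(2, 2, 1, 1, 1, 1))
#' @export
summarize_counts <- function(counts) {
  n <- length(counts)
  if (n < 1) stop("empty count vector")
  list(mean = mean(counts),
       sem = if (n > 1) stats::sd(counts) / sqrt(n) else 0,
       n = n)
}
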