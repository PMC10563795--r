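#' Exact and chi-square tests for a 2x2 contingency table
#'
#' The two-sided exact p-value is computed by full hypergeometric
#' enumeration: with margins fixed, every achievable table whose point
#' probability does not exceed that of the observed table (within a relative
#' tolerance of 1e-7 for floating-point ties) contributes to p. The
#' uncorrected and Yates-corrected chi-square p-values are reported alongside
#' so a chi-square-labelled result can be audited against the exact one. The
#' odds ratio is the cross-product ad/bc (Inf when bc = 0).
#'
#' For the headline subtype-by-1q use, rows are classical/basal and columns
#' are 1q gain / no gain.
#'
#' @param a,b,c,d cell counts (row-major); `a` may also be a length-4 vector
#'   or 2x2 matrix.
#' @return list with `p_exact`, `p_chisq`, `p_chisq_yates`, `odds_ratio`,
#'   `table`.
#' @export
exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) { x <- as.vector(t(a)) }
  else if (length(a) == 4) { x <- a }
  else { x <- c(a, b, c, d) }
  if (length(x) != 4 || any(x < 0) || any(x != round(x)))
    stopf("need four nonnegative integer counts")
  x <- as.integer(x)
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  n <- a + b + c + d
  if (n == 0) stopf("empty table")
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warning("zero margin: p = 1")
    or <- if (b * c == 0) {
      if (a * d == 0) NaN else Inf
    } else (a * d) / (b * c)
    return(list(p_exact = 1, p_chisq = 1, p_chisq_yates = 1,
                odds_ratio = or, table = matrix(x, 2, byrow = TRUE)))
  }
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  p_exact <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  m <- matrix(x, 2, byrow = TRUE)
  p_chisq <- suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
  p_yates <- suppressWarnings(chisq.test(m, correct = TRUE)$p.value)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(p_exact = p_exact, p_chisq = p_chisq, p_chisq_yates = p_yates,
       odds_ratio = or, table = m)
}

#' Paired and unpaired comparison of a per-region statistic between grades
#'
#' Compares a per-region quantity (aneuploidy score, mutation burden, ...)
#' between high-grade and low-grade regions: an unpaired rank-sum test over
#' all regions of each grade, and a paired signed-rank test over the
#' patient-matched (LG, HG) pairs, with per-pair deltas (positive delta =
#' increase upon progression).
#'
#' @param values named numeric vector, names are region ids.
#' @param grades named character vector region -> grade (LG/HG/...).
#' @param pairs data.frame with columns `patient`, `lg`, `hg` (region ids);
#'   may be NULL or empty, in which case the paired analysis is omitted with
#'   a warning.
#' @param high,low grade labels to compare, defaults "HG" vs "LG".
#' @return list with `p_unpaired`, `p_paired`, `deltas`, group summaries.
#' @export
compare_grades <- function(values, grades, pairs = NULL,
                           high = "HG", low = "LG") {
  regions <- names(values)
  hg <- values[regions[grades[regions] == high]]
  lg <- values[regions[grades[regions] == low]]
  hg <- hg[!is.na(hg)]; lg <- lg[!is.na(lg)]
  if (length(hg) < 2 || length(lg) < 2)
    stopf("need at least two values per grade group")
  p_unpaired <- suppressWarnings(wilcox.test(hg, lg)$p.value)
  p_paired <- NA_real_; deltas <- numeric()
  if (!is.null(pairs) && nrow(pairs)) {
    ok <- pairs$lg %in% names(values) & pairs$hg %in% names(values)
    pairs <- pairs[ok, , drop = FALSE]
    if (nrow(pairs)) {
      deltas <- setNames(values[pairs$hg] - values[pairs$lg], pairs$patient)
      if (all(deltas == 0)) {
        p_paired <- 1
      } else {
        p_paired <- suppressWarnings(
          wilcox.test(deltas, mu = 0, exact = TRUE)$p.value)
      }
    }
  }
  if (!length(deltas)) warning("no valid pairs: paired result omitted")
  list(p_unpaired = p_unpaired, p_paired = p_paired, deltas = deltas,
       mean_high = mean(hg), mean_low = mean(lg),
       n_high = length(hg), n_low = length(lg))
}
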