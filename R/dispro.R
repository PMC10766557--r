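#' 2x2 reporting contingency tables and reporting odds ratios
#'
#' A reporting odds ratio (ROR) compares how often a condition is reported in
#' one stratum versus another. The same machinery backs all three screens:
#' the event-versus-pandemic ratio (rows = years 2020/2019, columns = event
#' present/absent), the drug-event ratio within a matched cohort (rows = drug
#' present/absent) and the pair-versus-pandemic ratio.
#'
#' `contingency_table()` records the four counts with their margin labels.
#' Cell order is `(a, b, c, d)` = row1 (a, b), row2 (c, d); the ROR is the
#' cross-product `(a*d) / (b*c)`.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param labels Optional character(4) describing the cells.
#' @return A `contingency_table` object.
#' @export
#' @examples
#' t <- contingency_table(20, 80, 10, 90)
#' ror_point(t)   # 2.25
#' ror_ci95(t)
#' fisher_exact_2tail(t)
contingency_table <- function(a, b, c, d, labels = NULL) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative counts")
  }
  structure(list(a = a, b = b, c = c, d = d,
                 labels = labels %||% c("a", "b", "c", "d")),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE)
  dimnames(m) <- list(c("row1", "row2"), c("col1", "col2"))
  print(m)
  invisible(x)
}

as_cells <- function(t) {
  if (inherits(t, "contingency_table")) c(t$a, t$b, t$c, t$d) else as.numeric(t)
}

# Haldane-Anscombe continuity correction: +0.5 to every cell when any is zero.
# Returns list(cells, corrected).
correct_cells <- function(cells, zero_correction = TRUE) {
  corrected <- zero_correction && any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(cells = cells, corrected = corrected)
}

#' Reporting odds ratio point estimate
#'
#' The cross-product ratio `(a*d) / (b*c)`. When any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to all four cells (the standard
#' pharmacovigilance remedy) before forming the ratio.
#'
#' @param t A [contingency_table()] or numeric vector `c(a, b, c, d)`.
#' @param zero_correction Apply the +0.5 correction on zero cells
#'   (default `TRUE`).
#' @return A positive real.
#' @export
ror_point <- function(t, zero_correction = TRUE) {
  cc <- correct_cells(as_cells(t), zero_correction)
  x <- cc$cells
  if (x[2] * x[3] == 0) stop("odds ratio undefined: zero denominator cell")
  (x[1] * x[4]) / (x[2] * x[3])
}

#' Wald 95% confidence interval of a reporting odds ratio
#'
#' `exp(ln(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`, on the (possibly
#' zero-corrected) cells.
#'
#' @inheritParams ror_point
#' @return Named numeric `c(low, high)`.
#' @export
ror_ci95 <- function(t, zero_correction = TRUE) {
  cc <- correct_cells(as_cells(t), zero_correction)
  x <- cc$cells
  if (any(x == 0)) stop("confidence interval undefined: zero cell")
  or <- (x[1] * x[4]) / (x[2] * x[3])
  se <- sqrt(sum(1 / x))
  c(low = exp(log(or) - 1.96 * se), high = exp(log(or) + 1.96 * se))
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' The two-sided p-value under the hypergeometric null with all margins
#' fixed, using the probability-mass rule: the sum of the point probabilities
#' of every table (with the same margins) whose probability does not exceed
#' that of the observed table. Point masses come from [stats::dhyper];
#' "does not exceed" carries the customary relative slack of 1e-7 so that
#' ties are not broken by floating-point noise.
#'
#' @inheritParams ror_point
#' @return A p-value in `[0, 1]`.
#' @export
fisher_exact_2tail <- function(t) {
  x <- as_cells(t)
  if (any(x != round(x))) stop("Fisher test requires integer cells")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

make_signal_result <- function(subject, cells, p_raw, n_tests, alpha = 0.05,
                               zero_correction = TRUE) {
  cc <- correct_cells(cells, zero_correction)
  or <- (cc$cells[1] * cc$cells[4]) / (cc$cells[2] * cc$cells[3])
  ci <- ror_ci95(cells, zero_correction)
  p_adj <- min(1, p_raw * n_tests)
  classification <- "not-significant"
  if (p_adj < alpha && ci[["low"]] > 1) classification <- "enriched"
  if (p_adj < alpha && ci[["high"]] < 1) classification <- "purified"
  list(subject = subject, ror = or, ci_low = unname(ci[["low"]]),
       ci_high = unname(ci[["high"]]), p_raw = p_raw, p_adj = p_adj,
       n_tests = n_tests, classification = classification,
       correction_applied = cc$corrected)
}

# default exclusion list: event terms naming the pandemic pathogen itself,
# removed from downstream stages because their association is definitional
COVID_AE_TERMS <- c("coronavirus infection", "coronavirus test positive",
                    "covid-19", "suspected covid-19", "covid-19 pneumonia")

#' Step 1: disproportionality screen of every adverse event
#'
#' For each adverse event, forms the 2x2 table of event-present /
#' event-absent counts in the pandemic-window year versus the comparator year
#' and tests whether its reporting changed: ROR with Wald 95% CI, two-tailed
#' Fisher exact p, Bonferroni correction over the events actually tested.
#' An event is classified `enriched` when the adjusted p is below `alpha`
#' and the lower CI bound exceeds 1; `purified` when the adjusted p is below
#' `alpha` and the upper CI bound is below 1; otherwise `not-significant`.
#'
#' Events on the exclusion list (by default the five pathogen-named terms)
#' are tested and reported but flagged so later stages can drop them. Events
#' with fewer than `n_min` reports across the two years are not tested and
#' do not enter the Bonferroni family.
#'
#' @param reports Deduplicated `ae_reports`.
#' @param year_pair Integer `c(comparator, pandemic)` years, default
#'   `c(2019, 2020)`.
#' @param spec A [cohort_spec()] applied before counting (set `years` to
#'   cover `year_pair`).
#' @param n_min Minimum combined report count for an event to be tested
#'   (default 3).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param exclude_aes Character vector of event ids to flag as excluded.
#' @return A tibble with one row per tested event: `ae_id`, `n_2020`/`n_2019`
#'   style counts (named by the actual years), `ror`, `ci_low`, `ci_high`,
#'   `p_raw`, `p_adj`, `n_tests`, `classification`, `correction_applied`,
#'   `excluded`.
#' @export
screen_aes <- function(reports, year_pair = c(2019L, 2020L),
                       spec = cohort_spec(years = year_pair),
                       n_min = 3L, alpha = 0.05,
                       exclude_aes = COVID_AE_TERMS) {
  reports <- filter_cohort(as_ae_reports(reports), spec)
  y_ref <- as.integer(year_pair[1])
  y_pan <- as.integer(year_pair[2])
  tab <- ae_year_counts(reports, c(y_ref, y_pan))
  n_ref <- tab$totals[[as.character(y_ref)]]
  n_pan <- tab$totals[[as.character(y_pan)]]
  if (n_ref == 0L || n_pan == 0L) {
    stop("empty year stratum: ", if (n_ref == 0L) y_ref else y_pan,
         " has no cohort reports")
  }
  cnt <- tab$counts
  eligible <- rowSums(cnt) >= n_min
  cnt <- cnt[eligible, , drop = FALSE]
  n_tests <- nrow(cnt)
  if (n_tests == 0L) {
    return(tibble::tibble(ae_id = character(), n_pandemic = integer(),
                          n_reference = integer(), ror = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          p_raw = numeric(), p_adj = numeric(),
                          n_tests = integer(), classification = character(),
                          correction_applied = logical(), excluded = logical()))
  }
  res <- lapply(seq_len(n_tests), function(i) {
    a <- cnt[i, as.character(y_pan)]          # event present, pandemic year
    c_ <- cnt[i, as.character(y_ref)]         # event present, comparator
    cells <- c(a, n_pan - a, c_, n_ref - c_)
    p <- fisher_exact_2tail(cells)
    make_signal_result(rownames(cnt)[i], cells, p, n_tests, alpha)
  })
  out <- tibble::tibble(
    ae_id = vapply(res, `[[`, character(1), "subject"),
    n_pandemic = as.integer(cnt[, as.character(y_pan)]),
    n_reference = as.integer(cnt[, as.character(y_ref)]),
    ror = vapply(res, `[[`, numeric(1), "ror"),
    ci_low = vapply(res, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(res, `[[`, numeric(1), "ci_high"),
    p_raw = vapply(res, `[[`, numeric(1), "p_raw"),
    p_adj = vapply(res, `[[`, numeric(1), "p_adj"),
    n_tests = n_tests,
    classification = vapply(res, `[[`, character(1), "classification"),
    correction_applied = vapply(res, `[[`, logical(1), "correction_applied")
  )
  out$excluded <- tolower(out$ae_id) %in% tolower(exclude_aes)
  out[order(out$ae_id), , drop = FALSE]
}
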