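#' Count reports matching a conjunctive predicate
#'
#' The counting function over report collections: the number of reports whose
#' drug set, adverse-event set and submission year jointly satisfy the bound
#' clauses. A negated drug clause counts reports *without* the drug; likewise
#' for the adverse event. Unbound (`NULL`) clauses are free.
#'
#' @param reports An `ae_reports` collection, typically already cohort-filtered.
#' @param drug Optional drug id to bind.
#' @param ae Optional adverse-event id to bind.
#' @param year Optional calendar year to bind.
#' @param drug_negated,ae_negated If `TRUE`, the corresponding clause is
#'   negated (drug/AE absent from the report's set).
#' @return A non-negative integer count.
#' @export
#' @examples
#' r <- ae_reports(case_id = c("a", "b"), date = as.Date(c("2020-04-01", "2020-05-01")),
#'                 drugs = list("d1", character()), aes = list("ae1", "ae1"))
#' count_reports(r, ae = "ae1")            # 2
#' count_reports(r, drug = "d1", ae = "ae1")  # 1
#' count_reports(r, drug = "d1", drug_negated = TRUE)  # 1
count_reports <- function(reports, drug = NULL, ae = NULL, year = NULL,
                          drug_negated = FALSE, ae_negated = FALSE) {
  reports <- as_ae_reports(reports)
  if (is.null(drug) && is.null(ae) && is.null(year)) {
    stop("at least one clause (drug, ae, year) must be bound")
  }
  keep <- rep(TRUE, nrow(reports))
  if (!is.null(year)) keep <- keep & report_year(reports) %in% as.integer(year)
  if (!is.null(drug)) {
    stopifnot_scalar_chr(drug, "drug")
    has <- set_membership(reports$drugs, drug)
    keep <- keep & (if (drug_negated) !has else has)
  }
  if (!is.null(ae)) {
    stopifnot_scalar_chr(ae, "ae")
    has <- set_membership(reports$aes, ae)
    keep <- keep & (if (ae_negated) !has else has)
  }
  sum(keep)
}

# fast membership of `id` in each element of a list-of-character column
set_membership <- function(sets, id) {
  n <- length(sets)
  if (n == 0L) return(logical())
  lens <- lengths(sets)
  hit <- unlist(sets, use.names = FALSE) == id
  idx <- rep.int(seq_len(n), lens)
  out <- logical(n)
  if (any(hit)) out[unique(idx[hit])] <- TRUE
  out
}

#' Yearly reporting proportion of an adverse event
#'
#' The fraction of the year's reports whose adverse-event set contains the
#' given event; the building block of reporting trajectories.
#'
#' @param reports Cohort-filtered `ae_reports`.
#' @param ae_id Adverse-event id.
#' @param year Calendar year; the year must contain at least one report.
#' @return A fraction in `[0, 1]`.
#' @export
yearly_proportion <- function(reports, ae_id, year) {
  reports <- as_ae_reports(reports)
  denom <- count_reports(reports, year = year)
  if (denom == 0L) {
    stop("no reports in year ", year, "; yearly proportion is undefined")
  }
  count_reports(reports, ae = ae_id, year = year) / denom
}

# One-pass tabulation of (ae, year) report counts; returns a list with
# `counts` (matrix AE x year) and `totals` (named vector of per-year report
# counts). Used by the screening stages to avoid per-AE scans.
ae_year_counts <- function(reports, years) {
  years <- as.integer(years)
  yr <- report_year(reports)
  totals <- vapply(years, function(k) sum(yr == k), integer(1))
  names(totals) <- as.character(years)
  in_years <- yr %in% years
  sets <- reports$aes[in_years]
  yr_in <- yr[in_years]
  lens <- lengths(sets)
  ae_flat <- unlist(sets, use.names = FALSE)
  yr_flat <- rep.int(yr_in, lens)
  if (length(ae_flat) == 0L) {
    m <- matrix(0L, nrow = 0L, ncol = length(years),
                dimnames = list(NULL, as.character(years)))
    return(list(counts = m, totals = totals))
  }
  tab <- table(factor(ae_flat), factor(yr_flat, levels = as.character(years)))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), as.character(years)))
  list(counts = m, totals = totals)
}
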