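#' Define a report cohort
#'
#' A cohort specification selects reports by submission year, an in-year
#' calendar window, country of occurrence, reporter qualification, and
#' (optionally) patient sex and age group. Defaults reproduce the main study
#' cohort: US reports submitted by healthcare professionals (physicians,
#' pharmacists, other professionals) inside the 11 March - 30 September
#' window of each year 2013-2020.
#'
#' @param years Integer vector of calendar years to keep.
#' @param window Length-2 character `c("MM-DD", "MM-DD")` giving the inclusive
#'   in-year window, or `NULL` for whole years. Default `c("03-11", "09-30")`
#'   (the pandemic-declaration window and its same-period comparators).
#' @param countries Character vector of allowed ISO country codes, or `NULL`
#'   for no country filter. Default `"US"`.
#' @param qualifications Integer vector of allowed reporter qualifications
#'   (1 physician, 2 pharmacist, 3 other professional, 4 lawyer, 5 consumer),
#'   or `NULL` for no filter. Default `c(1, 2, 3)` (healthcare professionals).
#' @param sex Optional single value 1 (male) or 2 (female).
#' @param age_group Optional named list `list(label =, min =, max =)` with
#'   inclusive integer-age bounds, e.g. `list(label = "elderly", min = 66,
#'   max = Inf)`.
#' @param label Cohort label carried into outputs.
#' @return A `cohort_spec` list.
#' @export
#' @examples
#' cohort_spec(years = 2019:2020)
#' cohort_spec(sex = 2, label = "female")
cohort_spec <- function(years = 2013:2020,
                        window = c("03-11", "09-30"),
                        countries = "US",
                        qualifications = c(1L, 2L, 3L),
                        sex = NULL,
                        age_group = NULL,
                        label = "overall") {
  years <- as.integer(years)
  if (length(years) < 1L || anyNA(years)) stop("`years` must be non-empty integers")
  if (!is.null(window)) {
    if (length(window) != 2L) stop("`window` must be c('MM-DD','MM-DD') or NULL")
    w <- c(parse_month_day(window[1]), parse_month_day(window[2]))
    if (w[1] > w[2]) stop("window start must not be after window end")
  }
  if (!is.null(sex)) {
    sex <- as.integer(sex)
    if (length(sex) != 1L || !(sex %in% c(1L, 2L))) stop("`sex` must be 1 or 2")
  }
  if (!is.null(age_group)) {
    if (is.null(age_group$min) || is.null(age_group$max) ||
        age_group$min < 0 || age_group$min > age_group$max) {
      stop("`age_group` must have non-negative ordered `min` <= `max`")
    }
    age_group$label <- age_group$label %||% sprintf("age_%s_%s", age_group$min, age_group$max)
  }
  structure(
    list(years = years, window = window, countries = countries,
         qualifications = if (is.null(qualifications)) NULL else as.integer(qualifications),
         sex = sex, age_group = age_group, label = label),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec '%s': years %s-%s", x$label, min(x$years), max(x$years)))
  if (!is.null(x$window)) cat(sprintf(", window %s..%s", x$window[1], x$window[2]))
  if (!is.null(x$countries)) cat(", countries ", paste(x$countries, collapse = "/"))
  if (!is.null(x$qualifications)) cat(", qual {", paste(x$qualifications, collapse = ","), "}")
  if (!is.null(x$sex)) cat(", sex ", x$sex)
  if (!is.null(x$age_group)) cat(sprintf(", age [%s,%s]", x$age_group$min, x$age_group$max))
  cat(">\n")
  invisible(x)
}

#' Keep only the latest version of each case
#'
#' Collapses multiple submissions of the same case number to a single report:
#' the one with the latest submission date; date ties are broken by the larger
#' version number, then by input order (the later row wins). The result is
#' sorted by case id, so the output order does not depend on the input order.
#'
#' @param reports An `ae_reports` collection.
#' @return Deduplicated `ae_reports`, one row per case id.
#' @export
deduplicate_reports <- function(reports) {
  reports <- as_ae_reports(reports)
  if (nrow(reports) <= 1L) {
    return(reports[order(reports$case_id), , drop = FALSE])
  }
  # last row wins among ties after a stable sort on (date, version, input order)
  ord <- order(reports$date, reports$version, seq_len(nrow(reports)))
  sorted <- reports[ord, , drop = FALSE]
  keep <- !duplicated(sorted$case_id, fromLast = TRUE)
  out <- sorted[keep, , drop = FALSE]
  out[order(out$case_id), , drop = FALSE]
}

#' Filter reports to a cohort
#'
#' Applies every bound clause of a [cohort_spec()]: submission year, in-year
#' calendar window (inclusive on both ends, compared by month-day so all years
#' including leap years are treated uniformly), country, reporter
#' qualification, sex, age group. Reports with an unknown value are excluded
#' only when the corresponding filter is set.
#'
#' @param reports An `ae_reports` collection.
#' @param spec A [cohort_spec()].
#' @return The filtered `ae_reports`.
#' @export
filter_cohort <- function(reports, spec = cohort_spec()) {
  reports <- as_ae_reports(reports)
  stopifnot(inherits(spec, "cohort_spec"))
  if (nrow(reports) == 0L) return(reports)
  keep <- report_year(reports) %in% spec$years
  if (!is.null(spec$window)) {
    md <- month_day_code(reports$date)
    w1 <- parse_month_day(spec$window[1])
    w2 <- parse_month_day(spec$window[2])
    keep <- keep & md >= w1 & md <= w2
  }
  if (!is.null(spec$countries)) {
    keep <- keep & !is.na(reports$country) & reports$country %in% spec$countries
  }
  if (!is.null(spec$qualifications)) {
    keep <- keep & !is.na(reports$qualification) &
      reports$qualification %in% spec$qualifications
  }
  if (!is.null(spec$sex)) {
    keep <- keep & !is.na(reports$sex) & reports$sex == spec$sex
  }
  if (!is.null(spec$age_group)) {
    keep <- keep & !is.na(reports$age) &
      reports$age >= spec$age_group$min & reports$age <= spec$age_group$max
  }
  reports[keep, , drop = FALSE]
}
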