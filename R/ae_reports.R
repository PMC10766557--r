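#' Adverse event report collections
#'
#' An `ae_reports` object is a tibble with one row per safety report and a
#' fixed set of columns mirroring the spontaneous-report tuple used throughout
#' the package: the drugs taken, the adverse events experienced, patient
#' demographics, reporter qualification, a six-flag severity vector and the
#' submission date.
#'
#' Columns:
#' \describe{
#'   \item{case_id}{character; FAERS-style case number (shared across versions
#'     of the same case).}
#'   \item{version}{integer; submission version, larger = later.}
#'   \item{date}{`Date`; submission date.}
#'   \item{country}{character; ISO-3166 alpha-2 country of occurrence, `NA`
#'     if unknown.}
#'   \item{age}{numeric; patient age in years, `NA` if unknown.}
#'   \item{sex}{integer; 1 = male, 2 = female, `NA` = unknown.}
#'   \item{weight}{numeric; patient weight in kg, `NA` if unknown.}
#'   \item{qualification}{integer 1-5; 1 = physician, 2 = pharmacist,
#'     3 = other health professional, 4 = lawyer, 5 = consumer, `NA` unknown.}
#'   \item{severity}{character; 6-character bitstring over the outcomes
#'     (death, life-threatening, hospitalization, disability, congenital
#'     anomaly, other), e.g. `"010000"`.}
#'   \item{drugs}{list of character vectors; the drug set of the report (may
#'     be empty).}
#'   \item{aes}{list of character vectors; the adverse event set (non-empty
#'     after ingestion).}
#'   \item{t}{integer; days from 2000-01-01 to `date`.}
#' }
#'
#' @param case_id,version,date,country,age,sex,weight,qualification,severity,drugs,aes
#'   Column values as described above; `version` defaults to 1, `t` is derived
#'   from `date`.
#' @return An `ae_reports` tibble.
#' @export
#' @examples
#' r <- ae_reports(
#'   case_id = "C1", date = as.Date("2020-04-01"), country = "US",
#'   age = 60, sex = 2, weight = 70, qualification = 1,
#'   severity = "001000", drugs = list(c("d1", "d2")), aes = list("headache")
#' )
#' r
ae_reports <- function(case_id = character(), version = 1L, date = as.Date(character()),
                       country = NA_character_, age = NA_real_, sex = NA_integer_,
                       weight = NA_real_, qualification = NA_integer_,
                       severity = "000000", drugs = list(), aes = list()) {
  n <- length(case_id)
  if (n > 0L && length(drugs) == 0L) drugs <- rep(list(character()), n)
  if (n > 0L && length(aes) == 0L) aes <- rep(list(character()), n)
  out <- tibble::tibble(
    case_id = as.character(case_id),
    version = rep_len(as.integer(version), n),
    date = rep_len(as.Date(date), n),
    country = rep_len(as.character(country), n),
    age = rep_len(as.numeric(age), n),
    sex = rep_len(as.integer(sex), n),
    weight = rep_len(as.numeric(weight), n),
    qualification = rep_len(as.integer(qualification), n),
    severity = rep_len(as.character(severity), n),
    drugs = drugs,
    aes = aes,
    t = days_since_calibration(rep_len(as.Date(date), n))
  )
  new_ae_reports(out)
}

new_ae_reports <- function(x) {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  class(x) <- c("ae_reports", class(x))
  validate_ae_reports(x)
}

REPORT_COLUMNS <- c("case_id", "version", "date", "country", "age", "sex",
                    "weight", "qualification", "severity", "drugs", "aes", "t")

validate_ae_reports <- function(x) {
  missing_cols <- setdiff(REPORT_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    stop("ae_reports is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) > 0L) {
    bad_sev <- which(nchar(x$severity) != 6L | grepl("[^01]", x$severity))
    if (length(bad_sev) > 0L) {
      stop("severity must be a 6-character 0/1 bitstring; bad row(s): ",
           paste(utils::head(bad_sev, 5L), collapse = ", "), call. = FALSE)
    }
    bad_sex <- which(!is.na(x$sex) & !(x$sex %in% c(1L, 2L)))
    if (length(bad_sex) > 0L) {
      stop("sex must be 1 (male), 2 (female) or NA; bad row(s): ",
           paste(utils::head(bad_sex, 5L), collapse = ", "), call. = FALSE)
    }
    bad_q <- which(!is.na(x$qualification) & !(x$qualification %in% 1:5))
    if (length(bad_q) > 0L) {
      stop("qualification must be in 1..5 or NA; bad row(s): ",
           paste(utils::head(bad_q, 5L), collapse = ", "), call. = FALSE)
    }
  }
  x
}

#' Coerce a data frame to an `ae_reports` collection
#'
#' @param x A data frame with the columns documented in [ae_reports()]
#'   (`t` is recomputed from `date` if absent).
#' @return An `ae_reports` tibble.
#' @export
as_ae_reports <- function(x) {
  if (inherits(x, "ae_reports")) return(x)
  x <- tibble::as_tibble(x)
  if (!"t" %in% names(x) && "date" %in% names(x)) {
    x$t <- days_since_calibration(as.Date(x$date))
  }
  if (!"version" %in% names(x)) x$version <- 1L
  new_ae_reports(x)
}

#' @export
print.ae_reports <- function(x, ...) {
  cat(sprintf("<ae_reports: %d report(s)", nrow(x)))
  if (nrow(x) > 0L) {
    yrs <- range(report_year(x))
    cat(sprintf(", %d-%d, %d distinct AE(s), %d distinct drug(s)",
                yrs[1], yrs[2],
                length(unique(unlist(x$aes))),
                length(unique(unlist(x$drugs)))))
  }
  cat(">\n")
  NextMethod()
  invisible(x)
}

# keep the class through row subsetting
#' @export
`[.ae_reports` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(REPORT_COLUMNS %in% names(out))) {
    class(out) <- c("ae_reports", setdiff(class(out), "ae_reports"))
  }
  out
}

#' Severity flags as a numeric matrix
#'
#' Expands the 6-character severity bitstring into an n x 6 0/1 matrix with
#' columns death, life_threatening, hospitalization, disability,
#' congenital_anomaly, other.
#'
#' @param reports An `ae_reports` collection.
#' @return Integer matrix with one row per report.
#' @export
severity_matrix <- function(reports) {
  flags <- c("death", "life_threatening", "hospitalization", "disability",
             "congenital_anomaly", "other")
  if (nrow(reports) == 0L) {
    return(matrix(integer(), ncol = 6L, dimnames = list(NULL, flags)))
  }
  m <- matrix(as.integer(unlist(strsplit(reports$severity, "", fixed = TRUE))),
              ncol = 6L, byrow = TRUE)
  colnames(m) <- flags
  m
}
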