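#' Read the simplified report-table dialect
#'
#' Reads a UTF-8 tab-separated report table (one row per report) with the
#' columns `caseid, version, date, country, age_years, sex, weight_kg,
#' qualification, severity, drugs, aes`. Multi-valued fields (`drugs`, `aes`)
#' are semicolon-joined; `sex` is coded M/F/U; missing numerics are `NA`.
#'
#' @param path Path to the TSV file (header row required).
#' @return An `ae_reports` collection.
#' @export
read_report_table <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           na.strings = character(), check.names = FALSE,
                           fileEncoding = "UTF-8")
  required <- c("caseid", "version", "date", "country", "age_years", "sex",
                "weight_kg", "qualification", "severity", "drugs", "aes")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("report table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) return(ae_reports())
  drugs <- split_multi(raw$drugs, "drugs")
  aes <- split_multi(raw$aes, "aes")
  ae_reports(
    case_id = raw$caseid,
    version = parse_int(raw$version),
    date = as.Date(raw$date),
    country = ifelse(raw$country %in% c("", "NA"), NA_character_, raw$country),
    age = parse_num(raw$age_years),
    sex = c(M = 1L, F = 2L)[raw$sex],
    weight = parse_num(raw$weight_kg),
    qualification = parse_int(raw$qualification),
    severity = raw$severity,
    drugs = drugs,
    aes = aes
  )
}

parse_num <- function(x) suppressWarnings(as.numeric(ifelse(x %in% c("", "NA"), NA, x)))
parse_int <- function(x) suppressWarnings(as.integer(ifelse(x %in% c("", "NA"), NA, x)))

# split semicolon-joined multi-value fields; reject malformed entries
# (empty tokens inside a non-empty field) with their row numbers
split_multi <- function(x, field) {
  parts <- strsplit(x, ";", fixed = TRUE)
  bad <- which(nzchar(x) & vapply(parts, function(p) any(!nzchar(p)), logical(1)))
  bad <- union(bad, which(grepl("^;|;;|;$", x)))
  if (length(bad) > 0L) {
    stop("malformed multi-value `", field, "` field in row(s): ",
         paste(sort(utils::head(bad, 5L)), collapse = ", "), call. = FALSE)
  }
  lapply(parts, function(p) unique(p[nzchar(p)]))
}

#' Write reports in the simplified report-table dialect
#'
#' Inverse of [read_report_table()]: the written file round-trips losslessly.
#'
#' @param reports An `ae_reports` collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(reports, path) {
  reports <- as_ae_reports(reports)
  out <- data.frame(
    caseid = reports$case_id,
    version = reports$version,
    date = format(reports$date, "%Y-%m-%d"),
    country = ifelse(is.na(reports$country), "NA", reports$country),
    age_years = ifelse(is.na(reports$age), "NA", as.character(reports$age)),
    sex = ifelse(is.na(reports$sex), "U", c("M", "F")[reports$sex]),
    weight_kg = ifelse(is.na(reports$weight), "NA", as.character(reports$weight)),
    qualification = ifelse(is.na(reports$qualification), "NA",
                           as.character(reports$qualification)),
    severity = reports$severity,
    drugs = vapply(reports$drugs, paste, character(1), collapse = ";"),
    aes = vapply(reports$aes, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a two-column term mapping table
#'
#' Mapping tables (raw term -> mapped id) connect verbatim FAERS adverse-event
#' terms or drug names to MedDRA-PT / drug ids or to SOC / ATC classes. They
#' are user-supplied: the MedDRA and ATC vocabularies are license-restricted
#' and not shipped.
#'
#' @param path TSV with two columns: raw term, mapped id (header optional but
#'   recommended: `raw_term`, `mapped_id`).
#' @return A named character vector (names = raw terms).
#' @export
read_mapping <- function(path) {
  m <- utils::read.delim(path, sep = "\t", colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(m) < 2L) stop("mapping file must have two columns: raw_term, mapped_id")
  stats::setNames(m[[2]], m[[1]])
}

#' Read FAERS quarterly ASCII tables
#'
#' Joins the $-delimited DEMO, DRUG, REAC and OUTC quarterly extracts on
#' `primaryid` into an `ae_reports` collection. Adverse-event terms and drug
#' names are passed through optional user-supplied mapping tables; unmapped
#' terms are kept verbatim and reported. Age units are normalised to years.
#' DRUG/REAC/OUTC rows whose `primaryid` has no DEMO match are skipped and
#' counted in the attached ingest report.
#'
#' @param demo_path,drug_path,reac_path,outc_path Paths to the four tables.
#' @param ae_map,drug_map Optional named character vectors (see
#'   [read_mapping()]) mapping verbatim terms to ids.
#' @return An `ae_reports` collection with attribute `ingest` (a list with
#'   `skipped_drug`, `skipped_reac`, `skipped_outc` orphan-row counts and
#'   `unmapped_aes`, `unmapped_drugs` term vectors).
#' @export
read_faers_ascii <- function(demo_path, drug_path, reac_path, outc_path,
                             ae_map = NULL, drug_map = NULL) {
  read_dollar <- function(p) {
    utils::read.delim(p, sep = "$", colClasses = "character",
                      na.strings = character(), check.names = FALSE,
                      fileEncoding = "UTF-8")
  }
  demo <- read_dollar(demo_path)
  drug <- read_dollar(drug_path)
  reac <- read_dollar(reac_path)
  outc <- read_dollar(outc_path)
  names(demo) <- tolower(names(demo)); names(drug) <- tolower(names(drug))
  names(reac) <- tolower(names(reac)); names(outc) <- tolower(names(outc))
  for (nm in c("primaryid", "caseid")) {
    if (!nm %in% names(demo)) stop("DEMO table is missing column `", nm, "`")
  }
  ids <- demo$primaryid
  orphans <- function(tab) sum(!(tab$primaryid %in% ids))
  ingest <- list(skipped_drug = orphans(drug), skipped_reac = orphans(reac),
                 skipped_outc = orphans(outc),
                 unmapped_aes = character(), unmapped_drugs = character())

  map_terms <- function(terms, map, slot) {
    if (is.null(map)) return(terms)
    mapped <- unname(map[terms])
    unmapped <- terms[is.na(mapped)]
    if (length(unmapped) > 0L) {
      ingest[[slot]] <<- sort(unique(c(ingest[[slot]], unmapped)))
    }
    ifelse(is.na(mapped), terms, mapped)
  }
  drug_sets <- split(map_terms(drug$drugname, drug_map, "unmapped_drugs"),
                     factor(drug$primaryid, levels = ids))
  reac_sets <- split(map_terms(reac$pt, ae_map, "unmapped_aes"),
                     factor(reac$primaryid, levels = ids))
  drug_sets <- lapply(drug_sets, function(x) unique(x[nzchar(x)]))
  reac_sets <- lapply(reac_sets, function(x) unique(x[nzchar(x)]))

  outc_codes <- c(DE = 1L, LT = 2L, HO = 3L, DS = 4L, CA = 5L, OT = 6L)
  sev <- vapply(split(outc$outc_cod, factor(outc$primaryid, levels = ids)),
                function(codes) {
                  bits <- rep("0", 6L)
                  bits[stats::na.omit(outc_codes[codes])] <- "1"
                  paste(bits, collapse = "")
                }, character(1))

  occp_codes <- c(MD = 1L, PH = 2L, OT = 3L, HP = 3L, LW = 4L, CN = 5L)
  qual <- if ("occp_cod" %in% names(demo)) {
    unname(occp_codes[demo$occp_cod])
  } else rep(NA_integer_, length(ids))

  date_col <- intersect(c("fda_dt", "event_dt", "init_fda_dt"), names(demo))[1]
  if (is.na(date_col)) stop("DEMO table has no recognised date column (fda_dt)")
  dates <- as.Date(demo[[date_col]], format = "%Y%m%d")

  country_col <- intersect(c("occr_country", "reporter_country"), names(demo))[1]
  country <- if (!is.na(country_col)) {
    ifelse(nzchar(demo[[country_col]]), demo[[country_col]], NA_character_)
  } else rep(NA_character_, length(ids))

  sex_col <- intersect(c("sex", "gndr_cod"), names(demo))[1]
  sex <- if (!is.na(sex_col)) {
    unname(c(M = 1L, F = 2L)[demo[[sex_col]]])
  } else rep(NA_integer_, length(ids))

  age <- faers_age_years(demo$age %||% rep("", length(ids)),
                         demo$age_cod %||% rep("YR", length(ids)))
  weight <- parse_num(demo$wt %||% rep("", length(ids)))

  version <- parse_int(demo$caseversion %||% rep("1", length(ids)))
  version[is.na(version)] <- 1L
  out <- ae_reports(
    case_id = demo$caseid,
    version = version,
    date = dates,
    country = country,
    age = age,
    sex = sex,
    weight = weight,
    qualification = qual,
    severity = unname(sev),
    drugs = unname(drug_sets),
    aes = unname(reac_sets)
  )
  attr(out, "ingest") <- ingest
  out
}

# normalise FAERS age + unit code to years
faers_age_years <- function(age, age_cod) {
  a <- parse_num(age)
  unit <- toupper(age_cod)
  factor_to_years <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1775,
                       DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor_to_years[unit]
  f[is.na(f)] <- 1
  a * unname(f)
}
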