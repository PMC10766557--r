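#' Configure the synthetic report generator
#'
#' Builds the configuration for [generate_reports()]. The generator emulates
#' the structure of a spontaneous-report stream: per-report drug and
#' adverse-event sets, demographics with realistic missingness, reporter
#' qualification, a six-flag severity vector and submission dates inside the
#' 11 March - 30 September window of each year 2013-2020. Ground truth is
#' planted through three mechanisms: per-event linear yearly trends in
#' reporting proportion, a multiplicative pandemic effect on the 2020
#' in-window proportion, and drug-event associations expressed as odds
#' multipliers on P(event | drug present), optionally with an extra
#' pandemic-interaction multiplier active only in the 2020 window.
#'
#' With all pandemic effects at 1 and no planted associations the generated
#' data satisfy the null of every downstream screen.
#'
#' @param n_reports_per_year Reports per year; a scalar or a vector named by
#'   year ("2013".."2020"). Default 20000.
#' @param ae_catalog Data frame with columns `ae_id`, `baseline` (reporting
#'   proportion in 2013) and `slope` (change in proportion per year). Default:
#'   60 null events with baselines evenly spaced between 0.005 and 0.095
#'   (about three events per report, so event-free reports are rare), slope 0.
#' @param pandemic_effects Named numeric vector, event id -> multiplicative
#'   effect on the 2020 in-window reporting proportion (1 = null).
#' @param drug_catalog Data frame with columns `drug_id`, `p_include`
#'   (baseline inclusion probability per report). Default: 20 drugs with
#'   inclusion probabilities between 0.01 and 0.08.
#' @param planted_associations Data frame with columns `drug_id`, `ae_id`,
#'   `or_mult` (odds multiplier on the event given the drug) and optional
#'   `pandemic_mult` (additional multiplier in the 2020 window). Default none.
#' @param demographics List overriding any of: `p_sex` (probabilities of
#'   male/female/unknown), `age_mean`, `age_sd`, `p_age_unknown`,
#'   `weight_mean`, `weight_sd`, `p_weight_unknown`, `p_qualification`
#'   (probabilities of codes 1-5 and unknown), `p_severity` (six flag
#'   probabilities).
#' @param dup_fraction Fraction of case ids emitted twice with a strictly
#'   later date (exercises deduplication). Default 0.
#' @param out_of_window_fraction Fraction of each year's reports dated outside
#'   the 11 Mar - 30 Sep window. Default 0.
#' @param filler_ae Event id assigned to reports whose drawn event set is
#'   empty (report event sets are non-empty by construction). Default
#'   `"ae_other"`.
#' @param seed Integer RNG seed; generation is fully reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_reports_per_year = 20000L,
                             ae_catalog = NULL,
                             pandemic_effects = NULL,
                             drug_catalog = NULL,
                             planted_associations = NULL,
                             demographics = list(),
                             dup_fraction = 0,
                             out_of_window_fraction = 0,
                             filler_ae = "ae_other",
                             seed = 1L) {
  years <- 2013:2020
  if (length(n_reports_per_year) == 1L) {
    n_reports_per_year <- stats::setNames(rep(as.integer(n_reports_per_year), 8L),
                                          as.character(years))
  }
  if (!all(as.character(years) %in% names(n_reports_per_year))) {
    stop("`n_reports_per_year` must cover all years 2013-2020")
  }
  n_reports_per_year <- as.integer(n_reports_per_year[as.character(years)])
  if (any(n_reports_per_year < 1L)) stop("`n_reports_per_year` must be >= 1")

  if (is.null(ae_catalog)) {
    # ~3 events per report on average, so genuinely event-free reports (which
    # receive the filler id) are rare (~5%), as in real report streams
    ae_catalog <- data.frame(
      ae_id = sprintf("ae%02d", 1:60),
      baseline = seq(0.005, 0.095, length.out = 60),
      slope = 0
    )
  }
  stopifnot(all(c("ae_id", "baseline", "slope") %in% names(ae_catalog)))
  if (any(ae_catalog$baseline < 0 | ae_catalog$baseline > 1)) {
    stop("ae_catalog baselines must be in [0,1]")
  }
  if (is.null(drug_catalog)) {
    drug_catalog <- data.frame(
      drug_id = sprintf("drug%02d", 1:20),
      p_include = seq(0.01, 0.08, length.out = 20)
    )
  }
  stopifnot(all(c("drug_id", "p_include") %in% names(drug_catalog)))
  if (any(drug_catalog$p_include < 0 | drug_catalog$p_include > 1)) {
    stop("drug inclusion probabilities must be in [0,1]")
  }
  pandemic_effects <- pandemic_effects %||% stats::setNames(numeric(), character())
  if (any(pandemic_effects <= 0)) stop("pandemic effects must be > 0")
  if (is.null(planted_associations)) {
    planted_associations <- data.frame(drug_id = character(), ae_id = character(),
                                       or_mult = numeric(), pandemic_mult = numeric())
  }
  if (!"pandemic_mult" %in% names(planted_associations)) {
    planted_associations$pandemic_mult <- rep(1, nrow(planted_associations))
  }
  if (nrow(planted_associations) > 0 &&
      any(planted_associations$or_mult <= 0 | planted_associations$pandemic_mult <= 0)) {
    stop("association multipliers must be > 0")
  }

  demo_defaults <- list(
    # 62/38 female/male split among sex-known reports, 10% unknown
    p_sex = c(male = 0.342, female = 0.558, unknown = 0.10),
    age_mean = 55, age_sd = 18, p_age_unknown = 0.15,
    weight_mean = 75, weight_sd = 16, p_weight_unknown = 0.40,
    # physicians, pharmacists, other professionals, lawyers, consumers, unknown
    p_qualification = c(0.160, 0.076, 0.148, 0.031, 0.551, 0.034),
    p_severity = c(death = 0.05, life_threatening = 0.04, hospitalization = 0.30,
                   disability = 0.03, congenital_anomaly = 0.005, other = 0.50)
  )
  demographics <- utils::modifyList(demo_defaults, demographics)
  stopifnot(dup_fraction >= 0, dup_fraction < 1,
            out_of_window_fraction >= 0, out_of_window_fraction < 1)

  structure(
    list(years = years, n_reports_per_year = n_reports_per_year,
         ae_catalog = ae_catalog, pandemic_effects = pandemic_effects,
         drug_catalog = drug_catalog, planted_associations = planted_associations,
         demographics = demographics, dup_fraction = dup_fraction,
         out_of_window_fraction = out_of_window_fraction,
         filler_ae = filler_ae, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_config: %s reports/year, %d AEs, %d drugs, ",
                     "%d pandemic effect(s), %d planted association(s), seed %d>\n"),
              paste(range(x$n_reports_per_year), collapse = "-"),
              nrow(x$ae_catalog), nrow(x$drug_catalog),
              length(x$pandemic_effects), nrow(x$planted_associations), x$seed))
  invisible(x)
}

#' Generate a synthetic report collection
#'
#' Draws reports for every year 2013-2020 under a [synthetic_config()]. Drug
#' sets are independent per-drug Bernoulli draws; event sets are per-event
#' Bernoulli draws at proportion `baseline + slope * (year - 2013)`, scaled by
#' the pandemic effect in the 2020 window, with planted drug-event odds
#' multipliers applied given the report's drug set. Proportions pushed outside
#' `[0, 1]` by a trend or effect are clamped with a warning. Reports whose
#' drawn event set is empty receive the filler event id. A `dup_fraction` of
#' case ids is emitted twice with a strictly later date.
#'
#' @param config A [synthetic_config()].
#' @return An `ae_reports` collection with attribute `ground_truth` (the
#'   planted associations and pandemic effects).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    yearly <- lapply(seq_along(config$years), function(iy) {
      generate_year(config, config$years[iy], config$n_reports_per_year[iy])
    })
    out <- do.call(rbind, yearly)
    out$case_id <- sprintf("C%07d", seq_len(nrow(out)))
    out$t <- days_since_calibration(out$date)
    out <- new_ae_reports(out)
    if (config$dup_fraction > 0) {
      out <- add_duplicates(out, config$dup_fraction)
    }
    attr(out, "ground_truth") <- list(
      pandemic_effects = config$pandemic_effects,
      planted_associations = config$planted_associations
    )
    out
  })
}

generate_year <- function(config, year, n) {
  d <- config$demographics
  window_start <- as.Date(sprintf("%d-03-11", year))
  window_end <- as.Date(sprintf("%d-09-30", year))
  in_window <- stats::runif(n) >= config$out_of_window_fraction
  offset <- floor(stats::runif(n) * (as.integer(window_end - window_start) + 1L))
  dates <- window_start + offset
  if (any(!in_window)) {
    # out-of-window dates: uniform over the rest of the year
    lo <- as.Date(sprintf("%d-01-01", year))
    hi <- as.Date(sprintf("%d-12-31", year))
    pool_all <- seq(lo, hi, by = "day")
    pool <- pool_all[pool_all < window_start | pool_all > window_end]
    dates[!in_window] <- sample(pool, sum(!in_window), replace = TRUE)
  }

  # drug sets: independent Bernoulli per drug
  n_drug <- nrow(config$drug_catalog)
  drug_draw <- matrix(stats::runif(n * n_drug), n, n_drug) <
    matrix(config$drug_catalog$p_include, n, n_drug, byrow = TRUE)
  colnames(drug_draw) <- config$drug_catalog$drug_id

  # event probabilities: trend, pandemic effect (in-window 2020), planted
  # drug-coupled odds multipliers
  cat_ae <- config$ae_catalog
  ae_draw <- matrix(FALSE, n, nrow(cat_ae))
  colnames(ae_draw) <- cat_ae$ae_id
  pandemic_on <- (year == 2020L) & in_window
  for (j in seq_len(nrow(cat_ae))) {
    p_base <- cat_ae$baseline[j] + cat_ae$slope[j] * (year - 2013L)
    effect <- unname(config$pandemic_effects[cat_ae$ae_id[j]])
    if (is.na(effect)) effect <- 1
    p <- rep(p_base, n)
    p[pandemic_on] <- p_base * effect
    if (any(p < 0 | p > 1)) {
      warning("reporting proportion for ", cat_ae$ae_id[j], " in ", year,
              " clamped to [0,1]", call. = FALSE)
      p <- clamp01(p)
    }
    assoc <- config$planted_associations[
      config$planted_associations$ae_id == cat_ae$ae_id[j], , drop = FALSE]
    if (nrow(assoc) > 0L) {
      log_odds <- log(p) - log1p(-p)  # p in (0,1) whenever associations matter
      for (k in seq_len(nrow(assoc))) {
        exposed <- drug_draw[, assoc$drug_id[k]]
        mult <- assoc$or_mult[k] *
          ifelse(pandemic_on, assoc$pandemic_mult[k], 1)
        log_odds[exposed] <- log_odds[exposed] + log(mult[exposed])
      }
      p <- 1 / (1 + exp(-log_odds))
    }
    ae_draw[, j] <- stats::runif(n) < p
  }

  drugs <- apply_sets(drug_draw)
  aes <- apply_sets(ae_draw)
  empty <- lengths(aes) == 0L
  aes[empty] <- list(config$filler_ae)

  sex_code <- sample(c(1L, 2L, NA_integer_), n, replace = TRUE, prob = d$p_sex)
  age <- round(pmin(pmax(stats::rnorm(n, d$age_mean, d$age_sd), 0), 105))
  age[stats::runif(n) < d$p_age_unknown] <- NA_real_
  weight <- round(pmin(pmax(stats::rnorm(n, d$weight_mean, d$weight_sd), 30), 200), 1)
  weight[stats::runif(n) < d$p_weight_unknown] <- NA_real_
  qual <- sample(c(1:5, NA_integer_), n, replace = TRUE, prob = d$p_qualification)
  sev_draw <- matrix(stats::runif(n * 6L), n, 6L) <
    matrix(d$p_severity, n, 6L, byrow = TRUE)
  severity <- do.call(paste0, as.data.frame(matrix(as.integer(sev_draw), n, 6L)))

  tibble::tibble(
    case_id = NA_character_, version = 1L, date = dates, country = "US",
    age = age, sex = sex_code, weight = weight, qualification = qual,
    severity = severity, drugs = drugs, aes = aes,
    t = days_since_calibration(dates)
  )
}

# convert a logical membership matrix into a list of id sets
apply_sets <- function(m) {
  ids <- colnames(m)
  idx <- which(m, arr.ind = TRUE)
  sets <- rep(list(character()), nrow(m))
  if (nrow(idx) > 0L) {
    sets[sort(unique(idx[, 1]))] <- split(ids[idx[, 2]], idx[, 1])
  }
  unname(sets)
}

add_duplicates <- function(reports, dup_fraction) {
  n_dup <- floor(dup_fraction * nrow(reports))
  if (n_dup < 1L) return(reports)
  # only duplicate reports whose date can be strictly increased inside the year
  year_end <- as.Date(sprintf("%d-12-31", report_year(reports)))
  eligible <- which(reports$date < year_end)
  picked <- sort(sample(eligible, min(n_dup, length(eligible))))
  dup <- reports[picked, , drop = FALSE]
  headroom <- as.integer(year_end[picked] - dup$date)
  dup$date <- dup$date + 1L + floor(stats::runif(length(picked)) * headroom)
  dup$version <- dup$version + 1L
  dup$t <- days_since_calibration(dup$date)
  out <- rbind(reports, dup)
  attr_gt <- attr(reports, "ground_truth")
  out <- new_ae_reports(out)
  attr(out, "ground_truth") <- attr_gt
  out
}
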