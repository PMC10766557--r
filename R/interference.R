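#' Step 3: drug interference filtering
#'
#' The final stage checks that each surviving adverse event can be attributed
#' to at least one drug: the event must be significantly associated with the
#' drug within a propensity-matched 2020 cohort (the gamma odds ratio), and
#' the drug-event pair itself must be significantly associated with the
#' pandemic across years (the delta odds ratio).
#'
#' @name interference
NULL

#' Characteristic vectors for propensity matching
#'
#' Builds the fixed-order 11-component numeric vector per report:
#' `[age, sex, weight, qualification, b1..b6, t]` (age in years, weight in
#' kg, sex/qualification as their integer codes, the six severity flags, and
#' the day count since 2000-01-01). Missing age and weight are imputed with
#' the cohort median; missing sex and qualification get a dedicated numeric
#' "unknown" level of 0. An imputation mask records exactly which positions
#' were filled in.
#'
#' @param reports An `ae_reports` cohort.
#' @param standardize z-score every column over the cohort (default `TRUE`);
#'   raw components live on wildly different scales (days vs. 0/1 flags) and
#'   would otherwise dominate the cosine similarity.
#' @return List with `z` (n x 11 matrix), `mask` (n x 11 logical matrix of
#'   imputed positions).
#' @export
characteristic_matrix <- function(reports, standardize = TRUE) {
  reports <- as_ae_reports(reports)
  n <- nrow(reports)
  sev <- severity_matrix(reports)
  z <- cbind(
    age = reports$age,
    sex = as.numeric(reports$sex),
    weight = reports$weight,
    qualification = as.numeric(reports$qualification),
    sev,
    t = as.numeric(reports$t)
  )
  mask <- is.na(z)
  med <- function(x) {
    m <- stats::median(x, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }
  z[mask[, "age"], "age"] <- med(reports$age)
  z[mask[, "weight"], "weight"] <- med(reports$weight)
  z[mask[, "sex"], "sex"] <- 0            # dedicated unknown level
  z[mask[, "qualification"], "qualification"] <- 0
  if (standardize && n > 1L) {
    mu <- colMeans(z)
    sd <- apply(z, 2L, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1
    z <- sweep(sweep(z, 2L, mu, "-"), 2L, sd, "/")
  }
  list(z = z, mask = mask)
}

#' Drugs co-occurring with an adverse event in the pandemic cohort
#'
#' The candidate set for the gamma screen: every drug appearing in at least
#' one pandemic-window report that also contains the event.
#'
#' @param reports_2020 Pandemic-window (2020) cohort `ae_reports`.
#' @param ae_id Adverse-event id.
#' @return Sorted character vector of drug ids (possibly empty).
#' @export
candidate_drugs <- function(reports_2020, ae_id) {
  reports_2020 <- as_ae_reports(reports_2020)
  has_ae <- set_membership(reports_2020$aes, ae_id)
  sort(unique(as.character(unlist(reports_2020$drugs[has_ae], use.names = FALSE))))
}

#' Nearest-neighbour propensity matching of a drug cohort
#'
#' Splits the pandemic cohort into the test group (reports containing the
#' drug) and candidate controls (reports without it) and selects, for each
#' test report in ascending case-id order, the `ratio` unexposed reports with
#' the highest cosine similarity between standardized characteristic vectors.
#' Controls are used without replacement across test reports, so
#' `|C| = ratio * |T|` whenever the candidate pool suffices; ties are broken
#' deterministically by (similarity, case id). If the pool runs short the
#' cohort is built with fewer controls and flagged `short_match`.
#'
#' @param reports_2020 Pandemic-window cohort `ae_reports` (case ids must be
#'   unique, i.e. deduplicated).
#' @param drug_id Drug id defining the test group.
#' @param ratio Controls matched per test report (default 10).
#' @return A `matched_cohort` list: `drug_id`, `test_ids`, `control_ids`,
#'   `assignment` (named list test id -> its control ids), `short_match`.
#' @export
match_controls <- function(reports_2020, drug_id, ratio = 10L) {
  reports_2020 <- as_ae_reports(reports_2020)
  if (anyDuplicated(reports_2020$case_id)) {
    stop("case ids must be unique; deduplicate the cohort first")
  }
  exposed <- set_membership(reports_2020$drugs, drug_id)
  if (!any(exposed)) stop("no reports contain drug ", drug_id)
  zm <- characteristic_matrix(reports_2020)$z
  # unit-normalise rows so the cross product is the cosine similarity
  norms <- sqrt(rowSums(zm^2))
  norms[norms == 0] <- 1
  zm <- zm / norms
  test_idx <- which(exposed)
  ctrl_idx <- which(!exposed)
  test_ids <- reports_2020$case_id[test_idx]
  ctrl_ids <- reports_2020$case_id[ctrl_idx]
  test_order <- order(test_ids)
  sims <- zm[test_idx, , drop = FALSE] %*% t(zm[ctrl_idx, , drop = FALSE])
  used <- logical(length(ctrl_idx))
  assignment <- vector("list", length(test_idx))
  names(assignment) <- test_ids
  short <- FALSE
  for (i in test_order) {
    # candidates ranked by similarity desc, case id asc
    ord <- order(-sims[i, ], ctrl_ids)
    avail <- ord[!used[ord]]
    take <- utils::head(avail, ratio)
    if (length(take) < ratio) short <- TRUE
    used[take] <- TRUE
    assignment[[i]] <- ctrl_ids[take]
  }
  structure(
    list(drug_id = drug_id,
         test_ids = sort(test_ids),
         control_ids = sort(unlist(assignment, use.names = FALSE)),
         assignment = assignment[order(names(assignment))],
         short_match = short),
    class = "matched_cohort"
  )
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort drug '%s': |T| = %d, |C| = %d%s>\n",
              x$drug_id, length(x$test_ids), length(x$control_ids),
              if (x$short_match) ", short_match" else ""))
  invisible(x)
}

#' Gamma: drug-event odds ratio within the matched cohort
#'
#' The 2x2 table is formed inside the matched set (test group = drug present,
#' control group = drug absent; columns = event present/absent):
#' `gamma = f(d, s) f(!d, !s) / (f(d, !s) f(!d, s))`, with Wald 95% CI,
#' two-tailed Fisher p and the zero-cell policy of the disproportionality
#' screen. `counts = "cohort"` instead forms the table over the whole 2020
#' cohort (drug present/absent), for sensitivity analyses.
#'
#' @param matched A [match_controls()] result.
#' @param reports_2020 The cohort the matching was built from.
#' @param ae_id Adverse-event id.
#' @param n_tests Bonferroni family size (pairs tested in the gamma stage);
#'   default 1 for a standalone call.
#' @param alpha Significance level (default 0.05).
#' @param counts `"matched"` (default) or `"cohort"`.
#' @return A one-row tibble: `drug_id`, `ae_id`, the four cells, `ror`,
#'   `ci_low`, `ci_high`, `p_raw`, `p_adj`, `significant`,
#'   `correction_applied`, `short_match`.
#' @export
gamma_or <- function(matched, reports_2020, ae_id, n_tests = 1L, alpha = 0.05,
                     counts = c("matched", "cohort")) {
  counts <- match.arg(counts)
  reports_2020 <- as_ae_reports(reports_2020)
  has_ae <- stats::setNames(set_membership(reports_2020$aes, ae_id),
                            reports_2020$case_id)
  if (counts == "matched") {
    t_ae <- has_ae[matched$test_ids]
    c_ae <- has_ae[matched$control_ids]
  } else {
    exposed <- set_membership(reports_2020$drugs, matched$drug_id)
    t_ae <- has_ae[exposed]
    c_ae <- has_ae[!exposed]
  }
  cells <- c(sum(t_ae), sum(!t_ae), sum(c_ae), sum(!c_ae))
  p <- fisher_exact_2tail(cells)
  r <- make_signal_result(ae_id, cells, p, n_tests, alpha)
  tibble::tibble(
    drug_id = matched$drug_id, ae_id = ae_id,
    n_drug_ae = cells[1], n_drug_noae = cells[2],
    n_nodrug_ae = cells[3], n_nodrug_noae = cells[4],
    ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
    p_raw = r$p_raw, p_adj = r$p_adj,
    significant = r$classification != "not-significant",
    correction_applied = r$correction_applied,
    short_match = matched$short_match
  )
}

#' Delta: pair-pandemic odds ratio across years
#'
#' Tests whether a drug-event pair's reporting is itself associated with the
#' pandemic, over the full year cohorts:
#' `delta = f(d, s, 2020) f(!d, !s, 2019) / (f(d, s, 2019) f(!d, !s, 2020))`,
#' with the Wald CI on those four cells, two-tailed Fisher p on the
#' pair-present / pair-complement by year table, Bonferroni over the pairs
#' entering the delta stage.
#'
#' @param reports Deduplicated `ae_reports` covering both years (already
#'   cohort-filtered).
#' @param drug_id,ae_id The pair.
#' @param year_pair Integer `c(comparator, pandemic)`, default `c(2019, 2020)`.
#' @param n_tests Bonferroni family size (default 1).
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble like [gamma_or()]'s.
#' @export
delta_or <- function(reports, drug_id, ae_id, year_pair = c(2019L, 2020L),
                     n_tests = 1L, alpha = 0.05) {
  reports <- as_ae_reports(reports)
  y_ref <- as.integer(year_pair[1]); y_pan <- as.integer(year_pair[2])
  yr <- report_year(reports)
  has_drug <- set_membership(reports$drugs, drug_id)
  has_ae <- set_membership(reports$aes, ae_id)
  pair <- has_drug & has_ae
  neither <- !has_drug & !has_ae
  cells <- c(sum(pair & yr == y_pan),      # f(d, s, 2020)
             sum(neither & yr == y_pan),   # f(!d, !s, 2020)
             sum(pair & yr == y_ref),      # f(d, s, 2019)
             sum(neither & yr == y_ref))   # f(!d, !s, 2019)
  p <- fisher_exact_2tail(cells)
  r <- make_signal_result(ae_id, cells, p, n_tests, alpha)
  tibble::tibble(
    drug_id = drug_id, ae_id = ae_id,
    n_pair_pandemic = cells[1], n_neither_pandemic = cells[2],
    n_pair_reference = cells[3], n_neither_reference = cells[4],
    ror = r$ror, ci_low = r$ci_low, ci_high = r$ci_high,
    p_raw = r$p_raw, p_adj = r$p_adj,
    significant = r$classification != "not-significant",
    correction_applied = r$correction_applied
  )
}

#' Step 3 screen: attribute surviving events to drugs
#'
#' For every Step-2 survivor, collects the drugs co-occurring with it in the
#' pandemic cohort, builds one matched cohort per drug (cached across events),
#' runs the gamma test on every (drug, event) pair with a Bonferroni family
#' equal to all pairs tested, then runs the delta test on the gamma-significant
#' pairs (family = pairs entering the delta stage). An event is retained when
#' at least one drug passes both screens.
#'
#' @param step2 Output of [screen_trajectories()]; rows with `passed == TRUE`
#'   are screened.
#' @param reports Deduplicated `ae_reports`.
#' @param spec A [cohort_spec()]; the pandemic cohort is its pandemic year,
#'   the delta comparator its reference year.
#' @param year_pair Integer `c(comparator, pandemic)`, default `c(2019, 2020)`.
#' @param ratio Matching ratio (default 10).
#' @param alpha Significance level (default 0.05).
#' @param gamma_counts Passed to [gamma_or()] (`"matched"` or `"cohort"`).
#' @return List with `attribution` (tibble `ae_id`, `drugs`, `n_drugs` over
#'   retained events), `gamma` and `delta` (full per-pair audit tables).
#' @export
screen_interference <- function(step2, reports, spec = cohort_spec(),
                                year_pair = c(2019L, 2020L), ratio = 10L,
                                alpha = 0.05,
                                gamma_counts = c("matched", "cohort")) {
  gamma_counts <- match.arg(gamma_counts)
  survivors <- step2$ae_id[step2$passed]
  empty_result <- list(
    attribution = tibble::tibble(ae_id = character(), drugs = list(),
                                 n_drugs = integer()),
    gamma = NULL, delta = NULL
  )
  if (length(survivors) == 0L) return(empty_result)
  cohort <- filter_cohort(as_ae_reports(reports), spec)
  yr <- report_year(cohort)
  reports_2020 <- cohort[yr == as.integer(year_pair[2]), , drop = FALSE]
  two_years <- cohort[yr %in% as.integer(year_pair), , drop = FALSE]
  pairs <- do.call(rbind, lapply(survivors, function(ae) {
    drugs <- candidate_drugs(reports_2020, ae)
    if (length(drugs) == 0L) return(NULL)
    data.frame(ae_id = ae, drug_id = drugs, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty_result)

  match_cache <- new.env(parent = emptyenv())
  get_match <- function(drug_id) {
    key <- paste0("d_", drug_id)
    if (!is.null(match_cache[[key]])) return(match_cache[[key]])
    m <- match_controls(reports_2020, drug_id, ratio = ratio)
    match_cache[[key]] <- m
    m
  }
  n_gamma <- nrow(pairs)
  gamma_tab <- do.call(rbind, lapply(seq_len(n_gamma), function(i) {
    gamma_or(get_match(pairs$drug_id[i]), reports_2020, pairs$ae_id[i],
             n_tests = n_gamma, alpha = alpha, counts = gamma_counts)
  }))
  sig <- gamma_tab[gamma_tab$significant, , drop = FALSE]
  delta_tab <- NULL
  attributed <- list()
  if (nrow(sig) > 0L) {
    n_delta <- nrow(sig)
    delta_tab <- do.call(rbind, lapply(seq_len(n_delta), function(i) {
      delta_or(two_years, sig$drug_id[i], sig$ae_id[i],
               year_pair = year_pair, n_tests = n_delta, alpha = alpha)
    }))
    keep <- delta_tab[delta_tab$significant, , drop = FALSE]
    if (nrow(keep) > 0L) {
      attributed <- split(keep$drug_id, keep$ae_id)
    }
  }
  attribution <- tibble::tibble(
    ae_id = names(attributed) %||% character(),
    drugs = lapply(unname(attributed), sort),
    n_drugs = unname(lengths(attributed))
  )
  list(attribution = attribution, gamma = gamma_tab, delta = delta_tab)
}
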