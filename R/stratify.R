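#' Demographic stratification and summary outputs
#'
#' Runs the three-stage screen per demographic cohort and summarises
#' disparities: female proportions with bootstrap uncertainty, signed gender
#' gaps (raw and per-million normalised), enriched-events-per-million rates,
#' system-organ-class rollups and drug-event association network export.
#'
#' @name stratify
NULL

#' Default demographic cohorts
#'
#' Overall, female, male, young (age < 20), adult (20-65) and elderly
#' (over 65). The elderly bound follows the study convention (age > 65); the
#' young/adult boundary is a package default, recorded in output metadata.
#'
#' @param years,window,countries,qualifications Passed to [cohort_spec()].
#' @return Named list of [cohort_spec()]s.
#' @export
default_cohorts <- function(years = 2013:2020, window = c("03-11", "09-30"),
                            countries = "US", qualifications = c(1L, 2L, 3L)) {
  base <- function(...) cohort_spec(years = years, window = window,
                                    countries = countries,
                                    qualifications = qualifications, ...)
  list(
    overall = base(label = "overall"),
    female = base(sex = 2L, label = "female"),
    male = base(sex = 1L, label = "male"),
    young = base(age_group = list(label = "young", min = 0, max = 19), label = "young"),
    adult = base(age_group = list(label = "adult", min = 20, max = 65), label = "adult"),
    elderly = base(age_group = list(label = "elderly", min = 66, max = Inf),
                   label = "elderly")
  )
}

#' Run the full three-stage screen on one cohort
#'
#' @param reports Deduplicated `ae_reports`.
#' @param spec A [cohort_spec()].
#' @param year_pair Integer `c(comparator, pandemic)` for Steps 1 and 3.
#' @param n_min,alpha,exclude_aes Passed to [screen_aes()].
#' @param paeai_base,ar_intercept Passed to [screen_trajectories()].
#' @param ratio,gamma_counts Passed to [screen_interference()].
#' @return List with `step1`, `step2`, `step3`, `final_aes` (character) and
#'   `funnel` (named survivor counts: tested, step1, step2, step3).
#' @export
run_screens <- function(reports, spec = cohort_spec(),
                        year_pair = c(2019L, 2020L), n_min = 3L, alpha = 0.05,
                        exclude_aes = COVID_AE_TERMS, paeai_base = 10,
                        ar_intercept = TRUE, ratio = 10L,
                        gamma_counts = "matched") {
  reports <- as_ae_reports(reports)
  step1 <- screen_aes(reports, year_pair = year_pair,
                      spec = cohort_spec(years = as.integer(year_pair),
                                         window = spec$window,
                                         countries = spec$countries,
                                         qualifications = spec$qualifications,
                                         sex = spec$sex,
                                         age_group = spec$age_group,
                                         label = spec$label),
                      n_min = n_min, alpha = alpha, exclude_aes = exclude_aes)
  step2 <- screen_trajectories(step1, reports, spec = spec, base = paeai_base,
                               intercept = ar_intercept)
  step3 <- screen_interference(step2, reports, spec = spec,
                               year_pair = year_pair, ratio = ratio,
                               alpha = alpha, gamma_counts = gamma_counts)
  funnel <- c(
    tested = nrow(step1),
    step1 = sum(step1$classification != "not-significant" & !step1$excluded),
    step2 = sum(step2$passed),
    step3 = nrow(step3$attribution)
  )
  list(step1 = step1, step2 = step2, step3 = step3,
       final_aes = sort(step3$attribution$ae_id), funnel = funnel)
}

#' Run the screen independently on several cohorts
#'
#' Cohorts with an empty year stratum are skipped with a warning.
#'
#' @param reports Deduplicated `ae_reports`.
#' @param cohort_specs Named list of [cohort_spec()]s
#'   (default [default_cohorts()]).
#' @param ... Passed to [run_screens()].
#' @return Named list of [run_screens()] bundles (skipped cohorts absent).
#' @export
run_cohort_pipeline <- function(reports, cohort_specs = default_cohorts(), ...) {
  reports <- as_ae_reports(reports)
  out <- list()
  for (nm in names(cohort_specs)) {
    res <- tryCatch(run_screens(reports, spec = cohort_specs[[nm]], ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("cohort '", nm, "' skipped: ", conditionMessage(res), call. = FALSE)
    } else {
      out[[nm]] <- res
    }
  }
  out
}

#' Female proportion of an adverse event's reports, with bootstrap SD
#'
#' The fraction of female patients among the sex-known reports containing the
#' event in the given period; the standard deviation comes from resampling
#' those reports with replacement.
#'
#' @param reports Cohort-filtered `ae_reports`.
#' @param ae_id Adverse-event id.
#' @param years Years forming the period (e.g. `2013:2019` before, `2020`
#'   during).
#' @param B Bootstrap resamples (default 1000).
#' @param seed Optional seed for the bootstrap.
#' @return List `(prop, sd, n)`; `prop` is `NA` (flagged by `n = 0`) when no
#'   sex-known report carries the event.
#' @export
female_proportion <- function(reports, ae_id, years, B = 1000L, seed = NULL) {
  reports <- as_ae_reports(reports)
  sel <- set_membership(reports$aes, ae_id) &
    report_year(reports) %in% as.integer(years) & !is.na(reports$sex)
  x <- reports$sex[sel] == 2L
  n <- length(x)
  if (n == 0L) return(list(prop = NA_real_, sd = NA_real_, n = 0L))
  prop <- mean(x)
  sd_boot <- with_seed(seed, {
    draws <- matrix(sample(x, n * B, replace = TRUE), nrow = n)
    stats::sd(colMeans(draws))
  })
  list(prop = prop, sd = sd_boot, n = n)
}

#' Signed gender gap in an adverse event's reports
#'
#' `#female - #male` reports containing the event in the period; a negative
#' value means the event is reported less often in women than in men. With
#' `normalize = TRUE` each count is first divided by the cohort's total
#' same-sex report count in the period and the difference is expressed per
#' million reports.
#'
#' @param reports Cohort-filtered `ae_reports`.
#' @param ae_id Adverse-event id.
#' @param years Years forming the period.
#' @param normalize Per-million normalisation by same-sex report totals.
#' @return A signed real (integer count difference unless normalised).
#' @export
gender_gap <- function(reports, ae_id, years, normalize = FALSE) {
  reports <- as_ae_reports(reports)
  in_period <- report_year(reports) %in% as.integer(years)
  has_ae <- set_membership(reports$aes, ae_id)
  n_f <- sum(in_period & has_ae & !is.na(reports$sex) & reports$sex == 2L)
  n_m <- sum(in_period & has_ae & !is.na(reports$sex) & reports$sex == 1L)
  if (!normalize) return(n_f - n_m)
  tot_f <- sum(in_period & !is.na(reports$sex) & reports$sex == 2L)
  tot_m <- sum(in_period & !is.na(reports$sex) & reports$sex == 1L)
  if (tot_f == 0L || tot_m == 0L) {
    stop("cannot normalise: a sex stratum has no reports in the period")
  }
  (n_f / tot_f - n_m / tot_m) * 1e6
}

#' Enriched adverse events per million cohort reports
#'
#' @param n_enriched_aes Number of enriched events found in the cohort.
#' @param cohort_report_count Total reports in the cohort (the population
#'   proxy: patient-level counts are not available in spontaneous-report
#'   data).
#' @return Events per million reports.
#' @export
per_million_rate <- function(n_enriched_aes, cohort_report_count) {
  if (cohort_report_count <= 0) stop("cohort report count must be positive")
  n_enriched_aes / cohort_report_count * 1e6
}

#' Roll identified events up to system-organ classes
#'
#' @param results A data frame with columns `ae_id` and `classification`
#'   (e.g. the [screen_aes()] output).
#' @param soc_mapping Named character vector event id -> SOC class (see
#'   [read_mapping()]); unmapped events fall into `"unclassified"`.
#' @param classifications Which classifications to count (default enriched
#'   and purified).
#' @return Tibble `soc`, `classification`, `n`.
#' @export
soc_rollup <- function(results, soc_mapping,
                       classifications = c("enriched", "purified")) {
  keep <- results[results$classification %in% classifications, , drop = FALSE]
  soc <- unname(soc_mapping[keep$ae_id])
  soc[is.na(soc)] <- "unclassified"
  if (nrow(keep) == 0L) {
    return(tibble::tibble(soc = character(), classification = character(),
                          n = integer()))
  }
  agg <- stats::aggregate(list(n = seq_len(nrow(keep))),
                          by = list(soc = soc, classification = keep$classification),
                          FUN = length)
  tibble::as_tibble(agg[order(agg$soc, agg$classification), , drop = FALSE])
}

#' Export the drug-adverse event association network
#'
#' One edge per (drug, event) pair surviving the interference screen, with
#' the gamma and delta summary statistics, optional ATC/SOC annotations and a
#' confounder flag set when the event is listed as an indication of the drug
#' (the association may then reflect the treated disease rather than a side
#' effect).
#'
#' @param step3 A [screen_interference()] result.
#' @param path_tsv Output TSV path.
#' @param path_graphml Optional GraphML output path (bipartite graph, node
#'   attribute `type` = drug/ae plus class annotations, edge attributes
#'   gamma, delta, confounder).
#' @param drug_atc,ae_soc Optional named character vectors id -> class.
#' @param indications Optional data frame with columns `drug_id`, `ae_id`
#'   listing known indications.
#' @param cohort Cohort label recorded on each edge.
#' @return The edge tibble, invisibly.
#' @export
export_network <- function(step3, path_tsv, path_graphml = NULL,
                           drug_atc = NULL, ae_soc = NULL, indications = NULL,
                           cohort = "overall") {
  att <- step3$attribution
  edges <- if (nrow(att) == 0L) {
    tibble::tibble(drug_id = character(), ae_id = character(),
                   cohort = character(), atc = character(), soc = character(),
                   gamma = numeric(), gamma_ci_low = numeric(),
                   gamma_ci_high = numeric(), gamma_p_adj = numeric(),
                   delta = numeric(), delta_ci_low = numeric(),
                   delta_ci_high = numeric(), delta_p_adj = numeric(),
                   confounder = logical())
  } else {
    pairs <- do.call(rbind, lapply(seq_len(nrow(att)), function(i) {
      data.frame(ae_id = att$ae_id[i], drug_id = att$drugs[[i]],
                 stringsAsFactors = FALSE)
    }))
    g <- step3$gamma; d <- step3$delta
    gi <- match(paste(pairs$drug_id, pairs$ae_id),
                paste(g$drug_id, g$ae_id))
    di <- match(paste(pairs$drug_id, pairs$ae_id),
                paste(d$drug_id, d$ae_id))
    conf <- if (is.null(indications)) rep(FALSE, nrow(pairs)) else {
      paste(pairs$drug_id, pairs$ae_id) %in%
        paste(indications$drug_id, indications$ae_id)
    }
    tibble::tibble(
      drug_id = pairs$drug_id, ae_id = pairs$ae_id, cohort = cohort,
      atc = if (is.null(drug_atc)) NA_character_ else
        unname(drug_atc[pairs$drug_id]),
      soc = if (is.null(ae_soc)) NA_character_ else unname(ae_soc[pairs$ae_id]),
      gamma = g$ror[gi], gamma_ci_low = g$ci_low[gi],
      gamma_ci_high = g$ci_high[gi], gamma_p_adj = g$p_adj[gi],
      delta = d$ror[di], delta_ci_low = d$ci_low[di],
      delta_ci_high = d$ci_high[di], delta_p_adj = d$p_adj[di],
      confounder = conf
    )
  }
  utils::write.table(edges, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_graphml)) {
    if (nrow(edges) == 0L) {
      g <- igraph::make_empty_graph(directed = FALSE)
    } else {
      verts <- rbind(
        data.frame(name = unique(edges$drug_id), type = "drug",
                   class = if (is.null(drug_atc)) NA_character_ else
                     unname(drug_atc[unique(edges$drug_id)])),
        data.frame(name = unique(edges$ae_id), type = "ae",
                   class = if (is.null(ae_soc)) NA_character_ else
                     unname(ae_soc[unique(edges$ae_id)]))
      )
      g <- igraph::graph_from_data_frame(
        edges[, c("drug_id", "ae_id", "gamma", "delta", "confounder")],
        directed = FALSE, vertices = verts
      )
    }
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  invisible(edges)
}
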