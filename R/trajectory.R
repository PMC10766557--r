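#' Step 2: reporting trajectories and the PAEAI deviation index
#'
#' The trajectory of an adverse event is the vector of its yearly reporting
#' proportions 2013-2020 inside the analysis window. A second-order
#' autoregressive model fitted to the 2013-2019 history predicts each year
#' one step ahead; the pandemic adverse event association index (PAEAI)
#' compares the absolute standardized residual of 2020 to the mean absolute
#' standardized residual of 2015-2019. A positive PAEAI means the 2020
#' deviation exceeds historical fluctuation, i.e. the change cannot be
#' explained by the event's own trend.
#'
#' @name trajectory
NULL

TRAJECTORY_YEARS <- 2013:2020

#' Build the yearly-proportion trajectory of an adverse event
#'
#' @param reports Deduplicated `ae_reports`.
#' @param ae_id Adverse-event id.
#' @param spec A [cohort_spec()]; its `years` must cover 2013-2020 and every
#'   year must contain at least one cohort report.
#' @return Named numeric vector `v` of length 8 (years 2013-2020).
#' @export
build_trajectory <- function(reports, ae_id, spec = cohort_spec()) {
  reports <- filter_cohort(as_ae_reports(reports), spec)
  tab <- ae_year_counts(reports, TRAJECTORY_YEARS)
  empty <- names(tab$totals)[tab$totals == 0L]
  if (length(empty) > 0L) {
    stop("trajectory undefined: no cohort reports in year(s) ",
         paste(empty, collapse = ", "))
  }
  cnt <- if (ae_id %in% rownames(tab$counts)) {
    tab$counts[ae_id, ]
  } else {
    stats::setNames(rep(0L, length(TRAJECTORY_YEARS)), as.character(TRAJECTORY_YEARS))
  }
  cnt / tab$totals
}

#' Fit an AR(2) model to a 7-point history
#'
#' Conditional least squares on the five one-step equations
#' `v_k = c + phi1 * v_{k-1} + phi2 * v_{k-2}`, k = 2015..2019, fitted to the
#' 2013-2019 history. Each event is fitted independently (no parameter
#' sharing). A rank-deficient design (e.g. a constant history) falls back to
#' an intercept-only mean predictor and is flagged degenerate.
#'
#' @param v7 Numeric history of length 7 (years 2013-2019).
#' @param intercept Include the intercept term (default `TRUE`; proportions
#'   are not mean-zero).
#' @return List with `coef` (named `c`, `phi1`, `phi2`), `r2` (coefficient of
#'   determination over the five fitted points; `NA` when the fitted values
#'   are constant) and `degenerate` flag.
#' @export
fit_ar2 <- function(v7, intercept = TRUE) {
  stopifnot(length(v7) == 7L, !anyNA(v7))
  y <- v7[3:7]
  X <- cbind(lag1 = v7[2:6], lag2 = v7[1:5])
  if (intercept) X <- cbind(`(c)` = 1, X)
  qrX <- qr(X)
  degenerate <- qrX$rank < ncol(X)
  if (degenerate) {
    coef <- c(c = mean(y), phi1 = 0, phi2 = 0)
    fitted <- rep(mean(y), 5L)
  } else {
    b <- qr.coef(qrX, y)
    coef <- if (intercept) {
      c(c = unname(b[1]), phi1 = unname(b[2]), phi2 = unname(b[3]))
    } else {
      c(c = 0, phi1 = unname(b[1]), phi2 = unname(b[2]))
    }
    fitted <- coef[["c"]] + coef[["phi1"]] * v7[2:6] + coef[["phi2"]] * v7[1:5]
  }
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - fitted)^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  list(coef = coef, r2 = r2, degenerate = degenerate)
}

#' One-step-ahead predictions from a fitted AR(2)
#'
#' `v'_k = c + phi1 * v_{k-1} + phi2 * v_{k-2}` for k = 2015..2020, always
#' using the *observed* lags (so the 2020 prediction uses the observed 2019
#' and 2018 values). The first two years seed the lags and have no
#' prediction.
#'
#' @param coef Named coefficients `c`, `phi1`, `phi2` (from [fit_ar2()]).
#' @param v Observed trajectory of length 8 (years 2013-2020).
#' @return Named numeric vector `v_pred` of length 6 (years 2015-2020).
#' @export
predict_one_step <- function(coef, v) {
  stopifnot(length(v) == 8L)
  pred <- coef[["c"]] + coef[["phi1"]] * v[2:7] + coef[["phi2"]] * v[1:6]
  stats::setNames(as.numeric(pred), as.character(2015:2020))
}

#' PAEAI: pandemic adverse event association index
#'
#' `log_B( |r_2020| / mean(|r_2015..2019|) )` where `r_k` are the
#' standardized residuals `e_k / sqrt(mean(e_{2015..2020}^2))`. Because the
#' standardization constant is common to numerator and denominator it
#' cancels, so the index equals `log_B(|e_2020| / mean(|e_2015..2019|))`.
#'
#' Degenerate inputs map to signed-infinity sentinels: a zero historical mean
#' residual gives `+Inf` (any 2020 deviation is infinitely surprising), a
#' zero 2020 residual gives `-Inf` (the year is exactly on trend).
#'
#' @param e Residuals `v'_k - v_k` for k = 2015..2020 (length 6).
#' @param base Logarithm base (default 10).
#' @return A real number (possibly `+/-Inf`).
#' @export
paeai <- function(e, base = 10) {
  stopifnot(length(e) == 6L, !anyNA(e))
  hist_mean <- mean(abs(e[1:5]))
  if (abs(e[6]) == 0) return(-Inf)   # exactly on trend (checked first: a
                                     # perfect fit everywhere is still on trend)
  if (hist_mean == 0) return(Inf)
  log(abs(e[6]) / hist_mean, base = base)
}

#' Standardized residuals of a trajectory fit
#'
#' `r_k = e_k / sqrt((1/6) * sum(e^2))` over k = 2015..2020; their squares
#' sum to 6 whenever any residual is nonzero.
#'
#' @param e Residuals of length 6 (years 2015-2020).
#' @return Numeric vector of length 6.
#' @export
standardized_residuals <- function(e) {
  stopifnot(length(e) == 6L)
  denom <- sqrt(mean(e^2))
  if (denom == 0) return(rep(0, 6L))
  e / denom
}

#' Step 2 screen: trajectory deviation of the Step-1 survivors
#'
#' For every event passing the disproportionality screen, builds its
#' trajectory, fits the AR(2) on 2013-2019, predicts one step ahead and
#' computes the PAEAI. Events with a positive PAEAI pass to the drug
#' interference stage.
#'
#' @param step1 Output of [screen_aes()]; rows classified `enriched` or
#'   `purified` and not excluded are screened.
#' @param reports Deduplicated `ae_reports` covering 2013-2020.
#' @param spec A [cohort_spec()] for the trajectory years.
#' @param base Logarithm base for the PAEAI (default 10).
#' @param intercept Include an AR(2) intercept (default `TRUE`).
#' @return A tibble with one row per screened event: the trajectory
#'   (`v_2013`..`v_2020`), coefficients (`c`, `phi1`, `phi2`), `r2`,
#'   residuals (`e_2015`..`e_2020`), `paeai`, `passed` (paeai > 0) and
#'   `degenerate` flag.
#' @export
screen_trajectories <- function(step1, reports, spec = cohort_spec(),
                                base = 10, intercept = TRUE) {
  survivors <- step1$ae_id[step1$classification %in% c("enriched", "purified") &
                             !step1$excluded]
  reports <- filter_cohort(as_ae_reports(reports), spec)
  tab <- ae_year_counts(reports, TRAJECTORY_YEARS)
  empty <- names(tab$totals)[tab$totals == 0L]
  if (length(empty) > 0L) {
    stop("trajectory undefined: no cohort reports in year(s) ",
         paste(empty, collapse = ", "))
  }
  rows <- lapply(survivors, function(ae) {
    cnt <- if (ae %in% rownames(tab$counts)) tab$counts[ae, ] else
      rep(0L, length(TRAJECTORY_YEARS))
    v <- as.numeric(cnt / tab$totals)
    fit <- fit_ar2(v[1:7], intercept = intercept)
    v_pred <- predict_one_step(fit$coef, v)
    e <- as.numeric(v_pred) - v[3:8]
    idx <- paeai(e, base = base)
    c(list(ae_id = ae),
      stats::setNames(as.list(v), paste0("v_", TRAJECTORY_YEARS)),
      list(c = fit$coef[["c"]], phi1 = fit$coef[["phi1"]],
           phi2 = fit$coef[["phi2"]], r2 = fit$r2),
      stats::setNames(as.list(e), paste0("e_", 2015:2020)),
      list(paeai = idx, passed = idx > 0,
           degenerate = fit$degenerate || !is.finite(idx)))
  })
  if (length(rows) == 0L) {
    nm <- c("ae_id", paste0("v_", TRAJECTORY_YEARS), "c", "phi1", "phi2", "r2",
            paste0("e_", 2015:2020), "paeai", "passed", "degenerate")
    out <- tibble::as_tibble(stats::setNames(
      c(list(character()), rep(list(numeric()), 19L),
        list(logical()), list(logical())),
      nm))
    return(out)
  }
  tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    tibble::as_tibble(r)
  })))
}
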