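# Shared fixture builders. All synthetic inputs are built in code at test
# time; no binary fixtures.

# a minimal hand-rolled report collection
mk_reports <- function(case_id, date, drugs = NULL, aes = NULL,
                       country = "US", qualification = 1L, sex = NA_integer_,
                       age = NA_real_, weight = NA_real_, version = 1L,
                       severity = "000000") {
  n <- length(case_id)
  ae_reports(
    case_id = case_id, version = version, date = as.Date(date),
    country = country, age = age, sex = sex, weight = weight,
    qualification = qualification, severity = severity,
    drugs = drugs %||% rep(list(character()), n),
    aes = aes %||% rep(list("ae_x"), n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n reports per year spread uniformly in the analysis window, with the given
# AE present in `k[year]` of them
mk_yearly_reports <- function(n_per_year, ae_counts, ae_id = "ae1",
                              years = 2013:2020) {
  rows <- lapply(seq_along(years), function(i) {
    y <- years[i]
    n <- n_per_year[i]
    k <- ae_counts[i]
    dates <- seq(as.Date(sprintf("%d-03-11", y)), as.Date(sprintf("%d-09-30", y)),
                 length.out = n)
    aes <- c(rep(list(c(ae_id, "bg")), k), rep(list("bg"), n - k))
    mk_reports(sprintf("%d_%04d", y, seq_len(n)), dates, aes = aes)
  })
  do.call(rbind, rows)
}

# independent brute-force two-sided Fisher p: enumerate every table with the
# observed margins via log-binomial coefficients (no dhyper)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p_all <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-7)]))
}

# small synthetic configs used across files
null_config <- function(seed, n_per_year = 2000L) {
  synthetic_config(n_reports_per_year = n_per_year, seed = seed)
}

planted_config <- function(seed, n_per_year = 20000L,
                           effect = 3, or_mult = 4) {
  planted <- data.frame(
    drug_id = c("drug10", "drug12", "drug14", "drug16", "drug18"),
    ae_id = c("ae05", "ae07", "ae09", "ae11", "ae13"),
    or_mult = or_mult, pandemic_mult = 1
  )
  synthetic_config(
    n_reports_per_year = n_per_year,
    pandemic_effects = stats::setNames(rep(effect, nrow(planted)), planted$ae_id),
    planted_associations = planted,
    seed = seed
  )
}
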