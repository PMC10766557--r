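# A small 2020 cohort with controllable characteristic vectors.
mk_cohort_2020 <- function(n, exposed_idx, drug = "dX", age = NULL, aes = NULL) {
  ids <- sprintf("r%03d", seq_len(n))
  drugs <- rep(list(character()), n)
  drugs[exposed_idx] <- list(drug)
  mk_reports(ids, rep("2020-05-01", n), drugs = drugs,
             aes = aes %||% rep(list("ae_bg"), n),
             age = age %||% rep(50, n), sex = 1L, weight = 70)
}

test_that("candidate drugs are exactly the co-occurring ones", {
  r <- mk_reports(c("a", "b", "c"), rep("2020-05-01", 3),
                  drugs = list(c("d1", "d2"), "d3", character()),
                  aes = list(c("ae1"), c("ae2"), c("ae1")))
  expect_equal(candidate_drugs(r, "ae1"), c("d1", "d2"))
  expect_equal(candidate_drugs(r, "absent"), character())
  cfg <- planted_config(seed = 2, n_per_year = 3000)
  g <- generate_reports(cfg)
  g20 <- g[format(g$date, "%Y") == "2020", ]
  expect_true("drug10" %in% candidate_drugs(g20, "ae05"))
})

test_that("matching yields |C| = 10 |T| without replacement, flags short pools", {
  r <- mk_cohort_2020(31, exposed_idx = 1, age = c(50, 30 + seq_len(30)))
  m <- match_controls(r, "dX")
  expect_length(m$test_ids, 1L)
  expect_length(m$control_ids, 10L)
  expect_false(m$short_match)
  expect_length(intersect(m$test_ids, m$control_ids), 0L)
  # 3 positives, 25 negatives: pool exhausted, short_match flagged
  r2 <- mk_cohort_2020(28, exposed_idx = 1:3)
  m2 <- match_controls(r2, "dX")
  expect_true(m2$short_match)
  expect_length(m2$control_ids, 25L)
  expect_equal(anyDuplicated(m2$control_ids), 0L)
})

test_that("identical candidates tie-break to the lexicographically smallest ids", {
  r <- mk_cohort_2020(25, exposed_idx = 5)
  m <- match_controls(r, "dX")
  expect_equal(m$control_ids, sort(setdiff(r$case_id, "r005"))[1:10])
})

test_that("matching selects the brute-force top-10 by cosine similarity", {
  # one positive; negatives at graded age distances from it
  ages <- c(50, 50 + (1:30) * 1.5)
  r <- mk_cohort_2020(31, exposed_idx = 1, age = ages)
  m <- match_controls(r, "dX")
  z <- characteristic_matrix(r)$z
  z <- z / sqrt(rowSums(z^2))
  sims <- as.numeric(z[2:31, , drop = FALSE] %*% z[1, ])
  oracle <- r$case_id[2:31][order(-sims, r$case_id[2:31])][1:10]
  expect_setequal(m$assignment[[1]], oracle)
  # matching is deterministic
  expect_identical(match_controls(r, "dX"), m)
})

test_that("characteristic vectors impute with a mask and standardize", {
  r <- mk_reports(c("a", "b", "c"), rep("2020-05-01", 3),
                  age = c(40, NA, 60), sex = c(1L, NA, 2L), weight = c(NA, 70, 90))
  cm <- characteristic_matrix(r, standardize = FALSE)
  expect_equal(dim(cm$z), c(3L, 11L))
  expect_equal(unname(cm$z[2, "age"]), 50)   # cohort median
  expect_equal(unname(cm$z[1, "weight"]), 80)
  expect_equal(unname(cm$z[2, "sex"]), 0)    # dedicated unknown level
  expect_equal(which(cm$mask[, "age"]), 2L)
  expect_equal(which(cm$mask[, "weight"]), 1L)
  zs <- characteristic_matrix(r)$z
  expect_equal(unname(colMeans(zs)), rep(0, 11), tolerance = 1e-12)
})

test_that("gamma odds ratio matches the cross product on matched counts", {
  # 20 exposed (15 with AE), 200 controls picked from 280 (AE-free cohort
  # apart from planted rates) -> verify against manually derived cells
  n <- 300L
  exposed_idx <- 1:20
  aes <- rep(list("other"), n)
  aes[1:15] <- list(c("aeQ", "other"))      # 15 of the exposed have the AE
  aes[21:50] <- list(c("aeQ", "other"))     # 30 of the unexposed have it
  r <- mk_cohort_2020(n, exposed_idx, aes = aes)
  m <- match_controls(r, "dX")
  g <- gamma_or(m, r, "aeQ")
  a <- g$n_drug_ae; b <- g$n_drug_noae; c_ <- g$n_nodrug_ae; d <- g$n_nodrug_noae
  expect_equal(a, 15L)
  expect_equal(b, 5L)
  expect_equal(a + b, 20L)
  expect_equal(c_ + d, 200L)
  expect_equal(g$ror, (a * d) / (b * c_))
  ci <- ror_ci95(c(a, b, c_, d))
  expect_equal(g$ci_low, unname(ci["low"]))
  expect_equal(fisher_exact_2tail(c(a, b, c_, d)), g$p_raw)
  # fixed counts example
  expect_equal(ror_point(c(20, 80, 10, 90)), 2.25)
})

test_that("gamma on matched nulls is near 1; planted OR 4 is detected near 4", {
  cfg <- planted_config(seed = 31, n_per_year = 12000)
  r <- deduplicate_reports(generate_reports(cfg))
  r20 <- filter_cohort(r, cohort_spec(years = 2020))
  m <- match_controls(r20, "drug10")
  g <- gamma_or(m, r20, "ae05")
  cells <- c(g$n_drug_ae, g$n_drug_noae, g$n_nodrug_ae, g$n_nodrug_noae)
  se <- sqrt(sum(1 / cells))
  expect_lt(abs(log(g$ror) - log(4)), 3 * se)
  expect_true(g$significant)
  # an unrelated drug-AE pair stays consistent with gamma = 1
  g0 <- gamma_or(match_controls(r20, "drug05"), r20, "ae20")
  cells0 <- c(g0$n_drug_ae, g0$n_drug_noae, g0$n_nodrug_ae, g0$n_nodrug_noae)
  expect_lt(abs(log(g0$ror)), 3 * sqrt(sum(1 / cells0)))
})

test_that("delta odds ratio follows its four-cell definition", {
  # identical pair frequencies in both years -> delta = 1
  mk_two_years <- function(n_pair_2019, n_pair_2020) {
    mk_year <- function(year, n_pair) {
      n <- 100L
      drugs <- c(rep(list("dP"), n_pair), rep(list(character()), n - n_pair))
      aes <- c(rep(list("aeP"), n_pair), rep(list("bg"), n - n_pair))
      mk_reports(sprintf("%d_%03d", year, 1:n), rep(sprintf("%d-05-01", year), n),
                 drugs = drugs, aes = aes)
    }
    rbind(mk_year(2019, n_pair_2019), mk_year(2020, n_pair_2020))
  }
  d1 <- delta_or(mk_two_years(10, 10), "dP", "aeP")
  expect_equal(d1$ror, 1)
  expect_false(d1$significant)
  # pair count doubles while complements stay stable
  d2 <- delta_or(mk_two_years(10, 20), "dP", "aeP")
  expect_equal(d2$ror, (20 * 90) / (10 * 80))
  expect_equal(d2$n_pair_pandemic, 20L)
  expect_equal(d2$n_neither_reference, 90L)
})

test_that("interference screen retains only pairs passing both gamma and delta", {
  # drug associated with the AE (gamma) but with stable pair frequency across
  # years (delta ~ 1): planted association without any pandemic effect
  stable <- synthetic_config(
    n_reports_per_year = 8000,
    planted_associations = data.frame(drug_id = "drug15", ae_id = "ae10",
                                      or_mult = 6, pandemic_mult = 1),
    seed = 12)
  r <- deduplicate_reports(generate_reports(stable))
  step2 <- tibble::tibble(ae_id = "ae10", passed = TRUE)
  s3 <- screen_interference(step2, r)
  g <- s3$gamma[s3$gamma$drug_id == "drug15" & s3$gamma$ae_id == "ae10", ]
  expect_true(g$significant)
  if (!is.null(s3$delta)) {
    d <- s3$delta[s3$delta$drug_id == "drug15" & s3$delta$ae_id == "ae10", ]
    expect_false(isTRUE(d$significant))
  }
  if (nrow(s3$attribution) > 0) {
    expect_false("drug15" %in% unlist(s3$attribution$drugs[s3$attribution$ae_id == "ae10"]))
  }
  # an AE with no co-occurring drug association at all is dropped outright
  none <- screen_interference(tibble::tibble(ae_id = "nonexistent", passed = TRUE), r)
  expect_equal(nrow(none$attribution), 0L)
})
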