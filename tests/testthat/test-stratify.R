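test_that("female proportion and its bootstrap SD behave like a binomial", {
  # all-female reports -> proportion 1, SD 0
  r <- mk_reports(sprintf("f%02d", 1:20), rep("2020-05-01", 20), sex = 2L,
                  aes = rep(list("aeF"), 20))
  fp <- female_proportion(r, "aeF", 2020, B = 200, seed = 1)
  expect_equal(fp$prop, 1)
  expect_equal(fp$sd, 0)
  # 50/50 with n = 400: SD within 20% of the binomial closed form
  r2 <- mk_reports(sprintf("m%03d", 1:400), rep("2020-05-01", 400),
                   sex = rep(c(1L, 2L), 200), aes = rep(list("aeB"), 400))
  fp2 <- female_proportion(r2, "aeB", 2020, B = 1000, seed = 2)
  expect_equal(fp2$prop, 0.5)
  expect_lt(abs(fp2$sd - sqrt(0.25 / 400)) / sqrt(0.25 / 400), 0.2)
  # no sex-known reports -> flagged undefined
  r3 <- mk_reports("u1", "2020-05-01", sex = NA_integer_, aes = list("aeU"))
  expect_equal(female_proportion(r3, "aeU", 2020)$n, 0L)
  expect_true(is.na(female_proportion(r3, "aeU", 2020)$prop))
})

test_that("bootstrap SD shrinks with sample size at fixed proportion", {
  sd_at <- function(n) {
    r <- mk_reports(sprintf("x%05d", 1:n), rep("2020-05-01", n),
                    sex = rep(c(1L, 2L), n / 2), aes = rep(list("ae"), n))
    female_proportion(r, "ae", 2020, B = 400, seed = 3)$sd
  }
  expect_gt(sd_at(100), 3 * sd_at(10000))
})

test_that("gender gap sign convention and normalisation", {
  r <- mk_reports(sprintf("g%02d", 1:30), rep("2020-05-01", 30),
                  sex = c(rep(2L, 12), rep(1L, 5), rep(2L, 8), rep(1L, 5)),
                  aes = c(rep(list("aeG"), 17), rep(list("bg"), 13)))
  expect_equal(gender_gap(r, "aeG", 2020), 12 - 5)
  expect_equal(gender_gap(r, "bg", 2020), 8 - 5)
  # swapping sexes flips the sign
  r_sw <- r; r_sw$sex <- ifelse(r$sex == 1L, 2L, 1L)
  expect_equal(gender_gap(r_sw, "aeG", 2020), -gender_gap(r, "aeG", 2020))
  # normalised: per-million difference of same-sex rates
  tot_f <- 20; tot_m <- 10
  expect_equal(gender_gap(r, "aeG", 2020, normalize = TRUE),
               (12 / tot_f - 5 / tot_m) * 1e6)
  expect_equal(gender_gap(r, "aeG", c(2019, 2020)), 7)  # period union
})

test_that("per-million rate is a plain scaling with guarded denominator", {
  expect_equal(per_million_rate(0, 1000), 0)
  expect_equal(per_million_rate(10, 200000), 50)
  expect_error(per_million_rate(1, 0), "positive")
})

test_that("SOC rollup buckets mapped and unmapped events", {
  res <- tibble::tibble(
    ae_id = sprintf("ae%02d", 1:18),
    classification = c(rep("enriched", 16), "purified", "not-significant"))
  soc_map <- c(stats::setNames(rep("nervous", 9), sprintf("ae%02d", 1:9)),
               stats::setNames(rep("vascular", 7), sprintf("ae%02d", 10:16)))
  roll <- soc_rollup(res, soc_map)
  expect_equal(roll$n[roll$soc == "nervous"], 9L)
  expect_equal(roll$n[roll$soc == "vascular"], 7L)
  expect_equal(roll$n[roll$soc == "unclassified"], 1L)  # the purified ae17
  expect_equal(sum(roll$n), 17L)  # the not-significant ae18 is not counted
  one <- soc_rollup(res[1:9, ], soc_map)
  expect_equal(nrow(one), 1L)
})

test_that("cohort pipeline runs per stratum and the sexes partition the overall", {
  cfg <- synthetic_config(n_reports_per_year = 2000, seed = 41)
  r <- deduplicate_reports(generate_reports(cfg))
  specs <- default_cohorts()
  overall <- filter_cohort(r, specs$overall)
  n_f <- nrow(filter_cohort(r, specs$female))
  n_m <- nrow(filter_cohort(r, specs$male))
  expect_equal(n_f + n_m + sum(is.na(overall$sex)), nrow(overall))
  # an effect planted only in female reports shows up in the female cohort only
  shocked <- deduplicate_reports(generate_reports(
    synthetic_config(n_reports_per_year = 6000, seed = 43,
                     pandemic_effects = c(ae40 = 3))))
  null_r <- deduplicate_reports(generate_reports(
    synthetic_config(n_reports_per_year = 6000, seed = 44)))
  shocked$sex <- 2L
  null_r$sex <- 1L
  null_r$case_id <- paste0("m_", null_r$case_id)
  shock_f <- rbind(shocked, null_r)
  res <- run_cohort_pipeline(shock_f, specs[c("female", "male")])
  s1f <- res$female$step1
  s1m <- res$male$step1
  expect_equal(s1f$classification[s1f$ae_id == "ae40"], "enriched")
  expect_equal(s1m$classification[s1m$ae_id == "ae40"], "not-significant")
})

test_that("network export writes edges with annotations and confounder flags", {
  step3 <- list(
    attribution = tibble::tibble(ae_id = "aeX", drugs = list(c("d1", "d2")),
                                 n_drugs = 2L),
    gamma = tibble::tibble(drug_id = c("d1", "d2"), ae_id = "aeX",
                           ror = c(4.2, 3.1), ci_low = c(2, 1.5),
                           ci_high = c(8, 6), p_adj = c(1e-4, 1e-3)),
    delta = tibble::tibble(drug_id = c("d1", "d2"), ae_id = "aeX",
                           ror = c(2.5, 2.0), ci_low = c(1.2, 1.1),
                           ci_high = c(5, 4), p_adj = c(0.01, 0.02))
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  edges <- export_network(step3, tsv, gml,
                          drug_atc = c(d1 = "N05", d2 = "C01"),
                          ae_soc = c(aeX = "nervous"),
                          indications = data.frame(drug_id = "d2", ae_id = "aeX"))
  expect_equal(nrow(edges), 2L)
  expect_equal(edges$confounder, c(FALSE, TRUE))
  expect_equal(edges$atc, c("N05", "C01"))
  expect_equal(edges$gamma, c(4.2, 3.1))
  on_disk <- utils::read.delim(tsv)
  expect_equal(nrow(on_disk), 2L)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  # empty attribution -> header-only edge file
  empty <- list(attribution = tibble::tibble(ae_id = character(), drugs = list(),
                                             n_drugs = integer()))
  export_network(empty, tsv)
  expect_equal(nrow(utils::read.delim(tsv)), 0L)
})
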