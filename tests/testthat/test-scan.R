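scan_fixture <- function(...) {
  m <- build_peptide_pathway(make_toy_model(seed = 1)$model, ll37_spec())
  carbon_scan(m, toy_carbon_sources(), ..., peptide_exchange_id = "EX_ll37_e")
}

test_that("zero uptake yields zero growth and zero peptide", {
  res <- scan_fixture(uptake_rates = c(0, 5))
  expect_true(all(abs(res$growth[, "0"]) < 1e-9))
  expect_true(all(abs(res$peptide_flux[, "0"]) < 1e-9))
})

test_that("each scan cell equals a fresh single-condition FBA solve", {
  m <- build_peptide_pathway(make_toy_model(seed = 1)$model, ll37_spec())
  res <- carbon_scan(m, toy_carbon_sources(), c(2, 7))
  for (src in toy_carbon_sources()) {
    for (r in c(2, 7)) {
      med <- medium_condition("chk", setNames(r, src$exchange_id),
        closed_exchanges = setdiff(c("EX_glc_e", "EX_dis_e", "EX_soh_e"),
                                   src$exchange_id))
      expect_equal(res$growth[src$name, as.character(r)],
                   solve_fba(apply_medium(m, med))$objective_value,
                   tolerance = 1e-8)
    }
  }
})

test_that("disaccharide at rate r grows exactly like monosaccharide at 2r", {
  m <- make_toy_model(seed = 1)$model
  res <- carbon_scan(m, toy_carbon_sources(), 1:10)
  for (r in 1:5)
    expect_equal(res$growth["trehalose", as.character(r)],
                 res$growth["glucose", as.character(2 * r)],
                 tolerance = 1e-6)
})

test_that("growth rows are non-decreasing in uptake rate", {
  res <- scan_fixture(uptake_rates = c(1, 2, 4, 8))
  expect_true(all(apply(res$growth, 1, function(v) all(diff(v) >= -1e-9))))
})

test_that("yield arithmetic matches its defining ratios", {
  expect_equal(biomass_yield(X = 0.5, X0 = 0.1, S = 10), 0.04)
  expect_equal(biomass_yield(X = 0.3, X0 = 0.3, S = 5), 0)
  expect_error(biomass_yield(0.5, 0.1, 0), "positive")
  expect_equal(peptide_yield(P = 0.16, S = 10), 0.016)
  expect_equal(peptide_yield(0, 10), 0)
  expect_equal(peptide_yield(0.32, 10), 2 * peptide_yield(0.16, 10))
  expect_error(peptide_yield(0.1, -1), "positive")
})

test_that("growth ranking puts the disaccharide first at equal molar uptake", {
  res <- scan_fixture(uptake_rates = c(2, 5, 10))
  rk <- rank_sources(res, by = "growth")
  expect_identical(rk$source[1], "trehalose")
  expect_identical(rk$category[1], "disaccharide")
})

test_that("peptide ranking at equal carbon delivery puts the sugar alcohol first", {
  res <- scan_fixture(uptake_rates = c(2, 5, 10), normalize_carbon = TRUE)
  rk <- rank_sources(res, by = "peptide")
  expect_identical(rk$source[1], "sorbitol")
  expect_identical(rk$category[1], "sugar_alcohol")
})

test_that("an all-zero matrix ranks by name", {
  res <- scan_fixture(uptake_rates = 0)
  rk <- rank_sources(res, by = "growth")
  expect_identical(rk$source, sort(vapply(toy_carbon_sources(), `[[`, "", "name")))
})

test_that("peptide flux responds to the growth_fraction trade-off as expected", {
  m <- build_peptide_pathway(make_toy_model(seed = 1)$model, ll37_spec())
  src <- toy_carbon_sources()[1]
  fl <- vapply(c(0, 0.3, 0.7, 1), function(f)
    carbon_scan(m, src, 10, peptide_exchange_id = "EX_ll37_e",
                growth_fraction = f)$peptide_flux[1, 1], numeric(1))
  expect_true(all(diff(fl) <= 1e-9))        # non-increasing in the fraction
  expect_gt(fl[1], fl[4])
  # at fraction 1 biomass is pinned at its maximum: growth-coupled peptide
  expect_gte(fl[4], 0)
})

test_that("a source absent from the model warns and yields NaN, not an abort", {
  m <- make_toy_model(seed = 1)$model
  srcs <- c(toy_carbon_sources(),
            list(carbon_source("mystery", "EX_missing_e", 6, "other")))
  expect_warning(res <- carbon_scan(m, srcs, c(1, 2)), "absent")
  expect_true(all(is.nan(res$growth["mystery", ])))
  expect_false(anyNA(res$growth["glucose", ]))
})
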