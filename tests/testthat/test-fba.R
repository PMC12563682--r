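test_that("apply_medium sets uptake bounds with the negative-uptake convention", {
  m <- make_toy_model(seed = 1)$model
  med <- medium_condition("glc10", uptake_limits = c(EX_glc_e = 10),
                          closed_exchanges = "EX_soh_e")
  m2 <- apply_medium(m, med)
  expect_equal(m2$reactions$lower_bound[m2$reactions$id == "EX_glc_e"], -10)
  i <- match("EX_soh_e", m2$reactions$id)
  expect_equal(m2$reactions$lower_bound[i], 0)
  expect_equal(m2$reactions$upper_bound[i],
               m$reactions$upper_bound[match("EX_soh_e", m$reactions$id)])
  expect_error(
    apply_medium(m, medium_condition("bad", c(GLYC = 1))),
    "not an exchange")
  # the original model is untouched (copy semantics)
  expect_equal(m$reactions$lower_bound[match("EX_glc_e", m$reactions$id)], -10)
})

test_that("a linear chain carries its uptake limit to the objective", {
  sol <- solve_fba(chain_model(uptake = 10))
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
})

test_that("closing all carbon exchanges abolishes growth", {
  m <- make_toy_model(seed = 1)$model
  med <- medium_condition("starve",
                          closed_exchanges = c("EX_glc_e", "EX_dis_e", "EX_soh_e"))
  sol <- solve_fba(apply_medium(m, med))
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("FBA objective matches the enumeration oracle on small networks", {
  for (uptake in c(1, 4, 10)) {
    m <- parallel_model(uptake)
    expect_equal(solve_fba(m)$objective_value,
                 fba_objective_by_oracle(m), tolerance = 1e-6)
  }
})

test_that("optimal solutions satisfy steady state and bounds", {
  m <- make_toy_model(seed = 1)$model
  for (src in list(c(EX_glc_e = 10), c(EX_dis_e = 3), c(EX_soh_e = 7))) {
    med <- medium_condition("m", src,
      closed_exchanges = setdiff(c("EX_glc_e", "EX_dis_e", "EX_soh_e"), names(src)))
    m2 <- apply_medium(m, med)
    sol <- solve_fba(m2)
    expect_identical(sol$status, "optimal")
    S <- stoichiometric_matrix(m2)
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
    expect_true(all(sol$fluxes >= m2$reactions$lower_bound - 1e-9))
    expect_true(all(sol$fluxes <= m2$reactions$upper_bound + 1e-9))
  }
})

test_that("growth is non-decreasing in the uptake limit", {
  m <- make_toy_model(seed = 1)$model
  vals <- vapply(1:8, function(u) {
    med <- medium_condition("g", c(EX_glc_e = u),
                            closed_exchanges = c("EX_dis_e", "EX_soh_e"))
    solve_fba(apply_medium(m, med))$objective_value
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("every reaction of a redundancy-free chain is essential", {
  ess <- essential_reactions(chain_model())
  expect_setequal(ess, c("EX_a_e", "T_a", "CONV", "BIO"))
})

test_that("parallel equivalent paths protect each other from essentiality", {
  ess <- essential_reactions(parallel_model())
  expect_false("CONV" %in% ess)
  expect_false("CONV2" %in% ess)
  expect_true("T_a" %in% ess)
})

test_that("essentiality screen equals the exhaustive knockout loop", {
  m <- make_toy_model(seed = 1)$model
  ess <- essential_reactions(m, growth_fraction_threshold = 0.01)
  wt <- solve_fba(m)$objective_value
  brute <- character(0)
  for (rid in m$reactions$id) {
    ko <- m
    i <- match(rid, ko$reactions$id)
    ko$reactions$lower_bound[i] <- 0
    ko$reactions$upper_bound[i] <- 0
    sol <- solve_fba(ko)
    if (sol$status != "optimal" || sol$objective_value < 0.01 * wt)
      brute <- c(brute, rid)
  }
  expect_setequal(ess, brute)
})

test_that("essentiality is undefined without wild-type growth", {
  m <- make_toy_model(seed = 1)$model
  med <- medium_condition("starve",
                          closed_exchanges = c("EX_glc_e", "EX_dis_e", "EX_soh_e"))
  expect_error(essential_reactions(apply_medium(m, med)), "undefined")
})
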