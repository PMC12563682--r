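test_that("the manifest reports the generator's true composition", {
  toy <- make_toy_model(seed = 1)
  st <- model_stats(toy$model)
  expect_identical(toy$manifest$counts$reactions, st$n_reactions)
  expect_identical(toy$manifest$counts$metabolites, st$n_metabolites)
  expect_identical(toy$manifest$counts$internal, st$n_internal)
  expect_identical(toy$manifest$counts$transport, st$n_transport)
  expect_identical(toy$manifest$counts$exchange, st$n_exchange)
  expect_identical(toy$manifest$counts$genes, st$n_genes)
})

test_that("FBA reproduces the hand-derived optima for every source and seed", {
  srcs <- toy_carbon_sources()
  for (seed in c(1, 7, 99)) {
    toy <- make_toy_model(seed = seed)
    slopes <- toy$manifest$growth_slopes
    for (src in srcs) {
      for (u in c(1, 4, 10)) {
        med <- medium_condition("m", setNames(u, src$exchange_id),
          closed_exchanges = setdiff(vapply(srcs, `[[`, "", "exchange_id"),
                                     src$exchange_id))
        sol <- solve_fba(apply_medium(toy$model, med))
        expect_equal(sol$objective_value, slopes[[src$name]] * u,
                     tolerance = 1e-6,
                     label = paste(src$name, "uptake", u, "seed", seed))
      }
    }
  }
})

test_that("monosaccharide at 10 equals disaccharide at 5", {
  m <- make_toy_model(seed = 1)$model
  close_all <- c("EX_glc_e", "EX_dis_e", "EX_soh_e")
  g <- solve_fba(apply_medium(m, medium_condition(
    "g", c(EX_glc_e = 10), setdiff(close_all, "EX_glc_e"))))
  d <- solve_fba(apply_medium(m, medium_condition(
    "d", c(EX_dis_e = 5), setdiff(close_all, "EX_dis_e"))))
  expect_equal(g$objective_value, d$objective_value, tolerance = 1e-9)
})

test_that("generation is bit-reproducible given the seed", {
  expect_identical(make_toy_model(seed = 5), make_toy_model(seed = 5))
  a <- make_toy_model(seed = 5)$model
  b <- make_toy_model(seed = 6)$model
  expect_false(identical(a$stoichiometry, b$stoichiometry))  # decoys differ
})

test_that("generated SBML fixtures validate and round-trip", {
  m <- make_toy_model(seed = 11)$model
  p <- tempfile(fileext = ".xml")
  write_model(m, p, "sbml")
  m2 <- read_model(p, "sbml")
  expect_same_model(m, m2)
  expect_equal(solve_fba(m2)$objective_value, solve_fba(m)$objective_value,
               tolerance = 1e-9)
})

test_that("degradation removes essentials, zeroes growth, and is repairable", {
  m <- make_toy_model(seed = 1)$model
  deg <- degrade_model(m, n_removed = 1, seed = 2)
  expect_equal(solve_fba(deg$model)$objective_value, 0, tolerance = 1e-9)
  uni <- make_universal_set(m, deg$removed_ids, n_decoys = 3, seed = 2)
  gf <- find_gapfill_set(deg$model, uni)
  expect_identical(gf$added_reaction_ids, deg$removed_ids)
  # identity at zero removals, determinism across calls
  expect_identical(degrade_model(m, 0)$model$reactions, m$reactions)
  expect_identical(degrade_model(m, 2, seed = 9)$removed_ids,
                   degrade_model(m, 2, seed = 9)$removed_ids)
  expect_error(degrade_model(m, 1000, seed = 1), "must be below")
})

test_that("noise-free simulated curves sit exactly on the logistic", {
  cv <- make_dose_response(bottom = 10, top = 90, ic50 = 8, noise_sd = 0)
  fit <- list(Bottom = 10, Top = 90, logIC50 = log10(8))
  expect_equal(cv$responses, four_pl(log10(cv$concentrations), fit),
               tolerance = 1e-12)
  expect_error(make_dose_response(ic50 = 500), "within the generated dose range")
})
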