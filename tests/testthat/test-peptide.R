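test_that("amino-acid composition counts the sequence plus the His-tag", {
  kr12 <- peptide_spec("kr12", "KRIVQRIKDFLR")
  comp <- aa_composition(kr12)
  expect_identical(sum(comp), 12L)
  expect_identical(comp[["R"]], 3L)
  expect_identical(comp[["K"]], 2L)
  expect_identical(comp[["I"]], 2L)
  expect_identical(comp[["V"]], 1L)
  expect_identical(comp[["Q"]], 1L)
  expect_identical(comp[["D"]], 1L)
  expect_identical(comp[["F"]], 1L)
  expect_identical(comp[["L"]], 1L)

  expect_identical(aa_composition(peptide_spec("gg", "GG")), c(G = 2L))

  tagged <- ll37_spec(his_tag = TRUE)
  comp <- aa_composition(tagged)
  expect_identical(sum(comp), 43L)          # 37 residues + His6
  expect_identical(comp[["H"]], 6L)         # no histidine in LL-37 itself
})

test_that("invalid residues are refused with their position", {
  expect_error(peptide_spec("bad", "GXG"), "position 2")
  expect_error(peptide_spec("empty", ""), "empty")
})

test_that("average molecular weights follow residue-mass summation", {
  tab <- residue_mass_table()
  expect_equal(peptide_average_mw(peptide_spec("g", "G")),
               (57.0513 + 18.0153) / 1000, tolerance = 1e-9)
  expect_equal(peptide_average_mw(peptide_spec("gg", "GG")),
               (2 * 57.0513 + 18.0153) / 1000, tolerance = 1e-9)
  # independent summation over the sequence string
  ll <- ll37_spec(his_tag = FALSE)
  by_hand <- sum(tab$masses[strsplit(ll$sequence, "")[[1]]]) + tab$water_mass
  expect_equal(peptide_average_mw(ll), by_hand / 1000, tolerance = 1e-9)
  expect_equal(round(peptide_average_mw(ll), 3), 4.493)
})

test_that("composition and molecular weight are additive over concatenation", {
  seqs <- c("GG", "KRIVQRIKDFLR", "LLGDFFRKSKEKIGKEFKRIVQRIKDFLRNLVPRTES",
            "ACDEFGHIKLMNPQRSTVWY")
  w <- residue_mass_table()$water_mass / 1000
  for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
    s1 <- peptide_spec("a", seqs[i]); s2 <- peptide_spec("b", seqs[j])
    s12 <- peptide_spec("ab", paste0(seqs[i], seqs[j]))
    c1 <- aa_composition(s1); c2 <- aa_composition(s2); c12 <- aa_composition(s12)
    for (a in union(names(c1), names(c2))) {
      expect_identical(
        c12[[a]],
        (if (a %in% names(c1)) c1[[a]] else 0L) +
          (if (a %in% names(c2)) c2[[a]] else 0L))
    }
    expect_equal(peptide_average_mw(s12),
                 peptide_average_mw(s1) + peptide_average_mw(s2) - w,
                 tolerance = 1e-9)
  }
})

test_that("the synthesis reaction instantiates the stoichiometric template", {
  m <- make_toy_model(seed = 1)$model
  mg <- build_peptide_pathway(m, peptide_spec("gg", "GG", secreted = FALSE))
  st <- mg$stoichiometry[["SYN_gg"]]
  expect_equal(st[["aa_g_c"]], -2)
  expect_equal(st[["atp_c"]], -8)
  expect_equal(st[["h2o_c"]], -7)   # 8 hydrolyses minus 1 condensation water
  expect_equal(st[["gg_c"]], 1)
  expect_equal(st[["adp_c"]], 8)
  expect_equal(st[["pi_c"]], 8)
})

test_that("a secreted peptide adds 3 classified reactions and 2 metabolites", {
  m <- make_toy_model(seed = 1)$model
  m2 <- build_peptide_pathway(m, ll37_spec())
  expect_identical(nrow(m2$reactions) - nrow(m$reactions), 3L)
  expect_identical(nrow(m2$metabolites) - nrow(m$metabolites), 2L)
  expect_identical(classify_reaction(m2, "SYN_ll37"), "internal")
  expect_identical(classify_reaction(m2, "T_ll37"), "transport")
  expect_identical(classify_reaction(m2, "EX_ll37_e"), "exchange")
})

test_that("the augmented model can export peptide at a positive optimum", {
  m <- build_peptide_pathway(make_toy_model(seed = 1)$model, ll37_spec())
  sol <- solve_fba(m, objective_id = "EX_ll37_e")
  expect_identical(sol$status, "optimal")
  expect_gt(sol$objective_value, 0)
})

test_that("the synthesis reaction is elementally balanced given residue formulas", {
  m <- build_peptide_pathway(make_toy_model(seed = 1)$model, ll37_spec())
  rep <- check_mass_balance(m)
  expect_false("SYN_ll37" %in% rep$reaction_id)
  expect_false("SYN_ll37" %in% attr(rep, "unchecked"))
})

test_that("forcing peptide production weakly reduces maximal growth", {
  m <- build_peptide_pathway(make_toy_model(seed = 1)$model, ll37_spec())
  mu_free <- solve_fba(m)$objective_value
  forced <- m
  i <- match("EX_ll37_e", forced$reactions$id)
  forced$reactions$lower_bound[i] <- 0.01
  mu_forced <- solve_fba(forced)$objective_value
  expect_lte(mu_forced, mu_free + 1e-9)
  expect_lt(mu_forced, mu_free)  # resources are genuinely diverted
})

test_that("missing precursors are reported by id", {
  m <- chain_model()
  expect_error(build_peptide_pathway(m, ll37_spec()), "missing from model")
})
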