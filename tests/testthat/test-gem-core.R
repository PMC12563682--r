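test_that("reaction classification follows the boundary/compartment rule", {
  m <- make_toy_model(seed = 1)$model
  expect_identical(classify_reaction(m, "EX_glc_e"), "exchange")
  expect_identical(classify_reaction(m, "PTS_glc"), "transport")
  expect_identical(classify_reaction(m, "GLYC"), "internal")
  expect_error(classify_reaction(m, "NOPE"), "unknown reaction")
  # invariant under positive scaling of the stoichiometry
  for (rid in c("EX_glc_e", "PTS_glc", "GLYC")) {
    scaled <- m
    scaled$stoichiometry[[rid]] <- 3.7 * scaled$stoichiometry[[rid]]
    expect_identical(classify_reaction(scaled, rid), classify_reaction(m, rid))
  }
})

test_that("reaction classes partition the reaction set", {
  m <- make_toy_model(seed = 4)$model
  cls <- vapply(m$reactions$id, classify_reaction, "", model = m)
  expect_true(all(cls %in% c("internal", "transport", "exchange")))
  st <- model_stats(m)
  expect_identical(st$n_internal + st$n_transport + st$n_exchange,
                   st$n_reactions)
})

test_that("genome gene inclusion is a plain percentage", {
  m <- chain_model()
  m$genes <- paste0("g", seq_len(505))
  st <- model_stats(m, genome_gene_count = 1983)
  expect_equal(st$included_gene_fraction, 100 * 505 / 1983, tolerance = 1e-12)
  expect_equal(round(st$included_gene_fraction, 2), 25.47)
  expect_error(model_stats(m, genome_gene_count = 0), "positive")
})

test_that("mass balance check reports per-element imbalances and skips unknowns", {
  mets <- data.frame(
    id = c("g6p_c", "f6p_c", "glc_c", "pyr_c", "x_c", "w_e"),
    name = "", formula = c("C6H13O9P", "C6H13O9P", "C6H12O6", "C3H4O3", "", "H2O"),
    charge = NA_integer_, compartment = c("c", "c", "c", "c", "c", "e"),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("PGI", "BADC", "UNK", "EX_w_e"), name = "",
    lower_bound = 0, upper_bound = 1000, gene_rule = "", subsystem = "",
    stringsAsFactors = FALSE)
  m <- metabolic_model("mb", mets, rxns, list(
    PGI = c(g6p_c = -1, f6p_c = 1),          # isomerization: balanced
    BADC = c(glc_c = -1, pyr_c = 1),         # C6 -> C3: carbon off by -3
    UNK = c(x_c = -1, pyr_c = 1),            # no formula: unchecked
    EX_w_e = c(w_e = -1)),                   # exchange: excluded
    objective_id = "PGI")
  rep <- check_mass_balance(m)
  expect_false("PGI" %in% rep$reaction_id)
  expect_false("EX_w_e" %in% rep$reaction_id)
  carbon <- rep[rep$reaction_id == "BADC" & rep$element == "C", ]
  expect_equal(carbon$imbalance, -3)
  expect_identical(attr(rep, "unchecked"), "UNK")
})

test_that("models round-trip losslessly through both dialects", {
  toy <- make_toy_model(seed = 2)$model
  for (fmt in c("sbml", "tsv")) {
    path <- if (fmt == "sbml") tempfile(fileext = ".xml") else tempfile()
    write_model(toy, path, fmt)
    expect_same_model(toy, read_model(path, fmt))
  }
  for (seed in 1:100) {
    m <- random_model(seed)
    fmt <- if (seed %% 2 == 0) "sbml" else "tsv"
    path <- if (fmt == "sbml") tempfile(fileext = ".xml") else tempfile()
    write_model(m, path, fmt)
    expect_same_model(m, read_model(path, fmt))
  }
})

test_that("empty gene rules and wide bounds survive the round-trip", {
  m <- random_model(3)
  m$reactions$gene_rule <- ""
  m$reactions$lower_bound[] <- -1000
  m$reactions$upper_bound[] <- 1000
  p <- tempfile(fileext = ".xml")
  write_model(m, p, "sbml")
  m2 <- read_model(p, "sbml")
  expect_identical(m2$reactions$gene_rule, m$reactions$gene_rule)
  expect_identical(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_identical(m2$reactions$upper_bound, m$reactions$upper_bound)
})

test_that("a TSV fixture reports its true composition through model_stats", {
  m <- random_model(8)
  p <- tempfile()
  write_model(m, p, "tsv")
  st <- model_stats(read_model(p, "tsv"))
  expect_identical(st$n_reactions, nrow(m$reactions))
  expect_identical(st$n_metabolites, nrow(m$metabolites))
})

test_that("validation rejects broken models and files", {
  m <- chain_model()
  bad <- m
  bad$stoichiometry[["CONV"]] <- c(ghost_c = -1, b_c = 1)
  expect_error(validate_model(bad), "undeclared metabolite ghost_c")
  bad2 <- m
  bad2$metabolites$compartment[1] <- "x"
  expect_error(validate_model(bad2), "unknown compartment")
  bad3 <- m
  bad3$reactions$lower_bound[2] <- 5
  bad3$reactions$upper_bound[2] <- -5
  expect_error(validate_model(bad3), "lower_bound > upper_bound")
  expect_error(read_model(tempfile(), "sbml"), "no such file")
  junk <- tempfile(fileext = ".xml")
  writeLines("<sbml><model>", junk)
  expect_error(read_model(junk, "sbml"), "parse error")
})

test_that("gene rules parse, canonicalize and expose their gene ids", {
  m <- make_toy_model(seed = 1)$model
  expect_true(all(c("ptsG", "ptsT", "treH", "pntAB") %in% m$genes))
  p <- tempfile(fileext = ".xml")
  write_model(m, p, "sbml")
  m2 <- read_model(p, "sbml")
  expect_identical(
    m2$reactions$gene_rule[m2$reactions$id == "PTS_dis"], "ptsT and treH")
})
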