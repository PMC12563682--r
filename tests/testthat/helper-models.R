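# Small hand-built networks used across the suite.

# EX_a (uptake <= 10) -> a_e --T--> a_c --CONV--> b_c --BIO--> (drain)
chain_model <- function(uptake = 10) {
  metabolic_model(
    id = "chain",
    metabolites = data.frame(
      id = c("a_e", "a_c", "b_c"), name = "", formula = "",
      charge = NA_integer_, compartment = c("e", "c", "c"),
      stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_a_e", "T_a", "CONV", "BIO"), name = "",
      lower_bound = c(-uptake, 0, 0, 0), upper_bound = 1000,
      gene_rule = "", subsystem = "", stringsAsFactors = FALSE),
    stoichiometry = list(
      EX_a_e = c(a_e = -1), T_a = c(a_e = -1, a_c = 1),
      CONV = c(a_c = -1, b_c = 1), BIO = c(b_c = -1)),
    objective_id = "BIO")
}

# two equivalent parallel conversion paths between a_c and b_c
parallel_model <- function(uptake = 10) {
  m <- chain_model(uptake)
  add_reactions(m,
    reactions = data.frame(
      id = "CONV2", name = "", lower_bound = 0, upper_bound = 1000,
      gene_rule = "", subsystem = "", stringsAsFactors = FALSE),
    stoichiometry = list(CONV2 = c(a_c = -1, b_c = 1)))
}

# random small network for solver-vs-oracle checks; bounded, possibly
# infeasible or with zero optimum -- every outcome is compared
random_lp_case <- function(seed) {
  set.seed(seed)
  m <- sample(2:4, 1)
  n <- m + sample(1:4, 1)
  list(
    A = matrix(sample(-2:2, m * n, replace = TRUE), m, n),
    b = if (runif(1) < 0.5) rep(0, m) else sample(-2:2, m, replace = TRUE),
    obj = stats::rnorm(n),
    lb = ifelse(runif(n) < 0.35, -10, 0),
    ub = ifelse(runif(n) < 0.2, 5, 10),
    maximize = runif(1) < 0.5)
}

# randomized small metabolic model for I/O round-trip checks
random_model <- function(seed) {
  set.seed(seed)
  n_met <- sample(3:6, 1)
  mets <- data.frame(
    id = paste0("m", seq_len(n_met), "_", sample(c("c", "e"), n_met, TRUE)),
    name = paste("met", seq_len(n_met)),
    formula = sample(c("", "C3H4O3", "C6H12O6"), n_met, TRUE),
    charge = sample(c(NA_integer_, -1L, 0L, 2L), n_met, TRUE),
    stringsAsFactors = FALSE)
  mets$compartment <- sub(".*_", "", mets$id)
  n_rxn <- sample(2:5, 1)
  rules <- c("", "g1", "g1 and g2", "(g1 and g2) or g3")
  rxns <- data.frame(
    id = paste0("r", seq_len(n_rxn)),
    name = paste("reaction", seq_len(n_rxn)),
    lower_bound = sample(c(-1000, 0, -2.5), n_rxn, TRUE),
    upper_bound = sample(c(1000, 5, 99.25), n_rxn, TRUE),
    gene_rule = sample(rules, n_rxn, TRUE),
    subsystem = sample(c("", "core"), n_rxn, TRUE),
    stringsAsFactors = FALSE)
  stoich <- lapply(seq_len(n_rxn), function(i) {
    k <- sample(1:min(3, n_met), 1)
    picked <- sample(mets$id, k)
    setNames(sample(c(-2, -1, 1, 0.5), k, TRUE), picked)
  })
  names(stoich) <- rxns$id
  metabolic_model(id = paste0("rand", seed), metabolites = mets,
                  reactions = rxns, stoichiometry = stoich,
                  genes = c("g1", "g2", "g3"), objective_id = "r1")
}

expect_same_model <- function(a, b) {
  expect_identical(a$id, b$id)
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$reactions, b$reactions)
  expect_identical(a$objective_id, b$objective_id)
  expect_true(setequal(a$genes, b$genes))
  expect_setequal(names(a$stoichiometry), names(b$stoichiometry))
  for (rid in names(a$stoichiometry)) {
    sa <- a$stoichiometry[[rid]]; sb <- b$stoichiometry[[rid]]
    expect_setequal(names(sa), names(sb))
    expect_equal(unname(sa[names(sa)]), unname(sb[names(sa)]),
                 tolerance = 1e-12)
  }
}

# FBA wrapper for raw matrices: used as the independent route in oracle tests
fba_objective_by_oracle <- function(model, objective_id = model$objective_id) {
  S <- stoichiometric_matrix(model)
  enumerate_lp_optimum(S, rep(0, nrow(S)),
                       as.numeric(colnames(S) == objective_id),
                       model$reactions$lower_bound,
                       model$reactions$upper_bound)$objective
}
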