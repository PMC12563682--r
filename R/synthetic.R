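AA_FORMULAS <- c(
  A = "C3H7NO2", R = "C6H14N4O2", N = "C4H8N2O3", D = "C4H7NO4",
  C = "C3H7NO2S", E = "C5H9NO4", Q = "C5H10N2O3", G = "C2H5NO2",
  H = "C6H9N3O2", I = "C6H13NO2", L = "C6H13NO2", K = "C6H14N2O2",
  M = "C5H11NO2S", F = "C9H11NO2", P = "C5H9NO2", S = "C3H7NO3",
  T = "C4H9NO3", W = "C11H12N2O2", Y = "C9H11NO3", V = "C5H11NO2")

#' Generate the synthetic toy fermentation model
#'
#' A small two-compartment lactic-acid-bacterium-style network that stands in
#' for a full genome-scale reconstruction in every test and example. It
#' carries three carbon routes feeding a common hexose-phosphate pool via
#' PTS-type (phosphoenolpyruvate-consuming) uptake:
#'
#' * glucose (6C monosaccharide),
#' * trehalose (12C disaccharide) whose uptake reaction is stoichiometrically
#'   exactly twice the glucose one, so growth on trehalose at rate r equals
#'   growth on glucose at 2r,
#' * sorbitol (6C sugar alcohol), oxidized by an NADP-linked dehydrogenase so
#'   that each mole delivers one "free" NADPH on top of the glucose-
#'   equivalent carbon.
#'
#' Downstream: lumped glycolysis, pyruvate kinase, fermentative sinks
#' (lactate, ethanol+CO2, acetate+formate with substrate-level ATP), an
#' ATP-driven transhydrogenase as the NADPH source on non-alcohol sugars,
#' reductive amination to all 20 amino acids (2 NADPH each), and a biomass
#' reaction draining the amino-acid pool plus ATP. NAD(P)(H) metabolites
#' deliberately carry no formula, so lumped redox reactions are reported as
#' unchecked by [check_mass_balance()] rather than as spuriously imbalanced
#' (mirroring draft reconstructions with formula-less cofactors); all other
#' reactions are elementally balanced.
#'
#' The linear structure admits hand-derived optima. With biomass requiring
#' 10 amino acids + 20 ATP per unit and amino-acid synthesis costing
#' 1 pyruvate + 1 ATP + 2 NADPH, the maximal growth per unit uptake U is
#' 0.06 U (glucose), 0.12 U (trehalose) and 0.07 U (sorbitol); the manifest
#' records these for the generated uptake grid. Randomness (the seed) only
#' shapes decoy dead-end reactions, so the optima hold for every seed.
#'
#' @param seed integer seed controlling decoy generation.
#' @param n_decoys number of dead-end decoy reactions (default 3; they can
#'   carry no flux and exist to exercise classification and gap-fill search).
#' @param glucose_uptake default glucose uptake limit (mmol/gDW/h) so the
#'   fresh model grows out of the box.
#' @param uptake_grid uptake rates tabulated in the manifest's analytic
#'   optima.
#' @return list with `model` (a `metabolic_model`) and `manifest` (seed,
#'   counts, analytic optima with per-source growth slopes).
#' @export
make_toy_model <- function(seed = 1L, n_decoys = 3L, glucose_uptake = 10,
                           uptake_grid = 1:10) {
  mets <- list()
  met <- function(id, name, formula, compartment) {
    mets[[length(mets) + 1L]] <<- data.frame(
      id = id, name = name, formula = formula, charge = NA_integer_,
      compartment = compartment, stringsAsFactors = FALSE)
  }
  met("glc_e", "D-glucose", "C6H12O6", "e")
  met("dis_e", "trehalose", "C12H22O11", "e")
  met("soh_e", "D-sorbitol", "C6H14O6", "e")
  met("nh4_e", "ammonium", "H3N", "e")
  met("h2o_e", "water", "H2O", "e")
  met("lac_e", "L-lactate", "C3H6O3", "e")
  met("ac_e", "acetate", "C2H4O2", "e")
  met("etoh_e", "ethanol", "C2H6O", "e")
  met("for_e", "formate", "CH2O2", "e")
  met("co2_e", "carbon dioxide", "CO2", "e")
  met("g6p_c", "glucose 6-phosphate", "C6H13O9P", "c")
  met("soh6p_c", "sorbitol 6-phosphate", "C6H15O9P", "c")
  met("pep_c", "phosphoenolpyruvate", "C3H5O6P", "c")
  met("pyr_c", "pyruvate", "C3H4O3", "c")
  met("atp_c", "ATP", "C10H16N5O13P3", "c")
  met("adp_c", "ADP", "C10H15N5O10P2", "c")
  met("pi_c", "phosphate", "H3O4P", "c")
  met("nad_c", "NAD+", "", "c")
  met("nadh_c", "NADH", "", "c")
  met("nadp_c", "NADP+", "", "c")
  met("nadph_c", "NADPH", "", "c")
  met("nh4_c", "ammonium", "H3N", "c")
  met("lac_c", "L-lactate", "C3H6O3", "c")
  met("ac_c", "acetate", "C2H4O2", "c")
  met("etoh_c", "ethanol", "C2H6O", "c")
  met("for_c", "formate", "CH2O2", "c")
  met("co2_c", "carbon dioxide", "CO2", "c")
  met("h2o_c", "water", "H2O", "c")
  met("biomass_c", "biomass", "", "c")
  for (a in AA_LETTERS)
    met(paste0("aa_", tolower(a), "_c"), paste0("amino acid (", a, ")"),
        AA_FORMULAS[[a]], "c")

  rxns <- list(); stoich <- list()
  rxn <- function(id, name, st, lb = 0, ub = 1000, gpr = "", subsystem = "") {
    rxns[[length(rxns) + 1L]] <<- data.frame(
      id = id, name = name, lower_bound = lb, upper_bound = ub,
      gene_rule = gpr, subsystem = subsystem, stringsAsFactors = FALSE)
    stoich[[id]] <<- st
  }
  # exchanges (uptake = negative flux)
  rxn("EX_glc_e", "glucose exchange", c(glc_e = -1), lb = -glucose_uptake)
  rxn("EX_dis_e", "trehalose exchange", c(dis_e = -1))
  rxn("EX_soh_e", "sorbitol exchange", c(soh_e = -1))
  rxn("EX_nh4_e", "ammonium exchange", c(nh4_e = -1), lb = -1000)
  rxn("EX_h2o_e", "water exchange", c(h2o_e = -1), lb = -1000)
  rxn("EX_lac_e", "lactate exchange", c(lac_e = -1))
  rxn("EX_ac_e", "acetate exchange", c(ac_e = -1))
  rxn("EX_etoh_e", "ethanol exchange", c(etoh_e = -1))
  rxn("EX_for_e", "formate exchange", c(for_e = -1))
  rxn("EX_co2_e", "CO2 exchange", c(co2_e = -1))
  # transport
  rxn("PTS_glc", "glucose PTS",
      c(glc_e = -1, pep_c = -1, g6p_c = 1, pyr_c = 1), gpr = "ptsG",
      subsystem = "PTS")
  rxn("PTS_dis", "trehalose PTS + phospho-hydrolysis",
      c(dis_e = -1, pep_c = -2, h2o_c = -1, g6p_c = 2, pyr_c = 2),
      gpr = "ptsT and treH", subsystem = "PTS")
  rxn("PTS_soh", "sorbitol PTS",
      c(soh_e = -1, pep_c = -1, soh6p_c = 1, pyr_c = 1), gpr = "ptsS",
      subsystem = "PTS")
  rxn("NH4t", "ammonium transport", c(nh4_e = -1, nh4_c = 1), lb = -1000,
      gpr = "amtB")
  rxn("H2Ot", "water transport", c(h2o_e = -1, h2o_c = 1), lb = -1000)
  rxn("LACt", "lactate export", c(lac_c = -1, lac_e = 1))
  rxn("ACt", "acetate export", c(ac_c = -1, ac_e = 1))
  rxn("ETOHt", "ethanol export", c(etoh_c = -1, etoh_e = 1))
  rxn("FORt", "formate export", c(for_c = -1, for_e = 1))
  rxn("CO2t", "CO2 export", c(co2_c = -1, co2_e = 1))
  # core metabolism
  rxn("SOHDH", "sorbitol-6-phosphate dehydrogenase (NADP)",
      c(soh6p_c = -1, nadp_c = -1, g6p_c = 1, nadph_c = 1), gpr = "srlD",
      subsystem = "alcohol sugar utilization")
  rxn("GLYC", "glycolysis (lumped, G6P to 2 PEP)",
      c(g6p_c = -1, adp_c = -1, pi_c = -2, nad_c = -2,
        pep_c = 2, atp_c = 1, nadh_c = 2, h2o_c = 2),
      gpr = "pfkA and gapA and eno1", subsystem = "glycolysis")
  rxn("PYK", "pyruvate kinase",
      c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1), gpr = "pykF",
      subsystem = "glycolysis")
  rxn("LDH", "lactate dehydrogenase",
      c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1), gpr = "ldh1",
      subsystem = "fermentation")
  rxn("ADH", "ethanol route (lumped, 2 NADH sink)",
      c(pyr_c = -1, nadh_c = -2, etoh_c = 1, co2_c = 1, nad_c = 2),
      gpr = "adhE", subsystem = "fermentation")
  rxn("PFL_ACK", "pyruvate formate-lyase + acetate kinase (lumped)",
      c(pyr_c = -1, adp_c = -1, pi_c = -1,
        ac_c = 1, for_c = 1, atp_c = 1), gpr = "pflB and ackA",
      subsystem = "fermentation")
  rxn("THD", "ATP-driven transhydrogenase",
      c(atp_c = -1, h2o_c = -1, nadh_c = -1, nadp_c = -1,
        adp_c = 1, pi_c = 1, nad_c = 1, nadph_c = 1), gpr = "pntAB",
      subsystem = "redox")
  for (a in AA_LETTERS) {
    al <- tolower(a)
    rxn(paste0("AA_SYN_", al), paste0("amino acid synthesis (", a, ")"),
        setNames(c(-1, -1, -2, -1, 1, 2, 1, 1),
                 c("pyr_c", "atp_c", "nadph_c", "nh4_c",
                   paste0("aa_", al, "_c"), "nadp_c", "adp_c", "pi_c")),
        gpr = paste0("aaS_", al), subsystem = "amino acid biosynthesis")
  }
  bm <- c(setNames(rep(-0.5, 20), paste0("aa_", tolower(AA_LETTERS), "_c")),
          atp_c = -20, h2o_c = -20, adp_c = 20, pi_c = 20, biomass_c = 1)
  rxn("BIOMASS", "biomass assembly", bm, subsystem = "biomass")
  rxn("DM_biomass", "biomass drain", c(biomass_c = -1), subsystem = "biomass")

  # decoy dead-end reactions: seeded randomness, zero attainable flux
  decoy_genes <- character(0)
  if (n_decoys > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    for (i in seq_len(n_decoys)) {
      a <- paste0("dcy", i, "a_c"); b <- paste0("dcy", i, "b_c")
      met(a, paste("decoy metabolite", i, "a"), "", "c")
      met(b, paste("decoy metabolite", i, "b"), "", "c")
      g <- paste0("dcy", i)
      decoy_genes <- c(decoy_genes, g)
      rxn(paste0("DCY", i), paste("decoy reaction", i),
          setNames(c(-sample(1:3, 1), sample(1:3, 1)), c(a, b)),
          gpr = g, subsystem = "decoy")
    }
  }

  metabolites <- do.call(rbind, mets)
  reactions <- do.call(rbind, rxns)
  genes <- unique(c(unlist(lapply(reactions$gene_rule, gpr_gene_ids))))
  model <- metabolic_model(
    id = "toy_ferment", metabolites = metabolites, reactions = reactions,
    stoichiometry = stoich, genes = genes, objective_id = "BIOMASS")

  slopes <- c(glucose = 0.06, trehalose = 0.12, sorbitol = 0.07)
  optima <- expand.grid(source = names(slopes), uptake = uptake_grid,
                        stringsAsFactors = FALSE)
  optima$growth <- slopes[optima$source] * optima$uptake
  st <- model_stats(model)
  manifest <- list(
    seed = seed, n_carbon_sources = 3L,
    counts = list(genes = st$n_genes, metabolites = st$n_metabolites,
                  reactions = st$n_reactions, internal = st$n_internal,
                  transport = st$n_transport, exchange = st$n_exchange),
    growth_slopes = slopes, analytic_optima = optima)
  list(model = model, manifest = manifest)
}

#' Carbon-source definitions matching the toy model
#'
#' @return list of `carbon_source` objects for glucose, trehalose, sorbitol.
#' @export
toy_carbon_sources <- function() {
  list(carbon_source("glucose", "EX_glc_e", 6, "monosaccharide"),
       carbon_source("trehalose", "EX_dis_e", 12, "disaccharide"),
       carbon_source("sorbitol", "EX_soh_e", 6, "sugar_alcohol"))
}

#' Knock essential reactions out of a model (gap-fill test harness)
#'
#' Removes `n_removed` reactions drawn (seeded) from the model's essential
#' internal reactions, excluding the objective, leaving a model with zero
#' growth whose repair set is known.
#'
#' @param model a growing `metabolic_model`.
#' @param n_removed how many essentials to delete.
#' @param seed sampling seed.
#' @return list with `model` (degraded) and `removed` (the deleted reaction
#'   rows + stoichiometries, reusable as a universal set).
#' @export
degrade_model <- function(model, n_removed, seed = 1L) {
  if (n_removed == 0) return(list(model = model, removed_ids = character(0)))
  internal <- model$reactions$id[
    vapply(model$reactions$id, classify_reaction, "", model = model) == "internal"]
  candidates <- setdiff(
    essential_reactions(model, reaction_ids = internal), model$objective_id)
  if (n_removed >= length(candidates))
    stop("n_removed (", n_removed, ") must be below the essential internal ",
         "reaction count (", length(candidates), ")")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  removed_ids <- sort(sample(candidates, n_removed))
  list(model = remove_reactions(model, removed_ids), removed_ids = removed_ids)
}

#' Build a universal candidate set from donor reactions plus decoys
#'
#' Packs the given reactions of a donor model (typically the ones
#' [degrade_model()] removed) together with seeded decoy candidates --
#' dead-end conversions that cannot restore growth -- into a
#' `universal_reaction_set` for gap-fill testing.
#'
#' @param donor model still containing the reactions named in `ids`.
#' @param ids donor reaction ids to include.
#' @param n_decoys decoy candidates to add.
#' @param seed decoy generation seed.
#' @return a `universal_reaction_set`.
#' @export
make_universal_set <- function(donor, ids, n_decoys = 5L, seed = 1L) {
  sel <- donor$reactions$id %in% ids
  reactions <- donor$reactions[sel, , drop = FALSE]
  reactions$gene_rule <- rep("", nrow(reactions))  # candidates carry no GPR
  stoich <- donor$stoichiometry[reactions$id]
  mets <- NULL
  if (n_decoys > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed + 1L)
    dm <- list()
    for (i in seq_len(n_decoys)) {
      a <- paste0("univ_dcy", i, "a_c"); b <- paste0("univ_dcy", i, "b_c")
      dm[[length(dm) + 1L]] <- data.frame(
        id = c(a, b), name = paste("universal decoy metabolite", i, c("a", "b")),
        formula = "", charge = NA_integer_, compartment = "c",
        stringsAsFactors = FALSE)
      rid <- paste0("U_DCY", i)
      reactions <- rbind(reactions, data.frame(
        id = rid, name = paste("universal decoy", i),
        lower_bound = 0, upper_bound = 1000, gene_rule = "", subsystem = "decoy",
        stringsAsFactors = FALSE))
      stoich[[rid]] <- setNames(c(-sample(1:2, 1), 1), c(a, b))
    }
    mets <- do.call(rbind, dm)
  }
  universal_reaction_set(reactions, stoich, metabolites = mets,
                         source_tag = "synthetic donor + decoys")
}

#' Simulate a dose-response curve from the 4PL model
#'
#' Doses follow the standard two-fold dilution series from `max_dose`;
#' inhibition responses sit exactly on the logistic curve plus optional
#' Gaussian noise. Deterministic per seed.
#'
#' @param bottom,top,ic50 true curve parameters (ic50 must lie inside the
#'   generated dose range).
#' @param n_doses number of doses (default 8).
#' @param noise_sd Gaussian noise SD in response-percent units (5 = "5%
#'   noise").
#' @param seed RNG seed.
#' @param max_dose top of the dilution series (default 50 µM).
#' @return a `dose_response_curve` (inhibition).
#' @export
make_dose_response <- function(bottom = 0, top = 100, ic50 = 15,
                               n_doses = 8L, noise_sd = 0, seed = 1L,
                               max_dose = 50) {
  doses <- max_dose / 2^(seq_len(n_doses) - 1)
  if (ic50 < min(doses) || ic50 > max(doses))
    stop("ic50 must lie within the generated dose range [",
         sprintf("%.3g", min(doses)), ", ", max_dose, "]")
  fit <- list(Bottom = bottom, Top = top, logIC50 = log10(ic50))
  resp <- four_pl(log10(doses), fit)
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    resp <- resp + stats::rnorm(length(doses), sd = noise_sd)
  }
  dose_response_curve(doses, resp, response_type = "inhibition")
}
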