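AA_LETTERS <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Average residue masses of the 20 canonical amino acids
#'
#' Residue (monomer minus water) masses in Da, average isotopic composition,
#' plus the mass of one water molecule. Used by [peptide_average_mw()];
#' average rather than monoisotopic masses match how expression titers are
#' reported (kDa-scale constructs quantified by ELISA).
#'
#' @return list with `masses` (named numeric, Da) and `water_mass` (Da).
#' @export
residue_mass_table <- function() {
  list(masses = c(
    A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0513, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326),
    water_mass = 18.0153)
}

#' Specify a peptide to be produced by the cell factory
#'
#' @param name token used to derive metabolite/reaction ids.
#' @param sequence one-letter amino-acid string (20 canonical letters).
#' @param his_tag_length histidines appended C-terminally (6 for a standard
#'   His6 detection tag; 0 for the bare peptide).
#' @param atp_per_residue ATP-equivalents hydrolyzed per residue polymerized.
#'   Default 4: two for amino-acid activation plus two GTP-equivalents for
#'   ribosomal elongation, the textbook cost of protein synthesis; tRNA
#'   charging and initiation/termination machinery are lumped into this
#'   number.
#' @param secreted should transport + exchange reactions be added so the
#'   peptide leaves the cell?
#' @return object of class `peptide_spec`.
#' @export
peptide_spec <- function(name, sequence, his_tag_length = 0L,
                         atp_per_residue = 4, secreted = TRUE) {
  if (nchar(sequence) == 0) stop("peptide sequence is empty")
  letters_ <- strsplit(sequence, "")[[1]]
  bad <- which(!letters_ %in% AA_LETTERS)
  if (length(bad) > 0)
    stop("non-canonical residue '", letters_[bad[1]], "' at position ", bad[1])
  stopifnot(his_tag_length >= 0, atp_per_residue >= 0)
  structure(list(name = name, sequence = sequence,
                 his_tag_length = as.integer(his_tag_length),
                 atp_per_residue = atp_per_residue, secreted = secreted),
            class = "peptide_spec")
}

#' Amino-acid composition of a peptide (tag included)
#'
#' @param spec a `peptide_spec`.
#' @return named integer vector, residue -> count, over residues present;
#'   the His-tag contributes `his_tag_length` histidines.
#' @export
aa_composition <- function(spec) {
  letters_ <- strsplit(spec$sequence, "")[[1]]
  counts <- table(factor(letters_, levels = AA_LETTERS))
  counts <- counts + setNames(
    as.integer(AA_LETTERS == "H") * spec$his_tag_length, AA_LETTERS)
  out <- c(counts[counts > 0])
  setNames(as.integer(out), names(out))
}

#' Average molecular weight of a peptide in kDa
#'
#' Sum of average residue masses over the composition (His-tag included) plus
#' one water, converted to kDa.
#'
#' @param spec a `peptide_spec`.
#' @param masses a residue mass table, see [residue_mass_table()].
#' @return molecular weight in kDa.
#' @export
peptide_average_mw <- function(spec, masses = residue_mass_table()) {
  comp <- aa_composition(spec)
  missing <- setdiff(names(comp), names(masses$masses))
  if (length(missing) > 0)
    stop("no residue mass for: ", paste(missing, collapse = ", "))
  (sum(masses$masses[names(comp)] * comp) + masses$water_mass) / 1000
}

#' Default metabolite id map for peptide pathway construction
#'
#' Maps the 20 one-letter residue codes and the energy/water cofactors to
#' cytoplasmic metabolite ids as used by the synthetic toy model
#' (`aa_<lower-case letter>_c`, `atp_c`, `adp_c`, `pi_c`, `h2o_c`). Supply
#' your own map to target other models.
#'
#' @return named character vector.
#' @export
default_precursor_map <- function() {
  c(setNames(paste0("aa_", tolower(AA_LETTERS), "_c"), AA_LETTERS),
    atp = "atp_c", adp = "adp_c", pi = "pi_c", h2o = "h2o_c")
}

#' Add a peptide biosynthesis pathway to a model
#'
#' Builds the "modified model": a lumped synthesis reaction polymerizing the
#' peptide from free cytoplasmic amino acids at an ATP cost of
#' `atp_per_residue` per residue, plus (for secreted peptides) a transport
#' reaction to the extracellular space and an exchange reaction. For a
#' peptide of n residues with ATP cost k per residue the synthesis reaction
#' is
#'
#'   sum(n_aa . aa_c) + k*n ATP + (k*n - (n-1)) H2O ->
#'       peptide_c + k*n ADP + k*n Pi
#'
#' (hydrolysis consumes k*n waters while peptide-bond condensation releases
#' n-1). When the model's amino-acid metabolites carry formulas, the peptide
#' metabolite receives the composition-derived formula (sum of residues minus
#' n-1 waters) so the synthesis reaction passes [check_mass_balance()].
#'
#' @param model a `metabolic_model` containing cytoplasmic amino-acid, ATP,
#'   ADP, Pi and H2O metabolites.
#' @param spec a `peptide_spec`.
#' @param id_map named map from residue letters and `atp`/`adp`/`pi`/`h2o` to
#'   metabolite ids, see [default_precursor_map()].
#' @return the augmented model (2 metabolites and 3 reactions added for a
#'   secreted peptide; 1 and 1 otherwise).
#' @export
build_peptide_pathway <- function(model, spec, id_map = default_precursor_map()) {
  comp <- aa_composition(spec)
  need <- c(names(comp), "atp", "adp", "pi", "h2o")
  unmapped <- setdiff(need, names(id_map))
  if (length(unmapped) > 0)
    stop("id_map lacks entries for: ", paste(unmapped, collapse = ", "))
  absent <- setdiff(unname(id_map[need]), model$metabolites$id)
  if (length(absent) > 0)
    stop("precursor metabolite(s) missing from model: ",
         paste(absent, collapse = ", "))

  n <- sum(comp)
  k <- spec$atp_per_residue
  pep_c <- paste0(spec$name, "_c")
  pep_e <- paste0(spec$name, "_e")

  # composition-derived formula, if residue formulas are available
  aa_formulas <- model$metabolites$formula[match(id_map[names(comp)],
                                                 model$metabolites$id)]
  pep_formula <- ""
  if (all(!is.na(aa_formulas) & aa_formulas != "")) {
    tot <- list()
    for (i in seq_along(comp)) {
      f <- parse_formula(aa_formulas[i])
      for (el in names(f)) tot[[el]] <- (tot[[el]] %||% 0) + comp[i] * f[[el]]
    }
    tot[["H"]] <- tot[["H"]] - 2 * (n - 1)
    tot[["O"]] <- tot[["O"]] - (n - 1)
    els <- sort(names(tot))
    pep_formula <- paste0(els, ifelse(unlist(tot[els]) == 1, "",
                                      unlist(tot[els])), collapse = "")
  }

  st_syn <- c(setNames(-as.numeric(comp), unname(id_map[names(comp)])),
              setNames(c(-k * n, -(k * n - (n - 1)), 1, k * n, k * n),
                       c(id_map[["atp"]], id_map[["h2o"]], pep_c,
                         id_map[["adp"]], id_map[["pi"]])))
  st_syn <- st_syn[st_syn != 0]

  mets <- data.frame(id = pep_c, name = paste(spec$name, "peptide"),
                     formula = pep_formula, charge = NA_integer_,
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- data.frame(id = paste0("SYN_", spec$name),
                     name = paste(spec$name, "synthesis"),
                     lower_bound = 0, upper_bound = 1000, gene_rule = "",
                     subsystem = "peptide production",
                     stringsAsFactors = FALSE)
  stoich <- setNames(list(st_syn), rxns$id)

  if (spec$secreted) {
    mets <- rbind(mets, data.frame(
      id = pep_e, name = paste(spec$name, "peptide (extracellular)"),
      formula = pep_formula, charge = NA_integer_, compartment = "e",
      stringsAsFactors = FALSE))
    tr <- data.frame(id = paste0("T_", spec$name),
                     name = paste(spec$name, "secretion"),
                     lower_bound = 0, upper_bound = 1000, gene_rule = "",
                     subsystem = "peptide production", stringsAsFactors = FALSE)
    ex <- data.frame(id = paste0("EX_", spec$name, "_e"),
                     name = paste(spec$name, "exchange"),
                     lower_bound = 0, upper_bound = 1000, gene_rule = "",
                     subsystem = "peptide production", stringsAsFactors = FALSE)
    rxns <- rbind(rxns, tr, ex)
    stoich[[tr$id]] <- setNames(c(-1, 1), c(pep_c, pep_e))
    stoich[[ex$id]] <- setNames(-1, pep_e)
  }
  add_reactions(model, rxns, stoich, metabolites = mets)
}

#' Exchange reaction id created for a secreted peptide
#' @param spec a `peptide_spec`.
#' @return the exchange reaction id used by [build_peptide_pathway()].
#' @export
peptide_exchange_id <- function(spec) paste0("EX_", spec$name, "_e")

#' The LL-37 cathelicidin peptide specification
#'
#' Human cathelicidin-derived 37-residue peptide, the package's flagship
#' product, optionally with the C-terminal His6 detection tag used for
#' ELISA quantification of the secreted construct.
#'
#' @param his_tag with the His6 tag (default `TRUE`)?
#' @return a `peptide_spec`.
#' @export
ll37_spec <- function(his_tag = TRUE) {
  peptide_spec("ll37", "LLGDFFRKSKEKIGKEFKRIVQRIKDFLRNLVPRTES",
               his_tag_length = if (his_tag) 6L else 0L)
}
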