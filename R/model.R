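#' Construct a compartmentalized stoichiometric model
#'
#' The central container of the package: a metabolic network with metabolites
#' assigned to compartments, reactions with flux bounds and optional
#' gene-protein-reaction (GPR) rules, and a designated objective reaction
#' (typically biomass). Flux units throughout are mmol/gDW/h, with the
#' standard constraint-based sign convention on exchange reactions: negative
#' flux is uptake, positive flux is secretion.
#'
#' @param id model identifier.
#' @param metabolites data frame with columns `id`, `name`, `formula`,
#'   `charge`, `compartment`. `formula` may be `""` (unknown); `charge` may be
#'   `NA`.
#' @param reactions data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gene_rule`, `subsystem`.
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of signed coefficients over metabolite ids (negative =
#'   consumed).
#' @param genes character vector of gene ids.
#' @param objective_id id of the objective reaction.
#' @param compartments character vector of compartment tokens (default
#'   cytoplasm `"c"` and extracellular `"e"`).
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            genes = character(), objective_id,
                            compartments = c("c", "e")) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (col in c("name", "formula", "compartment")) {
    if (is.null(metabolites[[col]])) metabolites[[col]] <- ""
  }
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  if (is.null(reactions$name)) reactions$name <- ""
  if (is.null(reactions$gene_rule)) reactions$gene_rule <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, genes = genes,
         objective_id = objective_id, compartments = compartments),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, compartment membership, bound ordering, non-empty
#' stoichiometries, resolvable metabolite references, the existence of the
#' objective reaction and that every gene referenced by a GPR rule is in the
#' model's gene set. Called by every constructor and reader; errors name the
#' offending element.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  met <- model$metabolites; rxn <- model$reactions
  if (anyDuplicated(met$id)) stop("duplicated metabolite id: ",
                                  met$id[duplicated(met$id)][1])
  if (anyDuplicated(rxn$id)) stop("duplicated reaction id: ",
                                  rxn$id[duplicated(rxn$id)][1])
  bad_comp <- setdiff(unique(met$compartment), model$compartments)
  if (length(bad_comp) > 0) stop("unknown compartment '", bad_comp[1],
                                 "' (declared: ",
                                 paste(model$compartments, collapse = ", "), ")")
  if (any(rxn$lower_bound > rxn$upper_bound))
    stop("lower_bound > upper_bound for reaction ",
         rxn$id[which(rxn$lower_bound > rxn$upper_bound)[1]])
  if (!setequal(names(model$stoichiometry), rxn$id))
    stop("stoichiometry entries do not match reaction ids")
  for (rid in rxn$id) {
    st <- model$stoichiometry[[rid]]
    if (length(st) == 0) stop("empty stoichiometry for reaction ", rid)
    missing_met <- setdiff(names(st), met$id)
    if (length(missing_met) > 0)
      stop("reaction ", rid, " references undeclared metabolite ",
           missing_met[1])
  }
  if (!model$objective_id %in% rxn$id)
    stop("objective reaction '", model$objective_id, "' not in model")
  rule_genes <- unique(unlist(lapply(rxn$gene_rule, gpr_gene_ids)))
  extra <- setdiff(rule_genes, model$genes)
  if (length(extra) > 0)
    stop("gene '", extra[1], "' used in a GPR rule but absent from gene set")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  st <- model_stats(x)
  cat("Metabolic model '", x$id, "'\n", sep = "")
  cat("  metabolites: ", st$n_metabolites,
      "  reactions: ", st$n_reactions,
      " (internal ", st$n_internal, ", transport ", st$n_transport,
      ", exchange ", st$n_exchange, ")\n", sep = "")
  cat("  genes: ", st$n_genes, "   objective: ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix S (metabolites x reactions), dimnames set.
#' @export
stoichiometric_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    st <- model$stoichiometry[[rxns[j]]]
    S[names(st), j] <- st
  }
  S
}

#' Classify a reaction as internal, transport or exchange
#'
#' Exchange: a one-sided boundary over a single extracellular metabolite.
#' Transport: participants span at least two compartments. Internal:
#' everything else. The classification is invariant under scaling of the
#' stoichiometry.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to classify.
#' @return one of `"internal"`, `"transport"`, `"exchange"`.
#' @export
classify_reaction <- function(model, reaction_id) {
  st <- model$stoichiometry[[reaction_id]]
  if (is.null(st)) stop("unknown reaction id: ", reaction_id)
  comps <- model$metabolites$compartment[match(names(st), model$metabolites$id)]
  if (length(st) == 1 && comps == "e") return("exchange")
  if (length(unique(comps)) >= 2) return("transport")
  "internal"
}

#' Model size statistics and genome coverage
#'
#' Counts genes, metabolites and reactions, splits reactions into
#' internal/transport/exchange via [classify_reaction()], and, when the
#' annotated genome size is supplied, reports the percentage of genome genes
#' included in the model.
#'
#' @param model a `metabolic_model`.
#' @param genome_gene_count total annotated genes in the genome, or `NULL`.
#' @return object of class `model_stats`: a list with counts and (optionally)
#'   `included_gene_fraction` in percent.
#' @export
model_stats <- function(model, genome_gene_count = NULL) {
  classes <- vapply(model$reactions$id, classify_reaction,
                    character(1), model = model)
  out <- list(
    n_genes = length(model$genes),
    n_metabolites = nrow(model$metabolites),
    n_reactions = nrow(model$reactions),
    n_internal = sum(classes == "internal"),
    n_transport = sum(classes == "transport"),
    n_exchange = sum(classes == "exchange"),
    included_gene_fraction = NA_real_)
  if (!is.null(genome_gene_count)) {
    if (genome_gene_count <= 0) stop("genome_gene_count must be positive")
    out$included_gene_fraction <- 100 * out$n_genes / genome_gene_count
  }
  class(out) <- "model_stats"
  out
}

#' @export
print.model_stats <- function(x, ...) {
  cat("genes:", x$n_genes, " metabolites:", x$n_metabolites,
      " reactions:", x$n_reactions, "\n")
  cat("  internal:", x$n_internal, " transport:", x$n_transport,
      " exchange:", x$n_exchange, "\n")
  if (!is.na(x$included_gene_fraction))
    cat("  genome gene inclusion:",
        sprintf("%.2f%%", x$included_gene_fraction), "\n")
  invisible(x)
}

#' Parse an elemental formula string
#'
#' @param formula e.g. `"C6H12O6"`; `""` parses to an empty vector.
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || formula == "") return(setNames(numeric(0), character(0)))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  cnt <- as.numeric(sub("^[A-Za-z]+", "", toks))
  cnt[is.na(cnt)] <- 1
  tapply(cnt, el, sum)
}

#' Elemental mass-balance report
#'
#' Quality gate for curated reactions: for every non-exchange reaction whose
#' participants all carry formulas, the signed per-element sum is computed;
#' any non-zero entry is an imbalance. Reactions touching a metabolite with
#' no formula (common for redox cofactors and pseudo-metabolites in draft
#' reconstructions) are skipped and listed as unchecked. Report-only: never
#' errors.
#'
#' @param model a `metabolic_model`.
#' @param tol absolute tolerance on per-element sums.
#' @return data frame with columns `reaction_id`, `element`, `imbalance`
#'   (empty when all checked reactions balance); attribute `"unchecked"`
#'   holds the ids of skipped reactions.
#' @export
check_mass_balance <- function(model, tol = 1e-6) {
  res <- list()
  unchecked <- character(0)
  formulas <- setNames(model$metabolites$formula, model$metabolites$id)
  for (rid in model$reactions$id) {
    if (classify_reaction(model, rid) == "exchange") next
    st <- model$stoichiometry[[rid]]
    fs <- formulas[names(st)]
    if (any(is.na(fs) | fs == "")) {
      unchecked <- c(unchecked, rid)
      next
    }
    tot <- list()
    for (k in seq_along(st)) {
      comp <- parse_formula(fs[k])
      for (el in names(comp))
        tot[[el]] <- (tot[[el]] %||% 0) + st[k] * comp[[el]]
    }
    for (el in names(tot)) {
      if (abs(tot[[el]]) > tol)
        res[[length(res) + 1L]] <- data.frame(
          reaction_id = rid, element = el, imbalance = tot[[el]],
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(reaction_id = character(0), element = character(0),
               imbalance = numeric(0), stringsAsFactors = FALSE)
  attr(out, "unchecked") <- unchecked
  out
}

#' Add reactions (and any new metabolites) to a model
#'
#' @param model a `metabolic_model`.
#' @param reactions data frame in the same layout as `model$reactions`.
#' @param stoichiometry named list of stoichiometries for the new reactions.
#' @param metabolites optional data frame of metabolites to add first.
#' @param genes optional gene ids to add.
#' @return the extended, validated model.
#' @export
add_reactions <- function(model, reactions, stoichiometry,
                          metabolites = NULL, genes = character()) {
  if (!is.null(metabolites)) {
    newm <- metabolites[!metabolites$id %in% model$metabolites$id, , drop = FALSE]
    for (col in c("name", "formula")) if (is.null(newm[[col]])) newm[[col]] <- ""
    if (is.null(newm$charge)) newm$charge <- NA_integer_
    model$metabolites <- rbind(model$metabolites,
                               newm[, colnames(model$metabolites)])
  }
  if (any(reactions$id %in% model$reactions$id))
    stop("reaction id already in model: ",
         intersect(reactions$id, model$reactions$id)[1])
  for (col in c("name", "gene_rule", "subsystem"))
    if (is.null(reactions[[col]])) reactions[[col]] <- ""
  model$reactions <- rbind(model$reactions,
                           reactions[, colnames(model$reactions)])
  model$stoichiometry <- c(model$stoichiometry, stoichiometry)
  model$genes <- union(model$genes, genes)
  validate_model(model)
  model
}

#' Remove reactions from a model
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids ids to drop (must not include the objective).
#' @return the reduced model.
#' @export
remove_reactions <- function(model, reaction_ids) {
  missing <- setdiff(reaction_ids, model$reactions$id)
  if (length(missing) > 0) stop("unknown reaction id: ", missing[1])
  if (model$objective_id %in% reaction_ids)
    stop("cannot remove the objective reaction")
  keep <- !model$reactions$id %in% reaction_ids
  model$reactions <- model$reactions[keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  model
}

# ---- GPR rule handling ----------------------------------------------------

# tokenize a boolean gene rule: ids, "and", "or", parentheses
gpr_tokens <- function(rule) {
  if (is.na(rule) || rule == "") return(character(0))
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", rule)[[1]]
  regmatches(rule, list(m))[[1]]
}

# recursive-descent parse into nested list AST: list(op="and"/"or", args=...)
# or a plain gene id string
gpr_parse <- function(rule) {
  toks <- gpr_tokens(rule)
  if (length(toks) == 0) return(NULL)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance(); args <- c(args, list(parse_and()))
    }
    if (length(args) == 1) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_primary())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance(); args <- c(args, list(parse_primary()))
    }
    if (length(args) == 1) args[[1]] else list(op = "and", args = args)
  }
  parse_primary <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed gene rule: ", rule)
    if (t == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in rule: ", rule)
      advance()
      node
    } else if (tolower(t) %in% c("and", "or", ")")) {
      stop("malformed gene rule: ", rule)
    } else {
      advance()
    }
  }
  out <- parse_or()
  if (pos <= length(toks)) stop("trailing tokens in gene rule: ", rule)
  out
}

# canonical string form of a GPR AST ("and" children of "or" are parenthesized)
gpr_deparse <- function(node) {
  if (is.null(node)) return("")
  if (is.character(node)) return(node)
  parts <- vapply(node$args, function(a) {
    s <- gpr_deparse(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", node$op, " "))
}

# gene ids appearing in a rule string
gpr_gene_ids <- function(rule) {
  toks <- gpr_tokens(rule)
  toks[!tolower(toks) %in% c("and", "or", "(", ")")]
}
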