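#' Define a universal (candidate) reaction set for gap-filling
#'
#' @param reactions data frame in the layout of `model$reactions`.
#' @param stoichiometry named list of stoichiometries, one per candidate.
#' @param metabolites optional data frame of metabolites the candidates need
#'   beyond the target model's.
#' @param source_tag free-text provenance label.
#' @return object of class `universal_reaction_set`.
#' @export
universal_reaction_set <- function(reactions, stoichiometry,
                                   metabolites = NULL, source_tag = "") {
  stopifnot(setequal(names(stoichiometry), reactions$id))
  structure(list(reactions = reactions, stoichiometry = stoichiometry,
                 metabolites = metabolites, source_tag = source_tag),
            class = "universal_reaction_set")
}

augment_with <- function(model, universal, ids) {
  if (length(ids) == 0) return(model)
  sel <- universal$reactions$id %in% ids
  add_reactions(model,
                reactions = universal$reactions[sel, , drop = FALSE],
                stoichiometry = universal$stoichiometry[ids],
                metabolites = universal$metabolites)
}

#' Find a minimal reaction set restoring flux to the objective
#'
#' Adds candidate reactions from a universal set to a model whose objective
#' cannot reach `min_objective`, searching for the smallest augmentation that
#' does. For universal sets of at most `exact_below` candidates the search
#' enumerates subsets in order of cardinality (then lexicographically over
#' id-sorted candidates), so the returned set is provably cardinality-minimal.
#' Larger sets use an add-all-then-prune greedy pass: candidates are deleted
#' one at a time in id order and a deletion is kept whenever the objective
#' stays above threshold; the result is then subset-minimal but flagged
#' `minimal = FALSE` since a smaller set may exist. Exchange reactions are
#' never created implicitly: any boundary reaction a fill needs must be a
#' candidate itself.
#'
#' @param model a `metabolic_model` whose objective is below `min_objective`.
#' @param universal a `universal_reaction_set`; candidate ids must be disjoint
#'   from the model's reaction ids.
#' @param objective_id reaction to restore (default: model objective).
#' @param min_objective flux the augmented model must reach (default 1e-3,
#'   distinguishing genuine growth from numerical residue).
#' @param exact_below exhaustive-search size limit (default 12).
#' @return object of class `gapfill_result`: `added_reaction_ids`,
#'   `achieved_objective`, `minimal`.
#' @export
find_gapfill_set <- function(model, universal,
                             objective_id = model$objective_id,
                             min_objective = 1e-3, exact_below = 12L) {
  overlap <- intersect(universal$reactions$id, model$reactions$id)
  if (length(overlap) > 0)
    stop("universal set overlaps model reactions: ", overlap[1])
  obj_of <- function(ids) {
    sol <- solve_fba(augment_with(model, universal, ids), objective_id)
    if (sol$status == "optimal") sol$objective_value else -Inf
  }
  base <- obj_of(character(0))
  if (base >= min_objective)
    return(structure(list(added_reaction_ids = character(0),
                          achieved_objective = base, minimal = TRUE),
                     class = "gapfill_result"))
  cand <- sort(universal$reactions$id)
  full <- obj_of(cand)
  if (full < min_objective)
    stop("unfillable: even the full universal set does not reach ",
         min_objective)
  if (length(cand) <= exact_below) {
    for (k in seq_along(cand)) {
      for (pick in utils::combn(cand, k, simplify = FALSE)) {
        val <- obj_of(pick)
        if (val >= min_objective)
          return(structure(list(added_reaction_ids = pick,
                                achieved_objective = val, minimal = TRUE),
                           class = "gapfill_result"))
      }
    }
    stop("unfillable: no subset reaches ", min_objective)  # unreachable: full set passed
  }
  # greedy prune from the full set, id order
  keep <- cand
  for (rid in cand) {
    trial <- setdiff(keep, rid)
    if (obj_of(trial) >= min_objective) keep <- trial
  }
  structure(list(added_reaction_ids = keep,
                 achieved_objective = obj_of(keep), minimal = FALSE),
            class = "gapfill_result")
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat("gap-fill:", length(x$added_reaction_ids), "reaction(s) added",
      if (x$minimal) "(cardinality-minimal)" else "(subset-minimal)", "\n")
  if (length(x$added_reaction_ids) > 0)
    cat(" ", paste(x$added_reaction_ids, collapse = ", "), "\n")
  cat("  achieved objective:", format(x$achieved_objective, digits = 8), "\n")
  invisible(x)
}
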