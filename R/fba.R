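#' Define a growth-medium condition
#'
#' A medium is a set of uptake limits on exchange reactions plus a set of
#' exchanges closed to uptake entirely. Limits are magnitudes in
#' mmol/gDW/h; the sign convention (uptake = negative exchange flux) is
#' applied by [apply_medium()].
#'
#' @param name medium label.
#' @param uptake_limits named numeric vector: exchange reaction id -> maximum
#'   uptake rate (non-negative).
#' @param closed_exchanges exchange ids forced to zero uptake.
#' @return object of class `medium_condition`.
#' @export
medium_condition <- function(name, uptake_limits = numeric(0),
                             closed_exchanges = character(0)) {
  stopifnot(all(uptake_limits >= 0))
  structure(list(name = name, uptake_limits = uptake_limits,
                 closed_exchanges = closed_exchanges),
            class = "medium_condition")
}

#' Apply a medium condition to a model
#'
#' Returns a copy of the model in which every exchange in
#' `closed_exchanges` has its lower bound raised to 0 (no uptake) and every
#' exchange with an uptake limit gets lower bound `-limit`. Upper
#' (secretion) bounds are untouched, as are all non-exchange reactions.
#'
#' @param model a `metabolic_model`.
#' @param medium a `medium_condition`.
#' @return the constrained model.
#' @export
apply_medium <- function(model, medium) {
  ids <- c(names(medium$uptake_limits), medium$closed_exchanges)
  for (rid in ids) {
    if (!rid %in% model$reactions$id) stop("unknown reaction id: ", rid)
    if (classify_reaction(model, rid) != "exchange")
      stop("'", rid, "' is not an exchange reaction")
  }
  i <- match(medium$closed_exchanges, model$reactions$id)
  model$reactions$lower_bound[i] <- 0
  i <- match(names(medium$uptake_limits), model$reactions$id)
  model$reactions$lower_bound[i] <- -unname(medium$uptake_limits)
  model
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) the flux of a target reaction subject to
#' steady-state mass balance `S v = 0` and the model's flux bounds — the
#' standard FBA linear program. Only the objective value and constraint
#' satisfaction are contractual: the flux vector of a degenerate optimum is
#' one of possibly many alternative optima (the solver is deterministic, so
#' repeated calls return the same vertex).
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction to optimize; defaults to the model objective.
#' @param direction `"max"` or `"min"`.
#' @return object of class `flux_solution`: list with `status`
#'   (`"optimal"`, `"infeasible"`, `"unbounded"`), `objective_value` and
#'   `fluxes` (named vector over reaction ids).
#' @export
solve_fba <- function(model, objective_id = model$objective_id,
                      direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (!objective_id %in% model$reactions$id)
    stop("unknown objective reaction: ", objective_id)
  S <- stoichiometric_matrix(model)
  n <- ncol(S)
  obj <- as.numeric(colnames(S) == objective_id)
  res <- solve_lp(S, rep(0, nrow(S)), obj,
                  lb = model$reactions$lower_bound,
                  ub = model$reactions$upper_bound,
                  maximize = direction == "max")
  structure(list(
    status = res$status,
    objective_value = if (res$status == "optimal") res$objective else NA_real_,
    fluxes = if (res$status == "optimal") setNames(res$x, colnames(S)) else
      setNames(rep(NA_real_, n), colnames(S))),
    class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution: status =", x$status)
  if (x$status == "optimal")
    cat(", objective =", format(x$objective_value, digits = 8))
  cat("\n")
  invisible(x)
}

#' Identify essential reactions by single-knockout scan
#'
#' A reaction is essential when constraining its flux to zero drops the
#' re-optimized objective below `growth_fraction_threshold` times the
#' wild-type optimum. The default threshold of 1% separates numerically-zero
#' growth from merely reduced growth.
#'
#' @param model a `metabolic_model` with a feasible, positive objective.
#' @param growth_fraction_threshold fraction in (0, 1).
#' @param reaction_ids subset of reactions to screen (default: all).
#' @return character vector of essential reaction ids.
#' @export
essential_reactions <- function(model, growth_fraction_threshold = 0.01,
                                reaction_ids = model$reactions$id) {
  stopifnot(growth_fraction_threshold > 0, growth_fraction_threshold < 1)
  wt <- solve_fba(model)
  if (wt$status != "optimal" || wt$objective_value <= 1e-9)
    stop("wild-type growth is zero or infeasible; essentiality is undefined")
  cutoff <- growth_fraction_threshold * wt$objective_value
  essential <- character(0)
  for (rid in reaction_ids) {
    ko <- model
    i <- match(rid, model$reactions$id)
    ko$reactions$lower_bound[i] <- 0
    ko$reactions$upper_bound[i] <- 0
    sol <- solve_fba(ko)
    if (sol$status != "optimal" || sol$objective_value < cutoff)
      essential <- c(essential, rid)
  }
  essential
}
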