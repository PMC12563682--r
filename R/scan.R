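#' Define a carbon source for scanning
#'
#' @param name display name.
#' @param exchange_id exchange reaction feeding this source.
#' @param carbons_per_mole carbon atoms per molecule.
#' @param category one of oligosaccharide, monosaccharide, disaccharide,
#'   sugar_alcohol, other.
#' @return object of class `carbon_source`.
#' @export
carbon_source <- function(name, exchange_id, carbons_per_mole,
                          category = c("monosaccharide", "disaccharide",
                                       "oligosaccharide", "sugar_alcohol",
                                       "other")) {
  category <- match.arg(category)
  stopifnot(carbons_per_mole > 0)
  structure(list(name = name, exchange_id = exchange_id,
                 carbons_per_mole = as.integer(carbons_per_mole),
                 category = category),
            class = "carbon_source")
}

#' Growth / peptide-production scan over carbon sources and uptake rates
#'
#' For every (source, rate) cell the model is put on a minimal medium in
#' which all scanned carbon exchanges are closed except the focal source,
#' limited to the given uptake rate, and biomass is maximized. When a
#' peptide exchange id is given, a second stage fixes biomass at
#' `growth_fraction` of its cell-wise maximum and maximizes peptide export
#' (two-stage optimization; the trade-off fraction is recorded in
#' `strategy`). Rates are molar by default; with `normalize_carbon = TRUE`
#' each rate r is interpreted as r hexose-equivalents, i.e. the molar limit
#' becomes `r * 6 / carbons_per_mole`, for comparisons at equal carbon
#' delivery.
#'
#' @param model a `metabolic_model` (typically peptide-augmented).
#' @param sources list of `carbon_source` objects.
#' @param uptake_rates positive numeric vector (mmol/gDW/h, or
#'   hexose-equivalents under `normalize_carbon`).
#' @param peptide_exchange_id exchange reaction of the secreted product, or
#'   `NULL` for a growth-only scan.
#' @param growth_fraction biomass fraction held during peptide maximization
#'   (default 0.1).
#' @param normalize_carbon compare sources at equal carbon uptake instead of
#'   equal molar uptake.
#' @return object of class `scan_result`: `growth` and `peptide_flux`
#'   matrices (source x rate), the axes, and `strategy`.
#' @export
carbon_scan <- function(model, sources, uptake_rates,
                        peptide_exchange_id = NULL, growth_fraction = 0.1,
                        normalize_carbon = FALSE) {
  stopifnot(length(sources) > 0, all(uptake_rates >= 0))
  stopifnot(growth_fraction >= 0, growth_fraction <= 1)
  src_names <- vapply(sources, `[[`, "", "name")
  growth <- matrix(NA_real_, length(sources), length(uptake_rates),
                   dimnames = list(src_names, as.character(uptake_rates)))
  pep <- growth
  scan_exchanges <- vapply(sources, `[[`, "", "exchange_id")
  for (i in seq_along(sources)) {
    src <- sources[[i]]
    if (!src$exchange_id %in% model$reactions$id) {
      warning("exchange '", src$exchange_id, "' absent from model; ",
              "NaN row for source '", src$name, "'")
      growth[i, ] <- NaN; pep[i, ] <- NaN
      next
    }
    for (j in seq_along(uptake_rates)) {
      rate <- uptake_rates[j]
      if (normalize_carbon) rate <- rate * 6 / src$carbons_per_mole
      present <- intersect(setdiff(scan_exchanges, src$exchange_id),
                           model$reactions$id)
      med <- medium_condition(
        name = paste0(src$name, "_", rate),
        uptake_limits = setNames(rate, src$exchange_id),
        closed_exchanges = present)
      m <- apply_medium(model, med)
      sol <- solve_fba(m)
      growth[i, j] <- if (sol$status == "optimal") sol$objective_value else 0
      if (!is.null(peptide_exchange_id)) {
        idx <- match(model$objective_id, m$reactions$id)
        m$reactions$lower_bound[idx] <- growth_fraction * growth[i, j]
        psol <- solve_fba(m, objective_id = peptide_exchange_id)
        pep[i, j] <- if (psol$status == "optimal") psol$objective_value else 0
      }
    }
  }
  structure(list(
    sources = sources, uptake_rates = uptake_rates, growth = growth,
    peptide_flux = if (is.null(peptide_exchange_id)) NULL else pep,
    strategy = if (is.null(peptide_exchange_id)) "growth-only" else
      sprintf("two-stage: biomass fixed at %.2f of maximum, peptide export maximized",
              growth_fraction),
    normalize_carbon = normalize_carbon),
    class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("carbon scan (", x$strategy, ")\n", sep = "")
  cat("growth (h^-1):\n")
  print(round(x$growth, 4))
  if (!is.null(x$peptide_flux)) {
    cat("peptide flux (mmol/gDW/h):\n")
    print(round(x$peptide_flux, 4))
  }
  invisible(x)
}

#' Biomass yield on a substrate
#'
#' `(X - X0) / S`: the gain in biomass flux of the peptide-producing model
#' over the intermediate (pre-peptide) model, per unit substrate uptake.
#' Reported in the flux-ratio units of the defining arithmetic (labelled
#' gDW/mmol).
#'
#' @param X biomass flux of the modified (peptide) model.
#' @param X0 biomass flux of the intermediate model (0 when no intermediate
#'   model is available).
#' @param S substrate uptake flux (mmol/gDW/h), must be positive.
#' @return yield.
#' @export
biomass_yield <- function(X, X0, S) {
  if (S <= 0) stop("substrate flux S must be positive")
  (X - X0) / S
}

#' Peptide production yield on a substrate
#'
#' `P / S`: peptide synthesis flux per unit substrate uptake.
#'
#' @param P peptide synthesis flux (mmol/gDW/h).
#' @param S substrate uptake flux (mmol/gDW/h), must be positive.
#' @return yield.
#' @export
peptide_yield <- function(P, S) {
  if (S <= 0) stop("substrate flux S must be positive")
  P / S
}

#' Rank carbon sources by best growth or peptide production
#'
#' Sources are ordered by the row maximum of the chosen scan matrix,
#' descending; ties break alphabetically by source name.
#'
#' @param result a `scan_result`.
#' @param by `"growth"` or `"peptide"`.
#' @return data frame with columns `source`, `category`, `best`.
#' @export
rank_sources <- function(result, by = c("growth", "peptide")) {
  by <- match.arg(by)
  mat <- if (by == "growth") result$growth else result$peptide_flux
  if (is.null(mat)) stop("scan has no peptide matrix; run with a peptide exchange")
  best <- apply(mat, 1, max)
  ord <- order(-best, rownames(mat))
  data.frame(
    source = rownames(mat)[ord],
    category = vapply(result$sources, `[[`, "", "category")[ord],
    best = unname(best[ord]),
    stringsAsFactors = FALSE)
}
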