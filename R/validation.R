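#' Convert a mass titer to a molar concentration
#'
#' `1000 * titer / MW`: g/L divided by kDa gives µM (a 5.38 kDa peptide at
#' 0.16 g/L is 29.74 µM).
#'
#' @param titer_mass product titer in g/L.
#' @param mw_kDa molecular weight in kDa (> 0).
#' @return concentration in µM.
#' @export
concentration_uM <- function(titer_mass, mw_kDa) {
  if (mw_kDa <= 0) stop("molecular weight must be positive")
  1000 * titer_mass / mw_kDa
}

#' Convert a specific production flux to a mass titer
#'
#' Bridges FBA output to culture-scale units:
#' `v_p [mmol/gDW/h] * biomass [gDW/L] * duration [h] * MW [g/mmol = kDa]`
#' gives g/L.
#'
#' @param v_p specific production flux (mmol/gDW/h).
#' @param biomass culture biomass density (gDW/L).
#' @param duration production time (h).
#' @param mw_kDa molecular weight (kDa; numerically g/mmol).
#' @return titer in g/L.
#' @export
mass_titer <- function(v_p, biomass, duration, mw_kDa) {
  stopifnot(v_p >= 0, biomass >= 0, duration >= 0, mw_kDa >= 0)
  v_p * biomass * duration * mw_kDa
}

#' Prediction accuracy as a symmetric min/max ratio
#'
#' `100 * min(predicted, observed) / max(predicted, observed)`: 100% iff the
#' two agree, decreasing as their ratio departs from 1, symmetric in its
#' arguments.
#'
#' @param predicted,observed positive values in the same unit.
#' @return accuracy in percent (0-100].
#' @export
accuracy_percent <- function(predicted, observed) {
  if (predicted <= 0 || observed <= 0)
    stop("accuracy requires positive predicted and observed values")
  100 * min(predicted, observed) / max(predicted, observed)
}

#' Build a predicted-vs-observed validation record
#'
#' @param quantity `"biomass"` or `"peptide_concentration"`.
#' @param predicted,observed values; must share one unit.
#' @param unit unit of the predicted value.
#' @param observed_unit unit of the observed value; defaults to `unit` and
#'   must equal it (comparing values in different units is refused).
#' @return object of class `validation_record` (one-row data frame with the
#'   accuracy filled in).
#' @export
validation_record <- function(quantity = c("biomass", "peptide_concentration"),
                              predicted, observed, unit,
                              observed_unit = unit) {
  quantity <- match.arg(quantity)
  if (!identical(unit, observed_unit))
    stop("unit mismatch: predicted in '", unit, "' but observed in '",
         observed_unit, "'")
  out <- data.frame(quantity = quantity, predicted = predicted,
                    observed = observed, unit = unit,
                    accuracy_percent = accuracy_percent(predicted, observed),
                    stringsAsFactors = FALSE)
  class(out) <- c("validation_record", "data.frame")
  out
}

#' Write a predicted-vs-observed validation report
#'
#' Emits a JSON file plus a human-readable table mirroring the
#' prediction-vs-measurement comparison layout. Records must each carry one
#' unit; an explicit `predicted`/`observed` unit mismatch inside a record is
#' impossible by construction, so the check here is that all records are
#' well-formed `validation_record`s.
#'
#' @param records list of `validation_record` objects (may be empty).
#' @param path output path for the JSON report; a `.txt` table is written
#'   alongside it.
#' @return the combined data frame, invisibly.
#' @export
validation_report <- function(records, path) {
  if (!all(vapply(records, inherits, TRUE, "validation_record")))
    stop("all records must be validation_record objects")
  tab <- if (length(records) > 0) do.call(rbind, records) else
    data.frame(quantity = character(0), predicted = numeric(0),
               observed = numeric(0), unit = character(0),
               accuracy_percent = numeric(0))
  jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  txt <- sub("\\.json$", ".txt", path)
  if (txt == path) txt <- paste0(path, ".txt")
  con <- file(txt, "w")
  writeLines("# predicted vs observed (in-silico model validation)", con)
  if (nrow(tab) > 0)
    utils::write.table(format(tab, digits = 6), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  close(con)
  invisible(tab)
}
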