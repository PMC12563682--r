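#!/usr/bin/env Rscript
# Stage 5: the prediction-vs-measurement arithmetic. The flux predicted for
# the producing strain (0.16 mmol/gDW/h) is converted to a molar
# concentration at the 5.38 kDa construct weight and compared with the
# 26.96 uM ELISA measurement; predicted and measured biomass are compared
# the same way.

library(gemfac)
dir.create("results", showWarnings = FALSE)

pred_flux <- 0.16       # mmol/gDW/h, model prediction for the sucrose medium
mw <- 5.38              # kDa, expressed LL-37-His6 construct
obs_conc <- 26.96       # uM, ELISA
pred_biomass <- 1.933   # g/L, model prediction
obs_biomass <- 2.166    # g/L, measured

pred_conc <- concentration_uM(pred_flux, mw)
cat(sprintf("predicted concentration: %.4f uM (%.2f g/L eq. at 1 gDW/L for 1 h)\n",
            pred_conc, mass_titer(pred_flux, 1, 1, mw)))
cat(sprintf("accuracy vs ELISA: %.2f%%\n", accuracy_percent(pred_conc, obs_conc)))
cat(sprintf("biomass accuracy: %.2f%%\n",
            accuracy_percent(pred_biomass, obs_biomass)))

records <- list(
  validation_record("biomass", pred_biomass, obs_biomass, "g/L"),
  validation_record("peptide_concentration", pred_conc, obs_conc, "uM"))
tab <- validation_report(records, "results/validation_report.json")
print(tab, row.names = FALSE)
cat("wrote results/validation_report.json (+ .txt)\n")
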