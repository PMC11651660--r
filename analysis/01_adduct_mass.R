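#!/usr/bin/env Rscript
# Covalent-adduct mass bookkeeping: reproduce the published exact-mass
# calibration set, predict protein adduct shifts for the packaged
# compounds, and demonstrate shift matching on a synthetic deconvoluted
# peak list mimicking the intact-mass experiment.

suppressPackageStartupMessages(library(covalentCA))
dir.create("results", showWarnings = FALSE)

# 1. Exact-mass calibration: computed ion m/z vs published values ------
ref <- load_hrms_reference()
ref$computed_mz <- mapply(ion_mz, ref$formula, ref$species)
ref$error_mDa <- (ref$computed_mz - ref$calc_mz) * 1000
write.csv(ref, "results/hrms_check.csv", row.names = FALSE)
message(sprintf("HRMS calibration: %d formula/species pairs, max |error| %.3f mDa",
                nrow(ref), max(abs(ref$error_mDa))))

# 2. Adduct shifts of the packaged covalent compounds ------------------
cpds <- load_fixture_compounds()
shifts <- do.call(rbind, lapply(cpds, function(cpd) {
  sh <- adduct_shift(cpd)
  data.frame(id = cpd$id, warhead = cpd$warhead_class,
             formula = format_formula(cpd$formula),
             shift_monoisotopic_Da = sh[["monoisotopic"]],
             shift_average_Da = sh[["average"]])
}))
write.csv(shifts, "results/adduct_shifts.csv", row.names = FALSE)
message(sprintf("Ester adduct shift (cpd 12): %.2f Da average (printed difference ~319 Da)",
                shifts[shifts$id == "12", "shift_average_Da"]))
message(sprintf("Carbamate adduct shift (cpd 22): %.4f Da monoisotopic",
                shifts[shifts$id == "22", "shift_monoisotopic_Da"]))

# 3. Shift matching on a synthetic two-site modification pattern -------
# Base mass is the published unmodified 29,575 Da isozyme peak; the
# generated pattern mirrors the observed unmodified / +1 / +2 peaks.
sh12 <- adduct_shift(cpds[["12"]])[["average"]]
g <- gen_ms_peaklist(29574.69, sh12, occupancies = c(0.45, 0.05),
                     cfg = gen_config(seed = 17))
m <- match_shift(g$peaks, base = 29574.69, candidates = cpds)
write.csv(m, "results/ms_match.csv", row.names = FALSE)
message(sprintf("Synthetic peak list: %d/%d shifted peaks matched to compound 12",
                sum(m$candidate_id == "12", na.rm = TRUE), nrow(m) - 1))
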