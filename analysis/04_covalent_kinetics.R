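#!/usr/bin/env Rscript
# Two-step covalent inhibition kinetics: modification time courses for
# the ester and carbamate regimes, the collapse of the apparent IC50
# toward half the target concentration, and the dialysis washout
# contrast between covalent and reversible inhibition.

suppressPackageStartupMessages(library(covalentCA))
dir.create("results", showWarnings = FALSE)

# 1. Modification time courses at 1:1 micromolar stoichiometry ---------
tg <- c(0, 10^seq(1, 6, by = 0.1))
summ <- do.call(rbind, lapply(c("ester-fast", "carbamate-slow"),
  function(preset) {
    st <- simulate_kinetics(kinetics_preset(preset), 1e-6, 1e-6, tg)
    fm <- fraction_modified(st)
    data.frame(preset = preset,
               half_time_s = tg[min(which(fm >= 0.5))],
               frac_3min = stats::approx(tg, fm, 180)$y,
               frac_2h = stats::approx(tg, fm, 7200)$y)
  }))
write.csv(summ, "results/kinetics_summary.csv", row.names = FALSE)
message(sprintf("ester: %.0f%% modified at 3 min, %.1f%% at 2 h",
                100 * summ$frac_3min[1], 100 * summ$frac_2h[1]))
message(sprintf("carbamate half-time %.2g s (~%.0fx the ester's %.2g s)",
                summ$half_time_s[2],
                summ$half_time_s[2] / summ$half_time_s[1],
                summ$half_time_s[1]))

# 2. Time-dependent apparent IC50 --------------------------------------
E0 <- 1e-7
doses <- 10^seq(-9, -5.5, by = 0.1)
r <- kinetics_preset("ester-fast")
ic_tab <- do.call(rbind, lapply(c(60, 600, 3600, 3e4, 1e6), function(t) {
  ic <- apparent_ic50(r, E0, t, doses)
  data.frame(t_s = t, ic50_M = ic$ic50, ic50_over_halfE0 = ic$ic50 / (E0 / 2))
}))
write.csv(ic_tab, "results/ic50_vs_time.csv", row.names = FALSE)
message(sprintf("IC50 collapses from %.3g M at 1 min to %.3g M (E0/2 = %.3g M) at long times",
                ic_tab$ic50_M[1], ic_tab$ic50_M[nrow(ic_tab)], E0 / 2))

# 3. Dialysis washout ---------------------------------------------------
# pre-incubate enzyme 1:10 with covalent and with reversible compound
# (a 20 nM-affinity non-covalent binder), then 32 h of first-order
# dialysis (2 h half-time)
pre_cov <- simulate_kinetics(r, 1.5e-6, 15e-6, c(0, 7200))
r_rev <- rate_constants(1e6, 0.02, 0, 0)
pre_rev <- simulate_kinetics(r_rev, 1.5e-6, 15e-6, c(0, 7200))
w <- lapply(list(covalent = list(r, pre_cov), reversible = list(r_rev, pre_rev)),
            function(x) washout(x[[1]], as.list(x[[2]][2, -1])))
wash <- data.frame(compound_class = names(w),
                   terminal_recovery = vapply(w, `[[`, 0,
                                              "terminal_recovery"))
write.csv(wash, "results/washout.csv", row.names = FALSE)
message(sprintf("washout recovery: covalent %.3f, reversible %.3f (finite 2 h-half-time dialysis of a tight binder)",
                wash$terminal_recovery[1], wash$terminal_recovery[2]))
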