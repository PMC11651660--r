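#' Generator configuration
#'
#' Seeded noise configuration shared by all synthetic-data generators.
#' Defaults: fluorescence sigma 1% of amplitude, Tm sigma 0.2 K, mass
#' error 20 ppm, competition signal CV 5%. Identical configurations give
#' identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param fluor_sigma Fluorescence noise as a fraction of curve amplitude.
#' @param tm_sigma Tm noise, K.
#' @param mass_ppm Mass jitter, ppm.
#' @param signal_cv Multiplicative competition-signal CV.
#' @return Object of class `gen_config`.
#' @export
gen_config <- function(seed = 1L, fluor_sigma = 0.01, tm_sigma = 0.2,
                       mass_ppm = 20, signal_cv = 0.05) {
  structure(list(seed = as.integer(seed), fluor_sigma = fluor_sigma,
                 tm_sigma = tm_sigma, mass_ppm = mass_ppm,
                 signal_cv = signal_cv), class = "gen_config")
}

#' Final assay concentrations of a serial-dilution scheme
#'
#' Plate chemistry of the thermal-shift assay: serial dilution of the
#' compound stock in DMSO (8-point two-fold or 12-point 1.5-fold), a
#' 12.5-fold dilution into assay buffer, then 1:1 mixing with the
#' protein solution. A zero-ligand point is appended. The default 10 mM
#' stock under the two-fold scheme gives a 400 uM top final dose.
#'
#' @param scheme `"twofold-8"` or `"onehalf-12"`.
#' @param stock Stock concentration, M (default 0.01).
#' @return Decreasing vector of final concentrations, M, ending with 0.
#' @export
gen_dose_grid <- function(scheme = c("twofold-8", "onehalf-12"),
                          stock = 0.01) {
  scheme <- match.arg(scheme)
  stopifnot(stock > 0)
  top <- stock / 12.5 / 2
  conc <- switch(scheme,
                 "twofold-8" = top / 2^(0:7),
                 "onehalf-12" = top / 1.5^(0:11))
  c(conc, 0)
}

#' Generate a synthetic thermal-shift dosing plate
#'
#' Per-dose true melting temperatures from the dosing model
#' ([tm_at_dose()]), Gaussian Tm noise, and full melt curves simulated on
#' the instrument's 25-90 degC ramp (1 degC spacing) with fractional
#' fluorescence noise. A truth record accompanies the data.
#'
#' @param Kd_ref True dissociation constant at the reference
#'   temperature, M.
#' @param s Ligand-free [stability_params()].
#' @param b_args List of [binding_thermo()] arguments other than
#'   `Kd_ref` (reference temperature, enthalpy, heat capacity).
#' @param grid Dose grid, M (default [gen_dose_grid()] `"twofold-8"`).
#' @param Pt Total protein, M.
#' @param cfg A [gen_config()].
#' @param replicates Number of plate replicates.
#' @return List: `tm_table` (well_id, Lt_M, Tm_C, Pt_M, replicate),
#'   `melt` (long-format well_id, temperature_C, fluorescence),
#'   `truth` (Kd_ref, per-well true Tm, parameters).
#' @export
gen_ftsa_plate <- function(Kd_ref, s = stability_params(332.15, 6e5),
                           b_args = list(T0 = 310.15, dHb = -42000,
                                         dCpb = -800),
                           grid = gen_dose_grid("twofold-8"),
                           Pt = 5e-6, cfg = gen_config(),
                           replicates = 1L) {
  b <- do.call(binding_thermo, c(list(Kd_ref = Kd_ref), b_args))
  tm_true <- tm_at_dose(grid, s, b, Pt, bracket = 60)
  set.seed(cfg$seed)
  Tk <- celsius_to_kelvin(seq(25, 90, by = 1))
  rows <- list(); curves <- list()
  for (r in seq_len(replicates)) {
    tm_obs <- tm_true + stats::rnorm(length(grid), 0, cfg$tm_sigma)
    well <- sprintf("R%d_W%02d", r, seq_along(grid))
    rows[[r]] <- data.frame(well_id = well, Lt_M = grid,
                            Tm_C = kelvin_to_celsius(tm_obs), Pt_M = Pt,
                            replicate = r)
    curves[[r]] <- do.call(rbind, lapply(seq_along(grid), function(i) {
      si <- stability_params(tm_true[i], s$dHu, s$dCpu)
      mc <- simulate_melt(si, list(bN0 = 0.1, bN1 = -0.001,
                                   bU0 = 1, bU1 = -0.002), Tk)
      amp <- diff(range(mc$fluorescence))
      data.frame(well_id = well[i],
                 temperature_C = kelvin_to_celsius(Tk),
                 fluorescence = mc$fluorescence +
                   stats::rnorm(length(Tk), 0, cfg$fluor_sigma * amp))
    }))
  }
  list(tm_table = do.call(rbind, rows), melt = do.call(rbind, curves),
       truth = list(Kd_ref = Kd_ref, tm_true_K = tm_true, grid_M = grid,
                    Pt = Pt, stability = s, binding = b, cfg = cfg))
}

#' Generate a synthetic probe-displacement competition plate
#'
#' Signal = background + scale * bound-probe fraction, with
#' multiplicative noise. The default dose grid mirrors the cell assay:
#' 10 two-fold dilutions from 80 nM halved by 1:1 probe addition (top
#' final 40 nM) plus a no-competitor well.
#'
#' @param KdA True competitor dissociation constant, M.
#' @param setup A [competition_setup()].
#' @param grid Competitor totals, M (default as above).
#' @param cfg A [gen_config()].
#' @param scale,background Signal model parameters.
#' @param replicates Number of replicates.
#' @return List: `data` (well_id, competitor_total_M, signal, replicate),
#'   `truth`.
#' @export
gen_competition_plate <- function(KdA, setup = competition_setup(),
                                  grid = c(80e-9 / 2^(0:9) / 2, 0),
                                  cfg = gen_config(), scale = 1000,
                                  background = 50, replicates = 1L) {
  occ <- occupancy_curve(setup, KdA, grid)
  set.seed(cfg$seed)
  rows <- lapply(seq_len(replicates), function(r) {
    noise <- stats::rnorm(length(grid), 1, cfg$signal_cv)
    data.frame(well_id = sprintf("R%d_W%02d", r, seq_along(grid)),
               competitor_total_M = grid,
               signal = (background + scale * occ) * noise,
               replicate = r)
  })
  list(data = do.call(rbind, rows),
       truth = list(KdA = KdA, occupancy = occ, setup = setup,
                    scale = scale, background = background, cfg = cfg))
}

#' Generate a synthetic deconvoluted intact-protein peak list
#'
#' Peaks at base + k * shift for k = 0..length(occupancies), with
#' intensities proportional to site occupancies and ppm-scale mass
#' jitter; emulates the unmodified / singly / doubly modified pattern of
#' intact-mass spectra.
#'
#' @param base Unmodified protein mass, Da.
#' @param shift Adduct mass shift, Da.
#' @param occupancies Fractions of 1x, 2x, ... modified protein (sum
#'   <= 1; the remainder is unmodified).
#' @param cfg A [gen_config()].
#' @return List: `peaks` (data frame mass_da, intensity), `truth`.
#' @export
gen_ms_peaklist <- function(base, shift, occupancies, cfg = gen_config()) {
  stopifnot(base > 0, all(occupancies >= 0), sum(occupancies) <= 1)
  set.seed(cfg$seed)
  frac <- c(1 - sum(occupancies), occupancies)
  masses <- base + (0:length(occupancies)) * shift
  jitter <- stats::rnorm(length(masses), 0, cfg$mass_ppm * 1e-6 * masses)
  keep <- frac > 0
  list(peaks = data.frame(mass_da = (masses + jitter)[keep],
                          intensity = 1000 * frac[keep]),
       truth = list(base = base, shift = shift,
                    occupancies = occupancies, cfg = cfg))
}

#' Generate a noisy covalent-modification time course
#'
#' @param rates A [rate_constants()] object.
#' @param E0,I0 Totals, M.
#' @param t_grid Time grid, s.
#' @param cfg A [gen_config()]; `fluor_sigma` is reused as the absolute
#'   noise on the modified fraction.
#' @return List: `data` (time_s, fraction_modified, clipped to \[0,1\]),
#'   `truth` (noise-free series).
#' @export
gen_kinetics_timecourse <- function(rates, E0, I0,
                                    t_grid = seq(0, 7200, by = 60),
                                    cfg = gen_config()) {
  st <- simulate_kinetics(rates, E0, I0, t_grid)
  fm <- fraction_modified(st)
  set.seed(cfg$seed)
  noisy <- pmin(pmax(fm + stats::rnorm(length(fm), 0, cfg$fluor_sigma),
                     0), 1)
  list(data = data.frame(time_s = t_grid, fraction_modified = noisy),
       truth = list(fraction_modified = fm, rates = rates, E0 = E0,
                    I0 = I0, cfg = cfg))
}
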