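#' Two-state protein stability parameters
#'
#' @param Tm_ref Melting temperature of the ligand-free protein, K.
#' @param dHu Unfolding enthalpy at `Tm_ref`, J/mol (> 0).
#' @param dCpu Unfolding heat-capacity change, J/(mol K). Single melt
#'   curves cannot identify it; it is carried as a fixed parameter
#'   (default 17 kJ/(mol K), typical for a ~30 kDa globular protein).
#' @return Object of class `stability_params`.
#' @export
stability_params <- function(Tm_ref, dHu, dCpu = 17000) {
  stopifnot(Tm_ref > 273, Tm_ref < 373, dHu > 0)
  structure(list(Tm_ref = Tm_ref, dHu = dHu, dCpu = dCpu),
            class = "stability_params")
}

#' Unfolding Gibbs free energy at temperature T
#'
#' Gibbs-Helmholtz form anchored at the melting temperature:
#' dG_u(T) = dHu (1 - T/Tm) + dCpu (T - Tm - T ln(T/Tm)).
#'
#' @param T Temperature(s), K.
#' @param s A [stability_params()] object.
#' @return Free energy in J/mol (0 at `Tm_ref`).
#' @export
unfolding_free_energy <- function(T, s) {
  stopifnot(inherits(s, "stability_params"), all(T > 0))
  s$dHu * (1 - T / s$Tm_ref) +
    s$dCpu * (T - s$Tm_ref - T * log(T / s$Tm_ref))
}

#' Equilibrium folded fraction at temperature T
#'
#' @inheritParams unfolding_free_energy
#' @return Fraction folded in \[0, 1\]; 0.5 at `Tm_ref`.
#' @export
folded_fraction <- function(T, s) {
  1 / (1 + exp(-unfolding_free_energy(T, s) / (.RGAS * T)))
}

#' Simulate a dye-fluorescence melt curve
#'
#' Linear native and unfolded baselines (anchored at `Tm_ref`) mixed by
#' the folded fraction:
#' F(T) = (bN0 + bN1 (T - Tm)) fN + (bU0 + bU1 (T - Tm)) (1 - fN).
#'
#' @inheritParams unfolding_free_energy
#' @param baselines List with `bN0`, `bN1`, `bU0`, `bU1` (native/unfolded
#'   intercepts at `Tm_ref` and slopes).
#' @param Tgrid Strictly increasing temperature grid, K.
#' @return Data frame with columns `temperature_K`, `fluorescence`.
#' @export
simulate_melt <- function(s, baselines = list(bN0 = 0, bN1 = 0,
                                              bU0 = 1, bU1 = 0),
                          Tgrid) {
  stopifnot(all(diff(Tgrid) > 0))
  fN <- folded_fraction(Tgrid, s)
  dT <- Tgrid - s$Tm_ref
  f <- (baselines$bN0 + baselines$bN1 * dT) * fN +
    (baselines$bU0 + baselines$bU1 * dT) * (1 - fN)
  data.frame(temperature_K = Tgrid, fluorescence = f)
}

# Initial guesses: Tm from the extremum of the Savitzky-Golay-smoothed
# derivative, baselines from the first/last 10% of points.
.melt_start <- function(temps, fluor) {
  n <- length(temps)
  k <- max(3L, floor(n * 0.1))
  lo <- seq_len(k); hi <- seq(n - k + 1L, n)
  fitN <- stats::lm.fit(cbind(1, temps[lo]), fluor[lo])$coefficients
  fitU <- stats::lm.fit(cbind(1, temps[hi]), fluor[hi])$coefficients
  fl <- min(21L, if (n %% 2L == 1L) n else n - 1L)
  sm <- if (fl >= 5) signal::sgolayfilt(fluor, p = 3, n = fl) else fluor
  d <- diff(sm) / diff(temps)
  Tm0 <- temps[which.max(abs(d))]
  list(Tm0 = Tm0, fitN = fitN, fitU = fitU)
}

#' Fit the two-state melt model to a fluorescence trace
#'
#' Nonlinear least squares over \{Tm, dHu, four baseline parameters\}
#' with `dCpu` held fixed. Tm is the temperature of half-unfolding
#' (folded fraction 0.5).
#'
#' @param temps Temperatures, K (or a `MeltCurve`-style data frame via
#'   `curve`).
#' @param fluor Fluorescence values, same length.
#' @param dCpu Fixed unfolding heat-capacity change, J/(mol K).
#' @return List: `ok` (logical), `params` ([stability_params()] estimate),
#'   `baselines`, `Tm_se` (standard error, K), `residual_sd`, `amplitude`
#'   (unfolded minus native signal at Tm), and `reason` when `ok` is
#'   FALSE. A transition amplitude below 3x the residual noise is flagged
#'   as a failure rather than reported as a number.
#' @export
fit_melt <- function(temps, fluor, dCpu = 17000) {
  stopifnot(length(temps) == length(fluor), length(temps) >= 20,
            all(is.finite(temps)), all(is.finite(fluor)),
            all(diff(temps) > 0))
  st <- .melt_start(temps, fluor)
  start <- list(Tm = st$Tm0, dHu = 4e5,
                bN0 = unname(st$fitN[1] + st$fitN[2] * st$Tm0),
                bN1 = unname(st$fitN[2]),
                bU0 = unname(st$fitU[1] + st$fitU[2] * st$Tm0),
                bU1 = unname(st$fitU[2]))
  model <- function(Tm, dHu, bN0, bN1, bU0, bU1) {
    fN <- 1 / (1 + exp(-(dHu * (1 - temps / Tm) +
      dCpu * (temps - Tm - temps * log(temps / Tm))) / (.RGAS * temps)))
    (bN0 + bN1 * (temps - Tm)) * fN +
      (bU0 + bU1 * (temps - Tm)) * (1 - fN)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fluor ~ model(Tm, dHu, bN0, bN1, bU0, bU1),
      start = start,
      lower = c(Tm = min(temps), dHu = 1e3, bN0 = -Inf, bN1 = -Inf,
                bU0 = -Inf, bU1 = -Inf),
      upper = c(Tm = max(temps), dHu = 5e6, bN0 = Inf, bN1 = Inf,
                bU0 = Inf, bU1 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(ok = FALSE, reason = paste("fit failed:",
                                           conditionMessage(fit))))
  }
  cf <- stats::coef(fit)
  res_sd <- stats::sd(stats::resid(fit))
  amplitude <- abs(cf[["bU0"]] - cf[["bN0"]])
  if (!is.finite(amplitude) || amplitude < 3 * res_sd) {
    return(list(ok = FALSE, reason = "no transition detected",
                residual_sd = res_sd, amplitude = amplitude))
  }
  se <- tryCatch(summary(fit)$coefficients["Tm", "Std. Error"],
                 error = function(e) NA_real_)
  list(ok = TRUE,
       params = stability_params(cf[["Tm"]], cf[["dHu"]], dCpu),
       baselines = list(bN0 = cf[["bN0"]], bN1 = cf[["bN1"]],
                        bU0 = cf[["bU0"]], bU1 = cf[["bU1"]]),
       Tm_se = se, residual_sd = res_sd, amplitude = amplitude)
}

#' Convert Celsius to kelvin and back
#'
#' Temperatures are kelvin internally and Celsius at file boundaries.
#' @param x Temperature(s).
#' @return Converted temperature(s).
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - 273.15
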