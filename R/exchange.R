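# Lumped-parameter physics of the test circuit: carrier CO2 chemistry,
# conditioning-lung loading, artificial-lung removal, reservoir balance.

R_GAS <- 0.0820573  # L atm / (mol K)

#' CO2 content of the carrier fluid at a given partial pressure
#'
#' Water follows Henry's law, `content = alpha * pco2`; blood uses an
#' empirical power-law dissociation curve `content = k1 * pco2^k2`
#' (dissolved + bicarbonate-bound CO2). Both are strictly increasing and
#' invertible, which the reservoir mass balance relies on.
#'
#' @param fluid `"water"` or `"blood"`.
#' @param pco2 Partial pressure, mmHg (vectorised, must be >= 0).
#' @param alpha Water solubility, mmol/(L mmHg).
#' @param k1,k2 Blood dissociation constants (mmol/L at 1 mmHg; exponent).
#' @return CO2 content, mmol/L.
#' @export
#' @examples
#' content_curve("water", 40)          # 1.2 mmol/L
#' content_curve("blood", 40)
content_curve <- function(fluid, pco2, alpha = 0.03, k1 = 2.2, k2 = 0.40) {
  if (any(pco2 < 0)) stop("pco2 must be >= 0")
  if (fluid == "water") alpha * pco2 else k1 * pco2^k2
}

#' Invert the content curve: partial pressure from CO2 content
#'
#' @param fluid `"water"` or `"blood"`.
#' @param content CO2 content, mmol/L (>= 0).
#' @inheritParams content_curve
#' @return pCO2, mmHg.
#' @export
pco2_from_content <- function(fluid, content, alpha = 0.03, k1 = 2.2, k2 = 0.40) {
  if (any(content < 0)) stop("content must be >= 0")
  if (fluid == "water") content / alpha else (content / k1)^(1 / k2)
}

#' Exhaust-gas CO2 as a function of sweep flow
#'
#' Single-transfer-unit gas-side equilibration model:
#' `EGCO2 = pL * (1 - exp(-beta / sweep))`. As sweep flow falls the gas has
#' more time to equilibrate with the liquid and EGCO2 approaches the liquid
#' inlet pCO2; as sweep rises the gas-liquid gap widens. EGCO2 never exceeds
#' the liquid inlet pCO2 (the device can only remove CO2). `sweep = 0`
#' returns the full-equilibration limit `pl_in`.
#'
#' @param pl_in Liquid inlet pCO2, mmHg (>= 0).
#' @param sweep Sweep gas flow, L/min (>= 0).
#' @param beta Gas-side equilibration parameter, L/min.
#' @return EGCO2, mmHg. Vectorised over `pl_in` and `sweep`.
#' @export
#' @examples
#' egco2_of_sweep(40, 2, beta = 2)  # 40 * (1 - exp(-1))
egco2_of_sweep <- function(pl_in, sweep, beta = 1.2) {
  if (any(pl_in < 0) || any(sweep < 0)) stop("pl_in and sweep must be >= 0")
  stopifnot(beta > 0)
  ifelse(sweep <= 0, pl_in, pl_in * (1 - exp(-beta / sweep)))
}

#' Fit the gas-side equilibration parameter to one operating point
#'
#' Solves `egco2 = pl_in * (1 - exp(-beta/sweep))` for `beta`, letting users
#' calibrate the exchange model to a measured (sweep, EGCO2) pair.
#'
#' @param pl_in Liquid inlet pCO2, mmHg.
#' @param sweep Sweep flow at the measurement, L/min (> 0).
#' @param egco2 Measured EGCO2, mmHg (0 < egco2 < pl_in).
#' @return beta, L/min.
#' @export
fit_beta <- function(pl_in, sweep, egco2) {
  stopifnot(sweep > 0, pl_in > 0)
  if (egco2 <= 0 || egco2 >= pl_in)
    stop("egco2 must lie strictly between 0 and pl_in")
  -sweep * log(1 - egco2 / pl_in)
}

#' Molar CO2 carried away by the sweep gas
#'
#' Ideal-gas conversion of the exhaust CO2 fraction to a molar rate:
#' `sweep * (egco2/pressure) * (pressure/760 atm) * 1000 / (R * temp)`.
#'
#' @param egco2 Exhaust CO2 partial pressure, mmHg.
#' @param sweep Sweep flow, L/min (at outlet conditions).
#' @param pressure Total pressure, mmHg.
#' @param temp Temperature, K (> 0).
#' @return Removal rate, mmol/min.
#' @export
removal_rate <- function(egco2, sweep, pressure = 760, temp = 310) {
  if (any(temp <= 0)) stop("temp must be > 0")
  if (any(egco2 < 0) || any(sweep < 0) || any(pressure < 0))
    stop("inputs must be >= 0")
  sweep * (egco2 / pressure) * (pressure / 760) * 1000 / (R_GAS * temp)
}

#' Gas-side inlet pCO2 of the conditioning lung
#'
#' Mole fraction of the CO2/air mixture fed to the conditioning lung times
#' total pressure; air's ~0.04% CO2 is neglected.
#'
#' @param air_flow Air flow, L/min.
#' @param co2_flow CO2 flow, L/min.
#' @param pressure Total pressure, mmHg.
#' @return Gas inlet pCO2, mmHg.
#' @export
#' @examples
#' conditioning_inlet_pco2(2, 0.1)  # ~36.19 mmHg
conditioning_inlet_pco2 <- function(air_flow, co2_flow, pressure = 760) {
  if (any(air_flow < 0) || any(co2_flow < 0)) stop("flows must be >= 0")
  if (any(air_flow + co2_flow <= 0)) stop("total conditioning gas flow is zero")
  pressure * co2_flow / (air_flow + co2_flow)
}

#' One pass of the carrier fluid through the conditioning lung
#'
#' The conditioning lung loads CO2 into the fluid to emulate patient
#' metabolism. Outlet pCO2 relaxes toward the gas inlet pCO2 by the
#' configured per-pass efficiency (fraction of the gas-liquid gap closed).
#'
#' @param pco2_in Liquid inlet pCO2, mmHg.
#' @param gas_pco2 Conditioning gas inlet pCO2, mmHg.
#' @param efficiency Per-pass equilibration fraction in (0, 1].
#' @return Liquid outlet pCO2, mmHg.
#' @export
conditioning_pass <- function(pco2_in, gas_pco2, efficiency = 0.22) {
  stopifnot(efficiency > 0, efficiency <= 1)
  pco2_in + efficiency * (gas_pco2 - pco2_in)
}

#' One pass of the carrier fluid through the artificial lung
#'
#' Computes EGCO2 from the gas-side equilibration model, converts the
#' exhaust CO2 carriage to a molar removal rate, and debits it from the
#' liquid. The liquid outlet pCO2 is floored at EGCO2 (the liquid cannot be
#' stripped below the gas-side outlet partial pressure), so at water's low
#' CO2 capacity the realised removal is liquid-limited; the returned
#' `removal` is the realised (capped) rate, which is what the reservoir
#' balance must use for mass conservation.
#'
#' @param pco2_in Liquid inlet pCO2, mmHg.
#' @param fluid `"water"` or `"blood"`.
#' @param liquid_flow Liquid flow, L/min (> 0).
#' @param sweep Sweep gas flow, L/min.
#' @param beta Gas-side equilibration parameter, L/min.
#' @param pressure Ambient pressure, mmHg.
#' @param temp Temperature, K.
#' @inheritParams content_curve
#' @return List with `egco2` (mmHg), `pco2_out` (mmHg), `content_out`
#'   (mmol/L) and `removal` (mmol/min).
#' @export
al_pass <- function(pco2_in, fluid = "water", liquid_flow = 1, sweep = 1,
                    beta = 1.2, pressure = 760, temp = 310,
                    alpha = 0.03, k1 = 2.2, k2 = 0.40) {
  stopifnot(liquid_flow > 0)
  egco2 <- egco2_of_sweep(pco2_in, sweep, beta)
  gas_rate <- removal_rate(egco2, sweep, pressure, temp)
  c_in <- content_curve(fluid, pco2_in, alpha, k1, k2)
  c_floor <- content_curve(fluid, egco2, alpha, k1, k2)
  c_out <- max(c_floor, c_in - gas_rate / liquid_flow)
  list(egco2 = egco2,
       pco2_out = pco2_from_content(fluid, c_out, alpha, k1, k2),
       content_out = c_out,
       removal = liquid_flow * (c_in - c_out))
}

#' Advance the well-mixed reservoir by one time step
#'
#' Explicit convective update of the single-compartment reservoir:
#' `content' = content + (flow/volume) * (content_return - content) * dt/60`.
#' Mass is conserved: `volume * d(content)` equals the net convective influx
#' over `dt`.
#'
#' @param content Reservoir CO2 content, mmol/L.
#' @param volume Reservoir volume, L (> 0).
#' @param flow Liquid loop flow, L/min.
#' @param content_return CO2 content of the returning liquid, mmol/L.
#' @param dt Time step, s (> 0).
#' @return Updated content, mmol/L.
#' @export
reservoir_step <- function(content, volume, flow, content_return, dt) {
  stopifnot(dt > 0, volume > 0)
  content + (flow / volume) * (content_return - content) * dt / 60
}
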