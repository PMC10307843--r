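#' Magnetostimulation (PNS) threshold parameters
#'
#' Parameters of the fundamental law of magnetostimulation for the human leg:
#' the asymptotic peak-to-peak threshold and the chronaxie time constant of
#' nerve depolarization, evaluated at a drive frequency.
#'
#' @param delta_B_min_pp asymptotic peak-to-peak threshold in mT.
#' @param tau_c chronaxie in s.
#' @param f drive frequency in Hz.
#' @return An object of class `pns_params`.
#' @export
pns_params <- function(delta_B_min_pp = 47.5, tau_c = 295e-6, f = 2480) {
  if (delta_B_min_pp <= 0 || tau_c <= 0) stop("parameters must be positive")
  if (f < 0) stop("f must be non-negative")
  structure(list(delta_B_min_pp = delta_B_min_pp, tau_c = tau_c, f = f),
            class = "pns_params")
}

#' Peak-to-peak PNS amplitude threshold
#'
#' Fundamental law of magnetostimulation:
#' `B_th,pp = delta_B_min_pp * (1 + 1 / (2 * tau_c * f))`. Strictly
#' decreasing in `f` with asymptote `delta_B_min_pp`. At the default leg
#' parameters and 2480 Hz the threshold is about 80 mT peak-to-peak.
#'
#' @param p a [pns_params()].
#' @return Threshold in mT peak-to-peak.
#' @export
#' @examples
#' pns_threshold(pns_params())  # ~79.96 mT
pns_threshold <- function(p) {
  stopifnot(inherits(p, "pns_params"))
  if (p$f == 0) stop("f must be positive for a finite threshold")
  p$delta_B_min_pp * (1 + 1 / (2 * p$tau_c * p$f))
}

#' SAR scaled from a reference operating point
#'
#' Tissue heating scales with `f^2 B^2`; this calculator anchors that scaling
#' at a known operating point (default: 0.15 W/kg at 2480 Hz and 35 mT
#' amplitude) rather than modeling tissue explicitly.
#'
#' @param f drive frequency in Hz.
#' @param B field amplitude in mT.
#' @param ref reference point: named list/vector with `f_ref` (Hz), `B_ref`
#'   (mT) and `sar_ref` (W/kg).
#' @return SAR in W/kg.
#' @export
#' @examples
#' sar_scaled(2480, 35)   # 0.15 at the anchor
#' sar_scaled(1240, 35)   # a quarter of it
sar_scaled <- function(f, B, ref = c(f_ref = 2480, B_ref = 35, sar_ref = 0.15)) {
  if (f < 0 || B < 0) stop("f and B must be non-negative")
  ref <- as.list(ref)
  ref$sar_ref * (f / ref$f_ref)^2 * (B / ref$B_ref)^2
}

#' Effective channel power
#'
#' `P_eff = 1/2 * R * I^2` for a sinusoidal drive of peak current `I` through
#' resistance `R`.
#'
#' @param R coil resistance in Ohm.
#' @param I peak current in A.
#' @return Power in W.
#' @export
#' @examples
#' channel_power(0.5, 165)  # 6806.25 W
channel_power <- function(R, I) {
  if (R <= 0) stop("R must be positive")
  if (!is.finite(I)) stop("I must be finite")
  0.5 * R * I^2
}

#' Coil specification for thermal estimates
#'
#' @param R resistance in Ohm.
#' @param I peak current in A.
#' @param l_wire litz-wire length in m.
#' @param A_wire copper cross-section in m^2 (default `pi` mm^2, i.e.
#'   400 strands of 0.1 mm diameter).
#' @param rho_cu copper density in kg/m^3.
#' @param c_cu copper specific heat in J/(kg K).
#' @param A_surface coil surface area in m^2.
#' @param alpha convective heat-transfer coefficient in W/(m^2 K)
#'   (about 10 for free and 30 for forced convection).
#' @return An object of class `coil_spec`.
#' @export
coil_spec <- function(R, I, l_wire, A_wire = pi * 1e-6, rho_cu = 8960,
                      c_cu = 383, A_surface = 0.168, alpha = 10) {
  vals <- c(R = R, I = I, l_wire = l_wire, A_wire = A_wire, rho_cu = rho_cu,
            c_cu = c_cu, A_surface = A_surface, alpha = alpha)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all coil parameters must be positive and finite")
  structure(as.list(vals), class = "coil_spec")
}

#' @rdname coil_spec
#' @export
coil_ch12 <- function(I = 165) {
  coil_spec(R = 0.5, I = I, l_wire = 90, A_surface = 0.168)
}

#' @rdname coil_spec
#' @export
coil_ch3 <- function(I = 110) {
  coil_spec(R = 0.6, I = I, l_wire = 105, A_surface = 0.171)
}

#' Copper mass of a coil
#'
#' `m = A_wire * l_wire * rho_cu`.
#'
#' @param spec a [coil_spec()].
#' @return Mass in kg.
#' @export
#' @examples
#' copper_mass(coil_ch12())  # ~2.53 kg
copper_mass <- function(spec) {
  stopifnot(inherits(spec, "coil_spec"))
  spec$A_wire * spec$l_wire * spec$rho_cu
}

#' Coil temperature rise per burst
#'
#' Adiabatic estimate from `P * dt = m * c * dT`: all burst energy goes into
#' the coil's copper thermal mass.
#'
#' @param P dissipated power in W.
#' @param dt burst duration in s.
#' @param m copper mass in kg.
#' @param c specific heat in J/(kg K).
#' @return Temperature rise in K.
#' @export
#' @examples
#' heat_per_frame(6600, 0.06, copper_mass(coil_ch12()), 383)  # ~0.41 K
heat_per_frame <- function(P, dt, m, c = 383) {
  if (m <= 0 || c <= 0) stop("m and c must be positive")
  if (P < 0 || dt < 0) stop("P and dt must be non-negative")
  P * dt / (m * c)
}

#' Convective cooling rate of a coil
#'
#' From the heat-transfer law `Q/t = alpha * A * dT`: the temperature
#' decrease per second of a coil `delta_T` above ambient.
#'
#' @param alpha heat-transfer coefficient in W/(m^2 K).
#' @param A_surface coil surface area in m^2.
#' @param delta_T coil-to-air temperature difference in K.
#' @param m copper mass in kg.
#' @param c specific heat in J/(kg K).
#' @return Cooling rate in K/s.
#' @export
#' @examples
#' cooling_rate(10, 0.168, 50, copper_mass(coil_ch12()))  # ~0.087 K/s
cooling_rate <- function(alpha, A_surface, delta_T, m, c = 383) {
  vals <- c(alpha, A_surface, m, c)
  if (any(vals <= 0)) stop("alpha, A_surface, m and c must be positive")
  if (delta_T < 0) stop("delta_T must be non-negative")
  alpha * A_surface * delta_T / (m * c)
}

#' Continuous-operation duty-cycle plan
#'
#' Balances per-frame heating against convective cooling: the net heating
#' rate is `frame_rate * heat_frame - cool_rate`. Operation is sustainable
#' when the net rate is non-positive; otherwise the scanner can run for
#' `delta_T_limit / net` seconds before reaching the allowed temperature
#' rise.
#'
#' @param frame_rate frames per second.
#' @param heat_frame temperature rise per frame in K.
#' @param cool_rate cooling rate in K/s.
#' @param delta_T_limit allowed temperature rise in K.
#' @return List with `max_continuous` (s, `Inf` if sustainable),
#'   `sustainable` (logical) and `net_rate` (K/s).
#' @export
#' @examples
#' duty_cycle_plan(4, 0.41, 0.26, 50)
duty_cycle_plan <- function(frame_rate, heat_frame, cool_rate,
                            delta_T_limit = 50) {
  if (frame_rate <= 0 || delta_T_limit <= 0)
    stop("frame_rate and delta_T_limit must be positive")
  if (heat_frame < 0 || cool_rate < 0)
    stop("heat_frame and cool_rate must be non-negative")
  net <- frame_rate * heat_frame - cool_rate
  sustainable <- net <= 0
  list(max_continuous = if (sustainable) Inf else delta_T_limit / net,
       sustainable = sustainable, net_rate = net)
}

#' Composite safety and operations report
#'
#' Aggregates the PNS, SAR, power, heating and cooling calculators for one
#' scanner configuration: compares the operating peak-to-peak amplitude with
#' the magnetostimulation threshold at the deflection frequency, scales SAR
#' to the operating point, and derives per-channel power, per-frame heating,
#' free/forced cooling rates and the continuous-operation limit at the given
#' frame rate. A dose check compares the injected iron with the per-kg limit.
#'
#' @param config a [scanner_config()].
#' @param coils list with coil specs `ch12` and `ch3`; currents default to
#'   the operating currents in `config`.
#' @param pns a [pns_params()]; frequency defaults to `config$f3`.
#' @param frame_rate imaging frame rate in 1/s.
#' @param delta_T_limit allowed coil temperature rise in K.
#' @param dose_mg injected iron in mg (default: one 1 ml bolus of 8.5 mg/ml).
#' @param mg_per_kg,body_mass_kg dose-limit convention.
#' @return An object of class `safety_report` (a nested list of annotated
#'   quantities); see [write_safety_report()] for machine-readable output.
#' @export
#' @examples
#' safety_report(scanner_config())
safety_report <- function(config,
                          coils = list(ch12 = coil_ch12(I = config$I_ch12),
                                       ch3 = coil_ch3(I = config$I_ch3)),
                          pns = pns_params(f = config$f3),
                          frame_rate = 4, delta_T_limit = 50,
                          dose_mg = 8.5, mg_per_kg = 2.5, body_mass_kg = 80) {
  stopifnot(inherits(config, "scanner_config"))
  thr <- pns_threshold(pns)
  op_pp <- config$B_pp * 1000  # T -> mT
  sar <- sar_scaled(config$f3, op_pp / 2)
  per_channel <- lapply(coils, function(cs) {
    m <- copper_mass(cs)
    P <- channel_power(cs$R, cs$I)
    list(power_W = P, copper_kg = m,
         heat_per_frame_K = heat_per_frame(P, config$dt_burst, m, cs$c_cu),
         cooling_free_K_s = cooling_rate(10, cs$A_surface, delta_T_limit, m, cs$c_cu),
         cooling_forced_K_s = cooling_rate(30, cs$A_surface, delta_T_limit, m, cs$c_cu))
  })
  worst <- which.max(vapply(per_channel, function(p) p$heat_per_frame_K, 1))
  plan <- duty_cycle_plan(frame_rate,
                          per_channel[[worst]]$heat_per_frame_K,
                          per_channel[[worst]]$cooling_forced_K_s,
                          delta_T_limit)
  limit <- dose_limit(mg_per_kg, body_mass_kg)
  rep <- list(
    pns = list(threshold_pp_mT = thr, operating_pp_mT = op_pp,
               margin = thr / op_pp, flagged = op_pp > thr,
               f_Hz = pns$f),
    sar = list(W_kg = sar, f_Hz = config$f3, B_mT = op_pp / 2),
    channels = per_channel,
    duty_cycle = c(plan, list(frame_rate = frame_rate,
                              delta_T_limit_K = delta_T_limit,
                              worst_channel = names(per_channel)[worst])),
    dose = list(injected_mg = dose_mg, limit_mg = limit,
                mg_per_kg = mg_per_kg, body_mass_kg = body_mass_kg,
                flagged = dose_mg > limit)
  )
  structure(rep, class = "safety_report")
}

#' @export
print.safety_report <- function(x, ...) {
  cat("<safety_report>\n")
  cat(sprintf("  PNS: operating %.1f mT pp vs threshold %.1f mT pp at %g Hz -> %s (margin %.2f)\n",
              x$pns$operating_pp_mT, x$pns$threshold_pp_mT, x$pns$f_Hz,
              if (x$pns$flagged) "FLAGGED" else "clear", x$pns$margin))
  cat(sprintf("  SAR: %.3g W/kg at %g Hz, %g mT amplitude\n",
              x$sar$W_kg, x$sar$f_Hz, x$sar$B_mT))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %s: %.0f W, %.2f kg Cu, +%.3f K/frame, cooling %.3f (free) / %.3f (forced) K/s\n",
                nm, ch$power_W, ch$copper_kg, ch$heat_per_frame_K,
                ch$cooling_free_K_s, ch$cooling_forced_K_s))
  }
  dc <- x$duty_cycle
  cat(sprintf("  duty cycle at %g fps (worst: %s): %s\n", dc$frame_rate,
              dc$worst_channel,
              if (dc$sustainable) "sustainable indefinitely"
              else sprintf("max %.0f s continuous", dc$max_continuous)))
  cat(sprintf("  dose: %.3g mg Fe vs limit %.0f mg (%.1f mg/kg x %.0f kg) -> %s\n",
              x$dose$injected_mg, x$dose$limit_mg, x$dose$mg_per_kg,
              x$dose$body_mass_kg,
              if (x$dose$flagged) "FLAGGED" else "clear"))
  invisible(x)
}

#' Write a safety report as JSON
#'
#' @param report a [safety_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_safety_report <- function(report, path) {
  stopifnot(inherits(report, "safety_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
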