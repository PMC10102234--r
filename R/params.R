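# Parameter set for the PSM model: geometry, rate constants, Hill
# constants/exponents, delays, gradient shapes and scenario multipliers.
# Concentrations are dimensionless (mRNAs normalised by the maximal her
# transcription/degradation ratio, proteins by the Tbx6 autoregulatory
# production/degradation ratio), so only times (min) and lengths (um) carry
# units.

#' Calibrated wild-type parameter set
#'
#' Returns the full parameter set of the model with its calibrated wild-type
#' defaults. Geometry and the values that are fixed by construction
#' (`L = 400` um, `dx = 10` um, hence `N = 41` cells; Euler step
#' `dt = 0.01` min; warm-up 460 min; anterior/posterior Her translational
#' delay ratio `tau_H0/tau_HL = 6`; stepwise dpErk border geometry
#' `x_E = 200`, `delta = 60`, `x_e0 = 180` um) are set directly. The
#' remaining kinetic constants are calibrated so that
#'
#' * the single-cell *her* circuit oscillates with a posterior (tailbud)
#'   period of `T_clock = 30` min, a zebrafish-like segmentation period;
#' * the advection speed `u = 6 * dx / T_clock` lets one clock cycle advect
#'   exactly one somite of 6 cells;
#' * the Tbx6 switch (`K6 = 0.4`, `n6 = 2`) is bistable at low Fgf signal
#'   with stable states 0 and 0.8 and saddle-node degradation threshold
#'   `1/(2*K6) = 1.25`;
#' * the incoherent feedforward input confines the rise to the high Tbx6
#'   state to the mid PSM (monostable-high there), leaving tailbud cells on
#'   the low branch and the anterior PSM bistable;
#' * the peak Ripply-boosted degradation factor `1 + eta * max(p_r)`
#'   comfortably exceeds the saddle-node threshold.
#'
#' Derived quantities (`u`, `N`, `tau_H0`) are computed in code from the
#' primitive choices rather than written out, so the calibration is
#' executable. All delays are rounded to the nearest multiple of `dt` (see
#' [normalize_delays()]).
#'
#' @param ... named overrides applied on top of the defaults, e.g.
#'   `default_parameters(tau_H0 = 2.1)` for a spatially uniform delay.
#' @return An object of class `psm_params` (a named list).
#' @seealso [validate_parameters()], [apply_perturbation()],
#'   [simulate_psm()]
#' @examples
#' p <- default_parameters()
#' p$N        # 41 cells
#' p$tau_H0 / p$tau_HL
#' @export
default_parameters <- function(...) {
  L <- 400; dx <- 10
  T_clock <- 30                    # calibrated intrinsic tailbud clock period, min
  somite_cells <- 6                # one somite per clock cycle
  u <- somite_cells * dx / T_clock # 2 um/min: 6 cells advected per cycle

  tau_HL <- 2.1                    # posterior Her translational delay, min
  delay_ratio <- 6                 # tau_H0 / tau_HL
  tau_H0 <- delay_ratio * tau_HL   # 12.6 min at x = 0

  p <- list(
    # geometry / integration
    L = L, dx = dx, N = as.integer(round(L / dx)) + 1L, u = u,
    dt = 0.01, t_warmup = 460, T_clock = T_clock,
    # mRNA kinetics (mu1 is the reference mRNA timescale, 1/min; ripply
    # mature mRNA turns over twice as fast as her mRNA so the Ripply pulse
    # tracks its clock-gated transcription closely)
    mu1 = 0.3, mu_sh = 3, mu_sr = 3, mu2 = 2,
    # protein kinetics (mu3 is the reference protein timescale, 1/min;
    # Ripply protein is short-lived, half-life ~1.4 min)
    mu3 = 0.25, mu4 = 1, mu5 = 2,
    # production strengths
    nu1 = 3, nu2 = 2, nu3 = 16, nu_e = 1,
    # Hill dissociation constants
    K1 = 0.1, K2 = 0.5, K3 = 0.2, K4 = 0.15, K5 = 0.5, K6 = 0.4,
    K_FA = 0.25, K_FR = 0.4,
    # Hill exponents (the ripply gates n3/n4 and the feedforward input are
    # sharper than the core loops so the pulse is decisively on or off)
    n1 = 2, n2 = 2, n3 = 4, n4 = 4, n5 = 2, n6 = 2, nA = 4, nR = 4,
    # delays, min
    tau_h = 5.4, tau_r = 2, tau_H0 = tau_H0, tau_HL = tau_HL, tau_R = 1,
    # spatial organisation
    x_h = 250,                     # her/Tbx6-dependence switch position, um
    gamma = 0.5,                   # IFFL production weight
    eta = 3,                       # Ripply-boosted Tbx6 degradation coupling
    F0 = 1, x_f = 100,             # Fgf gradient amplitude and length scale
    # dpErk profile
    q = 0.2,                       # dpErk rise inverse length scale, 1/um
    x_E = 200, delta = 60, x_e0 = 180, erk_mode = "fixed",
    # scenario multipliers (wild type: both 1)
    her_tx_mult = 1, pfl_mult = 1
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  p <- normalize_delays(p)
  class(p) <- "psm_params"
  p
}

#' Round all delays to the integrator grid
#'
#' Delays are rounded to the nearest multiple of the Euler step `dt`
#' (maximum rounding error `dt/2`), which makes every history lookup an
#' exact ring-buffer index and keeps the integration deterministic.
#'
#' @param p a `psm_params` object or plain named list.
#' @return `p` with `tau_h`, `tau_r`, `tau_H0`, `tau_HL`, `tau_R` snapped to
#'   the `dt` grid.
#' @export
normalize_delays <- function(p) {
  for (f in c("tau_h", "tau_r", "tau_H0", "tau_HL", "tau_R"))
    p[[f]] <- round(p[[f]] / p$dt) * p$dt
  p
}

.positive_fields <- c(
  "L", "dx", "u", "dt", "T_clock",
  "mu1", "mu_sh", "mu_sr", "mu2", "mu3", "mu4", "mu5",
  "nu2", "nu3", "q",
  "K1", "K2", "K3", "K4", "K5", "K6", "K_FA", "K_FR",
  "tau_h", "tau_r", "tau_H0", "tau_HL", "tau_R",
  "x_f", "F0"
)
.nonneg_fields <- c("nu1", "nu_e", "gamma", "eta", "t_warmup",
                    "her_tx_mult", "pfl_mult", "delta")
.hill_exponents <- c("n1", "n2", "n3", "n4", "n5", "n6", "nA", "nR")

#' Validate a parameter set
#'
#' Checks every structural invariant of the model and returns the violations
#' as data, not exceptions: an empty character vector means the set is
#' valid. Rules: strict positivity of rates, constants, delays and length
#' scales (production strengths `nu1`, `nu_e` and the scenario multipliers
#' may be zero, as the knockout scenarios require); Hill exponents at least
#' 1; `K_FA < K_FR` (the feedforward activation threshold sits below the
#' repression threshold); `1 <= tau_H0/tau_HL <= 7`;
#' `N == round(L/dx) + 1`; `0 < x_h < L`; `0 <= delta < x_E <= L`; `dt`
#' divides `dx/u` exactly (advection as an exact index shift); all delays
#' multiples of `dt`; a known `erk_mode`.
#'
#' @param p parameter set as from [default_parameters()].
#' @return character vector of violation descriptions (empty if valid).
#' @examples
#' validate_parameters(default_parameters())       # character(0)
#' p <- default_parameters(); p$K_FA <- p$K_FR
#' validate_parameters(p)
#' @export
validate_parameters <- function(p) {
  v <- character(0)
  num <- c(.positive_fields, .nonneg_fields, .hill_exponents,
           "N", "x_h", "x_E", "x_e0")
  miss <- setdiff(c(num, "erk_mode"), names(p))
  if (length(miss))
    return(paste0("missing field(s): ", paste(miss, collapse = ", ")))
  for (f in num)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]))
      v <- c(v, paste0(f, ": must be a single finite number"))
  if (length(v)) return(v)

  for (f in .positive_fields)
    if (p[[f]] <= 0) v <- c(v, paste0(f, ": must be strictly positive"))
  for (f in .nonneg_fields)
    if (p[[f]] < 0) v <- c(v, paste0(f, ": must be non-negative"))
  for (f in .hill_exponents)
    if (p[[f]] < 1) v <- c(v, paste0(f, ": Hill exponent must be >= 1"))

  if (!(p$K_FA < p$K_FR))
    v <- c(v, "K_FA: must satisfy K_FA < K_FR (feedforward activation below repression)")
  r <- p$tau_H0 / p$tau_HL
  if (!(r >= 1 && r <= 7))
    v <- c(v, sprintf("tau_H0: delay ratio tau_H0/tau_HL = %.3g outside [1, 7]", r))
  if (p$N != round(p$L / p$dx) + 1L)
    v <- c(v, sprintf("N: must equal round(L/dx) + 1 = %d", round(p$L / p$dx) + 1L))
  if (!(p$x_h > 0 && p$x_h < p$L))
    v <- c(v, "x_h: must lie strictly inside (0, L)")
  if (!(p$delta >= 0 && p$delta < p$x_E && p$x_E <= p$L))
    v <- c(v, "x_E: must satisfy 0 <= delta < x_E <= L")
  if (!(p$x_e0 >= p$x_E - p$delta && p$x_e0 <= p$x_E))
    v <- c(v, "x_e0: initial dpErk border must lie in [x_E - delta, x_E]")
  shift <- p$dx / p$u / p$dt
  if (abs(shift - round(shift)) > 1e-9)
    v <- c(v, "dt: must divide dx/u exactly (advection is an exact index shift)")
  for (f in c("tau_h", "tau_r", "tau_H0", "tau_HL", "tau_R")) {
    k <- p[[f]] / p$dt
    if (abs(k - round(k)) > 1e-9)
      v <- c(v, paste0(f, ": delay must be a multiple of dt (see normalize_delays)"))
  }
  if (!is.character(p$erk_mode) || !p$erk_mode %in% c("fixed", "stepwise"))
    v <- c(v, "erk_mode: must be \"fixed\" or \"stepwise\"")
  v
}

#' Scenario names understood by [apply_perturbation()]
#' @export
psm_scenarios <- function() {
  c("wild_type", "her_ko", "ripply_ko", "mek_inhibition", "no_pfl",
    "erk_stepwise")
}

#' Apply a mutant or perturbation scenario to a parameter set
#'
#' Returns a modified copy; the input is never mutated.
#'
#' * `wild_type`: identity.
#' * `her_ko`: zeroes the *her* transcription term (multiplier
#'   `her_tx_mult = 0`), leaving splicing and decay intact.
#' * `ripply_ko`: `nu1 = 0` (no *ripply* transcription).
#' * `mek_inhibition`: divides the dpErk plateau `nu_e` by 10.
#' * `no_pfl`: disables Tbx6 autoregulation (`pfl_mult = 0`), removing the
#'   bistability of the switch.
#' * `erk_stepwise`: stepwise posterior shifts of the dpErk border with
#'   `x_E = 200`, `delta = 60`, `x_e0 = 180` um.
#'
#' @param p a valid parameter set.
#' @param scenario one of [psm_scenarios()].
#' @return a `psm_params` object with attribute `"scenario"`.
#' @examples
#' apply_perturbation(default_parameters(), "ripply_ko")$nu1  # 0
#' @export
apply_perturbation <- function(p, scenario = psm_scenarios()) {
  scenario <- match.arg(scenario)
  q <- p
  switch(scenario,
    wild_type = NULL,
    her_ko = { q$her_tx_mult <- 0 },
    ripply_ko = { q$nu1 <- 0 },
    mek_inhibition = { q$nu_e <- p$nu_e / 10 },
    no_pfl = { q$pfl_mult <- 0 },
    erk_stepwise = {
      q$erk_mode <- "stepwise"; q$x_E <- 200; q$delta <- 60; q$x_e0 <- 180
    }
  )
  attr(q, "scenario") <- scenario
  q
}

#' @export
print.psm_params <- function(x, ...) {
  cat("PSM model parameters\n")
  cat(sprintf("  domain: L = %g um, dx = %g um, N = %d cells, u = %g um/min\n",
              x$L, x$dx, x$N, x$u))
  cat(sprintf("  integration: dt = %g min, warm-up %g min, clock period %g min\n",
              x$dt, x$t_warmup, x$T_clock))
  cat(sprintf("  delays (min): tau_h = %g, tau_r = %g, tau_H0 = %g, tau_HL = %g, tau_R = %g\n",
              x$tau_h, x$tau_r, x$tau_H0, x$tau_HL, x$tau_R))
  cat(sprintf("  Tbx6 switch: K6 = %g (n6 = %g), gamma = %g, eta = %g\n",
              x$K6, x$n6, x$gamma, x$eta))
  cat(sprintf("  dpErk: mode %s, nu_e = %g, border x_E = %g um\n",
              x$erk_mode, x$nu_e, x$x_E))
  sc <- attr(x, "scenario")
  if (!is.null(sc)) cat("  scenario:", sc, "\n")
  nv <- length(validate_parameters(x))
  if (nv) cat("  ** INVALID:", nv, "violation(s); see validate_parameters()\n")
  invisible(x)
}

#' Write a parameter set to a JSON configuration file
#'
#' One key per field, flat structure; an optional `scenario` key records the
#' preset applied. The file round-trips through [read_config()].
#'
#' @param p parameter set.
#' @param path file to write.
#' @param scenario optional scenario name stored alongside the parameters.
#' @export
write_config <- function(p, path, scenario = attr(p, "scenario")) {
  x <- unclass(p)
  attr(x, "scenario") <- NULL
  x$scenario <- scenario
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a parameter configuration file
#'
#' Reads a flat JSON configuration. Missing keys fall back to the
#' calibrated defaults (with a message); unknown keys are an error. The
#' merged set is validated and all violations are reported at once.
#'
#' @param path JSON file as written by [write_config()] (any subset of the
#'   fields of [default_parameters()], optionally a `scenario` key).
#' @param quiet suppress the fallback notice.
#' @return a validated `psm_params` object; the scenario (if any) is
#'   attached as attribute `"scenario"` and already applied via
#'   [apply_perturbation()].
#' @export
read_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario <- raw$scenario
  raw$scenario <- NULL
  base <- default_parameters()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(names(base), names(raw))
  if (length(missing) && !quiet && length(missing) < length(base))
    message("config: using defaults for ", paste(missing, collapse = ", "))
  p <- utils::modifyList(unclass(base), raw)
  class(p) <- "psm_params"
  p <- normalize_delays(p)
  v <- validate_parameters(p)
  if (length(v))
    stop("invalid configuration:\n  ", paste(v, collapse = "\n  "))
  if (!is.null(scenario)) p <- apply_perturbation(p, scenario)
  p
}
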