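# Equilibrium and bifurcation analysis of the Tbx6 switch. Steady states
# solve P(p_t) = D(p_t) where P is the S-shaped production curve
# (autoregulation + feedforward input) and D = (1 + eta * p_r) * p_t the
# Ripply-boosted linear degradation. For n6 = 2 and gamma-term off the
# saddle-node degradation factor has the closed form 1/(2*K6), which the
# tests use as an independent oracle.

#' Production and degradation curves of the Tbx6 switch
#'
#' Evaluates `P` (production) and `D` (degradation) on a grid of Tbx6
#' levels at a given signal level and Ripply level, i.e. the two curves
#' whose intersections are the steady states.
#'
#' @param p_t_grid ascending non-negative grid of Tbx6 levels.
#' @param F signal (Fgf) level.
#' @param p_r Ripply level.
#' @param p parameter set.
#' @return data frame with columns `p_t`, `P`, `D`.
#' @export
production_degradation_curves <- function(p_t_grid, F, p_r, p) {
  if (length(p_t_grid) == 0) stop("empty p_t grid")
  if (is.unsorted(p_t_grid) || any(p_t_grid < 0))
    stop("p_t_grid must be ascending and non-negative")
  data.frame(
    p_t = p_t_grid,
    P = tbx6_production(p_t_grid, F, p),
    D = (1 + p$eta * p_r) * p_t_grid
  )
}

#' Tbx6 steady states at one signal and Ripply level
#'
#' Finds all roots of `P(p_t) = D(p_t)` on `[0, p_max]` by a sign-change
#' scan with bisection refinement, and labels their stability from the sign
#' of `d(P - D)/dp_t` (negative slope = stable). Generically there are 1 or
#' 3 states and the stabilities alternate stable/unstable/stable. The scan
#' is repeated at twice the resolution; a differing root count raises an
#' error (resolution too coarse).
#'
#' @param F signal level.
#' @param p_r Ripply level.
#' @param p parameter set.
#' @param resolution number of scan points (default 1e4).
#' @param p_max upper end of the scan; defaults to `10 * (pfl_mult + gamma)`
#'   which bounds the production term, hence all roots.
#' @return object of class `psm_steady_states`: data frame with columns
#'   `p_t` and `stability` (`"stable"`, `"unstable"` or `"sn"` for a
#'   tangency), sorted ascending, with `F` and `p_r` as attributes.
#' @examples
#' ss <- find_steady_states(F = 0, p_r = 0, p = default_parameters())
#' ss$p_t   # 0, 0.2, 0.8 for K6 = 0.4, n6 = 2
#' @export
find_steady_states <- function(F, p_r, p, resolution = 1e4, p_max = NULL) {
  if (F < 0 || p_r < 0) stop("F and p_r must be non-negative")
  if (is.null(p_max)) p_max <- 10 * (p$pfl_mult + p$gamma)
  h <- function(pt) tbx6_production(pt, F, p) - (1 + p$eta * p_r) * pt
  roots_at <- function(n) {
    grid <- seq(0, p_max, length.out = n)
    hv <- h(grid)
    roots <- numeric(0)
    if (hv[1] == 0) roots <- c(roots, 0)
    sgn <- sign(hv)
    # treat exact zeros on the grid interior as roots
    iz <- which(sgn[-1] == 0 & sgn[-length(sgn)] != 0)
    roots <- c(roots, grid[iz + 1])
    ic <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (i in ic) {
      r <- stats::uniroot(h, lower = grid[i], upper = grid[i + 1],
                          tol = 1e-12)
      roots <- c(roots, r$root)
    }
    sort(unique(roots))
  }
  res <- resolution
  for (try in 1:4) {
    r1 <- roots_at(res)
    r2 <- roots_at(2 * res)
    if (length(r1) == length(r2)) break
    res <- res * 4   # near-tangent root pairs need a finer scan
  }
  if (length(r1) != length(r2))
    stop(sprintf("root count differs between scan resolutions (%d vs %d): increase resolution",
                 length(r1), length(r2)))
  eps <- max(1e-8, 1e-6 * p_max)
  slope <- (h(pmin(r2 + eps, p_max + eps)) - h(pmax(r2 - eps, 0))) / (2 * eps)
  stability <- ifelse(abs(slope) < 1e-6, "sn",
                      ifelse(slope < 0, "stable", "unstable"))
  structure(
    data.frame(p_t = r2, stability = stability),
    F = F, p_r = p_r, class = c("psm_steady_states", "data.frame")
  )
}

#' Saddle-node threshold of the Ripply-boosted degradation factor
#'
#' Smallest degradation factor `d = 1 + eta * p_r` at which the upper
#' stable Tbx6 state and the unstable state collide and vanish (root count
#' drops from 3 to 1), found by bisection on the factor. If the switch is
#' not bistable at factor 1, returns 1 with attribute `bistable = FALSE`.
#' For `n6 = 2` and the feedforward term absent the exact value is
#' `1/(2*K6)`.
#'
#' @param F signal level (sets the feedforward production offset).
#' @param p parameter set.
#' @param tol relative bisection tolerance on the factor.
#' @return the critical factor, with attribute `bistable`.
#' @examples
#' sn_degradation_threshold(0, default_parameters(gamma = 0))  # 1.25
#' @export
sn_degradation_threshold <- function(F, p, tol = 1e-7) {
  nroots <- function(d) {
    pr_eq <- (d - 1) / p$eta
    nrow(find_steady_states(F, pr_eq, p))
  }
  if (nroots(1) < 3)
    return(structure(1, bistable = FALSE))
  d_lo <- 1
  d_hi <- 2
  while (nroots(d_hi) >= 3) {
    d_lo <- d_hi
    d_hi <- d_hi * 2
    if (d_hi > 1e6) stop("no saddle-node found below degradation factor 1e6")
  }
  while ((d_hi - d_lo) > tol * d_hi) {
    mid <- (d_lo + d_hi) / 2
    if (nroots(mid) >= 3) d_lo <- mid else d_hi <- mid
  }
  structure((d_lo + d_hi) / 2, bistable = TRUE)
}

#' Spatial bifurcation structure along the axis
#'
#' Computes the Tbx6 steady states at every grid position, with the signal
#' level from the Fgf gradient and Ripply from a supplied spatial profile.
#' With `p_r = 0` everywhere, the anterior PSM and the tailbud are bistable
#' (newly added tailbud cells occupy the low branch) while the feedforward
#' input makes the mid PSM monostable-high — this is what drives cells up
#' the switch as they leave the tailbud. A Ripply peak above the local
#' saddle-node threshold removes the high state at that position.
#'
#' @param p parameter set.
#' @param p_r_profile Ripply level per cell (length `N`), default all zero.
#' @return data frame with one row per steady state: `x`, `F`, `p_r`,
#'   `p_t`, `stability`.
#' @export
bifurcation_along_axis <- function(p, p_r_profile = rep(0, p$N)) {
  if (length(p_r_profile) != p$N)
    stop("p_r_profile must have one value per cell (length N)")
  x <- seq(0, p$L, by = p$dx)
  out <- lapply(seq_along(x), function(i) {
    ss <- find_steady_states(fgf_gradient(x[i], p), p_r_profile[i], p)
    data.frame(x = x[i], F = attr(ss, "F"), p_r = p_r_profile[i],
               p_t = ss$p_t, stability = ss$stability)
  })
  do.call(rbind, out)
}

#' Boundary-formation phase diagram
#'
#' For every combination of the positive-feedback strength (`K6`) and the
#' Ripply translation rate (`nu3`, which sets the attainable degradation
#' boost), runs the wild-type tissue simulation past warm-up and classifies
#' whether a persistent anterior Tbx6 boundary forms within one
#' segmentation cycle, i.e. before the Ripply wave has travelled one somite
#' (6 cells). The achieved maximal degradation factor
#' `1 + eta * max(p_r)` near the dpErk border is recorded as the
#' y-coordinate, and the saddle-node curve from
#' [sn_degradation_threshold()] is overlaid.
#'
#' @param p base parameter set (wild type).
#' @param K6_values,v3_values grids (log-spaced recommended).
#' @param t_end recorded window per point, min; default two clock periods
#'   so persistence over one full period can be assessed.
#' @param verbose print progress.
#' @return object of class `psm_phase_diagram`: data frame with columns
#'   `K6`, `nu3`, `factor` (achieved max degradation factor), `outcome`
#'   (`"boundary_formed"`/`"failed"`), `error` (simulation failure message
#'   or NA), plus the SN curve in attribute `"sn_curve"`.
#' @export
phase_diagram <- function(p, K6_values, v3_values, t_end = NULL,
                          verbose = FALSE) {
  if (is.null(t_end)) t_end <- 2 * p$T_clock
  grid <- expand.grid(K6 = K6_values, nu3 = v3_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    q <- p; q$K6 <- grid$K6[i]; q$nu3 <- grid$nu3[i]
    row <- data.frame(K6 = q$K6, nu3 = q$nu3, factor = NA_real_,
                      outcome = "failed", error = NA_character_,
                      stringsAsFactors = FALSE)
    sim <- tryCatch(simulate_psm(q, "wild_type", t_end = t_end),
                    error = function(e) e)
    if (inherits(sim, "error")) {
      row$error <- conditionMessage(sim)
      return(row)
    }
    # achieved degradation boost near the dpErk border (within one somite
    # anterior of it)
    near <- sim$x >= p$x_E - 6 * p$dx & sim$x <= p$x_E + p$dx
    row$factor <- 1 + q$eta * max(sim$p_r[, near])
    b <- tryCatch(
      detect_tbx6_boundaries(sim, persist_min = p$T_clock),
      error = function(e) NULL)
    if (!is.null(b) && any(b$persistent & b$time <= p$T_clock))
      row$outcome <- "boundary_formed"
    if (verbose)
      message(sprintf("K6 = %.3g, nu3 = %.3g: factor %.3g -> %s",
                      q$K6, q$nu3, row$factor, row$outcome))
    row
  })
  out <- do.call(rbind, res)
  sn <- vapply(K6_values, function(k6) {
    q <- p; q$K6 <- k6
    as.numeric(sn_degradation_threshold(0, q))
  }, numeric(1))
  attr(out, "sn_curve") <- data.frame(K6 = K6_values, factor = sn)
  class(out) <- c("psm_phase_diagram", "data.frame")
  out
}

#' @export
plot.psm_phase_diagram <- function(x, ...) {
  formed <- x$outcome == "boundary_formed"
  graphics::plot(x$K6, x$factor, log = "xy",
                 pch = ifelse(formed, 1, 4),
                 col = ifelse(formed, "blue", "red"),
                 xlab = "K6 (PFL strength; smaller = stronger)",
                 ylab = "max degradation factor 1 + eta * p_r", ...)
  sn <- attr(x, "sn_curve")
  graphics::lines(sn$K6, sn$factor, lwd = 2)
  graphics::legend("topright", c("boundary formed", "failed", "SN threshold"),
                   pch = c(1, 4, NA), lty = c(NA, NA, 1),
                   col = c("blue", "red", "black"), bty = "n")
  invisible(x)
}

#' Single-cell her oscillation scan over fixed Tbx6 levels
#'
#' Integrates the single-cell *her* subsystem (nascent and mature mRNA plus
#' protein) in the anterior regime, where transcription requires Tbx6, at a
#' series of constant Tbx6 levels and a constant translational delay
#' (default `tau_H = 7.45` min, the value near the anterior Tbx6 border).
#' After discarding a transient, reports the steady oscillation amplitude
#' (max - min of Her protein) and the mean peak-to-peak period; amplitude
#' (numerically) zero marks oscillation arrest.
#'
#' @param p_t_values Tbx6 levels to scan.
#' @param p parameter set.
#' @param tau_H fixed translational delay, min.
#' @param t_end integration time per level, min.
#' @param discard transient discarded before measuring, min.
#' @param amp_tol amplitude below which the cell counts as arrested.
#' @return data frame with columns `p_t`, `amplitude`, `period` (NA when
#'   arrested), `oscillating`.
#' @export
her_oscillation_scan <- function(p_t_values, p, tau_H = 7.45,
                                 t_end = 400, discard = 200,
                                 amp_tol = 1e-3) {
  tau_H <- round(tau_H / p$dt) * p$dt
  res <- lapply(p_t_values, function(pt) {
    if (pt < 0) stop("p_t must be non-negative")
    gate <- hill_act(pt, p$K2, p$n2)
    ph <- her_cell_cpp(unclass(p), gate, tau_H, t_end, p$dt * 10)
    keep <- ph[-seq_len(round(discard / (p$dt * 10)))]
    amp <- max(keep) - min(keep)
    per <- NA_real_
    if (amp > amp_tol) {
      pk <- find_peaks(keep, min_prom = 0.2 * amp)
      if (length(pk) >= 3) per <- mean(diff(pk)) * p$dt * 10
      else stop(sprintf("transient not settled at p_t = %g: fewer than 3 peaks", pt))
    }
    data.frame(p_t = pt, amplitude = amp, period = per,
               oscillating = amp > amp_tol)
  })
  do.call(rbind, res)
}

#' Single-cell Tbx6 response to a transient Ripply pulse
#'
#' Integrates the (delay-free) single-cell Tbx6 equation at a fixed signal
#' level under a prescribed square Ripply pulse and reports the trajectory.
#' Demonstrates the hysteresis of the switch: a pulse whose degradation
#' factor exceeds the saddle-node threshold drops the cell to the low state
#' permanently; a sub-threshold pulse lets it return to the high state.
#'
#' @param p parameter set.
#' @param F signal level.
#' @param factor degradation factor `1 + eta * p_r` during the pulse.
#' @param t_on,t_off pulse start and end, min.
#' @param t_end total integration, min.
#' @param p_t0 initial Tbx6 level (default: the upper stable state).
#' @return data frame with columns `t`, `p_r`, `p_t`.
#' @export
tbx6_pulse_response <- function(p, F = 0, factor = 2, t_on = 20, t_off = 40,
                                t_end = 160, p_t0 = NULL) {
  if (is.null(p_t0)) {
    ss <- find_steady_states(F, 0, p)
    st <- ss$p_t[ss$stability == "stable"]
    p_t0 <- max(st)
  }
  pr_pulse <- (factor - 1) / p$eta
  n <- round(t_end / p$dt)
  tt <- seq_len(n) * p$dt
  pt <- numeric(n)
  cur <- p_t0
  pr <- ifelse(tt >= t_on & tt < t_off, pr_pulse, 0)
  for (i in seq_len(n)) {
    cur <- cur + p$dt * p$mu3 * tbx6_rhs(cur, pr[i], F, p)
    if (cur < 0) cur <- 0
    pt[i] <- cur
  }
  data.frame(t = tt, p_r = pr, p_t = pt)
}
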