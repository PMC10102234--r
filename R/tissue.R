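# Geometry and prescribed fields of the moving 1-D PSM, plus a pure-R
# tissue state with per-cell delay histories. The R stepper here is the
# reference implementation against which the compiled integrator is
# checked; production runs go through simulate_psm().

#' Fgf signalling gradient
#'
#' `F(x) = F0 * exp(-(L - x) / x_f)`: maximal at the tailbud tip `x = L`,
#' decaying anteriorly with length scale `x_f`. The gradient is static in
#' the tailbud reference frame.
#'
#' @param x position(s) in `[0, L]`, um.
#' @param p parameter set.
#' @return signal level(s), non-negative.
#' @export
fgf_gradient <- function(x, p) {
  if (any(x < 0 | x > p$L)) stop("x outside the domain [0, L]")
  p$F0 * exp(-(p$L - x) / p$x_f)
}

#' Anterior border of the dpErk domain
#'
#' In `fixed` mode the border sits at `x_E` for all times. In `stepwise`
#' mode it is fixed in the lab frame between resets, i.e. it recedes at the
#' advection speed `u` in the tailbud frame from its current anchor, and
#' jumps back to `x_E` once it has travelled `delta`; the initial border is
#' `x_e0`. The resulting tailbud-frame trajectory is a sawtooth with period
#' `delta / u`.
#'
#' @param t time(s), min (0 = start of the simulation, i.e. start of
#'   warm-up).
#' @param p parameter set.
#' @return border position(s) in `[x_E - delta, x_E]`, um.
#' @export
dperk_border <- function(t, p) {
  if (identical(p$erk_mode, "fixed") || p$delta == 0) return(rep(p$x_E, length(t)))
  # distance travelled since the (virtual) last reset before t = 0
  d0 <- p$x_E - p$x_e0
  d <- (d0 + p$u * t) %% p$delta
  p$x_E - d
}

#' dpErk profile
#'
#' Zero anterior of the moving border `x_e(t)`, rising as
#' `nu_e * (1 - exp(-q * (x - x_e(t))))` at and posterior of it. The
#' profile is prescribed (no differential equation) and is resampled onto
#' the cells at every step.
#'
#' @param x position(s) in `[0, L]`, um.
#' @param t time, min (see [dperk_border()]).
#' @param p parameter set.
#' @param xe optional border override (used by the integrator, which tracks
#'   the border incrementally).
#' @return dpErk level(s), non-negative, non-decreasing in `x`.
#' @export
dperk_profile <- function(x, t = 0, p, xe = NULL) {
  if (any(x < 0 | x > p$L)) stop("x outside the domain [0, L]")
  if (is.null(xe)) xe <- dperk_border(t, p)
  ifelse(x < xe, 0, p$nu_e * (1 - exp(-p$q * (x - xe))))
}

#' Tailbud/lab frame conversion
#'
#' The tailbud tip moves posteriorly at speed `u` in the lab frame, so a
#' tailbud-frame position maps to `x_lab = x_tailbud + u * t`. Cells are
#' static in the lab frame: their tailbud-frame advection at speed `-u`
#' cancels the frame motion.
#'
#' @param x position(s), um.
#' @param t time(s), min.
#' @param p parameter set.
#' @return converted position(s), um.
#' @export
to_lab_frame <- function(x, t, p) x + p$u * t

#' @rdname to_lab_frame
#' @export
from_lab_frame <- function(x, t, p) x - p$u * t

# ---- tissue state (reference R implementation) -----------------------------

.hist_vars <- c("p_h", "p_t", "p_e", "M_h", "M_r")

.delay_steps <- function(p) {
  # nearest step, ties away from zero (matches the compiled integrator)
  rnd <- function(x) floor(x / p$dt + 0.5)
  ks <- list(
    h = rnd(p$tau_h), r = rnd(p$tau_r), R = rnd(p$tau_R),
    H = rnd(her_translation_delay(seq(0, p$L, p$dx), p))
  )
  ks$horizon <- max(ks$h, ks$r, ks$R, ks$H)
  ks
}

#' Initialise the tissue with the prescribed history
#'
#' All cells start with `m_h = M_h = 1`, `m_r = M_r = 0`,
#' `p_h = nu2 / mu4`, `p_r = 0` throughout the initial history window
#' `[-max(tau_h, tau_r, tau_H0, tau_R), 0]`; Tbx6 starts high (`p_t = 1`)
#' for `x <= x_h` and low (0) posterior of it; dpErk is set from its
#' prescribed profile at the initial border.
#'
#' @param p a valid parameter set.
#' @return an object of class `psm_tissue`: cell positions, the eight
#'   per-cell state variables, ring-buffer delay histories and bookkeeping
#'   counters.
#' @export
initialize_tissue <- function(p) {
  v <- validate_parameters(p)
  if (length(v)) stop("invalid parameters:\n  ", paste(v, collapse = "\n  "))
  x <- seq(0, p$L, by = p$dx)
  N <- p$N
  ks <- .delay_steps(p)
  H <- ks$horizon + 1L
  xe0 <- if (identical(p$erk_mode, "stepwise")) p$x_e0 else p$x_E
  state <- list(
    m_h = rep(1, N), M_h = rep(1, N),
    m_r = rep(0, N), M_r = rep(0, N),
    p_h = rep(p$nu2 / p$mu4, N), p_r = rep(0, N),
    p_t = ifelse(x <= p$x_h, 1, 0),
    p_e = dperk_profile(x, p = p, xe = xe0)
  )
  hist <- lapply(.hist_vars, function(v)
    matrix(rep(state[[v]], each = H), nrow = H, ncol = N))
  names(hist) <- .hist_vars
  structure(list(
    t = 0, step = 0L, x = x, state = state, hist = hist, H = H, ks = ks,
    xe = xe0, clamped = 0L, shifts = 0L, params = p
  ), class = "psm_tissue")
}

#' Look up a delayed per-cell sample
#'
#' Exact ring-buffer lookup of a stored variable `tau` minutes ago, where
#' `tau` must be a multiple of `dt` within the history horizon. During the
#' initial window the prescribed initial history is returned (the buffers
#' are pre-filled with it).
#'
#' @param tissue a `psm_tissue`.
#' @param var one of `"p_h"`, `"p_t"`, `"p_e"`, `"M_h"`, `"M_r"`.
#' @param tau delay, min; either a scalar or one value per cell.
#' @return the per-cell values at `t - tau`.
#' @export
history_lookup <- function(tissue, var, tau) {
  var <- match.arg(var, .hist_vars)
  k <- round(tau / tissue$params$dt)
  if (any(abs(tau / tissue$params$dt - k) > 1e-9))
    stop("tau must be a multiple of dt")
  if (any(k < 0) || any(k > tissue$H - 1L))
    stop(sprintf("tau beyond the history horizon of %g min",
                 (tissue$H - 1L) * tissue$params$dt))
  rows <- ((tissue$step - k) %% tissue$H) + 1L
  m <- tissue$hist[[var]]
  if (length(rows) == 1L) m[rows, ] else m[cbind(rows, seq_len(ncol(m)))]
}

#' Advect the cell array by one cell
#'
#' Shifts every cell one grid index anteriorly, removes the cell at
#' `x = 0`, and appends a new posterior cell at `x = L` that copies the
#' concentration variables *and the entire delay history* of its nearest
#' anterior neighbour. Must be called on schedule, i.e. when the simulated
#' time is a multiple of `dx/u`; the cell count is conserved exactly.
#'
#' @param tissue a `psm_tissue`.
#' @return the advected `psm_tissue`.
#' @export
advance_cells <- function(tissue) {
  p <- tissue$params
  sched <- p$dx / p$u
  if (abs(tissue$t / sched - round(tissue$t / sched)) > 1e-9)
    stop(sprintf("advance_cells called off-schedule at t = %g (schedule every %g min)",
                 tissue$t, sched))
  N <- p$N
  idx <- c(2:N, N)           # shift left; new posterior cell copies old last
  tissue$state <- lapply(tissue$state, function(v) v[idx])
  tissue$hist <- lapply(tissue$hist, function(m) m[, idx, drop = FALSE])
  tissue$shifts <- tissue$shifts + 1L
  tissue
}

#' One explicit-Euler step of the full delayed system (reference R engine)
#'
#' Updates the seven integrated variables of every cell from the delayed
#' terms, refreshes the prescribed dpErk field, appends the history
#' buffers, and applies advection when the schedule says so. This is the
#' reference implementation used to validate the compiled integrator; it
#' performs the identical operations in the identical order.
#'
#' @param tissue a `psm_tissue`.
#' @return the advanced `psm_tissue`.
#' @export
step_tissue <- function(tissue) {
  p <- tissue$params
  s <- tissue$step
  x <- tissue$x
  st <- tissue$state
  ks <- tissue$ks
  ph_h <- history_lookup(tissue, "p_h", p$tau_h)
  pt_h <- history_lookup(tissue, "p_t", p$tau_h)
  ph_r <- history_lookup(tissue, "p_h", p$tau_r)
  pt_r <- history_lookup(tissue, "p_t", p$tau_r)
  pe_r <- history_lookup(tissue, "p_e", p$tau_r)
  Mh_H <- history_lookup(tissue, "M_h", ks$H * p$dt)
  Mr_R <- history_lookup(tissue, "M_r", p$tau_R)
  Fx <- fgf_gradient(x, p)

  tx_h <- p$her_tx_mult * her_transcription(ph_h, pt_h, x, p)
  d <- list(
    m_h = p$mu1 * (tx_h - p$mu_sh * st$m_h),
    M_h = p$mu1 * mature_mrna_rhs(st$m_h, st$M_h, p$mu_sh, 1),
    p_h = p$mu3 * protein_rhs(Mh_H, st$p_h, p$nu2, p$mu4),
    m_r = p$mu1 * (ripply_transcription(ph_r, pe_r, pt_r, p) - p$mu_sr * st$m_r),
    M_r = p$mu1 * mature_mrna_rhs(st$m_r, st$M_r, p$mu_sr, p$mu2),
    p_r = p$mu3 * protein_rhs(Mr_R, st$p_r, p$nu3, p$mu5),
    p_t = p$mu3 * tbx6_rhs(st$p_t, st$p_r, Fx, p)
  )
  for (v in names(d)) {
    new <- st[[v]] + p$dt * d[[v]]
    neg <- new < 0
    if (any(neg)) {
      if (any(new < -1e-9))
        stop(sprintf("state went negative beyond tolerance: %s, cell %d, t = %g",
                     v, which.min(new), tissue$t))
      tissue$clamped <- tissue$clamped + sum(neg)
      new[neg] <- 0
    }
    st[[v]] <- new
  }
  s <- s + 1L
  t1 <- s * p$dt
  if (identical(p$erk_mode, "stepwise")) {
    xe <- tissue$xe - p$u * p$dt
    if (xe <= p$x_E - p$delta + 1e-9) xe <- p$x_E
    tissue$xe <- xe
  }
  st$p_e <- dperk_profile(x, p = p, xe = tissue$xe)
  tissue$state <- st
  tissue$step <- s
  tissue$t <- t1
  row <- (s %% tissue$H) + 1L
  for (v in .hist_vars) tissue$hist[[v]][row, ] <- st[[v]]
  shift_every <- round(p$dx / p$u / p$dt)
  if (s %% shift_every == 0L) tissue <- advance_cells(tissue)
  tissue
}
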