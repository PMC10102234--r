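# Scenario runs: warm-up, clock reset, recording. The compiled engine does
# the work; engine = "r" runs the reference R stepper (identical operations,
# used for validation and only sensible for short horizons).

.psm_vars <- c("m_h", "M_h", "m_r", "M_r", "p_h", "p_r", "p_t", "p_e")

#' Run the PSM model
#'
#' Applies a scenario to the parameter set, integrates the delay
#' differential equations through the warm-up period (by default
#' `t_warmup = 460` min, enough for the spatio-temporal pattern to become
#' regular), resets the clock to 0, then records snapshots of all eight
#' variables every `record_every` minutes until `t_end`.
#'
#' The integrator is the explicit Euler method at `dt = 0.01` min with
#' per-cell ring-buffer delay histories and advection realised as an exact
#' one-index shift every `dx/u` minutes. Euler excursions below zero are
#' clamped to 0 and counted (`$clamped`); excursions below `-1e-9` abort.
#' The run is fully deterministic.
#'
#' @param p parameter set, see [default_parameters()].
#' @param scenario one of [psm_scenarios()]; applied via
#'   [apply_perturbation()] before the run.
#' @param t_end recorded duration after the warm-up, min.
#' @param record_every snapshot interval, min (a multiple of `dt`).
#' @param t_warmup override of `p$t_warmup`, min.
#' @param engine `"cpp"` (default) or `"r"` (reference stepper; slow).
#' @return An object of class `psm_sim`: `times` (min, clock reset at the
#'   end of warm-up), `x` (tailbud-frame cell grid, um), one
#'   `length(times) x N` matrix per variable, the dpErk border trajectory
#'   `xe`, clamp and advection counters, the applied parameter snapshot and
#'   scenario name, and `frame = "tailbud"`.
#' @examples
#' \donttest{
#' p <- default_parameters()
#' sim <- simulate_psm(p, "wild_type", t_end = 60)
#' summary(sim)
#' }
#' @export
simulate_psm <- function(p = default_parameters(),
                         scenario = "wild_type",
                         t_end = 150, record_every = 1,
                         t_warmup = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  v <- validate_parameters(p)
  if (length(v)) stop("invalid parameters:\n  ", paste(v, collapse = "\n  "))
  p <- apply_perturbation(p, scenario)
  if (!is.null(t_warmup)) p$t_warmup <- t_warmup
  if (t_end <= 0) stop("t_end must be positive")
  k <- record_every / p$dt
  if (abs(k - round(k)) > 1e-9) stop("record_every must be a multiple of dt")

  if (engine == "cpp") {
    raw <- psm_simulate_cpp(unclass(p), t_end, record_every)
  } else {
    raw <- .simulate_r(p, t_end, record_every)
  }
  out <- list(
    times = as.numeric(raw$times), x = seq(0, p$L, by = p$dx),
    xe = as.numeric(raw$xe),
    clamped = raw$clamped, shifts = raw$shifts,
    params = p, scenario = scenario, frame = "tailbud",
    record_every = record_every, t_end = t_end
  )
  for (v in .psm_vars) {
    m <- raw[[v]]
    dimnames(m) <- NULL
    out[[v]] <- m
  }
  class(out) <- "psm_sim"
  out
}

.simulate_r <- function(p, t_end, record_every) {
  tis <- initialize_tissue(p)
  warm_steps <- round(p$t_warmup / p$dt)
  run_steps <- round(t_end / p$dt)
  rec_steps <- round(record_every / p$dt)
  nrec <- run_steps %/% rec_steps + 1L
  mats <- lapply(.psm_vars, function(v) matrix(NA_real_, nrec, p$N))
  names(mats) <- .psm_vars
  times <- numeric(nrec); xe <- numeric(nrec)
  irec <- 0L
  rec <- function(s) {
    irec <<- irec + 1L
    for (v in .psm_vars) mats[[v]][irec, ] <<- tis$state[[v]]
    times[irec] <<- (s - warm_steps) * p$dt
    xe[irec] <<- tis$xe
  }
  if (warm_steps == 0L) rec(0L)
  total <- warm_steps + run_steps
  for (s in seq_len(total)) {
    tis <- step_tissue(tis)
    if (s >= warm_steps && (s - warm_steps) %% rec_steps == 0L && irec < nrec)
      rec(s)
  }
  c(mats, list(times = times, xe = xe, clamped = tis$clamped,
               shifts = tis$shifts))
}

#' @export
print.psm_sim <- function(x, ...) {
  cat(sprintf("PSM simulation: scenario \"%s\", %d cells, %d snapshots (%g..%g min every %g min)\n",
              x$scenario, ncol(x$p_t), length(x$times),
              min(x$times), max(x$times), x$record_every))
  cat(sprintf("  frame: %s; advection events: %g; negative-Euler clamps: %g\n",
              x$frame, x$shifts, x$clamped))
  invisible(x)
}

#' @export
summary.psm_sim <- function(object, ...) {
  rng <- t(vapply(.psm_vars, function(v) range(object[[v]]), numeric(2)))
  colnames(rng) <- c("min", "max")
  b <- tryCatch(detect_tbx6_boundaries(object), error = function(e) NULL)
  structure(list(sim = object, ranges = rng, boundaries = b),
            class = "summary.psm_sim")
}

#' @export
print.summary.psm_sim <- function(x, ...) {
  print(x$sim)
  cat("  variable ranges:\n")
  print(round(x$ranges, 4))
  if (!is.null(x$boundaries) && nrow(x$boundaries) > 1) {
    sp <- somite_spacing(x$boundaries, x$sim$params)
    cat(sprintf("  Tbx6 boundary events: %d; mean spacing %.2f cells\n",
                nrow(x$boundaries), sp$mean_cells))
  } else {
    cat("  Tbx6 boundary events: ",
        if (is.null(x$boundaries)) 0 else nrow(x$boundaries), "\n", sep = "")
  }
  invisible(x)
}

#' Snapshot plot of a simulation
#'
#' Draws the spatial profiles of the requested variables at one recorded
#' time, in the tailbud frame (anterior left).
#'
#' @param x a `psm_sim`.
#' @param t snapshot time, min (nearest recorded time is used).
#' @param vars variables to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.psm_sim <- function(x, t = max(x$times),
                         vars = c("p_t", "p_h", "p_r", "m_r", "p_e"), ...) {
  i <- which.min(abs(x$times - t))
  y <- sapply(vars, function(v) x[[v]][i, ])
  graphics::matplot(x$x, y, type = "l", lty = 1, lwd = 2,
                    xlab = "position in tailbud frame (um)",
                    ylab = "level (dimensionless)",
                    main = sprintf("%s, t = %g min", x$scenario, x$times[i]),
                    ...)
  graphics::legend("topleft", legend = vars, col = seq_along(vars),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Simulate method for parameter sets
#'
#' Convenience wrapper so that `simulate(default_parameters())` runs the
#' model; the model is deterministic, so `nsim` and `seed` are ignored.
#'
#' @param object a `psm_params` object.
#' @param nsim,seed ignored (deterministic model).
#' @param ... passed to [simulate_psm()].
#' @export
simulate.psm_params <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_psm(object, ...)
}
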