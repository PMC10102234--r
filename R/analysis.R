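# Quantification of simulated (or synthetic) spatio-temporal patterns:
# Tbx6 boundary events, somite spacing, kymographs in either reference
# frame, oscillation period profiles, wave arrest and expression-domain
# extents. Detectors are validated against the ground-truth fixtures of
# generate_fixture().

#' Simple peak finder with a prominence threshold
#'
#' Local maxima whose prominence (height above the deeper of the two
#' flanking valleys, walking outwards until a higher sample) reaches
#' `min_prom`.
#'
#' @param y numeric series (NAs allowed at the ends).
#' @param min_prom minimal prominence.
#' @return integer indices of the peaks.
#' @export
find_peaks <- function(y, min_prom = 0) {
  ok <- !is.na(y)
  if (sum(ok) < 3) return(integer(0))
  off <- which(ok)[1] - 1L
  y <- y[ok]
  n <- length(y)
  s <- sign(diff(y))
  # carry the previous non-zero slope through plateaus so a flat-topped
  # peak yields a single candidate (its last plateau sample)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  cand <- which(diff(s) < 0) + 1L
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    k <- cand[i]
    lmin <- min(y[max(1, {
      j <- k; while (j > 1 && y[j] <= y[k]) j <- j - 1; j
    }):k])
    rmin <- min(y[k:min(n, {
      j <- k; while (j < n && y[j] <= y[k]) j <- j + 1; j
    })])
    keep[i] <- (y[k] - max(lmin, rmin)) >= min_prom
  }
  cand[keep] + off
}

#' Threshold separating low and high Tbx6 states
#'
#' Midpoint of the low and high stable Tbx6 steady states in the bistable
#' (anterior, low-signal) regime, computed from the parameter set rather
#' than hard-coded; falls back to half the maximal production if the switch
#' is not bistable.
#'
#' @param p parameter set.
#' @return a single level.
#' @export
tbx6_threshold <- function(p) {
  ss <- tryCatch(find_steady_states(0, 0, p), error = function(e) NULL)
  if (!is.null(ss)) {
    st <- ss$p_t[ss$stability == "stable"]
    if (length(st) >= 2) return((min(st) + max(st)) / 2)
  }
  (p$pfl_mult + p$gamma) / 2
}

# anteriormost upward crossing of `thr` in one snapshot; linear
# interpolation between grid points; 0 if the profile starts high, NA if it
# never reaches thr
.anterior_border <- function(prof, x, thr) {
  if (prof[1] >= thr) return(x[1])
  above <- prof >= thr
  i <- which(!above[-length(above)] & above[-1])
  if (!length(i)) return(NA_real_)
  i <- i[1]
  x[i] + (thr - prof[i]) / (prof[i + 1] - prof[i]) * (x[i + 1] - x[i])
}

#' Instantaneous anterior Tbx6 border trajectory
#'
#' Per recorded snapshot, the anteriormost upward crossing of Tbx6 through
#' the threshold, in both frames. The border drifts anteriorly with the
#' cells (lab-static) between boundary-formation events and jumps
#' posteriorly by one somite at each event.
#'
#' @param sim a `psm_sim` containing `p_t`.
#' @param threshold border level; default [tbx6_threshold()].
#' @return data frame with columns `time`, `tailbud`, `lab` (um; NA when
#'   the profile never crosses the threshold).
#' @export
tbx6_border_trajectory <- function(sim, threshold = NULL) {
  if (is.null(sim$p_t)) stop("simulation output does not contain p_t")
  p <- sim$params
  if (is.null(threshold)) threshold <- tbx6_threshold(p)
  btb <- vapply(seq_along(sim$times), function(i)
    .anterior_border(sim$p_t[i, ], sim$x, threshold), numeric(1))
  data.frame(time = sim$times, tailbud = btb,
             lab = to_lab_frame(btb, sim$times, p))
}

#' Detect anterior Tbx6 boundary-formation events
#'
#' Tracks, per snapshot, the anteriormost upward crossing of Tbx6 through
#' the midpoint of its low and high stable levels, converts it to the lab
#' frame, and records a new boundary whenever the border jumps posteriorly
#' by at least `min_jump_cells` cells between snapshots. Each event's
#' persistence is the time the new border then stays put (within one cell)
#' before it recovers anteriorly; an event is `persistent` if that duration
#' reaches `persist_min` (default one clock period) or lasts until the next
#' boundary-formation jump or the end of the record.
#'
#' @param sim a `psm_sim` containing `p_t` (tailbud frame).
#' @param threshold border level; default [tbx6_threshold()].
#' @param min_jump_cells posterior jump, in cells, that signals a new
#'   boundary rather than within-cycle erosion.
#' @param persist_min persistence required to call a boundary persistent,
#'   min.
#' @return data frame of class `psm_boundaries`: `time` (min), `position`
#'   (lab frame, um), `position_tailbud` (um), `spacing_cells` (to the
#'   previous boundary; NA for the first), `persistence` (min),
#'   `persistent` (logical), sorted by time.
#' @export
detect_tbx6_boundaries <- function(sim, threshold = NULL,
                                   min_jump_cells = 2, persist_min = NULL) {
  if (is.null(sim$p_t)) stop("simulation output does not contain p_t")
  p <- sim$params
  if (is.null(persist_min)) persist_min <- p$T_clock
  traj <- tbx6_border_trajectory(sim, threshold)
  tt <- traj$time
  btb <- traj$tailbud
  blab <- traj$lab
  jump <- which(diff(blab) >= min_jump_cells * p$dx & !is.na(diff(blab))) + 1L
  if (!length(jump))
    return(structure(data.frame(time = numeric(0), position = numeric(0),
                                position_tailbud = numeric(0),
                                spacing_cells = numeric(0),
                                persistence = numeric(0),
                                persistent = logical(0)),
                     class = c("psm_boundaries", "data.frame")))
  rec <- lapply(seq_along(jump), function(k) {
    i <- jump[k]
    pos <- blab[i]
    # the boundary persists until the border recovers anterior of it by
    # more than one cell (further posterior progression is the next
    # somite's business, not a failure of this boundary)
    later <- blab[seq(i, length(tt))]
    back <- which(!is.na(later) & later < pos - p$dx)
    dur <- if (length(back)) tt[i + back[1] - 1] - tt[i] else tt[length(tt)] - tt[i]
    data.frame(time = tt[i], position = pos, position_tailbud = btb[i],
               spacing_cells = NA_real_, persistence = dur,
               persistent = dur >= persist_min)
  })
  out <- do.call(rbind, rec)
  if (nrow(out) > 1)
    out$spacing_cells[-1] <- diff(out$position) / p$dx
  structure(out, class = c("psm_boundaries", "data.frame"))
}

#' Somite spacing from boundary events
#'
#' Lab-frame distances between consecutive anterior Tbx6 boundaries,
#' expressed in cells.
#'
#' @param boundaries output of [detect_tbx6_boundaries()] (at least 2
#'   rows).
#' @param p parameter set (for `dx`).
#' @return list with `intervals_cells` and `mean_cells`.
#' @export
somite_spacing <- function(boundaries, p) {
  if (nrow(boundaries) < 2)
    stop("need at least 2 boundaries to measure spacing")
  iv <- diff(boundaries$position) / p$dx
  list(intervals_cells = iv, mean_cells = mean(iv))
}

#' Kymograph of one variable
#'
#' In the tailbud frame the kymograph is the recorded space x time matrix
#' (columns = grid positions). In the lab frame columns are *cells*, which
#' are static lab positions: the matrix is rebuilt by undoing the advection
#' index shifts, so each column is the history of one cell (NA where the
#' cell is outside the domain). The transformation is exact integer
#' bookkeeping and loses nothing on the recorded grid.
#'
#' @param sim a `psm_sim`.
#' @param variable one of the eight recorded variables.
#' @param frame `"tailbud"` or `"lab"`.
#' @return object of class `psm_kymo`: `mat` (time x position), `times`,
#'   `x` (position axis, um), `frame`, `variable`.
#' @export
build_kymograph <- function(sim, variable = "p_h",
                            frame = c("tailbud", "lab")) {
  frame <- match.arg(frame)
  if (!variable %in% .psm_vars)
    stop("unknown variable \"", variable, "\"; recorded: ",
         paste(.psm_vars, collapse = ", "))
  p <- sim$params
  m <- sim[[variable]]
  if (frame == "tailbud") {
    k <- list(mat = m, times = sim$times, x = sim$x, frame = frame,
              variable = variable, params = p)
    class(k) <- "psm_kymo"
    return(k)
  }
  shift_min <- p$dx / p$u
  # number of shifts since the first recorded snapshot, per recorded time;
  # the shift schedule continues through the warm-up, whose step count sets
  # the phase
  warm_steps <- round(p$t_warmup / p$dt)
  shift_every <- round(p$dx / p$u / p$dt)
  s0 <- warm_steps %/% shift_every
  shifts <- (round((sim$times + p$t_warmup) / p$dt)) %/% shift_every - s0
  ncell <- p$N + max(shifts)
  mat <- matrix(NA_real_, nrow(m), ncell)
  for (i in seq_len(nrow(m)))
    mat[i, seq_len(p$N) + shifts[i]] <- m[i, ]
  # lab coordinate of cell c (1-based): founders at (c-1)*dx at t = 0;
  # entrants continue the grid posteriorly at one cell per shift
  off <- shift_min - (p$t_warmup %% shift_min)
  if (abs(off - shift_min) < 1e-9) off <- shift_min
  cells <- seq_len(ncell)
  xlab <- (cells - 1) * p$dx
  ent <- cells > p$N
  xlab[ent] <- (p$N - 1) * p$dx + p$u * (off + (cells[ent] - p$N - 1) * shift_min)
  k <- list(mat = mat, times = sim$times, x = xlab, frame = frame,
            variable = variable, params = p, shifts = shifts)
  class(k) <- "psm_kymo"
  k
}

#' Convert a lab-frame kymograph back to the tailbud frame
#'
#' Exact inverse of [build_kymograph()]'s lab-frame construction.
#'
#' @param k a lab-frame `psm_kymo`.
#' @return a tailbud-frame `psm_kymo`.
#' @export
kymo_to_tailbud <- function(k) {
  if (k$frame != "lab") return(k)
  p <- k$params
  m <- matrix(NA_real_, nrow(k$mat), p$N)
  for (i in seq_len(nrow(k$mat)))
    m[i, ] <- k$mat[i, seq_len(p$N) + k$shifts[i]]
  out <- list(mat = m, times = k$times, x = seq(0, p$L, by = p$dx),
              frame = "tailbud", variable = k$variable, params = p)
  class(out) <- "psm_kymo"
  out
}

#' @export
print.psm_kymo <- function(x, ...) {
  cat(sprintf("kymograph of %s (%s frame): %d times x %d positions\n",
              x$variable, x$frame, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' @export
plot.psm_kymo <- function(x, ...) {
  graphics::image(x$times, x$x, x$mat, col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (min)",
                  ylab = sprintf("position, %s frame (um)", x$frame),
                  main = x$variable, ...)
  invisible(x)
}

#' Oscillation period profile of a kymograph
#'
#' For every column (grid position in the tailbud frame, cell in the lab
#' frame), finds successive local maxima after discarding an initial
#' transient and reports the mean peak-to-peak interval. The prominence
#' threshold is a fraction of the posterior reference amplitude (the
#' largest columnwise amplitude among the most posterior quarter of
#' columns). Columns with fewer than 3 peaks are flagged, not dropped;
#' constant columns are flagged non-oscillatory.
#'
#' @param k a `psm_kymo`.
#' @param prominence_frac prominence as a fraction of the posterior
#'   amplitude.
#' @param discard transient discarded from the start of each column, min.
#' @return data frame with columns `position`, `n_peaks`, `mean_interval`
#'   (min; NA when flagged), `flagged`.
#' @export
measure_period_profile <- function(k, prominence_frac = 0.2, discard = 0) {
  dt_rec <- diff(k$times[1:2])
  i0 <- sum(k$times < k$times[1] + discard) + 1L
  m <- k$mat[i0:nrow(k$mat), , drop = FALSE]
  amp <- apply(m, 2, function(y) if (all(is.na(y))) NA else
    diff(range(y, na.rm = TRUE)))
  post <- which(seq_along(amp) > 0.75 * length(amp))
  ref <- max(amp[post], na.rm = TRUE)
  if (!is.finite(ref) || ref == 0) ref <- max(amp, na.rm = TRUE)
  res <- lapply(seq_len(ncol(m)), function(j) {
    y <- m[, j]
    if (all(is.na(y)) || is.na(amp[j]) || amp[j] == 0)
      return(data.frame(position = k$x[j], n_peaks = 0L,
                        mean_interval = NA_real_, flagged = TRUE))
    pk <- find_peaks(y, min_prom = prominence_frac * ref)
    if (length(pk) < 3)
      return(data.frame(position = k$x[j], n_peaks = length(pk),
                        mean_interval = NA_real_, flagged = TRUE))
    data.frame(position = k$x[j], n_peaks = length(pk),
               mean_interval = mean(diff(pk)) * dt_rec, flagged = FALSE)
  })
  do.call(rbind, res)
}

#' Per-cell oscillation period versus axial position
#'
#' Cells are autonomous delayed oscillators whose translational delay, and
#' hence period, depends on their current position: as a cell advects
#' anteriorly its peak-to-peak interval lengthens. This function extracts
#' every cell's Her peak times from the lab-frame kymograph (one column per
#' cell) and assigns each peak-to-peak interval to the cell's tailbud-frame
#' position at the interval midpoint, giving the spatial period profile of
#' the travelling waves.
#'
#' @param sim a `psm_sim`.
#' @param variable clock variable to analyse.
#' @param prominence_frac peak prominence as a fraction of the posterior
#'   reference amplitude.
#' @param min_level intervals are kept only where the peak level exceeds
#'   this fraction of the global maximum (drops the decaying tail after
#'   oscillation arrest).
#' @return data frame with one row per interval: `cell` (lab position,
#'   um), `position` (tailbud frame, um), `interval` (min), sorted by
#'   position.
#' @export
cell_period_profile <- function(sim, variable = "p_h",
                                prominence_frac = 0.2, min_level = 0.1) {
  k <- build_kymograph(sim, variable, "lab")
  p <- sim$params
  ref <- max(k$mat, na.rm = TRUE)
  rows <- lapply(seq_len(ncol(k$mat)), function(j) {
    y <- k$mat[, j]
    pk <- find_peaks(y, min_prom = prominence_frac * ref)
    pk <- pk[y[pk] >= min_level * ref]
    if (length(pk) < 2) return(NULL)
    tp <- k$times[pk]
    mid <- (tp[-1] + tp[-length(tp)]) / 2
    data.frame(cell = k$x[j],
               position = from_lab_frame(k$x[j], mid, p),
               interval = diff(tp))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(cell = numeric(0), position = numeric(0),
                      interval = numeric(0)))
  out <- out[out$position >= 0 & out$position <= p$L, ]
  out[order(out$position), ]
}

#' Anteriormost oscillating position (wave arrest)
#'
#' Computes each column's oscillation amplitude (max - min after an initial
#' transient) and returns the anteriormost position whose amplitude exceeds
#' `frac` of the posterior reference amplitude. In the wild type this sits
#' within a cell of the anterior Tbx6 border (oscillation dies where Tbx6
#' is removed); in the ripply knockout the waves never arrest and the
#' position is the anterior end of the domain.
#'
#' @param k a `psm_kymo` of a clock variable (`p_h` or `M_h`).
#' @param frac amplitude fraction defining "oscillating".
#' @param discard transient discarded, min.
#' @return the arrest position, um, with attribute `oscillating = FALSE`
#'   and value NA when nothing oscillates.
#' @export
wave_arrest_position <- function(k, frac = 0.2, discard = 0) {
  i0 <- sum(k$times < k$times[1] + discard) + 1L
  m <- k$mat[i0:nrow(k$mat), , drop = FALSE]
  amp <- apply(m, 2, function(y) if (all(is.na(y))) NA else
    diff(range(y, na.rm = TRUE)))
  post <- which(seq_along(amp) > 0.75 * length(amp))
  ref <- max(amp[post], na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0)
    return(structure(NA_real_, oscillating = FALSE))
  osc <- which(!is.na(amp) & amp >= frac * ref)
  if (!length(osc)) return(structure(NA_real_, oscillating = FALSE))
  structure(k$x[min(osc)], oscillating = TRUE)
}

#' Extent of an expression domain in one snapshot
#'
#' Extreme positions where the level exceeds `threshold_frac` of the
#' snapshot maximum. Used e.g. on nascent *ripply* mRNA to compare the
#' posterior extent of the expression domain between wild type and MEK
#' inhibition.
#'
#' @param snapshot per-cell levels (non-negative).
#' @param x matching positions, um.
#' @param threshold_frac fraction of the maximum.
#' @return `c(anterior, posterior)` positions, um; both NA with attribute
#'   `empty = TRUE` if the snapshot has no expression.
#' @export
domain_extent <- function(snapshot, x, threshold_frac = 0.2) {
  if (any(snapshot < 0)) stop("snapshot must be non-negative")
  mx <- max(snapshot)
  if (mx == 0)
    return(structure(c(anterior = NA_real_, posterior = NA_real_),
                     empty = TRUE))
  on <- which(snapshot > threshold_frac * mx)
  structure(c(anterior = x[min(on)], posterior = x[max(on)]), empty = FALSE)
}
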