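# Synthetic spatio-temporal profiles with known ground truth. These stand
# in for simulator output so every pattern detector can be validated
# independently of the DDE integrator, plus TSV/JSON serialisation of
# simulation outputs.

#' Specify a synthetic pattern fixture
#'
#' @param kind one of `"step"`, `"boxcar"`, `"sigmoid"`,
#'   `"traveling_wave"`, `"sawtooth_border"`.
#' @param N,dx geometry (cells and spacing, um).
#' @param t_end,record_every time axis, min.
#' @param seed RNG seed for the optional additive noise.
#' @param noise_sd Gaussian noise standard deviation (clipped at 0).
#' @param ... kind-specific parameters:
#'   * `step`/`sigmoid`: `edge` (um), `width` (sigmoid only, um);
#'   * `boxcar`: `from`, `to` (um), `level`;
#'   * `traveling_wave`: `T_posterior`, `T_anterior` (min; the period
#'     profile is linear in x between them), `lambda` (wavelength, um),
#'     `amp` (either a constant or a function of x);
#'   * `sawtooth_border`: `b0` (initial lab border, um), `period` (min
#'     between jumps), `jump_cells` (posterior jump per event).
#' @return a `psm_fixture_spec` list.
#' @export
fixture_spec <- function(kind = c("step", "boxcar", "sigmoid",
                                  "traveling_wave", "sawtooth_border"),
                         N = 41, dx = 10, t_end = 150, record_every = 1,
                         seed = 1, noise_sd = 0, ...) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, N = N, dx = dx, t_end = t_end,
               record_every = record_every, seed = seed, noise_sd = noise_sd,
               extra = list(...))
  class(spec) <- "psm_fixture_spec"
  spec
}

#' Generate a ground-truth fixture
#'
#' Builds a simulation-output-shaped object (class `psm_sim`) realising the
#' requested pattern, deterministic given the seed, with the exact ground
#' truth stored in attribute `"truth"`:
#'
#' * `step`, `sigmoid`: a static Tbx6 border at a known edge;
#' * `boxcar`: an expression domain with known support;
#' * `traveling_wave`:
#'   `level(x, t) = A(x) * (1 + sin(2*pi*(t/T(x) - x/lambda))) / 2` on the
#'   clock variables, so the period at every position is known exactly and
#'   waves slow anteriorly when `T_anterior > T_posterior`;
#' * `sawtooth_border`: a Tbx6 border that is static in the lab frame
#'   between programmed posterior jumps, emulating periodic boundary
#'   formation with known event times and positions.
#'
#' Noise, when requested, is additive Gaussian clipped at zero.
#'
#' @param spec a [fixture_spec()].
#' @return a `psm_sim` with attribute `"truth"` (a list; contents per
#'   kind).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "psm_fixture_spec"))
  N <- spec$N; dx <- spec$dx
  L <- (N - 1) * dx
  p <- default_parameters(L = L, dx = dx, N = as.integer(N))
  x <- seq(0, L, by = dx)
  times <- seq(0, spec$t_end, by = spec$record_every)
  nt <- length(times)
  e <- spec$extra
  zero <- matrix(0, nt, N)
  out <- list(times = times, x = x, xe = rep(p$x_E, nt), clamped = 0,
              shifts = 0, params = p, scenario = "fixture",
              frame = "tailbud", record_every = spec$record_every,
              t_end = spec$t_end)
  for (v in .psm_vars) out[[v]] <- zero
  truth <- list(kind = spec$kind)

  if (spec$kind == "step") {
    edge <- if (is.null(e$edge)) L / 2 else e$edge
    prof <- ifelse(x < edge, 0, 1)
    out$p_t <- matrix(prof, nt, N, byrow = TRUE)
    truth$edge <- edge
  } else if (spec$kind == "sigmoid") {
    edge <- if (is.null(e$edge)) L / 2 else e$edge
    w <- if (is.null(e$width)) dx else e$width
    prof <- 1 / (1 + exp(-(x - edge) / w))
    out$p_t <- matrix(prof, nt, N, byrow = TRUE)
    truth$edge <- edge
  } else if (spec$kind == "boxcar") {
    from <- if (is.null(e$from)) L / 4 else e$from
    to <- if (is.null(e$to)) 3 * L / 4 else e$to
    lev <- if (is.null(e$level)) 1 else e$level
    prof <- ifelse(x >= from & x <= to, lev, 0)
    out$m_r <- matrix(prof, nt, N, byrow = TRUE)
    truth$from <- from; truth$to <- to
  } else if (spec$kind == "traveling_wave") {
    Tp <- if (is.null(e$T_posterior)) 30 else e$T_posterior
    Ta <- if (is.null(e$T_anterior)) 60 else e$T_anterior
    lam <- if (is.null(e$lambda)) 200 else e$lambda
    A <- if (is.null(e$amp)) 1 else e$amp
    Ax <- if (is.function(A)) A(x) else rep(A, N)
    Tx <- Ta + (Tp - Ta) * x / L
    m <- outer(times, seq_len(N), function(t, j)
      Ax[j] * (1 + sin(2 * pi * (t / Tx[j] - x[j] / lam))) / 2)
    out$p_h <- m
    out$M_h <- m
    truth$period <- Tx; truth$amplitude <- Ax
  } else if (spec$kind == "sawtooth_border") {
    b0 <- if (is.null(e$b0)) 100 else e$b0
    period <- if (is.null(e$period)) 30 else e$period
    jump_cells <- if (is.null(e$jump_cells)) 6 else e$jump_cells
    ev <- seq(period, spec$t_end, by = period)
    blab <- function(t) b0 + jump_cells * dx * floor(t / period)
    btb <- vapply(times, function(t) blab(t) - p$u * t, numeric(1))
    out$p_t <- t(vapply(seq_len(nt), function(i)
      ifelse(x < btb[i], 0, 1), numeric(N)))
    truth$event_times <- ev
    truth$event_positions <- b0 + jump_cells * dx * seq_along(ev)
    truth$jump_cells <- jump_cells
  }

  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(spec$seed)
    for (v in .psm_vars)
      if (any(out[[v]] != 0))
        out[[v]] <- pmax(out[[v]] + matrix(
          stats::rnorm(nt * N, 0, spec$noise_sd), nt, N), 0)
  }
  class(out) <- "psm_sim"
  attr(out, "truth") <- truth
  out
}

.schema_version <- "1"

#' Write a simulation output to a directory
#'
#' One tab-delimited table per variable (first column `time`, one column
#' per tailbud-frame position; `%.17g` formatting, so the round trip
#' through [read_output()] is exact), plus a `manifest.json` with the
#' schema version, scenario, frame, parameter snapshot, dpErk border
#' trajectory and counters.
#'
#' @param sim a `psm_sim`.
#' @param dir directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_output <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in .psm_vars) {
    m <- cbind(sim$times, sim[[v]])
    txt <- apply(m, c(1, 2), function(z) sprintf("%.17g", z))
    colnames(txt) <- c("time", sprintf("%.17g", sim$x))
    utils::write.table(txt, file.path(dir, paste0(v, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    schema_version = .schema_version,
    scenario = sim$scenario, frame = sim$frame,
    variables = .psm_vars,
    record_every = sim$record_every, t_end = sim$t_end,
    clamped = sim$clamped, shifts = sim$shifts,
    xe = sim$xe,
    params = unclass(sim$params),
    truth = attr(sim, "truth")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulation output directory
#'
#' Inverse of [write_output()]; errors loudly on a schema-version mismatch
#' or a missing variable table.
#'
#' @param dir directory written by [write_output()].
#' @return a `psm_sim`.
#' @export
read_output <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.character(manifest$schema_version), .schema_version))
    stop(sprintf("schema version mismatch: file has \"%s\", this package reads \"%s\"",
                 manifest$schema_version, .schema_version))
  p <- manifest$params
  class(p) <- "psm_params"
  out <- list(xe = manifest$xe, clamped = manifest$clamped,
              shifts = manifest$shifts, params = p,
              scenario = manifest$scenario, frame = manifest$frame,
              record_every = manifest$record_every, t_end = manifest$t_end)
  for (v in manifest$variables) {
    f <- file.path(dir, paste0(v, ".tsv"))
    if (!file.exists(f))
      stop("output directory is missing the table for variable \"", v, "\"")
    tab <- utils::read.delim(f, check.names = FALSE)
    out$times <- as.numeric(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    out[[v]] <- m
    out$x <- as.numeric(colnames(tab)[-1])
  }
  class(out) <- "psm_sim"
  if (!is.null(manifest$truth)) attr(out, "truth") <- manifest$truth
  out
}
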