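test_that("find_peaks honours the prominence threshold", {
  t <- seq(0, 100, 0.5)
  y <- sin(2 * pi * t / 20) + 0.05 * sin(2 * pi * t / 3)
  pk <- find_peaks(y, min_prom = 0.5)
  expect_equal(length(pk), 5)
  expect_equal(diff(pk) * 0.5, rep(20, 4), tolerance = 0.06)
  expect_length(find_peaks(rep(1, 50), min_prom = 0.1), 0)
  # NA padding at the ends is tolerated
  expect_equal(find_peaks(c(NA, NA, y, NA), min_prom = 0.5) - 2, pk)
})

test_that("a step profile yields a single border at the step", {
  fx <- generate_fixture(fixture_spec("step", edge = 200, t_end = 20))
  traj <- tbx6_border_trajectory(fx, threshold = 0.5)
  expect_equal(traj$tailbud, rep(200, nrow(traj)), tolerance = 5)
  b <- detect_tbx6_boundaries(fx, threshold = 0.5)
  expect_equal(nrow(b), 0)    # static border, no formation events
})

test_that("programmed border jumps are recovered exactly", {
  spec <- fixture_spec("sawtooth_border", t_end = 150, b0 = 100,
                       period = 30, jump_cells = 6)
  fx <- generate_fixture(spec)
  truth <- attr(fx, "truth")
  b <- detect_tbx6_boundaries(fx, threshold = 0.5, persist_min = 25)
  expect_equal(nrow(b), length(truth$event_times))
  expect_equal(b$time, truth$event_times, tolerance = 1e-9)
  expect_equal(b$position, truth$event_positions, tolerance = 5)
  sp <- somite_spacing(b, fx$params)
  expect_equal(sp$mean_cells, truth$jump_cells, tolerance = 0.1)
  expect_true(all(b$persistent[-nrow(b)]))
})

test_that("somite spacing is plain lab-frame arithmetic", {
  p <- default_parameters()
  b <- data.frame(position = c(0, 60, 120))
  sp <- somite_spacing(b, p)
  expect_equal(sp$intervals_cells, c(6, 6))
  expect_equal(sp$mean_cells, 6)
  b2 <- data.frame(position = cumsum(c(0, 50, 70)))
  expect_equal(somite_spacing(b2, p)$intervals_cells, c(5, 7))
  expect_equal(somite_spacing(b2, p)$mean_cells, 6)
  expect_error(somite_spacing(b[1, , drop = FALSE], p), "at least 2")
})

test_that("kymographs convert between frames losslessly", {
  sim <- cached("wt60", function()
    simulate_psm(default_parameters(), "wild_type", t_end = 60))
  kt <- build_kymograph(sim, "p_t", "tailbud")
  expect_identical(kt$mat, sim$p_t)
  kl <- build_kymograph(sim, "p_t", "lab")
  back <- kymo_to_tailbud(kl)
  expect_equal(back$mat, kt$mat)
  expect_equal(back$x, kt$x)
  # a lab column is one cell: between advection events it must match the
  # grid column the cell occupies
  expect_error(build_kymograph(sim, "nonsense"), "unknown variable")
})

test_that("constant and wave fixtures give the expected kymographs", {
  fx <- generate_fixture(fixture_spec("boxcar", t_end = 30))
  k <- build_kymograph(fx, "m_r", "tailbud")
  expect_true(all(apply(k$mat, 2, function(col) length(unique(col)) == 1)))

  fw <- generate_fixture(fixture_spec("traveling_wave", t_end = 120,
                                      T_posterior = 30, T_anterior = 30))
  kw <- build_kymograph(fw, "p_h", "tailbud")
  # uniform period: all columns oscillate with period 30
  pp <- measure_period_profile(kw)
  ok <- !pp$flagged
  expect_true(any(ok))
  expect_equal(pp$mean_interval[ok], rep(30, sum(ok)), tolerance = 1 / 30)
})

test_that("period profiles recover the programmed linear slowing", {
  fw <- generate_fixture(fixture_spec("traveling_wave", t_end = 240,
                                      T_posterior = 30, T_anterior = 60))
  truth <- attr(fw, "truth")
  kw <- build_kymograph(fw, "p_h", "tailbud")
  pp <- measure_period_profile(kw)
  ok <- !pp$flagged
  # within one frame interval of the programmed period at each position
  expect_true(all(abs(pp$mean_interval[ok] - truth$period[ok]) <= 1 + 1e-9))
  # constant signal flagged non-oscillatory
  fc <- generate_fixture(fixture_spec("boxcar", t_end = 60))
  ppc <- measure_period_profile(build_kymograph(fc, "m_r", "tailbud"))
  expect_true(all(ppc$flagged))
})

test_that("wave arrest is found at a programmed amplitude cutoff", {
  cutoff <- 150
  amp_fun <- function(x) ifelse(x >= cutoff, 1, 0.01)
  fw <- generate_fixture(fixture_spec("traveling_wave", t_end = 120,
                                      amp = amp_fun, T_posterior = 30,
                                      T_anterior = 45))
  k <- build_kymograph(fw, "p_h", "tailbud")
  pos <- wave_arrest_position(k, frac = 0.2)
  expect_true(attr(pos, "oscillating"))
  expect_equal(as.numeric(pos), cutoff, tolerance = 10)
  # nothing oscillates in a static fixture
  fs <- generate_fixture(fixture_spec("step", t_end = 60))
  still <- wave_arrest_position(build_kymograph(fs, "p_t", "tailbud"))
  expect_false(attr(still, "oscillating"))
})

test_that("domain extent reads boxcar supports and flags empty snapshots", {
  p <- default_parameters()
  x <- seq(0, p$L, p$dx)
  prof <- ifelse(x >= 100 & x <= 250, 1, 0)
  ext <- domain_extent(prof, x)
  expect_equal(as.numeric(ext), c(100, 250))
  e2 <- domain_extent(rep(0, length(x)), x)
  expect_true(attr(e2, "empty"))
  expect_true(all(is.na(e2)))
  expect_error(domain_extent(c(-1, 1), c(0, 10)), "non-negative")
})

test_that("wild-type ripply transcription sits in the anterior half of the Tbx6 domain", {
  sim <- wt_sim()
  p <- sim$params
  thr <- tbx6_threshold(p)
  for (i in seq(61, 240, by = 13)) {
    mr <- sim$m_r[i, ]
    if (max(mr) < 0.05) next
    ext <- domain_extent(mr, sim$x)
    tbx_on <- sim$x[sim$p_t[i, ] >= thr]
    mid <- (min(tbx_on) + max(tbx_on)) / 2
    expect_lt(unname(ext["posterior"]), mid)
  }
})

test_that("boundary events are periodic in the wild type and absent in mutants", {
  sim <- wt_sim()
  p <- sim$params
  b <- detect_tbx6_boundaries(sim)
  expect_gte(nrow(b), 5)
  # inter-event times match the clock period within 10%
  expect_equal(diff(b$time), rep(p$T_clock, nrow(b) - 1),
               tolerance = 0.1)
  expect_true(all(b$persistent[-nrow(b)]))

  expect_equal(nrow(detect_tbx6_boundaries(ripply_ko_sim())), 0)
  bn <- detect_tbx6_boundaries(no_pfl_sim())
  expect_equal(sum(bn$persistent), 0)
})
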