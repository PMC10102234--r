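p0 <- default_parameters()

test_that("production/degradation curves have the expected shape", {
  p <- p0
  grid <- seq(0, 5, by = 0.01)
  cur <- production_degradation_curves(grid, F = 0, p_r = 0, p)
  expect_equal(cur$D, grid)              # identity line at p_r = 0
  expect_equal(cur$P[1], 0)              # no production at the origin, F = 0
  expect_lt(max(cur$P), p$pfl_mult + p$gamma)  # saturation bound
  cur2 <- production_degradation_curves(grid, F = 0, p_r = 2, p)
  expect_equal(cur2$D, (1 + p$eta * 2) * grid)
  expect_error(production_degradation_curves(numeric(0), 0, 0, p), "empty")
})

test_that("steady states of the bistable switch match the closed form", {
  ss <- find_steady_states(F = 0, p_r = 0, p = p0)   # K6 = 0.4, n6 = 2
  expect_equal(ss$p_t, c(0, 0.2, 0.8), tolerance = 1e-6)
  expect_equal(ss$stability, c("stable", "unstable", "stable"))
  # overwhelming degradation leaves only the low state
  ss2 <- find_steady_states(F = 0, p_r = 1e6, p = p0)
  expect_equal(nrow(ss2), 1)
  expect_equal(ss2$p_t, 0)
  expect_equal(ss2$stability, "stable")
})

test_that("root sets agree with a dense sign-scan oracle on random draws", {
  set.seed(7)
  for (i in 1:30) {
    p <- default_parameters(
      K6 = runif(1, 0.15, 0.6), gamma = runif(1, 0, 1),
      eta = runif(1, 1, 5), n6 = sample(2:4, 1),
      K_FA = 0.25, K_FR = 0.4)
    F <- runif(1, 0, 1); pr <- runif(1, 0, 0.5)
    ss <- find_steady_states(F, pr, p)
    orc <- oracle_roots(F, pr, p)
    expect_equal(nrow(ss), length(orc))
    if (length(orc)) {
      expect_true(all(abs(ss$p_t - orc) <= 10 * (p$pfl_mult + p$gamma) / 1e5))
      expect_true(ss$stability[1] %in% c("stable", "sn"))
      if (nrow(ss) == 3)
        expect_equal(ss$stability, c("stable", "unstable", "stable"))
    }
  }
})

test_that("the saddle-node degradation threshold has its closed form at n6 = 2", {
  expect_equal(as.numeric(sn_degradation_threshold(0, default_parameters(gamma = 0))),
               1 / (2 * 0.4), tolerance = 1e-5)
  expect_equal(as.numeric(sn_degradation_threshold(0, default_parameters(gamma = 0, K6 = 0.25))),
               2, tolerance = 1e-5)
  # not bistable at K6 >= 1/2: flagged
  d <- sn_degradation_threshold(0, default_parameters(gamma = 0, K6 = 0.6))
  expect_false(attr(d, "bistable"))
  expect_equal(as.numeric(d), 1)
  # monotone decreasing in K6, including n6 != 2
  for (n6 in c(2, 3)) {
    ds <- vapply(c(0.2, 0.3, 0.4), function(k6)
      as.numeric(sn_degradation_threshold(0, default_parameters(gamma = 0, K6 = k6, n6 = n6))),
      numeric(1))
    expect_true(all(diff(ds) < 0))
  }
})

test_that("the spatial bifurcation structure matches the wild-type geometry", {
  p <- p0
  bf <- bifurcation_along_axis(p)        # p_r = 0 everywhere
  n_by_x <- tapply(bf$p_t, bf$x, length)
  x <- as.numeric(names(n_by_x))
  expect_true(all(n_by_x[x <= 150] == 3))     # anterior PSM bistable
  # mid PSM: the feedforward input leaves only the high state
  expect_equal(unname(n_by_x[x == 280]), 1)
  expect_gt(bf$p_t[bf$x == 280], 0.5)
  # tailbud: bistable, with a low branch for the newly added cells
  expect_equal(unname(n_by_x[x == p$L]), 3)
  expect_lt(min(bf$p_t[bf$x == p$L]), 0.05)

  # a supra-threshold Ripply peak removes the high state at that position
  d_star <- as.numeric(sn_degradation_threshold(0, p))
  prof <- rep(0, p$N); prof[16] <- 2 * (d_star - 1) / p$eta  # x = 150
  bf2 <- bifurcation_along_axis(p, prof)
  expect_equal(sum(bf2$x == 150), 1)
  expect_lt(bf2$p_t[bf2$x == 150], 0.1)

  # with gamma = 0 the structure is position-independent
  bf3 <- bifurcation_along_axis(default_parameters(gamma = 0))
  counts <- tapply(bf3$p_t, bf3$x, length)
  expect_true(all(counts == counts[1]))
})

test_that("single-cell Tbx6 shows hysteresis around the saddle-node threshold", {
  p <- p0
  d_star <- as.numeric(sn_degradation_threshold(0, p))
  hi <- max(find_steady_states(0, 0, p)$p_t)
  r_sup <- tbx6_pulse_response(p, F = 0, factor = 1.5 * d_star,
                               t_on = 20, t_off = 40, t_end = 160)
  r_sub <- tbx6_pulse_response(p, F = 0, factor = 0.95 * d_star,
                               t_on = 20, t_off = 40, t_end = 160)
  # two clock periods after pulse removal
  late <- r_sup$t > 40 + 2 * p$T_clock
  expect_true(all(r_sup$p_t[late] < 0.05))
  expect_equal(tail(r_sub$p_t, 1), hi, tolerance = 1e-3)
})

test_that("boundary formation in the phase diagram requires clearing the saddle-node curve", {
  p <- default_parameters()
  v3 <- exp(seq(log(0.25), log(8), length.out = 6))
  pd <- phase_diagram(p, K6_values = c(0.3, 0.4), v3_values = v3)
  sn <- attr(pd, "sn_curve")
  expect_true(all(diff(sn$factor) < 0))   # SN threshold falls with weaker PFL
  for (k6 in unique(pd$K6)) {
    row <- pd[pd$K6 == k6, ]
    row <- row[order(row$nu3), ]
    d_star <- sn$factor[sn$K6 == k6]
    formed <- row$outcome == "boundary_formed"
    # outcomes are monotone in the Ripply translation rate
    expect_true(all(diff(as.integer(formed)) >= 0))
    expect_true(any(formed) && any(!formed))
    # every formed point sits above the saddle-node factor; the transition
    # lies within a modest margin above it
    expect_true(all(row$factor[formed] > d_star))
    lo <- max(row$factor[!formed]); hi <- min(row$factor[formed])
    expect_gt(hi, d_star)
    expect_lt(lo, 1.6 * d_star)
  }
})

test_that("her oscillation arrests at low Tbx6 and runs at the high state", {
  p <- p0
  hi <- max(find_steady_states(0, 0, p)$p_t)
  scan <- her_oscillation_scan(c(0, 0.05, 0.3, 0.5, hi), p)
  expect_false(scan$oscillating[1])
  expect_equal(scan$amplitude[1], 0, tolerance = 1e-6)
  expect_false(scan$oscillating[2])
  expect_true(scan$oscillating[5])        # wild-type anterior high state
  expect_gt(scan$amplitude[5], 0.1)
  # amplitude non-decreasing through the onset
  expect_true(all(diff(scan$amplitude) > -1e-6))
})
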