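p0 <- default_parameters()

test_that("her transcription combines Her repression with the spatial Tbx6 gate", {
  p <- default_parameters(n1 = 2, n2 = 2)
  # posterior of x_h no Tbx6 is needed
  expect_equal(her_transcription(0, 0, p$x_h + 1, p), 1)
  expect_equal(her_transcription(1e9, 0, p$x_h + 1, p), 0, tolerance = 1e-12)
  # two half-saturations multiply
  expect_equal(her_transcription(p$K1, p$K2, p$x_h, p), 0.25)
  # anterior with no Tbx6: off
  expect_equal(her_transcription(0, 0, 0, p), 0)
  expect_error(her_transcription(-1, 0, 0, p), "negative")
})

test_that("ripply transcription needs Tbx6 and is repressed by Her and dpErk", {
  p <- default_parameters(n3 = 2, n4 = 2, n5 = 2)
  expect_equal(ripply_transcription(0, 0, 0, p), 0)
  expect_equal(ripply_transcription(0, 0, 1e12, p), p$nu1, tolerance = 1e-10)
  expect_equal(ripply_transcription(p$K3, p$K4, p$K5, p), p$nu1 / 8)
  expect_error(ripply_transcription(0, -0.1, 0, p), "negative")
})

test_that("production terms are bounded and Hill terms monotone", {
  set.seed(42)
  p <- default_parameters()
  for (i in 1:50) {
    y <- sort(runif(2, 0, 20))
    expect_lte(hill_act(y[1], p$K6, p$n6), hill_act(y[2], p$K6, p$n6))
    expect_gte(hill_rep(y[1], p$K3, p$n3), hill_rep(y[2], p$K3, p$n3))
    ph <- runif(1, 0, 5); pt <- runif(1, 0, 5); x <- runif(1, 0, p$L)
    tx <- her_transcription(ph, pt, x, p)
    expect_gte(tx, 0); expect_lte(tx, 1)
    tr <- ripply_transcription(ph, runif(1, 0, 2), pt, p)
    expect_gte(tr, 0); expect_lte(tr, p$nu1)
    pr <- tbx6_production(pt, runif(1, 0, 1), p)
    expect_gte(pr, 0); expect_lte(pr, p$pfl_mult + p$gamma)
  }
})

test_that("mRNA and protein balances integrate to their closed forms", {
  p <- p0
  # pure decay of mature mRNA: M(t) = M0 * exp(-mu1 * t)
  M <- 1; dt <- p$dt
  for (s in seq_len(round(20 / dt)))
    M <- M + dt * p$mu1 * mature_mrna_rhs(0, M, p$mu_sh, 1)
  expect_lt(abs(M - exp(-p$mu1 * 20)), 1e-4)

  # relaxation to translation/decay balance: pp -> 1 - exp(-mu3*mu4*t)
  pp <- 0
  for (s in seq_len(round(20 / dt)))
    pp <- pp + dt * p$mu3 * protein_rhs(1, pp, p$mu4, p$mu4)
  expect_equal(pp, 1 - exp(-p$mu3 * p$mu4 * 20), tolerance = 1e-3)

  # algebraic steady state of the splicing balance
  expect_equal(mature_mrna_rhs(2, 2 * p$mu_sh / p$mu2, p$mu_sh, p$mu2), 0)
})

test_that("the Her translational delay gradient is linear between its endpoints", {
  p <- p0
  expect_equal(her_translation_delay(0, p), p$tau_H0)
  expect_equal(her_translation_delay(p$L, p), p$tau_HL)
  expect_equal(her_translation_delay(p$L / 2, p), (p$tau_H0 + p$tau_HL) / 2)
  expect_equal(her_translation_delay(0, p) / her_translation_delay(p$L, p),
               p$tau_H0 / p$tau_HL)
  expect_error(her_translation_delay(-1, p), "domain")
  expect_error(her_translation_delay(p$L + 1, p), "domain")
})

test_that("Tbx6 production reproduces the S-curve values", {
  p <- default_parameters(n6 = 2)
  expect_equal(tbx6_production(0, 0, p), 0)
  expect_equal(tbx6_production(p$K6, 0, p), 0.5)
  # feedforward term at F = K_FA = K_FR / 4 with squared exponents
  q <- default_parameters(nA = 2, nR = 2, K_FA = 0.1, K_FR = 0.4)
  expect_equal(tbx6_production(1e12, q$K_FA, q),
               1 + 8 * q$gamma / 17, tolerance = 1e-10)
})

test_that("the Tbx6 balance matches its direct evaluation", {
  p <- default_parameters(K6 = 0.4, n6 = 2)
  expect_equal(tbx6_rhs(0, 0, 0, p), 0)        # origin is a fixed point
  expect_equal(tbx6_rhs(0.4, 0, 0, p), 0.5 - 0.4)
  # unbounded Ripply makes degradation dominate
  expect_lt(tbx6_rhs(0.5, 1e9, 0, p), -1e6)
  expect_error(tbx6_rhs(0.5, -1, 0, p), "negative")
})

test_that("history lookup is exact ring-buffer arithmetic", {
  p <- default_parameters()
  tis <- initialize_tissue(p)
  # initial history returns the prescribed values at any admissible delay
  expect_equal(history_lookup(tis, "p_h", p$tau_h), rep(p$nu2 / p$mu4, p$N))
  expect_equal(history_lookup(tis, "M_h", 0), rep(1, p$N))
  # write a ramp into the buffer: state(t) = t for one variable
  for (i in 1:300) {
    tis$step <- tis$step + 1L
    tis$hist$p_h[(tis$step %% tis$H) + 1L, ] <- tis$step * p$dt
  }
  for (k in c(0, 7, 100))
    expect_equal(history_lookup(tis, "p_h", k * p$dt),
                 rep((300 - k) * p$dt, p$N))
  expect_error(history_lookup(tis, "p_h", 1e6), "horizon")
  expect_error(history_lookup(tis, "p_h", p$dt / 3), "multiple")
})
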