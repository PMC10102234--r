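test_that("calibrated defaults are valid and carry the fixed model constants", {
  p <- default_parameters()
  expect_length(validate_parameters(p), 0)
  expect_equal(p$L, 400)
  expect_equal(p$dx, 10)
  expect_equal(p$N, 41L)
  expect_equal(p$dt, 0.01)
  expect_equal(p$t_warmup, 460)
  expect_equal(p$tau_H0 / p$tau_HL, 6)
  expect_equal(p$x_E, 200)
  expect_equal(p$delta, 60)
  expect_equal(p$x_e0, 180)
  # derived geometry: one clock cycle advects one 6-cell somite
  expect_equal(p$u * p$T_clock, 6 * p$dx)
  expect_equal(p$N, round(p$L / p$dx) + 1L)
})

test_that("validate_parameters reports each broken invariant by field", {
  p <- default_parameters()
  q <- p; q$K_FA <- q$K_FR
  v <- validate_parameters(q)
  expect_length(v, 1)
  expect_match(v, "K_FA")

  q <- p; q$tau_H0 <- 8 * q$tau_HL
  v <- validate_parameters(q)
  expect_length(v, 1)
  expect_match(v, "tau_H0.*\\[1, 7\\]")

  q <- p; q$K6 <- -1
  expect_match(validate_parameters(q), "K6")
  q <- p; q$n6 <- 0.5
  expect_match(validate_parameters(q), "n6")
  q <- p; q$N <- 40L
  expect_match(validate_parameters(q), "N")
  q <- p; q$u <- 1.7        # dx/u no longer a multiple of dt
  expect_match(validate_parameters(q), "dt")
  q <- p; q$tau_h <- 5.4321
  expect_match(validate_parameters(q), "tau_h")
  q <- p; q$erk_mode <- "wavy"
  expect_match(validate_parameters(q), "erk_mode")
  q <- p; q$x_h <- 500
  expect_match(validate_parameters(q), "x_h")
})

test_that("perturbation scenarios modify exactly what they should", {
  p <- default_parameters()
  expect_equal(apply_perturbation(p, "ripply_ko")$nu1, 0)
  expect_equal(apply_perturbation(p, "her_ko")$her_tx_mult, 0)
  expect_equal(apply_perturbation(p, "mek_inhibition")$nu_e, p$nu_e / 10)
  expect_equal(apply_perturbation(p, "no_pfl")$pfl_mult, 0)
  s <- apply_perturbation(p, "erk_stepwise")
  expect_identical(s$erk_mode, "stepwise")
  expect_equal(c(s$x_E, s$delta, s$x_e0), c(200, 60, 180))

  wt <- apply_perturbation(p, "wild_type")
  attr(wt, "scenario") <- NULL
  expect_equal(unclass(wt), unclass(p))
  # input is never mutated
  apply_perturbation(p, "ripply_ko")
  expect_equal(p$nu1, default_parameters()$nu1)
  expect_error(apply_perturbation(p, "frizzled"), "wild_type")
})

test_that("every perturbed set remains structurally valid", {
  p <- default_parameters()
  for (sc in psm_scenarios())
    expect_length(validate_parameters(apply_perturbation(p, sc)), 0)
})

test_that("config files round-trip and fall back to defaults", {
  p <- default_parameters()
  f <- withr::local_tempfile(fileext = ".json")
  write_config(p, f, scenario = "wild_type")
  q <- read_config(f, quiet = TRUE)
  expect_equal(unclass(q)[order(names(q))],
               unclass(p)[order(names(p))], tolerance = 1e-12)

  # partial config: only tau_H0 overridden, defaults elsewhere
  jsonlite::write_json(list(tau_H0 = 10.5), f, auto_unbox = TRUE)
  q <- read_config(f, quiet = TRUE)
  expect_equal(q$tau_H0, 10.5)
  expect_equal(q$K6, p$K6)

  # empty config is the default set
  jsonlite::write_json(setNames(list(), character(0)), f)
  expect_equal(read_config(f, quiet = TRUE)$L, 400)

  jsonlite::write_json(list(K9000 = 1), f, auto_unbox = TRUE)
  expect_error(read_config(f, quiet = TRUE), "unknown config key")

  jsonlite::write_json(list(K6 = -2, nA = 0.1), f, auto_unbox = TRUE)
  err <- tryCatch(read_config(f, quiet = TRUE), error = conditionMessage)
  expect_match(err, "K6")
  expect_match(err, "nA")   # all violations reported at once
})

test_that("delays are normalised to the integrator grid", {
  p <- default_parameters(tau_h = 5.40301)
  expect_equal(p$tau_h, 5.40)
  expect_length(validate_parameters(p), 0)
})
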