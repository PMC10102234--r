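# Shared fixtures: simulation runs are deterministic, so expensive runs are
# computed once and reused across test files.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .run_cache)) assign(key, fn(), envir = .run_cache)
  get(key, envir = .run_cache)
}

wt_sim <- function() cached("wt240", function()
  simulate_psm(default_parameters(), "wild_type", t_end = 240))

ripply_ko_sim <- function() cached("rko240", function()
  simulate_psm(default_parameters(), "ripply_ko", t_end = 240))

her_ko_sim <- function() cached("hko60", function()
  simulate_psm(default_parameters(), "her_ko", t_end = 60))

mek_sim <- function() cached("mek60", function()
  simulate_psm(default_parameters(), "mek_inhibition", t_end = 60))

no_pfl_sim <- function() cached("npfl120", function()
  simulate_psm(default_parameters(), "no_pfl", t_end = 120))

uniform_delay_sim <- function() cached("unif240", function()
  simulate_psm(default_parameters(tau_H0 = 2.1), "wild_type", t_end = 240))

# brute-force steady-state oracle: sign changes of P - D on a dense grid
oracle_roots <- function(F, p_r, p, n = 1e5) {
  pmax <- 10 * (p$pfl_mult + p$gamma)
  grid <- seq(0, pmax, length.out = n)
  h <- tbx6_production(grid, F, p) - (1 + p$eta * p_r) * grid
  roots <- numeric(0)
  if (h[1] == 0) roots <- 0
  sgn <- sign(h)
  ic <- which(sgn[-1] * sgn[-n] < 0)
  mid <- (grid[ic] + grid[ic + 1]) / 2
  sort(c(roots, mid))
}
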