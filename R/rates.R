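# Per-cell right-hand-side terms of the delay differential equations.
# All functions are pure and vectorised over their first arguments; the
# caller supplies the *delayed* concentrations where the equations require
# them. Rates are expressed per reference time, i.e. they are multiplied by
# mu1 (mRNAs) or mu3 (proteins) by the integrator.

.check_nonneg <- function(..., .names = NULL) {
  args <- list(...)
  if (is.null(.names)) .names <- as.character(substitute(list(...)))[-1]
  for (i in seq_along(args))
    if (any(args[[i]] < 0, na.rm = TRUE))
      stop("negative concentration passed to a rate function: ", .names[i])
  invisible(NULL)
}

#' Hill activation and repression
#'
#' `hill_act(y, K, n) = (y/K)^n / (1 + (y/K)^n)` and
#' `hill_rep(y, K, n) = 1 / (1 + (y/K)^n)`. At `y = 0` they return exactly
#' 0 and 1 respectively (no epsilon regularisation).
#'
#' @param y concentration(s), non-negative.
#' @param K dissociation constant, positive.
#' @param n Hill exponent, `>= 1`.
#' @return values in `[0, 1]`.
#' @export
hill_act <- function(y, K, n) {
  r <- (y / K)^n
  r / (1 + r)
}

#' @rdname hill_act
#' @export
hill_rep <- function(y, K, n) 1 / (1 + (y / K)^n)

#' her transcription rate
#'
#' Repression by delayed Her protein times the position-dependent Tbx6
#' requirement: anterior of the switch position `x_h` transcription needs
#' Tbx6 (Hill activation with `K2`, `n2`); posterior of it the Tbx6 factor
#' is 1 (other T-box factors substitute in the tailbud). Bounded in
#' `[0, 1]`.
#'
#' @param p_h_del delayed Her protein level(s).
#' @param p_t_del delayed Tbx6 protein level(s).
#' @param x cell position(s) in the tailbud frame, um.
#' @param p parameter set.
#' @return dimensionless production rate(s) in `[0, 1]`.
#' @export
her_transcription <- function(p_h_del, p_t_del, x, p) {
  .check_nonneg(p_h_del, p_t_del, .names = c("p_h_del", "p_t_del"))
  gate <- ifelse(x <= p$x_h, hill_act(p_t_del, p$K2, p$n2), 1)
  hill_rep(p_h_del, p$K1, p$n1) * gate
}

#' ripply transcription rate
#'
#' Maximal rate `nu1`, repressed by delayed Her protein and delayed dpErk,
#' activated by delayed Tbx6. Bounded in `[0, nu1]`. The conjunction of the
#' three gates restricts *ripply* pulses to the anterior edge of the dpErk
#' gradient, inside the Tbx6 domain, at the trough of the Her oscillation.
#'
#' @param p_h_del,p_e_del,p_t_del delayed Her, dpErk and Tbx6 levels.
#' @param p parameter set.
#' @return dimensionless production rate(s) in `[0, nu1]`.
#' @export
ripply_transcription <- function(p_h_del, p_e_del, p_t_del, p) {
  .check_nonneg(p_h_del, p_e_del, p_t_del,
                .names = c("p_h_del", "p_e_del", "p_t_del"))
  p$nu1 * hill_rep(p_h_del, p$K3, p$n3) * hill_rep(p_e_del, p$K4, p$n4) *
    hill_act(p_t_del, p$K5, p$n5)
}

#' Mature mRNA balance
#'
#' `splice_rate * m - decay_rate * M`, per reference mRNA time (the caller
#' scales by `mu1`). *her* uses `decay_rate = 1` (its mature decay is the
#' reference), *ripply* uses `mu2`.
#'
#' @param m nascent mRNA level(s).
#' @param M mature mRNA level(s).
#' @param splice_rate relative splicing rate (`mu_sh` or `mu_sr`).
#' @param decay_rate relative mature decay rate.
#' @return time derivative of `M` per reference time.
#' @export
mature_mrna_rhs <- function(m, M, splice_rate, decay_rate) {
  .check_nonneg(m, M, .names = c("m", "M"))
  splice_rate * m - decay_rate * M
}

#' Protein balance
#'
#' `translation_rate * M_del - decay_rate * pp`, per reference protein time
#' (the caller scales by `mu3`). Her uses `(nu2, mu4)` with the
#' position-dependent delay [her_translation_delay()]; Ripply uses
#' `(nu3, mu5)` with delay `tau_R`.
#'
#' @param M_del delayed mature mRNA level(s).
#' @param pp current protein level(s).
#' @param translation_rate,decay_rate relative rates.
#' @return time derivative of the protein per reference time.
#' @export
protein_rhs <- function(M_del, pp, translation_rate, decay_rate) {
  .check_nonneg(M_del, pp, .names = c("M_del", "pp"))
  translation_rate * M_del - decay_rate * pp
}

#' Position-dependent Her translational delay
#'
#' Linear gradient `tau_H(x) = tau_H0 + (tau_HL - tau_H0) * x / L` between
#' the anterior (`x = 0`) and posterior (`x = L`) delay values. The
#' anterior slowdown of this delay is what lengthens the Her period and
#' makes the clock waves travel.
#'
#' @param x position(s) in `[0, L]`, um.
#' @param p parameter set.
#' @return delay(s) in minutes.
#' @export
her_translation_delay <- function(x, p) {
  if (any(x < 0 | x > p$L)) stop("x outside the domain [0, L]")
  p$tau_H0 + (p$tau_HL - p$tau_H0) * x / p$L
}

#' Tbx6 production term
#'
#' The S-shaped production curve of the switch: positive feedback
#' (`hill_act(p_t, K6, n6)`, scaled by the scenario multiplier `pfl_mult`)
#' plus the incoherent feedforward input
#' `gamma * hill_rep(F, K_FR, nR) * hill_act(F, K_FA, nA)`, which is large
#' only at intermediate signal levels because `K_FA < K_FR`.
#'
#' @param p_t Tbx6 level(s).
#' @param F signal (Fgf) level(s).
#' @param p parameter set.
#' @return production rate(s) in `[0, pfl_mult + gamma]`.
#' @export
tbx6_production <- function(p_t, F, p) {
  .check_nonneg(p_t, F, .names = c("p_t", "F"))
  p$pfl_mult * hill_act(p_t, p$K6, p$n6) +
    p$gamma * hill_rep(F, p$K_FR, p$nR) * hill_act(F, p$K_FA, p$nA)
}

#' Tbx6 balance
#'
#' Production minus Ripply-boosted degradation
#' `(1 + eta * p_r) * p_t`, per reference protein time (scaled by `mu3` by
#' the integrator). The degradation factor `1 + eta * p_r` is the quantity
#' whose excursion above the saddle-node threshold flips the switch.
#'
#' @param p_t Tbx6 level(s).
#' @param p_r Ripply level(s).
#' @param F signal level(s).
#' @param p parameter set.
#' @return time derivative of Tbx6 per reference time.
#' @export
tbx6_rhs <- function(p_t, p_r, F, p) {
  .check_nonneg(p_r, .names = "p_r")
  tbx6_production(p_t, F, p) - (1 + p$eta * p_r) * p_t
}
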