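#' Hill-type DPAGT1 transcription rate
#'
#' Transcriptional induction of DPAGT1 by the beta-catenin/TCF complex,
#' modeled as Hill-type activation with no basal term:
#' `Tmax * c^n / (KTmRNA^n + c^n)`.
#'
#' @param complex_conc beta-catenin/TCF complex concentration (nM), >= 0.
#' @param params parameter set (uses `Tmax`, `KTmRNA`, `n_hill`).
#' @return Transcription rate (nM/min).
#' @export
transcription_rate <- function(complex_conc, params) {
  if (any(complex_conc < 0)) stop("complex concentration must be >= 0")
  p <- as.list(params)
  cn <- complex_conc^p$n_hill
  p$Tmax * cn / (p$KTmRNA^p$n_hill + cn)
}

#' Adhesivity mixing rate for a transported E-cadherin pool
#'
#' Each pool's adhesivity factor relaxes toward that of the incoming
#' E-cadherin at the fractional influx rate:
#' `d sigma_dest / dt = f_gain * (sigma_source - sigma_dest)`.
#'
#' @param sigma_dest adhesivity of the receiving pool, in \[0, 1\].
#' @param sigma_source adhesivity of the incoming E-cadherin, in \[0, 1\].
#' @param f_gain fractional influx rate (incoming flux over pool
#'   concentration), 1/min, >= 0.
#' @return d(sigma_dest)/dt (1/min).
#' @export
adhesivity_rate <- function(sigma_dest, sigma_source, f_gain) {
  if (any(sigma_dest < 0 | sigma_dest > 1) ||
      any(sigma_source < 0 | sigma_source > 1))
    stop("adhesivity factors must lie in [0, 1]")
  if (any(f_gain < 0)) stop("f_gain must be >= 0")
  f_gain * (sigma_source - sigma_dest)
}

#' Adhesivity dynamics of the ER E-cadherin pool
#'
#' ER E-cadherin is synthesized, not transported from another pool, so its
#' adhesivity relaxes toward a synthesis target set by Michaelis-Menten
#' N-glycosylation by GPT:
#' `d sigma_ER / dt = f_gain * ((1 - lambda * gpt / (KM + gpt)) - sigma_ER)`
#' with the lumped extent `lambda = Vmax t / Gmax <= 1`.
#'
#' @param sigma_er ER adhesivity factor, in \[0, 1\].
#' @param gpt GPT concentration (nM), >= 0.
#' @param f_gain fractional synthesis influx rate (1/min), >= 0.
#' @param params parameter set (uses `lambda20`, `KM20`).
#' @return d(sigma_ER)/dt (1/min).
#' @export
er_adhesivity_rate <- function(sigma_er, gpt, f_gain, params) {
  if (any(gpt < 0)) stop("GPT concentration must be >= 0")
  if (any(sigma_er < 0 | sigma_er > 1))
    stop("adhesivity factors must lie in [0, 1]")
  if (any(f_gain < 0)) stop("f_gain must be >= 0")
  p <- as.list(params)
  target <- 1 - p$lambda20 * gpt / (p$KM20 + gpt)
  f_gain * (target - sigma_er)
}

#' Adhesivity-coupled adherens junction rates
#'
#' The AJ assembly rate is proportional to the adhesivity of membrane
#' E-cadherin and the disassembly rate decreases linearly with the
#' adhesivity of junctional E-cadherin: `k24 = c24 * sigma_M`,
#' `k_m24 = c24 * (1 - sigma_AJ)`. Both are first-order rate constants and
#' nonnegative over the admissible sigma range.
#'
#' @param sigma_m membrane-pool adhesivity, in \[0, 1\].
#' @param sigma_aj junction-pool adhesivity, in \[0, 1\].
#' @param params parameter set (uses `c24`).
#' @return List with `k24` (assembly, 1/min) and `km24` (disassembly, 1/min).
#' @export
aj_rates <- function(sigma_m, sigma_aj, params) {
  if (any(sigma_m < 0 | sigma_m > 1) || any(sigma_aj < 0 | sigma_aj > 1))
    stop("adhesivity factors must lie in [0, 1]")
  c24 <- as.list(params)$c24
  list(k24 = c24 * sigma_m, km24 = c24 * (1 - sigma_aj))
}

#' Net rates of the 26 processes
#'
#' Evaluates every process rate at a given full state, following the model's
#' rate-law conventions: mass action `k X Y - k_minus (X/Y)` for binding and
#' dissociation, constant rates for synthesis, first-order rates for
#' conversion, transport and degradation, Hill activation for transcription
#' (process 12), and adhesivity-coupled first-order exchange for AJ assembly
#' (process 24). For the rapid-equilibrium processes (1, 2, 6, 8, 11) the
#' reported net rate is the equilibrium displacement `(X Y / K - complex)`
#' per unit relaxation rate; it is zero at any resolved state.
#'
#' @param state full state vector (all 24 variables, nonnegative).
#' @param params parameter set.
#' @return Named numeric vector of 26 net rates (nM/min), names `r1`..`r26`.
#' @export
reaction_rates <- function(state, params) {
  validate_state(state)
  s <- as.list(state); p <- as.list(params)
  aj <- aj_rates(s$sigma_m, s$sigma_aj, params)
  r <- c(
    r1 = s$wnt * s$lrp_m / p$K1 - s$wnt_lrp,
    r2 = s$wnt_lrp * s$axin_gsk / p$K2 - s$wnt_lrp_ag,
    r3 = p$k3 * s$apc * s$axin_gsk - p$km3 * s$bdc,
    r4 = p$k4 * s$bcat_p,
    r5 = p$k5 * s$bcat_p,
    r6 = s$bcat * s$bdc / p$K6 - s$bdc_bcat,
    r7 = p$k7 * s$bdc_bcat,
    r8 = s$bcat_p * s$bdc / p$K8 - s$bdc_bcatp,
    r9 = p$nu9,
    r10 = p$k10 * s$bcat,
    r11 = s$bcat * s$tcf / p$K11 - s$bcat_tcf,
    r12 = transcription_rate(s$bcat_tcf, params),
    r13 = p$k13 * s$dpagt1_mrna,
    r14 = p$Pmax * s$dpagt1_mrna,
    r15 = p$nu15,
    r16 = p$k16 * s$lrp_i,
    r17 = p$k17 * s$gpt * s$lrp_i,
    r18 = p$k18 * s$lrp_m,
    r19 = p$k19 * s$gpt,
    r20 = p$nu20,
    r21 = p$K21 * s$ecad_er,
    r22 = p$k22 * s$ecad_m,
    r23 = p$k23 * s$ecad_erc,
    r24 = aj$k24 * s$ecad_m - aj$km24 * s$ecad_aj,
    r25 = p$k25 * s$ecad_erc,
    r26 = p$k26 * s$ecad_erc
  )
  r
}
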