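#' Right-hand side of the full (unreduced) ODE system
#'
#' Time derivatives of all 24 state variables with the five
#' rapid-equilibrium processes given explicit mass-action kinetics:
#' association `eq_speed / K_i` (1/(nM min)) and dissociation `eq_speed`
#' (1/min). As `eq_speed` grows the full system collapses onto the reduced
#' DAE; it serves as the reference the reduction is verified against, and at
#' `eq_speed = 1` as a plain ODE formulation of the scheme.
#'
#' @param state full state vector (24 variables).
#' @param params parameter set.
#' @param eq_speed relaxation rate (1/min) of the rapid-equilibrium
#'   processes 1, 2, 6, 8, 11.
#' @return Named numeric vector of 24 time derivatives (nM/min; 1/min for
#'   the adhesivity factors).
#' @export
ode_rhs <- function(state, params, eq_speed = 1) {
  validate_state(state)
  s <- as.list(state); p <- as.list(params)
  r <- reaction_rates(state, params)
  # rapid-equilibrium displacements scaled to finite relaxation rates
  r1 <- eq_speed * r[["r1"]]; r2 <- eq_speed * r[["r2"]]
  r6 <- eq_speed * r[["r6"]]; r8 <- eq_speed * r[["r8"]]
  r11 <- eq_speed * r[["r11"]]
  r3 <- r[["r3"]]
  k7c <- r[["r7"]]
  aj <- aj_rates(s$sigma_m, s$sigma_aj, params)
  k24f <- aj$k24 * s$ecad_m
  k24b <- aj$km24 * s$ecad_aj

  d <- c(
    bcat = p$nu9 - r6 - r11 + p$k4 * s$bcat_p - p$k10 * s$bcat +
      p$k26 * s$ecad_erc,
    bcat_p = -r8 - (p$k4 + p$k5) * s$bcat_p,
    bdc = r3 - r6 - r8,
    lrp_m = -r1 + r[["r17"]] - r[["r18"]],
    lrp_i = p$nu15 - r[["r16"]] - r[["r17"]],
    dpagt1_mrna = r[["r12"]] - r[["r13"]],
    gpt = r[["r14"]] - r[["r19"]],
    ecad_er = p$nu20 - r[["r21"]],
    ecad_m = r[["r21"]] + r[["r23"]] + k24b - r[["r22"]] - k24f,
    ecad_erc = r[["r22"]] - r[["r23"]] - r[["r25"]] - r[["r26"]],
    ecad_aj = k24f - k24b,
    sigma_er = er_adhesivity_rate(s$sigma_er, s$gpt,
                                  p$nu20 / (s$ecad_er + 1e-9), params),
    sigma_m = (r[["r21"]] * (s$sigma_er - s$sigma_m) +
               r[["r23"]] * (s$sigma_erc - s$sigma_m) +
               k24b * (s$sigma_aj - s$sigma_m)) / (s$ecad_m + 1e-9),
    sigma_erc = adhesivity_rate(s$sigma_erc, s$sigma_m,
                                r[["r22"]] / (s$ecad_erc + 1e-9)),
    sigma_aj = adhesivity_rate(s$sigma_aj, s$sigma_m,
                               k24f / (s$ecad_aj + 1e-9)),
    bcat_tcf = r11,
    tcf = -r11,
    bdc_bcat = r6 - k7c,
    bdc_bcatp = r8 + k7c,
    apc = -r3,
    axin_gsk = -r2 - r3,
    wnt = -r1,
    wnt_lrp = r1 - r2,
    wnt_lrp_ag = r2
  )
  d[species_names()]
}

# Reduced system right-hand side on the internal invariant coordinates
# (11 slow totals/species + 4 adhesivity factors). The rapid-equilibrium
# complexes and conserved free species are resolved algebraically at every
# evaluation, so only slow process rates appear.
#' @keywords internal
dae_rhs_y <- function(t, y, params) {
  p <- as.list(params)
  y <- pmax(unlist(y), 0)
  y[12:15] <- pmin(y[12:15], 1)
  r <- resolve_from_totals(y, params)
  lrp_i <- y[["lrp_i"]]; mrna <- y[["dpagt1_mrna"]]; gpt <- y[["gpt"]]
  eer <- y[["ecad_er"]]; em <- y[["ecad_m"]]
  eerc <- y[["ecad_erc"]]; eaj <- y[["ecad_aj"]]
  sER <- y[["sigma_er"]]; sM <- y[["sigma_m"]]
  sERC <- y[["sigma_erc"]]; sAJ <- y[["sigma_aj"]]

  k24 <- p$c24 * sM
  km24 <- p$c24 * (1 - sAJ)
  mat <- p$k17 * gpt * lrp_i
  hill <- transcription_rate(r$bcat_tcf, params)
  f_er <- p$K21 * eer; f_rec <- p$k23 * eerc
  f_int <- p$k22 * em
  f_asm <- k24 * em; f_dis <- km24 * eaj

  dy <- c(
    Xb = p$nu9 - p$k7 * r$bdc_bcat + p$k4 * r$Bp - p$k10 * r$B +
      p$k26 * eerc,
    Xbp = p$k7 * r$bdc_bcat - (p$k4 + p$k5) * r$Bp,
    Xbdc = p$k3 * r$apc * r$AG - p$km3 * r$BDC,
    Xlrp = mat - p$k18 * r$LRP,
    lrp_i = p$nu15 - p$k16 * lrp_i - mat,
    dpagt1_mrna = hill - p$k13 * mrna,
    gpt = p$Pmax * mrna - p$k19 * gpt,
    ecad_er = p$nu20 - f_er,
    ecad_m = f_er + f_rec + f_dis - f_int - f_asm,
    ecad_erc = f_int - (p$k23 + p$k25 + p$k26) * eerc,
    ecad_aj = f_asm - f_dis,
    sigma_er = er_adhesivity_rate(sER, gpt, p$nu20 / (eer + 1e-9), params),
    sigma_m = (f_er * (sER - sM) + f_rec * (sERC - sM) +
               f_dis * (sAJ - sM)) / (em + 1e-9),
    sigma_erc = f_int / (eerc + 1e-9) * (sM - sERC),
    sigma_aj = f_asm / (eaj + 1e-9) * (sM - sAJ)
  )
  list(dy)
}

#' Right-hand side of the reduced (DAE) system at a full state
#'
#' Evaluates the 15 differential equations of the reduced system (the slow
#' invariant coordinates plus the four adhesivity factors) at a state whose
#' dependent variables have been resolved.
#'
#' @param state full state vector.
#' @param params parameter set.
#' @return Named numeric vector of 15 derivatives.
#' @export
dae_rhs <- function(state, params) {
  validate_state(state)
  y <- state_to_y(state)
  d <- dae_rhs_y(0, y, params)[[1]]
  names(d) <- .y_names
  d
}

#' @keywords internal
integrate_y <- function(params, y0, times, rtol = 1e-8, atol = 1e-10) {
  out <- deSolve::ode(y = y0, times = times, func = dae_rhs_y,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1L] < 0)
    stop("stiff integration failed (lsoda istate ",
         attr(out, "istate")[1L], ") at t ~ ", max(out[, 1]))
  out
}

#' Damped Newton solver for steady states
#'
#' Generic root finder for `f(x) = 0` with numerical forward-difference
#' Jacobian and step-halving damping, used to polish integrated states into
#' machine-precision steady states. Exposed so that small test systems with
#' known equilibria can exercise the same solver the model uses.
#'
#' @param f vector-valued function of `x`.
#' @param x0 starting point (named numeric).
#' @param tol convergence tolerance on `max(|f| / (|x| + scale))` (1/min).
#' @param scale additive state scale guarding relative rates near zero.
#' @param maxit maximum Newton iterations.
#' @return List with `x` (root), `residual` (final scaled residual norm),
#'   `converged` (logical), `iterations`.
#' @export
steady_newton <- function(f, x0, tol = 1e-11, scale = 1e-6, maxit = 60) {
  x <- x0
  n <- length(x)
  resid <- function(x) max(abs(f(x)) / (abs(x) + scale))
  r0 <- resid(x)
  for (it in seq_len(maxit)) {
    if (r0 < tol)
      return(list(x = x, residual = r0, converged = TRUE, iterations = it - 1L))
    fx <- f(x)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- max(abs(x[j]), 1e-6) * 1e-7
      xh <- x; xh[j] <- xh[j] + h
      J[, j] <- (f(xh) - fx) / h
    }
    # variables with identically zero dynamics (frozen subsystems) carry
    # zero rows; solve the active block only
    active <- rowSums(abs(J)) > 0 | abs(fx) > 0
    step <- rep(0, n)
    sol <- tryCatch(solve(J[active, active, drop = FALSE], -fx[active]),
                    error = function(e) NULL)
    if (is.null(sol))
      return(list(x = x, residual = r0, converged = FALSE, iterations = it))
    step[active] <- sol
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      rn <- tryCatch(resid(xn), error = function(e) Inf)
      if (is.finite(rn) && rn < r0) break
      lambda <- lambda / 2
      if (lambda < 1e-6) break
    }
    if (lambda < 1e-6)
      return(list(x = x, residual = r0, converged = r0 < tol, iterations = it))
    x <- xn; r0 <- rn
  }
  list(x = x, residual = r0, converged = r0 < tol, iterations = maxit)
}

#' @keywords internal
default_initial_y <- function(params) {
  p <- as.list(params)
  y <- c(Xb = 10, Xbp = 1, Xbdc = 0.5 * p$AG0, Xlrp = 5, lrp_i = 5,
         dpagt1_mrna = 1, gpt = 5,
         ecad_er = p$nu20 / max(p$K21, 1e-6), ecad_m = 20, ecad_erc = 20,
         ecad_aj = 20,
         sigma_er = 0.5, sigma_m = 0.5, sigma_erc = 0.5, sigma_aj = 0.5)
  y[.y_names]
}
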