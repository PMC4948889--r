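# Independent oracles used by the reduction and acceptance tests.

# full mass-action system with explicit fast reactions
full_ode_traj <- function(params, init_state, times, eq_speed = 1000) {
  sig <- c("sigma_er", "sigma_m", "sigma_erc", "sigma_aj")
  f <- function(t, y, parms) {
    y <- pmax(y, 0)
    y[sig] <- pmin(y[sig], 1)
    list(ode_rhs(y, parms, eq_speed = eq_speed))
  }
  deSolve::ode(unclass(init_state), times, f, params, method = "lsoda",
               rtol = 1e-9, atol = 1e-11, maxsteps = 1e5)
}

# N-glycosylation and E-cadherin branches off; LRP and downstream pools
# pinned at their initial values
frozen_params <- function(p) {
  set_parameters(p, K11 = 1e9, Tmax = 0, k13 = 0, Pmax = 0, nu15 = 0,
                 k16 = 0, k17 = 0, k18 = 0, k19 = 0, nu20 = 0, K21 = 0,
                 k22 = 0, k23 = 0, c24 = 0, k25 = 0, k26 = 0)
}

# independent steady-state oracle for the Wnt/beta-catenin core: scalar
# root-finding on free beta-catenin, with the other species eliminated by
# hand-derived equilibrium and conservation algebra (never calls the
# package's right-hand side or Newton solver)
core_oracle <- function(p, wnt0, lrp_total) {
  p <- as.list(p)
  # free Axin/GSK3 for a given destruction-complex occupancy, by scalar
  # root-finding; the Wnt/LRP pair reduces to a quadratic in free Wnt3a
  solve_receptor <- function(occ) {
    agr <- max(p$AG0 - occ, 0)
    if (agr == 0) return(0)
    h <- function(AG) {
      a <- (1 + AG / p$K2) / p$K1
      qb <- 1 + a * lrp_total - a * wnt0
      W <- (-qb + sqrt(qb^2 + 4 * a * wnt0)) / (2 * a)
      LRP <- lrp_total / (1 + W * a)
      AG * (1 + W * LRP / (p$K1 * p$K2)) - agr
    }
    stats::uniroot(h, c(0, agr), tol = 1e-14)$root
  }
  # assembled destruction complex for a given free beta-catenin
  solve_bdc <- function(B) {
    g <- function(BDC) {
      Bp <- (p$k7 * BDC * B / p$K6) / (p$k4 + p$k5)
      load <- 1 + B / p$K6 + Bp / p$K8
      AG <- solve_receptor(BDC * load)
      apc <- max(p$APC0 - BDC * load, 0)
      p$k3 * apc * AG - p$km3 * BDC
    }
    stats::uniroot(g, c(0, p$AG0), tol = 1e-14)$root
  }
  resid <- function(B) {
    BDC <- solve_bdc(B)
    p$nu9 - p$k5 / (p$k4 + p$k5) * p$k7 * BDC * B / p$K6 - p$k10 * B
  }
  stats::uniroot(resid, c(1e-6, 1e4), tol = 1e-12)$root
}
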