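#' @keywords internal
.species <- list(
  independent = c("bcat", "bcat_p", "bdc", "lrp_m", "lrp_i", "dpagt1_mrna",
                  "gpt", "ecad_er", "ecad_m", "ecad_erc", "ecad_aj",
                  "sigma_er", "sigma_m", "sigma_erc", "sigma_aj"),
  dependent = c("bcat_tcf", "tcf", "bdc_bcat", "bdc_bcatp", "apc",
                "axin_gsk", "wnt", "wnt_lrp", "wnt_lrp_ag"),
  sigma = c("sigma_er", "sigma_m", "sigma_erc", "sigma_aj")
)

#' Species names of the model state
#'
#' The full state holds 24 variables: 20 molecular concentrations (nM) and 4
#' dimensionless per-pool E-cadherin adhesivity factors. Fifteen variables
#' are independent (carry differential equations in the reduced system:
#' eleven concentrations plus the four adhesivity factors) and nine are
#' dependent (slaved through the five rapid equilibria and the four
#' conservation laws).
#'
#' @return Character vector of variable names.
#' @export
species_names <- function() c(.species$independent, .species$dependent)

#' @rdname species_names
#' @export
independent_names <- function() .species$independent

#' @rdname species_names
#' @export
dependent_names <- function() .species$dependent

#' Construct and validate a state vector
#'
#' @param x named numeric vector holding all 24 state variables.
#' @return A named numeric vector of class `rcn_state`, ordered as
#'   [species_names()].
#' @export
as_rcn_state <- function(x) {
  nm <- species_names()
  missing <- setdiff(nm, names(x))
  if (length(missing))
    stop("missing state variables: ", paste(missing, collapse = ", "))
  s <- unlist(x)[nm]
  validate_state(s)
  class(s) <- "rcn_state"
  s
}

#' @keywords internal
validate_state <- function(s, tol = 1e-8) {
  if (any(!is.finite(s))) stop("state contains non-finite values")
  if (any(s < -tol)) stop("state contains negative concentrations")
  sig <- s[.species$sigma]
  if (any(sig < -tol) || any(sig > 1 + tol))
    stop("adhesivity factors must lie in [0, 1]")
  invisible(s)
}

#' Conserved totals of a state
#'
#' Sums the free and complexed forms of the four constitutively expressed
#' molecules. Along any trajectory these must equal `WNT0`, `APC0`, `TCF0`
#' and `AG0`.
#'
#' @param state a full state vector (named numeric with all 24 variables).
#' @return Named numeric vector `c(wnt, apc, tcf, axin_gsk)`.
#' @export
conserved_totals <- function(state) {
  s <- as.list(state)
  c(wnt = s$wnt + s$wnt_lrp + s$wnt_lrp_ag,
    apc = s$apc + s$bdc + s$bdc_bcat + s$bdc_bcatp,
    tcf = s$tcf + s$bcat_tcf,
    axin_gsk = s$axin_gsk + s$wnt_lrp_ag + s$bdc + s$bdc_bcat + s$bdc_bcatp)
}

#' Solve the algebraic relations for the dependent variables
#'
#' Given the 15 independent variables, solves the 9 algebraic relations of
#' the reduced system -- the rapid equilibria of processes 1, 2, 6, 8 and 11
#' and the conservation of Wnt3a, APC, TCF and Axin/GSK-3beta -- for the 9
#' dependent variables. Given the free species, the TCF, destruction-complex
#' and APC relations are closed-form; the coupled Wnt3a / Axin-GSK3 pair
#' reduces to a quadratic with a unique nonnegative root.
#'
#' @param independent named numeric vector with the 15 independent variables
#'   (see [independent_names()]).
#' @param params an `rcn_parameters` vector.
#' @return Full `rcn_state` vector satisfying all 9 residuals.
#' @export
resolve_dependent <- function(independent, params) {
  ind <- unlist(independent)[independent_names()]
  if (any(is.na(ind))) stop("independent state is incomplete")
  if (any(ind < 0)) stop("independent state has negative entries")
  p <- as.list(params)
  B <- ind[["bcat"]]; Bp <- ind[["bcat_p"]]; BDC <- ind[["bdc"]]
  LRP <- ind[["lrp_m"]]

  tcf <- p$TCF0 / (1 + B / p$K11)
  bcat_tcf <- B * tcf / p$K11
  bdc_bcat <- BDC * B / p$K6
  bdc_bcatp <- BDC * Bp / p$K8
  apc <- p$APC0 - BDC - bdc_bcat - bdc_bcatp
  if (apc < -1e-9 * max(1, p$APC0))
    stop("degenerate parameters: assembled destruction complex exceeds total APC")
  apc <- max(apc, 0)

  # Wnt3a / Axin-GSK3 coupling: with a = LRP/K1, b = LRP/(K1 K2),
  #   WNT0 = W (1 + a + b AG),  AGr = AG (1 + b W),  AGr = AG0 - BDC pools
  # eliminating W gives b AG^2 + (1 + a + b WNT0 - b AGr) AG - AGr (1+a) = 0.
  agr <- p$AG0 - BDC - bdc_bcat - bdc_bcatp
  if (agr < -1e-9 * max(1, p$AG0))
    stop("degenerate parameters: destruction-complex pools exceed total Axin/GSK3")
  agr <- max(agr, 0)
  a <- LRP / p$K1
  b <- LRP / (p$K1 * p$K2)
  if (b == 0) {
    ag <- agr
    wnt <- p$WNT0 / (1 + a)
  } else {
    qb <- 1 + a + b * p$WNT0 - b * agr
    qc <- -agr * (1 + a)
    disc <- sqrt(qb^2 - 4 * b * qc)
    # numerically stable positive root for either sign of qb
    ag <- if (qb >= 0) -2 * qc / (qb + disc) else (-qb + disc) / (2 * b)
    ag <- max(ag, 0)
    wnt <- p$WNT0 / (1 + a + b * ag)
  }
  wnt_lrp <- wnt * LRP / p$K1
  wnt_lrp_ag <- wnt_lrp * ag / p$K2

  as_rcn_state(c(ind,
                 bcat_tcf = bcat_tcf, tcf = tcf, bdc_bcat = bdc_bcat,
                 bdc_bcatp = bdc_bcatp, apc = apc, axin_gsk = ag,
                 wnt = wnt, wnt_lrp = wnt_lrp, wnt_lrp_ag = wnt_lrp_ag))
}

#' Residuals of the 9 algebraic relations
#'
#' @param state full state vector.
#' @param params parameter set.
#' @return Named numeric vector of 9 residuals (relative scale).
#' @export
algebraic_residuals <- function(state, params) {
  s <- as.list(state); p <- as.list(params)
  sc <- function(x) max(abs(x), 1e-12)
  r <- c(
    eq1  = (s$wnt * s$lrp_m / p$K1 - s$wnt_lrp) / sc(s$wnt_lrp),
    eq2  = (s$wnt_lrp * s$axin_gsk / p$K2 - s$wnt_lrp_ag) / sc(s$wnt_lrp_ag),
    eq6  = (s$bcat * s$bdc / p$K6 - s$bdc_bcat) / sc(s$bdc_bcat),
    eq8  = (s$bcat_p * s$bdc / p$K8 - s$bdc_bcatp) / sc(s$bdc_bcatp),
    eq11 = (s$bcat * s$tcf / p$K11 - s$bcat_tcf) / sc(s$bcat_tcf)
  )
  tot <- conserved_totals(state)
  cons <- c(cons_wnt = (tot[["wnt"]] - p$WNT0) / sc(p$WNT0),
            cons_apc = (tot[["apc"]] - p$APC0) / sc(p$APC0),
            cons_tcf = (tot[["tcf"]] - p$TCF0) / sc(p$TCF0),
            cons_ag  = (tot[["axin_gsk"]] - p$AG0) / sc(p$AG0))
  c(r, cons)
}

# --- internal reduced coordinates ------------------------------------------
#
# The reduced system integrates quantities invariant under the five rapid
# reactions: totals of non-phospho cytoplasmic beta-catenin (free + bound to
# the destruction complex + bound to TCF), of phospho-beta-catenin, of the
# assembled destruction-complex core, and of mature LRP (free + Wnt-bound),
# plus the slow species and the adhesivity factors. This is the exact slow
# reduction; the naive species-level slaving does not conserve mass through
# the fast complexes during transients.

#' @keywords internal
.y_names <- c("Xb", "Xbp", "Xbdc", "Xlrp", "lrp_i", "dpagt1_mrna", "gpt",
              "ecad_er", "ecad_m", "ecad_erc", "ecad_aj",
              "sigma_er", "sigma_m", "sigma_erc", "sigma_aj")

#' @keywords internal
state_to_y <- function(state) {
  s <- as.list(state)
  y <- c(Xb = s$bcat + s$bdc_bcat + s$bcat_tcf,
         Xbp = s$bcat_p + s$bdc_bcatp,
         Xbdc = s$bdc + s$bdc_bcat + s$bdc_bcatp,
         Xlrp = s$lrp_m + s$wnt_lrp + s$wnt_lrp_ag,
         lrp_i = s$lrp_i, dpagt1_mrna = s$dpagt1_mrna, gpt = s$gpt,
         ecad_er = s$ecad_er, ecad_m = s$ecad_m, ecad_erc = s$ecad_erc,
         ecad_aj = s$ecad_aj,
         sigma_er = s$sigma_er, sigma_m = s$sigma_m,
         sigma_erc = s$sigma_erc, sigma_aj = s$sigma_aj)
  y[.y_names]
}

# Resolve the free species underlying the invariant totals, by damped fixed
# point on two small closed subsystems (each inner update is closed form).
#' @keywords internal
resolve_from_totals <- function(y, params, tol = 1e-12, maxit = 500) {
  p <- as.list(params)
  y <- pmax(y, 0)
  Xb <- y[["Xb"]]; Xbp <- y[["Xbp"]]; Xbdc <- y[["Xbdc"]]; Xlrp <- y[["Xlrp"]]

  # beta-catenin subsystem: free B, Bp, BDC from (Xb, Xbp, Xbdc)
  B <- Xb; Bp <- Xbp; BDC <- Xbdc
  for (i in seq_len(maxit)) {
    BDC_new <- Xbdc / (1 + B / p$K6 + Bp / p$K8)
    Bp_new <- Xbp / (1 + BDC_new / p$K8)
    a <- 1 + BDC_new / p$K6
    qb <- a * p$K11 + p$TCF0 - Xb
    disc <- sqrt(qb^2 + 4 * a * Xb * p$K11)
    B_new <- if (Xb == 0) 0 else if (qb >= 0)
      2 * Xb * p$K11 / (qb + disc) else (-qb + disc) / (2 * a)
    d <- max(abs(BDC_new - BDC), abs(Bp_new - Bp), abs(B_new - B))
    B <- B_new; Bp <- Bp_new; BDC <- BDC_new
    if (d < tol * max(1, B, Bp, BDC)) break
    if (i == maxit) stop("rapid-equilibrium resolution failed to converge (beta-catenin block)")
  }

  # receptor subsystem: free W, AG, LRP from (Xlrp, totals)
  agr <- max(p$AG0 - Xbdc, 0)
  W <- p$WNT0; AG <- agr; LRP <- Xlrp
  for (i in seq_len(maxit)) {
    LRP_new <- Xlrp / (1 + W / p$K1 + W * AG / (p$K1 * p$K2))
    W_new <- p$WNT0 / (1 + LRP_new / p$K1 + LRP_new * AG / (p$K1 * p$K2))
    AG_new <- agr / (1 + W_new * LRP_new / (p$K1 * p$K2))
    d <- max(abs(LRP_new - LRP), abs(W_new - W), abs(AG_new - AG))
    W <- W_new; AG <- AG_new; LRP <- LRP_new
    if (d < tol * max(1, W, AG, LRP)) break
    if (i == maxit) stop("rapid-equilibrium resolution failed to converge (receptor block)")
  }

  list(B = B, Bp = Bp, BDC = BDC, W = W, AG = AG, LRP = LRP,
       bdc_bcat = BDC * B / p$K6, bdc_bcatp = BDC * Bp / p$K8,
       bcat_tcf = B * p$TCF0 / (p$K11 + B),
       tcf = p$TCF0 / (1 + B / p$K11),
       apc = max(p$APC0 - Xbdc, 0),
       wnt_lrp = W * LRP / p$K1,
       wnt_lrp_ag = W * LRP * AG / (p$K1 * p$K2))
}

#' @keywords internal
y_to_state <- function(y, params) {
  r <- resolve_from_totals(y, params)
  s <- c(bcat = r$B, bcat_p = r$Bp, bdc = r$BDC, lrp_m = r$LRP,
         lrp_i = max(y[["lrp_i"]], 0), dpagt1_mrna = max(y[["dpagt1_mrna"]], 0),
         gpt = max(y[["gpt"]], 0),
         ecad_er = max(y[["ecad_er"]], 0), ecad_m = max(y[["ecad_m"]], 0),
         ecad_erc = max(y[["ecad_erc"]], 0), ecad_aj = max(y[["ecad_aj"]], 0),
         sigma_er = min(max(y[["sigma_er"]], 0), 1),
         sigma_m = min(max(y[["sigma_m"]], 0), 1),
         sigma_erc = min(max(y[["sigma_erc"]], 0), 1),
         sigma_aj = min(max(y[["sigma_aj"]], 0), 1),
         bcat_tcf = r$bcat_tcf, tcf = r$tcf, bdc_bcat = r$bdc_bcat,
         bdc_bcatp = r$bdc_bcatp, apc = r$apc, axin_gsk = r$AG,
         wnt = r$W, wnt_lrp = r$wnt_lrp, wnt_lrp_ag = r$wnt_lrp_ag)
  as_rcn_state(s)
}
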