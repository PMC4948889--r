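test_that("transcription rate follows Hill activation", {
  p <- ref_params()
  expect_equal(transcription_rate(0, p), 0)
  expect_equal(transcription_rate(p[["KTmRNA"]], p), p[["Tmax"]] / 2)
  expect_equal(transcription_rate(1e9, p), p[["Tmax"]], tolerance = 1e-6)
  expect_error(transcription_rate(-1, p), ">= 0")
})

test_that("adhesivity mixing and ER glycosylation rates follow their laws", {
  p <- ref_params()
  expect_equal(adhesivity_rate(0.5, 0.5, 0.3), 0)
  expect_equal(adhesivity_rate(0.2, 0.8, 0), 0)
  expect_equal(adhesivity_rate(0.2, 0.8, 0.1), 0.06)
  expect_error(adhesivity_rate(1.2, 0.5, 0.1), "\\[0, 1\\]")

  # gpt = 0: relaxes toward fully adhesive target
  expect_equal(er_adhesivity_rate(0.4, 0, 0.2, p), 0.2 * (1 - 0.4))
  # half saturation with lambda = 1
  p1 <- set_parameters(p, lambda20 = 1)
  expect_equal(er_adhesivity_rate(0.2, p1[["KM20"]], 0.1, p1),
               0.1 * (0.5 - 0.2))
  # saturating gpt with lambda = 1 drives target to 0
  expect_equal(er_adhesivity_rate(0, 1e12, 0.1, p1), 0, tolerance = 1e-9)
  expect_error(er_adhesivity_rate(0.5, -1, 0.1, p), ">= 0")
})

test_that("adherens-junction rates couple linearly to adhesivity", {
  p <- ref_params()
  expect_equal(aj_rates(0, 0.5, p)$k24, 0)
  expect_equal(aj_rates(0.5, 1, p)$km24, 0)
  expect_equal(aj_rates(1, 0.5, p)$k24, p[["c24"]])
  r <- aj_rates(0.3, 0.7, p)
  expect_gte(r$k24, 0)
  expect_gte(r$km24, 0)
})

test_that("process rates follow the mass-action conventions", {
  p <- ref_params()
  st <- ref_off()
  r <- reaction_rates(st, p)
  expect_length(r, 26)
  # synthesis rates are state-independent constants
  expect_equal(r[["r9"]], p[["nu9"]])
  expect_equal(r[["r20"]], p[["nu20"]])
  # rapid-equilibrium processes have zero net rate at a resolved state
  expect_equal(unname(r[c("r1", "r2", "r6", "r8", "r11")]),
               rep(0, 5), tolerance = 1e-10)
  # binding with absent partners and absent complex: zero rate
  st0 <- unclass(st)
  st0[c("wnt", "lrp_m", "wnt_lrp")] <- 0
  expect_equal(reaction_rates(as_rcn_state(st0), p)[["r1"]], 0)
  st0["bcat"] <- -1
  expect_error(reaction_rates(st0, p), "negative")
})

test_that("full ODE right-hand side conserves the constitutive totals", {
  p <- ref_params()
  for (st in list(ref_off(), ref_on())) {
    d <- ode_rhs(st, p, eq_speed = 7)
    expect_equal(d[["wnt"]] + d[["wnt_lrp"]] + d[["wnt_lrp_ag"]], 0,
                 tolerance = 1e-12)
    expect_equal(d[["apc"]] + d[["bdc"]] + d[["bdc_bcat"]] +
                   d[["bdc_bcatp"]], 0, tolerance = 1e-12)
    expect_equal(d[["tcf"]] + d[["bcat_tcf"]], 0, tolerance = 1e-12)
    expect_equal(d[["axin_gsk"]] + d[["wnt_lrp_ag"]] + d[["bdc"]] +
                   d[["bdc_bcat"]] + d[["bdc_bcatp"]], 0, tolerance = 1e-12)
  }
})

test_that("slow dynamics vanish at the resolved equilibrium", {
  # at the reduced equilibrium the fast-invariant combinations of the full
  # system are stationary (individual complexes still carry the slow flux)
  d <- ode_rhs(ref_off(), ref_params(), eq_speed = 100)
  sums <- c(
    d[["bcat"]] + d[["bdc_bcat"]] + d[["bcat_tcf"]],
    d[["bcat_p"]] + d[["bdc_bcatp"]],
    d[["bdc"]] + d[["bdc_bcat"]] + d[["bdc_bcatp"]],
    d[["lrp_m"]] + d[["wnt_lrp"]] + d[["wnt_lrp_ag"]],
    d[c("lrp_i", "dpagt1_mrna", "gpt", "ecad_er", "ecad_m", "ecad_erc",
        "ecad_aj", "sigma_er", "sigma_m", "sigma_erc", "sigma_aj")])
  expect_lt(max(abs(sums)), 1e-9)
  # and the reduced right-hand side itself is zero there
  expect_lt(max(abs(dae_rhs(ref_off(), ref_params()))), 1e-9)
})

test_that("single-reaction scheme matches a hand-written mass-action oracle", {
  # A + B <-> C alone: package rate law vs direct formula on random states
  toy <- toy_binding_network(K = 2, A0 = 3, B0 = 5, kon = 0.7)
  set.seed(42)
  for (cc in runif(5, 0, 3)) {
    manual <- 0.7 * ((3 - cc) * (5 - cc) - 2 * cc)
    expect_equal(toy$rhs(cc), manual)
  }
})

test_that("resolve_dependent satisfies all nine algebraic relations", {
  p <- ref_params()
  ind <- unclass(ref_off())[independent_names()]
  st <- resolve_dependent(ind, p)
  expect_lt(max(abs(algebraic_residuals(st, p))), 1e-9)
  tot <- conserved_totals(st)
  expect_equal(unname(tot), unname(p[c("WNT0", "APC0", "TCF0", "AG0")]),
               tolerance = 1e-9)
  # all binding partners absent: every complex is zero
  ind0 <- ind
  ind0[c("bcat", "bcat_p", "bdc", "lrp_m")] <- 0
  st0 <- resolve_dependent(ind0, set_parameters(p, WNT0 = 0))
  expect_equal(unname(st0[c("bcat_tcf", "bdc_bcat", "bdc_bcatp",
                            "wnt_lrp", "wnt_lrp_ag")]), rep(0, 5))
  expect_error(resolve_dependent(ind[-1], p), "incomplete")
})

test_that("dependent resolution agrees with a fast-equilibrium ODE run", {
  # long-time limit of the full ODE with rapid reactions sped up x1000
  p <- ref_params()
  st <- ref_off()
  y0 <- unclass(st)
  # perturb the complexes away from equilibrium; totals kept by moving mass
  y0["bcat_tcf"] <- y0["bcat_tcf"] * 0.5
  y0["tcf"] <- p[["TCF0"]] - y0["bcat_tcf"]
  f <- function(t, y, parms) {
    y <- pmax(y, 0)
    y[c("sigma_er", "sigma_m", "sigma_erc", "sigma_aj")] <-
      pmin(y[c("sigma_er", "sigma_m", "sigma_erc", "sigma_aj")], 1)
    list(ode_rhs(y, parms, eq_speed = 1000))
  }
  out <- deSolve::ode(y0, c(0, 5), f, p, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  final <- out[nrow(out), -1]
  res <- resolve_dependent(final[independent_names()], p)
  # residual displacement of the fast complexes scales as 1/eq_speed
  expect_equal(unname(final[dependent_names()]),
               unname(res[dependent_names()]), tolerance = 1e-3)
})
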