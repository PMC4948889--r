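test_that("the Newton solver reproduces the toy network's closed form", {
  toy <- toy_binding_network(K = 1, A0 = 1, B0 = 1)
  ns <- steady_newton(function(x) toy$rhs(x), c(c = 0.1))
  expect_true(ns$converged)
  expect_equal(unname(ns$x), (3 - sqrt(5)) / 2, tolerance = 1e-9)
  # weak and tight binding limits
  expect_lt(toy_binding_network(K = 1e9)$equilibrium, 1e-8)
  expect_equal(toy_binding_network(K = 1e-12, A0 = 1, B0 = 2)$equilibrium,
               1, tolerance = 1e-5)
})

test_that("steady states persist under re-integration", {
  p <- ref_params()
  st <- ref_off()
  expect_lt(attr(st, "residual"), 1e-10)
  traj <- time_course(p, initial = st, t_grid = c(0, 500, 1000))
  drift <- abs(as.numeric(traj[nrow(traj), -1]) - as.numeric(st)) /
    (abs(as.numeric(st)) + 1e-8)
  expect_lt(max(drift), 1e-4)
})

test_that("activation at the OFF level leaves the trajectory flat", {
  p <- ref_params()
  traj <- time_course(p, initial = ref_off(), wnt0_on = p[["WNT0"]],
                      t_grid = c(0, 200, 1000, 3000))
  for (v in species_names())
    expect_equal(traj[[v]], rep(traj[[v]][1], nrow(traj)),
                 tolerance = 1e-6)
})

test_that("conserved totals stay constant along activation trajectories", {
  traj <- time_course(ref_params(), initial = ref_off(), wnt0_on = 28.062,
                      t_grid = c(0, 10, 100, 1000, 4320))
  tot <- t(apply(traj[, -1], 1, function(r) conserved_totals(r)))
  expected <- c(28.062, 100, 15, 30)
  for (j in 1:4)
    expect_equal(tot[, j], rep(expected[j], nrow(tot)), tolerance = 1e-6)
})

test_that("fold change is the ratio to the OFF equilibrium", {
  off <- ref_off()
  traj <- time_course(ref_params(), initial = off, wnt0_on = 28.062,
                      t_grid = c(0, 100, 4320))
  fc <- fold_change(traj, off, times = 4320,
                    variables = c("bcat", "gpt", "ecad_aj"))
  expect_equal(fc$fold[fc$variable == "bcat"],
               traj$bcat[traj$time == 4320] / off[["bcat"]])
  expect_gt(fc$fold[fc$variable == "bcat"], 1)
  # identical ON and OFF: all ratios one
  d0 <- cbind(time = 0, as.data.frame(t(unclass(off))))
  fc0 <- fold_change(d0, off, times = 0)
  expect_equal(fc0$fold, rep(1, nrow(fc0)), tolerance = 1e-9)
  # zero OFF concentration is rejected
  off0 <- unclass(off); off0["gpt"] <- 0
  expect_error(fold_change(traj, off0, variables = "gpt"), "undefined")
  # fold at 72 h equals an independent re-integration
  traj2 <- time_course(ref_params(), initial = off, wnt0_on = 28.062,
                       t_grid = c(0, 1440, 4320))
  expect_equal(traj$bcat[traj$time == 4320],
               traj2$bcat[traj2$time == 4320], tolerance = 1e-7)
})

test_that("steady-state fold change matches the trajectory limit", {
  f <- ref_fold()
  traj <- time_course(ref_params(), initial = ref_off(), wnt0_on = 28.062,
                      t_grid = c(0, 9000))
  expect_equal(traj$bcat[2] / ref_off()[["bcat"]], f[["bcat"]],
               tolerance = 1e-3)
})

test_that("activation strength is monotone in total Wnt3a", {
  p <- ref_params()
  off <- ref_off()
  folds <- vapply(c(1, 5, 12, 28.062), function(w)
    find_steady_state(p, wnt0 = w, init = off)[["bcat"]] / off[["bcat"]],
    numeric(1))
  expect_true(all(diff(folds) >= -1e-9))
  expect_equal(folds[1], 1, tolerance = 1e-8)
})

test_that("condition presets are deterministic and correctly wired", {
  pr <- run_preset("reference", "wnt_off")
  expect_equal(as.numeric(pr$state), as.numeric(ref_off()),
               tolerance = 1e-9)
  expect_equal(pr$params[["WNT0"]], 1)
  pd <- run_preset("dysregulated", "wnt_on")
  expect_equal(pd$params[["K11"]], 2 * ref_params()[["K11"]])
  expect_equal(pd$params[["WNT0"]], 28.062)
  pd2 <- run_preset("dysregulated", "wnt_on")
  expect_identical(pd$observables, pd2$observables)
  expect_error(run_preset("nonsense"), "arg")
})

test_that("trajectories export as tidy CSV", {
  traj <- time_course(ref_params(), initial = ref_off(),
                      t_grid = c(0, 100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  long <- utils::read.csv(path)
  expect_named(long, c("time", "variable", "value"))
  expect_equal(nrow(long), 2 * 24)
  expect_equal(long$value[long$variable == "bcat" & long$time == 0],
               ref_off()[["bcat"]], tolerance = 1e-9)
})
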