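test_that("sweep factors form a symmetric log grid over two decades", {
  f <- sweep_factors()
  expect_equal(length(f), 18)
  expect_equal(min(f), 0.1)
  expect_equal(max(f), 10)
  expect_false(any(f == 1))
  expect_equal(sort(log10(f)), sort(-log10(f)), tolerance = 1e-12)
  expect_error(sweep_factors(1), ">= 2")
})

test_that("relative sensitivity follows its defining ratio", {
  expect_equal(relative_sensitivity(2, 2, 10), 0)
  expect_equal(relative_sensitivity(2 * 1.5, 1.5, 10), 1 / 9)
  # sign-blind and unit-free
  expect_equal(relative_sensitivity(0.5, 1, 0.1),
               relative_sensitivity(0.5 * 7, 1 * 7, 0.1))
  expect_error(relative_sensitivity(1, 1, 1), "F = 1")
  expect_error(relative_sensitivity(1, 0, 2), "> 0")
})

test_that("small-factor sensitivity approaches the log-derivative", {
  # oracle: central finite difference of the fold change in nu9
  p <- ref_params()
  fp <- ref_fold()
  h <- 0.01
  f_up <- steady_fold_change(set_parameters(p, nu9 = p[["nu9"]] * (1 + h)),
                             28.062, off_init = ref_off(), on_init = ref_on())
  f_dn <- steady_fold_change(set_parameters(p, nu9 = p[["nu9"]] * (1 - h)),
                             28.062, off_init = ref_off(), on_init = ref_on())
  for (v in c("bcat", "gpt", "ecad_aj")) {
    oracle <- abs((f_up[[v]] - f_dn[[v]]) / (2 * h * fp[[v]]))
    s_small <- relative_sensitivity(f_up[[v]], fp[[v]], 1 + h)
    expect_equal(s_small, oracle, tolerance = 0.05)
  }
})

test_that("impact classification applies the twice/half rule", {
  m <- matrix(1, nrow = 4, ncol = 2,
              dimnames = list(paste0("p", 1:4), c("a", "b")))
  expect_true(all(classify_impact(m) == "neutral"))
  m[1, 1] <- 10
  fl <- classify_impact(m)
  expect_equal(fl["p1", "a"], "high")
  expect_equal(unname(fl[2:4, "a"]), rep("low", 3))
  # scale invariance
  expect_identical(classify_impact(m), classify_impact(m * 137))
})

test_that("sensitivity sweep is deterministic and order-invariant", {
  p <- ref_params()
  fac <- c(0.5, 2)
  s1 <- suppressWarnings(
    lsa(p, factors = fac, variables = c("bcat", "gpt", "ecad_aj")))
  s2 <- suppressWarnings(
    lsa(p, factors = rev(fac), variables = c("bcat", "gpt", "ecad_aj")))
  expect_equal(nrow(s1$ranking), 33)
  o <- order(s1$cells$parameter, s1$cells$factor, s1$cells$variable)
  o2 <- order(s2$cells$parameter, s2$cells$factor, s2$cells$variable)
  expect_equal(s1$cells[o, ], s2$cells[o2, ], ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(s1$ranking$parameter, s2$ranking$parameter)
})
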