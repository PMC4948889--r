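make_frame <- function(u, v, n = 8, spacing = 10) {
  g <- expand.grid(x = (seq_len(n) - 1) * spacing,
                   y = (seq_len(n) - 1) * spacing)
  data.frame(time = 30, x = g$x, y = g$y, u = u, v = v)
}

test_that("lateral fluctuations are zero-mean deviations of the y-component", {
  fr <- make_frame(u = 0.5, v = 0.2)   # uniform lateral flow
  expect_equal(lateral_fluctuations(fr), rep(0, nrow(fr)))
  fr2 <- make_frame(u = rnorm(64), v = 0)  # purely wound-directed
  expect_equal(lateral_fluctuations(fr2), rep(0, 64))
  set.seed(1)
  fr3 <- make_frame(u = 0, v = rnorm(64))
  expect_equal(mean(lateral_fluctuations(fr3)), 0, tolerance = 1e-12)
  expect_error(lateral_fluctuations(fr3[1, ]), "at least 2")
})

test_that("correlation profile is normalized and detects independence", {
  set.seed(11)
  fr <- make_frame(u = 0, v = rnorm(64))
  pr <- correlation_profile(fr)
  expect_equal(pr$C[pr$r == 0], 1)
  expect_true(all(abs(pr$C) <= 1 + 1e-12))
  # white noise: correlations at r > 0 are small
  expect_lt(max(abs(pr$C[pr$r > 0 & pr$n_pairs > 50])), 0.35)
  expect_error(correlation_profile(make_frame(u = 1, v = 0)),
               "zero-variance")
})

test_that("correlation profile is invariant to drift and rescaling", {
  set.seed(4)
  fr <- make_frame(u = 0.1, v = rnorm(64))
  pr <- correlation_profile(fr)
  fr_shift <- fr; fr_shift$v <- fr$v + 3.7
  fr_scale <- fr; fr_scale$u <- fr$u * 5; fr_scale$v <- fr$v * 5
  expect_equal(correlation_profile(fr_shift)$C, pr$C, tolerance = 1e-12)
  expect_equal(correlation_profile(fr_scale)$C, pr$C, tolerance = 1e-12)
})

test_that("imposed correlation length is recovered from synthetic fields", {
  vf <- synthetic_velocity_fields(L = 50, n_frames = 12, seed = 7)
  L_fit <- correlation_length(vf, method = "fit")
  expect_lt(abs(L_fit - 50) / 50, 0.25)
  # delta-correlated field: threshold length collapses to the first bin
  vf_w <- synthetic_velocity_fields(L = 1e-3, fluct_sd = 0.3, angle_sd = 0,
                                    n_frames = 3, seed = 5)
  L_thr <- correlation_length(vf_w, method = "threshold")
  expect_lte(L_thr, 24 * 1.5)
  # time-constant sequence: the average equals the single-frame value
  one <- vf[vf$time == max(vf$time), ]
  two <- rbind(transform(one, time = 90), transform(one, time = 120))
  cl <- correlation_length(as_velocity_fields(two), method = "fit")
  pf <- attr(cl, "per_frame")
  expect_equal(pf[1], pf[2])
  expect_equal(as.numeric(cl), pf[1])
})

test_that("exclusion window drops the first frames", {
  vf <- synthetic_velocity_fields(L = 50, n_frames = 4, frame_interval = 30,
                                  seed = 2)
  cl <- correlation_length(vf, exclusion = 60, method = "fit")
  expect_length(attr(cl, "per_frame"), 2)  # frames at 90 and 120 min kept
  expect_error(correlation_length(vf, exclusion = 1e5), "no frames")
})

test_that("movement-angle maps are normalized occupancy histograms", {
  fr <- make_frame(u = 1, v = 0)
  m <- movement_angle_map(as_velocity_fields(fr))
  expect_equal(rowSums(m), c("30" = 1))
  centers <- as.numeric(colnames(m))
  expect_equal(sum(m[1, abs(centers) < 5]), 1)  # all mass in the 0-deg bin
  # isotropic field: approximately uniform occupancy
  vf_iso <- synthetic_velocity_fields(angle_sd = 360, fluct_sd = 0,
                                      shape = c(40, 40), n_frames = 6,
                                      seed = 9)
  m_iso <- movement_angle_map(vf_iso, n_bins = 12)
  expect_equal(rowSums(m_iso), rep(1, 6), ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(m_iso) - 1 / 12)), 0.02)
  # rotation by one bin width shifts the map by one bin
  fr_rot <- fr
  ang <- 2 * pi * 5 / 360
  fr_rot$u <- fr$u * cos(ang); fr_rot$v <- fr$u * sin(ang)
  m_rot <- movement_angle_map(as_velocity_fields(fr_rot))
  expect_equal(unname(m_rot[1, ]), c(unname(m[1, ncol(m)]),
                                     unname(m[1, -ncol(m)])))
  # zero vectors are excluded and counted
  fr0 <- rbind(fr, transform(fr[1:3, ], u = 0, v = 0))
  m0 <- movement_angle_map(as_velocity_fields(fr0))
  expect_equal(attr(m0, "n_zero"), 3L)
  expect_equal(rowSums(m0), c("30" = 1))
})

test_that("leading-edge speed follows front arithmetic and survives noise", {
  # 10 px/frame at 1 um/px and 30 min/frame: 20 um/h
  masks <- synthetic_front_masks(speed = 20, noise_px = 0, n_frames = 10,
                                 nx = 120, pixel_size = 1,
                                 frame_interval = 30)
  sp <- leading_edge_speed(masks, frame_interval = 30, pixel_size = 1)
  expect_equal(as.numeric(sp), 20, tolerance = 0.02)
  # static front
  m0 <- synthetic_front_masks(speed = 0, n_frames = 4)
  expect_equal(as.numeric(leading_edge_speed(m0)), 0, tolerance = 1e-9)
  # noisy front recovered within 5%
  mn <- synthetic_front_masks(speed = 20, noise_px = 2, seed = 3)
  spn <- leading_edge_speed(mn, frame_interval = 30, pixel_size = 1.125)
  expect_lt(abs(as.numeric(spn) - 20) / 20, 0.05)
  # front that never reaches the FOV end: slope fallback is flagged
  mshort <- synthetic_front_masks(speed = 5, n_frames = 5, nx = 500)
  sps <- leading_edge_speed(mshort, frame_interval = 30, pixel_size = 1.125)
  expect_true(attr(sps, "fallback"))
  expect_equal(as.numeric(sps), 5, tolerance = 0.2)
})

test_that("velocity fields round-trip through CSV and frame directories", {
  vf <- synthetic_velocity_fields(n_frames = 2, shape = c(8, 8), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_velocity_fields(vf, path)
  back <- read_velocity_fields(path)
  expect_equal(as.data.frame(back), as.data.frame(vf), tolerance = 1e-12)
  # per-frame directory layout
  dir <- withr::local_tempdir()
  for (t in unique(vf$time)) {
    fr <- vf[vf$time == t, c("x", "y", "u", "v")]
    utils::write.csv(fr, file.path(dir, sprintf("frame_%03d.csv", t)),
                     row.names = FALSE)
  }
  back2 <- read_velocity_fields(dir, frame_interval = 30)
  expect_equal(sort(unique(back2$time)), c(30, 60))
  expect_equal(back2$u, back$u, tolerance = 1e-12)
})
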