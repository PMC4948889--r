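#' Analytically solvable two-species binding network
#'
#' A single reversible binding reaction `A + B <-> C` with dissociation
#' constant `K` and conserved totals, whose equilibrium complex
#' concentration has the closed quadratic form
#' `C* = ((A0 + B0 + K) - sqrt((A0 + B0 + K)^2 - 4 A0 B0)) / 2`.
#' Used as an independent oracle for the steady-state solver.
#'
#' @param K dissociation constant (nM).
#' @param A0,B0 conserved totals (nM).
#' @param kon association rate (1/(nM min)); `koff = kon * K`.
#' @return List with `params`, `rhs(c)` (the complex ODE right-hand side),
#'   and `equilibrium` (closed-form complex concentration).
#' @examples
#' toy <- toy_binding_network(K = 1, A0 = 1, B0 = 1)
#' toy$equilibrium            # (3 - sqrt(5)) / 2
#' @export
toy_binding_network <- function(K = 1, A0 = 1, B0 = 1, kon = 1) {
  if (K <= 0 || A0 < 0 || B0 < 0) stop("invalid toy-network parameters")
  s <- A0 + B0 + K
  ceq <- (s - sqrt(s^2 - 4 * A0 * B0)) / 2
  list(params = c(K = K, A0 = A0, B0 = B0, kon = kon),
       rhs = function(cc) kon * ((A0 - cc) * (B0 - cc) - K * cc),
       equilibrium = ceq)
}

# Zero-mean Gaussian random field on an nx x ny grid (spacing h, um) with
# isotropic exponential covariance exp(-r/L), by spectral filtering of white
# noise with the 2-D spectral density S(k) ~ (1 + (kL)^2)^(-3/2).
#' @keywords internal
correlated_field <- function(nx, ny, h, L, pad = 2) {
  Nx <- pad * nx; Ny <- pad * ny
  kx <- 2 * pi * c(0:(Nx %/% 2), -((Nx - Nx %/% 2 - 1):1)) / (Nx * h)
  ky <- 2 * pi * c(0:(Ny %/% 2), -((Ny - Ny %/% 2 - 1):1)) / (Ny * h)
  k2 <- outer(kx^2, ky^2, "+")
  amp <- (1 + k2 * L^2)^(-0.75)
  w <- matrix(stats::rnorm(Nx * Ny), Nx, Ny)
  f <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (Nx * Ny)
  f <- f[seq_len(nx), seq_len(ny)]
  (f - mean(f)) / stats::sd(f)
}

#' Synthetic PIV velocity fields with imposed correlation structure
#'
#' Emulates PIV output from a wound-closure recording: a mean flow toward
#' the wound (+x) with per-vector directional noise, plus lateral velocity
#' fluctuations drawn from a Gaussian random field with exponential spatial
#' covariance of length `L`. Deterministic for a given seed.
#'
#' @param L lateral correlation length (um).
#' @param v_mean mean wound-directed speed (um/min).
#' @param angle_sd per-vector directional spread (degrees); values >= 180
#'   give isotropic directions.
#' @param fluct_sd standard deviation of the correlated lateral
#'   fluctuations (um/min).
#' @param shape grid dimensions `c(nx, ny)` (each >= 8).
#' @param spacing grid spacing (um); default 24 (PIV window scale).
#' @param n_frames number of frames.
#' @param frame_interval min between frames.
#' @param seed RNG seed.
#' @return An `rcn_velocity_fields` data.frame.
#' @export
synthetic_velocity_fields <- function(L = 50, v_mean = 0.3, angle_sd = 15,
                                      fluct_sd = 0.15, shape = c(24, 24),
                                      spacing = 24, n_frames = 28,
                                      frame_interval = 30, seed = 1) {
  if (L <= 0) stop("L must be > 0")
  if (any(shape < 8)) stop("grid must be at least 8 x 8")
  set.seed(seed)
  nx <- shape[1]; ny <- shape[2]
  grid <- expand.grid(x = (seq_len(nx) - 1) * spacing,
                      y = (seq_len(ny) - 1) * spacing)
  frames <- lapply(seq_len(n_frames), function(k) {
    if (angle_sd >= 180) {
      theta <- stats::runif(nrow(grid), -pi, pi)
    } else {
      theta <- stats::rnorm(nrow(grid), 0, angle_sd * pi / 180)
    }
    fl <- fluct_sd * as.vector(correlated_field(nx, ny, spacing, L))
    data.frame(time = k * frame_interval, x = grid$x, y = grid$y,
               u = v_mean * cos(theta),
               v = v_mean * sin(theta) + fl)
  })
  as_velocity_fields(do.call(rbind, frames))
}

#' Synthetic advancing-front mask stack
#'
#' Binary fluorescence-front masks of a monolayer edge advancing at a known
#' speed with per-row pixel jitter, for testing the leading-edge speed
#' estimator.
#'
#' @param speed front speed (um/h).
#' @param noise_px per-row front jitter (pixels, s.d.).
#' @param n_frames number of frames.
#' @param ny,nx mask dimensions (pixels).
#' @param pixel_size um per pixel.
#' @param frame_interval min between frames.
#' @param x0 initial front position (pixels).
#' @param seed RNG seed.
#' @return Logical array `ny x nx x n_frames` with attributes `pixel_size`
#'   and `frame_interval`.
#' @export
synthetic_front_masks <- function(speed = 20, noise_px = 0, n_frames = 28,
                                  ny = 64, nx = 128, pixel_size = 1.125,
                                  frame_interval = 30, x0 = 5, seed = 1) {
  if (speed < 0) stop("speed must be >= 0")
  set.seed(seed)
  arr <- array(FALSE, dim = c(ny, nx, n_frames))
  for (k in seq_len(n_frames)) {
    t_h <- (k - 1) * frame_interval / 60
    pos <- rep(x0 + speed * t_h / pixel_size, ny) +
      if (noise_px > 0) stats::rnorm(ny, 0, noise_px) else 0
    pos <- pmin(pmax(round(pos), 1), nx)
    for (i in seq_len(ny)) arr[i, seq_len(pos[i]), k] <- TRUE
  }
  attr(arr, "pixel_size") <- pixel_size
  attr(arr, "frame_interval") <- frame_interval
  arr
}

#' Noisy fold-change observations as a calibration constraint set
#'
#' Simulates the reference Wnt OFF equilibrium and the activation fold
#' changes under a given parameter set, perturbs the observables with
#' lognormal noise, and packages them as calibration targets. With zero
#' noise, [constraint_report()] on the generating parameters passes
#' exactly.
#'
#' @param params generating parameter set.
#' @param noise_sd_log standard deviation of the lognormal noise (log
#'   scale).
#' @param seed RNG seed.
#' @param variables observables to include as fold-change targets.
#' @param wnt0_on ON-state total Wnt3a (nM).
#' @param tol relative tolerance recorded on each target.
#' @return An `rcn_constraints` list (see [as_constraints()]).
#' @export
noisy_foldchange_observations <- function(params, noise_sd_log = 0,
                                          seed = 1,
                                          variables = c("bcat", "gpt",
                                                        "ecad_aj",
                                                        "sigma_aj"),
                                          wnt0_on = 28.062, tol = 0.1) {
  set.seed(seed)
  f <- steady_fold_change(params, wnt0_on)
  off <- attr(f, "off")
  noise <- function() if (noise_sd_log > 0)
    exp(stats::rnorm(1, 0, noise_sd_log)) else 1
  cs <- lapply(variables, function(v)
    list(name = paste0("fold_", v), type = "fold_change", variable = v,
         wnt0_on = wnt0_on, target = unname(f[[v]]) * noise(),
         tol = tol, weight = 1))
  cs <- c(cs, list(list(name = "bcat_off", type = "steady_state",
                        variable = "bcat", wnt0 = params[["WNT0"]],
                        target = unname(off[["bcat"]]) * noise(),
                        tol = tol, weight = 1)))
  as_constraints(cs)
}
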