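#' Velocity-field containers
#'
#' Collective-migration metrics consume time-resolved 2-D velocity fields as
#' produced by particle image velocimetry (PIV): regular grid positions
#' (um) with per-vector velocity components (um/min). By convention `u` is
#' the component along the wound-closure axis (x) and `v` the lateral
#' component (y).
#'
#' @param df data.frame with columns `time` (min), `x`, `y` (um), `u`, `v`
#'   (um/min).
#' @return A `rcn_velocity_fields` data.frame.
#' @export
as_velocity_fields <- function(df) {
  need <- c("time", "x", "y", "u", "v")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(df[need]))))
    stop("velocity fields must be finite")
  df <- as.data.frame(df)[need]
  class(df) <- c("rcn_velocity_fields", "data.frame")
  df
}

#' Read or write velocity fields
#'
#' Long-format delimited text with columns `time`, `x`, `y`, `u`, `v`
#' (single file), or one file per frame with columns `x`, `y`, `u`, `v`.
#'
#' @param path CSV file (long format) or directory of per-frame files.
#' @param fields an `rcn_velocity_fields` object.
#' @param frame_interval min between frames, used to assign times when
#'   reading a per-frame directory.
#' @return `read_velocity_fields()` returns an `rcn_velocity_fields`;
#'   `write_velocity_fields()` returns `path` invisibly.
#' @export
read_velocity_fields <- function(path, frame_interval = 30) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(csv|txt|tsv)$",
                             full.names = TRUE))
    if (!length(files)) stop("no frame files found in ", path)
    frames <- lapply(seq_along(files), function(i) {
      d <- utils::read.csv(files[i])
      d$time <- i * frame_interval
      d
    })
    return(as_velocity_fields(do.call(rbind, frames)))
  }
  as_velocity_fields(utils::read.csv(path))
}

#' @rdname read_velocity_fields
#' @export
write_velocity_fields <- function(fields, path) {
  utils::write.csv(as.data.frame(fields), path, row.names = FALSE)
  invisible(path)
}

#' Lateral velocity fluctuations of one frame
#'
#' The fluctuation used by the spatial correlation analysis: each vector's
#' lateral component minus the frame-mean lateral component; zero-mean by
#' construction.
#'
#' @param frame data.frame of one frame (columns `x`, `y`, `v` at least).
#' @return Numeric vector of lateral fluctuations (um/min).
#' @export
lateral_fluctuations <- function(frame) {
  if (nrow(frame) < 2) stop("need at least 2 vectors")
  frame$v - mean(frame$v)
}

#' Spatial correlation profile of lateral velocity fluctuations
#'
#' Normalized two-point correlation of the lateral fluctuations at binned
#' separations: `C(r) = <u(r') u(r'+r)> / sqrt(<u(r')^2> <u(r'+r)^2>)`,
#' averaged over all vector pairs at separation r within one frame.
#' `C(0) = 1` by construction.
#'
#' @param frame one frame (data.frame with `x`, `y`, `v`).
#' @param bin_width separation bin width (um); default the median
#'   nearest-neighbor grid spacing.
#' @return Data.frame of class `rcn_correlation_profile` with columns `r`
#'   (bin-center separation, um), `C`, and `n_pairs`.
#' @export
correlation_profile <- function(frame, bin_width = NULL) {
  u <- lateral_fluctuations(frame)
  if (stats::var(u) == 0)
    stop("zero-variance lateral fluctuations: correlation undefined")
  if (is.null(bin_width)) {
    dx <- sort(unique(frame$x)); dy <- sort(unique(frame$y))
    sp <- c(diff(dx), diff(dy))
    bin_width <- if (length(sp)) stats::median(sp) else 1
  }
  d <- as.matrix(stats::dist(cbind(frame$x, frame$y)))
  idx <- which(upper.tri(d, diag = TRUE), arr.ind = TRUE)
  r <- d[idx]
  ui <- u[idx[, 1]]; uj <- u[idx[, 2]]
  bin <- floor(r / bin_width + 0.5)
  num <- tapply(ui * uj, bin, mean)
  d1 <- tapply(ui^2, bin, mean)
  d2 <- tapply(uj^2, bin, mean)
  n <- tapply(r, bin, length)
  prof <- data.frame(r = as.numeric(names(num)) * bin_width,
                     C = as.numeric(num / sqrt(d1 * d2)),
                     n_pairs = as.integer(n))
  prof <- prof[order(prof$r), ]
  rownames(prof) <- NULL
  class(prof) <- c("rcn_correlation_profile", "data.frame")
  prof
}

#' @keywords internal
profile_length_threshold <- function(prof, threshold = 0.05) {
  r <- prof$r; C <- prof$C
  below0 <- which(C < 0)
  if (length(below0)) {
    i <- below0[1]
    if (i == 1) return(r[1])
    # linear interpolation of the zero crossing
    return(r[i - 1] + (r[i] - r[i - 1]) * C[i - 1] / (C[i - 1] - C[i]))
  }
  small <- which(C < threshold)
  if (length(small)) return(r[small[1]])
  structure(max(r), no_crossing = TRUE)
}

#' @keywords internal
profile_length_fit <- function(prof) {
  # contiguous initial decay only: bins beyond the first drop below 0.05
  # carry no signal and would bias the fit
  stop_at <- which(prof$C <= 0.05)[1]
  keep <- if (is.na(stop_at)) seq_len(nrow(prof)) else seq_len(stop_at - 1)
  keep <- setdiff(keep, which(prof$r == 0))
  if (length(keep) < 2) return(profile_length_threshold(prof))
  # free intercept absorbs the uncorrelated (nugget) variance share
  fit <- stats::lm(log(C) ~ r, data = prof[keep, ])
  L <- -1 / stats::coef(fit)[[2]]
  if (!is.finite(L) || L <= 0) return(profile_length_threshold(prof))
  L
}

#' Correlation length of a migrating sheet
#'
#' Per-frame correlation length averaged over the analysis window. Frames
#' within the initial `exclusion` period after scratching are discarded (by
#' default the first hour, retaining the final 13.5 h of a 15-h recording at
#' 30-min cadence).
#'
#' Two estimators are available: `"threshold"` takes the distance at which
#' the correlation becomes negligible (first zero crossing, falling back to
#' C < 0.05), matching the convention used for experimental profiles;
#' `"fit"` estimates the decay length of an exponential profile
#' `C(r) = exp(-r / L)` by log-linear regression over the reliable bins and
#' recovers the imposed length of synthetic fields.
#'
#' @param fields `rcn_velocity_fields` (multiple frames), or a list of
#'   precomputed `rcn_correlation_profile`s with a `time` attribute each.
#' @param exclusion initial exclusion window (min).
#' @param method `"threshold"` or `"fit"`.
#' @return Mean correlation length (um) with attribute `per_frame` (the
#'   per-frame lengths) and `flagged` (count of profiles with no crossing,
#'   reported at the field extent).
#' @export
correlation_length <- function(fields, exclusion = 60,
                               method = c("threshold", "fit")) {
  method <- match.arg(method)
  if (inherits(fields, "rcn_velocity_fields") || is.data.frame(fields)) {
    times <- sort(unique(fields$time))
    profs <- lapply(times, function(t) {
      p <- correlation_profile(fields[fields$time == t, ])
      attr(p, "time") <- t
      p
    })
  } else {
    profs <- fields
    times <- vapply(profs, function(p) attr(p, "time"), numeric(1))
  }
  keep <- times > exclusion
  if (!any(keep)) stop("no frames left after the exclusion window")
  profs <- profs[keep]
  est <- if (method == "fit") profile_length_fit else profile_length_threshold
  lens <- lapply(profs, est)
  flagged <- sum(vapply(lens, function(l) isTRUE(attr(l, "no_crossing")),
                        logical(1)))
  lens <- vapply(lens, as.numeric, numeric(1))
  structure(mean(lens), per_frame = lens, flagged = flagged)
}

#' Movement-angle occupancy map
#'
#' Per-frame normalized histogram of the angle between each velocity vector
#' and the wound-closure direction (0 degrees, the +x axis), over
#' (-180, 180]. Zero-magnitude vectors are excluded and counted.
#'
#' @param fields `rcn_velocity_fields`.
#' @param n_bins number of angle bins (default 72, i.e. 5-degree bins).
#' @return Matrix (frames x bins) of occupancy fractions; each row sums
#'   to 1. Row names are frame times, column names bin centers (degrees).
#'   Attribute `n_zero` counts excluded zero vectors.
#' @export
movement_angle_map <- function(fields, n_bins = 72) {
  times <- sort(unique(fields$time))
  breaks <- seq(-180, 180, length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  n_zero <- 0L
  m <- t(vapply(times, function(t) {
    fr <- fields[fields$time == t, ]
    mag <- sqrt(fr$u^2 + fr$v^2)
    n_zero <<- n_zero + sum(mag == 0)
    fr <- fr[mag > 0, ]
    if (!nrow(fr)) return(rep(NA_real_, n_bins))
    ang <- atan2(fr$v, fr$u) * 180 / pi
    ang[ang <= -180] <- ang[ang <= -180] + 360
    h <- tabulate(findInterval(ang, breaks, left.open = TRUE,
                               all.inside = TRUE), n_bins)
    h / sum(h)
  }, numeric(n_bins)))
  dimnames(m) <- list(times, centers)
  attr(m, "n_zero") <- n_zero
  m
}

#' Leading-edge speed from fluorescence front masks
#'
#' The leading front is the average foremost detected signal along the
#' wound; the speed is the time taken for the average front to traverse the
#' field of view. If the front never reaches the end of the FOV, the slope
#' of a linear fit of front position against time is reported and flagged.
#'
#' @param mask_stack logical (or 0/1) array `ny x nx x n_frames`; `TRUE`
#'   marks detected fluorescence. Advancing direction is increasing column
#'   index.
#' @param frame_interval min between frames.
#' @param pixel_size um per pixel.
#' @return Speed (um/h), with attributes `front` (per-frame average front
#'   position, um) and `fallback` (`TRUE` when the slope-based estimate was
#'   used).
#' @export
leading_edge_speed <- function(mask_stack, frame_interval = 30,
                               pixel_size = 1.125) {
  dm <- dim(mask_stack)
  if (length(dm) != 3 || dm[3] < 2) stop("need a ny x nx x (>=2) mask stack")
  n_frames <- dm[3]; nx <- dm[2]
  front <- vapply(seq_len(n_frames), function(k) {
    m <- mask_stack[, , k]
    fm <- apply(m, 1, function(row) {
      w <- which(row != 0)
      if (length(w)) max(w) else 0L
    })
    mean(fm) * pixel_size
  }, numeric(1))
  t_h <- (seq_len(n_frames) - 1) * frame_interval / 60
  fov_end <- nx * pixel_size
  reached <- which(front >= fov_end - pixel_size / 2)
  if (length(reached) && reached[1] > 1) {
    k <- reached[1]
    speed <- (front[k] - front[1]) / (t_h[k] - t_h[1])
    fallback <- FALSE
  } else {
    speed <- stats::coef(stats::lm(front ~ t_h))[[2]]
    fallback <- TRUE
  }
  structure(speed, front = front, fallback = fallback)
}
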