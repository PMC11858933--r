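# Trajectory conditioning: zero-phase low-pass filtering, resampling, gap
# filling and temporal alignment.
#
# The zero-phase filter is a 4th-order Butterworth applied forward and
# backward with odd-extension padding and steady-state initial conditions,
# so a constant signal passes through exactly (DC gain 1 to machine
# precision). Note that odd-extension zero-phase filtering preserves the
# endpoint samples exactly, so stopband attenuation holds in the interior
# of a record, not at its first/last samples.

# Steady-state initial state of a direct-form-II-transposed filter for unit
# DC input (the classic lfilter_zi construction).
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a))) / a[1]
  b <- c(b, numeric(n - length(b))) / a[1]
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[-1]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# Direct-form-II-transposed IIR filter with initial state.
filter_df2t <- function(b, a, x, zi) {
  nz <- length(b) - 1
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    if (nz > 1) z[1:(nz - 1)] <- b[2:nz] * x[i] + z[2:nz] - a[2:nz] * y[i]
    z[nz] <- b[nz + 1] * x[i] - a[nz + 1] * y[i]
  }
  y
}

# Zero-phase filtering of one numeric vector (no NAs).
filtfilt_zp <- function(b, a, x) {
  m <- length(x)
  pad <- min(m - 1, 3 * (max(length(a), length(b)) - 1))
  zi <- lfilter_zi(b, a)
  xe <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[m] - rev(x[(m - pad):(m - 1)]))
  y <- filter_df2t(b, a, xe, zi * xe[1])
  y <- rev(y)
  y <- rev(filter_df2t(b, a, y, zi * y[1]))
  y[(pad + 1):(pad + m)]
}

# Contiguous runs of TRUE in a logical vector, as a list of index ranges.
logical_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(c, starts[r$values], ends[r$values])
}

#' Zero-phase low-pass filter a 3D track
#'
#' A zero-phase (forward-backward) 4th-order Butterworth low-pass filter is
#' applied independently per landmark and coordinate on each contiguous
#' visible run longer than `3 * fs / cutoff` samples; shorter runs pass
#' through unfiltered. The visibility mask is unchanged.
#'
#' @param track a [track3d()].
#' @param cutoff cutoff frequency in Hz (default 6).
#' @param order filter order (default 4).
#' @return the filtered [track3d()].
#' @export
lowpass <- function(track, cutoff = 6, order = 4) {
  fs <- track$fs
  if (cutoff >= fs / 2)
    stop("cutoff must be below the Nyquist frequency fs/2")
  bw <- signal::butter(order, cutoff / (fs / 2))
  b <- bw$b; a <- bw$a
  min_run <- 3 * fs / cutoff
  out <- track$data
  for (l in seq_along(track$landmark_names)) {
    for (run in logical_runs(track$visible[, l])) {
      n <- run[2] - run[1] + 1
      if (n <= min_run) next
      idx <- run[1]:run[2]
      for (k in 1:3) out[idx, l, k] <- filtfilt_zp(b, a, track$data[idx, l, k])
    }
  }
  track3d(out, visible = track$visible, landmark_names = track$landmark_names,
          fs = fs, t0 = track$t0, interpolated = track$interpolated)
}

#' Resample a 3D track by linear interpolation
#'
#' A resampled point is visible only if both bracketing source frames are
#' visible (and interpolation-flagged if either is flagged); `t0` is
#' preserved.
#'
#' @param track a [track3d()] with at least 2 frames.
#' @param fs_out target sampling rate in Hz.
#' @return a [track3d()] at `fs_out` covering the same time span.
#' @export
resample_track <- function(track, fs_out) {
  if (fs_out <= 0) stop("fs_out must be positive")
  TT <- n_frames(track)
  if (TT < 2) stop("track must have at least 2 frames")
  t_src <- track_times(track)
  span <- t_src[TT] - t_src[1]
  n_out <- floor(span * fs_out + 1e-9) + 1
  t_out <- track$t0 + (seq_len(n_out) - 1) / fs_out
  L <- length(track$landmark_names)
  lo <- findInterval(t_out, t_src, rightmost.closed = TRUE)
  lo <- pmin(pmax(lo, 1L), TT - 1L)
  hi <- lo + 1L
  w <- (t_out - t_src[lo]) / (t_src[hi] - t_src[lo])
  exact_lo <- abs(w) < 1e-9
  exact_hi <- abs(w - 1) < 1e-9
  data <- array(NaN, c(n_out, L, 3))
  visible <- matrix(FALSE, n_out, L)
  interp <- matrix(FALSE, n_out, L)
  for (l in seq_len(L)) {
    vl <- track$visible[, l]
    vis_out <- ifelse(exact_lo, vl[lo], ifelse(exact_hi, vl[hi], vl[lo] & vl[hi]))
    visible[, l] <- vis_out
    interp[, l] <- ifelse(exact_lo, track$interpolated[lo, l],
                          ifelse(exact_hi, track$interpolated[hi, l],
                                 track$interpolated[lo, l] | track$interpolated[hi, l]))
    for (k in 1:3) {
      x <- track$data[, l, k]
      data[, l, k] <- (1 - w) * x[lo] + w * x[hi]
      data[exact_lo, l, k] <- x[lo[exact_lo]]
      data[exact_hi, l, k] <- x[hi[exact_hi]]
    }
  }
  track3d(data, visible = visible, landmark_names = track$landmark_names,
          fs = fs_out, t0 = track$t0, interpolated = interp)
}

#' Fill short gaps in a 3D track by cubic-spline interpolation
#'
#' Gaps no longer than `max_gap_s` are filled across from the surrounding
#' visible samples and flagged in the `interpolated` provenance mask
#' (visible = TRUE), so downstream evaluation can still exclude them.
#' Longer gaps and gaps touching the track ends are left untouched.
#'
#' @param track a [track3d()].
#' @param max_gap_s maximum gap duration to fill, in seconds.
#' @return the gap-filled [track3d()].
#' @export
fill_gaps <- function(track, max_gap_s) {
  TT <- n_frames(track)
  max_len <- floor(max_gap_s * track$fs + 1e-9)
  data <- track$data
  visible <- track$visible
  interp <- track$interpolated
  for (l in seq_along(track$landmark_names)) {
    vl <- track$visible[, l]
    if (all(vl) || sum(vl) < 2) next
    gaps <- logical_runs(!vl)
    fillable <- Filter(function(g)
      g[1] > 1 && g[2] < TT && (g[2] - g[1] + 1) <= max_len, gaps)
    if (!length(fillable)) next
    ti <- which(vl)
    for (k in 1:3) {
      sp <- stats::splinefun(ti, track$data[ti, l, k], method = "fmm")
      for (g in fillable) data[g[1]:g[2], l, k] <- sp(g[1]:g[2])
    }
    for (g in fillable) {
      visible[g[1]:g[2], l] <- TRUE
      interp[g[1]:g[2], l] <- TRUE
    }
  }
  track3d(data, visible = visible, landmark_names = track$landmark_names,
          fs = track$fs, t0 = track$t0, interpolated = interp)
}

#' Estimate the temporal lag between two scalar series
#'
#' Argmax of the normalized cross-correlation within `±max_lag_s`; ties are
#' broken toward the smallest absolute lag. A positive lag means `b` is
#' delayed relative to `a` (b[t] ~ a[t - lag]). Both series must share the
#' sampling rate `fs`; non-finite samples are ignored pairwise.
#'
#' @param a,b numeric vectors on a common sampling grid.
#' @param fs sampling rate in Hz.
#' @param max_lag_s lag search bound in seconds (default 2).
#' @return integer lag in frames, with attribute `"correlation"`.
#' @export
estimate_lag <- function(a, b, fs, max_lag_s = 2) {
  max_lag <- floor(max_lag_s * fs)
  n <- min(length(a), length(b))
  if (n < 2 * max_lag)
    stop("series overlap must be at least twice the maximum lag")
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  lags <- -max_lag:max_lag
  cors <- vapply(lags, function(k) {
    if (k >= 0) { ai <- 1:(n - k); bi <- (1 + k):n }
    else { ai <- (1 - k):n; bi <- 1:(n + k) }
    x <- a[ai]; y <- b[bi]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) return(NA_real_)
    x <- x[ok]; y <- y[ok]
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (sx < 1e-12 || sy < 1e-12) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  if (all(!is.finite(cors)))
    stop("no signal: series have zero variance within the lag window")
  best <- max(cors, na.rm = TRUE)
  # near-ties (e.g. periodic movements, where every multiple of the period
  # correlates equally) resolve toward the smallest absolute lag
  cand <- which(cors >= best - 1e-4)
  lag <- lags[cand[which.min(abs(lags[cand]))]]
  structure(lag, correlation = best)
}
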