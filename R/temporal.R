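#' Normalized autocorrelation
#'
#' Autocorrelation of a series at lags `0..max_lag`, normalized so the
#' lag-0 value is 1. For a multivariate series (matrix, one column per
#' measurement) the per-column autocorrelations are averaged, giving a
#' single curve describing how temporally sustained the measurements are.
#'
#' @param series Numeric vector or matrix (frames x dimensions).
#' @param max_lag Largest lag, in frames.
#' @return Numeric vector of length `max_lag + 1`, names "lag0".."lagN".
#' @export
autocorrelation <- function(series, max_lag) {
  series <- as.matrix(series)
  if (nrow(series) <= max_lag)
    stop("series must be longer than max_lag", call. = FALSE)
  if (any(!is.finite(series))) stop("series contains non-finite values", call. = FALSE)
  v <- apply(series, 2L, stats::var)
  if (any(v == 0)) stop("zero-variance series: autocorrelation undefined", call. = FALSE)
  per_dim <- vapply(seq_len(ncol(series)), function(j) {
    as.numeric(stats::acf(series[, j], lag.max = max_lag, plot = FALSE,
                          demean = TRUE)$acf)
  }, numeric(max_lag + 1L))
  out <- rowMeans(per_dim)
  names(out) <- paste0("lag", 0L:max_lag)
  out
}

#' Welch power spectral density estimate
#'
#' One-sided spectral density on `[0, frame_rate/2]` by Welch's method:
#' the series is cut into overlapping windows, each demeaned and tapered
#' with a Hann window, and the windowed periodograms are averaged. Used
#' to locate the periodic components of the behavior (the band between
#' 0.12 and 1.20 Hz corresponds to behavioral units of 0.8-8 s).
#'
#' @param series Numeric vector.
#' @param frame_rate Sampling rate in frames per second.
#' @param window_seconds Window length in seconds (default 25.6 s = 256
#'   samples at 10 Hz, resolving the 0.12 Hz lower band edge).
#' @param overlap_fraction Fractional overlap of consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @return List with `frequency` (Hz) and `power` (density, units^2/Hz);
#'   the density integrates to approximately the series variance.
#' @export
welch_psd <- function(series, frame_rate, window_seconds = 25.6,
                      overlap_fraction = 0.5) {
  series <- as.numeric(series)
  nw <- round(window_seconds * frame_rate)
  if (nw < 8L) stop("window must cover at least 8 samples", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)", call. = FALSE)
  if (length(series) < nw)
    stop("series shorter than one window", call. = FALSE)
  step <- max(1L, floor(nw * (1 - overlap_fraction)))
  starts <- seq(1L, length(series) - nw + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0L, nw - 1L) / nw))  # periodic Hann
  scale <- frame_rate * sum(w^2)
  half <- nw %/% 2L
  acc <- numeric(half + 1L)
  for (s in starts) {
    x <- series[s:(s + nw - 1L)]
    x <- (x - mean(x)) * w
    p <- abs(stats::fft(x))^2 / scale
    p1 <- p[1:(half + 1L)]
    # one-sided: double every bin except DC (and Nyquist when nw is even)
    dbl <- 2:(half + if (nw %% 2L == 0L) 0L else 1L)
    p1[dbl] <- 2 * p1[dbl]
    acc <- acc + p1
  }
  list(frequency = seq(0L, half) * frame_rate / nw,
       power = acc / length(starts))
}

# Segment cost: summed squared residuals around the segment mean,
# totalled over dimensions; O(1) per query via cumulative sums.
make_sse_cost <- function(series) {
  series <- as.matrix(series)
  S1 <- rbind(0, apply(series, 2L, cumsum))
  S2 <- rbind(0, apply(series^2, 2L, cumsum))
  function(a, b) {  # cost of frames (a, b], 0-based a
    len <- b - a
    d1 <- S1[b + 1L, ] - S1[a + 1L, ]
    d2 <- S2[b + 1L, ] - S2[a + 1L, ]
    sum(d2 - d1^2 / len)
  }
}

#' Penalized changepoint segmentation
#'
#' Exact minimizer of summed within-segment squared error plus
#' `penalty` per additional segment, for a piecewise-constant-mean model
#' of a (possibly multivariate) series. Solved by pruned dynamic
#' programming (PELT), which detects frames where the measurements
#' suddenly change; the distribution of the resulting block durations is
#' the reference used to tune the module stickiness.
#'
#' @param series Numeric vector or matrix (frames x dimensions).
#' @param penalty Positive penalty per changepoint.
#' @param frame_rate Frames per second, for durations in seconds.
#' @return A `changepoint_result`: list with `breakpoints` (1-based
#'   indices of the first frame of each new block, strictly increasing,
#'   excluding frame 1), `block_durations` (seconds), `penalty`.
#' @export
changepoints <- function(series, penalty, frame_rate = 10) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (n < 2L) stop("series must have at least 2 frames", call. = FALSE)
  if (!is.numeric(penalty) || penalty <= 0)
    stop("penalty must be positive", call. = FALSE)
  if (any(!is.finite(series))) stop("series contains non-finite values", call. = FALSE)
  cost <- make_sse_cost(series)
  F <- c(-penalty, rep(Inf, n))
  prev <- integer(n + 1L)
  cand <- 0L
  for (t in seq_len(n)) {
    vals <- vapply(cand, function(s) F[s + 1L] + cost(s, t) + penalty, numeric(1L))
    j <- which.min(vals)
    F[t + 1L] <- vals[j]
    prev[t + 1L] <- cand[j]
    cand <- cand[vals <= F[t + 1L] + penalty]  # PELT pruning (K = 0)
    cand <- c(cand, t)
  }
  ends <- integer(0)
  t <- n
  while (t > 0L) {
    ends <- c(prev[t + 1L], ends)
    t <- prev[t + 1L]
  }
  bps <- ends[ends > 0L] + 1L  # first frame of each new block
  lens <- diff(c(0L, bps - 1L, n))
  structure(list(breakpoints = bps,
                 block_durations = lens / frame_rate,
                 penalty = penalty),
            class = "changepoint_result")
}

#' Summarize a block-duration distribution
#'
#' @param durations Nonempty numeric vector of durations in seconds.
#' @param n_bins Number of log-spaced histogram bins.
#' @return List with `quantiles` (5, 25, 50, 75, 95 percent,
#'   linear-interpolation), `histogram` (data frame: lower, upper, count),
#'   and `range_5_95`.
#' @export
duration_summary <- function(durations, n_bins = 20L) {
  if (length(durations) == 0L) stop("durations must be nonempty", call. = FALSE)
  q <- stats::quantile(durations, c(0.05, 0.25, 0.5, 0.75, 0.95), names = TRUE)
  lo <- min(durations); hi <- max(durations)
  if (lo <= 0) stop("durations must be positive", call. = FALSE)
  breaks <- if (lo == hi) c(lo * 0.999, hi * 1.001) else
    exp(seq(log(lo), log(hi), length.out = n_bins + 1L))
  h <- graphics::hist(durations, breaks = breaks, plot = FALSE)
  list(quantiles = q,
       histogram = data.frame(lower = h$breaks[-length(h$breaks)],
                              upper = h$breaks[-1L],
                              count = h$counts),
       range_5_95 = unname(q[c(1L, 5L)]))
}

#' Choose a changepoint penalty whose blocks match a target median duration
#'
#' Sweeps a penalty grid and returns the penalty whose median block
#' duration is closest (in log space) to `target_median_s`, mirroring the
#' observation that most behavioral blocks concentrate between 0.4 and
#' 5 s.
#'
#' @param series Series passed to [changepoints()].
#' @param penalty_grid Positive penalties to try.
#' @param frame_rate Frames per second.
#' @param target_median_s Target median block duration in seconds.
#' @return List with `penalty` (the selected value) and `sweep` (data
#'   frame of penalty, n_blocks, median_duration_s).
#' @export
tune_changepoint_penalty <- function(series, penalty_grid, frame_rate = 10,
                                     target_median_s = 1.5) {
  sweep <- do.call(rbind, lapply(penalty_grid, function(p) {
    cp <- changepoints(series, p, frame_rate)
    data.frame(penalty = p,
               n_blocks = length(cp$block_durations),
               median_duration_s = stats::median(cp$block_durations))
  }))
  best <- which.min(abs(log(sweep$median_duration_s) - log(target_median_s)))
  list(penalty = sweep$penalty[best], sweep = sweep)
}
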