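#' Ground-truth autoregressive hidden Markov model
#'
#' Container for the generative model behind synthetic recordings: a
#' Markov chain over `n_states` hidden states, each equipped with a
#' vector-autoregressive observation process
#' \eqn{y_t = A_1 y_{t-1} + \dots + A_L y_{t-L} + b + \epsilon},
#' \eqn{\epsilon \sim N(0, \Sigma)}.
#'
#' @param A Per-state lag matrices: list (length `n_states`) of lists
#'   (length `ar_lag`) of d x d matrices.
#' @param b Per-state bias vectors (list of length-d vectors).
#' @param Sigma Per-state noise covariances (list of symmetric
#'   positive-definite d x d matrices).
#' @param trans Row-stochastic `n_states` x `n_states` transition matrix.
#' @return A `ground_truth_model` list with fields `n_states`, `ar_lag`,
#'   `d`, `A`, `b`, `Sigma`, `trans`.
#' @export
ground_truth_model <- function(A, b, Sigma, trans) {
  trans <- as.matrix(trans)
  K <- nrow(trans)
  if (ncol(trans) != K || K < 1L)
    stop("transition matrix must be square", call. = FALSE)
  if (any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-9))
    stop("invalid model: transition rows must be nonnegative and sum to 1", call. = FALSE)
  if (length(A) != K || length(b) != K || length(Sigma) != K)
    stop("A, b, Sigma must each have one entry per state", call. = FALSE)
  d <- length(b[[1L]])
  L <- length(A[[1L]])
  for (k in seq_len(K)) {
    S <- Sigma[[k]]
    if (max(abs(S - t(S))) > 1e-8 || any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("noise covariances must be symmetric positive-definite", call. = FALSE)
  }
  structure(list(n_states = K, ar_lag = L, d = d, A = A, b = b,
                 Sigma = Sigma, trans = trans),
            class = "ground_truth_model")
}

#' Build a sticky transition matrix
#'
#' Each state self-transits with probability `self_prob`; the remaining
#' mass is spread uniformly over the other states.
#'
#' @param n_states Number of states.
#' @param self_prob Self-transition probability (module stickiness).
#' @return Row-stochastic matrix.
#' @export
sticky_transition_matrix <- function(n_states, self_prob = 0.95) {
  if (n_states == 1L) return(matrix(1, 1L, 1L))
  off <- (1 - self_prob) / (n_states - 1L)
  m <- matrix(off, n_states, n_states)
  diag(m) <- self_prob
  m
}

#' Random well-separated ground truth for simulation studies
#'
#' Draws a model whose states differ in their AR rotation/contraction and
#' stationary mean, the regime the fitter is meant to recover. Dynamics
#' are kept stable (spectral radius below 1).
#'
#' @param n_states Number of behavioral states (default 3).
#' @param d Observation dimension (default 12, a reduced stand-in for the
#'   59 measurements).
#' @param self_prob Self-transition probability of every state.
#' @param ar_coef Magnitude of the AR(1) dynamics (default 0.90).
#' @param noise_sd Innovation standard deviation.
#' @param mean_scale Spread of the per-state stationary means.
#' @param seed Integer seed.
#' @return A [ground_truth_model()].
#' @export
synthetic_ground_truth <- function(n_states = 3L, d = 12L, self_prob = 0.95,
                                   ar_coef = 0.9, noise_sd = 0.25,
                                   mean_scale = 2, seed = 1L) {
  set.seed(seed)
  A <- vector("list", n_states)
  b <- vector("list", n_states)
  Sigma <- vector("list", n_states)
  for (k in seq_len(n_states)) {
    # block-diagonal 2-D rotations at a state-specific angle: distinct,
    # stable dynamics with oscillatory signatures
    theta <- 2 * pi * (k - 1) / n_states / 6 + 0.05
    rot <- ar_coef * matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2L, 2L)
    Ak <- matrix(0, d, d)
    for (j in seq_len(d %/% 2L)) {
      ix <- (2L * j - 1L):(2L * j)
      Ak[ix, ix] <- rot
    }
    if (d %% 2L == 1L) Ak[d, d] <- ar_coef
    mu <- mean_scale * stats::rnorm(d)
    A[[k]] <- list(Ak)
    b[[k]] <- as.numeric((diag(d) - Ak) %*% mu)
    Sigma[[k]] <- diag(noise_sd^2, d)
  }
  ground_truth_model(A, b, Sigma, sticky_transition_matrix(n_states, self_prob))
}

#' Ground truth whose observations are a renderable 59-vector
#'
#' States differ in a smooth posture waveform over the 19 angle slots and
#' in per-segment activity levels near 1 for the 40 ventral/dorsal slots,
#' so the AR output can be integrated into a midline and converted into
#' fluorescence channel pairs.
#'
#' @param n_states Number of states.
#' @param anatomy An [anatomy_config()].
#' @param self_prob Self-transition probability.
#' @param ar_coef AR(1) persistence toward the state mean.
#' @param noise_sd Innovation standard deviation (kept small so angles
#'   stay in a physical range).
#' @param seed Integer seed.
#' @return A [ground_truth_model()] with `d = 59` for the default anatomy.
#' @export
renderable_ground_truth <- function(n_states = 3L, anatomy = anatomy_config(),
                                    self_prob = 0.95, ar_coef = 0.9,
                                    noise_sd = 0.02, seed = 1L) {
  set.seed(seed)
  d <- n_measurements(anatomy)
  na <- anatomy$n_angles
  ns <- anatomy$n_segments
  A <- vector("list", n_states)
  b <- vector("list", n_states)
  Sigma <- vector("list", n_states)
  for (k in seq_len(n_states)) {
    s <- seq_len(na)
    # one body wave per state: distinct wavelength, phase and amplitude
    ang_mu <- (0.08 + 0.04 * k) * sin(2 * pi * s / (na / (1 + 0.5 * k)) + k)
    act_v <- 1 + 0.4 * sin(2 * pi * seq_len(ns) / ns + 2 * k)
    act_d <- 1 + 0.4 * cos(2 * pi * seq_len(ns) / ns + k)
    mu <- c(ang_mu, act_v, act_d)
    Ak <- diag(ar_coef, d)
    A[[k]] <- list(Ak)
    b[[k]] <- as.numeric((diag(d) - Ak) %*% mu)
    Sigma[[k]] <- diag(noise_sd^2, d)
  }
  ground_truth_model(A, b, Sigma, sticky_transition_matrix(n_states, self_prob))
}

#' Sample a hidden-state label sequence from the Markov chain
#'
#' @param model A [ground_truth_model()] (only its transition matrix is
#'   used).
#' @param n_frames Number of frames to draw.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return Integer vector of state ids in `1..n_states`.
#' @export
sample_labels <- function(model, n_frames, seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be at least 1", call. = FALSE)
  trans <- model$trans
  if (any(trans < 0) || any(abs(rowSums(trans) - 1) > 1e-9))
    stop("invalid model: transition matrix is not row-stochastic", call. = FALSE)
  K <- nrow(trans)
  set.seed(seed)
  z <- integer(n_frames)
  z[1L] <- sample.int(K, 1L)
  if (n_frames > 1L) {
    cum <- t(apply(trans, 1L, cumsum))
    u <- stats::runif(n_frames - 1L)
    for (t in 2L:n_frames) {
      z[t] <- findInterval(u[t - 1L], cum[z[t - 1L], ], left.open = TRUE) + 1L
    }
  }
  z
}

# Simulate the switching AR observation sequence for a given label path.
simulate_observations <- function(labels, model) {
  d <- model$d
  L <- model$ar_lag
  n <- length(labels)
  Y <- matrix(0, n, d)
  chol_S <- lapply(model$Sigma, chol)
  # stationary-ish start: state mean of the first label (lag-1 solve)
  A1 <- Reduce(`+`, model$A[[labels[1L]]])
  mu1 <- tryCatch(solve(diag(d) - A1, model$b[[labels[1L]]]),
                  error = function(e) model$b[[labels[1L]]])
  for (t in seq_len(n)) {
    k <- labels[t]
    if (t <= L) {
      Y[t, ] <- mu1 + stats::rnorm(d) %*% chol_S[[k]]
    } else {
      pred <- model$b[[k]]
      for (l in seq_len(L)) pred <- pred + model$A[[k]][[l]] %*% Y[t - l, ]
      Y[t, ] <- as.numeric(pred) + stats::rnorm(d) %*% chol_S[[k]]
    }
  }
  if (any(!is.finite(Y))) stop("generation error: non-finite AR output", call. = FALSE)
  Y
}

# Integrate 19 turning angles into a 21-point midline of constant arc length.
integrate_midline <- function(angles, anatomy, origin = c(0, 0), heading0 = 0) {
  seg_len <- anatomy$body_length / anatomy$n_segments
  # angles are curvature integrals over body_length / n_angles; the chord
  # turn between consecutive segments is the matching fraction of that
  phi <- heading0 + c(0, cumsum(angles * anatomy$n_angles / anatomy$n_segments))
  dx <- seg_len * cos(phi)
  dy <- seg_len * sin(phi)
  cbind(x = origin[1L] + c(0, cumsum(dx)),
        y = origin[2L] + c(0, cumsum(dy)))
}

# TRUE if any two non-adjacent midline segments intersect.
midline_self_crosses <- function(pts) {
  n <- nrow(pts) - 1L
  p <- pts[-nrow(pts), , drop = FALSE]
  d <- pts[-1L, , drop = FALSE] - p
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      den <- d[i, 1L] * d[j, 2L] - d[i, 2L] * d[j, 1L]
      if (abs(den) < 1e-12) next
      rx <- p[j, 1L] - p[i, 1L]; ry <- p[j, 2L] - p[i, 2L]
      t1 <- (rx * d[j, 2L] - ry * d[j, 1L]) / den
      t2 <- (rx * d[i, 2L] - ry * d[i, 1L]) / den
      if (t1 > 0 && t1 < 1 && t2 > 0 && t2 < 1) return(TRUE)
    }
  }
  FALSE
}

#' Render a labeled synthetic recording
#'
#' Simulates the per-frame 59-vector from each state's AR process, then
#' realizes it physically: the first 19 entries are treated as signed
#' turning angles and integrated into a constant arc-length midline; the
#' 40 activity entries become fluorescence channel pairs with
#' `GCaMP = activity * mDsRed * (1 + multiplicative noise)`, where mDsRed
#' is a smooth per-segment expression profile with slow temporal drift.
#'
#' @param labels Integer state sequence from [sample_labels()].
#' @param model A [ground_truth_model()] whose dimension matches the
#'   anatomy's 59-slot layout.
#' @param anatomy An [anatomy_config()].
#' @param noise_scale Standard deviation of the log-normal multiplicative
#'   channel noise (0 = noiseless channels).
#' @param seed Integer seed.
#' @param vulva_position Optional 2-D point recorded in the metadata.
#' @return A `synthetic_recording`: list with `labels`, `truth` (frames x
#'   59 generating vectors), `midlines` (list of 21 x 2 matrices),
#'   `channels` (`gcamp_v`, `gcamp_d`, `mdsred_v`, `mdsred_d`; frames x 20
#'   each), `quant` (a [recording_quant()]), `failure_mask`,
#'   `self_crossing`, `anatomy`, `seed`, `vulva_position`.
#' @export
render_recording <- function(labels, model, anatomy = anatomy_config(),
                             noise_scale = 0, seed = 1L,
                             vulva_position = NULL) {
  if (model$d != n_measurements(anatomy))
    stop("model dimension must match the anatomy's measurement layout", call. = FALSE)
  if (any(labels < 1L | labels > model$n_states))
    stop("labels outside the model's state set", call. = FALSE)
  if (noise_scale < 0) stop("noise_scale must be nonnegative", call. = FALSE)
  set.seed(seed)
  n <- length(labels)
  na <- anatomy$n_angles
  ns <- anatomy$n_segments
  Y <- simulate_observations(labels, model)

  midlines <- vector("list", n)
  crossing <- logical(n)
  for (t in seq_len(n)) {
    midlines[[t]] <- integrate_midline(Y[t, seq_len(na)], anatomy)
    crossing[t] <- midline_self_crosses(midlines[[t]])
  }

  seg <- seq_len(ns)
  base_v <- 100 * (1 + 0.2 * sin(2 * pi * seg / ns))
  base_d <- 100 * (1 + 0.2 * cos(2 * pi * seg / ns))
  drift <- 1 + 0.05 * sin(2 * pi * seq_len(n) / (60 * anatomy$frame_rate))
  mdsred_v <- outer(drift, base_v)
  mdsred_d <- outer(drift, base_d)
  mult <- function() {
    if (noise_scale == 0) return(matrix(1, n, ns))
    matrix(exp(stats::rnorm(n * ns, mean = -noise_scale^2 / 2, sd = noise_scale)), n, ns)
  }
  act_v <- Y[, na + seg, drop = FALSE]
  act_d <- Y[, na + ns + seg, drop = FALSE]
  gcamp_v <- act_v * mdsred_v * mult()
  gcamp_d <- act_d * mdsred_d * mult()

  frames <- lapply(seq_len(n), function(t) {
    measure_frame(midlines[[t]],
                  gcamp = list(ventral = gcamp_v[t, ], dorsal = gcamp_d[t, ]),
                  mdsred = list(ventral = mdsred_v[t, ], dorsal = mdsred_d[t, ]),
                  anatomy = anatomy)
  })
  quant <- recording_quant(frames, anatomy)

  structure(
    list(labels = labels, truth = Y, midlines = midlines,
         channels = list(gcamp_v = gcamp_v, gcamp_d = gcamp_d,
                         mdsred_v = mdsred_v, mdsred_d = mdsred_d),
         quant = quant, failure_mask = logical(n), self_crossing = crossing,
         anatomy = anatomy, seed = seed, vulva_position = vulva_position),
    class = "synthetic_recording"
  )
}

#' Mark a fraction of frames as failed
#'
#' Emulates the defective frames of real recordings (blur, animal overlap,
#' out-of-frame) by setting the failure mask on approximately
#' `fraction * n` frames, placed in runs of at most `max_run` frames, and
#' invalidating their quantification.
#'
#' @param rec A `synthetic_recording` from [render_recording()].
#' @param fraction Target fraction of failed frames in `[0, 1]`.
#' @param max_run Longest run of consecutive failed frames placed (at
#'   high fractions adjacent runs may merge).
#' @param seed Integer seed.
#' @return The recording with `failure_mask` set and the corresponding
#'   `quant` frames flagged invalid (measurements and centroids NA).
#' @export
corrupt_frames <- function(rec, fraction, max_run = 10L, seed = 1L) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]", call. = FALSE)
  n <- length(rec$labels)
  need <- round(fraction * n)
  if (need == 0L) return(rec)
  set.seed(seed)
  mask <- rec$failure_mask
  guard <- 0L
  while (sum(mask) < need && guard < 1000L * n) {
    guard <- guard + 1L
    start <- sample.int(n, 1L)
    len <- sample.int(min(max_run, need - sum(mask)), 1L)
    idx <- start:min(start + len - 1L, n)
    # avoid touching existing runs so placed runs stay <= max_run
    lo <- max(1L, start - 1L); hi <- min(n, idx[length(idx)] + 1L)
    if (any(mask[lo:hi])) next
    mask[idx] <- TRUE
  }
  if (sum(mask) < need) {  # dense fractions: fill remaining frames in order
    free <- which(!mask)
    mask[free[seq_len(need - sum(mask))]] <- TRUE
  }
  rec$failure_mask <- mask
  rec$quant$valid[mask] <- FALSE
  rec$quant$measurements[mask, ] <- NA_real_
  rec$quant$centroids[mask, ] <- NA_real_
  rec
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("synthetic_recording: %d frames, %d states, %d failed, seed %d\n",
              length(x$labels), length(unique(x$labels)), sum(x$failure_mask),
              x$seed))
  invisible(x)
}

#' Write a synthetic recording to plain-text artifacts
#'
#' Emits the quant table (`quant.csv`, canonical 59-column layout plus
#' `frame`, `valid`, `cx`, `cy`), the midlines in long format
#' (`midlines.csv`: frame, point, x, y), the ground-truth labels
#' (`labels.csv`), the four channel tables, and a `metadata.json` with the
#' seed, calibration and genotype tag. Frame and point indices in files
#' are 0-based.
#'
#' @param rec A `synthetic_recording`.
#' @param dir Output directory (created if missing).
#' @param genotype Genotype tag stored in the metadata.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_recording <- function(rec, dir, genotype = "wt") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(quant = file.path(dir, "quant.csv"),
             midlines = file.path(dir, "midlines.csv"),
             labels = file.path(dir, "labels.csv"),
             channels = file.path(dir, "channels.csv"),
             metadata = file.path(dir, "metadata.json"))
  write_quant_csv(rec$quant, paths[["quant"]])
  n <- length(rec$midlines)
  npt <- nrow(rec$midlines[[1L]])
  ml <- data.frame(
    frame = rep(seq_len(n) - 1L, each = npt),
    point = rep(seq_len(npt) - 1L, times = n),
    x = unlist(lapply(rec$midlines, function(m) m[, 1L])),
    y = unlist(lapply(rec$midlines, function(m) m[, 2L]))
  )
  utils::write.csv(ml, paths[["midlines"]], row.names = FALSE)
  utils::write.csv(data.frame(frame = seq_along(rec$labels) - 1L,
                              label = rec$labels,
                              failed = as.integer(rec$failure_mask)),
                   paths[["labels"]], row.names = FALSE)
  ns <- rec$anatomy$n_segments
  ch <- data.frame(frame = rep(seq_len(n) - 1L, each = ns),
                   segment = rep(seq_len(ns), times = n),
                   gcamp_v = as.numeric(t(rec$channels$gcamp_v)),
                   gcamp_d = as.numeric(t(rec$channels$gcamp_d)),
                   mdsred_v = as.numeric(t(rec$channels$mdsred_v)),
                   mdsred_d = as.numeric(t(rec$channels$mdsred_d)))
  utils::write.csv(ch, paths[["channels"]], row.names = FALSE)
  meta <- list(seed = rec$seed, genotype = genotype,
               frame_rate = rec$anatomy$frame_rate,
               pixel_size = rec$anatomy$pixel_size,
               n_frames = n,
               vulva_position = rec$vulva_position)
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
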