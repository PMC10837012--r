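# Shared fixtures and independent oracles used across test files.

# flat channel fixture: every segment intensity equal
flat_channels <- function(value = 1, n_segments = 20L) {
  list(ventral = rep(value, n_segments), dorsal = rep(value, n_segments))
}

# circular arc midline spanning `span` radians, sampled at n points
arc_midline <- function(span, radius = 100, n = 200L, ccw = TRUE) {
  th <- seq(0, span, length.out = n)
  if (!ccw) th <- -th
  radius * cbind(cos(th), sin(th))
}

# exhaustive O(n^2) dynamic program for penalized mean-shift segmentation
# (no pruning; independent of the package's PELT implementation)
dp_changepoints <- function(series, penalty) {
  series <- as.matrix(series)
  n <- nrow(series)
  sse <- function(a, b) {  # frames a..b inclusive, 1-based
    seg <- series[a:b, , drop = FALSE]
    sum(sweep(seg, 2L, colMeans(seg))^2)
  }
  F <- c(-penalty, rep(Inf, n))
  prev <- integer(n + 1L)
  for (t in seq_len(n)) {
    for (s in 0:(t - 1L)) {
      v <- F[s + 1L] + sse(s + 1L, t) + penalty
      if (v < F[t + 1L]) {
        F[t + 1L] <- v
        prev[t + 1L] <- s
      }
    }
  }
  bounds <- integer(0)
  t <- n
  while (t > 0L) {
    bounds <- c(prev[t + 1L], bounds)
    t <- prev[t + 1L]
  }
  bounds[bounds > 0L] + 1L  # first frame of each new block
}

# exact Mann-Whitney U by pair counting plus exact two-sided p-value by
# enumerating all group assignments of the pooled sample
enum_mann_whitney <- function(x, y) {
  u_stat <- function(xx, yy)
    sum(outer(xx, yy, `>`)) + 0.5 * sum(outer(xx, yy, `==`))
  u_obs <- u_stat(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2L, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mu <- n1 * length(y) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = p)
}

# independent maximal-alternating-run decomposition: at each position,
# determine the longest alternating run by explicit pattern matching
# (ids[k] must equal ids[i + ((k - i) %% 2)]), accept it when long enough
brute_force_repeats <- function(ids, min_blocks = 3L) {
  n <- length(ids)
  run_len <- function(i) {
    if (i >= n || ids[i] == ids[i + 1L]) return(1L)
    k <- i
    while (k < n && ids[k + 1L] == ids[i + (k + 1L - i) %% 2L]) k <- k + 1L
    k - i + 1L
  }
  out <- list()
  i <- 1L
  while (i <= n) {
    len <- run_len(i)
    if (len >= min_blocks) {
      pair <- sort(c(ids[i], ids[i + 1L]))
      out[[length(out) + 1L]] <- c(a = pair[1L], b = pair[2L],
                                   first = i, last = i + len - 1L,
                                   n_blocks = len)
      i <- i + len
    } else {
      i <- i + 1L
    }
  }
  out
}

# block table from a module-id sequence with unit-length blocks
blocks_from_ids <- function(ids, recording = "r1", frame_rate = 10) {
  data.frame(recording = recording, module = ids,
             start = seq_along(ids) - 1L, end = seq_along(ids),
             n_frames = 1L, duration_s = 1 / frame_rate,
             stringsAsFactors = FALSE)
}

# small z-scored AR-HMM dataset with known labels
make_arhmm_data <- function(n_states = 3L, d = 12L, n_frames = 3000L,
                            seed = 1L, ...) {
  gt <- synthetic_ground_truth(n_states, d = d, seed = seed, ...)
  z <- sample_labels(gt, n_frames, seed = seed + 1L)
  set.seed(seed + 2L)
  Y <- wormmodes:::simulate_observations(z, gt)
  list(model = gt, labels = z, Y = Y, Yz = zscore_columns(Y))
}

# compact signatures of a repeat decomposition, for bulk comparison
repeat_signature <- function(reps) {
  if (nrow(reps) == 0L) return("")
  paste(sprintf("%d-%d@%d:%d", reps$module_a, reps$module_b,
                reps$first_block, reps$n_blocks), collapse = ";")
}
oracle_signature <- function(want) {
  if (length(want) == 0L) return("")
  paste(vapply(want, function(w)
    sprintf("%d-%d@%d:%d", w[["a"]], w[["b"]], w[["first"]], w[["n_blocks"]]),
    character(1)), collapse = ";")
}
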