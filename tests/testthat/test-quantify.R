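test_that("straight midline with equal channels gives zero angles and unit ratios", {
  a <- anatomy_config()
  mid <- cbind(seq(0, 200, length.out = 50), 0)
  fq <- measure_frame(mid, flat_channels(3), flat_channels(3), a)
  expect_true(fq$valid)
  expect_equal(fq$angles, rep(0, 19), tolerance = 1e-9)
  expect_equal(fq$ventral_ratio, rep(1, 20))
  expect_equal(fq$dorsal_ratio, rep(1, 20))
  # consecutive resampled points are collinear
  pts <- resample_midline(mid, 21)
  v <- diff(pts)
  cross <- v[-19, 1] * v[-1, 2] - v[-19, 2] * v[-1, 1]
  expect_lt(max(abs(cross)), 1e-9)
})

test_that("every valid frame yields the full measurement contract", {
  a <- anatomy_config()
  fq <- measure_frame(arc_midline(pi / 3), flat_channels(2), flat_channels(5), a)
  vec <- c(fq$angles, fq$ventral_ratio, fq$dorsal_ratio)
  expect_length(vec, 59)
  expect_length(fq$angles, 19)
  expect_length(measurement_names(a), 59)
})

test_that("constant-curvature arcs read the closed-form angle at every boundary", {
  a <- anatomy_config()
  for (span in c(pi / 2, pi / 4, 1.2)) {
    fq <- measure_frame(arc_midline(span), flat_channels(), flat_channels(), a)
    expect_equal(abs(fq$angles), rep(span / 19, 19), tolerance = 1e-4)
    expect_length(unique(sign(fq$angles)), 1L)
  }
})

test_that("gentle sine-wave midline matches windowed curvature integrals", {
  a <- anatomy_config()
  lam <- 600; amp <- 2
  x <- seq(0, 400, length.out = 4000)
  y <- amp * sin(2 * pi * x / lam)
  mid <- cbind(x, y)[seq(1, 4000, by = 20), ]  # 200-point midline
  fq <- measure_frame(mid, flat_channels(), flat_channels(), a)
  # closed-form signed curvature of y = A sin(2 pi x / lambda), integrated
  # over windows of body_length/19 centred at the 19 segment boundaries
  dy <- (2 * pi * amp / lam) * cos(2 * pi * x / lam)
  d2y <- -(2 * pi / lam)^2 * amp * sin(2 * pi * x / lam)
  kap <- d2y / (1 + dy^2)^1.5
  ds <- sqrt(1 + dy^2) * diff(x)[1]
  s <- cumsum(ds) - ds[1]
  L <- s[length(s)]
  bounds <- seq(0, L, length.out = 21)[2:20]
  oracle <- vapply(bounds, function(b) {
    sel <- s >= b - L / 38 & s < b + L / 38
    sum(kap[sel] * ds[sel])
  }, numeric(1))
  expect_lt(max(abs(fq$angles - oracle)), 1e-4)
})

test_that("mirroring the midline across the body axis negates every angle", {
  a <- anatomy_config()
  set.seed(5)
  ang <- 0.2 * sin(seq_len(19) / 3) + 0.02 * rnorm(19)
  mid <- wormmodes:::integrate_midline(ang, a)
  mirrored <- cbind(mid[, 1], -mid[, 2])
  f1 <- measure_frame(mid, flat_channels(), flat_channels(), a)
  f2 <- measure_frame(mirrored, flat_channels(), flat_channels(), a)
  expect_equal(f2$angles, -f1$angles, tolerance = 1e-12)
})

test_that("scaling both channels leaves ratios unchanged; zero mDsRed invalidates", {
  a <- anatomy_config()
  set.seed(6)
  g <- list(ventral = runif(20, 1, 5), dorsal = runif(20, 1, 5))
  r <- list(ventral = runif(20, 1, 5), dorsal = runif(20, 1, 5))
  mid <- arc_midline(0.8)
  f1 <- measure_frame(mid, g, r, a)
  f2 <- measure_frame(mid, lapply(g, `*`, 7.3), lapply(r, `*`, 7.3), a)
  expect_equal(f1$ventral_ratio, f2$ventral_ratio)
  expect_equal(f1$dorsal_ratio, f2$dorsal_ratio)
  r0 <- r; r0$ventral[4] <- 0
  expect_false(measure_frame(mid, g, r0, a)$valid)
})

test_that("degenerate midlines are flagged invalid, not fatal", {
  a <- anatomy_config()
  expect_false(measure_frame(cbind(c(1, 1), c(2, 2)), flat_channels(),
                             flat_channels(), a)$valid)
  expect_false(measure_frame(matrix(1, 10, 2), flat_channels(),
                             flat_channels(), a)$valid)
})

test_that("arc-length resampling yields equal segment lengths on smooth curves", {
  pts <- resample_midline(arc_midline(pi / 2, n = 500L), 21)
  seg <- sqrt(rowSums(diff(pts)^2))
  expect_lt(diff(range(seg)) / mean(seg), 0.001)
})

test_that("image-mode quantification recovers per-side intensity ratios", {
  a <- anatomy_config(body_length = 100)
  mid <- cbind(seq(10, 110, length.out = 50), 60)
  img_g <- matrix(0, 120, 130)
  img_r <- matrix(0, 120, 130)
  mask <- matrix(FALSE, 120, 130)
  # band of pixels above (y < 60: dorsal for ventral_sign = +1 since the
  # segment direction is +x and cross = dx*ry) and below the midline
  for (r in 50:70) for (cc in 10:110) {
    mask[r, cc] <- TRUE
    img_r[r, cc] <- 2
    img_g[r, cc] <- if (r > 60) 6 else 3  # below midline vs above
  }
  fq <- measure_frame(mid, list(image = img_g, mask = mask),
                      list(image = img_r, mask = mask), a)
  expect_true(fq$valid)
  # one side reads ratio 3, the other 1.5, uniformly along the body
  sides <- sort(c(unique(round(fq$ventral_ratio, 6)),
                  unique(round(fq$dorsal_ratio, 6))))
  expect_equal(sides, c(1.5, 3))
})

test_that("clean_recording interpolates short gaps and leaves long gaps invalid", {
  a <- anatomy_config()
  mk <- function(val, valid = TRUE) {
    f <- wormmodes:::invalid_frame(a)
    if (valid) {
      f$angles[] <- val; f$ventral_ratio[] <- val; f$dorsal_ratio[] <- val
      f$centroid <- c(val, val); f$valid <- TRUE
    }
    f
  }
  frames <- list(mk(0), mk(NA, FALSE), mk(1))
  rec <- recording_quant(frames, a)
  out <- clean_recording(rec, max_gap = 5)
  expect_true(all(out$valid))
  expect_equal(unname(out$measurements[2, 1]), 0.5)

  # run of max_gap + 1 stays invalid
  frames2 <- c(list(mk(0)), replicate(6, mk(NA, FALSE), simplify = FALSE),
               list(mk(1)))
  out2 <- clean_recording(recording_quant(frames2, a), max_gap = 5)
  expect_equal(sum(!out2$valid), 6)

  # no invalid frames: identity
  rec3 <- recording_quant(list(mk(0), mk(1), mk(2)), a)
  expect_identical(clean_recording(rec3, 5), rec3)

  # leading invalid run is never interpolated
  out4 <- clean_recording(recording_quant(list(mk(NA, FALSE), mk(1), mk(2)), a), 5)
  expect_false(out4$valid[1])

  expect_error(clean_recording(recording_quant(list(mk(NA, FALSE)), a)),
               "all frames invalid")
})

test_that("signed speed reproduces the printed calibration", {
  a <- anatomy_config()  # 2.6 um/pixel, 10 Hz
  n <- 11
  heads <- matrix(rep(c(1, 0), each = n), ncol = 2)
  fwd <- compute_speed(cbind(seq(0, 40, by = 4), 0), heads, a)
  expect_equal(fwd$speed_umps[-1], rep(104, n - 1))   # 4 px/0.1 s
  bwd <- compute_speed(cbind(seq(0, -10, by = -1), 0), heads, a)
  expect_equal(bwd$speed_umps[-1], rep(-26, n - 1))   # 1 px/0.1 s backward
  still <- compute_speed(matrix(5, n, 2), heads, a)
  expect_equal(still$speed_umps[-1], rep(0, n - 1))
  expect_error(compute_speed(matrix(0, 3, 2), matrix(0, 4, 2), a),
               "same number of frames")
})
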