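#' Resample a midline polyline to uniform arc length
#'
#' Reparameterizes an ordered head-to-tail midline by cumulative arc length
#' and returns `n_out` points at equal arc-length spacing (so consecutive
#' points delimit equal-length body segments).
#'
#' @param points Numeric matrix with columns x, y; ordered head to tail.
#' @param n_out Number of output points (n_segments + 1 for quantification).
#' @return `n_out` x 2 numeric matrix.
#' @export
resample_midline <- function(points, n_out) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("midline must have two columns (x, y)", call. = FALSE)
  # drop only consecutive duplicates; a self-crossing path may revisit points
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] - points[-nrow(points), , drop = FALSE])^2))
  nz <- c(TRUE, seg > 0)
  points <- points[nz, , drop = FALSE]
  if (nrow(points) < 2L) stop("degenerate midline: fewer than 2 distinct points", call. = FALSE)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] - points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate midline: zero arc length", call. = FALSE)
  target <- seq(0, total, length.out = n_out)
  cbind(stats::approx(s, points[, 1L], xout = target)$y,
        stats::approx(s, points[, 2L], xout = target)$y)
}

#' Signed turning angles of a polyline
#'
#' Angle at each interior vertex between consecutive segment vectors, in
#' radians. The raw sign follows the cross product in image coordinates
#' (x rightward, y downward); `ventral_sign` flips it so that ventral
#' bending is positive, per the recording's ventral-side annotation.
#'
#' @param points m x 2 matrix of resampled midline points.
#' @param ventral_sign +1 or -1; maps the geometric sign to ventral-positive.
#' @return Numeric vector of m - 2 signed angles.
#' @export
turning_angles <- function(points, ventral_sign = 1) {
  v <- points[-1L, , drop = FALSE] - points[-nrow(points), , drop = FALSE]
  a <- v[-nrow(v), , drop = FALSE]
  b <- v[-1L, , drop = FALSE]
  cross <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  dot <- a[, 1L] * b[, 1L] + a[, 2L] * b[, 2L]
  ventral_sign * atan2(cross, dot)
}

invalid_frame <- function(anatomy) {
  structure(
    list(angles = rep(NA_real_, anatomy$n_angles),
         ventral_ratio = rep(NA_real_, anatomy$n_segments),
         dorsal_ratio = rep(NA_real_, anatomy$n_segments),
         centroid = c(NA_real_, NA_real_),
         valid = FALSE),
    class = "frame_quant"
  )
}

#' Quantify one frame: posture angles and muscle-activity ratios
#'
#' Resamples the midline into `n_segments` equal arc-length segments,
#' measures the 19 signed bending angles (ventral positive), and computes
#' per-segment ventral and dorsal activity as the ratio of summed GCaMP to
#' summed mDsRed intensity. For the default anatomy this yields the
#' 59-measurement vector (19 angles + 20 ventral + 20 dorsal ratios).
#'
#' Channels are accepted in two forms:
#' * table mode: `list(ventral = <n_segments values>, dorsal = <...>)` of
#'   per-segment intensities for each fluorophore;
#' * image mode: `list(image = <matrix>, mask = <logical matrix>)`; masked
#'   pixels are assigned to the nearest midline segment by perpendicular
#'   projection and split by the side of the midline they fall on, then
#'   summed (ratio cancels region area).
#'
#' Each angle is the polyline turning angle at a segment boundary scaled
#' by `n_segments / n_angles`, making it the integral of signed curvature
#' over one nineteenth of the body: the 19 angles sum to the total
#' tangent turning, so a quarter-circle body reads `(pi/2)/19` radians at
#' every boundary.
#'
#' Degenerate midlines (under 3 distinct points or near-zero arc length)
#' and frames with a non-positive mDsRed segment sum are marked invalid
#' rather than raising an error.
#'
#' @param midline Ordered head-to-tail 2-column matrix of midline points.
#' @param gcamp GCaMP channel (table or image form, see Details).
#' @param mdsred mDsRed channel, same form as `gcamp`.
#' @param anatomy An [anatomy_config()].
#' @param ventral_sign +1 if the ventral side has positive geometric
#'   turning sign in this recording, -1 otherwise.
#' @return A `frame_quant`: list with `angles`, `ventral_ratio`,
#'   `dorsal_ratio`, `centroid`, `valid`.
#' @export
measure_frame <- function(midline, gcamp, mdsred, anatomy = anatomy_config(),
                          ventral_sign = 1) {
  midline <- as.matrix(midline)
  ok <- tryCatch({
    distinct <- nrow(unique(midline[stats::complete.cases(midline), , drop = FALSE]))
    distinct >= 3L
  }, error = function(e) FALSE)
  if (!ok || anyNA(midline)) return(invalid_frame(anatomy))
  pts <- tryCatch(resample_midline(midline, anatomy$n_segments + 1L),
                  error = function(e) NULL)
  if (is.null(pts)) return(invalid_frame(anatomy))

  if (!is.null(gcamp$image)) {
    gi <- segment_intensities(gcamp$image, gcamp$mask, pts, ventral_sign)
    ri <- segment_intensities(mdsred$image, mdsred$mask, pts, ventral_sign)
    gv <- gi$ventral; gd <- gi$dorsal
    rv <- ri$ventral; rd <- ri$dorsal
  } else {
    gv <- as.numeric(gcamp$ventral); gd <- as.numeric(gcamp$dorsal)
    rv <- as.numeric(mdsred$ventral); rd <- as.numeric(mdsred$dorsal)
  }
  if (length(gv) != anatomy$n_segments || length(gd) != anatomy$n_segments ||
      length(rv) != anatomy$n_segments || length(rd) != anatomy$n_segments)
    stop("channel intensities must have one value per segment", call. = FALSE)
  if (any(!is.finite(rv)) || any(!is.finite(rd)) || any(rv <= 0) || any(rd <= 0))
    return(invalid_frame(anatomy))

  # chord turning at the 19 interior boundaries covers only 19/20 of the
  # tangent turning; rescale so the angles tile the full body curvature
  # (each angle = integral of curvature over body_length / 19)
  angle_scale <- anatomy$n_segments / anatomy$n_angles
  structure(
    list(angles = angle_scale * turning_angles(pts, ventral_sign),
         ventral_ratio = gv / rv,
         dorsal_ratio = gd / rd,
         centroid = colMeans(pts),
         valid = TRUE),
    class = "frame_quant"
  )
}

# Sum image intensities over mask pixels, split by nearest midline segment
# (perpendicular projection, clamped to the segment) and by midline side.
segment_intensities <- function(image, mask, pts, ventral_sign = 1) {
  idx <- which(mask, arr.ind = TRUE)
  n_seg <- nrow(pts) - 1L
  ventral <- numeric(n_seg)
  dorsal <- numeric(n_seg)
  if (nrow(idx) == 0L) return(list(ventral = ventral, dorsal = dorsal))
  px <- idx[, 2L]  # x = column
  py <- idx[, 1L]  # y = row
  vals <- image[idx]
  a <- pts[-nrow(pts), , drop = FALSE]
  d <- pts[-1L, , drop = FALSE] - a
  len2 <- pmax(rowSums(d^2), .Machine$double.eps)
  best_d2 <- rep(Inf, length(px))
  best_seg <- integer(length(px))
  best_side <- numeric(length(px))
  for (s in seq_len(n_seg)) {
    rx <- px - a[s, 1L]; ry <- py - a[s, 2L]
    t <- pmin(pmax((rx * d[s, 1L] + ry * d[s, 2L]) / len2[s], 0), 1)
    dx <- rx - t * d[s, 1L]; dy <- ry - t * d[s, 2L]
    d2 <- dx^2 + dy^2
    hit <- d2 < best_d2
    best_d2[hit] <- d2[hit]
    best_seg[hit] <- s
    best_side[hit] <- sign(d[s, 1L] * ry[hit] - d[s, 2L] * rx[hit]) * ventral_sign
  }
  for (s in seq_len(n_seg)) {
    in_s <- best_seg == s
    ventral[s] <- sum(vals[in_s & best_side > 0])
    dorsal[s] <- sum(vals[in_s & best_side <= 0])
  }
  list(ventral = ventral, dorsal = dorsal)
}

#' Assemble per-frame quantifications into a recording
#'
#' @param frames List of `frame_quant` objects (one per video frame, fixed
#'   frame rate).
#' @param anatomy An [anatomy_config()].
#' @param genotype Genotype label for the recording.
#' @param source_id Identifier of the source recording.
#' @return A `recording_quant`: list with `measurements` (frames x 59
#'   matrix, canonical A/V/D column order), `valid` (logical per frame),
#'   `centroids` (frames x 2), `anatomy`, `genotype`, `source_id`.
#' @export
recording_quant <- function(frames, anatomy = anatomy_config(),
                            genotype = "wt", source_id = "rec") {
  if (length(frames) == 0L) stop("recording has no frames", call. = FALSE)
  m <- t(vapply(frames, function(f) c(f$angles, f$ventral_ratio, f$dorsal_ratio),
                numeric(n_measurements(anatomy))))
  colnames(m) <- measurement_names(anatomy)
  structure(
    list(measurements = m,
         valid = vapply(frames, function(f) isTRUE(f$valid), logical(1L)),
         centroids = t(vapply(frames, function(f) f$centroid, numeric(2L))),
         anatomy = anatomy,
         genotype = genotype,
         source_id = source_id),
    class = "recording_quant"
  )
}

#' @export
print.recording_quant <- function(x, ...) {
  cat(sprintf("recording_quant '%s' (%s): %d frames, %d valid, %d measurements/frame\n",
              x$source_id, x$genotype, nrow(x$measurements), sum(x$valid),
              ncol(x$measurements)))
  invisible(x)
}

#' Interpolate short runs of failed frames
#'
#' Invalid runs of length at most `max_gap` that are flanked by valid
#' frames are replaced by per-measurement linear interpolation between the
#' flanking frames and re-flagged valid. Longer runs, and leading or
#' trailing invalid runs, are left invalid and excluded downstream.
#'
#' @param rec A [recording_quant()].
#' @param max_gap Longest invalid run to interpolate, in frames. The
#'   default 5 frames (0.5 s at 10 Hz) stays below the shortest
#'   behavioral-unit scale of about 0.8 s.
#' @return The cleaned `recording_quant`.
#' @export
clean_recording <- function(rec, max_gap = 5L) {
  if (!any(rec$valid)) stop("all frames invalid: nothing to clean", call. = FALSE)
  bad <- !rec$valid
  if (!any(bad)) return(rec)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] || r$lengths[i] > max_gap) next
    lo <- starts[i] - 1L
    hi <- ends[i] + 1L
    if (lo < 1L || hi > length(rec$valid)) next  # leading/trailing run
    if (!rec$valid[lo] || !rec$valid[hi]) next
    w <- (seq(starts[i], ends[i]) - lo) / (hi - lo)
    for (j in seq_along(w)) {
      t <- starts[i] + j - 1L
      rec$measurements[t, ] <- (1 - w[j]) * rec$measurements[lo, ] +
        w[j] * rec$measurements[hi, ]
      rec$centroids[t, ] <- (1 - w[j]) * rec$centroids[lo, ] +
        w[j] * rec$centroids[hi, ]
      rec$valid[t] <- TRUE
    }
  }
  rec
}

#' Signed centroid speed
#'
#' Frame-to-frame centroid displacement converted to speed, signed by the
#' direction of travel along the body axis: positive when the displacement
#' projects forward (toward the head), negative when backward.
#'
#' @param centroids Frames x 2 matrix of centroid positions in pixels.
#' @param headings Frames x 2 matrix of body-axis unit vectors pointing
#'   posterior to anterior (see [body_heading()]).
#' @param anatomy An [anatomy_config()] providing `pixel_size` and
#'   `frame_rate`.
#' @return Data frame with `speed_umps` (micrometres/second) and
#'   `speed_pxpf` (pixels/frame); row t holds the displacement from frame
#'   t-1 to t, so row 1 is NA.
#' @export
compute_speed <- function(centroids, headings, anatomy = anatomy_config()) {
  centroids <- as.matrix(centroids)
  headings <- as.matrix(headings)
  if (nrow(centroids) != nrow(headings))
    stop("centroids and headings must have the same number of frames", call. = FALSE)
  if (nrow(centroids) < 2L)
    stop("need at least 2 frames to compute speed", call. = FALSE)
  disp <- centroids[-1L, , drop = FALSE] - centroids[-nrow(centroids), , drop = FALSE]
  h <- headings[-1L, , drop = FALSE]
  mag <- sqrt(rowSums(disp^2))
  fwd <- rowSums(disp * h)
  sgn <- ifelse(fwd >= 0, 1, -1)
  pxpf <- sgn * mag
  data.frame(
    speed_umps = c(NA_real_, pxpf * anatomy$frame_rate * anatomy$pixel_size),
    speed_pxpf = c(NA_real_, pxpf)
  )
}

#' Body-axis heading from a resampled midline
#'
#' Unit vector from resampled midline point 15 to point 5 (posterior to
#' anterior), used to sign centroid speed as forward or backward.
#'
#' @param pts Resampled midline points (n_segments + 1 rows).
#' @param anterior_point,posterior_point Indices of the two reference points.
#' @return Length-2 unit vector.
#' @export
body_heading <- function(pts, anterior_point = 5L, posterior_point = 15L) {
  v <- pts[anterior_point, ] - pts[posterior_point, ]
  n <- sqrt(sum(v^2))
  if (n == 0) return(c(NA_real_, NA_real_))
  v / n
}
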