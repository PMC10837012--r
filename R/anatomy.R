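#' Anatomy and acquisition configuration
#'
#' Describes the body model and imaging calibration shared by every stage of
#' the pipeline. The male body is divided into `n_segments` equal arc-length
#' segments along the anterior-posterior axis; posture is the `n_segments - 1`
#' signed turning angles between consecutive segments. The 95 body-wall
#' muscles sit in four longitudinal quadrants (three of 24 muscles, one of
#' 23), so each segment approximates one set of four muscles.
#'
#' @param n_segments Number of equal body segments (default 20).
#' @param quadrant_muscle_counts Muscle counts of the four longitudinal
#'   quadrants; must sum to 95.
#' @param pixel_size Spatial calibration in micrometres per pixel. The
#'   default 2.6 is implied by a preferred crawl speed of 4 pixels per
#'   0.1 s corresponding to roughly 104 micrometres per second.
#' @param frame_rate Acquisition rate in frames per second (default 10).
#' @param body_length Worm body length in pixels, pharynx end to tail tip.
#'
#' @return An object of class `anatomy_config`: a list with fields
#'   `n_segments`, `n_angles`, `quadrant_muscle_counts`, `total_muscles`,
#'   `pixel_size`, `frame_rate`, `body_length`.
#' @examples
#' a <- anatomy_config()
#' a$n_angles        # 19
#' a$total_muscles   # 95
#' @export
anatomy_config <- function(n_segments = 20L,
                           quadrant_muscle_counts = c(24L, 24L, 24L, 23L),
                           pixel_size = 2.6,
                           frame_rate = 10,
                           body_length = 200) {
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L)
    stop("n_segments must be at least 2", call. = FALSE)
  if (length(quadrant_muscle_counts) != 4L || any(quadrant_muscle_counts < 0))
    stop("quadrant_muscle_counts must be four nonnegative counts", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive", call. = FALSE)
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be positive", call. = FALSE)
  if (!is.numeric(body_length) || body_length <= 0)
    stop("body_length must be positive", call. = FALSE)
  structure(
    list(
      n_segments = n_segments,
      n_angles = n_segments - 1L,
      quadrant_muscle_counts = as.integer(quadrant_muscle_counts),
      total_muscles = sum(as.integer(quadrant_muscle_counts)),
      pixel_size = pixel_size,
      frame_rate = frame_rate,
      body_length = body_length
    ),
    class = "anatomy_config"
  )
}

#' @export
print.anatomy_config <- function(x, ...) {
  cat(sprintf(
    "anatomy_config: %d segments (%d angles), %d muscles in quadrants [%s]\n",
    x$n_segments, x$n_angles, x$total_muscles,
    paste(x$quadrant_muscle_counts, collapse = ", ")
  ))
  cat(sprintf("  %.3g um/pixel, %.3g frames/s, body length %.3g px\n",
              x$pixel_size, x$frame_rate, x$body_length))
  invisible(x)
}

# Number of measurement slots per frame: angles + ventral + dorsal ratios.
n_measurements <- function(anatomy) {
  anatomy$n_angles + 2L * anatomy$n_segments
}

#' Names of the per-frame measurement slots
#'
#' Column names of the measurement vector in its canonical layout:
#' angles `A01..A<n-1>`, ventral ratios `V01..V<n>`, dorsal ratios
#' `D01..D<n>` (59 slots for the default 20-segment anatomy).
#'
#' @param anatomy An [anatomy_config()].
#' @return Character vector of measurement names.
#' @export
measurement_names <- function(anatomy = anatomy_config()) {
  c(sprintf("A%02d", seq_len(anatomy$n_angles)),
    sprintf("V%02d", seq_len(anatomy$n_segments)),
    sprintf("D%02d", seq_len(anatomy$n_segments)))
}
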