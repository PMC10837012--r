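#' Module usage frequencies with genotype comparison
#'
#' For every recording, the fraction of frames spent in each module
#' (failed frames excluded from the numerator, so fractions sum to at
#' most 1). When two genotype groups are present, each module's
#' per-recording usage fractions are compared with a two-sided
#' Mann-Whitney U test and the p-values are Benjamini-Hochberg adjusted
#' across modules.
#'
#' @param blocks Block table over all recordings ([extract_blocks()]
#'   rows bound together).
#' @param genotypes Named character vector: recording id -> genotype.
#' @param failed_module Module id of failed frames (excluded).
#' @return List with `usage` (data frame: recording, genotype, module,
#'   usage) and `comparison` (data frame: module, statistic (U), p_value,
#'   p_adjusted, plus per-group mean usage), or `comparison = NULL` with
#'   a warning when a group has no recordings.
#' @export
usage_frequencies <- function(blocks, genotypes, failed_module = 0L) {
  recs <- unique(blocks$recording)
  mods <- sort(setdiff(unique(blocks$module), failed_module))
  usage <- do.call(rbind, lapply(recs, function(r) {
    br <- blocks[blocks$recording == r, ]
    total <- sum(br$n_frames)
    u <- vapply(mods, function(m)
      sum(br$n_frames[br$module == m]) / total, numeric(1L))
    data.frame(recording = r, genotype = unname(genotypes[r]),
               module = mods, usage = u, stringsAsFactors = FALSE)
  }))
  groups <- unique(usage$genotype)
  comparison <- NULL
  if (length(groups) == 2L) {
    n1 <- length(unique(usage$recording[usage$genotype == groups[1L]]))
    n2 <- length(unique(usage$recording[usage$genotype == groups[2L]]))
    if (n1 == 0L || n2 == 0L) {
      warning("a genotype group has zero recordings: comparison skipped",
              call. = FALSE)
    } else {
      comparison <- do.call(rbind, lapply(mods, function(m) {
        x <- usage$usage[usage$module == m & usage$genotype == groups[1L]]
        y <- usage$usage[usage$module == m & usage$genotype == groups[2L]]
        wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                  correct = TRUE))
        pv <- wt$p.value
        if (!is.finite(pv)) pv <- 1  # all values tied: no evidence of shift
        data.frame(module = m, statistic = unname(wt$statistic),
                   p_value = pv,
                   mean_usage_1 = mean(x), mean_usage_2 = mean(y))
      }))
      names(comparison)[4:5] <- paste0("mean_usage_", groups)
      comparison$p_adjusted <- stats::p.adjust(comparison$p_value, "BH")
    }
  } else if (length(groups) > 2L) {
    warning("more than two genotype groups: pairwise comparison skipped",
            call. = FALSE)
  }
  list(usage = usage, comparison = comparison)
}

#' Mann-Whitney U statistic by direct pair counting
#'
#' The U statistic of group `x` versus group `y`: the number of pairs
#' with `x > y` plus half the tied pairs. Exposed so users can cross-check
#' the normal-approximation test used in [usage_frequencies()].
#'
#' @param x,y Numeric samples.
#' @return The U statistic (a number in `[0, n_x n_y]`).
#' @export
mann_whitney_u <- function(x, y) {
  sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
}

#' Per-module speed histograms
#'
#' Each sampled block is represented by its median signed speed; blocks
#' are then binned by travel direction (forward/backward) and speed
#' magnitude. Frequencies are fractions of the sampled blocks.
#'
#' @param blocks Block table for one module (or any block sample).
#' @param speeds List (or single vector) of per-frame signed speeds per
#'   recording, aligned to frames; units are whatever the caller chose
#'   (pixels/frame or micrometres/second).
#' @param magnitude_breaks Increasing magnitude bin edges; values beyond
#'   the last edge fall into an overflow bin.
#' @return Data frame with `direction`, `bin` (label), `lower`, `upper`,
#'   `count`, `frequency`.
#' @export
speed_histogram <- function(blocks, speeds,
                            magnitude_breaks = c(0, 1, 2, 4, 8)) {
  if (nrow(blocks) == 0L) stop("empty block sample", call. = FALSE)
  if (!is.list(speeds)) speeds <- stats::setNames(list(speeds), blocks$recording[1L])
  med <- vapply(seq_len(nrow(blocks)), function(i) {
    v <- speeds[[blocks$recording[i]]][(blocks$start[i] + 1L):blocks$end[i]]
    stats::median(v, na.rm = TRUE)
  }, numeric(1L))
  med <- med[is.finite(med)]  # blocks with no measurable displacement frames
  if (length(med) == 0L) stop("no blocks with finite speeds", call. = FALSE)
  edges <- c(magnitude_breaks, Inf)
  out <- expand.grid(direction = c("forward", "backward"),
                     bin = seq_len(length(edges) - 1L))
  out$lower <- edges[out$bin]
  out$upper <- edges[out$bin + 1L]
  out$count <- mapply(function(dir, lo, hi) {
    sel <- if (dir == "forward") med >= 0 else med < 0
    sum(sel & abs(med) >= lo & abs(med) < hi)
  }, out$direction, out$lower, out$upper)
  out$frequency <- out$count / length(med)
  out$bin <- sprintf("[%g,%g)", out$lower, out$upper)
  out
}

#' Extract posture curves from an angle vector
#'
#' A curve is a maximal run of same-sign nonzero turning angles. Its size
#' is the total turning (sum of absolute angles in the run, radians), its
#' center the boundary index carrying the largest absolute angle, and its
#' size class the S/M/L bin: S `[0, 0.5)`, M `[0.5, 1.5]`, L `(1.5, Inf)`
#' radians.
#'
#' @param angles Signed angle vector (19 values, ventral positive).
#' @return Data frame with `center`, `direction` ("ventral"/"dorsal"),
#'   `size`, `size_class`; zero rows for an all-zero frame. Every nonzero
#'   angle belongs to exactly one curve.
#' @export
extract_curves <- function(angles) {
  s <- sign(angles)
  r <- rle(s)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- which(r$values != 0)
  out <- lapply(keep, function(i) {
    idx <- start[i]:end[i]
    a <- angles[idx]
    size <- sum(abs(a))
    data.frame(center = idx[which.max(abs(a))],
               direction = if (r$values[i] > 0) "ventral" else "dorsal",
               size = size,
               size_class = curve_size_class(size),
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0L)
    return(data.frame(center = integer(0), direction = character(0),
                      size = numeric(0), size_class = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

curve_size_class <- function(size) {
  ifelse(size > 1.5, "L", ifelse(size >= 0.5, "M", "S"))
}

#' In-block percentile profiles over a block sample
#'
#' Draws a seeded sample of module blocks (without replacement; all
#' blocks if fewer qualify) and, within each block, computes the 5th
#' percentile (lowest), median, and 95th percentile (highest) of each
#' segment's signed curvature or activity: the in-block variance. The
#' spread of those per-block statistics across the sample is the
#' among-block variance, summarized per segment.
#'
#' @param blocks Block table for one module.
#' @param data List of per-recording measurement matrices (frames x
#'   segments): curvature angles or ventral/dorsal activity.
#' @param sample_size Number of blocks to sample (default 100).
#' @param min_frames Minimum frames for a block to qualify (default 10).
#' @param seed Integer seed for the block sample.
#' @return List with `per_block` (data frame: block, segment, p5, p50,
#'   p95) and `among_blocks` (data frame: segment, statistic, p5, p50,
#'   p95 of that statistic across sampled blocks).
#' @export
block_percentiles <- function(blocks, data, sample_size = 100L,
                              min_frames = 10L, seed = 1L) {
  qualifying <- blocks[blocks$n_frames >= min_frames, , drop = FALSE]
  if (nrow(qualifying) == 0L)
    stop("no blocks with at least min_frames frames", call. = FALSE)
  set.seed(seed)
  take <- if (nrow(qualifying) > sample_size)
    qualifying[sample.int(nrow(qualifying), sample_size), , drop = FALSE]
  else qualifying
  if (!is.list(data)) data <- stats::setNames(list(data), take$recording[1L])
  per_block <- do.call(rbind, lapply(seq_len(nrow(take)), function(i) {
    m <- data[[take$recording[i]]][(take$start[i] + 1L):take$end[i], , drop = FALSE]
    q <- apply(m, 2L, stats::quantile, probs = c(0.05, 0.5, 0.95), na.rm = TRUE)
    data.frame(block = i, segment = seq_len(ncol(m)),
               p5 = q[1L, ], p50 = q[2L, ], p95 = q[3L, ])
  }))
  among <- do.call(rbind, lapply(c("p5", "p50", "p95"), function(st) {
    agg <- do.call(rbind, lapply(split(per_block, per_block$segment), function(g) {
      q <- stats::quantile(g[[st]], probs = c(0.05, 0.5, 0.95))
      data.frame(segment = g$segment[1L], statistic = st,
                 p5 = q[1L], p50 = q[2L], p95 = q[3L])
    }))
    agg
  }))
  rownames(among) <- NULL
  list(per_block = per_block, among_blocks = among,
       sampled_blocks = take)
}

#' Overlapped fixed-length skeletons for one module block
#'
#' Resamples each frame's midline to a fixed number of points, rescales
#' to a common arc length, and translates so the body center points
#' coincide, as in skeleton-overlay graphs: regions that move across the
#' block spread into bundles, static regions collapse onto one line. The
#' spread score of a body region is the mean pairwise distance between
#' corresponding points across frames, averaged over the region's
#' points.
#'
#' @param midlines List of midline matrices, one per frame of the block.
#' @param n_points Points per resampled skeleton (odd so a center point
#'   exists; default 21).
#' @param arc_length Common arc length after rescaling (default 1).
#' @return List with `skeletons` (list of aligned n_points x 2 matrices)
#'   and `spread` (named vector: head, mid, tail).
#' @export
skeleton_overlay <- function(midlines, n_points = 21L, arc_length = 1) {
  if (length(midlines) == 0L) stop("no midlines for block", call. = FALSE)
  missing <- which(vapply(midlines, is.null, logical(1L)))
  if (length(missing) > 0L)
    stop(sprintf("missing midlines for frames: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  center_idx <- (n_points + 1L) %/% 2L
  skels <- lapply(midlines, function(m) {
    pts <- resample_midline(m, n_points)
    seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n_points, , drop = FALSE])^2))
    pts <- pts * (arc_length / sum(seg))
    sweep(pts, 2L, pts[center_idx, ])
  })
  n <- length(skels)
  point_spread <- vapply(seq_len(n_points), function(i) {
    xy <- t(vapply(skels, function(s) s[i, ], numeric(2L)))
    if (n < 2L) return(0)
    d <- stats::dist(xy)
    mean(d)
  }, numeric(1L))
  third <- n_points %/% 3L
  regions <- list(head = seq_len(third),
                  mid = (third + 1L):(2L * third),
                  tail = (2L * third + 1L):n_points)
  spread <- vapply(regions, function(ix) mean(point_spread[ix]), numeric(1L))
  list(skeletons = skels, spread = spread)
}

#' Classify vulva contact for module blocks
#'
#' A block is ON when the male's tail stays within `contact_radius` of
#' the vulva for every frame of the block (distance exactly at the radius
#' counts as contact), and ON/OFF when it slips off at least once.
#'
#' @param tail_positions Frames x 2 matrix of tail-tip positions for the
#'   block's frames.
#' @param vulva_position Length-2 vulva coordinate; `NULL` skips the
#'   classification with a warning.
#' @param contact_radius Contact threshold in the same units as the
#'   positions (default 2 body-segment lengths for the default anatomy).
#' @return `"ON"`, `"ON/OFF"`, or `NA` when the vulva is unannotated.
#' @export
vulva_contact <- function(tail_positions, vulva_position, contact_radius = 20) {
  if (is.null(vulva_position)) {
    warning("vulva position missing: contact classification skipped",
            call. = FALSE)
    return(NA_character_)
  }
  tail_positions <- as.matrix(tail_positions)
  if (nrow(tail_positions) == 0L) stop("block has no frames", call. = FALSE)
  d <- sqrt((tail_positions[, 1L] - vulva_position[1L])^2 +
              (tail_positions[, 2L] - vulva_position[2L])^2)
  if (all(d <= contact_radius)) "ON" else "ON/OFF"
}

#' Vulva-contact proportions over a block sample
#'
#' @param blocks Block table for one module.
#' @param tails List of per-recording frames x 2 tail-position matrices.
#' @param vulva_position Length-2 vulva coordinate.
#' @param contact_radius Contact threshold.
#' @return Data frame with `class` ("ON", "ON/OFF") and `proportion`.
#' @export
vulva_contact_proportions <- function(blocks, tails, vulva_position,
                                      contact_radius = 20) {
  if (!is.list(tails)) tails <- stats::setNames(list(tails), blocks$recording[1L])
  cls <- vapply(seq_len(nrow(blocks)), function(i) {
    tp <- tails[[blocks$recording[i]]][(blocks$start[i] + 1L):blocks$end[i], ,
                                       drop = FALSE]
    vulva_contact(tp, vulva_position, contact_radius)
  }, character(1L))
  tab <- table(factor(cls, levels = c("ON", "ON/OFF")))
  data.frame(class = names(tab), count = as.integer(tab),
             proportion = as.numeric(tab) / length(cls))
}
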