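#' Detect bi-module repeats
#'
#' A bi-module repeat is a maximal run of consecutive module blocks
#' alternating between exactly two module ids (e.g. 9-14-9-14-9), the
#' "repeat until success/give up" routine underlying most mating steps.
#' Detection is a greedy left-to-right scan: the longest alternating run
#' starting at the current block is taken when it spans at least
#' `min_blocks` blocks (default 3, one full A-B-A alternation); when two
#' candidate runs share a block, the shared block goes to the earlier
#' repeat. Remaining blocks stay unassigned.
#'
#' @param blocks Block table for one recording, ordered by start frame
#'   (filter out the failed-frame module first if it should not join
#'   repeats).
#' @param min_blocks Minimum constituent blocks for a repeat.
#' @return Data frame with `recording`, `module_a`, `module_b` (a < b),
#'   `start`, `end` (half-open frames), `n_blocks`, `first_block`,
#'   `last_block` (row indices into `blocks`).
#' @export
detect_repeats <- function(blocks, min_blocks = 3L) {
  empty <- data.frame(recording = character(0), module_a = integer(0),
                      module_b = integer(0), start = integer(0),
                      end = integer(0), n_blocks = integer(0),
                      first_block = integer(0), last_block = integer(0),
                      stringsAsFactors = FALSE)
  n <- nrow(blocks)
  if (n == 0L) return(empty)
  ids <- blocks$module
  out <- list()
  i <- 1L
  while (i < n) {
    if (ids[i] != ids[i + 1L]) {
      j <- i + 1L
      while (j < n && ids[j + 1L] == ids[j - 1L]) j <- j + 1L
      if (j - i + 1L >= min_blocks) {
        pair <- sort(c(ids[i], ids[i + 1L]))
        out[[length(out) + 1L]] <- data.frame(
          recording = blocks$recording[i],
          module_a = pair[1L], module_b = pair[2L],
          start = blocks$start[i], end = blocks$end[j],
          n_blocks = j - i + 1L, first_block = i, last_block = j,
          stringsAsFactors = FALSE)
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Version map of the named bi-module pairs
#'
#' Letter codes for the bi-module combinations: locomotion variants
#' f (9-14, continuous forward), s (14-24, slow), p (14-40, pause);
#' backing variants m (24-60, mating), r (14-60, rocking), va (9-60,
#' variable); prodding variants alpha (23-40) and gamma (10-40). The
#' remaining codes (v for variable locomotion; beta and delta prodding)
#' have no published module pair and are left for the user to supply.
#'
#' @return Named character vector: `"a-b"` -> code.
#' @export
default_version_map <- function() {
  c("9-14" = "f", "14-24" = "s", "14-40" = "p",
    "24-60" = "m", "14-60" = "r", "9-60" = "va",
    "23-40" = "alpha", "10-40" = "gamma")
}

#' Assign version codes to detected repeats
#'
#' @param repeats Output of [detect_repeats()].
#' @param version_map Named vector `"a-b"` -> code; pairs not in the map
#'   get the fallback code `"other:a-b"`.
#' @return The repeats table with a `version` column.
#' @export
assign_versions <- function(repeats, version_map = default_version_map()) {
  key <- paste(repeats$module_a, repeats$module_b, sep = "-")
  v <- unname(version_map[key])
  v[is.na(v)] <- paste0("other:", key[is.na(v)])
  repeats$version <- v
  repeats
}

#' Usage of bi-module repeat versions over time
#'
#' For each time bin, the fraction of a recording's frames occupied by
#' each repeat version, averaged over the recordings active in that bin.
#' A repeat spanning a bin boundary contributes proportionally to both
#' bins. The first bin is flagged unreliable (in real recordings most
#' males have not yet been captured during the first minute).
#'
#' @param repeats Coded repeats ([assign_versions()] output) across
#'   recordings.
#' @param rec_frames Named vector: recording id -> total frames.
#' @param frame_rate Frames per second.
#' @param bin_seconds Bin width in seconds (default 60).
#' @return Data frame with `bin`, `t_start`, `t_end`, `version`,
#'   `frequency`, `reliable` (FALSE for the first bin).
#' @export
usage_over_time <- function(repeats, rec_frames, frame_rate = 10,
                            bin_seconds = 60) {
  if (bin_seconds <= 0) stop("bin_seconds must be positive", call. = FALSE)
  max_t <- max(rec_frames) / frame_rate
  n_bins <- ceiling(max_t / bin_seconds)
  versions <- sort(unique(repeats$version))
  rows <- list()
  for (b in seq_len(n_bins)) {
    lo <- (b - 1L) * bin_seconds
    hi <- b * bin_seconds
    active <- names(rec_frames)[rec_frames / frame_rate > lo]
    if (length(active) == 0L) next
    for (v in versions) {
      fr <- vapply(active, function(r) {
        cover <- min(hi, rec_frames[[r]] / frame_rate) - lo
        rr <- repeats[repeats$recording == r & repeats$version == v, , drop = FALSE]
        if (nrow(rr) == 0L) return(0)
        ov <- pmax(0, pmin(hi, rr$end / frame_rate) - pmax(lo, rr$start / frame_rate))
        sum(ov) / cover
      }, numeric(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, t_start = lo, t_end = hi, version = v,
        frequency = mean(fr), reliable = b > 1L)
    }
  }
  do.call(rbind, rows)
}

#' Transitions between consecutive bi-module repeats
#'
#' Consecutive coded repeats within a recording become transition events
#' when the unassigned gap between them is at most `gap_tolerance_s`
#' seconds; longer gaps sever the path. Events are aggregated into a
#' count matrix with median transition times, the data behind chord-style
#' path diagrams.
#'
#' @param repeats Coded repeats across recordings.
#' @param frame_rate Frames per second.
#' @param gap_tolerance_s Longest unassigned gap still linking two
#'   repeats (default 2 s).
#' @return List with `events` (data frame: recording, from, to,
#'   time_s) and `paths` (data frame: from, to, count, median_time_s).
#' @export
transition_paths <- function(repeats, frame_rate = 10, gap_tolerance_s = 2) {
  events <- list()
  for (r in unique(repeats$recording)) {
    rr <- repeats[repeats$recording == r, , drop = FALSE]
    rr <- rr[order(rr$start), , drop = FALSE]
    if (nrow(rr) < 2L) next
    for (i in seq_len(nrow(rr) - 1L)) {
      gap <- (rr$start[i + 1L] - rr$end[i]) / frame_rate
      if (gap > gap_tolerance_s) next
      events[[length(events) + 1L]] <- data.frame(
        recording = r, from = rr$version[i], to = rr$version[i + 1L],
        time_s = rr$start[i + 1L] / frame_rate, stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0L)
    return(list(events = data.frame(recording = character(0),
                                    from = character(0), to = character(0),
                                    time_s = numeric(0)),
                paths = data.frame(from = character(0), to = character(0),
                                   count = integer(0),
                                   median_time_s = numeric(0))))
  ev <- do.call(rbind, events)
  paths <- do.call(rbind, lapply(split(ev, paste(ev$from, ev$to, sep = "\r")),
                                 function(g) data.frame(
                                   from = g$from[1L], to = g$to[1L],
                                   count = nrow(g),
                                   median_time_s = stats::median(g$time_s),
                                   stringsAsFactors = FALSE)))
  rownames(paths) <- NULL
  list(events = ev, paths = paths[order(-paths$count), ])
}

#' Export chord-diagram data for repeat transitions
#'
#' @param paths Aggregated paths from [transition_paths()].
#' @param path Output JSON file.
#' @return The path, invisibly.
#' @export
write_chord_json <- function(paths, path) {
  nodes <- sort(unique(c(paths$from, paths$to)))
  jsonlite::write_json(list(nodes = nodes, edges = paths), path,
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(path)
}
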