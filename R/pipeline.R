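#' Write / read the canonical quant table
#'
#' The 59-column quant CSV is the contract between quantification and
#' modeling: columns `frame` (0-based), `A01..A19`, `V01..V20`,
#' `D01..D20`, `valid` (0/1), `cx`, `cy`. Reading validates the schema
#' and names any missing or unexpected columns.
#'
#' @param rec A [recording_quant()].
#' @param path CSV file path.
#' @param anatomy An [anatomy_config()] fixing the expected layout.
#' @param genotype,source_id Labels restored onto the read recording.
#' @return `write_quant_csv` the path invisibly; `read_quant_csv` a
#'   `recording_quant`.
#' @export
write_quant_csv <- function(rec, path) {
  df <- data.frame(frame = seq_len(nrow(rec$measurements)) - 1L)
  df <- cbind(df, as.data.frame(rec$measurements))
  df$valid <- as.integer(rec$valid)
  df$cx <- rec$centroids[, 1L]
  df$cy <- rec$centroids[, 2L]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant_csv
#' @export
read_quant_csv <- function(path, anatomy = anatomy_config(),
                           genotype = "wt", source_id = "rec") {
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- c("frame", measurement_names(anatomy), "valid", "cx", "cy")
  missing <- setdiff(expected, names(df))
  extra <- setdiff(names(df), expected)
  if (length(missing) > 0L || length(extra) > 0L)
    stop(sprintf("quant schema mismatch: missing [%s], unexpected [%s]",
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  m <- as.matrix(df[, measurement_names(anatomy), drop = FALSE])
  structure(
    list(measurements = m, valid = df$valid == 1L,
         centroids = cbind(df$cx, df$cy),
         anatomy = anatomy, genotype = genotype, source_id = source_id),
    class = "recording_quant"
  )
}

#' Quantify a recording from midline and channel tables
#'
#' Reads the long-format midline CSV (`frame`, `point`, `x`, `y`) and the
#' channel CSV (`frame`, `segment`, `gcamp_v`, `gcamp_d`, `mdsred_v`,
#' `mdsred_d`) as written by [write_recording()] and runs
#' [measure_frame()] on every frame.
#'
#' @param midlines_csv,channels_csv Input file paths.
#' @param anatomy An [anatomy_config()].
#' @param ventral_sign Recording-wide ventral-side sign flag.
#' @param failed_frames Optional 0-based indices of frames to mark
#'   invalid regardless of their content.
#' @return A [recording_quant()].
#' @export
quantify_from_files <- function(midlines_csv, channels_csv,
                                anatomy = anatomy_config(), ventral_sign = 1,
                                failed_frames = integer(0)) {
  ml <- utils::read.csv(midlines_csv)
  ch <- utils::read.csv(channels_csv)
  frames_ids <- sort(unique(ml$frame))
  frames <- lapply(frames_ids, function(f) {
    if (f %in% failed_frames) return(invalid_frame(anatomy))
    m <- ml[ml$frame == f, ]
    m <- m[order(m$point), ]
    cc <- ch[ch$frame == f, ]
    cc <- cc[order(cc$segment), ]
    measure_frame(cbind(m$x, m$y),
                  gcamp = list(ventral = cc$gcamp_v, dorsal = cc$gcamp_d),
                  mdsred = list(ventral = cc$mdsred_v, dorsal = cc$mdsred_d),
                  anatomy = anatomy, ventral_sign = ventral_sign)
  })
  recording_quant(frames, anatomy)
}

#' Pipeline run configuration
#'
#' Bundles the per-stage options of a full synthetic run with a single
#' global seed; every stochastic stage consumes a child seed derived
#' deterministically from it.
#'
#' @param seed Global integer seed.
#' @param anatomy An [anatomy_config()].
#' @param n_recordings Recordings per genotype group.
#' @param n_frames Frames per recording.
#' @param n_states Ground-truth states of the generator.
#' @param noise_scale Multiplicative channel noise of the generator.
#' @param corrupt_fraction Fraction of failed frames planted.
#' @param max_run Longest planted failure run.
#' @param max_gap Longest invalid run interpolated during cleaning.
#' @param variance_target,pc_cap PCA retention rule (default 0.9 / 30).
#' @param penalty Changepoint penalty.
#' @param kappa Self-transition bias used for the final fit.
#' @param K_max,ar_lag,n_iter,burn_in Sampler options.
#' @param usage_threshold Major-module usage cutoff.
#' @param min_blocks,bin_seconds,gap_tolerance_s Syntax options.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L, anatomy = anatomy_config(),
                       n_recordings = 2L, n_frames = 1500L, n_states = 3L,
                       noise_scale = 0.05, corrupt_fraction = 0.02,
                       max_run = 5L, max_gap = 5L,
                       variance_target = 0.9, pc_cap = 30L,
                       penalty = 40, kappa = 200, K_max = 6L, ar_lag = 1L,
                       n_iter = 40L, burn_in = 20L,
                       usage_threshold = 0.01, min_blocks = 3L,
                       bin_seconds = 60, gap_tolerance_s = 2) {
  cfg <- list(seed = as.integer(seed), anatomy = anatomy,
              n_recordings = as.integer(n_recordings),
              n_frames = as.integer(n_frames), n_states = as.integer(n_states),
              noise_scale = noise_scale, corrupt_fraction = corrupt_fraction,
              max_run = as.integer(max_run), max_gap = as.integer(max_gap),
              variance_target = variance_target, pc_cap = as.integer(pc_cap),
              penalty = penalty, kappa = kappa, K_max = as.integer(K_max),
              ar_lag = as.integer(ar_lag), n_iter = as.integer(n_iter),
              burn_in = as.integer(burn_in),
              usage_threshold = usage_threshold,
              min_blocks = as.integer(min_blocks), bin_seconds = bin_seconds,
              gap_tolerance_s = gap_tolerance_s)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (!inherits(cfg$anatomy, "anatomy_config"))
    stop("validation error: anatomy must be an anatomy_config", call. = FALSE)
  if (cfg$anatomy$frame_rate <= 0)
    stop("validation error: frame_rate must be positive", call. = FALSE)
  if (cfg$n_frames < 10L)
    stop("validation error: n_frames too small", call. = FALSE)
  if (cfg$corrupt_fraction < 0 || cfg$corrupt_fraction > 1)
    stop("validation error: corrupt_fraction outside [0, 1]", call. = FALSE)
  if (cfg$penalty <= 0)
    stop("validation error: penalty must be positive", call. = FALSE)
  if (cfg$kappa < 0)
    stop("validation error: kappa must be nonnegative", call. = FALSE)
  invisible(TRUE)
}

# Deterministic child seed for stage k of a run.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483563)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline on synthetic recordings
#'
#' Executes synthetic generation, quantification and cleaning, temporal
#' analyses, PCA + sticky AR-HMM fitting, module statistics, and
#' bi-module syntax analysis, writing every intermediate artifact under
#' `out_dir` and a JSON manifest listing files, per-stage seeds and
#' durations. Two runs with the same configuration produce byte-identical
#' label and repeat tables.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The manifest list, invisibly; also written as
#'   `manifest.json`.
#' @export
run_end_to_end <- function(config, out_dir) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  anatomy <- config$anatomy
  fr <- anatomy$frame_rate
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   seeds = list(), durations = list(), files = list(),
                   stages = character(0))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$durations[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages <<- c(manifest$stages, name)
    res
  }

  genotypes_pool <- c("wt", "hypo")
  rec_ids <- unlist(lapply(genotypes_pool, function(g)
    paste0(g, "_", seq_len(config$n_recordings))))
  genotypes <- stats::setNames(rep(genotypes_pool, each = config$n_recordings),
                               rec_ids)

  # --- synthetic --------------------------------------------------------
  recs <- stage("synthetic", {
    model <- renderable_ground_truth(config$n_states, anatomy,
                                     seed = child_seed(config$seed, 1L))
    manifest$seeds$model <- child_seed(config$seed, 1L)
    out <- list()
    for (i in seq_along(rec_ids)) {
      s1 <- child_seed(config$seed, 10L + 3L * i)
      s2 <- child_seed(config$seed, 11L + 3L * i)
      s3 <- child_seed(config$seed, 12L + 3L * i)
      labels <- sample_labels(model, config$n_frames, seed = s1)
      rec <- render_recording(labels, model, anatomy,
                              noise_scale = config$noise_scale, seed = s2,
                              vulva_position = c(anatomy$body_length, 0))
      rec <- corrupt_frames(rec, config$corrupt_fraction, config$max_run,
                            seed = s3)
      dir_i <- file.path(out_dir, "recordings", rec_ids[i])
      write_recording(rec, dir_i, genotype = genotypes[[rec_ids[i]]])
      manifest$seeds[[rec_ids[i]]] <- c(labels = s1, render = s2, corrupt = s3)
      out[[rec_ids[i]]] <- rec
    }
    manifest$files$recordings <- file.path(out_dir, "recordings", rec_ids)
    out
  })

  # --- quantify + clean -------------------------------------------------
  quants <- stage("quantify", {
    lapply(recs, function(r) clean_recording(r$quant, config$max_gap))
  })

  # --- temporal ---------------------------------------------------------
  tmp <- stage("temporal", {
    allm <- do.call(rbind, lapply(quants, function(q)
      q$measurements[q$valid, , drop = FALSE]))
    pca <- fit_pca(allm, config$variance_target, config$pc_cap)
    zs_ref <- zscore_columns(pca_project(pca, allm))
    ctr <- attr(zs_ref, "center"); scl <- attr(zs_ref, "scale")
    acf_curve <- autocorrelation(zs_ref, max_lag = min(100L, nrow(zs_ref) - 1L))
    psd <- welch_psd(zs_ref[, 1L], fr,
                     window_seconds = min(25.6, floor(nrow(zs_ref) / fr / 2)))
    durs <- unlist(lapply(quants, function(q) {
      z <- zscore_columns(pca_project(pca, q$measurements[q$valid, , drop = FALSE]),
                          center = ctr, scale = scl)
      changepoints(z, config$penalty, fr)$block_durations
    }))
    report <- list(acf = unname(acf_curve),
                   psd_frequency = psd$frequency, psd_power = psd$power,
                   block_durations = durs,
                   duration_quantiles = duration_summary(durs)$quantiles)
    jsonlite::write_json(report, file.path(out_dir, "temporal.json"),
                         digits = NA, auto_unbox = TRUE)
    manifest$files$temporal <- file.path(out_dir, "temporal.json")
    list(pca = pca, center = ctr, scale = scl, durations = durs)
  })

  # --- arhmm ------------------------------------------------------------
  fit_out <- stage("arhmm", {
    chunks <- list(); chunk_map <- list()
    for (id in names(quants)) {
      q <- quants[[id]]
      r <- rle(q$valid)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (j in which(r$values & r$lengths > config$ar_lag + 2L)) {
        z <- zscore_columns(
          pca_project(tmp$pca, q$measurements[starts[j]:ends[j], , drop = FALSE]),
          center = tmp$center, scale = tmp$scale)
        chunks[[length(chunks) + 1L]] <- z
        chunk_map[[length(chunk_map) + 1L]] <- list(recording = id,
                                                    start = starts[j],
                                                    end = ends[j])
      }
    }
    cfg <- arhmm_config(K_max = config$K_max, ar_lag = config$ar_lag,
                        kappa = config$kappa, n_iter = config$n_iter,
                        burn_in = config$burn_in,
                        seed = child_seed(config$seed, 5L))
    manifest$seeds$arhmm <- cfg$seed
    fit <- gibbs_fit(chunks, cfg)
    labels <- lapply(quants, function(q) rep(NA_integer_, length(q$valid)))
    for (j in seq_along(chunk_map)) {
      cm <- chunk_map[[j]]
      labels[[cm$recording]][cm$start:cm$end] <- fit$labels[[j]]
    }
    dir.create(file.path(out_dir, "labels"), showWarnings = FALSE)
    for (id in names(labels)) {
      utils::write.csv(
        data.frame(frame = seq_along(labels[[id]]) - 1L,
                   module = ifelse(is.na(labels[[id]]), 0L, labels[[id]])),
        file.path(out_dir, "labels", paste0(id, ".csv")), row.names = FALSE)
    }
    write_model_json(fit, file.path(out_dir, "model.json"), pca = tmp$pca)
    manifest$files$labels <- file.path(out_dir, "labels",
                                        paste0(names(labels), ".csv"))
    manifest$files$model <- file.path(out_dir, "model.json")
    list(fit = fit, labels = labels)
  })

  # --- modstats ---------------------------------------------------------
  stats_out <- stage("modstats", {
    blocks <- do.call(rbind, lapply(names(fit_out$labels), function(id)
      extract_blocks(fit_out$labels[[id]], fr, id)))
    majors <- major_modules(blocks, config$usage_threshold)
    uf <- usage_frequencies(blocks, genotypes)
    speeds <- lapply(names(recs), function(id) {
      r <- recs[[id]]
      heads <- t(vapply(r$midlines, function(m)
        body_heading(resample_midline(m, anatomy$n_segments + 1L)), numeric(2L)))
      compute_speed(quants[[id]]$centroids, heads, anatomy)$speed_pxpf
    })
    names(speeds) <- names(recs)
    top <- majors$module[majors$major][1L]
    top_blocks <- blocks[blocks$module == top, , drop = FALSE]
    sh <- speed_histogram(top_blocks, speeds)
    angle_data <- lapply(quants, function(q)
      q$measurements[, seq_len(anatomy$n_angles), drop = FALSE])
    bp <- tryCatch(block_percentiles(top_blocks, angle_data,
                                     seed = child_seed(config$seed, 7L)),
                   error = function(e) NULL)
    manifest$seeds$block_sample <- child_seed(config$seed, 7L)
    curves <- do.call(rbind, lapply(names(quants), function(id) {
      q <- quants[[id]]
      idx <- which(q$valid)
      do.call(rbind, lapply(idx, function(t)
        extract_curves(q$measurements[t, seq_len(anatomy$n_angles)])))
    }))
    utils::write.csv(uf$usage, file.path(out_dir, "usage.csv"), row.names = FALSE)
    if (!is.null(uf$comparison))
      utils::write.csv(uf$comparison, file.path(out_dir, "usage_comparison.csv"),
                       row.names = FALSE)
    utils::write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
    utils::write.csv(sh, file.path(out_dir, "speed_histogram.csv"),
                     row.names = FALSE)
    manifest$files$modstats <- file.path(out_dir, c("usage.csv", "curves.csv",
                                                     "speed_histogram.csv"))
    list(blocks = blocks, majors = majors, usage = uf, percentiles = bp)
  })

  # --- syntax -----------------------------------------------------------
  syn <- stage("syntax", {
    reps <- do.call(rbind, lapply(names(fit_out$labels), function(id) {
      b <- stats_out$blocks[stats_out$blocks$recording == id, , drop = FALSE]
      detect_repeats(b, config$min_blocks)
    }))
    reps <- assign_versions(reps)
    rec_frames <- vapply(quants, function(q) length(q$valid), integer(1L))
    uot <- usage_over_time(reps, rec_frames, fr, config$bin_seconds)
    tp <- transition_paths(reps, fr, config$gap_tolerance_s)
    utils::write.csv(reps, file.path(out_dir, "repeats.csv"), row.names = FALSE)
    utils::write.csv(tp$events, file.path(out_dir, "transitions.csv"),
                     row.names = FALSE)
    if (!is.null(uot))
      utils::write.csv(uot, file.path(out_dir, "usage_over_time.csv"),
                       row.names = FALSE)
    write_chord_json(tp$paths, file.path(out_dir, "chord.json"))
    manifest$files$syntax <- file.path(out_dir, c("repeats.csv",
                                                   "transitions.csv",
                                                   "chord.json"))
    list(repeats = reps, transitions = tp, usage_over_time = uot)
  })

  manifest$n_major_modules <- sum(stats_out$majors$major)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(manifest = manifest, quants = quants, temporal = tmp,
                 fit = fit_out$fit, labels = fit_out$labels,
                 blocks = stats_out$blocks, majors = stats_out$majors,
                 usage = stats_out$usage, syntax = syn))
}
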