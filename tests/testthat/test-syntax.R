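test_that("repeat detection handles the canonical examples", {
  r1 <- detect_repeats(blocks_from_ids(c(9L, 14L, 9L, 14L, 9L)))
  expect_equal(nrow(r1), 1L)
  expect_equal(c(r1$module_a, r1$module_b, r1$n_blocks), c(9L, 14L, 5L))

  expect_equal(nrow(detect_repeats(blocks_from_ids(c(9L, 14L, 23L)))), 0L)

  r2 <- detect_repeats(blocks_from_ids(c(9L, 14L, 9L, 23L)))
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$module_a, r2$module_b, r2$n_blocks), c(9L, 14L, 3L))
  expect_equal(r2$last_block, 3L)  # block 4 (module 23) stays unassigned

  r3 <- detect_repeats(blocks_from_ids(c(10L, 40L, 10L, 40L, 23L, 40L, 23L, 40L, 23L)))
  expect_equal(nrow(r3), 2L)
  expect_equal(r3$module_a, c(10L, 23L))
  expect_equal(r3$module_b, c(40L, 40L))
  expect_equal(r3$n_blocks, c(4L, 5L))

  # shared block goes to the earlier repeat
  r4 <- detect_repeats(blocks_from_ids(c(1L, 2L, 1L, 3L, 1L)))
  expect_equal(nrow(r4), 1L)
  expect_equal(c(r4$module_a, r4$module_b), c(1L, 2L))
})

test_that("greedy detection matches the brute-force decomposition on random sequences", {
  set.seed(30)
  mismatches <- 0L
  for (i in 1:300) {
    ids <- as.integer(sample(1:4, sample(2:12, 1), replace = TRUE))
    if (repeat_signature(detect_repeats(blocks_from_ids(ids))) !=
        oracle_signature(brute_force_repeats(ids))) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("repeats are maximal and conserve frames on random inputs", {
  set.seed(31)
  for (i in 1:50) {
    ids <- as.integer(sample(1:4, sample(5:40, 1), replace = TRUE))
    lens <- sample(1:10, length(ids), replace = TRUE)
    ends <- cumsum(lens)
    blocks <- data.frame(recording = "r1", module = ids,
                         start = ends - lens, end = ends, n_frames = lens,
                         duration_s = lens / 10)
    reps <- detect_repeats(blocks)
    if (nrow(reps) == 0) next
    # frame conservation: repeat frames + unassigned block frames = total
    assigned <- unlist(mapply(seq, reps$first_block, reps$last_block,
                              SIMPLIFY = FALSE))
    expect_false(any(duplicated(assigned)))
    expect_equal(sum(blocks$n_frames[assigned]) +
                   sum(blocks$n_frames[-assigned]), sum(blocks$n_frames))
    expect_equal(sum(reps$end - reps$start), sum(blocks$n_frames[assigned]))
    # maximality: an unassigned left neighbor or any right neighbor must
    # break the alternation, otherwise the repeat could be extended
    for (j in seq_len(nrow(reps))) {
      f <- reps$first_block[j]; l <- reps$last_block[j]
      if (f > 1 && !((f - 1) %in% assigned))
        expect_false(ids[f - 1] == ids[f + 1])
      if (l < length(ids)) expect_false(ids[l + 1] == ids[l - 1])
    }
  }
})

test_that("version codes follow the shipped map with a fallback", {
  reps <- detect_repeats(blocks_from_ids(c(9L, 14L, 9L, 60L, 24L, 60L, 24L)))
  coded <- assign_versions(reps)
  expect_equal(coded$version[coded$module_a == 9 & coded$module_b == 14], "f")
  expect_equal(coded$version[coded$module_a == 24 & coded$module_b == 60], "m")

  odd <- detect_repeats(blocks_from_ids(c(3L, 8L, 3L, 8L)))
  expect_equal(assign_versions(odd)$version, "other:3-8")

  vm <- default_version_map()
  expect_equal(unname(vm[c("9-14", "14-24", "14-40", "24-60", "14-60", "9-60")]),
               c("f", "s", "p", "m", "r", "va"))
})

test_that("usage over time recovers planted schedules and conserves frames", {
  fr <- 10
  # one recording fully inside version f
  reps <- data.frame(recording = "r1", module_a = 9L, module_b = 14L,
                     start = 0L, end = 3000L, n_blocks = 10L,
                     first_block = 1L, last_block = 10L, version = "f")
  u <- usage_over_time(reps, c(r1 = 3000L), fr, bin_seconds = 60)
  expect_true(all(u$frequency[u$version == "f"] == 1))
  expect_false(u$reliable[u$bin == 1][1])

  # a repeat spanning a bin boundary splits proportionally
  reps2 <- data.frame(recording = "r1", module_a = 9L, module_b = 14L,
                      start = 450L, end = 750L, n_blocks = 5L,
                      first_block = 1L, last_block = 5L, version = "f")
  u2 <- usage_over_time(reps2, c(r1 = 1200L), fr, bin_seconds = 60)
  covered <- sum(u2$frequency[u2$version == "f"] * 60)
  expect_equal(covered, (750 - 450) / fr)

  # planted schedule: f in minutes 1-3, m in minutes 4-6
  reps3 <- rbind(
    data.frame(recording = "r1", module_a = 9L, module_b = 14L,
               start = 600L, end = 1800L, n_blocks = 9L, first_block = 1L,
               last_block = 9L, version = "f"),
    data.frame(recording = "r1", module_a = 24L, module_b = 60L,
               start = 2400L, end = 3600L, n_blocks = 9L, first_block = 11L,
               last_block = 19L, version = "m"))
  u3 <- usage_over_time(reps3, c(r1 = 3600L), fr, bin_seconds = 60)
  f_bins <- u3$bin[u3$version == "f" & u3$frequency == 1]
  m_bins <- u3$bin[u3$version == "m" & u3$frequency == 1]
  expect_equal(f_bins, 2:3)
  expect_equal(m_bins, 5:6)
})

test_that("transition paths link repeats within the gap tolerance", {
  reps <- data.frame(recording = "r1",
                     module_a = c(9L, 14L, 10L), module_b = c(14L, 60L, 40L),
                     start = c(0L, 110L, 500L), end = c(100L, 300L, 700L),
                     n_blocks = 3L, first_block = 1L, last_block = 3L,
                     version = c("f", "r", "gamma"))
  tp <- transition_paths(reps, frame_rate = 10, gap_tolerance_s = 2)
  # gap f->r is 1 s (linked); r->gamma is 20 s (severed)
  expect_equal(nrow(tp$events), 1L)
  expect_equal(c(tp$events$from, tp$events$to), c("f", "r"))
  expect_equal(tp$events$time_s, 11)

  single <- transition_paths(reps[1, ], 10)
  expect_equal(nrow(single$events), 0L)

  # planted branching probabilities recovered within binomial bounds
  set.seed(32)
  all_reps <- do.call(rbind, lapply(1:100, function(r) {
    nxt <- if (runif(1) < 0.8) "r" else "va"
    data.frame(recording = paste0("rec", r), module_a = c(9L, 14L),
               module_b = c(14L, 60L), start = c(0L, 105L),
               end = c(100L, 200L), n_blocks = 3L, first_block = 1:2,
               last_block = 1:2, version = c("f", nxt))
  }))
  tp2 <- transition_paths(all_reps, 10)
  p_r <- tp2$paths$count[tp2$paths$to == "r"] / 100
  expect_lt(abs(p_r - 0.8), 0.06 + 0.06)
})

test_that("chord diagram export lists nodes and edges", {
  paths <- data.frame(from = c("f", "r"), to = c("r", "f"),
                      count = c(5L, 2L), median_time_s = c(30, 90))
  f <- withr::local_tempfile(fileext = ".json")
  write_chord_json(paths, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(sort(back$nodes), c("f", "r"))
  expect_equal(nrow(back$edges), 2L)
})
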