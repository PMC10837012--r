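test_that("usage fractions and Mann-Whitney comparison behave on known cases", {
  # one recording entirely in module 5
  b1 <- extract_blocks(rep(5L, 100), 10, "rA")
  b2 <- extract_blocks(rep(c(5L, 9L), each = 50), 10, "rB")
  out <- usage_frequencies(rbind(b1, b2), c(rA = "wt", rB = "hypo"))
  uA <- out$usage[out$usage$recording == "rA", ]
  expect_equal(uA$usage[uA$module == 5], 1)
  expect_equal(uA$usage[uA$module == 9], 0)

  # identical usage in both groups: U = n1 n2 / 2 and p = 1
  mk_group <- function(g, usages) do.call(rbind, lapply(seq_along(usages),
    function(i) {
      n5 <- round(100 * usages[i])
      extract_blocks(c(rep(5L, n5), rep(9L, 100 - n5)), 10,
                     sprintf("%s%d", g, i))
    }))
  blocks <- rbind(mk_group("w", c(0.2, 0.5, 0.8)), mk_group("h", c(0.2, 0.5, 0.8)))
  gen <- setNames(rep(c("wt", "hypo"), each = 3),
                  c(paste0("w", 1:3), paste0("h", 1:3)))
  cmp <- usage_frequencies(blocks, gen)$comparison
  expect_equal(cmp$statistic, c(4.5, 4.5))
  expect_equal(cmp$p_value, c(1, 1))

  # fully separated groups: U = 0, matching exhaustive enumeration
  blocks2 <- rbind(mk_group("w", c(0.1, 0.2, 0.3)), mk_group("h", c(0.4, 0.5, 0.6)))
  cmp2 <- usage_frequencies(blocks2, gen)$comparison
  m5 <- cmp2[cmp2$module == 5, ]
  expect_equal(m5$statistic, 0)
  expect_equal(m5$statistic, enum_mann_whitney(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))$U)
  expect_equal(cmp2$p_adjusted, p.adjust(cmp2$p_value, "BH"))
})

test_that("U statistic agrees with exhaustive rank enumeration for small groups", {
  set.seed(21)
  for (n1 in 2:5) for (n2 in 2:5) {
    x <- round(runif(n1), 2)
    y <- round(runif(n2), 2)
    oracle <- enum_mann_whitney(x, y)
    expect_equal(mann_whitney_u(x, y), oracle$U)
    w <- suppressWarnings(wilcox.test(x, y))
    expect_equal(unname(w$statistic), oracle$U)
  }
})

test_that("speed histograms bin block medians by direction and magnitude", {
  blocks <- extract_blocks(rep(1:4, each = 25), 10, "r")
  static <- list(r = rep(0, 100))
  h <- speed_histogram(blocks, static)
  expect_equal(sum(h$frequency), 1)
  expect_equal(h$frequency[h$direction == "forward" & h$lower == 0], 1)

  fast <- list(r = rep(4, 100))
  h2 <- speed_histogram(blocks, fast)
  expect_equal(h2$frequency[h2$direction == "forward" & h2$lower == 4], 1)

  # 70/30 forward/backward mixture over 1000 one-frame blocks
  set.seed(22)
  dirs <- sample(c(2, -2), 1000, replace = TRUE, prob = c(0.7, 0.3))
  blocks3 <- blocks_from_ids(rep(1L, 1000))
  h3 <- speed_histogram(blocks3, list(r1 = dirs))
  fwd <- sum(h3$frequency[h3$direction == "forward"])
  expect_lt(abs(fwd - 0.7), 0.04)

  expect_error(speed_histogram(blocks[0, ], static), "empty")
})

test_that("curve extraction partitions sign runs and honors the S/M/L bounds", {
  ang <- rep(0, 19); ang[4:7] <- 0.25  # single ventral run summing 1.0
  cv <- extract_curves(ang)
  expect_equal(nrow(cv), 1L)
  expect_equal(cv$size, 1.0)
  expect_equal(cv$size_class, "M")
  expect_equal(cv$direction, "ventral")

  ang2 <- rep(0, 19); ang2[1:4] <- -0.4  # dorsal run summing 1.6
  cv2 <- extract_curves(ang2)
  expect_equal(cv2$size_class, "L")
  expect_equal(cv2$direction, "dorsal")

  # boundary sizes: 0.5 and 1.5 are M, just outside are S and L
  expect_equal(wormmodes:::curve_size_class(c(0.49, 0.5, 1.5, 1.51)),
               c("S", "M", "M", "L"))

  alt <- rep(c(0.1, -0.1), length.out = 19)
  cva <- extract_curves(alt)
  expect_equal(nrow(cva), 19L)
  expect_true(all(cva$size_class == "S"))

  expect_equal(nrow(extract_curves(rep(0, 19))), 0L)

  # every nonzero angle belongs to exactly one curve
  set.seed(23)
  for (i in 1:50) {
    a <- rnorm(19) * rbinom(19, 1, 0.7)
    cv <- extract_curves(a)
    expect_equal(sum(cv$size), sum(abs(a)), tolerance = 1e-12)
  }
})

test_that("block percentiles match a sort-based quantile oracle", {
  vals <- matrix(0:100, ncol = 1)
  blocks <- data.frame(recording = "r", module = 1L, start = 0L, end = 101L,
                       n_frames = 101L, duration_s = 10.1)
  bp <- block_percentiles(blocks, list(r = vals), sample_size = 10,
                          min_frames = 10, seed = 1)
  expect_equal(unname(unlist(bp$per_block[1, c("p5", "p50", "p95")])),
               c(5, 50, 95))

  # constant block: p5 = p50 = p95
  cblocks <- data.frame(recording = "r", module = 1L, start = 0L, end = 20L,
                        n_frames = 20L, duration_s = 2)
  cbp <- block_percentiles(cblocks, list(r = matrix(3, 20, 2)), seed = 1)
  expect_true(all(cbp$per_block$p5 == 3 & cbp$per_block$p95 == 3))

  # fewer qualifying blocks than sample_size: all returned once
  many <- do.call(rbind, lapply(0:4, function(i)
    data.frame(recording = "r", module = 1L, start = 20L * i, end = 20L * (i + 1L),
               n_frames = 20L, duration_s = 2)))
  mbp <- block_percentiles(many, list(r = matrix(rnorm(100), 100, 1)),
                           sample_size = 100, seed = 2)
  expect_equal(nrow(mbp$sampled_blocks), 5L)
  expect_false(any(duplicated(mbp$sampled_blocks$start)))

  # sampling is seed-reproducible
  lots <- do.call(rbind, lapply(0:19, function(i)
    data.frame(recording = "r", module = 1L, start = 10L * i, end = 10L * (i + 1L),
               n_frames = 10L, duration_s = 1)))
  dat <- list(r = matrix(rnorm(200), 200, 1))
  s1 <- block_percentiles(lots, dat, sample_size = 5, seed = 7)
  s2 <- block_percentiles(lots, dat, sample_size = 5, seed = 7)
  expect_identical(s1$per_block, s2$per_block)

  expect_error(block_percentiles(cblocks[0, ], list(r = vals)), "min_frames")
})

test_that("skeleton overlays expose which body region moves", {
  a <- anatomy_config()
  base <- 0.1 * sin(seq_len(19) / 3)
  still <- lapply(1:10, function(i) wormmodes:::integrate_midline(base, a))
  ov <- skeleton_overlay(still)
  expect_equal(unname(ov$spread), c(0, 0, 0))

  # translation between frames is removed by center alignment
  shifted <- lapply(1:10, function(i)
    wormmodes:::integrate_midline(base, a, origin = c(13 * i, -4 * i)))
  ov2 <- skeleton_overlay(shifted)
  expect_equal(unname(ov2$spread), c(0, 0, 0), tolerance = 1e-9)

  # oscillating the anterior angles spreads the head far more than the tail
  wob <- lapply(1:10, function(i) {
    ang <- base
    ang[1:5] <- ang[1:5] + 0.3 * sin(i)
    # integrate tail-to-head so the perturbation lands at the head end only
    m <- wormmodes:::integrate_midline(rev(ang), a)
    m[21:1, ]
  })
  ov3 <- skeleton_overlay(wob)
  expect_gt(ov3$spread[["head"]], 5 * ov3$spread[["tail"]])

  expect_error(skeleton_overlay(list(still[[1]], NULL)), "missing midlines")
})

test_that("vulva contact is ON only when every frame stays within the radius", {
  tails <- rbind(c(0, 0), c(1, 1), c(2, 0))
  expect_equal(vulva_contact(tails, c(0, 0), contact_radius = 5), "ON")
  expect_equal(vulva_contact(tails, c(0, 0), contact_radius = 1.5), "ON/OFF")
  # distance exactly at the radius counts as contact
  expect_equal(vulva_contact(rbind(c(3, 4)), c(0, 0), contact_radius = 5), "ON")
  expect_warning(res <- vulva_contact(tails, NULL), "missing")
  expect_true(is.na(res))

  blocks <- blocks_from_ids(rep(1L, 3))
  tl <- list(r1 = rbind(c(0, 0), c(0, 10), c(0, 1)))
  pr <- vulva_contact_proportions(blocks, tl, c(0, 0), contact_radius = 2)
  expect_equal(pr$proportion[pr$class == "ON"], 2 / 3)
})
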