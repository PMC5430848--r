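lay <- device_layout(pixel_size = 2)

test_that("metrics match closed forms on hand-constructed tracks", {
  x <- c(0, 3, 3); y <- c(0, 0, 4)
  expect_equal(path_length(x, y), 7)
  expect_equal(directional_persistence(x, y), 5 / 7)
  expect_equal(track_displacement(c(0, 300), c(0, 400)), 500)
  expect_equal(track_displacement(c(0, 300), c(0, 400), "horizontal"), 300)
  expect_equal(track_speed(c(0, 10), c(0, 0), c(0, 5), 1), 2)
  # degenerate segments are missing, not errors
  expect_true(is.na(path_length(1, 1)))
  expect_true(is.na(track_speed(1, 1, 0, 2)))
  expect_true(is.na(directional_persistence(c(1, 1), c(2, 2))))
  # closed loop: zero displacement in both modes, DP 0
  xl <- c(0, 10, 10, 0, 0); yl <- c(0, 0, 10, 10, 0)
  expect_equal(track_displacement(xl, yl), 0)
  expect_equal(track_displacement(xl, yl, "horizontal"), 0)
  expect_equal(directional_persistence(xl, yl), 0)
  # straight axial track: euclidean = horizontal = path length, DP 1
  xs <- c(0, 5, 12, 30); ys <- rep(2, 4)
  expect_equal(track_displacement(xs, ys), path_length(xs, ys))
  expect_equal(track_displacement(xs, ys, "horizontal"), path_length(xs, ys))
  expect_equal(directional_persistence(xs, ys), 1)
})

test_that("path length equals a brute-force step accumulation", {
  set.seed(77)
  x <- cumsum(rnorm(100)); y <- cumsum(rnorm(100))
  acc <- 0
  for (i in 2:100) acc <- acc + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  expect_equal(path_length(x, y), acc)
})

test_that("DP stays in [0,1] and the triangle inequality holds", {
  set.seed(78)
  for (r in 1:50) {
    n <- sample(3:60, 1)
    x <- cumsum(rnorm(n, sd = 3)); y <- cumsum(rnorm(n, sd = 3))
    dp <- directional_persistence(x, y)
    expect_gte(dp, 0); expect_lte(dp, 1)
    expect_gte(path_length(x, y), track_displacement(x, y))
  }
})

test_that("migration classification distinguishes chamber, channel, tumor", {
  imm <- lay$rects[lay$rects$region == "immune", ]
  # confined to the immune chamber
  m1 <- classify_migration(seq(imm$x0 + 50, imm$x0 + 200, length.out = 5),
                           rep(600, 5), 0:4, lay)
  expect_false(m1$migrated); expect_false(m1$infiltrated)
  expect_true(is.na(m1$side))
  # ends mid-channel
  ch <- lay$rects[lay$rects$region == "channel_right", ][1, ]
  ymid <- (ch$y0 + ch$y1) / 2
  m2 <- classify_migration(c(ch$x0 - 30, ch$x0 + 50), rep(ymid, 2), 0:1, lay)
  expect_true(m2$migrated); expect_false(m2$infiltrated)
  expect_equal(m2$side, "right")
  # reverse crossing after infiltration is flagged
  m3 <- classify_migration(c(ch$x0 - 10, ch$x0 + 100, ch$x1 + 50, ch$x0 + 100),
                           rep(ymid, 4), 0:3, lay)
  expect_true(m3$infiltrated)
  expect_true(m3$reverse_crossing)
})

test_that("event counting uses half-open windows keyed to the event frame", {
  ch <- lay$rects[lay$rects$region == "channel_right", ][1, ]
  ymid <- (ch$y0 + ch$y1) / 2
  imm <- lay$rects[lay$rects$region == "immune", ]
  # 60-min frames; enters the channel at frame 30 (= 30 h), tumor at 31
  n <- 40
  x <- c(seq(imm$x0 + 600, ch$x0 - 1, length.out = 30),
         ch$x0 + 100, rep(ch$x1 + 50, n - 31))
  tk <- tibble::tibble(track_id = 1, class = "dc", frame = 0:(n - 1),
                       x_um = x, y_um = ymid)
  cnt <- count_by_window(tk, lay, window_spec(), frame_interval = 60,
                         mode = "event")
  right <- cnt[cnt$side == "right", ]
  expect_equal(right$migrating, c(0L, 1L, 0L))
  expect_equal(right$infiltrated, c(0L, 1L, 0L))
  expect_true(all(cnt$migrating[cnt$side == "left"] == 0))
  # event exactly at 24 h falls in the 24-48 h window; the cell then stays
  # in the channel until 60 h
  x2 <- c(seq(imm$x0 + 600, ch$x0 - 1, length.out = 24),
          rep(ch$x0 + 100, 36))
  tk2 <- tibble::tibble(track_id = 1, class = "dc", frame = 0:59,
                        x_um = x2, y_um = ymid)
  cnt2 <- count_by_window(tk2, lay, window_spec(), frame_interval = 60,
                          mode = "event")
  expect_equal(cnt2$migrating[cnt2$side == "right"], c(0L, 1L, 0L))
  # presence mode counts the cell in every window it occupies the regions
  cnt3 <- count_by_window(tk2, lay, window_spec(), frame_interval = 60,
                          mode = "presence")
  expect_equal(cnt3$migrating[cnt3$side == "right"], c(0L, 1L, 1L))
})

test_that("migrated counts contain infiltrated counts in biased cohorts", {
  cfg <- sim_config(n_dcs = 60, n_cancer_per_chamber = 0, n_frames = 200,
                    speed_mean = 5, bias_strength = 0.7, bias_side = "right",
                    seed = 19)
  tr <- simulate_tracks(cfg, lay)
  tk <- dplyr::rename(tr, track_id = "agent_id")
  ws <- window_spec(rbind(c(0, 2), c(2, 4), c(4, 7)))
  # occupancy: a cell in a tumor chamber is also a migrating cell, so
  # containment holds within every window
  cntp <- count_by_window(tk, lay, ws, frame_interval = cfg$frame_interval,
                          mode = "presence")
  expect_true(all(cntp$migrating >= cntp$infiltrated))
  # first-event counts satisfy containment in aggregate (the channel-entry
  # event can fall in an earlier window than the infiltration event)
  cnte <- count_by_window(tk, lay, ws, frame_interval = cfg$frame_interval,
                          mode = "event")
  tot <- dplyr::summarise(dplyr::group_by(cnte, side),
                          m = sum(migrating), i = sum(infiltrated))
  expect_true(all(tot$m >= tot$i))
})

test_that("fold increase is a guarded ratio", {
  expect_equal(fold_increase(30, 6), 5)
  expect_equal(fold_increase(7, 7), 1)
  expect_warning(fi <- fold_increase(3, 0), "control")
  expect_true(is.na(fi))
})

test_that("window metrics are computed on window-local sub-segments", {
  imm <- lay$rects[lay$rects$region == "immune", ]
  # straight mover spanning two 24 h windows at 60-min frames
  n <- 40
  tk <- tibble::tibble(track_id = 1, class = "dc", frame = 0:(n - 1),
                       x_um = seq(imm$x0 + 50, imm$x0 + 50 + (n - 1) * 5,
                                  by = 5),
                       y_um = 600)
  wm <- window_metrics(tk, lay, window_spec(), frame_interval = 60)
  expect_equal(nrow(wm), 2)
  expect_equal(wm$window, c("0-24h", "24-48h"))
  expect_equal(wm$dp, c(1, 1))
  # segment-local path: 23 and 15 steps of 5 um
  expect_equal(wm$path_length, c(23 * 5, 15 * 5))
  # a window holding a single frame contributes no row
  tk2 <- tk[tk$frame <= 24, ]
  wm2 <- window_metrics(tk2, lay,
                        window_spec(min_frames_in_window = 5),
                        frame_interval = 60)
  expect_equal(nrow(wm2), 1)
  expect_equal(wm2$window, "0-24h")
})

test_that("pre- and post-channel speeds are restricted to their chambers", {
  ch <- lay$rects[lay$rects$region == "channel_right", ][1, ]
  ymid <- (ch$y0 + ch$y1) / 2
  imm <- lay$rects[lay$rects$region == "immune", ]
  # 6 frames immune (5 um/frame), 4 in channel, 6 in tumor (10 um/frame)
  x <- c(seq(ch$x0 - 26, ch$x0 - 1, by = 5),
         seq(ch$x0 + 20, ch$x0 + 180, length.out = 4),
         seq(ch$x1 + 10, ch$x1 + 60, by = 10))
  tk <- tibble::tibble(track_id = 1, class = "dc", frame = 0:15,
                       x_um = x, y_um = ymid)
  wm <- window_metrics(tk, lay, window_spec(rbind(c(0, 10))),
                       frame_interval = 2)
  expect_equal(wm$pre_channel_speed, 5 / 2)
  expect_equal(wm$post_channel_speed, 10 / 2)
  # a track never entering a tumor chamber has no post-channel speed
  tk2 <- tibble::tibble(track_id = 2, class = "dc", frame = 0:5,
                        x_um = seq(imm$x0 + 50, imm$x0 + 100, by = 10),
                        y_um = 600)
  wm2 <- window_metrics(tk2, lay, window_spec(rbind(c(0, 10))),
                        frame_interval = 2)
  expect_true(is.na(wm2$post_channel_speed))
  expect_false(is.na(wm2$pre_channel_speed))
})

test_that("simulated speed and DP are recovered through window metrics", {
  cfg <- sim_config(n_dcs = 200, n_cancer_per_chamber = 0, n_frames = 40,
                    speed_mean = 5, speed_sd = 1.5, persistence = 0,
                    seed = 57)
  tr <- simulate_tracks(cfg, lay)
  tk <- dplyr::rename(tr, track_id = "agent_id")
  wm <- window_metrics(tk, lay, window_spec(rbind(c(0, 2))),
                       frame_interval = cfg$frame_interval)
  se <- sd(wm$speed) / sqrt(nrow(wm))
  expect_lt(abs(mean(wm$speed) - 5), 3 * se)
})
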