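lay <- device_layout(pixel_size = 2)

test_that("layout background mask covers exactly the culture regions", {
  tr <- spaced_truth(lay, n = 5, n_frames = 1, seed = 1)
  stk <- render_stack(tr, lay, noise = noise_model(shot_scale = Inf),
                      frame_interval = 2)
  mask <- background_mask(stk, lay, mode = "layout")
  rm <- rasterize_regions(lay)
  lab <- rm$levels[rm$labels]
  expect_equal(sum(mask), sum(!(lab %in% c("background", "medium"))))
})

test_that("auto mask falls back to layout with a warning on short stacks", {
  tr <- spaced_truth(lay, n = 3, n_frames = 2, seed = 2)
  stk <- render_stack(tr, lay, noise = noise_model(shot_scale = Inf),
                      frame_interval = 2)
  expect_warning(m_auto <- background_mask(stk, lay, mode = "auto"),
                 "layout")
  m_lay <- background_mask(stk, lay, mode = "layout")
  expect_identical(m_auto, m_lay)
})

test_that("auto mask keeps moving-agent pixels and drops static regions", {
  # agents confined to the immune chamber; tumor chambers carry no signal
  set.seed(8)
  cfg <- sim_config(n_dcs = 20, n_cancer_per_chamber = 0, n_frames = 6,
                    speed_mean = 8, seed = 8)
  tr <- simulate_tracks(cfg, lay)
  stk <- render_stack(tr, lay,
                      noise = noise_model(background = 0.05, gradient = 0,
                                          shot_scale = Inf))
  m <- background_mask(stk, lay, mode = "auto", k = 2)
  rm <- rasterize_regions(lay)
  lab <- rm$levels[rm$labels]
  # variance criterion agrees with a direct per-pixel variance computation
  arr <- stk$channels$dc
  v <- apply(arr, c(1, 2), stats::var) * (dim(arr)[3] - 1) / dim(arr)[3]
  base <- !(lab %in% c("background", "medium"))
  direct <- (v > 2 * stats::median(v[base])) & base
  expect_gt(mean(m == direct), 0.999) # identical up to float rounding
  # static tumor-chamber pixels are excluded
  expect_equal(sum(m[lab == "tumor_left"]), 0)
  expect_gt(sum(m[lab == "immune"]), 0)
})

test_that("segmentation finds isolated rendered spots with high fidelity", {
  tr <- spaced_truth(lay, n = 50, spacing = 20, n_frames = 2, seed = 5)
  # SNR 5: amplitude 0.6 over shot noise sd sqrt(0.05 / 3.5) ~ 0.12
  set.seed(5)
  stk <- render_stack(tr, lay,
                      noise = noise_model(background = 0.05, gradient = 0.02,
                                          shot_scale = 3.5),
                      amplitude = 0.6, frame_interval = 2)
  det <- detect_stack(stk, lay,
                      detect_params(smooth_sigma = 1.5, min_area = 20,
                                    max_area = 2000))
  m <- match_detections(tr, det, tol = 10)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)

  # noiseless isolated spots: sub-half-pixel centroid accuracy
  stk0 <- render_stack(tr, lay,
                       noise = noise_model(background = 0.05, gradient = 0,
                                           shot_scale = Inf),
                       amplitude = 0.6, frame_interval = 2)
  det0 <- detect_stack(stk0, lay,
                       detect_params(smooth_sigma = 1.5, min_area = 20,
                                     max_area = 2000))
  m0 <- match_detections(tr, det0, tol = 10)
  expect_equal(m0$recall, 1)
  rmse_px <- sqrt(mean(m0$err_um^2)) / lay$pixel_size
  expect_lte(rmse_px, 0.5)
})

test_that("two spots separated by more than 4 blur sigmas stay distinct", {
  # spot sigma = 0.6 * 7 um = 4.2 um; separation 30 um > 4 sigma
  tr <- tibble::tibble(agent_id = 1:2, class = "dc", frame = 0,
                       x_um = c(1500, 1530), y_um = c(600, 600))
  stk <- render_stack(tr, lay, noise = noise_model(shot_scale = Inf),
                      frame_interval = 2)
  det <- detect_stack(stk, lay, detect_params(smooth_sigma = 1.5,
                                              min_area = 20, max_area = 2000))
  expect_equal(nrow(det), 2)
})

test_that("degenerate frames yield no detections", {
  mask <- matrix(TRUE, 20, 20)
  flat <- matrix(0.3, 20, 20)
  expect_equal(nrow(segment_frame(flat, mask, pixel_size = 2)), 0)
  expect_error(segment_frame(flat, matrix(FALSE, 20, 20)), "mask")
})

test_that("otsu split is invariant to a constant intensity offset", {
  set.seed(13)
  v <- c(rnorm(5000, 0.1, 0.02), rnorm(300, 0.6, 0.05))
  t1 <- cocultrack:::otsu_threshold(v)
  t2 <- cocultrack:::otsu_threshold(v + 0.2)
  expect_equal(t2 - t1, 0.2, tolerance = 1e-6)
  # and detections on an offset frame are unchanged (otsu mode)
  tr <- spaced_truth(lay, n = 10, n_frames = 1, seed = 3)
  stk <- render_stack(tr, lay, noise = noise_model(shot_scale = Inf),
                      frame_interval = 2)
  fr <- stk$channels$dc[, , 1]
  mask <- background_mask(stk, lay)
  p <- detect_params(smooth_sigma = 1.5, min_area = 20, max_area = 2000)
  d1 <- segment_frame(fr, mask, p, pixel_size = 2)
  d2 <- segment_frame(fr + 0.17, mask, p, pixel_size = 2)
  expect_equal(d1$x_um, d2$x_um, tolerance = 1e-8)
  expect_equal(d1$y_um, d2$y_um, tolerance = 1e-8)
})

test_that("detect_stack labels detections by channel role and region", {
  tr_dc <- spaced_truth(lay, n = 6, n_frames = 3, seed = 4, class = "dc")
  set.seed(6)
  ca_rect <- lay$rects[lay$rects$region == "tumor_right", ]
  tr_ca <- dplyr::bind_rows(lapply(0:2, function(f) {
    tibble::tibble(agent_id = 100 + 1:4, class = "cancer", frame = f,
                   x_um = seq(ca_rect$x0 + 100, ca_rect$x1 - 100,
                              length.out = 4),
                   y_um = seq(ca_rect$y0 + 100, ca_rect$y1 - 100,
                              length.out = 4))
  }))
  tr <- dplyr::bind_rows(tr_dc, tr_ca)
  stk <- render_stack(tr, lay, noise = noise_model(shot_scale = Inf),
                      frame_interval = 2)
  det <- detect_stack(stk, lay, detect_params(smooth_sigma = 1.5,
                                              min_area = 20, max_area = 2000))
  expect_setequal(unique(det$class), c("dc", "cancer"))
  # n spots per frame x frames per channel
  expect_equal(sum(det$class == "dc"), 6 * 3)
  expect_equal(sum(det$class == "cancer"), 4 * 3)
  expect_true(all(det$region[det$class == "cancer"] == "tumor_right"))
  expect_false(any(det$region == "background"))
})

test_that("rendering obeys its contract", {
  # single static agent, no noise: argmax at the agent's pixel
  tr <- tibble::tibble(agent_id = 1, class = "dc", frame = 0:1,
                       x_um = 1501, y_um = 601)
  stk <- render_stack(tr, lay, noise = noise_model(background = 0,
                                                   gradient = 0,
                                                   shot_scale = Inf),
                      frame_interval = 2)
  for (t in 1:2) {
    idx <- which(stk$channels$dc[, , t] ==
                   max(stk$channels$dc[, , t]), arr.ind = TRUE)
    expect_equal(as.numeric(idx[1, ]), c(301, 751), tolerance = 1)
  }
  # zero agents: frames equal the background model exactly
  empty <- tr[0, ]
  stk0 <- render_stack(empty, lay,
                       noise = noise_model(background = 0.05,
                                           gradient = 0.02,
                                           shot_scale = Inf),
                       frame_interval = 2, channels = "dc")
  h <- lay$extent_px[1]; w <- lay$extent_px[2]
  bg <- matrix(0.05, h, w) +
    0.02 * matrix(rep(seq(0, 1, length.out = w), each = h), h, w)
  expect_equal(stk0$channels$dc[, , 1], bg, tolerance = 1e-12)
  # two well-separated agents: integrated intensity ~ 2x a single agent
  one <- tibble::tibble(agent_id = 1, class = "dc", frame = 0,
                        x_um = 1200, y_um = 500)
  two <- dplyr::bind_rows(one, tibble::tibble(agent_id = 2, class = "dc",
                                              frame = 0, x_um = 1800,
                                              y_um = 700))
  s1 <- render_stack(one, lay, noise = noise_model(background = 0,
                                                   gradient = 0,
                                                   shot_scale = Inf),
                     frame_interval = 2)
  s2 <- render_stack(two, lay, noise = noise_model(background = 0,
                                                   gradient = 0,
                                                   shot_scale = Inf),
                     frame_interval = 2)
  expect_equal(sum(s2$channels$dc), 2 * sum(s1$channels$dc),
               tolerance = 1e-6)
})

test_that("frame stacks round trip through multi-page TIFF", {
  tr <- spaced_truth(lay, n = 4, n_frames = 3, seed = 12)
  set.seed(12)
  stk <- render_stack(tr, lay, noise = noise_model(shot_scale = 1000),
                      frame_interval = 2)
  prefix <- tempfile("stk_")
  write_stack(stk, prefix)
  stk2 <- read_stack(prefix)
  expect_equal(stk2$pixel_size, stk$pixel_size)
  expect_equal(stk2$frame_interval, stk$frame_interval)
  expect_equal(dim(stk2$channels$dc), dim(stk$channels$dc))
  # 16-bit quantization error only
  expect_lt(max(abs(stk2$channels$dc - stk$channels$dc)), 1 / 65535)
})
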