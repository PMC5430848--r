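#' Analysis time windows
#'
#' Half-open windows in hours over which per-cell metrics and counts are
#' aggregated; the defaults are the standard 0-24, 24-48 and 48-72 h
#' follow-up periods.
#'
#' @param windows Two-column matrix (or list of `c(start, end)`) of window
#'   bounds in hours; must be non-overlapping and increasing.
#' @param min_frames_in_window Minimum points a track must have inside a
#'   window to contribute a metrics row.
#' @return List of class `window_spec`.
#' @export
window_spec <- function(windows = rbind(c(0, 24), c(24, 48), c(48, 72)),
                        min_frames_in_window = 5) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  stopifnot(ncol(windows) == 2, all(windows[, 2] > windows[, 1]),
            min_frames_in_window >= 1)
  if (nrow(windows) > 1) {
    stopifnot(all(windows[-1, 1] >= windows[-nrow(windows), 2]))
  }
  structure(list(windows = windows,
                 min_frames_in_window = min_frames_in_window),
            class = "window_spec")
}

window_label <- function(w) sprintf("%g-%gh", w[1], w[2])

#' Total path length of a track segment
#'
#' Sum of consecutive Euclidean steps, µm. Segments with fewer than two
#' points have no defined path length and return `NA`.
#'
#' @param x,y Coordinate vectors, µm, in frame order.
#' @return Length in µm, or `NA_real_`.
#' @export
path_length <- function(x, y) {
  if (length(x) < 2) return(NA_real_)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Migration speed of a track segment
#'
#' The ratio of total distance travelled to the duration of migration,
#' µm/min.
#'
#' @param x,y Coordinates, µm.
#' @param frames Frame indices (same length).
#' @param frame_interval Minutes per frame.
#' @return Speed in µm/min, `NA` if the segment spans < 2 points.
#' @export
track_speed <- function(x, y, frames, frame_interval) {
  if (length(x) < 2) return(NA_real_)
  dur <- (max(frames) - min(frames)) * frame_interval
  if (dur <= 0) return(NA_real_)
  path_length(x, y) / dur
}

#' Net displacement of a track segment
#'
#' `mode = "euclidean"`: straight-line distance from the first to the last
#' position. `mode = "horizontal"`: absolute displacement along the
#' immune-to-tumor (x) axis, the horizontal path displacement.
#'
#' @param x,y Coordinates, µm.
#' @param mode `"euclidean"` or `"horizontal"`.
#' @return Displacement in µm (`NA` for < 2 points).
#' @export
track_displacement <- function(x, y, mode = c("euclidean", "horizontal")) {
  mode <- match.arg(mode)
  if (length(x) < 2) return(NA_real_)
  if (mode == "horizontal") {
    abs(x[length(x)] - x[1])
  } else {
    sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  }
}

#' Directional persistence of a track segment
#'
#' Ratio of the Euclidean distance between the starting and ending position
#' to the total path length. Values close to 1 indicate a strongly
#' directional path; values close to 0 indicate dominantly Brownian motion.
#'
#' @param x,y Coordinates, µm.
#' @return Value in `[0, 1]`, or `NA` when the path length is zero or the
#'   segment has < 2 points.
#' @export
directional_persistence <- function(x, y) {
  pl <- path_length(x, y)
  if (is.na(pl) || pl <= 0) return(NA_real_)
  min(track_displacement(x, y, "euclidean") / pl, 1)
}

#' Classify the migration status of one track
#'
#' A track has migrated when it reaches a connecting channel or a tumor
#' chamber (it crossed the channel entry boundary), and has infiltrated when
#' it reaches a tumor chamber. The side is that of the first channel or
#' tumor region visited. Re-entry into a channel after infiltration raises
#' `reverse_crossing` but cells stay counted once.
#'
#' @param x,y,frames Track coordinates (µm) and 0-based frame indices.
#' @param layout A [device_layout()].
#' @return One-row tibble: `migrated`, `infiltrated`, `side`,
#'   `first_entry_frame`, `first_infiltration_frame`, `reverse_crossing`.
#' @export
classify_migration <- function(x, y, frames, layout) {
  reg <- classify_point(layout, x, y)
  in_ch <- grepl("^channel", reg)
  in_tum <- grepl("^tumor", reg)
  mig_idx <- which(in_ch | in_tum)
  inf_idx <- which(in_tum)
  migrated <- length(mig_idx) > 0
  infiltrated <- length(inf_idx) > 0
  side <- if (migrated) sub("^(channel|tumor)_", "", reg[mig_idx[1]]) else NA_character_
  reverse <- FALSE
  if (infiltrated) {
    after <- seq(inf_idx[1], length(reg))
    reverse <- any(in_ch[after])
  }
  tibble(
    migrated = migrated,
    infiltrated = infiltrated,
    side = side,
    first_entry_frame = if (migrated) frames[mig_idx[1]] else NA_integer_,
    first_infiltration_frame = if (infiltrated) frames[inf_idx[1]] else NA_integer_,
    reverse_crossing = reverse
  )
}

#' Per-window counts of migrating and infiltrated cells by side
#'
#' `mode = "event"` assigns each track once per category to the window
#' containing its first qualifying event frame (a cell infiltrating at 30 h
#' is counted in the 24-48 h window only). `mode = "presence"` counts a
#' track once in every window during which it occupies a qualifying region
#' (channel or tumor for `migrating`, tumor for `infiltrated`), matching
#' image-based counts of cells present in the analysed areas at each
#' follow-up time. Windows are half-open `[start, end)` in hours.
#'
#' @param tracks Tracks tibble (`track_id`, `frame`, `x_um`, `y_um`),
#'   typically the `dc` class only.
#' @param layout A [device_layout()].
#' @param windows A [window_spec()].
#' @param frame_interval Minutes per frame.
#' @param mode `"event"` or `"presence"`.
#' @return Tibble: `side`, `window`, `migrating`, `infiltrated`.
#' @export
count_by_window <- function(tracks, layout, windows = window_spec(),
                            frame_interval, mode = c("event", "presence")) {
  mode <- match.arg(mode)
  W <- windows$windows
  grid <- tidyr::expand_grid(side = c("left", "right"),
                             wi = seq_len(nrow(W)))
  grid$window <- apply(W, 1, window_label)[grid$wi]
  grid$migrating <- 0L
  grid$infiltrated <- 0L
  if (nrow(tracks) == 0) return(dplyr::select(grid, -"wi"))
  tr_split <- split(tracks, tracks$track_id)
  for (tr in tr_split) {
    tr <- tr[order(tr$frame), ]
    hours <- tr$frame * frame_interval / 60
    reg <- classify_point(layout, tr$x_um, tr$y_um)
    in_ch <- grepl("^channel", reg)
    in_tum <- grepl("^tumor", reg)
    qual <- in_ch | in_tum
    if (!any(qual)) next
    side <- sub("^(channel|tumor)_", "", reg[which(qual)[1]])
    for (wi in seq_len(nrow(W))) {
      inw <- hours >= W[wi, 1] & hours < W[wi, 2]
      row <- which(grid$side == side & grid$wi == wi)
      if (mode == "presence") {
        if (any(qual & inw)) grid$migrating[row] <- grid$migrating[row] + 1L
        if (any(in_tum & inw)) grid$infiltrated[row] <- grid$infiltrated[row] + 1L
      } else {
        h_entry <- hours[which(qual)[1]]
        h_inf <- if (any(in_tum)) hours[which(in_tum)[1]] else NA
        if (h_entry >= W[wi, 1] && h_entry < W[wi, 2]) {
          grid$migrating[row] <- grid$migrating[row] + 1L
        }
        if (!is.na(h_inf) && h_inf >= W[wi, 1] && h_inf < W[wi, 2]) {
          grid$infiltrated[row] <- grid$infiltrated[row] + 1L
        }
      }
    }
  }
  dplyr::select(grid, -"wi")
}

#' Fold increase of a count relative to a control
#'
#' Ratio of infiltrated-cell counts in a condition versus the matrix
#' control; a control count of zero yields `NA` with a warning.
#'
#' @param count_condition,count_control Non-negative counts.
#' @return Dimensionless ratio.
#' @export
fold_increase <- function(count_condition, count_control) {
  if (any(count_control == 0)) {
    warning("control count is zero; fold increase undefined")
  }
  ifelse(count_control > 0, count_condition / count_control, NA_real_)
}

#' Per-track, per-window motility metrics
#'
#' For every track and analysis window, computes the metrics of the
#' sub-segment falling inside the window (at least
#' `windows$min_frames_in_window` points): path length, Euclidean and
#' horizontal displacement, directional persistence, pre-channel speed
#' (points in the immune chamber before the track's first channel entry),
#' post-channel speed (points in a tumor chamber after first infiltration),
#' overall segment speed, and the migration status of the whole track. The
#' `side` column is the track's migration side when it migrated, otherwise
#' the immune-chamber half (relative to the chamber midline) containing the
#' segment's mean position.
#'
#' @param tracks Tracks tibble (`track_id`, `class`, `frame`, `x_um`,
#'   `y_um`).
#' @param layout A [device_layout()].
#' @param windows A [window_spec()].
#' @param frame_interval Minutes per frame.
#' @return Tibble, one row per track x window with enough support.
#' @export
window_metrics <- function(tracks, layout, windows = window_spec(),
                           frame_interval) {
  W <- windows$windows
  imm <- layout$rects[layout$rects$region == "immune", ]
  mid_x <- (imm$x0 + imm$x1) / 2
  rows <- list()
  for (tr in split(tracks, tracks$track_id)) {
    tr <- tr[order(tr$frame), ]
    reg <- classify_point(layout, tr$x_um, tr$y_um)
    mig <- classify_migration(tr$x_um, tr$y_um, tr$frame, layout)
    hours <- tr$frame * frame_interval / 60
    first_ch <- if (!is.na(mig$first_entry_frame)) {
      match(mig$first_entry_frame, tr$frame)
    } else Inf
    first_inf <- if (!is.na(mig$first_infiltration_frame)) {
      match(mig$first_infiltration_frame, tr$frame)
    } else Inf
    for (wi in seq_len(nrow(W))) {
      sel <- which(hours >= W[wi, 1] & hours < W[wi, 2])
      if (length(sel) < windows$min_frames_in_window) next
      x <- tr$x_um[sel]; y <- tr$y_um[sel]; f <- tr$frame[sel]
      pre_sel <- sel[reg[sel] == "immune" & seq_along(tr$frame)[sel] < first_ch]
      post_sel <- sel[grepl("^tumor", reg[sel]) &
                        seq_along(tr$frame)[sel] >= first_inf]
      side <- if (!is.na(mig$side)) {
        mig$side
      } else if (mean(x) < mid_x) "left" else "right"
      rows[[length(rows) + 1]] <- tibble(
        track_id = tr$track_id[1],
        window = window_label(W[wi, ]),
        side = side,
        n_points = length(sel),
        path_length = path_length(x, y),
        displacement_euclid = track_displacement(x, y, "euclidean"),
        displacement_horiz = track_displacement(x, y, "horizontal"),
        dp = directional_persistence(x, y),
        speed = track_speed(x, y, f, frame_interval),
        pre_channel_speed = track_speed(tr$x_um[pre_sel], tr$y_um[pre_sel],
                                        tr$frame[pre_sel], frame_interval),
        post_channel_speed = track_speed(tr$x_um[post_sel], tr$y_um[post_sel],
                                         tr$frame[post_sel], frame_interval),
        migrated = mig$migrated,
        infiltrated = mig$infiltrated,
        reverse_crossing = mig$reverse_crossing
      )
    }
  }
  if (!length(rows)) {
    return(tibble(track_id = numeric(), window = character(),
                  side = character(), n_points = integer(),
                  path_length = numeric(), displacement_euclid = numeric(),
                  displacement_horiz = numeric(), dp = numeric(),
                  speed = numeric(), pre_channel_speed = numeric(),
                  post_channel_speed = numeric(), migrated = logical(),
                  infiltrated = logical(), reverse_crossing = logical()))
  }
  dplyr::bind_rows(rows)
}
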