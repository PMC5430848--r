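#' Detect DC-cancer cell interaction events
#'
#' For every (DC track, cancer track) pair, finds maximal runs of frames in
#' which the DC centroid lies within `radius` µm of the cancer-cell centroid
#' (a circular region of interaction around each cancer cell), merging runs
#' separated by at most `gap_tolerance` missing or out-of-radius frames.
#' Events are restricted to the tumor chambers; a DC inside the radii of two
#' cancer cells simultaneously yields one event per cancer cell.
#'
#' @param dc_tracks,cancer_tracks Track tibbles (`track_id`, `frame`,
#'   `x_um`, `y_um`); classes need not be set.
#' @param radius Interaction radius, µm (> 0). The default 20 µm is a
#'   7 µm DC radius plus a 9 µm cancer-cell radius plus a 4 µm margin.
#' @param gap_tolerance Frames of interruption tolerated inside one event.
#' @param frame_interval Minutes per frame.
#' @param layout Optional [device_layout()]; when given, in-radius frames
#'   also require the DC centroid inside a tumor chamber, and events carry
#'   the chamber side (otherwise side is inferred from the cancer cell's
#'   mean x relative to the DC-chamber midline).
#' @return Tibble of class events: `dc_track_id`, `cancer_track_id`, `side`,
#'   `start_frame`, `end_frame`, `duration_min` (= (end - start + 1) x
#'   `frame_interval`).
#' @export
detect_interactions <- function(dc_tracks, cancer_tracks, radius = 20,
                                gap_tolerance = 1, frame_interval = 2,
                                layout = NULL) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  stopifnot(gap_tolerance >= 0, frame_interval > 0)
  empty <- tibble(dc_track_id = numeric(), cancer_track_id = numeric(),
                  side = character(), start_frame = integer(),
                  end_frame = integer(), duration_min = numeric())
  if (nrow(dc_tracks) == 0 || nrow(cancer_tracks) == 0) return(empty)

  events <- list()
  for (ca in split(cancer_tracks, cancer_tracks$track_id)) {
    ca <- ca[order(ca$frame), ]
    side <- if (!is.null(layout)) {
      reg <- classify_point(layout, mean(ca$x_um), mean(ca$y_um))
      if (grepl("^tumor", reg)) sub("^tumor_", "", reg) else NA_character_
    } else NA_character_
    for (dc in split(dc_tracks, dc_tracks$track_id)) {
      dc <- dc[order(dc$frame), ]
      common <- intersect(dc$frame, ca$frame)
      if (!length(common)) next
      di <- match(common, dc$frame); ci <- match(common, ca$frame)
      dist <- sqrt((dc$x_um[di] - ca$x_um[ci])^2 +
                     (dc$y_um[di] - ca$y_um[ci])^2)
      inr <- dist <= radius
      if (!is.null(layout)) {
        dc_reg <- classify_point(layout, dc$x_um[di], dc$y_um[di])
        inr <- inr & grepl("^tumor", dc_reg)
      }
      if (!any(inr)) next
      fr <- common # sorted: both frame vectors are sorted
      hit <- fr[inr]
      # merge runs separated by <= gap_tolerance frames
      brk <- which(diff(hit) > gap_tolerance + 1)
      starts <- hit[c(1, brk + 1)]
      ends <- hit[c(brk, length(hit))]
      events[[length(events) + 1]] <- tibble(
        dc_track_id = dc$track_id[1],
        cancer_track_id = ca$track_id[1],
        side = side,
        start_frame = as.integer(starts),
        end_frame = as.integer(ends),
        duration_min = (ends - starts + 1) * frame_interval)
    }
  }
  if (!length(events)) return(empty)
  dplyr::arrange(dplyr::bind_rows(events), .data$dc_track_id,
                 .data$cancer_track_id, .data$start_frame)
}

#' Mean interaction time per side and analysis window
#'
#' Events are assigned to the window containing their start frame; per side
#' and window the mean, standard deviation and count of `duration_min` are
#' reported (windows without events give `NA` with `n = 0`).
#'
#' @param events Event tibble from [detect_interactions()].
#' @param windows A [window_spec()].
#' @param frame_interval Minutes per frame.
#' @return Tibble: `side`, `window`, `n`, `mean_min`, `sd_min`.
#' @export
mean_interaction_time <- function(events, windows = window_spec(),
                                  frame_interval = 2) {
  W <- windows$windows
  sides <- unique(stats::na.omit(events$side))
  if (!length(sides)) sides <- NA_character_
  grid <- tidyr::expand_grid(side = sides, wi = seq_len(nrow(W)))
  grid$window <- apply(W, 1, window_label)[grid$wi]
  grid$n <- 0L
  grid$mean_min <- NA_real_
  grid$sd_min <- NA_real_
  if (nrow(events)) {
    h <- events$start_frame * frame_interval / 60
    for (g in seq_len(nrow(grid))) {
      sel <- (is.na(grid$side[g]) | events$side %in% grid$side[g]) &
        h >= W[grid$wi[g], 1] & h < W[grid$wi[g], 2]
      if (any(sel)) {
        grid$n[g] <- sum(sel)
        grid$mean_min[g] <- mean(events$duration_min[sel])
        grid$sd_min[g] <- stats::sd(events$duration_min[sel])
      }
    }
  }
  dplyr::select(grid, -"wi")
}

#' @rdname detect_interactions
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
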