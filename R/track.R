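#' Linking parameters
#'
#' @param gate_distance Maximum link distance, µm per frame interval. The
#'   default 48 µm corresponds to 3 x an expected step of a 8 µm/min cell
#'   imaged every 2 min.
#' @param gap_frames Maximum number of consecutive missed frames bridged by
#'   gap closing.
#' @param min_track_length Minimum number of points for a track to be kept.
#' @return List of class `link_params`.
#' @export
link_params <- function(gate_distance = 48, gap_frames = 2,
                        min_track_length = 5) {
  stopifnot(gate_distance > 0, gap_frames >= 0, min_track_length >= 1)
  structure(list(gate_distance = gate_distance, gap_frames = gap_frames,
                 min_track_length = min_track_length),
            class = "link_params")
}

BIG_COST <- 1e12

#' Optimal frame-to-frame assignment of detections
#'
#' Minimum-total-cost one-to-one assignment between the detections of two
#' consecutive frames, with squared displacement as link cost, links
#' restricted to pairs within `gate_distance`, and a fixed alternative cost
#' of `gate_distance^2` for leaving a detection unmatched (track birth /
#' death). Solved exactly on the standard augmented square matrix by the
#' Hungarian method.
#'
#' @param d1,d2 Detection tibbles for the earlier and later frame (columns
#'   `x_um`, `y_um`).
#' @param params A [link_params()].
#' @return List with `matches` (two-column integer matrix: row index in
#'   `d1`, row index in `d2`) and `cost` (total objective value, matched
#'   squared distances plus `gate_distance^2` per unmatched detection).
#' @export
link_frames <- function(d1, d2, params = link_params()) {
  n1 <- nrow(d1); n2 <- nrow(d2)
  lambda <- params$gate_distance^2
  if (n1 == 0 || n2 == 0) {
    return(list(matches = matrix(integer(), ncol = 2),
                cost = lambda * (n1 + n2)))
  }
  D2 <- outer(d1$x_um, d2$x_um, "-")^2 + outer(d1$y_um, d2$y_um, "-")^2
  C <- matrix(BIG_COST, n1 + n2, n2 + n1)
  feas <- D2 <= lambda
  Ctl <- ifelse(feas, D2, BIG_COST)
  C[seq_len(n1), seq_len(n2)] <- Ctl
  C[cbind(seq_len(n1), n2 + seq_len(n1))] <- lambda        # deaths
  C[cbind(n1 + seq_len(n2), seq_len(n2))] <- lambda        # births
  C[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0               # slack block
  sol <- clue::solve_LSAP(C)
  assignment <- as.integer(sol)
  i <- seq_len(n1)
  j <- assignment[i]
  keep <- j <= n2 & feas[cbind(i, pmin(j, n2))]
  matches <- cbind(i[keep], j[keep])
  cost <- sum(D2[matches]) + lambda * ((n1 - nrow(matches)) +
                                         (n2 - nrow(matches)))
  list(matches = matches, cost = cost)
}

#' Link detections of a whole recording into tracks
#'
#' Runs [link_frames()] over every consecutive frame pair (per class),
#' chains the assignments into trajectories, closes short gaps with
#' [close_gaps()], and drops tracks shorter than `min_track_length`.
#'
#' @param detections Detections tibble (needs `frame`, `class`, `x_um`,
#'   `y_um`; extra columns are preserved).
#' @param params A [link_params()].
#' @return Tracks tibble: `track_id`, `class`, `frame`, `x_um`, `y_um`,
#'   `interpolated`, plus any preserved columns (NA on interpolated rows).
#' @export
track_stack <- function(detections, params = link_params()) {
  out <- lapply(split(detections, detections$class), function(det) {
    track_one_class(det, params)
  })
  # make ids globally unique across classes
  offset <- 0
  for (k in seq_along(out)) {
    out[[k]]$track_id <- out[[k]]$track_id + offset
    offset <- offset + max(out[[k]]$track_id, 0)
  }
  tracks <- dplyr::bind_rows(out)
  tracks <- close_gaps(tracks, params)
  keep <- table(tracks$track_id)
  keep <- names(keep)[keep >= params$min_track_length]
  tracks <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  dplyr::arrange(tracks, .data$track_id, .data$frame)
}

track_one_class <- function(det, params) {
  det <- dplyr::arrange(det, .data$frame)
  frames <- sort(unique(det$frame))
  by_frame <- split(det, det$frame)
  next_id <- 1L
  # assign ids frame by frame
  ids_by_frame <- list()
  first <- by_frame[[as.character(frames[1])]]
  ids_by_frame[[1]] <- seq_len(nrow(first))
  next_id <- nrow(first) + 1L
  if (length(frames) > 1) {
    for (k in seq_len(length(frames) - 1)) {
      f1 <- frames[k]; f2 <- frames[k + 1]
      d1 <- by_frame[[as.character(f1)]]
      d2 <- by_frame[[as.character(f2)]]
      ids2 <- rep(NA_integer_, nrow(d2))
      if (f2 - f1 == 1) {     # only adjacent frames are linked directly
        lk <- link_frames(d1, d2, params)
        if (nrow(lk$matches)) {
          ids2[lk$matches[, 2]] <- ids_by_frame[[k]][lk$matches[, 1]]
        }
      }
      nnew <- sum(is.na(ids2))
      ids2[is.na(ids2)] <- next_id + seq_len(nnew) - 1L
      next_id <- next_id + nnew
      ids_by_frame[[k + 1]] <- ids2
    }
  }
  det$track_id <- unlist(ids_by_frame)
  det$interpolated <- FALSE
  dplyr::select(det, "track_id", "class", "frame", "x_um", "y_um",
                "interpolated", dplyr::everything())
}

#' Close short temporal gaps between track fragments
#'
#' A track end and a later track start of the same class are merged when
#' separated by at most `gap_frames` missing frames and by a distance of at
#' most `gate_distance x frame gap`; candidate merges are applied greedily
#' in ascending squared-distance order. Missing frames are filled by linear
#' interpolation and flagged `interpolated = TRUE`.
#'
#' @param tracks Tracks tibble (from [track_stack()] internals or the track
#'   table reader).
#' @param params A [link_params()].
#' @return Tracks tibble with merged ids and interpolated rows added.
#' @export
close_gaps <- function(tracks, params = link_params()) {
  if (params$gap_frames == 0 || nrow(tracks) == 0) return(tracks)
  tracks <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  info <- dplyr::summarise(
    dplyr::group_by(tracks, .data$track_id, .data$class),
    f_start = min(.data$frame), f_end = max(.data$frame),
    x_start = .data$x_um[which.min(.data$frame)],
    y_start = .data$y_um[which.min(.data$frame)],
    x_end = .data$x_um[which.max(.data$frame)],
    y_end = .data$y_um[which.max(.data$frame)],
    .groups = "drop")
  # candidate pairs
  cand <- NULL
  for (a in seq_len(nrow(info))) {
    gapf <- info$f_start - info$f_end[a]
    ok <- which(info$class == info$class[a] & gapf >= 2 &
                  gapf <= params$gap_frames + 1)
    if (!length(ok)) next
    d2 <- (info$x_start[ok] - info$x_end[a])^2 +
      (info$y_start[ok] - info$y_end[a])^2
    lim <- (params$gate_distance * (gapf[ok]))^2
    ok2 <- d2 <= lim
    if (any(ok2)) {
      cand <- rbind(cand, cbind(a = a, b = ok[ok2], d2 = d2[ok2]))
    }
  }
  if (is.null(cand)) return(tracks)
  cand <- cand[order(cand[, "d2"]), , drop = FALSE]
  # greedy: each end used once, each start used once
  merged_into <- setNames(info$track_id, info$track_id) # id -> root id
  used_end <- used_start <- rep(FALSE, nrow(info))
  pairs <- list()
  for (r in seq_len(nrow(cand))) {
    a <- cand[r, "a"]; b <- cand[r, "b"]
    if (used_end[a] || used_start[b]) next
    used_end[a] <- TRUE; used_start[b] <- TRUE
    pairs[[length(pairs) + 1]] <- c(info$track_id[a], info$track_id[b])
  }
  resolve <- function(id) {
    while (merged_into[as.character(id)] != id) id <- merged_into[as.character(id)]
    id
  }
  interp_rows <- list()
  for (pr in pairs) {
    ida <- resolve(pr[1]); idb <- pr[2]
    merged_into[as.character(idb)] <- ida
    # interpolate missing frames between the two fragments
    a_end <- info[info$track_id == pr[1], ]
    b_start <- info[info$track_id == idb, ]
    gapf <- b_start$f_start - a_end$f_end
    if (gapf > 1) {
      tfrac <- seq_len(gapf - 1) / gapf
      interp_rows[[length(interp_rows) + 1]] <- tibble(
        track_id = ida,
        class = a_end$class,
        frame = a_end$f_end + seq_len(gapf - 1),
        x_um = a_end$x_end + tfrac * (b_start$x_start - a_end$x_end),
        y_um = a_end$y_end + tfrac * (b_start$y_start - a_end$y_end),
        interpolated = TRUE)
    }
  }
  root <- vapply(tracks$track_id, function(id) resolve(id), numeric(1))
  tracks$track_id <- root
  out <- dplyr::bind_rows(tracks, dplyr::bind_rows(interp_rows))
  dplyr::arrange(out, .data$track_id, .data$frame)
}

#' Write / read track tables
#'
#' CSV schema `track_id, class, frame, x_um, y_um, interpolated`; the reader
#' accepts the same schema, so externally produced tracks can enter the
#' motility analysis.
#'
#' @param tracks Tracks tibble.
#' @param path CSV path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(
    tracks[, c("track_id", "class", "frame", "x_um", "y_um", "interpolated")]),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!"interpolated" %in% names(df)) df$interpolated <- FALSE
  df
}
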