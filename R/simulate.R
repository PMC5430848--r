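#' Configuration for the synthetic time-lapse generator
#'
#' Parameters of the ground-truth motion model: mobile dendritic-cell-like
#' (DC) agents performing a confined, optionally chemotactically biased,
#' persistent random walk in the immune chamber and through the connecting
#' channels, and near-static collagen-embedded cancer-cell agents jittering
#' inside the tumor chambers.
#'
#' The per-step DC heading is a wrapped-normal turn about the previous
#' heading (concentration `persistence`; `persistence = 0` draws an
#' isotropic heading), mixed with a unit drift vector pointing toward the
#' biased tumor chamber with weight `bias_strength`. When `chemo_range` is
#' finite, the drift weight decays as `exp(-d / chemo_range)` with `d` the
#' distance to the biased side's channel entry line, emulating a chemokine
#' gradient of finite reach: recruitment then becomes diffusion-limited and
#' is spread over the whole recording rather than exhausted in the first
#' hours. Step lengths are drawn from a normal distribution truncated at
#' zero. Wall collisions are resolved by specular reflection; agents change
#' compartment only through shared channel openings.
#'
#' @param n_dcs Number of DC agents loaded in the immune chamber at frame 0.
#' @param n_cancer_per_chamber Cancer-cell agents per tumor chamber.
#' @param frame_interval Acquisition interval, minutes (default 2).
#' @param n_frames Number of frames.
#' @param speed_mean,speed_sd Mean and s.d. of instantaneous DC speed,
#'   µm/min. Defaults (4, 1.2) match reported pre-channel speeds of
#'   2–5.6 µm/min.
#' @param persistence Turning-angle concentration (1/variance of the turn in
#'   rad^2); 0 = uncorrelated headings (Brownian-like).
#' @param bias_strength Drift mixing weight in `[0, 1]` toward `bias_side`.
#' @param bias_side `"left"`, `"right"`, or `"none"`.
#' @param chemo_range Chemokine sensing length scale, µm (`Inf` = drift felt
#'   everywhere at full `bias_strength`).
#' @param cancer_jitter_sd Per-frame positional jitter of cancer agents, µm.
#' @param dc_radius,cancer_radius Agent radii, µm (rendering footprint).
#' @param seed Integer seed for the single root generator; `NULL` leaves the
#'   RNG state alone.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_dcs = 100,
                       n_cancer_per_chamber = 30,
                       frame_interval = 2,
                       n_frames = 720,
                       speed_mean = 4,
                       speed_sd = 1.2,
                       persistence = 1,
                       bias_strength = 0,
                       bias_side = "right",
                       chemo_range = Inf,
                       cancer_jitter_sd = 0.3,
                       dc_radius = 7,
                       cancer_radius = 9,
                       seed = NULL) {
  stopifnot(speed_mean > 0, speed_sd >= 0, frame_interval > 0,
            bias_strength >= 0, bias_strength <= 1,
            persistence >= 0, n_frames >= 0, n_dcs >= 0,
            n_cancer_per_chamber >= 0, chemo_range > 0)
  bias_side <- match.arg(bias_side, c("left", "right", "none"))
  structure(as.list(environment()), class = "sim_config")
}

# truncated-at-zero normal draws via inverse CDF
rtnorm_pos <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

# mirror coordinates into [lo, hi]
reflect_into <- function(v, lo, hi) {
  v <- ifelse(v < lo, 2 * lo - v, v)
  v <- ifelse(v > hi, 2 * hi - v, v)
  pmin(pmax(v, lo), hi)
}

#' Simulate ground-truth trajectories inside a device layout
#'
#' DC agents start uniformly distributed in the immune chamber and move by a
#' confined biased persistent random walk (see [sim_config()]); they may
#' enter connecting channels through the channel openings and, through them,
#' the tumor chambers, but never the medium channels or the background.
#' Cancer agents are placed uniformly inside each tumor chamber and jitter
#' around their anchor without leaving it. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param layout A [device_layout()].
#' @return A tibble (long format, one row per agent per frame) with columns
#'   `agent_id`, `class` (`dc`/`cancer`), `frame` (0-based), `x_um`, `y_um`,
#'   carrying the config and layout as attributes `sim_config` and `layout`.
#' @export
simulate_tracks <- function(config, layout) {
  stopifnot(inherits(config, "sim_config"))
  validate_layout(layout)
  if (!is.null(config$seed)) set.seed(config$seed)

  nT <- config$n_frames
  empty <- tibble(agent_id = integer(), class = character(),
                  frame = integer(), x_um = numeric(), y_um = numeric())
  if (nT == 0 || (config$n_dcs == 0 && config$n_cancer_per_chamber == 0)) {
    return(structure(empty, sim_config = config, layout = layout))
  }

  r <- layout$rects
  imm <- r[r$region == "immune", ]
  dt <- config$frame_interval

  # region adjacency legal for DC transitions (by rect index pairs)
  dc_regions <- c("immune", "channel_left", "channel_right",
                  "tumor_left", "tumor_right")
  allowed_idx <- which(r$region %in% dc_regions)

  legal_move <- function(from_idx, to_idx) {
    # same rect always legal; immune<->channel and channel<->tumor legal
    ok <- from_idx == to_idx
    fr <- r$region[from_idx]; to <- r$region[to_idx]
    pair_ok <- (fr == "immune" & grepl("^channel", to)) |
      (grepl("^channel", fr) & to == "immune") |
      (fr == "channel_left" & to == "tumor_left") |
      (fr == "tumor_left" & to == "channel_left") |
      (fr == "channel_right" & to == "tumor_right") |
      (fr == "tumor_right" & to == "channel_right")
    ok | pair_ok
  }

  dc_out <- NULL
  if (config$n_dcs > 0) {
    n <- config$n_dcs
    pad <- min(config$dc_radius, (imm$x1 - imm$x0) / 4)
    x <- runif(n, imm$x0 + pad, imm$x1 - pad)
    y <- runif(n, imm$y0 + pad, imm$y1 - pad)
    heading <- runif(n, -pi, pi)
    cur_idx <- rect_index_at(layout, x, y)

    # drift geometry; drift ceases inside the target chamber (the cell has
    # reached the chemokine source region and resumes unbiased local motion)
    if (config$bias_side != "none" && config$bias_strength > 0) {
      tum <- r[r$region == paste0("tumor_", config$bias_side), ]
      target <- c((tum$x0 + tum$x1) / 2, (tum$y0 + tum$y1) / 2)
      entry_x <- if (config$bias_side == "left") imm$x0 else imm$x1
      target_idx <- which(r$region == paste0("tumor_", config$bias_side))
    }

    X <- matrix(NA_real_, nrow = nT, ncol = n)
    Y <- matrix(NA_real_, nrow = nT, ncol = n)
    X[1, ] <- x; Y[1, ] <- y
    turn_sd <- if (config$persistence > 0) 1 / sqrt(config$persistence) else NA

    for (t in seq_len(nT - 1)) {
      if (is.na(turn_sd)) {
        heading_p <- runif(n, -pi, pi)
      } else {
        heading_p <- heading + rnorm(n, 0, turn_sd)
      }
      dx <- cos(heading_p); dy <- sin(heading_p)
      if (config$bias_side != "none" && config$bias_strength > 0) {
        gx <- target[1] - x; gy <- target[2] - y
        gn <- sqrt(gx^2 + gy^2); gn[gn == 0] <- 1
        d_entry <- if (config$bias_side == "left") {
          pmax(0, x - entry_x)
        } else {
          pmax(0, entry_x - x)
        }
        w <- config$bias_strength *
          if (is.finite(config$chemo_range)) exp(-d_entry / config$chemo_range) else 1
        w <- w * (cur_idx != target_idx)
        dx <- (1 - w) * dx + w * gx / gn
        dy <- (1 - w) * dy + w * gy / gn
        dn <- sqrt(dx^2 + dy^2)
        zero <- dn < 1e-12
        dx[zero] <- cos(heading_p[zero]); dy[zero] <- sin(heading_p[zero])
        dn[zero] <- 1
        dx <- dx / dn; dy <- dy / dn
      }
      step <- rtnorm_pos(n, config$speed_mean * dt, config$speed_sd * dt)
      px <- x + step * dx
      py <- y + step * dy

      new_idx <- rect_index_at(layout, px, py)
      valid <- !is.na(new_idx) & new_idx %in% allowed_idx &
        legal_move(cur_idx, ifelse(is.na(new_idx), cur_idx, new_idx))
      # invalid proposals: reflect inside the current rectangle
      if (any(!valid)) {
        iv <- which(!valid)
        px[iv] <- reflect_into(px[iv], r$x0[cur_idx[iv]], r$x1[cur_idx[iv]])
        py[iv] <- reflect_into(py[iv], r$y0[cur_idx[iv]], r$y1[cur_idx[iv]])
        new_idx[iv] <- cur_idx[iv]
      }
      moved <- (px - x)^2 + (py - y)^2 > 1e-16
      heading[moved] <- atan2(py[moved] - y[moved], px[moved] - x[moved])
      x <- px; y <- py; cur_idx <- new_idx
      X[t + 1, ] <- x; Y[t + 1, ] <- y
    }
    dc_out <- tibble(
      agent_id = rep(seq_len(n), each = nT),
      class = "dc",
      frame = rep(0:(nT - 1), times = n),
      x_um = as.vector(X),
      y_um = as.vector(Y)
    )
  }

  ca_out <- NULL
  if (config$n_cancer_per_chamber > 0) {
    per <- config$n_cancer_per_chamber
    offs <- config$n_dcs
    chambers <- r[r$region %in% c("tumor_left", "tumor_right"), ]
    pieces <- lapply(seq_len(nrow(chambers)), function(ci) {
      ch <- chambers[ci, ]
      pad <- min(config$cancer_radius, (ch$x1 - ch$x0) / 4)
      ax <- runif(per, ch$x0 + pad, ch$x1 - pad)
      ay <- runif(per, ch$y0 + pad, ch$y1 - pad)
      jx <- matrix(rnorm(per * nT, 0, config$cancer_jitter_sd),
                   nrow = nT, ncol = per)
      jy <- matrix(rnorm(per * nT, 0, config$cancer_jitter_sd),
                   nrow = nT, ncol = per)
      X <- pmin(pmax(rep(ax, each = nT) + as.vector(jx), ch$x0), ch$x1 - 1e-9)
      Y <- pmin(pmax(rep(ay, each = nT) + as.vector(jy), ch$y0), ch$y1 - 1e-9)
      tibble(
        agent_id = offs + (ci - 1) * per + rep(seq_len(per), each = nT),
        class = "cancer",
        frame = rep(0:(nT - 1), times = per),
        x_um = X, y_um = Y
      )
    })
    ca_out <- dplyr::bind_rows(pieces)
  }

  out <- dplyr::bind_rows(dc_out, ca_out)
  structure(out, sim_config = config, layout = layout)
}

#' Temporally downsample ground-truth tracks
#'
#' Keeps every `factor`-th frame (starting at frame 0) and renumbers frames
#' consecutively, emulating acquisition at a coarser interval. The
#' `sim_config` attribute is updated so `frame_interval` reflects the new
#' spacing.
#'
#' @param tracks Output of [simulate_tracks()].
#' @param factor Integer >= 1.
#' @return Downsampled track tibble with the same columns.
#' @export
downsample_tracks <- function(tracks, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  keep <- tracks$frame %% factor == 0
  out <- tracks[keep, , drop = FALSE]
  out$frame <- out$frame %/% factor
  cfg <- attr(tracks, "sim_config")
  if (!is.null(cfg)) {
    cfg$frame_interval <- cfg$frame_interval * factor
    cfg$n_frames <- length(unique(out$frame))
  }
  structure(out, sim_config = cfg, layout = attr(tracks, "layout"))
}

#' Write / read ground-truth track tables
#'
#' Plain CSV with columns `agent_id`, `class`, `frame`, `x_um`, `y_um`;
#' lossless round trip with [read_truth()].
#'
#' @param tracks Track tibble from [simulate_tracks()].
#' @param path CSV file path.
#' @export
write_truth <- function(tracks, path) {
  utils::write.csv(
    as.data.frame(tracks)[, c("agent_id", "class", "frame", "x_um", "y_um")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(df)
}
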