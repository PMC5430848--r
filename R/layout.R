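#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif qnorm pnorm sd setNames
#' @importFrom utils head tail
#' @importFrom rlang .data
NULL

REGION_LEVELS <- c("immune", "channel_left", "channel_right",
                   "tumor_left", "tumor_right", "medium", "background")

#' Parametric layout of a two-sided microfluidic co-culture device
#'
#' Builds the 2D coordinate model of the device: a central immune chamber
#' connected through two mirrored arrays of narrow channels (microgrooves) to
#' a collagen tumor chamber on each side, with an external medium channel
#' beyond each tumor chamber. All physical dimensions are in micrometres;
#' image coordinates have the origin at the top-left corner, x increasing
#' rightward (the immune-to-tumor migration axis) and y downward.
#'
#' Default dimensions follow the reference device: connecting channels with a
#' 12 µm wide x 200 µm long footprint (10 µm high, the height being metadata
#' only since tracking is 2D), tumor chambers with a 500 x 1000 µm footprint
#' (150 µm deep), and a 1.2 mm wide immune chamber.
#'
#' Rectangles use the half-open convention `[x0, x1) x [y0, y1)`; boundary
#' points shared between the immune chamber (or a tumor chamber) and a
#' channel belong to the channel, so that channel entry and exit events are
#' scored deterministically.
#'
#' @param pixel_size Pixel calibration, µm per pixel (> 0).
#' @param image_extent Optional `c(height, width)` of the image in pixels.
#'   Defaults to the tight bounding box of the device at `pixel_size`.
#'   An extent too small to contain the device is an error.
#' @param n_channels_per_side Number of connecting channels on each side.
#'   May be 0 (disconnected chambers).
#' @param immune_width Width (x, µm) of the central immune chamber.
#' @param channel_width,channel_length Footprint (y width, x length, µm) of
#'   each connecting channel.
#' @param channel_height Channel height (z, µm); metadata only.
#' @param tumor_width,tumor_length Footprint (x, y, µm) of each tumor chamber.
#' @param tumor_depth Tumor chamber depth (z, µm); metadata only.
#' @param medium_width Width (x, µm) of each external medium channel.
#' @param margin Border (µm) between the chamber block and the image edge.
#'
#' @return An object of class `device_layout`: a list with `pixel_size`,
#'   `extent_px` (`c(height, width)`), a `rects` tibble (one row per
#'   rectangle: `name`, `region`, `side`, `x0`, `x1`, `y0`, `y1` in µm), and
#'   `meta` (out-of-plane dimensions).
#' @examples
#' lay <- device_layout(pixel_size = 2)
#' lay$rects
#' @export
device_layout <- function(pixel_size,
                          image_extent = NULL,
                          n_channels_per_side = 20,
                          immune_width = 1200,
                          channel_width = 12,
                          channel_length = 200,
                          channel_height = 10,
                          tumor_width = 500,
                          tumor_length = 1000,
                          tumor_depth = 150,
                          medium_width = 200,
                          margin = 100) {
  stopifnot(pixel_size > 0, n_channels_per_side >= 0,
            immune_width > 0, channel_width > 0, channel_length > 0,
            tumor_width > 0, tumor_length > 0, medium_width > 0,
            margin >= 0)

  # x bands, left to right
  x_medL <- 0
  x_tumL <- x_medL + medium_width
  x_chL  <- x_tumL + tumor_width
  x_imm  <- x_chL + channel_length
  x_chR  <- x_imm + immune_width
  x_tumR <- x_chR + channel_length
  x_medR <- x_tumR + tumor_width
  x_end  <- x_medR + medium_width

  y0 <- margin
  y1 <- margin + tumor_length
  height_um <- tumor_length + 2 * margin
  width_um <- x_end

  rect <- function(name, region, side, x0, x1, ry0 = y0, ry1 = y1) {
    tibble(name = name, region = region, side = side,
           x0 = x0, x1 = x1, y0 = ry0, y1 = ry1)
  }
  rects <- dplyr::bind_rows(
    rect("medium_left", "medium", "left", x_medL, x_tumL),
    rect("tumor_left", "tumor_left", "left", x_tumL, x_chL),
    rect("immune", "immune", "center", x_imm, x_chR),
    rect("tumor_right", "tumor_right", "right", x_tumR, x_medR),
    rect("medium_right", "medium", "right", x_medR, x_end)
  )
  if (n_channels_per_side > 0) {
    centers <- y0 + tumor_length * (seq_len(n_channels_per_side) - 0.5) /
      n_channels_per_side
    cl <- dplyr::bind_rows(lapply(seq_len(n_channels_per_side), function(i) {
      rect(sprintf("channel_left_%02d", i), "channel_left", "left",
           x_chL, x_imm, centers[i] - channel_width / 2,
           centers[i] + channel_width / 2)
    }))
    cr <- dplyr::bind_rows(lapply(seq_len(n_channels_per_side), function(i) {
      rect(sprintf("channel_right_%02d", i), "channel_right", "right",
           x_chR, x_tumR, centers[i] - channel_width / 2,
           centers[i] + channel_width / 2)
    }))
    rects <- dplyr::bind_rows(rects, cl, cr)
  }

  if (is.null(image_extent)) {
    image_extent <- c(ceiling(height_um / pixel_size),
                      ceiling(width_um / pixel_size))
  }
  layout <- structure(list(
    pixel_size = pixel_size,
    extent_px = as.integer(image_extent),
    rects = rects,
    meta = list(channel_height = channel_height, tumor_depth = tumor_depth,
                n_channels_per_side = n_channels_per_side,
                channel_length = channel_length, margin = margin)
  ), class = "device_layout")
  validate_layout(layout)
  layout
}

#' @export
print.device_layout <- function(x, ...) {
  cat(sprintf(
    "<device_layout> %d x %d px @ %.3g um/px; %d rectangles (%d channels/side)\n",
    x$extent_px[1], x$extent_px[2], x$pixel_size, nrow(x$rects),
    x$meta$n_channels_per_side))
  invisible(x)
}

validate_layout <- function(layout) {
  stopifnot(inherits(layout, "device_layout"))
  r <- layout$rects
  ext_um <- layout$extent_px * layout$pixel_size # (height, width)
  too_wide <- r$x1 > ext_um[2] + 1e-9
  too_tall <- r$y1 > ext_um[1] + 1e-9
  if (any(too_wide | too_tall)) {
    stop("image extent too small for rectangle(s): ",
         paste(r$name[too_wide | too_tall], collapse = ", "),
         call. = FALSE)
  }
  # pairwise non-overlap (open interiors)
  n <- nrow(r)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ox <- min(r$x1[i], r$x1[j]) - max(r$x0[i], r$x0[j])
    oy <- min(r$y1[i], r$y1[j]) - max(r$y0[i], r$y0[j])
    if (ox > 1e-9 && oy > 1e-9) {
      stop("overlapping rectangles: ", r$name[i], " / ", r$name[j],
           call. = FALSE)
    }
  }
  # each channel spans exactly the gap between immune chamber and its tumor
  ch <- r[grepl("^channel", r$region), , drop = FALSE]
  if (nrow(ch) > 0) {
    imm <- r[r$region == "immune", ]
    for (k in seq_len(nrow(ch))) {
      side <- ch$side[k]
      tum <- r[r$region == paste0("tumor_", side), ]
      ok <- if (side == "left") {
        isTRUE(all.equal(ch$x1[k], imm$x0)) && isTRUE(all.equal(ch$x0[k], tum$x1))
      } else {
        isTRUE(all.equal(ch$x0[k], imm$x1)) && isTRUE(all.equal(ch$x1[k], tum$x0))
      }
      if (!ok) stop("channel ", ch$name[k],
                    " does not bridge immune and tumor chambers", call. = FALSE)
    }
  }
  invisible(layout)
}

#' Rasterize a device layout into a per-pixel region map
#'
#' Paints every rectangle of the layout onto an integer label image using the
#' half-open pixel convention; channels are painted last so that boundary
#' pixels they share with the chambers are labelled as channel. Unpainted
#' pixels are `background`.
#'
#' @param layout A [device_layout()].
#' @return An object of class `region_map`: list with `labels` (H x W integer
#'   matrix indexing into `levels`), `levels` (region label strings), and the
#'   originating `layout`.
#' @examples
#' rm <- rasterize_regions(device_layout(pixel_size = 4))
#' table(rm$levels[rm$labels])
#' @export
rasterize_regions <- function(layout) {
  validate_layout(layout)
  h <- layout$extent_px[1]; w <- layout$extent_px[2]
  p <- layout$pixel_size
  labels <- matrix(match("background", REGION_LEVELS), nrow = h, ncol = w)
  r <- layout$rects
  # paint chambers first, channels last (they own shared boundary pixels)
  ord <- order(grepl("^channel", r$region))
  for (k in ord) {
    c0 <- max(0L, as.integer(round(r$x0[k] / p)))
    c1 <- min(w, as.integer(round(r$x1[k] / p)))
    r0 <- max(0L, as.integer(round(r$y0[k] / p)))
    r1 <- min(h, as.integer(round(r$y1[k] / p)))
    if (c1 > c0 && r1 > r0) {
      labels[(r0 + 1):r1, (c0 + 1):c1] <- match(r$region[k], REGION_LEVELS)
    }
  }
  structure(list(labels = labels, levels = REGION_LEVELS, layout = layout),
            class = "region_map")
}

#' Classify points into device regions
#'
#' Assigns each (x, y) position (µm, image coordinates) the label of the
#' unique rectangle containing it. Channels are checked first with closed x
#' intervals, so points on the shared immune/channel or channel/tumor edge
#' are labelled as channel; all other rectangles use the half-open
#' convention. Points inside the image extent but in no rectangle are
#' `background`; points outside the extent are an error.
#'
#' @param layout A [device_layout()].
#' @param x,y Numeric vectors of coordinates in µm.
#' @return Character vector of region labels (one of
#'   `immune`, `channel_left`, `channel_right`, `tumor_left`, `tumor_right`,
#'   `medium`, `background`).
#' @export
classify_point <- function(layout, x, y) {
  stopifnot(length(x) == length(y))
  ext_um <- layout$extent_px * layout$pixel_size
  if (any(x < 0 | x > ext_um[2] | y < 0 | y > ext_um[1], na.rm = TRUE)) {
    stop("point outside image extent", call. = FALSE)
  }
  out <- rep("background", length(x))
  r <- layout$rects
  is_ch <- grepl("^channel", r$region)
  for (k in which(is_ch)) {
    hit <- x >= r$x0[k] & x <= r$x1[k] & y >= r$y0[k] & y < r$y1[k]
    out[hit] <- r$region[k]
  }
  for (k in which(!is_ch)) {
    hit <- out == "background" &
      x >= r$x0[k] & x < r$x1[k] & y >= r$y0[k] & y < r$y1[k]
    out[hit] <- r$region[k]
  }
  out
}

#' Channel entry and exit boundaries for one side of the device
#'
#' Returns the two vertical line segments used to score migration events on
#' one side: the entry line where the immune chamber opens into the channel
#' array, and the exit (infiltration) line where the channels open into the
#' tumor chamber. The segments span the channel array.
#'
#' @param layout A [device_layout()].
#' @param side `"left"` or `"right"`.
#' @return A tibble with columns `boundary` (`entry`/`exit`), `x`, `y0`, `y1`
#'   (µm).
#' @export
crossing_boundaries <- function(layout, side = c("left", "right")) {
  side <- match.arg(side)
  ch <- layout$rects[layout$rects$region == paste0("channel_", side), ]
  if (nrow(ch) == 0) {
    stop("no connecting channels on side '", side, "'", call. = FALSE)
  }
  imm <- layout$rects[layout$rects$region == "immune", ]
  entry_x <- if (side == "left") imm$x0 else imm$x1
  exit_x <- if (side == "left") min(ch$x0) else max(ch$x1)
  tibble(boundary = c("entry", "exit"), x = c(entry_x, exit_x),
         y0 = min(ch$y0), y1 = max(ch$y1))
}

#' Read / write a device layout as a plain-text YAML config
#'
#' All lengths are µm; `pixel_size` is mandatory on read.
#'
#' @param layout A [device_layout()].
#' @param path File path.
#' @return `read_layout` returns a `device_layout`; `write_layout` returns
#'   `path` invisibly.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  obj <- list(
    pixel_size = layout$pixel_size,
    image_extent = as.integer(layout$extent_px),
    meta = layout$meta,
    rectangles = lapply(seq_len(nrow(layout$rects)), function(i) {
      as.list(layout$rects[i, ])
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$pixel_size)) stop("layout config lacks pixel_size",
                                    call. = FALSE)
  rects <- dplyr::bind_rows(lapply(obj$rectangles, as_tibble))
  layout <- structure(list(
    pixel_size = obj$pixel_size,
    extent_px = as.integer(obj$image_extent),
    rects = rects,
    meta = obj$meta
  ), class = "device_layout")
  validate_layout(layout)
  layout
}

# rectangle (by name) containing each point; NA_integer_ if none.
# closed intervals with a small tolerance: used by the simulator for
# confinement tests, not for region labelling.
rect_index_at <- function(layout, x, y, tol = 1e-9) {
  r <- layout$rects
  idx <- rep(NA_integer_, length(x))
  for (k in seq_len(nrow(r))) {
    hit <- is.na(idx) &
      x >= r$x0[k] - tol & x <= r$x1[k] + tol &
      y >= r$y0[k] - tol & y <= r$y1[k] + tol
    idx[hit] <- k
  }
  idx
}
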