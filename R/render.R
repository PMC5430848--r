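#' Frame stack container
#'
#' A calibrated multi-channel time-lapse stack: one `H x W x T` numeric array
#' per fluorescence channel, intensities in `[0, 1]`.
#'
#' @param channels Named list of `H x W x T` arrays; names are channel roles
#'   (`"dc"`, `"cancer"`).
#' @param pixel_size µm per pixel.
#' @param frame_interval Minutes between frames.
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(channels, pixel_size, frame_interval) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), pixel_size > 0, frame_interval > 0)
  dims <- lapply(channels, dim)
  stopifnot(all(vapply(dims, length, 1L) == 3))
  structure(list(channels = channels, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel_roles = names(channels)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<frame_stack> %d x %d px, %d frames, channels: %s; %.3g um/px, %.3g min/frame\n",
              d[1], d[2], d[3], paste(x$channel_roles, collapse = ", "),
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Noise model for synthetic rendering
#'
#' @param background Constant background offset (fraction of dynamic range).
#' @param gradient Peak-to-peak amplitude of a left-to-right linear
#'   background ramp.
#' @param blur_sigma Extra optical blur applied to the final image, px
#'   (0 = none; spots are already Gaussian).
#' @param shot_scale Photon scale for shot-like noise: pixel values are
#'   replaced by `rpois(value * shot_scale) / shot_scale` (larger = cleaner;
#'   `Inf` disables noise).
#' @return List of class `noise_model`.
#' @export
noise_model <- function(background = 0.05, gradient = 0.02,
                        blur_sigma = 0, shot_scale = 2000) {
  stopifnot(background >= 0, gradient >= 0, blur_sigma >= 0, shot_scale > 0)
  structure(list(background = background, gradient = gradient,
                 blur_sigma = blur_sigma, shot_scale = shot_scale),
            class = "noise_model")
}

# stamp a 2D Gaussian spot (amplitude amp, sd sigma_px) onto `img` at
# pixel-space center (cx, cy) (0-based, pixel centers at integer + 0.5)
stamp_spot <- function(img, cx, cy, sigma_px, amp) {
  h <- nrow(img); w <- ncol(img)
  half <- ceiling(4 * sigma_px)
  c0 <- max(1L, floor(cx - half) + 1L); c1 <- min(w, ceiling(cx + half) + 1L)
  r0 <- max(1L, floor(cy - half) + 1L); r1 <- min(h, ceiling(cy + half) + 1L)
  if (c0 > c1 || r0 > r1) return(img)
  xs <- (c0:c1) - 1 + 0.5
  ys <- (r0:r1) - 1 + 0.5
  gx <- exp(-((xs - cx)^2) / (2 * sigma_px^2))
  gy <- exp(-((ys - cy)^2) / (2 * sigma_px^2))
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amp * outer(gy, gx)
  img
}

#' Render ground-truth tracks into a noisy fluorescence-like frame stack
#'
#' Each agent is drawn as a 2D Gaussian spot (s.d. = 0.6 x agent radius) on
#' the channel of its class; a background offset, a left-to-right linear
#' gradient, optional extra blur and Poisson ("shot") noise are then applied
#' and the result clipped to `[0, 1]`.
#'
#' @param tracks Track tibble from [simulate_tracks()] (or the same schema).
#' @param layout A [device_layout()].
#' @param noise A [noise_model()].
#' @param amplitude Peak spot amplitude above background (per unit dynamic
#'   range). The spot SNR is `amplitude / sqrt(background / shot_scale)`.
#' @param frame_interval Minutes per frame; defaults to the `sim_config`
#'   attribute of `tracks` if present, else 2.
#' @param channels Which classes to render (default all present).
#' @return A [frame_stack()].
#' @export
render_stack <- function(tracks, layout, noise = noise_model(),
                         amplitude = 0.6, frame_interval = NULL,
                         channels = NULL) {
  validate_layout(layout)
  cfg <- attr(tracks, "sim_config")
  if (is.null(frame_interval)) {
    frame_interval <- if (!is.null(cfg)) cfg$frame_interval else 2
  }
  radii <- c(dc = if (!is.null(cfg)) cfg$dc_radius else 7,
             cancer = if (!is.null(cfg)) cfg$cancer_radius else 9)
  h <- layout$extent_px[1]; w <- layout$extent_px[2]
  p <- layout$pixel_size
  nT <- if (nrow(tracks) > 0) max(tracks$frame) + 1L else 1L
  if (is.null(channels)) {
    channels <- unique(tracks$class)
    if (length(channels) == 0) channels <- "dc"
  }

  bg <- matrix(noise$background, h, w) +
    noise$gradient * matrix(rep(seq(0, 1, length.out = w), each = h), h, w)

  out <- list()
  for (ch in channels) {
    sigma_px <- 0.6 * radii[[ch]] / p
    sub <- tracks[tracks$class == ch, , drop = FALSE]
    arr <- array(0, dim = c(h, w, nT))
    by_frame <- split(sub, sub$frame)
    for (t in seq_len(nT)) {
      img <- bg
      fr <- by_frame[[as.character(t - 1)]]
      if (!is.null(fr) && nrow(fr) > 0) {
        for (i in seq_len(nrow(fr))) {
          img <- stamp_spot(img, fr$x_um[i] / p, fr$y_um[i] / p,
                            sigma_px, amplitude)
        }
      }
      if (noise$blur_sigma > 0) {
        img <- EBImage::gblur(img, sigma = noise$blur_sigma)
      }
      if (is.finite(noise$shot_scale)) {
        img <- matrix(stats::rpois(length(img), pmax(img, 0) * noise$shot_scale),
                      h, w) / noise$shot_scale
      }
      arr[, , t] <- pmin(pmax(img, 0), 1)
    }
    out[[ch]] <- arr
  }
  frame_stack(out, pixel_size = p, frame_interval = frame_interval)
}

#' Write / read a frame stack as multi-page TIFF
#'
#' One 16-bit multi-page TIFF per channel, named `<prefix>_<role>.tif`. The
#' calibration travels in a YAML sidecar `<prefix>_stack.yml`.
#'
#' @param stack A [frame_stack()].
#' @param prefix Path prefix for the output files.
#' @return `write_stack` returns the sidecar path invisibly; `read_stack`
#'   returns a [frame_stack()].
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "frame_stack"))
  files <- list()
  for (ch in stack$channel_roles) {
    arr <- stack$channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(t) arr[, , t])
    f <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, f, bits.per.sample = 16)
    files[[ch]] <- basename(f)
  }
  side <- paste0(prefix, "_stack.yml")
  yaml::write_yaml(list(pixel_size = stack$pixel_size,
                        frame_interval = stack$frame_interval,
                        channels = files), side)
  invisible(side)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  side <- paste0(prefix, "_stack.yml")
  meta <- yaml::read_yaml(side)
  dir <- dirname(side)
  chans <- lapply(meta$channels, function(f) {
    pages <- tiff::readTIFF(file.path(dir, f), all = TRUE)
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  })
  frame_stack(chans, pixel_size = meta$pixel_size,
              frame_interval = meta$frame_interval)
}
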