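#' Detection parameters
#'
#' Controls the per-frame segmentation chain: Gaussian smoothing, Otsu (on
#' the masked histogram) or fixed thresholding, optional morphological
#' opening, connected components, area filtering, intensity-weighted
#' centroids. Defaults are sized for 10–15 µm cells imaged at 1–4 µm/px.
#'
#' @param threshold_mode `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold intensity when `threshold_mode="fixed"`.
#' @param smooth_sigma Gaussian smoothing s.d., px.
#' @param bg_sigma S.d. (px) of the large-scale Gaussian background estimate
#'   subtracted before thresholding; removes offsets and slow illumination
#'   gradients so the threshold separates spots from flat residual noise.
#'   0 disables subtraction. Should be several times the spot size.
#' @param noise_floor_k Robust floor on the automatic threshold: the Otsu
#'   threshold is never taken below `median + k x MAD` of the masked
#'   (background-subtracted) intensities. Otsu's between-class criterion
#'   collapses into the noise mode when spots occupy well under 1% of the
#'   histogram; the floor keeps the split above the noise. 0 disables the
#'   floor (pure Otsu).
#' @param min_area,max_area Component area bounds, µm².
#' @param opening_radius Disc radius (px) of morphological opening applied to
#'   the binary image; 0 disables it (recommended at coarse pixel sizes where
#'   cells are only a few pixels across).
#' @return List of class `detect_params`.
#' @export
detect_params <- function(threshold_mode = c("otsu", "fixed"),
                          fixed_threshold = NULL,
                          smooth_sigma = 1,
                          bg_sigma = 8,
                          noise_floor_k = 6,
                          min_area = 25,
                          max_area = 2000,
                          opening_radius = 0) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" && is.null(fixed_threshold)) {
    stop("fixed_threshold required when threshold_mode='fixed'", call. = FALSE)
  }
  stopifnot(smooth_sigma >= 0, bg_sigma >= 0, noise_floor_k >= 0,
            min_area >= 0, max_area > min_area, opening_radius >= 0)
  structure(list(threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold,
                 smooth_sigma = smooth_sigma, bg_sigma = bg_sigma,
                 noise_floor_k = noise_floor_k,
                 min_area = min_area, max_area = max_area,
                 opening_radius = opening_radius),
            class = "detect_params")
}

#' Analysis mask restricting detection to the device interior
#'
#' Background elimination: restricts all segmentation to the confined
#' culture regions of the device. `mode = "layout"` takes the union of the
#' immune chamber, connecting channels and tumor chambers from the
#' rasterized layout. `mode = "auto"` additionally requires temporal
#' intensity variance above `k` times the median in-device variance
#' (image-driven refinement); it falls back to the layout mask with a
#' warning when fewer than 3 frames are available.
#'
#' @param stack A [frame_stack()] (any one channel is used for variance).
#' @param layout A [device_layout()] sharing the stack's calibration.
#' @param mode `"layout"` or `"auto"`.
#' @param k Variance threshold multiplier for `mode = "auto"`.
#' @return Logical H x W matrix.
#' @export
background_mask <- function(stack, layout, mode = c("layout", "auto"), k = 2) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "frame_stack"))
  if (abs(stack$pixel_size - layout$pixel_size) > 1e-9) {
    stop("stack and layout pixel_size differ", call. = FALSE)
  }
  rm <- rasterize_regions(layout)
  lab <- rm$levels[rm$labels]
  base <- matrix(!(lab %in% c("background", "medium")),
                 nrow = nrow(rm$labels), ncol = ncol(rm$labels))
  if (mode == "layout") return(base)
  arr <- stack$channels[[1]]
  if (dim(arr)[3] < 3) {
    warning("auto background mask needs >= 3 frames; using layout mask")
    return(base)
  }
  m <- apply(arr, c(1, 2), mean)
  v <- apply(arr, c(1, 2), function(z) mean(z^2)) - m^2
  thr <- k * stats::median(v[base])
  (v > thr) & base
}

# Otsu threshold of a numeric vector (maximum between-class variance over a
# binned histogram); shift-invariant because bins follow the value range.
otsu_threshold <- function(values, nbins = 256) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(
    as.integer((values - rng[1]) / diff(rng) * nbins) + 1L, 1L), nbins),
    nbins)
  w <- h / sum(h)
  omega <- cumsum(w)
  mu <- cumsum(w * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  kstar <- which.max(sigma_b)
  rng[1] + kstar / nbins * diff(rng)
}

#' Segment one frame into cell detections
#'
#' Within the analysis mask: Gaussian smoothing, thresholding (Otsu on the
#' masked histogram by default), optional opening, connected components,
#' area filtering, and background-subtracted intensity-weighted centroids.
#' Components touching the mask border are kept and flagged.
#'
#' @param frame H x W intensity matrix.
#' @param mask Logical H x W analysis mask (see [background_mask()]).
#' @param params A [detect_params()].
#' @param pixel_size µm per pixel.
#' @param layout Optional [device_layout()]; when given, detections carry
#'   the region label of their centroid.
#' @return Tibble with columns `x_um`, `y_um`, `area_um2`, `mean_intensity`,
#'   `on_border`, and `region` (if `layout` given).
#' @export
segment_frame <- function(frame, mask, params = detect_params(),
                          pixel_size = 1, layout = NULL) {
  stopifnot(is.matrix(frame), identical(dim(frame), dim(mask)))
  if (!any(mask)) stop("empty analysis mask", call. = FALSE)
  empty <- tibble(x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
                  mean_intensity = numeric(), on_border = logical())
  sm <- if (params$smooth_sigma > 0) {
    EBImage::gblur(frame, sigma = params$smooth_sigma)
  } else frame
  # background subtraction needs the frame to be larger than the blur brush
  if (params$bg_sigma > 0 &&
      all(dim(frame) > 2 * ceiling(3 * params$bg_sigma) + 1)) {
    sm <- sm - EBImage::gblur(sm, sigma = params$bg_sigma)
  }
  vals <- sm[mask]
  if (length(vals) == 0 || diff(range(vals)) == 0) {
    return(if (is.null(layout)) empty else
      dplyr::mutate(empty, region = character()))
  }
  thr <- if (params$threshold_mode == "otsu") {
    th <- otsu_threshold(vals)
    if (params$noise_floor_k > 0) {
      th <- max(th, stats::median(vals) +
                  params$noise_floor_k * stats::mad(vals))
    }
    th
  } else params$fixed_threshold
  bin <- sm > thr & mask
  if (params$opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * params$opening_radius + 1, shape = "disc")
    bin <- EBImage::opening(bin * 1, brush) > 0.5
  }
  lab <- EBImage::bwlabel(bin * 1)
  nlab <- max(lab)
  if (nlab == 0) {
    return(if (is.null(layout)) empty else
      dplyr::mutate(empty, region = character()))
  }
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- (idx - 1) %% nrow(frame) + 1
  cols <- (idx - 1) %/% nrow(frame) + 1
  wgt <- pmax(sm[idx] - thr, 0) + 1e-12
  a <- tapply(rep(1, length(idx)), comp, sum)
  cx <- tapply(wgt * (cols - 0.5), comp, sum) / tapply(wgt, comp, sum)
  cy <- tapply(wgt * (rows - 0.5), comp, sum) / tapply(wgt, comp, sum)
  mi <- tapply(frame[idx], comp, mean)
  # border contact: component touches a pixel where the mask ends
  dil_border <- !mask
  touches <- tapply(seq_along(idx), comp, function(ii) {
    r <- rows[ii]; c <- cols[ii]
    any(r == 1 | r == nrow(frame) | c == 1 | c == ncol(frame) |
          dil_border[cbind(pmax(r - 1, 1), c)] |
          dil_border[cbind(pmin(r + 1, nrow(frame)), c)] |
          dil_border[cbind(r, pmax(c - 1, 1))] |
          dil_border[cbind(r, pmin(c + 1, ncol(frame)))])
  })
  out <- tibble(
    x_um = as.numeric(cx) * pixel_size,
    y_um = as.numeric(cy) * pixel_size,
    area_um2 = as.numeric(a) * pixel_size^2,
    mean_intensity = as.numeric(mi),
    on_border = as.logical(touches)
  )
  out <- out[out$area_um2 >= params$min_area & out$area_um2 <= params$max_area, ]
  if (!is.null(layout)) {
    out$region <- if (nrow(out)) classify_point(layout, out$x_um, out$y_um)
    else character()
  }
  out
}

#' Detect cells in every frame and channel of a stack
#'
#' Applies [segment_frame()] to each frame of each fluorescence channel,
#' concatenating the results with `frame` (0-based) and `class` (the
#' channel role) columns. Deterministic given its inputs.
#'
#' @param stack A [frame_stack()].
#' @param layout A [device_layout()].
#' @param params A [detect_params()] (or a named list of them per channel
#'   role).
#' @param mask_mode Passed to [background_mask()].
#' @return Detections tibble: `frame`, `class`, `x_um`, `y_um`, `area_um2`,
#'   `mean_intensity`, `on_border`, `region`.
#' @export
detect_stack <- function(stack, layout, params = detect_params(),
                         mask_mode = "layout") {
  stopifnot(inherits(stack, "frame_stack"))
  mask <- background_mask(stack, layout, mode = mask_mode)
  per_channel <- lapply(stack$channel_roles, function(ch) {
    arr <- stack$channels[[ch]]
    pp <- if (inherits(params, "detect_params")) params else params[[ch]]
    frames <- lapply(seq_len(dim(arr)[3]), function(t) {
      d <- segment_frame(arr[, , t], mask, pp,
                         pixel_size = stack$pixel_size, layout = layout)
      if (nrow(d)) {
        d$frame <- t - 1L
        d$class <- ch
      }
      d
    })
    dplyr::bind_rows(frames)
  })
  out <- dplyr::bind_rows(per_channel)
  if (nrow(out)) {
    dplyr::select(out, "frame", "class", dplyr::everything())
  } else {
    tibble(frame = integer(), class = character(), x_um = numeric(),
           y_um = numeric(), area_um2 = numeric(), mean_intensity = numeric(),
           on_border = logical(), region = character())
  }
}

#' Write / read detection tables
#'
#' @param detections Detections tibble from [detect_stack()].
#' @param path CSV path.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(as.data.frame(detections), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
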