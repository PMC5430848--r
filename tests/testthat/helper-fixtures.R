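# Shared fixtures and independent oracles used across the test files.

# Static, well-separated agents inside the analysable device regions
# (rejection sampling on a minimum spacing). Returns a ground-truth track
# tibble spanning `n_frames` static frames.
spaced_truth <- function(layout, n = 50, spacing = 20, n_frames = 2,
                         seed = 5, class = "dc") {
  set.seed(seed)
  rects <- layout$rects[layout$rects$region %in%
                          c("immune", "tumor_left", "tumor_right"), ]
  xs <- ys <- numeric(0)
  while (length(xs) < n) {
    k <- sample(nrow(rects), 1)
    x <- runif(1, rects$x0[k] + 15, rects$x1[k] - 15)
    y <- runif(1, rects$y0[k] + 15, rects$y1[k] - 15)
    if (!length(xs) || all(sqrt((xs - x)^2 + (ys - y)^2) > spacing)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  dplyr::bind_rows(lapply(seq_len(n_frames) - 1, function(f) {
    tibble::tibble(agent_id = seq_len(n), class = class, frame = f,
                   x_um = xs, y_um = ys)
  }))
}

# Greedy nearest matching of detections to ground truth within `tol` µm;
# returns recall, precision and the per-match distances (µm).
match_detections <- function(truth, det, tol = 10) {
  tp <- 0; fp <- 0; fn <- 0; err <- numeric(0)
  for (f in unique(truth$frame)) {
    tt <- truth[truth$frame == f, ]
    dd <- det[det$frame == f, ]
    if (nrow(dd) == 0) { fn <- fn + nrow(tt); next }
    D <- sqrt(outer(tt$x_um, dd$x_um, "-")^2 + outer(tt$y_um, dd$y_um, "-")^2)
    used <- rep(FALSE, nrow(dd))
    for (i in seq_len(nrow(tt))) {
      j <- which.min(ifelse(used, Inf, D[i, ]))
      if (length(j) && is.finite(D[i, j]) && D[i, j] <= tol) {
        tp <- tp + 1; used[j] <- TRUE; err <- c(err, D[i, j])
      } else fn <- fn + 1
    }
    fp <- fp + sum(!used)
  }
  list(recall = tp / (tp + fn), precision = tp / max(tp + fp, 1), err_um = err)
}

# Exhaustive minimum-cost partial matching between two frames: every
# injective partial matching within the gate, cost = sum of squared matched
# distances + gate^2 per unmatched detection. Independent of the LSAP path.
brute_force_link_cost <- function(d1, d2, gate) {
  lambda <- gate^2
  n1 <- nrow(d1); n2 <- nrow(d2)
  if (n1 == 0 || n2 == 0) return(lambda * (n1 + n2))
  D2 <- outer(d1$x_um, d2$x_um, "-")^2 + outer(d1$y_um, d2$y_um, "-")^2
  best <- Inf
  rec <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > n1) { best <<- min(best, cost + lambda * sum(!used)); return() }
    rec(i + 1, used, cost + lambda)
    for (j in which(!used)) {
      if (D2[i, j] <= lambda) {
        u <- used; u[j] <- TRUE
        rec(i + 1, u, cost + D2[i, j])
      }
    }
  }
  rec(1, rep(FALSE, n2), 0)
  best
}

# per-track summary applied over a long-format track table
per_track <- function(tracks, fun) {
  vapply(split(tracks, tracks$agent_id %||% tracks$track_id),
         fun, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
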