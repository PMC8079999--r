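#' Nadir camera model
#'
#' Pinhole geometry for a hovering nadir drone: ground sample distance =
#' footprint width / frame width, plus a parametric radial lens distortion
#' `x_d = c + (x - c) (1 + k1 r^2 + k2 r^4)` with `r` the radius from the
#' principal point normalized by the half-diagonal.
#'
#' @param footprint metres (width, height) seen on the water surface;
#'   default 166.1 x 94.5 m (100 m altitude).
#' @param frame_size pixels (width, height).
#' @param k1,k2 radial distortion coefficients (0 = ideal lens).
#' @param frame_rate Hz.
#' @param altitude_m metres (metadata).
#' @return A list of class `camera_model` with `gsd` (m/px) filled in.
#' @export
camera_model <- function(footprint = c(166.1, 94.5),
                         frame_size = c(1661, 945),
                         k1 = 0, k2 = 0, frame_rate = 30,
                         altitude_m = 100) {
  assert_positive(c(footprint, frame_size, frame_rate), "camera geometry")
  gsd <- footprint[1] / frame_size[1]
  structure(list(footprint = footprint, frame_size = frame_size,
                 k1 = k1, k2 = k2, frame_rate = frame_rate,
                 altitude_m = altitude_m, gsd = gsd),
            class = "camera_model")
}

#' Apply / invert radial lens distortion in pixel coordinates
#'
#' @param x,y pixel coordinates (columns, rows).
#' @param camera a [camera_model()].
#' @return A list with distorted (or undistorted) `x`, `y`.
#' @export
distort_points <- function(x, y, camera) {
  cx <- (camera$frame_size[1] + 1) / 2
  cy <- (camera$frame_size[2] + 1) / 2
  R2 <- (camera$frame_size[1]^2 + camera$frame_size[2]^2) / 4
  dx <- x - cx; dy <- y - cy
  r2 <- (dx^2 + dy^2) / R2
  f <- 1 + camera$k1 * r2 + camera$k2 * r2^2
  list(x = cx + dx * f, y = cy + dy * f)
}

#' @rdname distort_points
#' @export
undistort_points <- function(x, y, camera) {
  if (camera$k1 == 0 && camera$k2 == 0) return(list(x = x, y = y))
  cx <- (camera$frame_size[1] + 1) / 2
  cy <- (camera$frame_size[2] + 1) / 2
  R2 <- (camera$frame_size[1]^2 + camera$frame_size[2]^2) / 4
  dxu <- x - cx; dyu <- y - cy   # initial guess: undistorted = distorted
  dxd <- x - cx; dyd <- y - cy
  for (i in 1:30) {
    r2 <- (dxu^2 + dyu^2) / R2
    f <- 1 + camera$k1 * r2 + camera$k2 * r2^2
    dxu <- dxd / f; dyu <- dyd / f
  }
  list(x = cx + dxu, y = cy + dyu)
}

# Gaussian-smoothed white-noise texture, values in [0, 1]. A Gaussian
# kernel gives the texture a Gaussian autocorrelation, which is what the
# PIV three-point Gaussian sub-pixel estimator assumes; box smoothing
# would bias fractional displacements low.
make_texture <- function(h, w, sigma = 1.1) {
  tx <- matrix(rnorm(h * w), h, w)
  half <- max(2L, ceiling(3 * sigma))
  kern <- dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  pad_filter <- function(x, n) {
    as.numeric(stats::filter(c(rev(x[1:half]), x, rev(x[(n - half + 1):n])),
                             kern, sides = 2)[(half + 1):(half + n)])
  }
  tx <- t(apply(tx, 1, pad_filter, n = w))
  tx <- apply(tx, 2, pad_filter, n = h)
  tx <- (tx - min(tx)) / (max(tx) - min(tx))
  tx
}

# bilinear sample of matrix M at fractional (row, col), with wrap-around
bilinear_wrap <- function(M, r, cc) {
  h <- nrow(M); w <- ncol(M)
  r <- (r - 1) %% h + 1
  cc <- (cc - 1) %% w + 1
  r0 <- floor(r); c0 <- floor(cc)
  fr <- r - r0; fc <- cc - c0
  r1 <- r0 %% h + 1; c1 <- c0 %% w + 1
  r0 <- (r0 - 1) %% h + 1; c0 <- (c0 - 1) %% w + 1
  M[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    M[cbind(r1, c0)] * fr * (1 - fc) +
    M[cbind(r0, c1)] * (1 - fr) * fc +
    M[cbind(r1, c1)] * fr * fc
}

# Catmull-Rom (cubic convolution) resampling with wrap-around; much lower
# high-frequency attenuation than bilinear, keeping frame-to-frame texture
# displacements unbiased for PIV
cubic_wrap <- function(M, r, cc) {
  h <- nrow(M); w <- ncol(M)
  r <- (r - 1) %% h + 1
  cc <- (cc - 1) %% w + 1
  r0 <- floor(r); c0 <- floor(cc)
  fr <- r - r0; fc <- cc - c0
  wcat <- function(f) {
    # Catmull-Rom weights for taps at offsets -1, 0, 1, 2
    f2 <- f * f; f3 <- f2 * f
    cbind(-0.5 * f3 + f2 - 0.5 * f,
          1.5 * f3 - 2.5 * f2 + 1,
          -1.5 * f3 + 2 * f2 + 0.5 * f,
          0.5 * f3 - 0.5 * f2)
  }
  wr <- wcat(fr); wc <- wcat(fc)
  out <- numeric(length(r))
  for (i in 0:3) {
    ri <- (r0 + i - 2) %% h + 1
    acc <- numeric(length(r))
    for (j in 0:3) {
      cj <- (c0 + j - 2) %% w + 1
      acc <- acc + wc[, j + 1] * M[cbind(ri, cj)]
    }
    out <- out + wr[, i + 1] * acc
  }
  out
}

disk_offsets <- function(radius) {
  d <- expand.grid(dr = -ceiling(radius):ceiling(radius),
                   dc = -ceiling(radius):ceiling(radius))
  d[d$dr^2 + d$dc^2 <= radius^2, ]
}

stamp_disk <- function(M, row, col, radius, value) {
  off <- disk_offsets(radius)
  rr <- round(row) + off$dr
  cc <- round(col) + off$dc
  ok <- rr >= 1 & rr <= nrow(M) & cc >= 1 & cc <= ncol(M)
  M[cbind(rr[ok], cc[ok])] <- value
  M
}

#' Render synthetic drone video frames
#'
#' The green channel carries a persistent random surface texture advected
#' semi-Lagrangianly by the simulated flow (so PIV can recover the flow);
#' the red channel carries bird blobs at the projected track positions plus
#' optional sun-glint speckles (area below the downstream size filter) and
#' large foam patches (area above it) as distractors.
#'
#' @param flow a `ground_truth_flow` (or a [flow_stack()]) covering the
#'   camera footprint.
#' @param tracks track tibble (`track_id`, `t`, `x`, `y`, metres), or
#'   `NULL` for bird-free frames.
#' @param camera a [camera_model()].
#' @param duration seconds to render (default: flow duration).
#' @param bird_radius_px disk radius of a rendered bird (default 3.2 px,
#'   area about 32 px^2).
#' @param n_glint expected glint speckles per frame (radius ~1 px).
#' @param n_foam number of persistent foam patches (radius 15 px).
#' @param seed integer seed for texture, glints and foam.
#' @return A list of class `frame_sequence`: `frames` (list of
#'   `[h, w, 3]` arrays in `[0, 1]`), `times` (s), `camera`.
#' @export
render_video <- function(flow, tracks, camera, duration = NULL,
                         bird_radius_px = 3.2, n_glint = 0, n_foam = 0,
                         seed = 1L) {
  stack <- if (inherits(flow, "ground_truth_flow")) flow$flow else flow
  stopifnot(inherits(stack, "flow_stack"), inherits(camera, "camera_model"))
  if (max(stack$x) < camera$footprint[1] - 1e-6 ||
      max(stack$y) < camera$footprint[2] - 1e-6) {
    stop("camera footprint extends beyond the simulated flow domain",
         call. = FALSE)
  }
  set.seed(substream_seed(seed, "video"))
  w <- camera$frame_size[1]; h <- camera$frame_size[2]
  gsd <- camera$gsd
  duration <- duration %||% max(stack$t)
  nfr <- floor(duration * camera$frame_rate) + 1
  dt <- 1 / camera$frame_rate
  # pixel-centre metric coordinates (row 1 = top of image = max y)
  col_x <- ((1:w) - 0.5) * gsd
  row_y <- (h - (1:h) + 0.5) * gsd
  Xq <- matrix(col_x, h, w, byrow = TRUE)
  Yq <- matrix(row_y, h, w)
  tx <- make_texture(h, w)
  foam <- if (n_foam > 0) {
    data.frame(x = runif(n_foam, 0.1, 0.9) * camera$footprint[1],
               y = runif(n_foam, 0.1, 0.9) * camera$footprint[2])
  } else NULL
  frames <- vector("list", nfr)
  times <- (seq_len(nfr) - 1) * dt
  adv_u <- mean(stack$u, na.rm = TRUE)  # foam rides the mean current
  # texture is advected by accumulating a per-pixel displacement and
  # resampling the ORIGINAL texture once per frame (no progressive blur);
  # the pixel-grid velocity is cached per flow snapshot and interpolated
  # linearly in time between the two bracketing snapshots
  tx0 <- tx
  Drow <- matrix(0, h, w); Dcol <- matrix(0, h, w)
  base_rows <- matrix(1:h, h, w); base_cols <- matrix(1:w, h, w, byrow = TRUE)
  snap_cache <- list(idx = c(NA, NA), u = list(), v = list())
  snap_field <- function(k) {
    key <- as.character(k)
    if (is.null(snap_cache$u[[key]])) {
      tq <- stack$t[k]
      uu <- interpolate_field(stack, as.vector(Xq), as.vector(Yq),
                              rep(tq, length(Xq)), "u")
      vv <- interpolate_field(stack, as.vector(Xq), as.vector(Yq),
                              rep(tq, length(Xq)), "v")
      uu[is.na(uu)] <- 0; vv[is.na(vv)] <- 0
      snap_cache$u[[key]] <<- matrix(uu, h, w)
      snap_cache$v[[key]] <<- matrix(vv, h, w)
    }
    list(u = snap_cache$u[[key]], v = snap_cache$v[[key]])
  }
  for (i in seq_len(nfr)) {
    t <- times[i]
    if (i > 1) {
      tq <- min(max(t, min(stack$t)), max(stack$t))
      k <- findInterval(tq, stack$t, rightmost.closed = TRUE)
      k <- min(max(k, 1L), max(length(stack$t) - 1L, 1L))
      f0 <- snap_field(k)
      f1 <- if (length(stack$t) > 1) snap_field(k + 1L) else f0
      wgt <- if (length(stack$t) > 1) {
        (tq - stack$t[k]) / (stack$t[k + 1L] - stack$t[k])
      } else 0
      # drop cached snapshots that are now behind us
      old_keys <- setdiff(names(snap_cache$u), as.character(c(k, k + 1L)))
      for (ok in old_keys) {
        snap_cache$u[[ok]] <- NULL; snap_cache$v[[ok]] <- NULL
      }
      uu <- (1 - wgt) * f0$u + wgt * f1$u
      vv <- (1 - wgt) * f0$v + wgt * f1$v
      Dcol <- Dcol + uu * dt / gsd
      Drow <- Drow + vv * dt / gsd   # +v (up) = decreasing row
      tx <- matrix(cubic_wrap(tx0, as.vector(base_rows + Drow),
                              as.vector(base_cols - Dcol)),
                   h, w)
    }
    red <- matrix(0.1, h, w)
    if (!is.null(foam)) {
      for (j in seq_len(nrow(foam))) {
        fx <- (foam$x[j] + adv_u * t) %% camera$footprint[1]
        red <- stamp_disk(red, h - fx_row(foam$y[j], gsd), fx / gsd + 0.5,
                          15, 0.6)
      }
    }
    if (n_glint > 0) {
      ng <- rpois(1, n_glint)
      if (ng > 0) {
        gr <- runif(ng, 1, h); gc <- runif(ng, 1, w)
        for (j in seq_len(ng)) red <- stamp_disk(red, gr[j], gc[j], 1.2, 0.9)
      }
    }
    if (!is.null(tracks) && nrow(tracks) > 0) {
      for (id in unique(tracks$track_id)) {
        tr <- tracks[tracks$track_id == id, ]
        if (t < min(tr$t) - 1e-9 || t > max(tr$t) + 1e-9) next
        bx <- approx(tr$t, tr$x, xout = t)$y
        by <- approx(tr$t, tr$y, xout = t)$y
        px <- bx / gsd + 0.5
        py <- h - by / gsd + 0.5
        dpt <- distort_points(px, py, camera)
        red <- stamp_disk(red, dpt$y, dpt$x, bird_radius_px, 1.0)
      }
    }
    fr <- array(0, c(h, w, 3))
    fr[, , 1] <- pmin(red, 1)
    fr[, , 2] <- tx
    fr[, , 3] <- 0.3 + 0.2 * tx
    frames[[i]] <- fr
  }
  structure(list(frames = frames, times = times, camera = camera),
            class = "frame_sequence")
}

fx_row <- function(y_m, gsd) y_m / gsd - 0.5

#' Extract one channel of a frame sequence as a list of matrices
#'
#' @param video a `frame_sequence`.
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @return List of numeric matrices.
#' @export
frames_channel <- function(video, channel = c("green", "red", "blue")) {
  channel <- match.arg(channel)
  k <- match(channel, c("red", "green", "blue"))
  lapply(video$frames, function(f) f[, , k])
}
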