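#' Detection configuration
#'
#' @param channel frame channel differenced for moving targets (`"red"`:
#'   birds stand out against the water there).
#' @param threshold binarization threshold for the absolute difference
#'   image; `"otsu"` (default) picks it per frame pair, or give a number.
#' @param morph_radius disk radius for the dilation-then-erosion cleanup.
#' @param min_area,max_area retained component area bounds in px^2
#'   (speckles below, foam patches above, are discarded).
#' @return A list of class `detect_config`.
#' @export
detect_config <- function(channel = "red", threshold = "otsu",
                          morph_radius = 9, min_area = 20, max_area = 500) {
  stopifnot(min_area <= max_area, morph_radius >= 1)
  structure(as.list(environment()), class = "detect_config")
}

need_ebimage <- function() {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("EBImage is required for detection morphology", call. = FALSE)
  }
}

#' Detect moving targets by frame differencing
#'
#' Absolute frame-to-frame difference of the chosen channel, binarized,
#' cleaned by dilation then erosion with a disk structuring element, then
#' connected components; components outside the configured area band are
#' discarded. Component shape/intensity features are returned for the
#' classifier.
#'
#' @param video a `frame_sequence` from [render_video()], or a list of
#'   single-channel matrices.
#' @param config a [detect_config()].
#' @return Tibble: `frame`, `t`, `x_px`, `y_px` (image coordinates,
#'   row-down), `area`, `eccentricity`, `intensity`, `label`
#'   (`"unknown"`).
#' @export
detect_targets <- function(video, config = detect_config()) {
  need_ebimage()
  if (inherits(video, "frame_sequence")) {
    frames <- frames_channel(video, config$channel)
    times <- video$times
  } else {
    frames <- video
    times <- seq_along(frames) - 1
  }
  stopifnot(length(frames) >= 2)
  brush <- EBImage::makeBrush(2 * config$morph_radius + 1, shape = "disc")
  out <- vector("list", length(frames) - 1)
  for (i in seq_len(length(frames) - 1)) {
    D <- abs(frames[[i + 1]] - frames[[i]])
    thr <- if (identical(config$threshold, "otsu")) {
      if (max(D) <= 0) 1 else EBImage::otsu(EBImage::Image(D / max(D))) * max(D)
    } else config$threshold
    mask <- D > thr
    if (!any(mask)) next
    img <- EBImage::Image(mask * 1)
    img <- EBImage::erode(EBImage::dilate(img, brush), brush)
    lab <- EBImage::bwlabel(img)
    nlab <- max(lab)
    if (nlab == 0) next
    labv <- as.integer(EBImage::imageData(lab))
    keep <- labv > 0
    idx <- which(keep)
    rc <- arrayInd(idx, dim(D))
    comp <- labv[keep]
    area <- tabulate(comp, nlab)
    # centroid and second moments per component
    mr <- tapply(rc[, 1], comp, mean)
    mc <- tapply(rc[, 2], comp, mean)
    vr <- tapply(rc[, 1], comp, var)
    vc <- tapply(rc[, 2], comp, var)
    vr[is.na(vr)] <- 0; vc[is.na(vc)] <- 0
    ecc <- pmin(vr, vc) / pmax(pmax(vr, vc), 1e-9)
    inten <- tapply(frames[[i + 1]][idx], comp, mean)
    ok <- area >= config$min_area & area <= config$max_area
    if (!any(ok)) next
    out[[i]] <- tibble::tibble(
      frame = i + 1L, t = times[i + 1],
      x_px = as.numeric(mc[ok]), y_px = as.numeric(mr[ok]),
      area = as.numeric(area[ok]),
      eccentricity = as.numeric(ecc[ok]),
      intensity = as.numeric(inten[ok]),
      label = "unknown")
  }
  empty <- tibble::tibble(frame = integer(0), t = numeric(0),
                          x_px = numeric(0), y_px = numeric(0),
                          area = numeric(0), eccentricity = numeric(0),
                          intensity = numeric(0), label = character(0))
  dplyr::bind_rows(c(list(empty), out))
}

#' Train the pluggable blob classifier
#'
#' A simple logistic model on shape and intensity features, standing in
#' for heavier image classifiers; any object with a `predict` method
#' returning bird probabilities can replace it.
#'
#' @param detections tibble of detections with `area`, `eccentricity`,
#'   `intensity` and a `label` column containing `"bird"` and non-bird
#'   labels.
#' @return An object of class `blob_classifier`.
#' @export
train_blob_classifier <- function(detections) {
  stopifnot(all(c("area", "eccentricity", "intensity", "label") %in%
                  names(detections)))
  df <- data.frame(y = as.integer(detections$label == "bird"),
                   area = detections$area,
                   eccentricity = detections$eccentricity,
                   intensity = detections$intensity)
  # perfect separation is common (and harmless) on cleanly simulated
  # patches; the fitted direction is all the classifier needs
  m <- suppressWarnings(
    stats::glm(y ~ area + eccentricity + intensity, data = df,
               family = stats::binomial()))
  structure(list(model = m), class = "blob_classifier")
}

#' Label detections with a trained classifier
#'
#' Only bird-labelled detections proceed to tracking.
#'
#' @param detections detection tibble from [detect_targets()].
#' @param classifier a `blob_classifier` (or `NULL` to keep all detections
#'   labelled `"bird"`, for fully synthetic scenes without distractors).
#' @param threshold bird-probability cut (default 0.5).
#' @return The detections with `label` set to `"bird"` or `"clutter"`.
#' @export
classify_detections <- function(detections, classifier, threshold = 0.5) {
  if (nrow(detections) == 0) return(detections)
  if (is.null(classifier)) {
    detections$label <- "bird"
    return(detections)
  }
  if (!inherits(classifier, "blob_classifier")) {
    stop("classifier must be a trained blob_classifier", call. = FALSE)
  }
  pr <- stats::predict(classifier$model,
                       newdata = data.frame(
                         area = detections$area,
                         eccentricity = detections$eccentricity,
                         intensity = detections$intensity),
                       type = "response")
  detections$label <- ifelse(pr >= threshold, "bird", "clutter")
  detections
}

#' Tracker configuration
#'
#' @param rate frame rate, Hz.
#' @param process_noise accel-noise intensity of the constant-velocity
#'   model (px/s^2).
#' @param meas_noise measurement noise sd (px).
#' @param gate Mahalanobis-squared gate for assignment (chi-squared 2 df).
#' @param gap_limit maximum consecutive missed frames filled by prediction.
#' @param splice_max_gap maximum frame gap bridged when splicing
#'   fragments.
#' @param splice_gate_px positional tolerance for splicing (px).
#' @param min_length minimum number of points for a reported track.
#' @return A list of class `track_config`.
#' @export
track_config <- function(rate = 30, process_noise = 200, meas_noise = 1,
                         gate = 13, gap_limit = 5, splice_max_gap = 10,
                         splice_gate_px = 12, min_length = 5) {
  structure(as.list(environment()), class = "track_config")
}

kf_new <- function(x, y, config) {
  list(state = c(x, y, 0, 0),
       P = diag(c(config$meas_noise^2, config$meas_noise^2, 400, 400)),
       miss = 0L)
}

kf_matrices <- function(dt, config) {
  F <- diag(4); F[1, 3] <- dt; F[2, 4] <- dt
  q <- config$process_noise^2
  Q <- q * diag(c(dt^4 / 4, dt^4 / 4, dt^2, dt^2))
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  R <- diag(config$meas_noise^2, 2)
  list(F = F, Q = Q, H = H, R = R)
}

kf_predict <- function(kf, m) {
  kf$state <- as.vector(m$F %*% kf$state)
  kf$P <- m$F %*% kf$P %*% t(m$F) + m$Q
  kf
}

kf_update <- function(kf, z, m) {
  S <- m$H %*% kf$P %*% t(m$H) + m$R
  K <- kf$P %*% t(m$H) %*% solve(S)
  innov <- z - as.vector(m$H %*% kf$state)
  kf$state <- kf$state + as.vector(K %*% innov)
  kf$P <- (diag(4) - K %*% m$H) %*% kf$P
  kf
}

kf_maha2 <- function(kf, z, m) {
  S <- m$H %*% kf$P %*% t(m$H) + m$R
  innov <- z - as.vector(m$H %*% kf$state)
  as.numeric(t(innov) %*% solve(S) %*% innov)
}

#' Compile tracks from bird detections with Kalman filters
#'
#' Constant-velocity Kalman filters with Mahalanobis-gated greedy
#' nearest-neighbour assignment; misses up to `gap_limit` frames are
#' bridged by prediction and flagged `gap_filled`; fragments whose
#' extrapolated and observed states agree within the splice gates are
#' joined automatically.
#'
#' @param detections bird-labelled detections (from
#'   [classify_detections()]); rows with other labels are ignored.
#' @param config a [track_config()].
#' @return Tibble: `track_id`, `frame`, `t`, `x_px`, `y_px`,
#'   `provenance` (`"detected"` / `"gap_filled"` / `"spliced"`).
#' @export
track_targets <- function(detections, config = track_config()) {
  det <- detections[detections$label %in% c("bird", "unknown"), ,
                    drop = FALSE]
  empty <- tibble::tibble(track_id = integer(0), frame = integer(0),
                          t = numeric(0), x_px = numeric(0),
                          y_px = numeric(0), provenance = character(0))
  if (nrow(det) == 0) return(empty)
  dt <- 1 / config$rate
  m <- kf_matrices(dt, config)
  frames <- sort(unique(det$frame))
  active <- list()     # each: kf, id, points (list)
  done <- list()
  next_id <- 1L
  for (f in seq(min(frames), max(frames))) {
    dets_f <- det[det$frame == f, , drop = FALSE]
    # predict
    active <- lapply(active, function(tr) { tr$kf <- kf_predict(tr$kf, m); tr })
    assigned_det <- rep(FALSE, nrow(dets_f))
    if (length(active) && nrow(dets_f)) {
      cost <- matrix(Inf, length(active), nrow(dets_f))
      for (i in seq_along(active)) {
        for (j in seq_len(nrow(dets_f))) {
          cost[i, j] <- kf_maha2(active[[i]]$kf,
                                 c(dets_f$x_px[j], dets_f$y_px[j]), m)
        }
      }
      matched_tr <- rep(FALSE, length(active))
      repeat {
        best <- which.min(cost)
        if (!length(best) || !is.finite(cost[best])) break
        ij <- arrayInd(best, dim(cost))
        i <- ij[1]; j <- ij[2]
        if (cost[i, j] > config$gate) break
        z <- c(dets_f$x_px[j], dets_f$y_px[j])
        active[[i]]$kf <- kf_update(active[[i]]$kf, z, m)
        active[[i]]$kf$miss <- 0L
        active[[i]]$points[[length(active[[i]]$points) + 1]] <-
          list(frame = f, x = z[1], y = z[2], prov = "detected")
        matched_tr[i] <- TRUE; assigned_det[j] <- TRUE
        cost[i, ] <- Inf; cost[, j] <- Inf
      }
      # unmatched active tracks coast
      for (i in which(!matched_tr)) {
        active[[i]]$kf$miss <- active[[i]]$kf$miss + 1L
        active[[i]]$points[[length(active[[i]]$points) + 1]] <-
          list(frame = f, x = active[[i]]$kf$state[1],
               y = active[[i]]$kf$state[2], prov = "gap_filled")
      }
    } else if (length(active)) {
      for (i in seq_along(active)) {
        active[[i]]$kf$miss <- active[[i]]$kf$miss + 1L
        active[[i]]$points[[length(active[[i]]$points) + 1]] <-
          list(frame = f, x = active[[i]]$kf$state[1],
               y = active[[i]]$kf$state[2], prov = "gap_filled")
      }
    }
    # retire tracks that exceeded the gap limit
    keep <- vapply(active, function(tr) tr$kf$miss <= config$gap_limit,
                   logical(1))
    done <- c(done, active[!keep])
    active <- active[keep]
    # births
    for (j in which(!assigned_det)) {
      kf <- kf_new(dets_f$x_px[j], dets_f$y_px[j], config)
      active[[length(active) + 1]] <- list(
        kf = kf, id = next_id,
        points = list(list(frame = f, x = dets_f$x_px[j],
                           y = dets_f$y_px[j], prov = "detected")))
      next_id <- next_id + 1L
    }
  }
  done <- c(done, active)
  tracks <- lapply(done, function(tr) {
    pts <- dplyr::bind_rows(lapply(tr$points, tibble::as_tibble))
    # trim trailing coasted points (never confirmed by a detection)
    last_det <- max(which(pts$prov == "detected"))
    pts <- pts[seq_len(last_det), , drop = FALSE]
    pts$track_id <- tr$id
    pts
  })
  tracks <- dplyr::bind_rows(tracks)
  if (nrow(tracks) == 0) return(empty)
  tracks <- splice_fragments(tracks, config)
  tracks <- tracks %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::filter(dplyr::n() >= config$min_length) %>%
    dplyr::ungroup()
  tibble::tibble(
    track_id = match(tracks$track_id, unique(tracks$track_id)),
    frame = as.integer(tracks$frame),
    t = (tracks$frame - 1) / config$rate,
    x_px = tracks$x, y_px = tracks$y,
    provenance = tracks$prov)
}

# join fragments whose extrapolation meets the next fragment's start
splice_fragments <- function(tracks, config) {
  repeat {
    ids <- unique(tracks$track_id)
    if (length(ids) < 2) return(tracks)
    info <- lapply(ids, function(id) {
      tr <- tracks[tracks$track_id == id, ]
      tr <- tr[order(tr$frame), ]
      n <- nrow(tr)
      vx <- if (n >= 3) (tr$x[n] - tr$x[n - 2]) / 2 else 0
      vy <- if (n >= 3) (tr$y[n] - tr$y[n - 2]) / 2 else 0
      list(id = id, f0 = tr$frame[1], f1 = tr$frame[n],
           x0 = tr$x[1], y0 = tr$y[1], x1 = tr$x[n], y1 = tr$y[n],
           vx = vx, vy = vy)
    })
    joined <- FALSE
    for (a in info) {
      for (b in info) {
        gap <- b$f0 - a$f1
        if (a$id == b$id || gap <= 0 || gap > config$splice_max_gap) next
        px <- a$x1 + a$vx * gap
        py <- a$y1 + a$vy * gap
        if (sqrt((px - b$x0)^2 + (py - b$y0)^2) <= config$splice_gate_px) {
          # linear fill across the gap, flagged
          if (gap > 1) {
            ff <- (a$f1 + 1):(b$f0 - 1)
            w <- (ff - a$f1) / gap
            fill <- tibble::tibble(frame = ff,
                                   x = a$x1 + w * (b$x0 - a$x1),
                                   y = a$y1 + w * (b$y0 - a$y1),
                                   prov = "gap_filled", track_id = a$id)
            tracks <- dplyr::bind_rows(tracks, fill)
          }
          tracks$prov[tracks$track_id == b$id & tracks$frame == b$f0] <-
            "spliced"
          tracks$track_id[tracks$track_id == b$id] <- a$id
          joined <- TRUE
          break
        }
      }
      if (joined) break
    }
    if (!joined) return(tracks)
  }
}

#' Undistort and metre-scale pixel tracks
#'
#' @param tracks tibble with `x_px`, `y_px` (image coordinates, row-down).
#' @param camera a [camera_model()].
#' @return The tracks with `x`, `y` in metres (y increasing up).
#' @export
geo_correct <- function(tracks, camera) {
  if (!inherits(camera, "camera_model")) {
    stop("a camera_model is required", call. = FALSE)
  }
  und <- undistort_points(tracks$x_px, tracks$y_px, camera)
  tracks$x <- (und$x - 0.5) * camera$gsd
  tracks$y <- (camera$frame_size[2] - und$y + 0.5) * camera$gsd
  tracks
}

#' Overall track tortuosity (path length / chord)
#'
#' @param x,y coordinate vectors.
#' @return Tortuosity; `Inf` when the chord is zero (closed loop).
#' @export
overall_tortuosity <- function(x, y) {
  path <- sum(sqrt(diff(x)^2 + diff(y)^2))
  chord <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  if (chord == 0) return(Inf)
  path / chord
}

#' Retain foraging tracks: long enough and tortuous enough
#'
#' Tracks shorter than `min_duration` seconds, or with overall tortuosity
#' below `min_tortuosity` ("transiting" birds), are removed. Closed loops
#' (zero chord) have infinite tortuosity and are retained.
#'
#' @param tracks tibble with `track_id`, `t`, `x`, `y`.
#' @param min_duration seconds (default 15).
#' @param min_tortuosity unitless (default 1.1).
#' @return The retained subset, same schema.
#' @export
filter_tracks <- function(tracks, min_duration = 15, min_tortuosity = 1.1) {
  tracks %>%
    dplyr::arrange(.data$track_id, .data$t) %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::filter(max(.data$t) - min(.data$t) >= min_duration,
                  overall_tortuosity(.data$x, .data$y) >= min_tortuosity) %>%
    dplyr::ungroup()
}
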