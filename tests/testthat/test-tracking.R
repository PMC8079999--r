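# synthetic single-channel scenes: background 0.1, moving bright disks
blob_frames <- function(n_frames, path_fn, radius = 3.2, h = 120, w = 160,
                        extra = NULL) {
  lapply(seq_len(n_frames), function(i) {
    fr <- matrix(0.1, h, w)
    p <- path_fn(i)
    if (!is.null(p)) {
      fr <- ternflow:::stamp_disk(fr, p[2], p[1], radius, 1)
    }
    if (!is.null(extra)) fr <- extra(fr, i)
    fr
  })
}

test_that("a static scene yields zero detections", {
  frames <- blob_frames(5, function(i) c(80, 60))  # blob never moves
  det <- detect_targets(frames, detect_config(threshold = 0.05))
  expect_equal(nrow(det), 0)
})

test_that("a moving blob is detected with a centroid within 1 px", {
  frames <- blob_frames(6, function(i) c(20 + 6 * i, 40 + 3 * i))
  det <- detect_targets(frames, detect_config(threshold = 0.05))
  expect_equal(sort(unique(det$frame)), 2:6)
  for (f in 2:6) {
    d <- det[det$frame == f, ]
    # frame differencing lights up both the old and new blob location;
    # at 9 px/frame they merge into one component spanning the two
    expect_gte(nrow(d), 1)
    err <- min(sqrt((d$x_px - (20 + 6 * f))^2 + (d$y_px - (40 + 3 * f))^2))
    expect_lt(err, 6)
  }
})

test_that("a well-separated jump leaves accurate disk centroids", {
  # 30 px/frame: the difference image carries clean disks at the old and
  # new positions; the one at the new position is centred within a pixel
  frames <- blob_frames(4, function(i) c(40 + 30 * i, 60), radius = 3.2)
  det <- detect_targets(frames, detect_config(threshold = 0.05))
  d <- det[det$frame == 3, ]
  expect_equal(nrow(d), 2)
  nearest <- which.min(abs(d$x_px - 130))
  expect_lt(abs(d$y_px[nearest] - 60), 1)
  expect_lt(abs(d$x_px[nearest] - 130), 1)
})

test_that("components outside the size band are discarded", {
  # 600 px^2 foam patch (radius ~14) and a 10 px^2 speckle (radius ~1.8)
  frames <- blob_frames(4, function(i) c(30 + 20 * i, 60), radius = 14)
  det <- detect_targets(frames, detect_config(threshold = 0.05))
  expect_equal(nrow(det), 0)
  frames2 <- blob_frames(4, function(i) c(30 + 20 * i, 60), radius = 1.6)
  det2 <- detect_targets(frames2, detect_config(threshold = 0.05))
  expect_equal(nrow(det2), 0)
  # a bird-sized blob passes
  frames3 <- blob_frames(4, function(i) c(30 + 20 * i, 60), radius = 3.2)
  det3 <- detect_targets(frames3, detect_config(threshold = 0.05))
  expect_gt(nrow(det3), 0)
  expect_true(all(det3$area >= 20 & det3$area <= 500))
})

test_that("detection is translation-equivariant", {
  f1 <- blob_frames(3, function(i) c(40 + 10 * i, 40))
  f2 <- blob_frames(3, function(i) c(60 + 10 * i, 70))
  d1 <- detect_targets(f1, detect_config(threshold = 0.05))
  d2 <- detect_targets(f2, detect_config(threshold = 0.05))
  expect_equal(d2$x_px - d1$x_px, rep(20, nrow(d1)), tolerance = 1e-6)
  expect_equal(d2$y_px - d1$y_px, rep(30, nrow(d1)), tolerance = 1e-6)
})

test_that("the blob classifier separates synthetic birds from clutter", {
  set.seed(5)
  n <- 120
  birds <- tibble::tibble(
    area = runif(n, 25, 60), eccentricity = runif(n, 0.6, 1),
    intensity = runif(n, 0.7, 1), label = "bird")
  foam <- tibble::tibble(
    area = runif(n, 250, 490), eccentricity = runif(n, 0.05, 0.5),
    intensity = runif(n, 0.2, 0.5), label = "clutter")
  all_d <- dplyr::bind_rows(birds, foam)[sample(2 * n), ]
  train <- all_d[1:(1.5 * n), ]; test <- all_d[(1.5 * n + 1):(2 * n), ]
  clf <- train_blob_classifier(train)
  got <- classify_detections(test, clf)
  expect_gt(mean(got$label == test$label), 0.9)
  # determinism: identical features, identical labels
  again <- classify_detections(test, clf)
  expect_identical(got$label, again$label)
  # empty input passes through
  expect_equal(nrow(classify_detections(all_d[0, ], clf)), 0)
  expect_error(classify_detections(test, "not a model"), "classifier")
})

cv_detections <- function(x0, y0, vx, vy, frames = 30, id_noise = 0,
                          label = "bird") {
  tibble::tibble(
    frame = seq_len(frames), t = (seq_len(frames) - 1) / 30,
    x_px = x0 + vx * (seq_len(frames) - 1) + rnorm(frames, 0, id_noise),
    y_px = y0 + vy * (seq_len(frames) - 1) + rnorm(frames, 0, id_noise),
    area = 30, eccentricity = 0.8, intensity = 0.9, label = label)
}

test_that("a noiseless constant-velocity target is tracked within 0.5 px", {
  det <- cv_detections(20, 30, 3, 1)
  tr <- track_targets(det, track_config())
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 30)
  expect_true(all(abs(tr$x_px - det$x_px) < 0.5))
  expect_true(all(abs(tr$y_px - det$y_px) < 0.5))
  expect_true(all(tr$provenance == "detected"))
})

test_that("a short occlusion is gap-filled and flagged", {
  det <- cv_detections(20, 30, 3, 1)
  occluded <- det[!det$frame %in% 15:17, ]
  tr <- track_targets(occluded, track_config())
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 30)
  filled <- tr[tr$frame %in% 15:17, ]
  expect_true(all(filled$provenance %in% c("gap_filled", "spliced")))
  # predictions stay on the true trajectory
  expect_true(all(abs(filled$x_px - (20 + 3 * (filled$frame - 1))) < 2))
})

test_that("crossing targets keep their identities via velocity gating", {
  set.seed(2)
  a <- cv_detections(10, 60, 4, 0, id_noise = 0.1)
  b <- cv_detections(130, 60, -4, 0, id_noise = 0.1)  # crosses a at frame ~16
  det <- dplyr::bind_rows(a, b) %>% dplyr::arrange(frame)
  tr <- track_targets(det, track_config())
  expect_equal(length(unique(tr$track_id)), 2)
  ends <- tr %>%
    dplyr::group_by(track_id) %>%
    dplyr::summarise(x0 = x_px[which.min(frame)], x1 = x_px[which.max(frame)])
  # the rightward mover ends right, the leftward mover ends left
  expect_true(any(ends$x0 < 30 & ends$x1 > 120))
  expect_true(any(ends$x0 > 120 & ends$x1 < 30))
})

test_that("geo correction undistorts and scales to metres", {
  cam <- camera_model(footprint = c(96, 54), frame_size = c(1600, 900),
                      k1 = -0.12, k2 = 0.02)
  # round trip: distort then undistort
  set.seed(3)
  x <- runif(50, 100, 1500); y <- runif(50, 100, 800)
  d <- distort_points(x, y, cam)
  u <- undistort_points(d$x, d$y, cam)
  expect_lt(max(abs(u$x - x)), 0.01)
  expect_lt(max(abs(u$y - y)), 0.01)
  # pure scaling when the lens is ideal: 100 px at GSD 0.06 -> 6 m
  cam0 <- camera_model(footprint = c(96, 54), frame_size = c(1600, 900))
  expect_equal(cam0$gsd, 0.06)
  tr <- tibble::tibble(track_id = 1, frame = 1:2, t = c(0, 1 / 30),
                       x_px = c(200, 300), y_px = c(450, 450),
                       provenance = "detected")
  m <- geo_correct(tr, cam0)
  expect_equal(diff(m$x), 6)
  expect_error(geo_correct(tr, list()), "camera_model")
})

test_that("track filters drop short and transiting tracks and keep the rest", {
  mk <- function(id, dur, tortuous, rate = 30) {
    t <- seq(0, dur, by = 1 / rate)
    if (tortuous) {
      x <- 5 * t + 3 * sin(t * 2); y <- 3 * sin(t * 1.3)
    } else {
      x <- 6 * t; y <- 0.01 * t
    }
    tibble::tibble(track_id = id, t = t, x = x, y = y)
  }
  tracks <- dplyr::bind_rows(
    mk(1, 20, FALSE),   # long transit: tortuosity ~ 1 -> removed
    mk(2, 10, TRUE),    # short: removed
    mk(3, 20, TRUE))    # long and tortuous: retained
  kept <- filter_tracks(tracks)
  expect_equal(unique(kept$track_id), 3)
  expect_gte(overall_tortuosity(kept$x, kept$y), 1.1)
  # idempotent and order-independent
  again <- filter_tracks(kept)
  expect_equal(again, kept)
  shuffled <- tracks[sample(nrow(tracks)), ]
  kept2 <- filter_tracks(shuffled)
  expect_setequal(unique(kept2$track_id), 3)
  # a closed loop has infinite tortuosity and is retained
  th <- seq(0, 2 * pi, length.out = 600)
  loop <- tibble::tibble(track_id = 9, t = seq(0, 20, length.out = 600),
                         x = cos(th), y = sin(th))
  expect_equal(unique(filter_tracks(loop)$track_id), 9)
})
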