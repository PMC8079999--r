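# Savitzky-Golay (local polynomial) design for an 11-point window. A
# quadratic is fitted to the centred window; on a symmetric window its
# centre value equals that of the cubic fit and its centre derivative that
# of the straight-line slope (the classic SG filter pairings), so linear
# and quadratic motion are reproduced exactly while the derivative filter
# attenuates wingbeat-band (>3 Hz) jitter by about an order of magnitude.
# The implied low-pass cut-off is rate / window (2.73 Hz at the defaults).
sg_matrices <- function(window, rate) {
  stopifnot(window %% 2 == 1, window >= 5)
  half <- (window - 1) / 2
  tt <- (-half:half) / rate
  X <- cbind(1, tt, tt^2)
  H <- solve(crossprod(X), t(X))   # 3 x window: polynomial coefficients
  list(value = H[1, ],             # smoothed position at the centre
       deriv = H[2, ],             # first derivative at the centre
       coef = H, tt = tt, X = X)
}

#' Implied low-pass cut-off frequency of the smoothing window
#'
#' The centred n-sample window at sampling rate `rate` passes signals
#' slower than roughly one cycle per window; its implied cut-off frequency
#' is `rate / window` (2.73 Hz for the default 11-sample window at 30 Hz).
#'
#' @param window window length in samples.
#' @param rate sampling rate, Hz.
#' @return Cut-off frequency in Hz.
#' @export
window_cutoff_hz <- function(window = 11, rate = 30) {
  stopifnot(window >= 1, rate > 0)
  rate / window
}

#' Spline-window kinematics: speed and log-tortuosity along a track
#'
#' For each interior point of a track, a local polynomial (Savitzky-Golay)
#' fit over the 11 raw positions centred on it smooths x(t) and y(t)
#' separately; the velocity is the first derivative of the window fit at
#' the centre time and the smoothed position its value (exact for linear
#' and quadratic motion, low-pass with cut-off about `rate / window`). Window tortuosity is the total distance along the 11
#' smoothed points divided by the chord between the first and last, floored
#' at 1; log-tortuosity is its natural log (floored at `log(1 + eps)` so
#' gamma emissions keep strictly positive support). The first and last
#' `(window-1)/2` points of each track yield no observations.
#'
#' @param track tibble with columns `track_id`, `t`, `x`, `y` (seconds and
#'   metres, regular sampling).
#' @param window odd window length (default 11, i.e. +/- 5 samples).
#' @param rate sampling rate in Hz; if `NULL`, inferred from `t`.
#' @param smooth_tortuosity compute tortuosity from the window's smoothed
#'   points (default) or from the raw positions.
#' @param max_tortuosity cap applied when the chord is (numerically) zero.
#' @param eps floor for `tortuosity - 1` inside the log.
#' @return A tibble: `track_id`, `t`, `x`, `y` (smoothed), `speed`,
#'   `tortuosity`, `log_tortuosity`.
#' @export
track_kinematics <- function(track, window = 11, rate = NULL,
                             smooth_tortuosity = TRUE,
                             max_tortuosity = 1e6, eps = 1e-8) {
  stopifnot(all(c("track_id", "t", "x", "y") %in% names(track)))
  track %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::group_modify(function(df, key) {
      kinematics_one(df, window, rate, smooth_tortuosity, max_tortuosity,
                     eps)
    }) %>%
    dplyr::ungroup()
}

kinematics_one <- function(df, window, rate, smooth_tortuosity,
                           max_tortuosity, eps) {
  df <- df[order(df$t), , drop = FALSE]
  n <- nrow(df)
  if (n < window) {
    return(tibble::tibble(t = numeric(0), x = numeric(0), y = numeric(0),
                          speed = numeric(0), tortuosity = numeric(0),
                          log_tortuosity = numeric(0)))
  }
  if (is.null(rate)) rate <- 1 / median(diff(df$t))
  sg <- sg_matrices(window, rate)
  half <- (window - 1) / 2
  centres <- (half + 1):(n - half)
  m <- length(centres)
  xs <- df$x; ys <- df$y
  out <- tibble::tibble(t = df$t[centres], x = NA_real_, y = NA_real_,
                        speed = NA_real_, tortuosity = NA_real_,
                        log_tortuosity = NA_real_)
  for (j in seq_len(m)) {
    i <- centres[j]
    wx <- xs[(i - half):(i + half)]
    wy <- ys[(i - half):(i + half)]
    out$x[j] <- sum(sg$value * wx)
    out$y[j] <- sum(sg$value * wy)
    vx <- sum(sg$deriv * wx)
    vy <- sum(sg$deriv * wy)
    out$speed[j] <- sqrt(vx^2 + vy^2)
    if (smooth_tortuosity) {
      cx <- sg$coef %*% wx
      cy <- sg$coef %*% wy
      px <- as.vector(sg$X %*% cx)
      py <- as.vector(sg$X %*% cy)
    } else {
      px <- wx; py <- wy
    }
    path <- sum(sqrt(diff(px)^2 + diff(py)^2))
    chord <- sqrt((px[window] - px[1])^2 + (py[window] - py[1])^2)
    tort <- if (chord < path * 1e-9 || chord == 0) max_tortuosity
            else max(path / chord, 1)
    out$tortuosity[j] <- min(tort, max_tortuosity)
    out$log_tortuosity[j] <- log(max(out$tortuosity[j], 1 + eps))
  }
  out
}

#' Subsample a kinematic series to a lower rate
#'
#' Keeps every k-th observation per track, `k = round(native / target)`.
#' Subsampling to `rate / window` (2.73 Hz for 11 samples at 30 Hz) removes
#' the serial correlation induced by overlapping smoothing windows.
#'
#' @param series tibble with `track_id` and `t` columns.
#' @param target_rate Hz.
#' @param native_rate Hz; inferred from `t` when `NULL`.
#' @return The subsampled tibble.
#' @export
subsample_series <- function(series, target_rate = 30 / 11,
                             native_rate = NULL) {
  stopifnot(all(c("track_id", "t") %in% names(series)))
  series %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$t), , drop = FALSE]
      nr <- native_rate %||% (1 / median(diff(df$t)))
      if (target_rate > nr + 1e-9) {
        stop("target_rate exceeds the native sampling rate", call. = FALSE)
      }
      k <- max(1L, as.integer(round(nr / target_rate)))
      df[seq(1, nrow(df), by = k), , drop = FALSE]
    }) %>%
    dplyr::ungroup()
}
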