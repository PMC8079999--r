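#' Configuration for the synthetic tern-trajectory simulator
#'
#' Trajectories follow a two-state Markov chain whose transition
#' probabilities depend on local flow covariates through the logit-linear
#' model `logit(Pr(i -> j)) = beta0 + beta1 * |curl| + beta2 * divergence`.
#' Conditional on the state, speed and log-tortuosity are drawn from gamma
#' distributions parametrized by mean and standard deviation. State 1 is the
#' slow, tortuous "active foraging" state; state 2 the faster, straighter
#' "transit" state, and the defaults echo field-plausible tern values
#' (state speeds ~4 and ~7 m/s).
#'
#' @param n_tracks number of tracks.
#' @param rate sampling rate, Hz.
#' @param duration_range length-2 seconds; each track's duration is uniform
#'   in this range.
#' @param speed_mean,speed_sd per-state gamma mean/sd of speed (m/s),
#'   length 2 (state 1, state 2); state 1 mean must be the smaller.
#' @param logtort_mean,logtort_sd per-state gamma mean/sd of
#'   log-tortuosity.
#' @param beta12,beta21 length-3 transition coefficients (intercept,
#'   |curl| slope, divergence slope) for 1->2 and 2->1.
#' @param d_curl,d_div time-to-contact delays (s) at which the generative
#'   chain reads its covariates.
#' @param mode `"emission"` (return the bivariate series directly, with
#'   synthetic smooth covariates) or `"kinematic"` (integrate positions
#'   through a simulated flow field).
#' @param heading_sd `NULL` to calibrate per-observation heading-increment
#'   noise from the drawn log-tortuosity (see
#'   [tortuosity_heading_lookup()]), or a length-2 numeric of fixed
#'   per-state heading-increment standard deviations (radians/step).
#' @param force_state `NULL`, or 1 or 2 to pin the chain to one state
#'   (used for calibration and tests).
#' @param curl_sd,div_sd stationary standard deviations of the synthetic
#'   AR(1) covariate processes used in emission mode (1/s).
#' @param cov_ar autocorrelation per step of those processes.
#' @param seed integer root seed.
#' @return A list of class `trajectory_sim_config`.
#' @export
trajectory_sim_config <- function(n_tracks = 20,
                                  rate = 30,
                                  duration_range = c(20, 40),
                                  speed_mean = c(3.981, 7.191),
                                  speed_sd = c(1.360, 2.097),
                                  logtort_mean = c(0.066, 0.009),
                                  logtort_sd = c(0.068, 0.008),
                                  beta12 = c(-2, -1.5, -1.2),
                                  beta21 = c(-2.5, 1.5, 1.2),
                                  d_curl = 0,
                                  d_div = 0,
                                  mode = c("emission", "kinematic"),
                                  heading_sd = NULL,
                                  force_state = NULL,
                                  curl_sd = 0.4,
                                  div_sd = 0.25,
                                  cov_ar = 0.95,
                                  seed = 1L) {
  mode <- match.arg(mode)
  assert_positive(c(speed_mean, speed_sd, logtort_mean, logtort_sd),
                  "gamma emission parameters")
  if (speed_mean[1] >= speed_mean[2]) {
    stop("labelling convention: state 1 must have the lower mean speed",
         call. = FALSE)
  }
  stopifnot(length(beta12) == 3, length(beta21) == 3,
            d_curl >= 0, d_div >= 0)
  structure(as.list(environment()), class = "trajectory_sim_config")
}

# gamma draws parametrized by mean and sd
rgamma_ms <- function(n, mean, sd) {
  rgamma(n, shape = (mean / sd)^2, scale = sd^2 / mean)
}

dgamma_ms <- function(x, mean, sd, log = FALSE) {
  dgamma(x, shape = (mean / sd)^2, scale = sd^2 / mean, log = log)
}

#' Per-step transition probabilities of the covariate-driven chain
#'
#' @param beta12,beta21 length-3 coefficient vectors (intercept, |curl|
#'   slope, divergence slope).
#' @param abs_curl,divergence covariate vectors (1/s).
#' @return A tibble with columns `p12`, `p21`.
#' @export
switching_probabilities <- function(beta12, beta21, abs_curl, divergence) {
  tibble::tibble(
    p12 = expit(beta12[1] + beta12[2] * abs_curl + beta12[3] * divergence),
    p21 = expit(beta21[1] + beta21[2] * abs_curl + beta21[3] * divergence))
}

# AR(1) series with stationary sd `s` and per-step correlation `phi`
ar1_series <- function(n, s, phi) {
  x <- numeric(n)
  x[1] <- rnorm(1, 0, s)
  innov_sd <- s * sqrt(1 - phi^2)
  for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + rnorm(1, 0, innov_sd)
  x
}

.ternflow_cache <- new.env(parent = emptyenv())

#' Lookup from target window tortuosity to heading-increment noise
#'
#' Positions in kinematic mode are integrated from drawn speeds and
#' heading increments; the increment scale is chosen so the realized
#' 11-point window tortuosity approximates the drawn log-tortuosity
#' emission. The mapping is tabulated once by simulation (mean realized
#' window tortuosity of an 11-step unit-speed walk as a function of the
#' heading-increment sd) and inverted by monotone interpolation.
#'
#' @param window window length in samples (11).
#' @return A function mapping log-tortuosity values to heading-increment
#'   standard deviations (radians per step).
#' @export
tortuosity_heading_lookup <- function(window = 11) {
  key <- paste0("headlut_", window)
  if (!is.null(.ternflow_cache[[key]])) return(.ternflow_cache[[key]])
  sds <- exp(seq(log(0.002), log(2.0), length.out = 25))
  # tabulation uses its own fixed stream; caller's RNG state is untouched
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(20260401)
  mean_tort <- vapply(sds, function(s) {
    tort <- replicate(400, {
      h <- cumsum(rnorm(window - 1, 0, s))
      dx <- cos(h); dy <- sin(h)
      path <- window - 1
      chord <- sqrt(sum(dx)^2 + sum(dy)^2)
      path / max(chord, 1e-9)
    })
    mean(tort)
  }, numeric(1))
  mean_tort <- cummax(mean_tort)  # enforce monotonicity for inversion
  lut <- function(log_tort) {
    target <- pmax(exp(log_tort), 1 + 1e-9)
    out <- approx(mean_tort, sds, xout = target, rule = 2)$y
    out
  }
  .ternflow_cache[[key]] <- lut
  lut
}

#' Simulate behaviour-switching tern trajectories
#'
#' @param config a [trajectory_sim_config()].
#' @param flow a `ground_truth_flow` (required in kinematic mode; ignored in
#'   emission mode, where synthetic smooth covariate series stand in for a
#'   flow field).
#' @return A list of class `track_simulation` with elements
#'   `observations` (tibble: `track_id`, `t`, `speed`, `log_tortuosity`,
#'   `abs_curl`, `divergence`, `state_true`) and, in kinematic mode,
#'   `tracks` (tibble: `track_id`, `t`, `x`, `y`, `state_true`,
#'   `provenance`).
#' @export
simulate_tracks <- function(config, flow = NULL) {
  stopifnot(inherits(config, "trajectory_sim_config"))
  if (config$mode == "kinematic" && is.null(flow)) {
    stop("kinematic mode requires a simulated flow", call. = FALSE)
  }
  set.seed(substream_seed(config$seed, "tracks"))
  dt <- 1 / config$rate
  obs <- vector("list", config$n_tracks)
  trk <- vector("list", config$n_tracks)
  lut <- if (is.null(config$heading_sd)) tortuosity_heading_lookup() else NULL
  for (k in seq_len(config$n_tracks)) {
    dur <- runif(1, config$duration_range[1], config$duration_range[2])
    n <- max(2L, round(dur * config$rate))
    tvec <- (seq_len(n) - 1) * dt
    if (config$mode == "emission") {
      res <- simulate_track_emission(config, n)
    } else {
      res <- simulate_track_kinematic(config, flow, n, dt, lut)
      trk[[k]] <- tibble::tibble(
        track_id = k, t = tvec[seq_len(nrow(res))],
        x = res$x, y = res$y, state_true = res$state,
        provenance = res$provenance)
    }
    obs[[k]] <- tibble::tibble(
      track_id = k, t = tvec[seq_len(nrow(res))],
      speed = res$speed, log_tortuosity = res$log_tort,
      abs_curl = res$abs_curl, divergence = res$divergence,
      state_true = res$state)
  }
  structure(
    list(observations = dplyr::bind_rows(obs),
         tracks = if (config$mode == "kinematic") dplyr::bind_rows(trk)
                  else NULL,
         config = config),
    class = "track_simulation")
}

# one emission-mode track: smooth AR covariates drive the chain directly
simulate_track_emission <- function(config, n) {
  abs_curl <- abs(ar1_series(n, config$curl_sd, config$cov_ar))
  divergence <- ar1_series(n, config$div_sd, config$cov_ar)
  pr <- switching_probabilities(config$beta12, config$beta21,
                                abs_curl, divergence)
  state <- integer(n)
  state[1] <- if (!is.null(config$force_state)) config$force_state else {
    d1 <- pr$p21[1] / (pr$p12[1] + pr$p21[1])
    if (runif(1) < d1) 1L else 2L
  }
  for (i in seq_len(n - 1)) {
    if (!is.null(config$force_state)) {
      state[i + 1] <- config$force_state
    } else if (state[i] == 1L) {
      state[i + 1] <- if (runif(1) < pr$p12[i + 1]) 2L else 1L
    } else {
      state[i + 1] <- if (runif(1) < pr$p21[i + 1]) 1L else 2L
    }
  }
  speed <- rgamma_ms(n, config$speed_mean[state], config$speed_sd[state])
  log_tort <- rgamma_ms(n, config$logtort_mean[state],
                        config$logtort_sd[state])
  data.frame(speed = speed, log_tort = log_tort, abs_curl = abs_curl,
             divergence = divergence, state = state)
}

# one kinematic-mode track: positions integrated through the flow; the
# chain reads |curl| and divergence at the dead-reckoned position at
# t + d (the feature state upon arrival)
simulate_track_kinematic <- function(config, flow, n, dt, lut) {
  stack <- flow$flow
  Lx <- max(stack$x); Ly <- max(stack$y)
  x <- numeric(n); y <- numeric(n)
  state <- integer(n); speed <- numeric(n); log_tort <- numeric(n)
  abs_curl <- numeric(n); divergence <- numeric(n)
  x[1] <- runif(1, 0.1 * Lx, 0.9 * Lx)
  y[1] <- runif(1, 0.1 * Ly, 0.9 * Ly)
  heading <- runif(1, 0, 2 * pi)
  lookup <- function(xq, yq, tq) {
    cz <- interpolate_field(stack, xq, yq, tq, what = "curl")
    dz <- interpolate_field(stack, xq, yq, tq, what = "div")
    c(abs(cz), dz)
  }
  z <- lookup(x[1], y[1], 0)
  if (any(is.na(z))) z <- c(0, 0)
  pr0 <- switching_probabilities(config$beta12, config$beta21, z[1], z[2])
  d1 <- pr0$p21 / (pr0$p12 + pr0$p21)
  state[1] <- if (!is.null(config$force_state)) config$force_state
              else if (runif(1) < d1) 1L else 2L
  trunc_at <- n
  for (i in seq_len(n)) {
    s <- state[i]
    speed[i] <- rgamma_ms(1, config$speed_mean[s], config$speed_sd[s])
    log_tort[i] <- rgamma_ms(1, config$logtort_mean[s], config$logtort_sd[s])
    t_now <- (i - 1) * dt
    # covariates recorded at the current position (delay applied in the
    # generative transition lookup below)
    z_here <- lookup(x[i], y[i], t_now)
    abs_curl[i] <- z_here[1]; divergence[i] <- z_here[2]
    if (i == n) break
    hsd <- if (!is.null(config$heading_sd)) config$heading_sd[s]
           else lut(log_tort[i])
    heading <- heading + if (hsd > 0) rnorm(1, 0, hsd) else 0
    x[i + 1] <- x[i] + speed[i] * dt * cos(heading)
    y[i + 1] <- y[i] + speed[i] * dt * sin(heading)
    if (x[i + 1] < 0 || x[i + 1] > Lx || y[i + 1] < 0 || y[i + 1] > Ly) {
      trunc_at <- i
      break
    }
    if (!is.null(config$force_state)) {
      state[i + 1] <- config$force_state
      next
    }
    # dead-reckoned positions ahead along the flight path; the step into
    # observation i+1 is driven by the covariate at t_{i+1} + d (the HMM
    # convention: the covariate row at an observation drives the
    # transition INTO it)
    zc <- lookup(x[i + 1] + speed[i] * config$d_curl * cos(heading),
                 y[i + 1] + speed[i] * config$d_curl * sin(heading),
                 min(t_now + dt + config$d_curl, max(stack$t)))
    zd <- lookup(x[i + 1] + speed[i] * config$d_div * cos(heading),
                 y[i + 1] + speed[i] * config$d_div * sin(heading),
                 min(t_now + dt + config$d_div, max(stack$t)))
    zc[is.na(zc)] <- 0; zd[is.na(zd)] <- 0
    pr <- switching_probabilities(config$beta12, config$beta21,
                                  c(zc[1]), c(zd[2]))
    if (s == 1L) {
      state[i + 1] <- if (runif(1) < pr$p12) 2L else 1L
    } else {
      state[i + 1] <- if (runif(1) < pr$p21) 1L else 2L
    }
  }
  idx <- seq_len(trunc_at)
  data.frame(x = x[idx], y = y[idx], speed = speed[idx],
             log_tort = log_tort[idx], abs_curl = abs_curl[idx],
             divergence = divergence[idx], state = state[idx],
             provenance = if (trunc_at < n) {
               c(rep("detected", trunc_at - 1), "truncated")
             } else rep("detected", n))
}

#' Simulate a time-to-contact delay study over a flow field
#'
#' Generator tailored to delay-scan experiments: flight-path geometry is
#' simulated first (constant nominal ground speed with heading random
#' walk), the transition covariates are then read along the realized path
#' at the true delays exactly as [attach_covariates()] will re-read them,
#' and finally states and gamma emissions are drawn. Because the covariate
#' that drives each transition is the one the matching stage recovers at
#' the true delay pair, the maximum-likelihood delay surface is centred on
#' the generative delays; observed speed and log-tortuosity are drawn from
#' the state laws independently of the path geometry (the decoupling is
#' deliberate and documented).
#'
#' @param flow a `ground_truth_flow` or [flow_stack()].
#' @param n_tracks,rate,duration_range as in [trajectory_sim_config()].
#' @param path_speed nominal ground speed of the simulated geometry, m/s.
#' @param heading_sd heading random-walk increment sd, radians/step.
#' @param beta12,beta21,d_curl,d_div transition model and true delays.
#' @param speed_mean,speed_sd,logtort_mean,logtort_sd gamma emission
#'   parameters per state.
#' @param max_delay truncation horizon passed to [attach_covariates()].
#' @param seed integer seed.
#' @return A list with `series` (kinematic series: `track_id`, `t`, `x`,
#'   `y`, `speed`, `log_tortuosity`) and `states` (the generative state
#'   sequence aligned with `series`).
#' @export
simulate_delay_study <- function(flow, n_tracks = 30, rate = 30 / 11,
                                 duration_range = c(55, 75),
                                 path_speed = 6, heading_sd = 0.15,
                                 beta12 = c(-2, -4, -3),
                                 beta21 = c(-2.5, 4, 3),
                                 d_curl = 0.25, d_div = 2,
                                 speed_mean = c(3.981, 7.191),
                                 speed_sd = c(1.360, 2.097),
                                 logtort_mean = c(0.066, 0.009),
                                 logtort_sd = c(0.068, 0.008),
                                 max_delay = max(d_curl, d_div),
                                 seed = 1L) {
  stack <- if (inherits(flow, "ground_truth_flow")) flow$flow else flow
  set.seed(substream_seed(seed, "delay_study"))
  Lx <- max(stack$x); Ly <- max(stack$y)
  dt <- 1 / rate
  out <- vector("list", n_tracks)
  for (k in seq_len(n_tracks)) {
    dur <- runif(1, duration_range[1], duration_range[2])
    n <- max(4L, round(dur * rate))
    x <- numeric(n); y <- numeric(n)
    x[1] <- runif(1, 0.1 * Lx, 0.9 * Lx)
    y[1] <- runif(1, 0.1 * Ly, 0.9 * Ly)
    heading <- runif(1, 0, 2 * pi)
    for (i in seq_len(n - 1)) {
      heading <- heading + rnorm(1, 0, heading_sd)
      # birds work the wake area: reflect the heading at the footprint
      # edges instead of leaving the observed domain
      step_x <- path_speed * dt * cos(heading)
      step_y <- path_speed * dt * sin(heading)
      if (x[i] + step_x < 0 || x[i] + step_x > Lx) {
        heading <- pi - heading
        step_x <- -step_x
      }
      if (y[i] + step_y < 0 || y[i] + step_y > Ly) {
        heading <- -heading
        step_y <- -step_y
      }
      x[i + 1] <- x[i] + step_x
      y[i + 1] <- y[i] + step_y
    }
    if (n < 4) next
    geom <- tibble::tibble(track_id = k, t = (seq_len(n) - 1) * dt,
                           x = x, y = y)
    cov <- attach_covariates(geom, stack, d_curl, d_div,
                             max_delay = max_delay)
    cov <- cov[!cov$missing, , drop = FALSE]
    m <- nrow(cov)
    if (m < 4) next
    pr <- switching_probabilities(beta12, beta21, cov$abs_curl,
                                  cov$divergence)
    st <- integer(m)
    st[1] <- if (runif(1) < pr$p21[1] / (pr$p12[1] + pr$p21[1])) 1L else 2L
    for (i in seq_len(m - 1)) {
      st[i + 1] <- if (st[i] == 1L) {
        if (runif(1) < pr$p12[i + 1]) 2L else 1L
      } else {
        if (runif(1) < pr$p21[i + 1]) 1L else 2L
      }
    }
    cov$speed <- rgamma_ms(m, speed_mean[st], speed_sd[st])
    cov$log_tortuosity <- rgamma_ms(m, logtort_mean[st], logtort_sd[st])
    cov$state_true <- st
    out[[k]] <- cov
  }
  all <- dplyr::bind_rows(out)
  list(series = all[, c("track_id", "t", "x", "y", "speed",
                        "log_tortuosity")],
       states = all$state_true,
       covariates = all[, c("abs_curl", "divergence")])
}
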