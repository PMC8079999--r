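#' Configuration for the synthetic wake-flow simulator
#'
#' The simulated surface flow is a superposition of (i) uniform downstream
#' advection, (ii) a street of alternating-sign Lamb-Oseen vortices shed
#' periodically from a virtual monopile and advected downstream, and
#' (iii) radially symmetric upwelling "boils" that erupt at random times and
#' locations, grow in radius and decay in peak divergence. Flow magnitudes
#' inside such wakes are site-specific; the defaults are order-of-magnitude
#' choices for a tidal-channel monopile wake and are all exposed here.
#'
#' @param domain_size numeric length 2, metres (Lx, Ly); default matches a
#'   nadir drone footprint of 166.1 x 94.5 m at 100 m altitude.
#' @param grid_spacing metres between grid nodes.
#' @param dt seconds between exported flow fields (default 0.25 s).
#' @param duration total simulated seconds.
#' @param advection_speed uniform downstream (x) current, m/s.
#' @param vortex_strength circulation of each shed vortex, m^2/s.
#' @param vortex_core_radius Lamb-Oseen core radius, m.
#' @param shedding_period seconds between successive shed vortices.
#' @param street_halfwidth lateral offset of the two vortex rows, m.
#' @param boil_rate eruption rate, boils per second over the whole domain.
#' @param boil_peak_divergence peak divergence of a fresh boil, 1/s.
#' @param boil_radius initial Gaussian radius of a boil, m.
#' @param boil_growth_rate radial growth rate, m/s.
#' @param boil_decay_time e-folding time of the peak divergence, s.
#' @param seed integer root seed for eruption times/locations.
#' @return A list of class `flow_sim_config`.
#' @export
flow_sim_config <- function(domain_size = c(166.1, 94.5),
                            grid_spacing = 2,
                            dt = 0.25,
                            duration = 30,
                            advection_speed = 0.8,
                            vortex_strength = 40,
                            vortex_core_radius = 8,
                            shedding_period = 12,
                            street_halfwidth = 12,
                            boil_rate = 0.08,
                            boil_peak_divergence = 0.3,
                            boil_radius = 5,
                            boil_growth_rate = 0.2,
                            boil_decay_time = 20,
                            seed = 1L) {
  assert_positive(c(domain_size, grid_spacing, dt, duration,
                    vortex_core_radius, shedding_period, boil_radius,
                    boil_growth_rate, boil_decay_time),
                  "flow_sim_config scales")
  if (vortex_strength != 0 && grid_spacing >= vortex_core_radius / 2) {
    stop("grid too coarse to resolve the vortex core: need grid_spacing < ",
         "vortex_core_radius / 2", call. = FALSE)
  }
  if (boil_rate > 0 && grid_spacing >= boil_radius / 2) {
    stop("grid too coarse to resolve boils: need grid_spacing < ",
         "boil_radius / 2", call. = FALSE)
  }
  structure(as.list(environment()), class = "flow_sim_config")
}

# tangential speed of a Lamb-Oseen vortex at radius r (circulation gamma,
# core radius rc); bounded everywhere, -> gamma/(2 pi r) far field
lamb_oseen_utheta <- function(r, gamma, rc) {
  out <- ifelse(r < 1e-12,
                0,
                gamma / (2 * pi * pmax(r, 1e-12)) * (1 - exp(-(r / rc)^2)))
  out
}

# closed-form vorticity of the Lamb-Oseen profile
lamb_oseen_vorticity <- function(r, gamma, rc) {
  gamma / (pi * rc^2) * exp(-(r / rc)^2)
}

# Gaussian-divergence boil: div(r) = peak * exp(-r^2 / (2 sigma^2));
# induced radial velocity u_r = peak * sigma^2 * (1 - exp(-r^2/(2 sigma^2))) / r
boil_radial_velocity <- function(r, peak, sigma) {
  ifelse(r < 1e-12,
         0,
         peak * sigma^2 * (1 - exp(-r^2 / (2 * sigma^2))) / pmax(r, 1e-12))
}

boil_divergence <- function(r, peak, sigma) {
  peak * exp(-r^2 / (2 * sigma^2))
}

# schedule of shed vortices covering [0, duration]; vortices shed before t=0
# are included so the street already spans the domain at t=0
vortex_schedule <- function(config) {
  if (config$vortex_strength == 0) {
    return(data.frame(t_shed = numeric(0), sign = numeric(0),
                      y0 = numeric(0)))
  }
  Lx <- config$domain_size[1]
  k0 <- if (config$advection_speed > 0) {
    travel <- (Lx + 4 * config$vortex_core_radius) / config$advection_speed
    -ceiling(travel / config$shedding_period) - 1
  } else 0  # static vortices: nothing advects in from upstream

  k1 <- ceiling(config$duration / config$shedding_period) + 1
  k <- k0:k1
  data.frame(
    t_shed = k * config$shedding_period,
    sign = ifelse(k %% 2 == 0, 1, -1),
    y0 = config$domain_size[2] / 2 +
      ifelse(k %% 2 == 0, 1, -1) * config$street_halfwidth)
}

boil_schedule <- function(config) {
  if (config$boil_rate == 0) {
    return(data.frame(t0 = numeric(0), x0 = numeric(0), y0 = numeric(0)))
  }
  set.seed(substream_seed(config$seed, "boils"))
  # eruptions as a Poisson process; include boils born up to one decay time
  # before t=0 so the field is statistically stationary from the start
  t_lo <- -config$boil_decay_time
  n <- rpois(1, config$boil_rate * (config$duration - t_lo))
  data.frame(
    t0 = sort(runif(n, t_lo, config$duration)),
    x0 = runif(n, 0, config$domain_size[1]),
    y0 = runif(n, 0, config$domain_size[2]))
}

#' Simulate a ground-truthed wake surface flow
#'
#' Evaluates the closed-form velocity model of [flow_sim_config()] on a
#' regular grid at each export time. Curl and divergence are provided both
#' analytically (exact for the closed-form model) and by central finite
#' differences of the gridded velocity, so discretization behaviour is
#' itself testable.
#'
#' @param config a [flow_sim_config()].
#' @param boils optional data frame (`t0`, `x0`, `y0`) of eruption times
#'   and locations, overriding the Poisson schedule (deterministic
#'   scenarios and tests).
#' @return A list of class `ground_truth_flow` with elements `flow`
#'   (a [flow_stack()] whose `curl`/`div` are the analytic grids),
#'   `curl_fd`, `div_fd` (finite-difference grids), and the schedules of
#'   vortices and boils actually used.
#' @export
simulate_flow <- function(config, boils = NULL) {
  stopifnot(inherits(config, "flow_sim_config"))
  # grids span the full domain: one node beyond when spacing does not
  # divide the extent, so interpolation covers every in-domain query
  cover_seq <- function(L, h) {
    n <- floor(L / h + 1e-9) + 1
    if ((n - 1) * h < L - 1e-9) n <- n + 1
    seq(0, by = h, length.out = n)
  }
  xs <- cover_seq(config$domain_size[1], config$grid_spacing)
  ys <- cover_seq(config$domain_size[2], config$grid_spacing)
  ts <- seq(0, config$duration, by = config$dt)
  vort <- vortex_schedule(config)
  if (is.null(boils)) boils <- boil_schedule(config)
  dm <- c(length(xs), length(ys), length(ts))
  u <- array(config$advection_speed, dm)
  v <- array(0, dm)
  curl <- array(0, dm)
  div <- array(0, dm)
  X <- matrix(xs, length(xs), length(ys))
  Y <- matrix(ys, length(xs), length(ys), byrow = TRUE)
  margin <- 4 * config$vortex_core_radius
  for (it in seq_along(ts)) {
    t <- ts[it]
    if (nrow(vort)) {
      live <- vort[vort$t_shed <= t, , drop = FALSE]
      if (nrow(live)) {
        xc <- config$advection_speed * (t - live$t_shed)
        keep <- xc > -margin & xc < config$domain_size[1] + margin
        live <- live[keep, , drop = FALSE]
        xc <- xc[keep]
        for (i in seq_len(nrow(live))) {
          dx <- X - xc[i]
          dy <- Y - live$y0[i]
          r <- sqrt(dx^2 + dy^2)
          ut <- live$sign[i] *
            lamb_oseen_utheta(r, config$vortex_strength,
                              config$vortex_core_radius)
          safe_r <- pmax(r, 1e-12)
          u[, , it] <- u[, , it] - ut * dy / safe_r
          v[, , it] <- v[, , it] + ut * dx / safe_r
          curl[, , it] <- curl[, , it] + live$sign[i] *
            lamb_oseen_vorticity(r, config$vortex_strength,
                                 config$vortex_core_radius)
        }
      }
    }
    if (nrow(boils)) {
      live <- boils[boils$t0 <= t &
                      t - boils$t0 < 6 * config$boil_decay_time, ,
                    drop = FALSE]
      for (i in seq_len(nrow(live))) {
        age <- t - live$t0[i]
        sigma <- config$boil_radius + config$boil_growth_rate * age
        peak <- config$boil_peak_divergence * exp(-age / config$boil_decay_time)
        dx <- X - live$x0[i]
        dy <- Y - live$y0[i]
        r <- sqrt(dx^2 + dy^2)
        ur <- boil_radial_velocity(r, peak, sigma)
        safe_r <- pmax(r, 1e-12)
        u[, , it] <- u[, , it] + ur * dx / safe_r
        v[, , it] <- v[, , it] + ur * dy / safe_r
        div[, , it] <- div[, , it] + boil_divergence(r, peak, sigma)
      }
    }
  }
  h <- config$grid_spacing
  curl_fd <- fd_derivative(v, h, 1) - fd_derivative(u, h, 2)
  div_fd <- fd_derivative(u, h, 1) + fd_derivative(v, h, 2)
  structure(
    list(flow = flow_stack(xs, ys, ts, u, v, NULL, curl, div),
         curl_fd = curl_fd, div_fd = div_fd,
         vortices = vort, boils = boils, config = config),
    class = "ground_truth_flow")
}

#' @export
print.ground_truth_flow <- function(x, ...) {
  cat("<ground_truth_flow>\n")
  print(x$flow)
  cat(sprintf("  %d vortices scheduled, %d boils\n",
              nrow(x$vortices), nrow(x$boils)))
  invisible(x)
}
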