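random_small_dataset <- function(T, seed, segments = 1) {
  set.seed(seed)
  tibble::tibble(
    track_id = sort(rep_len(seq_len(segments), T)),
    t = seq_len(T),
    speed = rgamma(T, 4, 1),
    log_tortuosity = rgamma(T, 2, 20),
    abs_curl = abs(rnorm(T, 0, 0.3)),
    divergence = rnorm(T, 0, 0.2))
}

random_params <- function(seed) {
  set.seed(seed + 1000)
  list(speed_mean = sort(runif(2, 2, 9)), speed_sd = runif(2, 0.5, 2),
       logtort_mean = sort(runif(2, 0.01, 0.2)), logtort_sd = runif(2, 0.01, 0.1),
       beta12 = rnorm(3, 0, 1), beta21 = rnorm(3, 0, 1))
}

# emission log-density matrix and chain inputs computed independently of
# the package internals, for the oracle
oracle_inputs <- function(ds, th) {
  shp <- function(m, s) (m / s)^2
  scl <- function(m, s) s^2 / m
  logb <- cbind(
    dgamma(ds$speed, shape = shp(th$speed_mean[1], th$speed_sd[1]),
           scale = scl(th$speed_mean[1], th$speed_sd[1]), log = TRUE) +
      dgamma(ds$log_tortuosity, shape = shp(th$logtort_mean[1], th$logtort_sd[1]),
             scale = scl(th$logtort_mean[1], th$logtort_sd[1]), log = TRUE),
    dgamma(ds$speed, shape = shp(th$speed_mean[2], th$speed_sd[2]),
           scale = scl(th$speed_mean[2], th$speed_sd[2]), log = TRUE) +
      dgamma(ds$log_tortuosity, shape = shp(th$logtort_mean[2], th$logtort_sd[2]),
             scale = scl(th$logtort_mean[2], th$logtort_sd[2]), log = TRUE))
  p12 <- plogis(th$beta12[1] + th$beta12[2] * ds$abs_curl +
                  th$beta12[3] * ds$divergence)
  p21 <- plogis(th$beta21[1] + th$beta21[2] * ds$abs_curl +
                  th$beta21[3] * ds$divergence)
  list(logb = logb, p12 = p12, p21 = p21)
}

test_that("the transition matrix is row-stochastic and saturates correctly", {
  expect_equal(transition_matrix(c(0, 0, 0), c(0, 0, 0)),
               matrix(0.5, 2, 2))
  set.seed(2)
  for (i in 1:20) {
    b12 <- rnorm(3); b21 <- rnorm(3); z <- rnorm(2)
    G <- transition_matrix(b12, b21, abs(z[1]), z[2])
    expect_equal(rowSums(G), c(1, 1), tolerance = 1e-12)
    expect_true(all(G > 0 & G < 1))
  }
  G <- transition_matrix(c(-20, 0, 0), c(0, 0, 0))
  expect_lt(G[1, 2], 1e-8)
})

test_that("a single observation gives the stationary-weighted mixture density", {
  ds <- random_small_dataset(1, 5)
  th <- random_params(5)
  io <- oracle_inputs(ds, th)
  d1 <- io$p21[1] / (io$p12[1] + io$p21[1])
  expected <- log(d1 * exp(io$logb[1, 1]) + (1 - d1) * exp(io$logb[1, 2]))
  got <- hmm_loglik(ds, th$speed_mean, th$speed_sd, th$logtort_mean,
                    th$logtort_sd, th$beta12, th$beta21)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("forward log-likelihood matches exhaustive enumeration for T <= 8", {
  for (seed in 1:6) {
    T <- sample(2:8, 1)
    ds <- random_small_dataset(T, seed)
    th <- random_params(seed)
    io <- oracle_inputs(ds, th)
    d1 <- io$p21[1] / (io$p12[1] + io$p21[1])
    oracle <- brute_force_loglik(io$logb, io$p12, io$p21, d1)
    got <- hmm_loglik(ds, th$speed_mean, th$speed_sd, th$logtort_mean,
                      th$logtort_sd, th$beta12, th$beta21)
    expect_lt(abs(got - oracle), 1e-10)
  }
})

test_that("the scaled forward pass agrees with an independent R recursion", {
  ds <- random_small_dataset(500, 77)
  th <- random_params(77)
  io <- oracle_inputs(ds, th)
  d1 <- io$p21[1] / (io$p12[1] + io$p21[1])
  expect_equal(hmm_loglik(ds, th$speed_mean, th$speed_sd, th$logtort_mean,
                          th$logtort_sd, th$beta12, th$beta21),
               forward_loglik_R(io$logb, io$p12, io$p21, d1),
               tolerance = 1e-9)
})

test_that("segment log-likelihoods add over independent tracks", {
  th <- random_params(9)
  ll_of <- function(ds) hmm_loglik(ds, th$speed_mean, th$speed_sd,
                                   th$logtort_mean, th$logtort_sd,
                                   th$beta12, th$beta21)
  a <- random_small_dataset(40, 1)
  b <- random_small_dataset(30, 2)
  b$track_id <- 2
  expect_equal(ll_of(dplyr::bind_rows(a, b)), ll_of(a) + ll_of(b),
               tolerance = 1e-10)
})

test_that("Viterbi matches exhaustive argmax for T <= 8", {
  fake_fit <- function(th) {
    shp <- function(m, s) (m / s)^2
    scl <- function(m, s) s^2 / m
    structure(list(
      emission = tibble::tibble(
        state = rep(1:2, 2),
        channel = rep(c("speed", "log_tortuosity"), each = 2),
        mean = c(th$speed_mean, th$logtort_mean),
        sd = c(th$speed_sd, th$logtort_sd),
        shape = c(shp(th$speed_mean, th$speed_sd),
                  shp(th$logtort_mean, th$logtort_sd)),
        scale = c(scl(th$speed_mean, th$speed_sd),
                  scl(th$logtort_mean, th$logtort_sd))),
      beta12 = setNames(th$beta12, c("(Intercept)", "abs_curl", "divergence")),
      beta21 = setNames(th$beta21, c("(Intercept)", "abs_curl", "divergence")),
      covariates = c("abs_curl", "divergence")),
      class = "ternflow_hmm")
  }
  for (seed in 1:6) {
    T <- sample(2:8, 1)
    ds <- random_small_dataset(T, seed + 50)
    th <- random_params(seed + 50)
    io <- oracle_inputs(ds, th)
    d1 <- io$p21[1] / (io$p12[1] + io$p21[1])
    oracle <- brute_force_viterbi(io$logb, io$p12, io$p21, d1)
    got <- hmm_viterbi(ds, fake_fit(th))
    expect_equal(got, unname(oracle))
  }
})

test_that("overwhelming emissions decode to the favoured constant path", {
  ds <- random_small_dataset(30, 3)
  ds$speed <- rgamma(30, shape = 400, scale = 0.01)  # tightly around 4
  th <- random_params(3)
  th$speed_mean <- c(4, 40); th$speed_sd <- c(0.2, 1)
  th$logtort_mean <- c(0.05, 0.05); th$logtort_sd <- c(0.05, 0.05)
  fit <- hmm_fit(ds, n_starts = 1, init = th, se = FALSE, maxit = 0)
  expect_true(all(hmm_viterbi(ds, fit) == 1))
})

test_that("stationary probabilities solve delta Gamma = delta", {
  st <- stationary_probabilities(c(qlogis(0.1), 0, 0), c(qlogis(0.3), 0, 0))
  expect_equal(st$pr_state1, 0.75, tolerance = 1e-12)
  st2 <- stationary_probabilities(c(0.4, 0.1, -0.2), c(0.4, 0.1, -0.2),
                                  abs_curl = 0.7, divergence = 0.1)
  expect_equal(st2$pr_state1, 0.5, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:10) {
    b12 <- rnorm(3); b21 <- rnorm(3); z <- c(abs(rnorm(1)), rnorm(1))
    st3 <- stationary_probabilities(b12, b21, z[1], z[2])
    delta <- c(st3$pr_state1, st3$pr_state2)
    G <- transition_matrix(b12, b21, z[1], z[2])
    expect_equal(as.vector(delta %*% G), delta, tolerance = 1e-12)
    expect_equal(sum(delta), 1, tolerance = 1e-12)
  }
  expect_error(stationary_probabilities(c(-800, 0, 0), c(-800, 0, 0)),
               "degenerate")
})

sim_emission_dataset <- function(seed, n_tracks = 30, dur = 60) {
  cfg <- trajectory_sim_config(
    n_tracks = n_tracks, rate = 30 / 11,
    duration_range = c(dur, dur),
    beta12 = c(-2, -1.5, -1.2), beta21 = c(-2.5, 1.5, 1.2),
    seed = seed)
  sim <- simulate_tracks(cfg)
  list(obs = sim$observations, cfg = cfg)
}

true_init <- function(cfg) {
  list(speed_mean = cfg$speed_mean, speed_sd = cfg$speed_sd,
       logtort_mean = cfg$logtort_mean, logtort_sd = cfg$logtort_sd,
       beta12 = cfg$beta12, beta21 = cfg$beta21)
}

test_that("optimization never falls below the likelihood of its own start", {
  d <- sim_emission_dataset(17, n_tracks = 10, dur = 40)
  th <- true_init(d$cfg)
  ll_truth <- hmm_loglik(d$obs, th$speed_mean, th$speed_sd, th$logtort_mean,
                         th$logtort_sd, th$beta12, th$beta21)
  fit <- hmm_fit(d$obs, n_starts = 1, init = th, se = FALSE)
  expect_gte(fit$loglik, ll_truth - 1e-6)
})

test_that("the fit is invariant to track order", {
  d <- sim_emission_dataset(23, n_tracks = 8, dur = 40)
  th <- true_init(d$cfg)
  fit1 <- hmm_fit(d$obs, n_starts = 1, init = th, se = FALSE)
  perm <- d$obs %>% dplyr::arrange(dplyr::desc(track_id), t)
  fit2 <- hmm_fit(perm, n_starts = 1, init = th, se = FALSE)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-6)
  expect_equal(fit1$emission$mean, fit2$emission$mean, tolerance = 1e-5)
})

test_that("fitting recovers emission parameters and slope signs", {
  d <- sim_emission_dataset(31, n_tracks = 40, dur = 60)
  fit <- hmm_fit(d$obs, n_starts = 3, seed = 2)
  cfg <- d$cfg
  sp <- fit$emission$mean[fit$emission$channel == "speed"]
  expect_lt(abs(sp[1] - cfg$speed_mean[1]) / cfg$speed_mean[1], 0.08)
  expect_lt(abs(sp[2] - cfg$speed_mean[2]) / cfg$speed_mean[2], 0.08)
  expect_lt(fit$beta12[["abs_curl"]], 0)
  expect_gt(fit$beta21[["abs_curl"]], 0)
  expect_true(all(fit$decoded %in% 1:2))
  acc <- mean(fit$decoded == d$obs$state_true)
  expect_gt(acc, 0.85)
})

test_that("state relabelling keeps state 1 as the slower state", {
  d <- sim_emission_dataset(37, n_tracks = 10, dur = 40)
  # start deliberately label-swapped
  th <- true_init(d$cfg)
  th_sw <- list(speed_mean = rev(th$speed_mean), speed_sd = rev(th$speed_sd),
                logtort_mean = rev(th$logtort_mean),
                logtort_sd = rev(th$logtort_sd),
                beta12 = th$beta21, beta21 = th$beta12)
  fit <- hmm_fit(d$obs, n_starts = 1, init = th_sw, se = FALSE)
  sp <- fit$emission$mean[fit$emission$channel == "speed"]
  expect_lt(sp[1], sp[2])
})

test_that("the homogeneous model is recovered when covariates are dropped", {
  d <- sim_emission_dataset(41, n_tracks = 10, dur = 40)
  fit0 <- hmm_fit(d$obs, covariates = character(0), n_starts = 2, seed = 1,
                  se = FALSE)
  expect_equal(fit0$n_par, 10)
  expect_equal(length(fit0$beta12), 1)
  fit2 <- hmm_fit(d$obs, n_starts = 2, seed = 1, se = FALSE)
  expect_equal(fit2$n_par, 14)
  # the richer model can only improve the maximized likelihood
  expect_gte(fit2$loglik, fit0$loglik - 1e-6)
})

test_that("AIC bookkeeping is consistent in the comparison table", {
  d <- sim_emission_dataset(43, n_tracks = 8, dur = 30)
  tb <- compare_models(d$obs, n_starts = 2, seed = 3, se = FALSE)
  expect_setequal(tb$model, c("full", "no_divergence", "no_abs_curl", "none"))
  expect_equal(tb$k[tb$model == "full"], 14)
  expect_equal(tb$k[tb$model == "no_divergence"], 12)
  expect_equal(tb$k[tb$model == "none"], 10)
  expect_equal(tb$aic, 2 * tb$k - 2 * tb$loglik, tolerance = 1e-10)
  expect_equal(min(tb$delta_aic), 0)
})

test_that("tidy and glance expose the fit in broom style", {
  d <- sim_emission_dataset(47, n_tracks = 8, dur = 30)
  fit <- hmm_fit(d$obs, n_starts = 1, init = true_init(d$cfg))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_equal(nrow(td), 8 + 6)
  expect_true(any(!is.na(td$std.error)))
  gl <- glance(fit)
  expect_equal(gl$AIC, fit$aic)
  expect_equal(gl$n_obs, nrow(d$obs))
})

test_that("fits serialize to JSON and back at full precision", {
  d <- sim_emission_dataset(53, n_tracks = 6, dur = 30)
  fit <- hmm_fit(d$obs, n_starts = 1, init = true_init(d$cfg), se = FALSE)
  path <- tempfile(fileext = ".json")
  write_hmm_json(fit, path)
  back <- read_hmm_json(path)
  expect_identical(back$loglik, fit$loglik)
  expect_equal(back$beta12, fit$beta12)
  expect_equal(back$decoded, fit$decoded)
  expect_equal(back$emission$mean, fit$emission$mean)
})

test_that("stationary curves respond monotonically to opposite-signed slopes", {
  b12 <- c(-2, -1.5, 0); b21 <- c(-2.5, 1.5, 0)
  z <- seq(0, 1, by = 0.1)
  st <- stationary_probabilities(b12, b21, abs_curl = z, divergence = 0)
  expect_true(all(diff(st$pr_state1) > 0))
})
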