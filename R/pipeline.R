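#' Write / read tracks (and observation datasets) as CSV
#'
#' @param x a tibble.
#' @param path file path.
#' @return The path (writer, invisibly) or the tibble (reader).
#' @export
write_tracks_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Serialize / restore a fitted HMM as JSON
#'
#' Numbers are written at full precision so the log-likelihood round-trips
#' exactly.
#'
#' @param fit a `ternflow_hmm`.
#' @param path file path.
#' @return `write_hmm_json` returns `path` invisibly; `read_hmm_json`
#'   a `ternflow_hmm` (without the working-scale covariance).
#' @export
write_hmm_json <- function(fit, path) {
  payload <- list(
    emission = fit$emission,
    beta12 = as.list(fit$beta12), beta21 = as.list(fit$beta21),
    beta_se = fit$beta_se, covariates = fit$covariates,
    loglik = fit$loglik, n_par = fit$n_par, aic = fit$aic,
    n_obs = fit$n_obs, convergence = fit$convergence,
    decoded = fit$decoded)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(emission = tibble::as_tibble(p$emission),
         beta12 = unlist(p$beta12), beta21 = unlist(p$beta21),
         beta_se = if (is.null(p$beta_se)) NULL else
           lapply(p$beta_se, unlist),
         covariates = p$covariates %||% character(0),
         loglik = p$loglik, n_par = p$n_par, aic = p$aic,
         n_obs = p$n_obs,
         convergence = p$convergence,
         decoded = as.integer(p$decoded),
         cov_center = NULL, cov_scale = NULL, vcov_working = NULL),
    class = "ternflow_hmm")
}

#' Default end-to-end pipeline configuration
#'
#' Nested per-stage configurations with a single root seed expanded into
#' named substreams; every stage is pure given its inputs and seed.
#'
#' @param seed root seed.
#' @param use_video run the rendered-video / PIV / detection path
#'   (slower); otherwise the kinematic simulator's tracks and the analytic
#'   flow are used directly.
#' @param flow a [flow_sim_config()].
#' @param tracks a [trajectory_sim_config()].
#' @param piv a [piv_config()].
#' @param camera a [camera_model()].
#' @param subsample_hz if non-`NULL`, subsample the kinematic series to
#'   this rate before fitting (e.g. `30/11` to decorrelate the smoothing
#'   windows).
#' @param d_curl,d_div covariate delays (s) used for the fit.
#' @param n_starts random starts for the HMM fit.
#' @param min_duration,min_tortuosity track filters applied to tracks
#'   recovered from video (defaults: 15 s, 1.1; set to 0/1 to keep all).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, use_video = FALSE,
                            flow = flow_sim_config(seed = seed),
                            tracks = trajectory_sim_config(
                              mode = "kinematic", seed = seed),
                            piv = piv_config(),
                            camera = camera_model(),
                            subsample_hz = NULL,
                            d_curl = 0.25, d_div = 2,
                            n_starts = 5,
                            min_duration = 15, min_tortuosity = 1.1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the simulate -> measure -> match -> fit workflow
#'
#' Simulates flow and behaviour-switching tracks, optionally renders video
#' and recovers flow/tracks from it (PIV + detection + Kalman tracking),
#' computes spline-window kinematics, attaches flow covariates at the
#' configured delays, fits the covariate HMM and reports the AIC table and
#' decoded states.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage artifacts (tracks
#'   CSV, observation CSV, flow CSV, model JSON) are persisted there.
#' @return A list of class `pipeline_result`: `flow`, `tracks`,
#'   `kinematics`, `observations`, `fit`, `aic_table`, `truth`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  gt <- simulate_flow(config$flow)
  sim <- simulate_tracks(config$tracks, flow = gt)
  truth <- sim$observations
  if (config$use_video) {
    video <- render_video(gt, sim$tracks, config$camera,
                          seed = substream_seed(config$seed, "render"))
    piv_cfg <- config$piv
    piv_cfg$ground_sample_distance <- config$camera$gsd
    piv_cfg$frame_rate <- config$camera$frame_rate
    stack <- piv_sequence(frames_channel(video, "green"), piv_cfg)
    det <- detect_targets(video)
    det <- classify_detections(det, NULL)
    px_tracks <- track_targets(det, track_config(
      rate = config$camera$frame_rate))
    tracks <- geo_correct(px_tracks, config$camera)
    tracks <- tracks[, c("track_id", "t", "x", "y", "provenance")]
    tracks <- filter_tracks(tracks, config$min_duration,
                            config$min_tortuosity)
  } else {
    stack <- gt$flow
    tracks <- sim$tracks
  }
  kin <- track_kinematics(tracks, rate = config$tracks$rate)
  if (!is.null(config$subsample_hz)) {
    kin <- subsample_series(kin, config$subsample_hz)
  }
  obs <- attach_covariates(kin, stack, config$d_curl, config$d_div)
  obs <- covariate_policy(obs, "drop")
  fit <- hmm_fit(obs, n_starts = config$n_starts,
                 seed = substream_seed(config$seed, "fit"))
  aic_tab <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tracks_csv(tracks, file.path(out_dir, "tracks.csv"))
    write_tracks_csv(obs, file.path(out_dir, "observations.csv"))
    write_flow_csv(stack, file.path(out_dir, "flow.csv"))
    write_hmm_json(fit, file.path(out_dir, "model.json"))
  }
  structure(list(flow = stack, tracks = tracks, kinematics = kin,
                 observations = obs, fit = fit, aic_table = aic_tab,
                 truth = truth, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d tracks, %d observations\n",
              dplyr::n_distinct(x$tracks$track_id), nrow(x$observations)))
  print(x$fit)
  invisible(x)
}
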