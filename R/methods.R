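#' Tidy a fitted two-state covariate HMM
#'
#' Returns one row per estimated quantity: gamma emission means/sds per
#' state and channel, and transition coefficients (with standard errors
#' where available) per transition and covariate term.
#'
#' @param x a `ternflow_hmm` from [hmm_fit()].
#' @param ... unused.
#' @return A tibble: `term`, `estimate`, `std.error`.
#' @export
tidy.ternflow_hmm <- function(x, ...) {
  em <- x$emission
  em_rows <- tibble::tibble(
    term = paste0(em$channel, "_mean_state", em$state),
    estimate = em$mean, std.error = NA_real_)
  em_sd <- tibble::tibble(
    term = paste0(em$channel, "_sd_state", em$state),
    estimate = em$sd, std.error = NA_real_)
  nm <- names(x$beta12)
  b_rows <- tibble::tibble(
    term = c(paste0("beta[1->2] ", nm), paste0("beta[2->1] ", nm)),
    estimate = c(unname(x$beta12), unname(x$beta21)),
    std.error = if (is.null(x$beta_se)) NA_real_
                else c(x$beta_se$beta12, x$beta_se$beta21))
  dplyr::bind_rows(em_rows, em_sd, b_rows)
}

#' One-row summary of a fitted HMM
#'
#' @param x a `ternflow_hmm`.
#' @param ... unused.
#' @return A tibble with `logLik`, `AIC`, `n_par`, `n_obs`, `n_converged`,
#'   `n_starts`.
#' @export
glance.ternflow_hmm <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, n_par = x$n_par,
                 n_obs = x$n_obs,
                 n_converged = x$convergence$n_converged,
                 n_starts = x$convergence$n_starts)
}

#' Plot state-dependent emission distributions over the data
#'
#' Histograms of observed speed and log-tortuosity overlaid with the
#' fitted gamma state-dependent densities, weighted by decoded state
#' occupancy (the standard display for movement HMMs).
#'
#' @param object a `ternflow_hmm`.
#' @param dataset the observation tibble the model was fitted to.
#' @param bins histogram bins.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ternflow_hmm <- function(object, dataset, bins = 40, ...) {
  occ <- tabulate(object$decoded, 2) / length(object$decoded)
  obs <- dataset %>%
    dplyr::select(dplyr::all_of(c("speed", "log_tortuosity"))) %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "channel",
                        values_to = "value")
  dens <- purrr::pmap_dfr(object$emission, function(state, channel, shape,
                                                    scale, ...) {
    xs <- seq(1e-6, max(obs$value[obs$channel == channel]),
              length.out = 200)
    tibble::tibble(state = state, channel = channel, value = xs,
                   density = occ[state] *
                     dgamma(xs, shape = shape, scale = scale))
  })
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85",
                            colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = factor(.data$state)),
                       linewidth = 0.9) +
    ggplot2::facet_wrap(~channel, scales = "free") +
    ggplot2::scale_colour_manual(
      values = c(`1` = "#E69F00", `2` = "#0072B2"),
      labels = c("active (1)", "transit (2)"), name = "state") +
    ggplot2::labs(x = NULL, y = "density") +
    ggplot2::theme_minimal()
}

#' Plot transition and stationary probabilities against a covariate
#'
#' @param fit a `ternflow_hmm`.
#' @param covariate which covariate to vary (the other is held at
#'   `at`).
#' @param range numeric length-2 covariate range (default: a plausible
#'   span around zero).
#' @param at fixed value of the other covariate.
#' @return A ggplot object with switching and stationary probability
#'   curves.
#' @export
plot_stationary <- function(fit, covariate = c("abs_curl", "divergence"),
                            range = c(0, 1), at = 0) {
  covariate <- match.arg(covariate)
  z <- seq(range[1], range[2], length.out = 200)
  ac <- if (covariate == "abs_curl") z else rep(at, length(z))
  dv <- if (covariate == "divergence") z else rep(at, length(z))
  b12 <- beta_for(fit, "beta12"); b21 <- beta_for(fit, "beta21")
  st <- stationary_probabilities(b12, b21, ac, dv)
  sw <- switching_probabilities(b12, b21, ac, dv)
  nz <- length(z)
  df <- tibble::tibble(
    z = rep(z, 4),
    prob = c(sw$p12, sw$p21, st$pr_state1, st$pr_state2),
    what = rep(c("Pr(1->2)", "Pr(2->1)", "Pr(state 1)", "Pr(state 2)"),
               each = nz),
    panel = rep(c("switching", "switching", "stationary", "stationary"),
                each = nz))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$prob,
                                   colour = .data$what)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = paste0(covariate, " (1/s)"), y = "probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

# expand a fit's coefficient vector onto the (abs_curl, divergence) basis,
# zero-filling covariates the model did not use
beta_for <- function(fit, which) {
  b <- fit[[which]]
  out <- c(b[["(Intercept)"]], 0, 0)
  if ("abs_curl" %in% names(b)) out[2] <- b[["abs_curl"]]
  if ("divergence" %in% names(b)) out[3] <- b[["divergence"]]
  out
}

#' Plot the log-likelihood surface of a delay grid search
#'
#' @param scan tibble from [delay_grid_search()].
#' @return A ggplot tile plot with the optimum marked.
#' @export
plot_delay_surface <- function(scan) {
  opt <- attr(scan, "optimum")
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$d_curl, y = .data$d_div,
                                     fill = .data$loglik)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = opt, ggplot2::aes(x = .data$d_curl,
                                                 y = .data$d_div),
                        inherit.aes = FALSE, shape = 4, size = 3,
                        colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "logL") +
    ggplot2::labs(x = "|curl| delay (s)", y = "divergence delay (s)") +
    ggplot2::theme_minimal()
}
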