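#' Covariate-dependent transition matrix of the two-state chain
#'
#' `logit(Pr(1 -> 2)) = beta12[1] + beta12[2] * |curl| + beta12[3] * div`
#' and symmetrically for 2 -> 1; diagonals complete the rows to one.
#'
#' @param beta12,beta21 length-3 coefficient vectors.
#' @param abs_curl,divergence scalar covariate values.
#' @return A 2 x 2 row-stochastic matrix.
#' @export
transition_matrix <- function(beta12, beta21, abs_curl = 0, divergence = 0) {
  p <- switching_probabilities(beta12, beta21, abs_curl, divergence)
  matrix(c(1 - p$p12, p$p21, p$p12, 1 - p$p21), 2, 2)
}

#' Stationary distribution of the chain at fixed covariate values
#'
#' Closed form for two states: `Pr(1) = p21 / (p12 + p21)`.
#'
#' @param beta12,beta21 length-3 coefficient vectors (or pass an
#'   `hmm_fit`'s coefficients).
#' @param abs_curl,divergence covariate vectors (recycled to equal length).
#' @return A tibble: `abs_curl`, `divergence`, `pr_state1`, `pr_state2`.
#' @export
stationary_probabilities <- function(beta12, beta21, abs_curl = 0,
                                     divergence = 0) {
  n <- max(length(abs_curl), length(divergence))
  abs_curl <- rep_len(abs_curl, n); divergence <- rep_len(divergence, n)
  p <- switching_probabilities(beta12, beta21, abs_curl, divergence)
  tot <- p$p12 + p$p21
  if (any(tot < 1e-300)) {
    stop("degenerate (absorbing) chain: p12 + p21 is numerically zero",
         call. = FALSE)
  }
  tibble::tibble(abs_curl = abs_curl, divergence = divergence,
                 pr_state1 = p$p21 / tot, pr_state2 = p$p12 / tot)
}

# ---- internal parametrization -------------------------------------------
# working vector: log-shape, log-scale for (state x channel) in the order
# (s1 speed, s2 speed, s1 logtort, s2 logtort), then beta12, beta21 on the
# (possibly standardized) covariate scale. p = number of covariates.

hmm_par_pack <- function(emission, beta12, beta21) {
  c(log(emission$shape), log(emission$scale), beta12, beta21)
}

hmm_par_unpack <- function(par, p) {
  shape <- exp(par[1:4]); scale <- exp(par[5:8])
  list(emission = list(shape = shape, scale = scale),
       beta12 = par[9:(9 + p)], beta21 = par[(10 + p):(10 + 2 * p)])
}

emission_ms_to_ss <- function(mean, sd) {
  list(shape = (mean / sd)^2, scale = sd^2 / mean)
}

emission_ss_to_ms <- function(shape, scale) {
  list(mean = shape * scale, sd = sqrt(shape) * scale)
}

# precomputed per-observation statistics for fast gamma log-densities
hmm_emission_data <- function(speed, log_tort) {
  sp <- pmax(speed, 1e-12); lt <- pmax(log_tort, 1e-12)
  list(sp = sp, lt = lt, log_sp = log(sp), log_lt = log(lt))
}

# gamma log-density from sufficient statistics:
# (shape-1) log x - x/scale - shape log scale - lgamma(shape)
gamma_logpdf_pre <- function(x, logx, shape, scale) {
  (shape - 1) * logx - x / scale - shape * log(scale) - lgamma(shape)
}

# log emission density matrix (T x 2): independent gamma laws for speed and
# log-tortuosity given the state
hmm_log_emissions_pre <- function(ed, em) {
  cbind(
    gamma_logpdf_pre(ed$sp, ed$log_sp, em$shape[1], em$scale[1]) +
      gamma_logpdf_pre(ed$lt, ed$log_lt, em$shape[3], em$scale[3]),
    gamma_logpdf_pre(ed$sp, ed$log_sp, em$shape[2], em$scale[2]) +
      gamma_logpdf_pre(ed$lt, ed$log_lt, em$shape[4], em$scale[4]))
}

hmm_log_emissions <- function(speed, log_tort, em) {
  hmm_log_emissions_pre(hmm_emission_data(speed, log_tort), em)
}

hmm_segments <- function(dataset) {
  seg <- if ("segment" %in% names(dataset)) dataset$segment
         else dataset$track_id
  seg <- as.character(seg)
  changes <- c(TRUE, seg[-1] != seg[-length(seg)])
  seg_start <- which(changes)
  seg_end <- c(seg_start[-1] - 1L, length(seg))
  list(start = as.integer(seg_start), end = as.integer(seg_end))
}

# per-step transition probabilities and per-segment initial distributions
hmm_chain_inputs <- function(Z, beta12, beta21, segs) {
  n <- nrow(Z)
  eta12 <- beta12[1] + if (ncol(Z)) drop(Z %*% beta12[-1]) else rep(0, n)
  eta21 <- beta21[1] + if (ncol(Z)) drop(Z %*% beta21[-1]) else rep(0, n)
  p12 <- expit(eta12); p21 <- expit(eta21)
  tot <- pmax(p12[segs$start] + p21[segs$start], 1e-300)
  init1 <- p21[segs$start] / tot
  list(p12 = p12, p21 = p21, init1 = init1)
}

#' Forward-algorithm log-likelihood of the covariate HMM
#'
#' Scaled forward recursion per contiguous likelihood segment; the initial
#' state distribution of each segment is the stationary distribution at
#' the segment's first covariate values; segment log-likelihoods add.
#'
#' @param dataset observation tibble with `speed`, `log_tortuosity`,
#'   covariate columns, and `track_id` (and optionally `segment`).
#' @param speed_mean,speed_sd,logtort_mean,logtort_sd length-2 per-state
#'   gamma parameters.
#' @param beta12,beta21 transition coefficients, length `1 + p` where `p`
#'   is the number of covariates used.
#' @param covariates character vector of covariate column names (default
#'   `c("abs_curl", "divergence")`; may be empty for the homogeneous
#'   model).
#' @return The log-likelihood (scalar).
#' @export
hmm_loglik <- function(dataset, speed_mean, speed_sd, logtort_mean,
                       logtort_sd, beta12, beta21,
                       covariates = c("abs_curl", "divergence")) {
  assert_positive(c(speed_mean, speed_sd, logtort_mean, logtort_sd),
                  "gamma parameters")
  if (any(dataset$speed <= 0) || any(dataset$log_tortuosity <= 0)) {
    stop("emissions require strictly positive observations", call. = FALSE)
  }
  sh <- emission_ms_to_ss(c(speed_mean, logtort_mean),
                          c(speed_sd, logtort_sd))
  em <- list(shape = sh$shape, scale = sh$scale)
  logb <- hmm_log_emissions(dataset$speed, dataset$log_tortuosity, em)
  Z <- as.matrix(dataset[, covariates, drop = FALSE])
  segs <- hmm_segments(dataset)
  ch <- hmm_chain_inputs(Z, beta12, beta21, segs)
  forward_loglik_cpp(logb, ch$p12, ch$p21, segs$start, segs$end, ch$init1)
}

# objective on the working scale (standardized covariates)
hmm_negloglik_working <- function(par, logb_fn, Z, segs, n_cov) {
  if (any(!is.finite(par)) || any(abs(par[1:8]) > 40)) return(1e10)
  th <- hmm_par_unpack(par, n_cov)
  logb <- logb_fn(th$emission)
  ch <- hmm_chain_inputs(Z, th$beta12, th$beta21, segs)
  ll <- forward_loglik_cpp(logb, ch$p12, ch$p21, segs$start, segs$end,
                          ch$init1)
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit the two-state covariate HMM by multi-start maximum likelihood
#'
#' Maximizes the forward log-likelihood over unconstrained working
#' parameters (log gamma shape/scale; identity for the transition
#' coefficients) by BFGS from `n_starts` randomized initializations.
#' Covariates are standardized internally for optimization and the
#' coefficients reported on the original scale; states are relabelled so
#' state 1 has the lower mean speed.
#'
#' @param dataset observation tibble (see [hmm_loglik()]).
#' @param covariates covariate column names entering the transition model
#'   (possibly empty: homogeneous chain).
#' @param n_starts number of random starts (default 25).
#' @param seed integer seed for the starts.
#' @param init optional list with `speed_mean`, `speed_sd`,
#'   `logtort_mean`, `logtort_sd`, `beta12`, `beta21` used as the first
#'   start (original covariate scale).
#' @param se compute standard errors from the numerical Hessian at the
#'   optimum (default TRUE).
#' @param maxit BFGS iteration cap per start.
#' @return An object of class `ternflow_hmm`.
#' @export
hmm_fit <- function(dataset, covariates = c("abs_curl", "divergence"),
                    n_starts = 25, seed = 1L, init = NULL, se = TRUE,
                    maxit = 300) {
  stopifnot(all(c("speed", "log_tortuosity") %in% names(dataset)),
            all(covariates %in% names(dataset)))
  if (any(dataset$speed <= 0) || any(dataset$log_tortuosity <= 0)) {
    stop("emissions require strictly positive observations", call. = FALSE)
  }
  p <- length(covariates)
  Zraw <- as.matrix(dataset[, covariates, drop = FALSE])
  zm <- if (p) colMeans(Zraw) else numeric(0)
  zs <- if (p) pmax(apply(Zraw, 2, sd), 1e-12) else numeric(0)
  Z <- if (p) sweep(sweep(Zraw, 2, zm), 2, zs, "/") else Zraw
  segs <- hmm_segments(dataset)
  sp <- dataset$speed; lt <- dataset$log_tortuosity
  ed <- hmm_emission_data(sp, lt)
  logb_fn <- function(em) hmm_log_emissions_pre(ed, em)

  # moment-based centre for the starts: median split on speed
  med <- median(sp)
  g1 <- sp <= med; g2 <- !g1
  base <- list(
    speed_mean = c(mean(sp[g1]), mean(sp[g2])),
    speed_sd = c(max(sd(sp[g1]), 1e-3), max(sd(sp[g2]), 1e-3)),
    logtort_mean = c(mean(lt[g1]), mean(lt[g2])),
    logtort_sd = c(max(sd(lt[g1]), 1e-4), max(sd(lt[g2]), 1e-4)),
    beta12 = c(logit(0.1), rep(0, p)),
    beta21 = c(logit(0.1), rep(0, p)))
  par_from <- function(th, standardized = FALSE) {
    b12 <- th$beta12; b21 <- th$beta21
    if (!standardized && p) {
      # original -> standardized coefficient scale
      b12 <- c(b12[1] + sum(b12[-1] * zm), b12[-1] * zs)
      b21 <- c(b21[1] + sum(b21[-1] * zm), b21[-1] * zs)
    }
    sh <- emission_ms_to_ss(c(th$speed_mean, th$logtort_mean),
                            c(th$speed_sd, th$logtort_sd))
    hmm_par_pack(list(shape = sh$shape, scale = sh$scale), b12, b21)
  }
  par0 <- par_from(init %||% base)
  set.seed(substream_seed(seed, "hmm_starts"))
  starts <- list(par0)
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- par0 + rnorm(length(par0), 0,
                                      c(rep(0.3, 8), rep(0.7, 2 * (p + 1))))
    }
  }
  best <- NULL; n_conv <- 0L
  for (s in starts) {
    fitres <- tryCatch(
      optim(s, hmm_negloglik_working, logb_fn = logb_fn, Z = Z,
            segs = segs, n_cov = p, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fitres) || !is.finite(fitres$value)) next
    if (fitres$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fitres$value < best$value) best <- fitres
  }
  if (is.null(best)) {
    stop("all optimization starts failed to produce a finite likelihood",
         call. = FALSE)
  }
  vc_work <- NULL
  if (se) {
    H <- tryCatch(
      stats::optimHess(best$par, hmm_negloglik_working, logb_fn = logb_fn,
                       Z = Z, segs = segs, n_cov = p),
      error = function(e) NULL)
    if (!is.null(H)) {
      vc_work <- tryCatch(solve(H), error = function(e) NULL)
    }
  }
  build_hmm_fit(best, vc_work, dataset, covariates, zm, zs, p, n_conv,
                length(starts))
}

# assemble the user-facing fit object: de-standardize, relabel, decode
build_hmm_fit <- function(best, vc_work, dataset, covariates, zm, zs, p,
                          n_conv, n_starts) {
  th <- hmm_par_unpack(best$par, p)
  ms <- emission_ss_to_ms(th$emission$shape, th$emission$scale)
  # standardized -> original coefficient scale
  destd <- function(b) {
    if (!p) return(b)
    c(b[1] - sum(b[-1] * zm / zs), b[-1] / zs)
  }
  beta12 <- destd(th$beta12); beta21 <- destd(th$beta21)
  # linear map standardized -> original for the delta method
  J_beta <- function() {
    J <- diag(1 + p)
    if (p) {
      J[1, -1] <- -zm / zs
      for (j in seq_len(p)) J[1 + j, 1 + j] <- 1 / zs[j]
    }
    J
  }
  swap <- ms$mean[1] > ms$mean[2]
  ord_em <- if (swap) c(2, 1, 4, 3) else 1:4
  if (swap) { tmp <- beta12; beta12 <- beta21; beta21 <- tmp }
  emission <- tibble::tibble(
    state = rep(1:2, 2),
    channel = rep(c("speed", "log_tortuosity"), each = 2),
    mean = unname(ms$mean[ord_em]), sd = unname(ms$sd[ord_em]),
    shape = unname(th$emission$shape[ord_em]),
    scale = unname(th$emission$scale[ord_em]))
  beta_se <- NULL
  if (!is.null(vc_work)) {
    Jb <- J_beta()
    i12 <- 9:(9 + p); i21 <- (10 + p):(10 + 2 * p)
    if (swap) { tmp <- i12; i12 <- i21; i21 <- tmp }
    se12 <- sqrt(pmax(diag(Jb %*% vc_work[i12, i12] %*% t(Jb)), 0))
    se21 <- sqrt(pmax(diag(Jb %*% vc_work[i21, i21] %*% t(Jb)), 0))
    beta_se <- list(beta12 = se12, beta21 = se21)
  }
  ll <- -best$value
  k <- 8 + 2 * (1 + p)
  fit <- structure(
    list(emission = emission,
         beta12 = setNames(beta12, c("(Intercept)", covariates)),
         beta21 = setNames(beta21, c("(Intercept)", covariates)),
         beta_se = beta_se,
         covariates = covariates,
         loglik = ll, n_par = k, aic = 2 * k - 2 * ll,
         n_obs = nrow(dataset),
         convergence = list(n_converged = n_conv, n_starts = n_starts,
                            code = best$convergence),
         cov_center = zm, cov_scale = zs,
         vcov_working = vc_work),
    class = "ternflow_hmm")
  fit$decoded <- hmm_viterbi(dataset, fit)
  fit
}

#' @export
print.ternflow_hmm <- function(x, ...) {
  cat(sprintf("<ternflow_hmm> 2 states, %d obs, logL = %.3f, AIC = %.2f\n",
              x$n_obs, x$loglik, x$aic))
  cat("emission (gamma mean/sd):\n")
  print(as.data.frame(x$emission[, c("state", "channel", "mean", "sd")]),
        row.names = FALSE)
  cat("transitions (logit scale):\n")
  print(rbind(`1->2` = x$beta12, `2->1` = x$beta21))
  invisible(x)
}

#' Viterbi decoding of the most probable state path
#'
#' Global argmax path per likelihood segment; ties broken toward state 1.
#'
#' @param dataset observation tibble used for (or compatible with) the fit.
#' @param fit a `ternflow_hmm`.
#' @return Integer vector of decoded states (1 or 2), one per observation.
#' @export
hmm_viterbi <- function(dataset, fit) {
  em_tab <- fit$emission
  getp <- function(ch) {
    i <- order(em_tab$state[em_tab$channel == ch])
    list(shape = em_tab$shape[em_tab$channel == ch][i],
         scale = em_tab$scale[em_tab$channel == ch][i])
  }
  spp <- getp("speed"); ltp <- getp("log_tortuosity")
  em <- list(shape = c(spp$shape, ltp$shape),
             scale = c(spp$scale, ltp$scale))
  logb <- hmm_log_emissions(dataset$speed, dataset$log_tortuosity, em)
  Z <- as.matrix(dataset[, fit$covariates, drop = FALSE])
  segs <- hmm_segments(dataset)
  ch <- hmm_chain_inputs(Z, fit$beta12, fit$beta21, segs)
  as.integer(viterbi_cpp(logb, ch$p12, ch$p21, segs$start, segs$end,
                         ch$init1))
}

#' AIC comparison of nested covariate specifications
#'
#' Fits the full model and reduced models with each covariate (or both)
#' dropped from both transition equations, and tabulates k, log-likelihood,
#' AIC and the AIC difference to the best model.
#'
#' @param dataset observation tibble.
#' @param specs named list of covariate vectors; defaults to the standard
#'   four: both covariates, no divergence, no |curl|, none.
#' @param n_starts,seed passed to [hmm_fit()].
#' @param ... further arguments to [hmm_fit()].
#' @return A tibble: `model`, `k`, `loglik`, `aic`, `delta_aic`, with the
#'   fits in an attribute `fits`.
#' @export
compare_models <- function(dataset, ...,
                           specs = list(
                             full = c("abs_curl", "divergence"),
                             no_divergence = "abs_curl",
                             no_abs_curl = "divergence",
                             none = character(0)),
                           n_starts = 10, seed = 1L) {
  fits <- lapply(seq_along(specs), function(i) {
    hmm_fit(dataset, covariates = specs[[i]], n_starts = n_starts,
            seed = substream_seed(seed, names(specs)[i]), ...)
  })
  names(fits) <- names(specs)
  tb <- tibble::tibble(
    model = names(specs),
    k = vapply(fits, function(f) f$n_par, numeric(1), USE.NAMES = FALSE),
    loglik = vapply(fits, function(f) f$loglik, numeric(1),
                    USE.NAMES = FALSE),
    aic = vapply(fits, function(f) f$aic, numeric(1), USE.NAMES = FALSE))
  tb$delta_aic <- tb$aic - min(tb$aic)
  attr(tb, "fits") <- fits
  tb
}

#' Scan time-to-contact delay pairs by maximum log-likelihood
#'
#' For each `(d_curl, d_div)` pair the observation dataset is rebuilt from
#' the kinematic series and flow fields via [attach_covariates()] (with the
#' common truncation horizon `max_delay`, so observation counts match
#' across the grid) and the HMM refitted; neighbouring fits warm-start each
#' other along the scan.
#'
#' @param kinematics kinematic series tibble (with `x`, `y` positions
#'   and `speed`, `log_tortuosity` observations).
#' @param stack a [flow_stack()] with curl and divergence.
#' @param delays_curl,delays_div numeric vectors of delays (s); the full
#'   field grid is `seq(0, 5, by = 0.25)` for each covariate.
#' @param n_starts random starts per fit (warm starts are added on top).
#' @param seed integer seed.
#' @param max_delay truncation horizon (default: max of the scanned
#'   delays).
#' @param policy missing-covariate policy (see [covariate_policy()]).
#' @param ... further arguments to [hmm_fit()].
#' @return A tibble `d_curl`, `d_div`, `loglik`, `aic`, `n_obs`, with the
#'   best pair in attribute `optimum`.
#' @export
delay_grid_search <- function(kinematics, stack,
                              delays_curl = seq(0, 5, by = 0.25),
                              delays_div = seq(0, 5, by = 0.25), ...,
                              n_starts = 3, seed = 1L,
                              max_delay = NULL, policy = "drop") {
  stopifnot(all(delays_curl >= 0), all(delays_curl <= 5),
            all(delays_div >= 0), all(delays_div <= 5))
  max_delay <- max_delay %||% max(delays_curl, delays_div)
  grid <- expand.grid(d_curl = delays_curl, d_div = delays_div,
                      KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(grid))
  warm <- NULL
  for (i in seq_len(nrow(grid))) {
    ds <- attach_covariates(kinematics, stack, grid$d_curl[i], grid$d_div[i],
                            max_delay = max_delay)
    ds <- covariate_policy(ds, policy)
    fit <- hmm_fit(ds, n_starts = n_starts,
                   seed = substream_seed(seed, paste0("scan", i)),
                   init = warm, ...)
    warm <- list(speed_mean = fit$emission$mean[fit$emission$channel == "speed"],
                 speed_sd = fit$emission$sd[fit$emission$channel == "speed"],
                 logtort_mean = fit$emission$mean[
                   fit$emission$channel == "log_tortuosity"],
                 logtort_sd = fit$emission$sd[
                   fit$emission$channel == "log_tortuosity"],
                 beta12 = unname(fit$beta12), beta21 = unname(fit$beta21))
    res[[i]] <- tibble::tibble(d_curl = grid$d_curl[i],
                               d_div = grid$d_div[i],
                               loglik = fit$loglik, aic = fit$aic,
                               n_obs = fit$n_obs)
  }
  out <- dplyr::bind_rows(res)
  attr(out, "optimum") <- out[which.max(out$loglik),
                              c("d_curl", "d_div", "loglik")]
  out
}
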