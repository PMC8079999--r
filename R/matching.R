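#' Trilinear space-time interpolation of a gridded flow quantity
#'
#' Bilinear in space, linear in time between the flow-field snapshots.
#' Queries outside the spatio-temporal hull, or whose 8-corner stencil
#' touches a masked (NA) cell, return `NA` (the missing-covariate flag is
#' applied downstream).
#'
#' @param stack a [flow_stack()].
#' @param xq,yq,tq query coordinates (vectors of equal length, metres and
#'   seconds).
#' @param what which grid to interpolate: `"curl"`, `"div"`, `"u"`, `"v"`,
#'   or `"corr"`.
#' @return Numeric vector of interpolated values (`NA` where missing).
#' @export
interpolate_field <- function(stack, xq, yq, tq, what = "curl") {
  stopifnot(inherits(stack, "flow_stack"))
  a <- stack[[what]]
  if (is.null(a)) stop("flow stack has no grid '", what, "'", call. = FALSE)
  nq <- length(xq)
  stopifnot(length(yq) == nq, length(tq) == nq)
  xs <- stack$x; ys <- stack$y; ts <- stack$t
  out <- rep(NA_real_, nq)
  inside <- xq >= xs[1] & xq <= xs[length(xs)] &
    yq >= ys[1] & yq <= ys[length(ys)]
  if (length(ts) == 1) {
    inside <- inside & abs(tq - ts[1]) < 1e-9
  } else {
    inside <- inside & tq >= ts[1] & tq <= ts[length(ts)]
  }
  if (!any(inside, na.rm = TRUE)) return(out)
  idx <- which(inside)
  locate <- function(q, grid) {
    i <- findInterval(q, grid, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(grid) - 1L)
    if (length(grid) == 1L) return(list(i = rep(1L, length(q)),
                                        w = rep(0, length(q)), i2 = rep(1L, length(q))))
    w <- (q - grid[i]) / (grid[i + 1L] - grid[i])
    list(i = i, w = w, i2 = i + 1L)
  }
  lx <- locate(xq[idx], xs); ly <- locate(yq[idx], ys); lt <- locate(tq[idx], ts)
  dm <- dim(a)
  val <- rep(0, length(idx))
  for (cx in 0:1) for (cy in 0:1) for (ct in 0:1) {
    ii <- if (cx == 0) lx$i else lx$i2
    jj <- if (cy == 0) ly$i else ly$i2
    kk <- if (ct == 0) lt$i else lt$i2
    corner <- a[cbind(ii, jj, kk)]
    wgt <- (if (cx == 0) 1 - lx$w else lx$w) *
      (if (cy == 0) 1 - ly$w else ly$w) *
      (if (ct == 0) 1 - lt$w else lt$w)
    # corners with zero weight may be NA without harm only if exactly on a
    # node; keep the strict policy: any NA corner with nonzero weight kills
    # the value, an NA corner with zero weight does not
    corner[wgt == 0 & is.na(corner)] <- 0
    val <- val + wgt * corner
  }
  out[idx] <- val
  out
}

#' Attach flow covariates to a kinematic series at time-to-contact delays
#'
#' For an observation at time `t`, `abs_curl` is the absolute interpolated
#' curl at the track's position at `t + d_curl`, and `divergence` the
#' interpolated divergence at the position at `t + d_div` (signed curl is
#' interpolated first, then the absolute value taken). The field is read at
#' time `t + d` (the feature's state when the bird arrives) by default, or
#' at `t` (the feature currently visible ahead) with
#' `field_time = "current"`. All series are truncated by `max_delay` so the
#' observation count is identical for every delay choice up to that
#' maximum.
#'
#' @param series a kinematic series tibble (columns `track_id`, `t`, `x`,
#'   `y`, plus any observation columns, e.g. from [track_kinematics()]).
#' @param stack a [flow_stack()] with `curl` and `div` grids.
#' @param d_curl,d_div delays in seconds (the field's own scan grid is
#'   `seq(0, 5, by = 0.25)`).
#' @param max_delay truncation horizon in seconds (default 5): terminal
#'   observations within `max_delay` of each track's end are dropped.
#' @param field_time `"arrival"` (field at `t + d`) or `"current"` (field
#'   at `t`).
#' @return An observation dataset tibble: `track_id`, `t`, observation
#'   columns, `abs_curl`, `divergence`, `missing` (logical).
#' @export
attach_covariates <- function(series, stack, d_curl = 0, d_div = 0,
                              max_delay = 5,
                              field_time = c("arrival", "current")) {
  field_time <- match.arg(field_time)
  stopifnot(all(c("track_id", "t", "x", "y") %in% names(series)),
            d_curl >= 0, d_div >= 0, max_delay >= max(d_curl, d_div))
  series %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::group_modify(function(df, key) {
      full <- df  # delayed lookups use positions beyond the truncation point
      pos_at <- function(tq) {
        list(x = approx(full$t, full$x, xout = tq, rule = 1)$y,
             y = approx(full$t, full$y, xout = tq, rule = 1)$y)
      }
      keep <- df$t <= max(df$t) - max_delay + 1e-9
      df <- df[keep, , drop = FALSE]
      if (nrow(df) == 0) {
        df$abs_curl <- numeric(0)
        df$divergence <- numeric(0)
        df$missing <- logical(0)
        return(df)
      }
      pc <- pos_at(df$t + d_curl)
      pd <- pos_at(df$t + d_div)
      tc <- if (field_time == "arrival") df$t + d_curl else df$t
      td <- if (field_time == "arrival") df$t + d_div else df$t
      df$abs_curl <- abs(interpolate_field(stack, pc$x, pc$y, tc, "curl"))
      df$divergence <- interpolate_field(stack, pd$x, pd$y, td, "div")
      df$missing <- is.na(df$abs_curl) | is.na(df$divergence)
      df
    }) %>%
    dplyr::ungroup()
}

#' Apply a missing-covariate policy to an observation dataset
#'
#' @param dataset an observation dataset with a logical `missing` column
#'   (from [attach_covariates()]).
#' @param policy `"drop"` (default: drop flagged observations and split
#'   each track's likelihood contribution into contiguous segments at the
#'   gaps), `"interpolate"` (linearly fill covariate gaps up to `max_gap`
#'   seconds within a track; longer gaps are dropped and split), or
#'   `"zero"` (replace missing covariates by zero; for ablation only).
#' @param max_gap seconds, for the interpolate policy.
#' @return The dataset with covariates resolved and a `segment` column
#'   identifying contiguous likelihood segments.
#' @export
covariate_policy <- function(dataset, policy = c("drop", "interpolate",
                                                 "zero"),
                             max_gap = 1) {
  policy <- match.arg(policy)
  stopifnot("missing" %in% names(dataset))
  ds <- dataset
  if (policy == "zero") {
    ds$abs_curl[ds$missing] <- 0
    ds$divergence[ds$missing] <- 0
    ds$missing <- FALSE
  } else if (policy == "interpolate") {
    ds <- ds %>%
      dplyr::group_by(.data$track_id) %>%
      dplyr::group_modify(function(df, key) {
        if (!any(df$missing) || sum(!df$missing) < 2) return(df)
        runs <- rle(df$missing)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1
        for (r in which(runs$values)) {
          gap_len <- df$t[ends[r]] - df$t[starts[r]]
          interior <- starts[r] > 1 && ends[r] < nrow(df)
          if (interior && gap_len <= max_gap) {
            ii <- starts[r]:ends[r]
            ok <- !df$missing
            df$abs_curl[ii] <- approx(df$t[ok], df$abs_curl[ok],
                                      xout = df$t[ii])$y
            df$divergence[ii] <- approx(df$t[ok], df$divergence[ok],
                                        xout = df$t[ii])$y
            df$missing[ii] <- FALSE
          }
        }
        df
      }) %>%
      dplyr::ungroup()
  }
  # drop remaining flagged observations; within a track a new likelihood
  # segment starts after every dropped observation
  ds <- ds %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::mutate(segment = cumsum(dplyr::lag(.data$missing,
                                              default = FALSE))) %>%
    dplyr::filter(!.data$missing) %>%
    dplyr::mutate(segment = paste0(.data$track_id, ".",
                                   match(.data$segment,
                                         unique(.data$segment)))) %>%
    dplyr::ungroup() %>%
    dplyr::select(-dplyr::any_of("missing"))
  ds$missing <- FALSE
  ds
}
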