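#' PIV configuration
#'
#' Interrogation windows of `window_px` x `window_px` pixels tile the frame
#' interior (inside a clear border of `border_px`) with the given overlap;
#' each window yields one velocity vector by zero-mean normalized
#' cross-correlation with three-point Gaussian sub-pixel peak refinement.
#' Three consecutive frame-pair fields (from four consecutive frames) are
#' merged by a 3 x 3 x 3 median filter into one clean field per
#' `field_interval`, then scaled to m/s from the flight altitude's ground
#' sample distance. Vorticity and divergence follow from central
#' differences after masking vectors below the correlation threshold.
#'
#' @param window_px interrogation window size, px (default 65).
#' @param overlap_fraction window overlap in `[0, 1)` (default 0.5).
#' @param border_px clear border excluded from interrogation (default 128).
#' @param frame_rate video frame rate, Hz (default 30).
#' @param field_interval seconds between exported merged fields
#'   (default 0.25).
#' @param corr_threshold minimum per-vector correlation kept when deriving
#'   curl and divergence (default 0.6).
#' @param ground_sample_distance metres per pixel on the water surface.
#' @param altitude_m flight altitude (metadata; the scaling itself uses
#'   `ground_sample_distance`).
#' @return A list of class `piv_config`.
#' @export
piv_config <- function(window_px = 65, overlap_fraction = 0.5,
                       border_px = 128, frame_rate = 30,
                       field_interval = 0.25, corr_threshold = 0.6,
                       ground_sample_distance = NULL, altitude_m = 100) {
  stopifnot(window_px >= 8, overlap_fraction >= 0, overlap_fraction < 1,
            border_px >= 0, frame_rate > 0, field_interval > 0,
            corr_threshold >= 0, corr_threshold <= 1)
  structure(as.list(environment()), class = "piv_config")
}

piv_window_grid <- function(frame_dim, config) {
  h <- frame_dim[1]; w <- frame_dim[2]
  win <- config$window_px
  step <- max(1L, as.integer(round(win * (1 - config$overlap_fraction))))
  b <- config$border_px
  x0 <- seq(b + 1, w - b - win + 1, by = step)
  y0 <- seq(b + 1, h - b - win + 1, by = step)
  if (length(x0) == 0 || length(y0) == 0) {
    stop("interrogation window does not fit inside the bordered frame",
         call. = FALSE)
  }
  list(x0 = x0, y0 = y0, step = step, win = win)
}

# circular cross-correlation peak with 3-point sub-pixel refinement along
# one axis; cc is the 2-D correlation plane, peak index (pi, pj) 1-based
subpixel_offset <- function(cc, peak_i, n) {
  im <- if (peak_i == 1) n else peak_i - 1
  ip <- if (peak_i == n) 1 else peak_i + 1
  c0 <- cc[peak_i]; cm <- cc[im]; cp <- cc[ip]
  if (cm > 0 && c0 > 0 && cp > 0 && (c0 >= cm && c0 >= cp)) {
    l0 <- log(c0); lm <- log(cm); lp <- log(cp)
    den <- 2 * (lm - 2 * l0 + lp)
    if (abs(den) > 1e-12) return((lm - lp) / den)
  }
  den <- 2 * (cm - 2 * c0 + cp)
  if (abs(den) > 1e-12) (cm - cp) / den else 0
}

#' Cross-correlate one frame pair into a raw velocity field
#'
#' @param frame_a,frame_b equal-size single-channel frames (numeric
#'   matrices, row 1 = top of the image).
#' @param config a [piv_config()].
#' @param t timestamp (s) attached to the output field.
#' @return A single-time [flow_stack()] in px/frame units, with grid
#'   coordinates in pixels (`y` increasing up the image) and per-vector
#'   peak correlation in `corr`. Flat (zero-variance) windows get
#'   `corr = 0` and `NA` displacement.
#' @export
correlate_pair <- function(frame_a, frame_b, config = piv_config(), t = 0) {
  stopifnot(is.matrix(frame_a), all(dim(frame_a) == dim(frame_b)))
  g <- piv_window_grid(dim(frame_a), config)
  win <- g$win
  nx <- length(g$x0); ny <- length(g$y0)
  u <- matrix(NA_real_, nx, ny)
  v <- matrix(NA_real_, nx, ny)
  corr <- matrix(0, nx, ny)
  half <- floor(win / 2)
  for (ix in seq_len(nx)) {
    for (iy in seq_len(ny)) {
      rows <- g$y0[iy]:(g$y0[iy] + win - 1)
      cols <- g$x0[ix]:(g$x0[ix] + win - 1)
      A <- frame_a[rows, cols]
      B <- frame_b[rows, cols]
      A <- A - mean(A); B <- B - mean(B)
      na2 <- sum(A^2); nb2 <- sum(B^2)
      if (na2 < 1e-20 || nb2 < 1e-20) next
      cc <- Re(fft(Conj(fft(A)) * fft(B), inverse = TRUE)) / length(A)
      cc <- cc / sqrt(na2 * nb2)
      pk <- arrayInd(which.max(cc), dim(cc))
      corr[ix, iy] <- cc[pk]
      dy <- pk[1] - 1; dx <- pk[2] - 1
      sub_y <- subpixel_offset(cc[, pk[2]], pk[1], win)
      sub_x <- subpixel_offset(cc[pk[1], ], pk[2], win)
      dy <- dy + sub_y; dx <- dx + sub_x
      if (dy > win / 2) dy <- dy - win
      if (dx > win / 2) dx <- dx - win
      u[ix, iy] <- dx
      v[ix, iy] <- -dy  # image rows grow downward; v is positive "up"
    }
  }
  h <- nrow(frame_a)
  xc <- g$x0 + (win - 1) / 2
  yc_img <- g$y0 + (win - 1) / 2
  yc <- h - yc_img            # flip so y increases up
  ord <- order(yc)
  flow_stack(xc, yc[ord], t, u[, ord, drop = FALSE], v[, ord, drop = FALSE],
             corr[, ord, drop = FALSE], units = "px/frame")
}

#' Merge three consecutive raw fields with a 3 x 3 x 3 median filter
#'
#' Each output component at a cell is the median over the cell's 3 x 3
#' spatial neighbourhood across the three fields (up to 27 values,
#' truncated at grid edges, `NA`s from flagged windows ignored); the
#' per-vector correlation is merged likewise. The output timestamp is the
#' mean of the three input timestamps (the centre of the 4-frame block).
#'
#' @param fields list of three single-time [flow_stack()]s on one grid.
#' @return A single-time [flow_stack()].
#' @export
merge_fields <- function(fields) {
  stopifnot(length(fields) == 3)
  f1 <- fields[[1]]
  for (f in fields[-1]) {
    if (!isTRUE(all.equal(f$x, f1$x)) || !isTRUE(all.equal(f$y, f1$y))) {
      stop("fields are not on the same grid", call. = FALSE)
    }
  }
  nx <- length(f1$x); ny <- length(f1$y)
  get3 <- function(comp) {
    vapply(fields, function(f) f[[comp]][, , 1], matrix(0, nx, ny))
  }
  U <- get3("u"); V <- get3("v"); C <- get3("corr")
  med_filter <- function(A) {
    out <- matrix(NA_real_, nx, ny)
    for (i in seq_len(nx)) {
      ii <- max(1, i - 1):min(nx, i + 1)
      for (j in seq_len(ny)) {
        jj <- max(1, j - 1):min(ny, j + 1)
        vals <- A[ii, jj, ]
        out[i, j] <- median(vals, na.rm = TRUE)
      }
    }
    out
  }
  tmid <- mean(vapply(fields, function(f) f$t, numeric(1)))
  flow_stack(f1$x, f1$y, tmid, med_filter(U), med_filter(V), med_filter(C),
             units = f1$units)
}

#' Scale a pixel-unit velocity field to metres per second
#'
#' Displacements in px/frame are multiplied by the ground sample distance
#' and the frame rate; grid coordinates move from pixels to metres.
#'
#' @param field a single- or multi-time [flow_stack()] in px/frame.
#' @param config a [piv_config()] with `ground_sample_distance` set.
#' @return The field in m/s.
#' @export
scale_field <- function(field, config) {
  stopifnot(inherits(field, "flow_stack"))
  gsd <- config$ground_sample_distance
  if (is.null(gsd) || !is.finite(gsd) || gsd <= 0) {
    stop("ground_sample_distance must be set to scale a field",
         call. = FALSE)
  }
  if (identical(field$units, "m/s")) {
    stop("field is already metre-scaled", call. = FALSE)
  }
  k <- gsd * config$frame_rate
  flow_stack(field$x * gsd, field$y * gsd, field$t,
             field$u * k, field$v * k, field$corr,
             field$curl, field$div, units = "m/s")
}

#' Derive vorticity and divergence grids from a velocity field
#'
#' `curl = dv/dx - du/dy`, `div = du/dx + dv/dy` by central differences
#' (one-sided at grid edges). A cell is masked (`NA`) if its own vector, or
#' any vector its difference stencil touches, has correlation below
#' `corr_threshold` or a flagged (`NA`) displacement: a poor vector must
#' not leak into neighbouring derivatives, and masked cells stay missing
#' rather than zero.
#'
#' @param field a metre-scaled [flow_stack()].
#' @param config a [piv_config()] (uses `corr_threshold`).
#' @return The field with `curl` and `div` grids (1/s) filled in.
#' @export
derive_turbulence <- function(field, config = piv_config()) {
  stopifnot(inherits(field, "flow_stack"))
  if (!identical(field$units, "m/s")) {
    stop("derive_turbulence expects a metre-scaled field", call. = FALSE)
  }
  nx <- length(field$x); ny <- length(field$y); nt <- length(field$t)
  hx <- if (nx > 1) field$x[2] - field$x[1] else 1
  hy <- if (ny > 1) field$y[2] - field$y[1] else 1
  dvdx <- fd_derivative(field$v, hx, 1)
  dudy <- fd_derivative(field$u, hy, 2)
  dudx <- fd_derivative(field$u, hx, 1)
  dvdy <- fd_derivative(field$v, hy, 2)
  curl <- dvdx - dudy
  div <- dudx + dvdy
  bad <- field$corr < config$corr_threshold | is.na(field$u) | is.na(field$v)
  # grow the bad mask over the stencil footprint (edge-clamped 4-neighbours)
  grow <- bad
  for (k in seq_len(nt)) {
    b <- bad[, , k, drop = FALSE][, , 1]
    g <- b
    g[-1, ] <- g[-1, ] | b[-nx, ]
    g[-nx, ] <- g[-nx, ] | b[-1, ]
    g[, -1] <- g[, -1] | b[, -ny]
    g[, -ny] <- g[, -ny] | b[, -1]
    grow[, , k] <- g
  }
  curl[grow] <- NA_real_
  div[grow] <- NA_real_
  flow_stack(field$x, field$y, field$t, field$u, field$v, field$corr,
             curl, div, units = field$units)
}

#' Run the full PIV chain over a frame sequence
#'
#' Every `field_interval` seconds, four consecutive frames give three raw
#' cross-correlation fields which are median-merged, metre-scaled, and
#' differentiated into curl and divergence.
#'
#' @param frames list of single-channel matrices (the water-colour
#'   channel), or a 3-D array `[h, w, n]`.
#' @param config a [piv_config()] with `ground_sample_distance` set.
#' @return A multi-time [flow_stack()] in m/s with `curl` and `div`.
#' @export
piv_sequence <- function(frames, config) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  nfr <- length(frames)
  stopifnot(nfr >= 4)
  stride <- config$field_interval * config$frame_rate
  starts <- unique(as.integer(round(seq(1, nfr - 3, by = stride))))
  starts <- starts[starts >= 1 & starts + 3 <= nfr]
  fields <- lapply(starts, function(s) {
    raw <- lapply(0:2, function(k) {
      correlate_pair(frames[[s + k]], frames[[s + k + 1]], config,
                     t = (s + k - 1 + 0.5) / config$frame_rate)
    })
    merge_fields(raw)
  })
  merged <- fields[[1]]
  dm <- c(length(merged$x), length(merged$y), length(fields))
  u <- array(NA_real_, dm); v <- array(NA_real_, dm)
  corr <- array(NA_real_, dm)
  for (i in seq_along(fields)) {
    u[, , i] <- fields[[i]]$u[, , 1]
    v[, , i] <- fields[[i]]$v[, , 1]
    corr[, , i] <- fields[[i]]$corr[, , 1]
  }
  ts <- vapply(fields, function(f) f$t, numeric(1))
  stack <- flow_stack(merged$x, merged$y, ts, u, v, corr,
                      units = "px/frame")
  stack <- scale_field(stack, config)
  derive_turbulence(stack, config)
}
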