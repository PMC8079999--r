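#' Gridded surface-flow container
#'
#' A `flow_stack` holds a time sequence of gridded surface velocity fields
#' together with per-vector quality and derived vorticity (curl) and
#' divergence grids. Arrays are indexed `[x, y, t]`; `x` increases east,
#' `y` increases "up" (away from the image bottom), so curl follows the
#' right-hand rule in the (x, y) plane.
#'
#' @param x,y,t coordinate vectors (metres, metres, seconds), strictly
#'   increasing and regularly spaced.
#' @param u,v velocity component arrays, m/s (or px/frame before scaling),
#'   dim `c(length(x), length(y), length(t))`.
#' @param corr per-vector correlation quality in `[-1, 1]` (1 for synthetic
#'   ground truth).
#' @param curl,div optional derived grids (1/s); `NA` where masked.
#' @param units character, `"m/s"` or `"px/frame"`.
#' @return An object of class `flow_stack`.
#' @export
flow_stack <- function(x, y, t, u, v, corr = NULL, curl = NULL, div = NULL,
                       units = "m/s") {
  dm <- c(length(x), length(y), length(t))
  as3 <- function(a) {
    if (is.null(a)) return(NULL)
    if (length(dim(a) %||% 1) == 2) a <- array(a, dim = dm)
    stopifnot(all(dim(a) == dm))
    a
  }
  u <- as3(u); v <- as3(v)
  corr <- as3(corr %||% array(1, dm))
  structure(
    list(x = as.numeric(x), y = as.numeric(y), t = as.numeric(t),
         u = u, v = v, corr = corr, curl = as3(curl), div = as3(div),
         units = units),
    class = "flow_stack")
}

#' @export
print.flow_stack <- function(x, ...) {
  cat(sprintf(
    "<flow_stack> %d x %d grid, %d time step(s) [%s]\n  x: %.2f..%.2f  y: %.2f..%.2f  t: %.2f..%.2f s\n",
    length(x$x), length(x$y), length(x$t), x$units,
    min(x$x), max(x$x), min(x$y), max(x$y), min(x$t), max(x$t)))
  if (!is.null(x$curl)) cat("  derived: curl, div\n")
  invisible(x)
}

#' @export
#' @importFrom tibble as_tibble
as_tibble.flow_stack <- function(x, ...) {
  g <- expand.grid(x = x$x, y = x$y, t = x$t, KEEP.OUT.ATTRS = FALSE)
  out <- tibble::as_tibble(g)[, c("t", "x", "y")]
  out$u <- as.vector(x$u); out$v <- as.vector(x$v)
  out$corr <- as.vector(x$corr)
  out$curl <- if (is.null(x$curl)) NA_real_ else as.vector(x$curl)
  out$div <- if (is.null(x$div)) NA_real_ else as.vector(x$div)
  out
}

#' Write / read a flow stack as plain-text CSV (long format)
#'
#' @param stack a [flow_stack()].
#' @param path file path for the CSV.
#' @return `write_flow_csv` returns `path` invisibly; `read_flow_csv`
#'   returns a [flow_stack()].
#' @export
write_flow_csv <- function(stack, path) {
  stopifnot(inherits(stack, "flow_stack"))
  tb <- as_tibble(stack)
  attrline <- sprintf("# units=%s", stack$units)
  writeLines(attrline, path)
  readr::write_csv(tb, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_flow_csv
#' @export
read_flow_csv <- function(path) {
  first <- readLines(path, n = 1)
  units <- sub("^# units=", "", first)
  tb <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  xs <- sort(unique(tb$x)); ys <- sort(unique(tb$y)); ts <- sort(unique(tb$t))
  dm <- c(length(xs), length(ys), length(ts))
  ord <- order(match(tb$t, ts), match(tb$y, ys), match(tb$x, xs))
  tb <- tb[ord, ]
  mk <- function(col) array(tb[[col]], dim = dm)
  curl <- if (all(is.na(tb$curl))) NULL else mk("curl")
  div <- if (all(is.na(tb$div))) NULL else mk("div")
  flow_stack(xs, ys, ts, mk("u"), mk("v"), mk("corr"), curl, div, units)
}

# central-difference derivative along one array dimension; one-sided at edges
fd_derivative <- function(a, h, dim_index) {
  n <- dim(a)[dim_index]
  if (n < 2) stop("need at least 2 grid points to differentiate")
  idx <- function(i) {
    ix <- lapply(dim(a), seq_len)
    ix[[dim_index]] <- i
    do.call(`[`, c(list(a), ix, list(drop = FALSE)))
  }
  out <- array(NA_real_, dim(a))
  # interior: (f[i+1] - f[i-1]) / 2h ; edges one-sided
  ix_all <- lapply(dim(a), seq_len)
  set_slice <- function(arr, i, val) {
    ix <- ix_all; ix[[dim_index]] <- i
    do.call(`[<-`, c(list(arr), ix, list(value = val)))
  }
  if (n > 2) {
    out <- set_slice(out, 2:(n - 1), (idx(3:n) - idx(1:(n - 2))) / (2 * h))
  }
  out <- set_slice(out, 1, (idx(2) - idx(1)) / h)
  out <- set_slice(out, n, (idx(n) - idx(n - 1)) / h)
  out
}
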