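# Independent reference implementations used as oracles. These deliberately
# avoid the package's own computational paths (pure R, brute force).

# exhaustive log-likelihood of a 2-state chain: sum over all 2^T state
# sequences of exp(log prior + log transitions + log emissions)
brute_force_loglik <- function(logb, p12, p21, init1) {
  T <- nrow(logb)
  states <- as.matrix(expand.grid(rep(list(1:2), T)))
  total <- -Inf
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    lp <- log(if (s[1] == 1) init1 else 1 - init1) + logb[1, s[1]]
    for (t in seq_len(T - 1)[T > 1]) {
      ptr <- if (s[t] == 1) {
        if (s[t + 1] == 2) p12[t + 1] else 1 - p12[t + 1]
      } else {
        if (s[t + 1] == 1) p21[t + 1] else 1 - p21[t + 1]
      }
      lp <- lp + log(ptr) + logb[t + 1, s[t + 1]]
    }
    total <- max(total, lp) + log1p(exp(min(total, lp) - max(total, lp)))
  }
  total
}

# exhaustive Viterbi: argmax over all 2^T sequences, ties toward the
# sequence with more (earlier) state-1 entries to mirror the tie-break
brute_force_viterbi <- function(logb, p12, p21, init1) {
  T <- nrow(logb)
  states <- as.matrix(expand.grid(rep(list(1:2), T)))
  best <- NULL; best_lp <- -Inf
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    lp <- log(if (s[1] == 1) init1 else 1 - init1) + logb[1, s[1]]
    for (t in seq_len(T - 1)[T > 1]) {
      ptr <- if (s[t] == 1) {
        if (s[t + 1] == 2) p12[t + 1] else 1 - p12[t + 1]
      } else {
        if (s[t + 1] == 1) p21[t + 1] else 1 - p21[t + 1]
      }
      lp <- lp + log(ptr) + logb[t + 1, s[t + 1]]
    }
    if (lp > best_lp + 1e-12) { best_lp <- lp; best <- s }
  }
  best
}

# pure-R scaled forward pass, structured differently from the C++ core
forward_loglik_R <- function(logb, p12, p21, init1) {
  T <- nrow(logb)
  alpha <- c(init1, 1 - init1) * exp(logb[1, ])
  ll <- log(sum(alpha)); alpha <- alpha / sum(alpha)
  if (T > 1) {
    for (t in 2:T) {
      G <- matrix(c(1 - p12[t], p12[t], p21[t], 1 - p21[t]), 2, 2,
                  byrow = TRUE)
      alpha <- as.vector(alpha %*% G) * exp(logb[t, ])
      ll <- ll + log(sum(alpha)); alpha <- alpha / sum(alpha)
    }
  }
  ll
}

# brute-force 3x3x3 edge-truncated median of three fields
brute_merge_oracle <- function(A3) {   # A3: nx x ny x 3
  nx <- dim(A3)[1]; ny <- dim(A3)[2]
  out <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    ii <- max(1, i - 1):min(nx, i + 1)
    jj <- max(1, j - 1):min(ny, j + 1)
    out[i, j] <- median(A3[ii, jj, ], na.rm = TRUE)
  }
  out
}

# textured frame for PIV tests: smooth random pattern, values in [0, 1]
piv_texture <- function(h, w, seed = 1, blur = 1) {
  set.seed(seed)
  tx <- matrix(rnorm((h + 40) * (w + 40)), h + 40, w + 40)
  k <- matrix(1, 2 * blur + 1, 2 * blur + 1)
  k <- k / sum(k)
  # simple separable smoothing
  sm <- t(apply(tx, 1, function(r) stats::filter(r, rep(1 / (2 * blur + 1),
                                                        2 * blur + 1))))
  sm <- apply(sm, 2, function(cc) stats::filter(cc, rep(1 / (2 * blur + 1),
                                                        2 * blur + 1)))
  sm <- sm[(21):(20 + h), (21):(20 + w)]
  (sm - min(sm)) / (max(sm) - min(sm))
}

# shift an image by a fractional amount with bilinear resampling
# (positive dx moves content right, dy moves it down)
shift_image <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  r <- matrix(1:h, h, w) - dy
  cc <- matrix(1:w, h, w, byrow = TRUE) - dx
  r0 <- pmin(pmax(floor(r), 1), h - 1); c0 <- pmin(pmax(floor(cc), 1), w - 1)
  fr <- r - r0; fc <- cc - c0
  out <- img[cbind(as.vector(r0), as.vector(c0))] * (1 - fr) * (1 - fc) +
    img[cbind(as.vector(r0 + 1), as.vector(c0))] * fr * (1 - fc) +
    img[cbind(as.vector(r0), as.vector(c0 + 1))] * (1 - fr) * fc +
    img[cbind(as.vector(r0 + 1), as.vector(c0 + 1))] * fr * fc
  matrix(out, h, w)
}

# constant (u, v) flow stack over a rectangular domain
uniform_stack <- function(u, v, Lx = 100, Ly = 60, h = 2, times = 0) {
  xs <- seq(0, Lx, by = h); ys <- seq(0, Ly, by = h)
  dm <- c(length(xs), length(ys), length(times))
  flow_stack(xs, ys, times, array(u, dm), array(v, dm))
}
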