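# Internal numerical helpers shared across modules.

# Derive a reproducible sub-stream seed from a user seed and a stream offset.
# Kept well below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  (abs(as.integer(seed)) %% 1000000L) * 1009L + as.integer(offset)
}

# Centered rolling mean with shrunken windows at the edges, O(n) via cumsum.
rolling_mean <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Truncated normal draws by inverse-CDF (exact, vectorized).
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lower), upper))
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

# Gamma draws parameterized by mean and coefficient of variation; cv = 0 is
# the deterministic limit.
rgamma_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, scale = mean / shape)
}

# von Mises draws (degrees), Best & Fisher (1979) rejection sampler.
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa <= 0) return(runif(n, 0, 360))
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      theta <- mu + sign(u3 - 0.5) * acos(f)
      out[i] <- theta
      i <- i + 1L
    }
  }
  (out * 180 / pi) %% 360
}

# von Mises density weight normalized to a maximum of 1 (for thinning).
vonmises_weight <- function(phase_deg, mu_deg, kappa) {
  exp(kappa * (cos((phase_deg - mu_deg) * pi / 180) - 1))
}

# Angular difference folded to [-180, 180).
angle_diff <- function(a, b) {
  ((a - b + 180) %% 360) - 180
}

# Merge possibly overlapping or touching intervals given as a two-column
# matrix/data frame (start, end), gap <= merge_gap collapses.
merge_intervals <- function(start, end, merge_gap = 0) {
  if (length(start) == 0L) {
    return(tibble::tibble(start = numeric(), end = numeric()))
  }
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] - me <= merge_gap) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

# Complement of a set of disjoint sorted intervals within [lo, hi].
complement_intervals <- function(start, end, lo, hi) {
  bounds_s <- c(lo, end)
  bounds_e <- c(start, hi)
  keep <- bounds_e - bounds_s > 0
  tibble::tibble(start = bounds_s[keep], end = bounds_e[keep])
}

# Membership of points in half-open intervals [start, end); returns the row
# index of the containing interval or NA.
interval_index <- function(x, start, end) {
  if (length(start) == 0L || length(x) == 0L) return(rep(NA_integer_, length(x)))
  idx <- findInterval(x, start)
  inside <- idx >= 1L & x < end[pmax(idx, 1L)]
  ifelse(inside, idx, NA_integer_)
}
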