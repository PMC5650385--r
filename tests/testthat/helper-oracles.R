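# Brute-force oracles, written independently of the package implementation:
# explicit loops and direct formula evaluation only.

oracle_glcm <- function(levels, Ng, directions, distance = 1L) {
  d <- dim(levels)
  counts <- matrix(0, Ng, Ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    l1 <- levels[x, y, z]
    if (l1 == 0) next
    for (r in seq_len(nrow(directions))) {
      o <- directions[r, ] * distance
      x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      l2 <- levels[x2, y2, z2]
      if (l2 == 0) next
      counts[l1, l2] <- counts[l1, l2] + 1
      counts[l2, l1] <- counts[l2, l1] + 1   # symmetric accumulation
    }
  }
  counts / sum(counts)
}

oracle_glrlm <- function(levels, Ng, directions) {
  d <- dim(levels)
  rmax <- max(d)
  counts <- matrix(0, Ng, rmax)
  inside <- function(p) all(p >= 1) && all(p <= d)
  for (r in seq_len(nrow(directions))) {
    o <- directions[r, ]
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      p <- c(x, y, z)
      l <- levels[x, y, z]
      if (l == 0) next
      prev <- p - o
      # only count runs at their starting voxel
      if (inside(prev) && levels[prev[1], prev[2], prev[3]] == l) next
      len <- 1L
      nxt <- p + o
      while (inside(nxt) && levels[nxt[1], nxt[2], nxt[3]] == l) {
        len <- len + 1L
        nxt <- nxt + o
      }
      counts[l, len] <- counts[l, len] + 1
    }
  }
  counts
}

oracle_discretize <- function(values, mask, n_bins) {
  x <- values[mask]
  lo <- min(x); hi <- max(x)
  out <- array(0L, dim(values))
  for (i in which(mask)) {
    if (hi == lo) { out[i] <- 1L; next }
    b <- floor((values[i] - lo) / (hi - lo) * n_bins) + 1
    out[i] <- as.integer(min(b, n_bins))
  }
  out
}

# type-7 quantile by explicit interpolation
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_firstorder <- function(x, voxvol, n_bins = 32L) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  p10 <- oracle_quantile7(x, 0.1)
  p90 <- oracle_quantile7(x, 0.9)
  inner <- x[x >= p10 & x <= p90]
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    cnt <- numeric(n_bins)
    for (v in x) {
      b <- min(floor((v - lo) / (hi - lo) * n_bins) + 1, n_bins)
      cnt[b] <- cnt[b] + 1
    }
    p <- cnt / n
  } else p <- 1
  pp <- p[p > 0]
  med <- if (n %% 2 == 1) sort(x)[(n + 1) / 2] else mean(sort(x)[n / 2 + 0:1])
  c(mean = mu, median = med, minimum = lo, maximum = hi, range = hi - lo,
    variance = m2, std = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    energy = sum(x^2), total_energy = voxvol * sum(x^2),
    entropy = -sum(pp * log2(pp)), uniformity = sum(p^2),
    rms = sqrt(sum(x^2) / n), mad = sum(abs(x - mu)) / n,
    robust_mad = sum(abs(inner - sum(inner) / length(inner))) / length(inner),
    p10 = p10, p90 = p90,
    iqr = oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25))
}

# 1D correlation along an axis with whole-sample symmetric extension,
# mirroring the package's documented alignment convention but computed
# point by point.
oracle_conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  n <- d[axis]
  L <- length(kernel)
  pl <- L %/% 2
  ext_idx <- function(i) {
    # map extended position i (may be < 1 or > n) to a source index
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i else i <- 2 * n + 1 - i
    }
    i
  }
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    pos <- c(x, y, z)
    acc <- 0
    for (k in seq_len(L)) {
      q <- pos
      q[axis] <- ext_idx(pos[axis] - pl + (k - 1))
      acc <- acc + kernel[k] * a[q[1], q[2], q[3]]
    }
    out[x, y, z] <- acc
  }
  out
}

# product-limit estimator by hand
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, survival = out)
}

# two-group log-rank statistic by hand (observed minus expected over event
# times, hypergeometric variance)
oracle_logrank2 <- function(time, event, group) {
  g <- as.integer(factor(group))
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    n_t <- sum(time >= t)
    n1 <- sum(time >= t & g == 1)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    e1 <- d_t * n1 / n_t
    o_minus_e <- o_minus_e + d1 - e1
    if (n_t > 1) {
      v <- v + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  stat <- o_minus_e^2 / v
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}
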