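# Brute-force reference implementations of every feature, coded directly from
# the definitions with plain loops and no shared code with the package.

bf_mvar1 <- function(epoch) {
  n_t <- ncol(epoch)
  y <- t(epoch[, 2:n_t, drop = FALSE])
  z <- t(epoch[, 1:(n_t - 1), drop = FALSE])
  t(solve(t(z) %*% z, t(z) %*% y))
}

bf_eigen_features <- function(a, threshold = 0.95) {
  ev <- abs(eigen(a)$values)
  c(max(ev), min(ev), sum(ev > threshold))
}

bf_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(sum((x - mu)^2) / (n - 1), m3 / m2^1.5, m4 / m2^2)
}

# Hann-windowed one-sided periodogram by explicit DFT.
bf_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xw <- (x - sum(x) / n) * w
  half <- 0:(floor(n / 2))
  psd <- numeric(length(half))
  for (k in seq_along(half)) {
    re <- 0
    im <- 0
    for (t in 0:(n - 1)) {
      ang <- -2 * pi * half[k] * t / n
      re <- re + xw[t + 1] * cos(ang)
      im <- im + xw[t + 1] * sin(ang)
    }
    psd[k] <- (re^2 + im^2) / (fs * sum(w^2))
    if (half[k] != 0 && !(n %% 2 == 0 && k == length(half))) psd[k] <- 2 * psd[k]
  }
  list(freq = half * fs / n, psd = psd, df = fs / n)
}

bf_band_powers <- function(x, fs) {
  pg <- bf_periodogram(x, fs)
  bp <- function(lo, hi, closed) {
    sel <- if (closed) pg$freq >= lo & pg$freq <= hi else pg$freq >= lo & pg$freq < hi
    sum(pg$psd[sel]) * pg$df
  }
  v <- c(bp(0.5, 4, FALSE), bp(4, 8, FALSE), bp(8, 13, FALSE),
         bp(13, 30, FALSE), bp(30, 50, TRUE))
  tot <- bp(0.5, 50, TRUE)
  c(v, (v[4] + v[5]) / tot, (v[1] + v[2]) / tot)
}

bf_median_frequency <- function(x, fs) {
  pg <- bf_periodogram(x, fs)
  sel <- which(pg$freq >= 0.5 & pg$freq <= 50)
  cum <- 0
  tot <- sum(pg$psd[sel])
  for (k in sel) {
    cum <- cum + pg$psd[k]
    if (cum >= tot / 2 * (1 - 1e-6)) return(pg$freq[k])
  }
  pg$freq[sel[length(sel)]]
}

bf_hurst <- function(x) {
  n <- length(x)
  sizes <- c()
  m <- 8
  while (m <= n / 4) {
    sizes <- c(sizes, m)
    m <- m * 2
  }
  lrs <- numeric(0)
  lm_ <- numeric(0)
  for (m in sizes) {
    rs <- c()
    for (b in seq_len(n %/% m)) {
      y <- x[((b - 1) * m + 1):(b * m)]
      mu <- mean(y)
      cs <- numeric(m)
      acc <- 0
      for (i in 1:m) {
        acc <- acc + (y[i] - mu)
        cs[i] <- acc
      }
      s <- sqrt(sum((y - mu)^2) / (m - 1))
      if (s > 0) rs <- c(rs, (max(cs) - min(cs)) / s)
    }
    if (length(rs) > 0) {
      lrs <- c(lrs, log(mean(rs)))
      lm_ <- c(lm_, log(m))
    }
  }
  sum((lm_ - mean(lm_)) * (lrs - mean(lrs))) / sum((lm_ - mean(lm_))^2)
}

bf_hjorth_complexity <- function(x) {
  v <- function(z) sum((z - mean(z))^2) / (length(z) - 1)
  d1 <- x[-1] - x[-length(x)]
  d2 <- d1[-1] - d1[-length(d1)]
  mob <- function(z, dz) sqrt(v(dz) / v(z))
  mob(d1, d2) / mob(x, d1)
}

bf_bin_equidistant <- function(x, nb) {
  edges <- seq(min(x), max(x), length.out = nb + 1)
  b <- integer(length(x))
  for (i in seq_along(x)) {
    k <- 1
    while (k < nb && x[i] >= edges[k + 1]) k <- k + 1
    b[i] <- k
  }
  b
}

bf_bin_equiprobable <- function(x, nb) {
  n <- length(x)
  r <- integer(n)
  ord <- order(x)
  for (i in seq_len(n)) r[ord[i]] <- i
  as.integer(ceiling(nb * r / n))
}

bf_ami <- function(bins, nb, tau) {
  n <- length(bins) - tau
  joint <- matrix(0, nb, nb)
  for (t in 1:n) joint[bins[t], bins[t + tau]] <- joint[bins[t], bins[t + tau]] + 1
  joint <- joint / n
  pi1 <- rowSums(joint)
  pi2 <- colSums(joint)
  mi <- 0
  for (i in 1:nb) {
    for (j in 1:nb) {
      if (joint[i, j] > 0) {
        mi <- mi + joint[i, j] * log2(joint[i, j] / (pi1[i] * pi2[j]))
      }
    }
  }
  mi
}

bf_ami_curve <- function(x, binning, nb, lags) {
  bins <- if (binning == "equidistant") bf_bin_equidistant(x, nb) else bf_bin_equiprobable(x, nb)
  vapply(lags, function(tau) bf_ami(bins, nb, tau), numeric(1))
}

bf_bicorrelation <- function(x, lags) {
  out <- 0
  for (tau in lags) {
    n <- length(x) - 2 * tau
    acc <- 0
    for (t in 1:n) acc <- acc + x[t] * x[t + tau] * x[t + 2 * tau]
    out <- out + acc / n
  }
  out / length(lags)
}

bf_autocorr <- function(x) {
  n <- length(x)
  mu <- mean(x)
  r <- function(k) {
    num <- 0
    for (t in 1:(n - k)) num <- num + (x[t] - mu) * (x[t + k] - mu)
    num / sum((x - mu)^2)
  }
  rk1 <- r(1)
  rk2 <- r(2)
  # midranks computed within each lagged subvector (Spearman of the pairs)
  midrank <- function(v) {
    m <- length(v)
    out <- numeric(m)
    ord <- order(v)
    i <- 1
    while (i <= m) {
      j <- i
      while (j < m && v[ord[j + 1]] == v[ord[i]]) j <- j + 1
      for (k in i:j) out[ord[k]] <- (i + j) / 2
      i <- j + 1
    }
    out
  }
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  c(pearson(midrank(x[1:(n - 1)]), midrank(x[2:n])),
    pearson(x[1:(n - 1)], x[2:n]),
    (rk2 - rk1^2) / (1 - rk1^2))
}

bf_cpei <- function(x, tie = 1e-6) {
  per_lag <- function(lag) {
    counts <- new.env()
    n <- length(x) - 2 * lag
    for (t in 1:n) {
      a <- x[t]; b <- x[t + lag]; c_ <- x[t + 2 * lag]
      s <- function(d) if (abs(d) <= tie) "0" else if (d > 0) "+" else "-"
      key <- paste0(s(b - a), s(c_ - b), s(c_ - a))
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
    h <- 0
    for (key in ls(counts)) {
      p <- counts[[key]] / n
      h <- h - p * log2(p)
    }
    h / log2(6)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  per_lag(1) + per_lag(2)
}
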