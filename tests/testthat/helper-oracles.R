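# Independent brute-force oracles for the HRV statistics and DBSCAN.
# Deliberately naive: direct formulas, double loops and exhaustive searches,
# kept free of any code path from the package implementation.

oracle_sdnn <- function(rr) {
  m <- sum(rr) / length(rr)
  sqrt(sum((rr - m)^2) / (length(rr) - 1))
}

oracle_rmssd <- function(rr) {
  d <- rr[-1] - rr[-length(rr)]
  sqrt(sum(d^2) / length(d))
}

oracle_pnn50 <- function(rr) {
  d <- rr[-1] - rr[-length(rr)]
  100 * sum(abs(d) > 50) / length(d)
}

oracle_sd12 <- function(rr) {
  n <- length(rr)
  x <- rr[1:(n - 1)]; y <- rr[2:n]
  vp <- function(v) sum((v - mean(v))^2) / length(v)
  c(sd1 = sqrt(vp(y - x) / 2), sd2 = sqrt(vp(y + x) / 2))
}

oracle_hist <- function(rr) {
  w <- 1000 / 128
  idx <- floor(rr / w)
  counts <- sapply(min(idx):max(idx), function(k) sum(idx == k))
  list(lo = min(idx), counts = counts, w = w)
}

oracle_hrv_index <- function(rr) {
  h <- oracle_hist(rr)
  length(rr) / max(h$counts)
}

# Exhaustive least-squares triangular fit over all (N, M) edge pairs,
# histogram padded by one empty bin on each side.
oracle_tinn <- function(rr) {
  h <- oracle_hist(rr)
  counts <- c(0, h$counts, 0)
  w <- h$w
  edges <- ((h$lo - 1):(h$lo + length(h$counts) + 1)) * w
  centers <- edges[-length(edges)] + w / 2
  p <- which.max(counts)
  X <- centers[p]; Y <- counts[p]
  best <- Inf; nm <- c(NA, NA)
  for (N in edges[edges <= edges[p]]) {
    for (M in edges[edges >= edges[p + 1]]) {
      q <- numeric(length(centers))
      for (i in seq_along(centers)) {
        x <- centers[i]
        if (x >= N && x <= X && X > N) q[i] <- Y * (x - N) / (X - N)
        else if (x == X) q[i] <- Y
        else if (x > X && x <= M && M > X) q[i] <- Y * (M - x) / (M - X)
      }
      err <- sum((counts - q)^2)
      if (err < best - 1e-12) { best <- err; nm <- c(N, M) }
    }
  }
  nm[2] - nm[1]
}

# Double-loop approximate entropy, self-matches included, Chebyshev distance.
oracle_apen <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    logs <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      logs[i] <- log(cnt / nt)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

# Direct-sum Lomb-Scargle with tau, one frequency at a time.
oracle_lomb <- function(t, y, freqs) {
  y <- y - mean(y)
  sapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  })
}

# Classical periodogram (1/N)|sum y exp(-2 pi i f t)|^2 at given frequencies.
oracle_periodogram <- function(t, y, freqs) {
  y <- y - mean(y)
  sapply(freqs, function(f) {
    Mod(sum(y * exp(-2i * pi * f * t)))^2 / length(y)
  })
}

# Brute-force DBSCAN over a precomputed distance matrix.
oracle_dbscan_n <- function(dmat, eps, min_pts) {
  n <- nrow(dmat)
  core <- sapply(seq_len(n), function(i) sum(dmat[i, ] <= eps) >= min_pts)
  lab <- rep(0L, n)
  cl <- 0L
  repeat {
    seedpt <- which(core & lab == 0L)
    if (!length(seedpt)) break
    cl <- cl + 1L
    members <- seedpt[1]
    repeat {
      reach <- which(lab == 0L &
                     sapply(seq_len(n), function(j)
                       any(dmat[j, members[core[members]]] <= eps)))
      reach <- setdiff(reach, members)
      if (!length(reach)) break
      members <- c(members, reach)
      lab[members] <- cl
    }
    lab[members] <- cl
  }
  cl
}

# Haversine distance in meters, radius 6371000 (independent of geosphere).
oracle_haversine <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  a <- sin((lat2 - lat1) * rad / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin((lon2 - lon1) * rad / 2)^2
  2 * 6371000 * asin(pmin(1, sqrt(a)))
}

# Random plausible RR series for property tests.
random_rr <- function(n, seed) {
  set.seed(seed)
  round(rnorm(n, 900, 60) + 40 * sin(seq_len(n) / 3), 3)
}
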