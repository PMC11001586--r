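# Independent brute-force oracles. Each re-derives a quantity by direct
# enumeration, without calling the package's implementation path.

# Scan a counts vector minute by minute and collect maximal zero runs of
# length >= min_bout.
oracle_bouts <- function(counts, min_bout = 5) {
  starts <- integer(0); durs <- integer(0)
  run <- 0L
  for (i in seq_along(counts)) {
    if (counts[i] == 0L) {
      run <- run + 1L
    } else {
      if (run >= min_bout) {
        starts <- c(starts, i - run); durs <- c(durs, run)
      }
      run <- 0L
    }
  }
  if (run >= min_bout) {
    starts <- c(starts, length(counts) - run + 1L); durs <- c(durs, run)
  }
  data.frame(start_min = starts, duration_min = durs)
}

# Per-minute sleep flags implied by the oracle bout list.
oracle_sleep_flags <- function(counts, min_bout = 5) {
  b <- oracle_bouts(counts, min_bout)
  flags <- logical(length(counts))
  for (i in seq_len(nrow(b)))
    flags[b$start_min[i]:(b$start_min[i] + b$duration_min[i] - 1L)] <- TRUE
  flags
}

# Exhaustive triangle threshold: evaluate the point-to-chord distance at
# every bin between the peak and the far end of the longer tail, using
# the vector cross-product form of the distance.
oracle_triangle <- function(h) {
  nz <- which(h > 0)
  peak <- which.max(h)
  lo <- nz[1]; hi <- nz[length(nz)]
  end <- if ((hi - peak) >= (peak - lo)) hi else lo
  cand <- if (end >= peak) peak:end else end:peak
  v <- c(end - peak, h[end] - h[peak])
  len <- sqrt(sum(v^2))
  best <- -Inf; best_bin <- NA
  for (i in cand) {
    w <- c(i - peak, h[i] - h[peak])
    d <- abs(v[1] * w[2] - v[2] * w[1]) / len
    if (d > best + 1e-12) { best <- d; best_bin <- i }
  }
  best_bin
}

# Exhaustive single-order Renyi entropic-sum maximizer, computing class
# distributions from scratch at every candidate split.
oracle_renyi_alpha <- function(h, alpha) {
  p <- h / sum(h)
  best <- -Inf; best_bin <- NA
  for (t in 1:(length(p) - 1)) {
    P1 <- sum(p[1:t])
    if (P1 <= 0 || P1 >= 1) next
    pb <- p[1:t][p[1:t] > 0] / P1
    pf <- p[(t + 1):length(p)][p[(t + 1):length(p)] > 0] / (1 - P1)
    H <- if (alpha == 1) {
      -sum(pb * log(pb)) - sum(pf * log(pf))
    } else {
      (log(sum(pb^alpha)) + log(sum(pf^alpha))) / (1 - alpha)
    }
    if (H > best + 1e-12) { best <- H; best_bin <- t }
  }
  best_bin
}

# Breadth-first flood fill labelling of a binary matrix.
oracle_label <- function(img, connectivity = 8) {
  nr <- nrow(img); nc <- ncol(img)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  cur <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!img[rr, cc] || lab[rr, cc] != 0L) next
    cur <- cur + 1L
    queue <- list(c(rr, cc))
    lab[rr, cc] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            img[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# Pixel-counting colocalization oracle: per-slice overlap / mito area,
# counted pixel by pixel via explicit indexing.
oracle_coloc <- function(mito, atg, start, n_slices) {
  end <- min(start + n_slices - 1, dim(mito)[3])
  total <- 0
  ratios <- numeric(0)
  for (z in start:end) {
    m <- 0L; o <- 0L
    for (i in seq_len(dim(mito)[1])) for (j in seq_len(dim(mito)[2])) {
      if (mito[i, j, z]) {
        m <- m + 1L
        if (atg[i, j, z]) o <- o + 1L
      }
    }
    ratios <- c(ratios, if (m == 0L) 0 else o / m)
  }
  list(ratios = ratios, index = sum(ratios))
}

# Random non-degenerate 256-bin histogram.
random_histogram <- function() {
  n_modes <- sample(1:3, 1)
  h <- stats::rpois(256, 1)
  for (m in seq_len(n_modes)) {
    center <- sample(10:246, 1)
    width <- sample(3:30, 1)
    h <- h + round(stats::dnorm(1:256, center, width) * stats::runif(1, 500, 50000))
  }
  if (sum(h > 0) < 2) h[c(10, 200)] <- h[c(10, 200)] + 5L
  h
}
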