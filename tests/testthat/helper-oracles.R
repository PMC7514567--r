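# Brute-force reference implementations used as independent oracles.
# They are deliberately written as plain per-pixel / per-element loops,
# independent of the package's kernels.

reflectIndex <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

windowValues <- function(img, r, c, offsets, border, value) {
  n <- nrow(offsets)
  out <- numeric(n)
  for (k in seq_len(n)) {
    rr <- r + offsets[k, 1]
    cc <- c + offsets[k, 2]
    if (rr < 1 || rr > nrow(img) || cc < 1 || cc > ncol(img)) {
      if (border == "reflect") {
        out[k] <- img[reflectIndex(rr, nrow(img)), reflectIndex(cc, ncol(img))]
      } else {
        out[k] <- value
      }
    } else {
      out[k] <- img[rr, cc]
    }
  }
  out
}

bruteLocalFilter <- function(img, window, op, bins = 256, range = c(0, 1),
                             base = exp(1)) {
  offsets <- cvmStager:::.windowOffsets(window)
  out <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      v <- windowValues(img, r, c, offsets, window$border, window$value)
      if (op == "mean") {
        out[r, c] <- mean(v)
      } else if (op == "median") {
        out[r, c] <- median(v)
      } else {
        v <- pmin(pmax(v, range[1]), range[2])
        b <- pmin(bins - 1, floor((v - range[1]) / diff(range) * bins))
        p <- table(b) / length(b)
        out[r, c] <- -sum(p * log(p)) / log(base)
      }
    }
  }
  out
}

bruteCrossEntropy <- function(Y, P, reduction = "mean", eps = 1e-12) {
  s <- 0
  for (i in seq_len(nrow(Y))) {
    for (j in seq_len(ncol(Y))) {
      s <- s - Y[i, j] * log(min(max(P[i, j], eps), 1))
    }
  }
  if (reduction == "mean") s / nrow(Y) else s
}

# 3x3 Sobel response computed by explicit kernel convolution with mirrored
# borders (independent of the package kernel).
bruteSobel <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # columns -1,0,1
  ky <- t(kx)
  out <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      gx <- 0; gy <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          v <- img[reflectIndex(r + di, nrow(img)),
                   reflectIndex(c + dj, ncol(img))]
          gx <- gx + v * kx[di + 2, dj + 2]
          gy <- gy + v * ky[di + 2, dj + 2]
        }
      }
      out[r, c] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

randomProbMatrix <- function(n, k) {
  p <- matrix(stats::rexp(n * k), n, k)
  p / rowSums(p)
}

randomOneHot <- function(n, k) {
  m <- matrix(0, n, k)
  m[cbind(seq_len(n), sample.int(k, n, replace = TRUE))] <- 1
  m
}
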