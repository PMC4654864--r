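# Independent brute-force oracles. These deliberately re-derive each
# operation from its definition (iterative fixpoints, per-pixel recursions,
# naive criterion scans) and share no code with the package internals.

# symmetric reflection index (half-sample), 1-based
oracleReflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# grayscale reconstruction by dilation: iterate J <- min(dilate8(J), mask)
# from J = min(marker, mask) until the fixpoint
oracleReconstruct <- function(marker, mask) {
  J <- pmin(marker, mask)
  nr <- nrow(J); nc <- ncol(J)
  repeat {
    D <- J
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- matrix(-Inf, nr, nc)
      rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
      okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
      sh[okr, okc] <- J[rs[okr], cs[okc]]
      D <- pmax(D, sh)
    }
    Jn <- pmin(D, mask)
    if (identical(Jn, J)) return(J)
    J <- Jn
  }
}

# regional maxima by explicit plateau flood: for every unvisited pixel flood
# its equal-value 8-connected plateau and test whether any boundary
# neighbour is strictly greater
oracleRegionalMaxima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  visited <- matrix(FALSE, nr, nc)
  out <- matrix(FALSE, nr, nc)
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (visited[r0, c0]) next
    v <- img[r0, c0]
    queue <- list(c(r0, c0))
    visited[r0, c0] <- TRUE
    plateau <- list()
    isMax <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      plateau[[length(plateau) + 1]] <- p
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        w <- img[rr, cc]
        if (w > v) isMax <- FALSE
        else if (w == v && !visited[rr, cc]) {
          visited[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    if (isMax) for (p in plateau) out[p[1], p[2]] <- TRUE
  }
  out
}

# per-pixel level A/B recursion of the adaptive median filter
oracleAdaptiveMedian <- function(img, smax) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    z <- img[r, c]
    s <- 3
    repeat {
      h <- (s - 1) / 2
      win <- numeric(0)
      for (dc in -h:h) for (dr in -h:h)
        win <- c(win, img[oracleReflect(r + dr, nr), oracleReflect(c + dc, nc)])
      zmin <- min(win); zmax <- max(win); zmed <- median(win)
      if (zmin < zmed && zmed < zmax) {
        out[r, c] <- if (zmin < z && z < zmax) z else zmed
        break
      }
      if (s >= smax) { out[r, c] <- zmed; break }
      s <- s + 2
    }
  }
  out
}

# naive exhaustive Otsu over 256 bins: recompute class statistics per
# threshold from the raw histogram
oracleOtsu <- function(img) {
  v <- as.vector(img)
  bin <- pmin(floor(v * 256), 255) + 1
  h <- tabulate(bin, 256)
  g <- (seq_len(256) - 0.5) / 256
  occ <- which(h > 0)
  best <- -Inf; bestT <- NA
  for (t in seq(min(occ), max(occ) - 1)) {
    i0 <- 1:t; i1 <- (t + 1):256
    n0 <- sum(h[i0]); n1 <- sum(h[i1])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[i0] * g[i0]) / n0
    mu1 <- sum(h[i1] * g[i1]) / n1
    bcv <- (n0 / length(v)) * (n1 / length(v)) * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; bestT <- t }
  }
  bestT / 256
}

# naive exhaustive Huang fuzzy-entropy threshold over 256 bins
oracleHuang <- function(img) {
  v <- as.vector(img)
  bin <- pmin(floor(v * 256), 255) + 1
  h <- tabulate(bin, 256)
  g <- (seq_len(256) - 0.5) / 256
  occ <- which(h > 0)
  C <- g[max(occ)] - g[min(occ)]
  S <- function(u) if (u <= 0 || u >= 1) 0 else -u * log(u) - (1 - u) * log(1 - u)
  best <- Inf; bestT <- NA
  for (t in seq(min(occ), max(occ) - 1)) {
    i0 <- 1:t; i1 <- (t + 1):256
    n0 <- sum(h[i0]); n1 <- sum(h[i1])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[i0] * g[i0]) / n0
    mu1 <- sum(h[i1] * g[i1]) / n1
    E <- 0
    for (k in seq_len(256)) {
      if (h[k] == 0) next
      mu <- if (k <= t) mu0 else mu1
      E <- E + h[k] * S(1 / (1 + abs(g[k] - mu) / C))
    }
    if (E < best) { best <- E; bestT <- t }
  }
  bestT / 256
}

# direct 2D convolution with reflect padding (for the pillbox filter)
oracleConvolve <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  h <- (nrow(kern) - 1) / 2
  out <- matrix(0, nr, nc)
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    acc <- 0
    for (dc in -h:h) for (dr in -h:h)
      acc <- acc + kern[dr + h + 1, dc + h + 1] *
        img[oracleReflect(r + dr, nr), oracleReflect(c + dc, nc)]
    out[r, c] <- acc
  }
  out
}

# binary dilation with a 3x3 square by explicit shifting (for bay closing)
oracleDilate3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    sh[okr, okc] <- mask[rs[okr], cs[okc]] > 0
    out <- out | sh
  }
  out * 1L
}
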