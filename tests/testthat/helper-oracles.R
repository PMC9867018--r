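# Independent reference implementations used as test oracles. These are
# deliberately naive (plain R loops, no shared code with the package paths
# they check) and are only ever run on tiny fixtures.

# Reference Canny: same documented conventions as the package (kernel-derived
# sigma, replicated borders, Sobel, 4-bin NMS with >= on both neighbours,
# 8-connected hysteresis), implemented independently with scalar loops.
oracle_canny <- function(img, ksize, low, high) {
  H <- nrow(img); W <- ncol(img)
  sigma <- 0.3 * ((ksize - 1) * 0.5 - 1) + 0.8
  r <- (ksize - 1) / 2
  g <- exp(-0.5 * (-r:r)^2 / sigma^2); g <- g / sum(g)
  cl <- function(i, n) min(max(i, 1), n)
  sm1 <- matrix(0, H, W); sm <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    s <- 0
    for (t in -r:r) s <- s + g[t + r + 1] * img[cl(i + t, H), j]
    sm1[i, j] <- s
  }
  for (i in 1:H) for (j in 1:W) {
    s <- 0
    for (t in -r:r) s <- s + g[t + r + 1] * sm1[i, cl(j + t, W)]
    sm[i, j] <- s
  }
  a <- function(i, j) sm[cl(i, H), cl(j, W)]
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    gx[i, j] <- (a(i - 1, j + 1) + 2 * a(i, j + 1) + a(i + 1, j + 1)) -
      (a(i - 1, j - 1) + 2 * a(i, j - 1) + a(i + 1, j - 1))
    gy[i, j] <- (a(i + 1, j - 1) + 2 * a(i + 1, j) + a(i + 1, j + 1)) -
      (a(i - 1, j - 1) + 2 * a(i - 1, j) + a(i - 1, j + 1))
  }
  mag <- sqrt(gx^2 + gy^2)
  magat <- function(i, j) if (i < 1 || i > H || j < 1 || j > W) 0 else mag[i, j]
  nms <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    m <- mag[i, j]
    if (m < low) next
    ang <- atan2(gy[i, j], gx[i, j]) * 180 / pi
    if (ang < 0) ang <- ang + 180
    d <- if (ang < 22.5 || ang >= 157.5) c(0, 1)
    else if (ang < 67.5) c(1, 1)
    else if (ang < 112.5) c(1, 0)
    else c(1, -1)
    if (m >= magat(i + d[1], j + d[2]) && m >= magat(i - d[1], j - d[2])) {
      nms[i, j] <- m
    }
  }
  out <- matrix(FALSE, H, W)
  queue <- which(nms >= high)
  seen <- logical(H * W); seen[queue] <- TRUE
  while (length(queue)) {
    q <- queue[length(queue)]; queue <- queue[-length(queue)]
    out[q] <- TRUE
    i <- (q - 1) %% H + 1; j <- (q - 1) %/% H + 1
    for (di in -1:1) for (dj in -1:1) {
      p <- i + di; s <- j + dj
      if (p < 1 || p > H || s < 1 || s > W) next
      lin <- p + H * (s - 1)
      if (!seen[lin] && nms[p, s] >= low) { seen[lin] <- TRUE; queue <- c(queue, lin) }
    }
  }
  out
}

# naive connected-component labeling by repeated scanning (slow, independent)
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nbrs <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  nxt <- 0L
  for (i in 1:H) for (j in 1:W) {
    if (!mask[i, j] || lab[i, j] > 0) next
    nxt <- nxt + 1L
    frontier <- list(c(i, j)); lab[i, j] <- nxt
    while (length(frontier)) {
      cur <- frontier[[1]]; frontier <- frontier[-1]
      for (t in seq_len(nrow(nbrs))) {
        p <- cur[1] + nbrs[t, 1]; q <- cur[2] + nbrs[t, 2]
        if (p < 1 || p > H || q < 1 || q > W) next
        if (mask[p, q] && lab[p, q] == 0) {
          lab[p, q] <- nxt
          frontier <- c(frontier, list(c(p, q)))
        }
      }
    }
  }
  lab
}

# 4-connected flood fill of the complement from the border (background)
oracle_background <- function(blocked) {
  H <- nrow(blocked); W <- ncol(blocked)
  open <- !blocked
  reach <- matrix(FALSE, H, W)
  frontier <- list()
  for (i in 1:H) for (j in c(1, W)) {
    if (open[i, j] && !reach[i, j]) { reach[i, j] <- TRUE; frontier <- c(frontier, list(c(i, j))) }
  }
  for (j in 1:W) for (i in c(1, H)) {
    if (open[i, j] && !reach[i, j]) { reach[i, j] <- TRUE; frontier <- c(frontier, list(c(i, j))) }
  }
  while (length(frontier)) {
    cur <- frontier[[1]]; frontier <- frontier[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      p <- cur[1] + d[1]; q <- cur[2] + d[2]
      if (p < 1 || p > H || q < 1 || q > W) next
      if (open[p, q] && !reach[p, q]) { reach[p, q] <- TRUE; frontier <- c(frontier, list(c(p, q))) }
    }
  }
  reach
}

# brute-force one-vs-rest confusion counts
oracle_confusion <- function(true, pred, cls) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(true)) {
    t <- true[i] == cls; p <- pred[i] == cls
    if (t && p) tp <- tp + 1L
    else if (!t && p) fp <- fp + 1L
    else if (t && !p) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# brute-force maximum-intersection component selection (mirrors the
# documented rule: max overlap, then larger area, then earliest row-major
# anchor), written over oracle_label
oracle_refine <- function(pseudo, loc) {
  lab <- oracle_label(pseudo, 8)
  n <- max(lab)
  if (n == 0 || !any(loc)) return(pseudo)
  stats <- data.frame(comp = seq_len(n))
  stats$inter <- vapply(stats$comp, function(c) sum(lab == c & loc), 0)
  if (all(stats$inter == 0)) return(pseudo)
  stats$area <- vapply(stats$comp, function(c) sum(lab == c), 0)
  stats$anchor <- vapply(stats$comp, function(c) which(t(lab) == c)[1], 0) # row-major
  o <- order(-stats$inter, -stats$area, stats$anchor)
  lab == stats$comp[o[1]]
}

binary_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) 1 else sum(a & b) / u
}
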