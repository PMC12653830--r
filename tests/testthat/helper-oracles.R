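# Naive brute-force enumerations of the texture matrices, kept deliberately
# independent of the package's C++ kernels: plain loops over all pixels.
# levels: integer matrix, 0 = outside mask.

naive_glcm <- function(lv, ng, dr, dc) {
  H <- nrow(lv); W <- ncol(lv)
  P <- matrix(0, ng, ng)
  for (r in 1:H) for (c in 1:W) {
    a <- lv[r, c]
    if (a <= 0) next
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
    b <- lv[r2, c2]
    if (b <= 0) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

naive_glrlm <- function(lv, ng, dr, dc) {
  H <- nrow(lv); W <- ncol(lv)
  P <- matrix(0, ng, max(H, W))
  inb <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W
  for (r in 1:H) for (c in 1:W) {
    a <- lv[r, c]
    if (a <= 0) next
    if (inb(r - dr, c - dc) && lv[r - dr, c - dc] == a) next
    len <- 0; rr <- r; cc <- c
    while (inb(rr, cc) && lv[rr, cc] == a) {
      len <- len + 1; rr <- rr + dr; cc <- cc + dc
    }
    P[a, len] <- P[a, len] + 1
  }
  P
}

naive_glszm_zones <- function(lv) {
  H <- nrow(lv); W <- ncol(lv)
  seen <- matrix(FALSE, H, W)
  zones <- list()
  for (r in 1:H) for (c in 1:W) {
    a <- lv[r, c]
    if (a <= 0 || seen[r, c]) next
    queue <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- q[1] + dr; c2 <- q[2] + dc
        if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
        if (!seen[r2, c2] && lv[r2, c2] == a) {
          seen[r2, c2] <- TRUE
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  do.call(rbind, zones)
}

naive_glszm <- function(lv, ng) {
  z <- naive_glszm_zones(lv)
  P <- matrix(0, ng, max(1, max(z[, 2])))
  for (i in seq_len(nrow(z))) P[z[i, 1], z[i, 2]] <- P[z[i, 1], z[i, 2]] + 1
  P
}

naive_gldm <- function(lv, ng, alpha) {
  H <- nrow(lv); W <- ncol(lv)
  P <- matrix(0, ng, 9)
  for (r in 1:H) for (c in 1:W) {
    a <- lv[r, c]
    if (a <= 0) next
    dep <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      b <- lv[r2, c2]
      if (b > 0 && abs(a - b) <= alpha) dep <- dep + 1
    }
    P[a, dep + 1] <- P[a, dep + 1] + 1
  }
  P
}

naive_ngtdm <- function(lv, ng) {
  H <- nrow(lv); W <- ncol(lv)
  NS <- matrix(0, ng, 2)
  for (r in 1:H) for (c in 1:W) {
    a <- lv[r, c]
    if (a <= 0) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
      if (lv[r2, c2] > 0) nb <- c(nb, lv[r2, c2])
    }
    if (!length(nb)) next
    NS[a, 1] <- NS[a, 1] + 1
    NS[a, 2] <- NS[a, 2] + abs(a - mean(nb))
  }
  NS
}

random_level_image <- function(seed, max_side = 8L, ng = 4L,
                               with_mask = TRUE) {
  set.seed(seed)
  H <- sample(2:max_side, 1); W <- sample(2:max_side, 1)
  lv <- matrix(sample.int(ng, H * W, replace = TRUE), H, W)
  if (with_mask && runif(1) < 0.7)
    lv[matrix(runif(H * W) < 0.2, H, W)] <- 0L
  lv
}
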