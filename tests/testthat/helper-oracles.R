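# Independent brute-force oracles.  These re-derive each quantity by the
# most literal method available (exhaustive search, per-pixel scans,
# iterated fixed points) and deliberately share no code with the package
# implementations they check.

# distance to the nearest false pixel, O(n^2) scan
oracle_edt <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  zer <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      if (!mask[r, c]) next
      out[r, c] <- sqrt(min((zer[, 1] - r)^2 + (zer[, 2] - c)^2))
    }
  }
  out
}

# exhaustive between-class-variance maximization over all 256 levels,
# written via the two class means rather than the cumulative form
oracle_otsu <- function(img) {
  v <- as.integer(round(img))
  hst <- tabulate(v + 1L, nbins = 256)
  n <- sum(hst)
  best <- -Inf; ks <- integer(0)
  for (k in 0:254) {
    n1 <- sum(hst[1:(k + 1)])
    if (n1 == 0 || n1 == n) next
    w1 <- n1 / n
    m1 <- sum((0:k) * hst[1:(k + 1)]) / n1
    m2 <- sum(((k + 1):255) * hst[(k + 2):256]) / (n - n1)
    s <- w1 * (1 - w1) * (m1 - m2)^2
    if (s > best + 1e-9) {
      best <- s; ks <- k
    } else if (abs(s - best) <= 1e-9) {
      ks <- c(ks, k)
    }
  }
  as.integer(floor(mean(ks)))
}

oracle_median <- function(img, window = 3) {
  H <- nrow(img); W <- ncol(img); half <- window %/% 2
  out <- img
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      rr <- pmin(pmax((r - half):(r + half), 1), H)
      cc <- pmin(pmax((c - half):(c + half), 1), W)
      v <- sort(as.vector(img[rr, cc]))
      out[r, c] <- v[(length(v) + 1) %/% 2]
    }
  }
  out
}

neighbor_offsets_r <- function(connectivity = 8) {
  offs <- NULL
  for (a in -1:1) for (b in -1:1) {
    if (a == 0 && b == 0) next
    if (connectivity == 4 && a != 0 && b != 0) next
    offs <- rbind(offs, c(a, b))
  }
  offs
}

# plateau-aware regional minima by explicit flood of each plateau
oracle_regional_minima <- function(surf, connectivity = 8) {
  H <- nrow(surf); W <- ncol(surf)
  offs <- neighbor_offsets_r(connectivity)
  seen <- matrix(FALSE, H, W)
  out <- matrix(FALSE, H, W)
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (seen[r0, c0]) next
    v <- surf[r0, c0]
    plateau <- matrix(c(r0, c0), 1)
    seen[r0, c0] <- TRUE
    is_min <- TRUE
    head <- 1
    while (head <= nrow(plateau)) {
      p <- plateau[head, ]; head <- head + 1
      for (k in seq_len(nrow(offs))) {
        rr <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        if (surf[rr, cc] < v) is_min <- FALSE
        if (surf[rr, cc] == v && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          plateau <- rbind(plateau, c(rr, cc))
        }
      }
    }
    if (is_min) out[plateau] <- TRUE
  }
  out
}

# reconstruction by erosion as a literal fixed point of
# J <- pmax(gray_erosion(J), mask)
oracle_reconstruct_erosion <- function(marker, mask, connectivity = 8) {
  offs <- rbind(c(0, 0), neighbor_offsets_r(connectivity))
  H <- nrow(marker); W <- ncol(marker)
  pad <- max(marker, mask) + 1
  ero <- function(m) {
    out <- matrix(Inf, H, W)
    for (k in seq_len(nrow(offs))) {
      sh <- matrix(pad, H, W)
      rs <- seq_len(H) + offs[k, 1]; cs <- seq_len(W) + offs[k, 2]
      okr <- rs >= 1 & rs <= H; okc <- cs >= 1 & cs <= W
      sh[okr, okc] <- m[rs[okr], cs[okc]]
      out <- pmin(out, sh)
    }
    out
  }
  J <- marker
  repeat {
    J2 <- pmax(ero(J), mask)
    if (identical(J2, J)) return(J)
    J <- J2
  }
}

oracle_extended_minima <- function(surf, h, connectivity = 8) {
  hm <- oracle_reconstruct_erosion(surf + h, surf, connectivity)
  oracle_regional_minima(hm, connectivity)
}

oracle_label <- function(mask, connectivity = 8) {
  offs <- neighbor_offsets_r(connectivity)
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(r0, c0), 1)
    lab[r0, c0] <- nxt
    head <- 1
    while (head <= nrow(queue)) {
      p <- queue[head, ]; head <- head + 1
      for (k in seq_len(nrow(offs))) {
        rr <- p[1] + offs[k, 1]; cc <- p[2] + offs[k, 2]
        if (rr < 1 || rr > H || cc < 1 || cc > W) next
        if (mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

# independent priority-flood watershed: seeds grow in ascending height,
# FIFO within a height level, raster-order seeding; conflicting neighbor
# labels at pop time produce a ridge (0)
oracle_watershed <- function(surfq, seeds, connectivity = 8) {
  H <- nrow(surfq); W <- ncol(surfq)
  offs <- neighbor_offsets_r(connectivity)
  lab <- seeds
  done <- matrix(FALSE, H, W)
  done[seeds > 0] <- TRUE
  qh <- numeric(0); qo <- numeric(0); qr <- integer(0); qc <- integer(0)
  cnt <- 0
  push <- function(r, c) {
    cnt <<- cnt + 1
    qh <<- c(qh, surfq[r, c]); qo <<- c(qo, cnt)
    qr <<- c(qr, r); qc <<- c(qc, c)
  }
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (seeds[r, c] <= 0) next
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      if (!done[rr, cc]) push(rr, cc)
    }
  }
  while (length(qh) > 0) {
    i <- order(qh, qo)[1]
    r <- qr[i]; c <- qc[i]
    qh <- qh[-i]; qo <- qo[-i]; qr <- qr[-i]; qc <- qc[-i]
    if (done[r, c]) next
    labs <- integer(0)
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      if (done[rr, cc] && lab[rr, cc] > 0) labs <- c(labs, lab[rr, cc])
    }
    labs <- unique(labs)
    if (length(labs) == 0) next
    done[r, c] <- TRUE
    if (length(labs) > 1) {
      lab[r, c] <- 0L
      next
    }
    lab[r, c] <- labs
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      if (!done[rr, cc]) push(rr, cc)
    }
  }
  lab
}

# label maps agree up to a bijective relabeling (0 must map to 0)
labels_permutation_equal <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!identical(a == 0, b == 0)) return(FALSE)
  key <- paste(a, b)
  map <- unique(cbind(as.vector(a), as.vector(b))[a > 0, , drop = FALSE])
  !any(duplicated(map[, 1])) && !any(duplicated(map[, 2]))
}

# geometry helpers for fixtures
rasterize_disk <- function(radius, pad = 3) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if ((i - ctr)^2 + (j - ctr)^2 <= radius^2) m[i, j] <- 1L
  }
  m
}

random_mask <- function(H, W, p = 0.5) matrix(stats::runif(H * W) < p, H, W)

# erosion derived from dilation through complementation on the infinite
# plane: the mask is false outside the raster, so its complement is true
# there, which the padded dilation makes visible
dual_erode <- function(A, B) {
  r <- (nrow(B) - 1) %/% 2
  H <- nrow(A); W <- ncol(A)
  pad <- matrix(TRUE, H + 2 * r, W + 2 * r)
  pad[r + seq_len(H), r + seq_len(W)] <- !A
  d <- dilate(pad, B)
  !d[r + seq_len(H), r + seq_len(W)]
}
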