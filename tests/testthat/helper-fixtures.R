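# geometric masks used across the shape/pipeline tests

disc_mask <- function(n, r, center = c((n + 1) / 2, (n + 1) / 2)) {
  rw <- row(matrix(0, n, n)); cl <- col(matrix(0, n, n))
  (rw - center[1])^2 + (cl - center[2])^2 <= r^2
}

ellipse_mask <- function(n, a, b, center = c((n + 1) / 2, (n + 1) / 2),
                         theta = 0) {
  rw <- row(matrix(0, n, n)) - center[1]
  cl <- col(matrix(0, n, n)) - center[2]
  u <- rw * cos(theta) + cl * sin(theta)
  v <- -rw * sin(theta) + cl * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

rect_mask <- function(n, rows, cols) {
  m <- matrix(FALSE, n, n)
  m[rows, cols] <- TRUE
  m
}

# a uniform-color slide_image
flat_slide <- function(n, rgb = c(255, 255, 255), mpp = 1) {
  px <- array(0, dim = c(n, n, 3))
  for (k in 1:3) px[, , k] <- rgb[k]
  slide_image(px, mpp = mpp)
}

# paint a mask with a flat RGB color onto a slide
paint <- function(slide, mask, rgb) {
  for (k in 1:3) {
    ch <- slide$pixels[, , k]
    ch[mask] <- rgb[k]
    slide$pixels[, , k] <- ch
  }
  slide
}

# independent hole filler: BFS over the dual-connectivity background from the
# border; background cells never reached are interior holes
oracle_fill <- function(mask, fg_connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (fg_connectivity == 8) {
    moves <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    moves <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  }
  reached <- matrix(FALSE, nr, nc)
  border <- unique(c(which(row(mask) == 1), which(row(mask) == nr),
                     which(col(mask) == 1), which(col(mask) == nc)))
  queue <- border[!mask[border]]
  reached[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    rc <- arrayInd(cur, dim(mask))
    for (m in seq_len(nrow(moves))) {
      r <- rc[1] + moves[m, 1]; c <- rc[2] + moves[m, 2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          !mask[r, c] && !reached[r, c]) {
        reached[r, c] <- TRUE
        queue <- c(queue, (c - 1) * nr + r)
      }
    }
  }
  mask | (!mask & !reached)
}

# independent BFS flood-fill component counter (oracle for .cc_label)
flood_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    moves <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    moves <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  count <- 0
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    count <- count + 1
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      rc <- arrayInd(cur, dim(mask))
      for (m in seq_len(nrow(moves))) {
        r <- rc[1] + moves[m, 1]; c <- rc[2] + moves[m, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue <- c(queue, (c - 1) * nr + r)
        }
      }
    }
  }
  count
}
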