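# Independent brute-force oracles. Each recomputes a quantity by direct
# enumeration or pixel-level loops, sharing no code path with the package
# implementation it checks.

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in perms(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
    }
  }
  out
}

# exhaustive minimum over square assignments
brute_assignment_cost <- function(C) {
  n <- nrow(C)
  best <- Inf
  for (p in perms(n)) {
    v <- sum(C[cbind(seq_len(n), p)])
    if (v < best) best <- v
  }
  best
}

# exhaustive minimum-cost gated partial matching: sum of squared
# displacements of linked pairs plus gate^2 per unmatched point
brute_matching_cost <- function(prev, curr, gate) {
  n <- nrow(prev); m <- nrow(curr)
  d2 <- outer(prev$x, curr$x, `-`)^2 + outer(prev$y, curr$y, `-`)^2
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) {
      tot <- acc + gate^2 * (m - sum(used))
      if (tot < best) best <<- tot
      return()
    }
    rec(i + 1L, used, acc + gate^2)          # leave row i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && d2[i, j] <= gate^2) {
        used[j] <- TRUE
        rec(i + 1L, used, acc + d2[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(m), 0)
  best
}

# exhaustive Otsu: maximize between-class variance over all midpoints of
# consecutive sorted unique values, computing both class moments directly
brute_otsu <- function(x) {
  ux <- sort(unique(x))
  cand <- (head(ux, -1) + tail(ux, -1)) / 2
  bcv <- vapply(cand, function(th) {
    a <- x[x <= th]; b <- x[x > th]
    (length(a) / length(x)) * (length(b) / length(x)) * (mean(a) - mean(b))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

# 8-connected components by breadth-first flood fill
brute_components8 <- function(frame) {
  lab <- matrix(0L, nrow(frame), ncol(frame))
  cur <- 0L
  for (start in which(frame != 0)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      p <- queue[1L]; queue <- queue[-1L]
      y <- ((p - 1L) %% nrow(frame)) + 1L
      x <- ((p - 1L) %/% nrow(frame)) + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1L && yy <= nrow(frame) && xx >= 1L && xx <= ncol(frame) &&
            frame[yy, xx] != 0 && lab[yy, xx] == 0L) {
          lab[yy, xx] <- cur
          queue <- c(queue, (xx - 1L) * nrow(frame) + yy)
        }
      }
    }
  }
  lab
}

# potential of death recomputed from raw pixel sets: flood-fill components,
# per-object mean and boundary centroid by loops, then the pairwise sum
brute_pdeath <- function(frame) {
  lab <- brute_components8(frame)
  n <- max(lab)
  if (n < 2L) return(0)
  means <- numeric(n); cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    px <- which(lab == i, arr.ind = TRUE)
    means[i] <- mean(frame[px])
    onb <- logical(nrow(px))
    for (k in seq_len(nrow(px))) {
      y <- px[k, 1]; x <- px[k, 2]
      nb4 <- rbind(c(y - 1, x), c(y + 1, x), c(y, x - 1), c(y, x + 1))
      for (q in seq_len(4)) {
        yy <- nb4[q, 1]; xx <- nb4[q, 2]
        if (yy < 1 || yy > nrow(frame) || xx < 1 || xx > ncol(frame) ||
            lab[yy, xx] != i) { onb[k] <- TRUE; break }
      }
    }
    bnd <- px[onb, , drop = FALSE]
    cx[i] <- mean(bnd[, 2]); cy[i] <- mean(bnd[, 1])
  }
  total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2) / max(dim(frame))
    total <- total + (means[i] + means[j]) / d
  }
  total / (2 * n)
}

# random sparse map frame holding a handful of constant-valued disks
random_object_frame <- function(side = 40, max_disks = 5) {
  fr <- matrix(0, side, side)
  for (k in seq_len(sample.int(max_disks + 1L, 1L) - 1L)) {
    r <- sample(2:4, 1)
    cx <- sample(seq(r + 1, side - r), 1)
    cy <- sample(seq(r + 1, side - r), 1)
    d2 <- outer((seq_len(side) - cy)^2, (seq_len(side) - cx)^2, `+`)
    fr[d2 <= r^2] <- fr[d2 <= r^2] + runif(1, 0.5, 4)
  }
  fr
}
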