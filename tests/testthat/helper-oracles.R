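# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain loops, no vectorization.

# naive FCM: runs exactly n_iter alternating updates from the given centers
naive_fcm <- function(x, k, m, n_iter, centers) {
  n <- length(x)
  u <- matrix(0, n, k)
  memb <- function(centers) {
    u <- matrix(0, n, k)
    for (i in seq_len(n)) {
      d <- numeric(k)
      for (j in seq_len(k)) d[j] <- abs(x[i] - centers[j])
      if (any(d < 1e-12)) {
        u[i, ] <- (d < 1e-12) / sum(d < 1e-12)
      } else {
        for (j in seq_len(k)) {
          s <- 0
          for (l in seq_len(k)) s <- s + (d[j] / d[l])^(2 / (m - 1))
          u[i, j] <- 1 / s
        }
      }
    }
    u
  }
  u <- memb(centers)
  for (iter in seq_len(n_iter)) {
    for (j in seq_len(k)) {
      num <- 0; den <- 0
      for (i in seq_len(n)) {
        num <- num + u[i, j]^m * x[i]
        den <- den + u[i, j]^m
      }
      if (den > 0) centers[j] <- num / den
    }
    u <- memb(centers)
  }
  list(centers = centers, memberships = u)
}

# exhaustive nearest-center scan
naive_assign <- function(x, centers) {
  out <- integer(length(x))
  for (i in seq_along(x)) {
    best <- 1L
    for (j in seq_along(centers)) {
      if (abs(x[i] - centers[j]) < abs(x[i] - centers[best])) best <- j
    }
    out[i] <- best
  }
  out
}

# stack-based flood fill labeling for arbitrary masks
flood_label <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {  # any scan order is fine
    if (!mask[rr, cc] || labels[rr, cc] > 0L) next
    cur <- cur + 1L
    stack <- list(c(rr, cc))
    labels[rr, cc] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        r2 <- p[1] + o[1]; c2 <- p[2] + o[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && labels[r2, c2] == 0L) {
          labels[r2, c2] <- cur
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  labels
}

# partition signature: set of sorted pixel-index groups, label-order agnostic
partition_signature <- function(labels) {
  fg <- which(labels > 0)
  unname(split(fg, labels[fg]))
}

same_partition <- function(a, b) {
  sa <- lapply(partition_signature(a), sort)
  sb <- lapply(partition_signature(b), sort)
  length(sa) == length(sb) &&
    setequal(vapply(sa, paste, character(1), collapse = ","),
             vapply(sb, paste, character(1), collapse = ","))
}

# circular distance between two rotations modulo pi (axis symmetry)
rotation_error <- function(a, b) {
  d <- abs((a - b) %% pi)
  min(d, pi - d)
}
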