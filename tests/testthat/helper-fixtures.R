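# Shared fixtures and independent oracles. Oracles deliberately use naive
# per-element loops so they share no code path with the implementation.

# small two-region volume: region 1 fills x < split, region 2 the rest,
# inside a one-voxel background margin
two_region_volume <- function(n = 8L, split = NULL) {
  if (is.null(split)) split <- n %/% 2L
  lab <- array(0L, dim = c(n, n, n))
  lab[2:(n - 1L), 2:(n - 1L), 2:(n - 1L)] <- 1L
  lab[(split + 1L):(n - 1L), 2:(n - 1L), 2:(n - 1L)] <- 2L
  atlas_volume(lab)
}

tiny_ontology <- function() {
  build_ontology(data.frame(
    id = c(1L, 2L, 3L),
    name = c("root", "A", "B"),
    parent_id = c(NA, 1L, 1L)))
}

# 10-node tree used for nearest-ancestor checks:
# 1 root; 2,3 children of 1; 4,5 children of 2; 6 child of 4;
# 7 child of 3; 8,9 children of 7; 10 child of 9
deep_ontology <- function() {
  build_ontology(data.frame(
    id = 1:10,
    name = paste0("n", 1:10),
    parent_id = c(NA, 1L, 1L, 2L, 2L, 4L, 3L, 7L, 7L, 9L)))
}

# oracle: slice lookup via an explicit per-pixel loop
oracle_slice <- function(volume, anchoring, width, height) {
  out <- matrix(0L, height, width)
  o <- anchoring$o; u <- anchoring$u; v <- anchoring$v
  sh <- volume$shape
  for (y in seq_len(height)) {
    for (x in seq_len(width)) {
      p <- o + ((x - 0.5) / width) * u + ((y - 0.5) / height) * v
      i <- floor(p + 0.5)
      if (all(i >= 0) && all(i < sh)) {
        out[y, x] <- volume$labels[i[1] + 1L, i[2] + 1L, i[3] + 1L]
      }
    }
  }
  out
}

# oracle: connected components by BFS flood fill
oracle_flood_fill <- function(pixels, connectivity = 8) {
  h <- nrow(pixels); w <- ncol(pixels)
  lab <- matrix(0L, h, w)
  nid <- 0L
  offs <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  for (c0 in seq_len(w)) for (r0 in seq_len(h)) {
    if (!pixels[r0, c0] || lab[r0, c0] != 0L) next
    nid <- nid + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nid
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r <- cur[1] + offs$dr[k]; c <- cur[2] + offs$dc[k]
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            pixels[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nid
          queue <- c(queue, list(c(r, c)))
        }
      }
    }
  }
  list(labels = lab, n_objects = nid)
}

# oracle: BH step-up straight from the definition (rank loop, no cummin)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# oracle: exact two-sided signed-rank p by enumerating all sign assignments
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  V_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  Vs <- as.matrix(signs) %*% rk
  mu <- n * (n + 1) / 4
  mean(abs(Vs - mu) >= abs(V_obs - mu) - 1e-12)
}

random_anchoring <- function(shape) {
  repeat {
    o <- runif(3, -2, shape + 1)
    u <- runif(3, -shape, shape)
    v <- runif(3, -shape, shape)
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    if (sqrt(sum(u^2)) > 1 && sqrt(sum(v^2)) > 1 &&
        sqrt(sum(cr^2)) > 1e-6) {
      return(linear_anchoring(o, u, v))
    }
  }
}
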