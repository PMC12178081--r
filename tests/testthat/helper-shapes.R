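# shared test utilities: small random shapes and independent mini-oracles

rand_config <- function(k, m = 2L) matrix(rnorm(k * m), k, m)

rand_landmark_set <- function(n, k, m = 2L) {
  arr <- array(rnorm(n * k * m), c(n, k, m))
  landmark_set(arr)
}

# similarity-transformed copy of a 2D configuration
sim_copy_2d <- function(cfg, angle, scale, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  sweep(cfg %*% R * scale, 2L, shift, `+`)
}

# brute-force full Procrustes distance for 2D configs: grid + refine over
# the rotation angle after centring and scaling (independent of the SVD
# solution used by the package)
brute_procrustes_2d <- function(a, b) {
  norm_cfg <- function(x) {
    x <- sweep(x, 2L, colMeans(x))
    x / sqrt(sum(x^2))
  }
  a <- norm_cfg(a); b <- norm_cfg(b)
  dist_at <- function(th) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    sqrt(sum((a - b %*% R)^2))
  }
  grid <- seq(0, 2 * pi, length.out = 721L)
  best <- grid[which.min(vapply(grid, dist_at, numeric(1L)))]
  stats::optimize(dist_at, interval = best + c(-0.02, 0.02))$objective
}

# min distance from each point of A to the point set B (both dense samples)
set_distance <- function(A, B) {
  max(apply(A, 1L, function(p) sqrt(min(colSums((t(B) - p)^2)))))
}

# O(q^2) Pareto domination oracle (maximisation in all columns)
brute_pareto <- function(W) {
  q <- nrow(W)
  which(vapply(seq_len(q), function(i) {
    !any(vapply(seq_len(q), function(j) {
      j != i && all(W[j, ] >= W[i, ]) && any(W[j, ] > W[i, ])
    }, logical(1L)))
  }, logical(1L)))
}

# recursive shared-path-length oracle for the BM tip covariance
recursive_vcv <- function(tree) {
  s <- length(tree$tip.label)
  C <- matrix(0, s, s, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(s), function(tip) {
    # edges on the root-to-tip path
    path <- integer()
    node <- tip
    repeat {
      e <- which(tree$edge[, 2L] == node)
      if (length(e) == 0L) break
      path <- c(path, e)
      node <- tree$edge[e, 1L]
    }
    path
  })
  for (i in seq_len(s)) for (j in seq_len(s)) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- sum(tree$edge.length[shared])
  }
  C
}
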