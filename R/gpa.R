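#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of the landmarks to their centroid.
#'
#' @param config numeric `k x m` matrix of landmark coordinates.
#' @return a positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 1L) stop("empty configuration", call. = FALSE)
  ctr <- colMeans(config)
  cs <- sqrt(sum(sweep(config, 2L, ctr)^2))
  if (cs == 0)
    stop("degenerate configuration: all landmarks coincide (centroid size 0)",
         call. = FALSE)
  cs
}

# optimal rotation of A onto B (both centered), reflections forbidden
opa_rotation <- function(A, B) {
  s <- svd(crossprod(A, B))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

center_scale_config <- function(cfg, id = "?") {
  cfg <- sweep(cfg, 2L, colMeans(cfg))
  cs <- sqrt(sum(cfg^2))
  if (cs < .Machine$double.eps * 100)
    stop("degenerate configuration for specimen '", id,
         "': centroid size is 0", call. = FALSE)
  cfg / cs
}

#' Generalized Procrustes alignment
#'
#' Iteratively removes position, scale and orientation differences from a
#' sample of landmark configurations. Each configuration is centred at the
#' origin, scaled to unit centroid size, and rotated (reflections are not
#' allowed) onto an iteratively updated consensus shape, until the consensus
#' stabilises.
#'
#' @param raw a [landmark_set] of raw configurations (`n >= 2`, `k >= 3`).
#' @param tol consensus-change convergence tolerance (Frobenius norm).
#' @param max_iter iteration cap.
#' @return a list with `aligned` (a [landmark_set], each configuration
#'   centred with unit centroid size), `consensus` (`k x m` mean shape, unit
#'   centroid size), `centroid_sizes` (the original sizes), `iterations` and
#'   `ss_trace` (summed squared distance to the consensus per iteration,
#'   non-increasing).
#' @export
procrustes_align <- function(raw, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(raw, "landmark_set"))
  d <- dim(raw$coords)
  n <- d[1L]; k <- d[2L]; m <- d[3L]
  if (n < 2L) stop("need at least two configurations", call. = FALSE)
  if (k < 3L) stop("need at least three landmarks", call. = FALSE)
  sizes <- numeric(n)
  confs <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- raw$coords[i, , ]
    ctr <- colMeans(cfg)
    cfg <- sweep(cfg, 2L, ctr)
    sizes[i] <- sqrt(sum(cfg^2))
    if (sizes[i] < .Machine$double.eps * 100)
      stop("degenerate configuration for specimen '", raw$ids[i],
           "': centroid size is 0", call. = FALSE)
    confs[[i]] <- cfg / sizes[i]
  }
  consensus <- confs[[1L]]
  iter <- 0L
  ss_trace <- numeric()
  repeat {
    iter <- iter + 1L
    rotated <- lapply(confs, function(cfg) cfg %*% opa_rotation(cfg, consensus))
    ss_trace[iter] <- sum(vapply(rotated, function(cfg)
      sum((cfg - consensus)^2), numeric(1L)))
    new_cons <- Reduce(`+`, rotated) / n
    new_cons <- sweep(new_cons, 2L, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    confs <- rotated
    if (delta < tol || iter >= max_iter) break
  }
  coords <- array(NA_real_, c(n, k, m))
  for (i in seq_len(n)) coords[i, , ] <- confs[[i]]
  list(aligned = landmark_set(coords, ids = raw$ids),
       consensus = consensus,
       centroid_sizes = sizes,
       iterations = iter,
       ss_trace = ss_trace)
}

#' Procrustes distance between two configurations
#'
#' Full Procrustes distance: both configurations are centred, scaled to unit
#' centroid size and optimally rotated (no reflection); the distance is the
#' root summed squared difference of the superimposed coordinates.
#'
#' @param a,b `k x m` landmark matrices with matching dimensions.
#' @return a non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("configurations must share dimensions", call. = FALSE)
  a <- center_scale_config(a, "a")
  b <- center_scale_config(b, "b")
  b <- b %*% opa_rotation(b, a)
  sqrt(sum((a - b)^2))
}
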