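#' Fit a thin-plate spline interpolant
#'
#' Solves the standard bordered thin-plate spline system mapping `source`
#' landmarks onto `target` values, with exact interpolation at the source
#' points. The radial kernel is U(r) = r^2 log(r^2) (with U(0) = 0) for 2D
#' sources and U(r) = r for 3D sources. `target` may have any number of
#' columns: `m` columns give the usual warp between landmark configurations,
#' a single column gives a scalar interpolant over the source positions
#' (used for performance landscapes).
#'
#' @param source `k x m` matrix of source landmarks (`m` 2 or 3;
#'   `k > m + 1`; no duplicated rows; not all collinear/coplanar).
#' @param target `k x d` matrix of target values (a vector is taken as one
#'   column).
#' @return an object of class `tps_map` with elements `source`, `target`,
#'   `weights` (`k x d` non-affine coefficients), `affine`
#'   (`(m+1) x d` coefficients, intercept row first) and `energy`
#'   (non-negative bending energy, summed over target columns).
#' @seealso [tps_warp()]
#' @export
tps_fit <- function(source, target) {
  source <- as.matrix(source)
  if (is.null(dim(target))) target <- matrix(target, ncol = 1L)
  target <- as.matrix(target)
  k <- nrow(source); m <- ncol(source)
  if (!m %in% c(2L, 3L)) stop("source must be 2D or 3D", call. = FALSE)
  if (nrow(target) != k)
    stop("source and target must have the same number of rows", call. = FALSE)
  if (k <= m + 1L)
    stop("need more than m + 1 = ", m + 1L, " landmarks", call. = FALSE)
  dmat <- as.matrix(stats::dist(source))
  dup <- which(dmat < 1e-12 & upper.tri(dmat), arr.ind = TRUE)
  if (nrow(dup) > 0L)
    stop("duplicated source landmarks: ",
         paste(apply(dup, 1L, function(r) paste(r[1L], r[2L], sep = "/")),
               collapse = ", "), call. = FALSE)
  K <- tps_kernel(dmat, m)
  P <- cbind(1, source)
  if (qr(P)$rank < m + 1L)
    stop("source landmarks are ",
         if (m == 2L) "collinear" else "coplanar",
         "; thin-plate spline system is singular", call. = FALSE)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, m + 1L, m + 1L)))
  rhs <- rbind(target, matrix(0, m + 1L, ncol(target)))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular thin-plate spline system: ", conditionMessage(e),
         call. = FALSE))
  W <- sol[seq_len(k), , drop = FALSE]
  A <- sol[k + seq_len(m + 1L), , drop = FALSE]
  e <- sum(W * (K %*% W))
  if (m == 3L) e <- -e  # U(r) = r is conditionally negative definite
  if (e < 0 && e > -1e-8) e <- 0
  structure(list(source = source, target = target, weights = W, affine = A,
                 dim = m, energy = e),
            class = "tps_map")
}

tps_kernel <- function(r, m) {
  if (m == 2L) {
    U <- matrix(0, nrow(r), ncol(r))
    pos <- r > 0
    U[pos] <- r[pos]^2 * log(r[pos]^2)
    U
  } else {
    r
  }
}

#' Evaluate a thin-plate spline at query points
#'
#' Deterministic evaluation of the affine plus radial-kernel terms of a
#' fitted [tps_fit()] map at arbitrary query positions.
#'
#' @param map a `tps_map`.
#' @param query `q x m` matrix of evaluation points (a vector of length `m`
#'   is taken as one point).
#' @return `q x d` matrix of warped points / interpolated values.
#' @export
tps_warp <- function(map, query) {
  stopifnot(inherits(map, "tps_map"))
  if (is.null(dim(query))) query <- matrix(query, ncol = map$dim)
  query <- as.matrix(query)
  if (ncol(query) != map$dim)
    stop("query dimension (", ncol(query), ") does not match map (",
         map$dim, ")", call. = FALSE)
  # distances query x source
  q2 <- rowSums(query^2); s2 <- rowSums(map$source^2)
  d2 <- outer(q2, s2, `+`) - 2 * query %*% t(map$source)
  d2[d2 < 0] <- 0
  U <- tps_kernel(sqrt(d2), map$dim)
  cbind(1, query) %*% map$affine + U %*% map$weights
}

#' @export
print.tps_map <- function(x, ...) {
  cat("<tps_map> ", nrow(x$source), " landmarks, ", x$dim, "D -> ",
      ncol(x$target), " target column(s); bending energy ",
      format(x$energy, digits = 4), "\n", sep = "")
  invisible(x)
}
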