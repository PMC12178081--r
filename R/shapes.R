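#' Landmark configuration set
#'
#' Container for a sample of 2D or 3D landmark configurations: an
#' `n x k x m` array of coordinates (`n` specimens, `k` landmarks,
#' `m` dimensions) plus specimen identifiers. Coordinates keep the input's
#' native units until Procrustes alignment, after which they are
#' dimensionless.
#'
#' @param coords numeric `n x k x m` array, or a single `k x m` matrix
#'   (promoted to `n = 1`).
#' @param ids character vector of specimen labels; defaults to
#'   `"s1", "s2", ...`.
#' @return an object of class `landmark_set` with elements `coords`, `ids`
#'   and `dim`.
#' @export
landmark_set <- function(coords, ids = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  if (length(dim(coords)) != 3L)
    stop("`coords` must be an n x k x m array", call. = FALSE)
  m <- dim(coords)[3L]
  if (!m %in% c(2L, 3L))
    stop("landmark dimensionality must be 2 or 3, got ", m, call. = FALSE)
  if (dim(coords)[2L] < 1L) stop("need at least one landmark", call. = FALSE)
  if (anyNA(coords)) stop("landmark coordinates contain NA/NaN", call. = FALSE)
  n <- dim(coords)[1L]
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  if (length(ids) != n)
    stop("`ids` length (", length(ids), ") != number of specimens (", n, ")",
         call. = FALSE)
  structure(list(coords = coords, ids = as.character(ids), dim = m),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  d <- dim(x$coords)
  cat("<landmark_set> ", d[1L], " specimens, ", d[2L], " landmarks, ",
      d[3L], "D\n", sep = "")
  invisible(x)
}

#' @export
length.landmark_set <- function(x) dim(x$coords)[1L]

#' Elliptic Fourier coefficient set
#'
#' Container for per-specimen elliptic Fourier descriptors of closed 2D
#' outlines: an `n x h x 4` array holding, for each harmonic `j`, the
#' quadruple (a_j, b_j, c_j, d_j), plus optional per-specimen centre
#' terms (A0, C0). Coefficients are assumed to be pre-normalised upstream
#' for starting point and rotation if such invariance is required; no
#' harmonic normalisation is applied here.
#'
#' @param coeffs numeric `n x h x 4` array, or an `h x 4` matrix (promoted
#'   to `n = 1`).
#' @param offset optional `n x 2` matrix of (A0, C0) centre terms; defaults
#'   to zeros.
#' @param ids specimen labels.
#' @return an object of class `outline_coeffs`.
#' @export
outline_coeffs <- function(coeffs, offset = NULL, ids = NULL) {
  if (is.matrix(coeffs)) coeffs <- array(coeffs, dim = c(1L, dim(coeffs)))
  if (length(dim(coeffs)) != 3L || dim(coeffs)[3L] != 4L)
    stop("`coeffs` must be an n x h x 4 array", call. = FALSE)
  if (dim(coeffs)[2L] < 1L) stop("need at least one harmonic", call. = FALSE)
  n <- dim(coeffs)[1L]
  if (is.null(offset)) offset <- matrix(0, n, 2L)
  offset <- matrix(offset, n, 2L)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  structure(list(coeffs = coeffs, offset = offset, ids = as.character(ids)),
            class = "outline_coeffs")
}

#' @export
print.outline_coeffs <- function(x, ...) {
  d <- dim(x$coeffs)
  cat("<outline_coeffs> ", d[1L], " outlines, ", d[2L], " harmonics\n",
      sep = "")
  invisible(x)
}

#' @export
length.outline_coeffs <- function(x) dim(x$coeffs)[1L]

#' Flattened shape-variable matrix
#'
#' The common currency of all ordinations: an `n x p` matrix of shape
#' variables with a stored mean vector and enough metadata (`kind`, `k`,
#' `m` or `h`) to map rows back to their native representation.
#' Landmark configurations are flattened landmark-major, coordinate-minor
#' (x1, y1\[, z1\], x2, ...); Fourier coefficients harmonic-major
#' (a1, b1, c1, d1, a2, ...).
#'
#' @param X numeric `n x p` matrix.
#' @param kind one of `"landmarks2d"`, `"landmarks3d"`, `"fourier"`.
#' @param k,m landmark count and dimensionality (landmark kinds).
#' @param h harmonic count (fourier kind).
#' @param ids row labels.
#' @param center optional stored mean; defaults to the column means of `X`.
#' @return an object of class `shape_matrix`.
#' @export
shape_matrix <- function(X, kind, k = NULL, m = NULL, h = NULL, ids = NULL,
                         center = NULL) {
  X <- as.matrix(X)
  kind <- match.arg(kind, c("landmarks2d", "landmarks3d", "fourier"))
  p <- ncol(X)
  if (kind == "fourier") {
    if (is.null(h)) h <- p %/% 4L
    if (h %% 1 != 0) stop("`h` must be an integer", call. = FALSE)
    h <- as.integer(h)
    if (p != 4L * h)
      stop("fourier shape matrix needs p = 4h columns; p = ", p, ", h = ", h,
           call. = FALSE)
  } else {
    m <- if (kind == "landmarks2d") 2L else 3L
    if (is.null(k)) k <- p %/% m
    if (k %% 1 != 0) stop("`k` must be an integer", call. = FALSE)
    k <- as.integer(k)
    if (p != k * m)
      stop("landmark shape matrix needs p = k*m columns; p = ", p,
           call. = FALSE)
  }
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  if (is.null(center)) center <- colMeans(X)
  if (length(center) != p) stop("`center` must have length p", call. = FALSE)
  rownames(X) <- ids
  if (is.null(colnames(X))) colnames(X) <- shape_var_names(kind, k, m, h)
  structure(list(X = X, mean = as.numeric(center), kind = kind,
                 k = k, m = m, h = h, ids = as.character(ids)),
            class = "shape_matrix")
}

shape_var_names <- function(kind, k, m, h) {
  if (kind == "fourier") {
    as.vector(t(outer(seq_len(h), c("a", "b", "c", "d"),
                      function(j, l) paste0(l, j))))
  } else {
    ax <- c("x", "y", "z")[seq_len(m)]
    as.vector(t(outer(seq_len(k), ax, function(i, a) paste0(a, i))))
  }
}

#' @export
print.shape_matrix <- function(x, ...) {
  cat("<shape_matrix> ", nrow(x$X), " x ", ncol(x$X), " (", x$kind, ")\n",
      sep = "")
  invisible(x)
}

#' @export
dim.shape_matrix <- function(x) dim(x$X)

#' Flatten shapes into a shape-variable matrix
#'
#' Converts a [landmark_set] or [outline_coeffs] into a [shape_matrix].
#' The flattening is a bijection: [unflatten_shapes()] restores the native
#' representation exactly.
#'
#' @param x a `landmark_set` or `outline_coeffs` object.
#' @param ... unused.
#' @return a [shape_matrix].
#' @export
as_shape_matrix <- function(x, ...) UseMethod("as_shape_matrix")

#' @export
as_shape_matrix.landmark_set <- function(x, ...) {
  d <- dim(x$coords)
  n <- d[1L]; k <- d[2L]; m <- d[3L]
  X <- t(apply(x$coords, 1L, function(cfg) as.vector(t(cfg))))
  X <- matrix(X, nrow = n)  # guard n = 1 collapse
  shape_matrix(X, kind = if (m == 2L) "landmarks2d" else "landmarks3d",
               k = k, m = m, ids = x$ids)
}

#' @export
as_shape_matrix.outline_coeffs <- function(x, ...) {
  d <- dim(x$coeffs)
  n <- d[1L]; h <- d[2L]
  X <- t(apply(x$coeffs, 1L, function(cf) as.vector(t(cf))))
  X <- matrix(X, nrow = n)
  shape_matrix(X, kind = "fourier", h = h, ids = x$ids)
}

#' @export
as_shape_matrix.shape_matrix <- function(x, ...) x

#' Restore the native shape representation from flattened rows
#'
#' Inverse of [as_shape_matrix()]. Given a matrix of flattened rows (by
#' default the shape matrix's own rows — but any compatible matrix, e.g.
#' background model shapes, can be supplied) returns a [landmark_set] or
#' [outline_coeffs] according to `sm$kind`.
#'
#' @param sm a [shape_matrix] carrying the metadata.
#' @param rows optional `q x p` matrix of flattened shapes; default `sm$X`.
#' @param ids labels for the restored shapes.
#' @return a [landmark_set] or [outline_coeffs].
#' @export
unflatten_shapes <- function(sm, rows = NULL, ids = NULL) {
  stopifnot(inherits(sm, "shape_matrix"))
  if (is.null(rows)) {
    rows <- sm$X
    if (is.null(ids)) ids <- sm$ids
  }
  rows <- matrix(rows, ncol = ncol(sm$X))
  if (sm$kind == "fourier") {
    h <- sm$h
    arr <- array(NA_real_, c(nrow(rows), h, 4L))
    for (i in seq_len(nrow(rows)))
      arr[i, , ] <- matrix(rows[i, ], nrow = h, ncol = 4L, byrow = TRUE)
    outline_coeffs(arr, ids = ids)
  } else {
    k <- sm$k; m <- sm$m
    arr <- array(NA_real_, c(nrow(rows), k, m))
    for (i in seq_len(nrow(rows)))
      arr[i, , ] <- matrix(rows[i, ], nrow = k, ncol = m, byrow = TRUE)
    landmark_set(arr, ids = ids)
  }
}

# single configuration -> flattened row (landmark-major)
flatten_config <- function(cfg) as.vector(t(cfg))

# flattened row -> k x m configuration
unflatten_config <- function(v, m) matrix(v, ncol = m, byrow = TRUE)
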