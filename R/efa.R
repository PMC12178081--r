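#' Elliptic Fourier decomposition of a closed outline
#'
#' Decomposes a closed 2D polyline into elliptic Fourier coefficients under
#' cumulative chord-length parameterisation: for harmonic j the quadruple
#' (a_j, b_j, c_j, d_j), plus the outline centre (A0, C0). No starting-point
#' or rotation normalisation is applied; outlines are assumed to be
#' pre-normalised upstream if such invariance is needed.
#'
#' @param outline `t x 2` matrix tracing the outline; if the trace is not
#'   closed the first point is appended. Needs `t >= 2h + 1` distinct points.
#' @param h number of harmonics.
#' @return an [outline_coeffs] with one row and `offset = (A0, C0)`.
#' @seealso [efa_reconstruct()]
#' @export
efa_decompose <- function(outline, h, id = "outline") {
  outline <- as.matrix(outline)
  if (ncol(outline) != 2L) stop("outline must be t x 2", call. = FALSE)
  if (h < 1L) stop("need h >= 1 harmonics", call. = FALSE)
  # close the trace, drop zero-length segments
  if (any(outline[1L, ] != outline[nrow(outline), ]))
    outline <- rbind(outline, outline[1L, ])
  seg <- diff(outline)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 0
  seg <- seg[keep, , drop = FALSE]
  len <- len[keep]
  if (length(len) == 0L || sum(len) == 0)
    stop("degenerate outline: zero perimeter", call. = FALSE)
  npts <- length(len) + 1L
  if (npts < 2L * h + 1L)
    stop("need at least 2h + 1 = ", 2L * h + 1L,
         " distinct outline points for h = ", h, " harmonics", call. = FALSE)
  pts <- outline[c(TRUE, keep), , drop = FALSE]
  tt <- c(0, cumsum(len))
  Tt <- tt[length(tt)]
  dx <- seg[, 1L]; dy <- seg[, 2L]
  t0 <- tt[-length(tt)]; t1 <- tt[-1L]
  cf <- matrix(NA_real_, h, 4L,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  for (j in seq_len(h)) {
    w <- 2 * pi * j / Tt
    cosd <- cos(w * t1) - cos(w * t0)
    sind <- sin(w * t1) - sin(w * t0)
    f <- Tt / (2 * pi^2 * j^2)
    cf[j, 1L] <- f * sum(dx / len * cosd)
    cf[j, 2L] <- f * sum(dx / len * sind)
    cf[j, 3L] <- f * sum(dy / len * cosd)
    cf[j, 4L] <- f * sum(dy / len * sind)
  }
  # centre terms: mean of the piecewise-linear trace over arc length
  x <- pts[, 1L]; y <- pts[, 2L]
  A0 <- sum(len * (x[-1L] + x[-length(x)]) / 2) / Tt
  C0 <- sum(len * (y[-1L] + y[-length(y)]) / 2) / Tt
  outline_coeffs(cf, offset = c(A0, C0), ids = id)
}

#' Reconstruct a closed outline from elliptic Fourier coefficients
#'
#' Evaluates x(t) = A0 + sum_j a_j cos(jt) + b_j sin(jt) and
#' y(t) = C0 + sum_j c_j cos(jt) + d_j sin(jt) at `n_points` evenly spaced
#' parameter values spanning one full period, so the returned polyline is
#' closed (first point equals last point).
#'
#' @param coeffs an [outline_coeffs]; if it holds several outlines, `row`
#'   selects one.
#' @param n_points number of points on the returned polyline (`>= 3`).
#' @param row which outline to reconstruct.
#' @return `n_points x 2` matrix tracing the closed outline.
#' @export
efa_reconstruct <- function(coeffs, n_points = 120L, row = 1L) {
  stopifnot(inherits(coeffs, "outline_coeffs"))
  if (n_points < 3L) stop("need n_points >= 3", call. = FALSE)
  cf <- coeffs$coeffs[row, , , drop = FALSE]
  h <- dim(cf)[2L]
  off <- coeffs$offset[row, ]
  th <- seq(0, 2 * pi, length.out = n_points)
  x <- rep(off[1L], n_points)
  y <- rep(off[2L], n_points)
  for (j in seq_len(h)) {
    x <- x + cf[1L, j, 1L] * cos(j * th) + cf[1L, j, 2L] * sin(j * th)
    y <- y + cf[1L, j, 3L] * cos(j * th) + cf[1L, j, 4L] * sin(j * th)
  }
  cbind(x = x, y = y)
}

#' Decompose many outlines at once
#'
#' @param outlines list of `t x 2` matrices.
#' @param h harmonic count shared by all outlines.
#' @param ids labels.
#' @return an [outline_coeffs] with one row per outline.
#' @export
efa_decompose_all <- function(outlines, h, ids = NULL) {
  n <- length(outlines)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  arr <- array(NA_real_, c(n, h, 4L))
  off <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    oc <- efa_decompose(outlines[[i]], h, id = ids[i])
    arr[i, , ] <- oc$coeffs[1L, , ]
    off[i, ] <- oc$offset[1L, ]
  }
  outline_coeffs(arr, offset = off, ids = ids)
}
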