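#' Project a performance landscape into morphospace
#'
#' Interpolates a functional/performance metric measured at morphospace
#' positions over the canvas range, giving a low-dimensional approximation
#' of the (performance component of the) adaptive landscape. In
#' `"empirical"` mode the support positions are scores of measured
#' specimens; in `"theoretical"` mode they are an [extract_shapes()] grid
#' whose shapes were measured externally. Interpolation is by thin-plate
#' spline (2D kernel; exact at the supports and reproducing affine
#' surfaces); an inverse-distance-weighting fallback is used if the TPS
#' system is near-singular.
#'
#' @param canvas an `mspace_canvas`.
#' @param positions `q x 2` support positions on the plotted plane
#'   (`q >= 4`, not all collinear).
#' @param values length-`q` performance values at the supports.
#' @param mode `"empirical"` or `"theoretical"` (annotation only; the
#'   interpolation is identical).
#' @param grid_n resolution of the interpolated grid per side.
#' @param interpolator `"tps"` or `"idw"`.
#' @return the canvas with a `"landscape"` layer holding an
#'   `mspace_landscape`: supports, values, `grid_x`, `grid_y` and the
#'   `grid_n x grid_n` value matrix `grid_values`.
#' @export
proj_landscape <- function(canvas, positions, values,
                           mode = c("empirical", "theoretical"),
                           grid_n = 32L, interpolator = c("tps", "idw")) {
  stopifnot(inherits(canvas, "mspace_canvas"))
  ls <- shape_landscape(positions, values, xlim = canvas$xlim,
                        ylim = canvas$ylim, mode = match.arg(mode),
                        grid_n = grid_n,
                        interpolator = match.arg(interpolator))
  add_layer(canvas, list(type = "landscape", landscape = ls))
}

#' Interpolated performance landscape over a score plane
#'
#' Standalone constructor behind [proj_landscape()].
#'
#' @inheritParams proj_landscape
#' @param xlim,ylim extent of the interpolated grid.
#' @return an object of class `mspace_landscape` with a `predict()`-like
#'   evaluator in `$interp` (function of a `q x 2` matrix).
#' @export
shape_landscape <- function(positions, values,
                            xlim = NULL, ylim = NULL,
                            mode = c("empirical", "theoretical"),
                            grid_n = 32L, interpolator = c("tps", "idw")) {
  positions <- as.matrix(positions)
  mode <- match.arg(mode)
  interpolator <- match.arg(interpolator)
  if (ncol(positions) != 2L) stop("positions must be q x 2", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) != nrow(positions))
    stop("one value per position required", call. = FALSE)
  if (anyNA(positions) || anyNA(values))
    stop("positions/values contain missing entries", call. = FALSE)
  if (nrow(positions) < 4L)
    stop("need at least 4 support positions", call. = FALSE)
  if (qr(cbind(1, positions))$rank < 3L)
    stop("support positions are collinear; add positions covering the ",
         "plane", call. = FALSE)
  if (is.null(xlim)) xlim <- range(positions[, 1L])
  if (is.null(ylim)) ylim <- range(positions[, 2L])
  interp <- NULL
  if (interpolator == "tps") {
    fit <- tryCatch(tps_fit(positions, values), error = function(e) NULL)
    if (!is.null(fit)) interp <- function(q) as.numeric(tps_warp(fit, q))
  }
  if (is.null(interp)) {
    interpolator <- "idw"
    interp <- idw_interpolator(positions, values)
  }
  gx <- seq(xlim[1L], xlim[2L], length.out = grid_n)
  gy <- seq(ylim[1L], ylim[2L], length.out = grid_n)
  gq <- as.matrix(expand.grid(x = gx, y = gy))
  gv <- matrix(interp(gq), grid_n, grid_n)
  structure(list(positions = positions, values = values, mode = mode,
                 interpolator = interpolator, interp = interp,
                 grid_x = gx, grid_y = gy, grid_values = gv),
            class = "mspace_landscape")
}

idw_interpolator <- function(positions, values, power = 2) {
  force(positions); force(values)
  function(q) {
    q <- as.matrix(q)
    apply(q, 1L, function(pt) {
      d2 <- colSums((t(positions) - pt)^2)
      hit <- which(d2 < 1e-24)
      if (length(hit) > 0L) return(values[hit[1L]])
      w <- 1 / d2^(power / 2)
      sum(w * values) / sum(w)
    })
  }
}

#' @export
print.mspace_landscape <- function(x, ...) {
  cat("<mspace_landscape> ", x$mode, ", ", nrow(x$positions),
      " supports, ", length(x$grid_x), " x ", length(x$grid_y),
      " grid (", x$interpolator, ")\n", sep = "")
  invisible(x)
}

#' Pareto front and optimality ranks for competing performance metrics
#'
#' For shapes scored on two (or more) performance metrics engaged in a
#' trade-off, finds the non-dominated subset (the Pareto front: no other
#' point is at least as good on every metric and strictly better on one)
#' and assigns every point an optimality rank by iterative front peeling
#' (rank 1 = the front; remove it, rank the next front 2, and so on).
#' The normalised rank, `1 - (rank - 1)/max(rank)`, is an optimality score
#' interpolable with [proj_landscape()] into a Pareto optimality surface.
#'
#' @param values `q x 2` (or more columns) matrix of performance metrics;
#'   all entries finite.
#' @param orientation per-metric `"max"` or `"min"` (recycled).
#' @return an object of class `pareto_result`: `front` (indices, sorted),
#'   `rank` (length `q`), `optimality` (normalised rank in (0, 1]) and
#'   `orientation`.
#' @export
pareto_front <- function(values, orientation = "max") {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop("need at least one point", call. = FALSE)
  if (any(!is.finite(values)))
    stop("performance values must be finite (no NaN/NA/Inf)", call. = FALSE)
  orientation <- rep_len(match.arg(orientation, c("max", "min"),
                                   several.ok = TRUE), ncol(values))
  W <- values
  for (j in seq_len(ncol(W))) if (orientation[j] == "min") W[, j] <- -W[, j]
  q <- nrow(W)
  rank <- rep(NA_integer_, q)
  remaining <- seq_len(q)
  r <- 0L
  while (length(remaining) > 0L) {
    r <- r + 1L
    sub <- W[remaining, , drop = FALSE]
    nd <- vapply(seq_along(remaining), function(i) {
      !any(vapply(seq_along(remaining), function(j) {
        j != i && all(sub[j, ] >= sub[i, ]) && any(sub[j, ] > sub[i, ])
      }, logical(1L)))
    }, logical(1L))
    rank[remaining[nd]] <- r
    remaining <- remaining[!nd]
  }
  structure(list(front = which(rank == 1L), rank = rank,
                 optimality = 1 - (rank - 1L) / max(rank),
                 orientation = orientation),
            class = "pareto_result")
}

#' @export
print.pareto_result <- function(x, ...) {
  cat("<pareto_result> ", length(x$rank), " points, front of ",
      length(x$front), ", ", max(x$rank), " peel(s)\n", sep = "")
  invisible(x)
}

#' Project a Pareto front and optimality surface into morphospace
#'
#' Convenience combination: computes [pareto_front()] for performance
#' values tied to morphospace positions, projects the front as a layer and
#' (optionally) the interpolated optimality surface as a landscape layer.
#'
#' @param canvas an `mspace_canvas`.
#' @param positions `q x 2` plane positions of the scored shapes.
#' @param values `q x k` performance metrics.
#' @param orientation per-metric `"max"`/`"min"`.
#' @param surface also add the interpolated optimality landscape?
#' @return the canvas with a `"pareto"` layer (and a `"landscape"` layer if
#'   `surface`).
#' @export
proj_pareto <- function(canvas, positions, values, orientation = "max",
                        surface = TRUE) {
  stopifnot(inherits(canvas, "mspace_canvas"))
  positions <- as.matrix(positions)
  res <- pareto_front(values, orientation)
  canvas <- add_layer(canvas, list(type = "pareto", result = res,
                                   positions = positions,
                                   front_xy = positions[res$front, ,
                                                        drop = FALSE]))
  if (surface)
    canvas <- proj_landscape(canvas, positions, res$optimality,
                             mode = "theoretical")
  canvas
}
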