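#' Build a morphospace canvas
#'
#' Lays out the plane spanned by a pair of ordination axes and computes a
#' grid of regularly spaced background shape models over it by inverse
#' mapping: the shape at grid position (s_i, s_j) is
#' `center + s_i * v_i + s_j * v_j`, with all non-plotted axes held at 0.
#' Rendering accessories (a wireframe edge list for landmark data, a
#' template polyline to be thin-plate-spline warped) are stored alongside.
#' Projection layers are added to the canvas with the `proj_*` family; the
#' underlying ordination is never mutated by layering.
#'
#' @param ord a `shape_ordination`.
#' @param axes integer pair (i, j) of distinct axis indices.
#' @param grid `c(ncol, nrow)` of background models along x and y.
#' @param padding fractional range padding around the observed scores.
#' @param wireframe optional 2-column matrix of landmark index pairs.
#' @param template optional `t x m` polyline in the mean shape's space,
#'   warped to each background model by TPS.
#' @return an object of class `mspace_canvas`; background shapes are in
#'   `$grid_shapes` (row-major over the grid, native representation) and
#'   layers accumulate in `$layers`.
#' @export
build_canvas <- function(ord, axes = c(1L, 2L), grid = c(6L, 5L),
                         padding = 0.05, wireframe = NULL, template = NULL) {
  stopifnot(inherits(ord, "shape_ordination"))
  q <- ncol(ord$loadings)
  if (length(axes) != 2L || axes[1L] == axes[2L])
    stop("`axes` must be two distinct indices", call. = FALSE)
  if (any(axes < 1L) || any(axes > q))
    stop("axis out of range: ordination has ", q, " axes", call. = FALSE)
  sc <- ord$scores[, axes, drop = FALSE]
  xr <- pad_range(range(sc[, 1L]), padding)
  yr <- pad_range(range(sc[, 2L]), padding)
  gx <- seq(xr[1L], xr[2L], length.out = grid[1L])
  gy <- seq(yr[1L], yr[2L], length.out = grid[2L])
  at <- as.matrix(expand.grid(x = gx, y = gy))
  shapes <- extract_shapes(ord, at, axes = axes)
  structure(list(ordination = ord, axes = axes, xlim = xr, ylim = yr,
                 grid_x = gx, grid_y = gy, grid_scores = at,
                 grid_shapes = shapes, padding = padding,
                 wireframe = wireframe, template = template,
                 layers = list()),
            class = "mspace_canvas")
}

pad_range <- function(r, padding) {
  w <- diff(r)
  if (w == 0) w <- max(abs(r), 1)
  r + c(-1, 1) * padding * w
}

#' @export
print.mspace_canvas <- function(x, ...) {
  cat("<mspace_canvas> axes (", x$axes[1L], ", ", x$axes[2L], "), ",
      length(x$grid_x), " x ", length(x$grid_y), " background models, ",
      length(x$layers), " layer(s)",
      if (length(x$layers)) paste0(": ",
        paste(vapply(x$layers, `[[`, "", "type"), collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

add_layer <- function(canvas, layer) {
  canvas$layers[[length(canvas$layers) + 1L]] <- layer
  canvas
}

#' Retrieve the most recently added canvas layer
#'
#' @param canvas an `mspace_canvas`.
#' @param type optional layer type to search for (latest match returned).
#' @return the layer list, or `NULL` if none matches.
#' @export
last_layer <- function(canvas, type = NULL) {
  ls <- canvas$layers
  if (!is.null(type)) ls <- Filter(function(l) l$type == type, ls)
  if (length(ls) == 0L) return(NULL)
  ls[[length(ls)]]
}

#' Theoretical shapes at arbitrary morphospace positions
#'
#' Inverse-maps score positions back to shape space:
#' `center + sum_a at[, a] * loadings[, axes[a]]`, the same linear
#' reconstruction the canvas background models use. Positions may lie
#' outside the empirical range, yielding theoretical shapes charting the
#' morphospace surroundings (e.g. for measuring performance of unrealised
#' morphologies).
#'
#' @param ord a `shape_ordination` (an `mspace_canvas` is also accepted).
#' @param at `q' x length(axes)` matrix of scores (vector = one position
#'   per axis).
#' @param axes the axes the columns of `at` refer to.
#' @return a [shape_matrix] of reconstructed shapes.
#' @export
extract_shapes <- function(ord, at, axes = c(1L, 2L)) {
  if (inherits(ord, "mspace_canvas")) {
    if (missing(axes)) axes <- ord$axes
    ord <- ord$ordination
  }
  stopifnot(inherits(ord, "shape_ordination"))
  if (is.null(dim(at))) at <- matrix(at, ncol = length(axes))
  at <- as.matrix(at)
  if (ncol(at) != length(axes))
    stop("`at` must have one column per axis", call. = FALSE)
  if (any(axes < 1L) || any(axes > ncol(ord$loadings)))
    stop("axis out of range", call. = FALSE)
  rec <- sweep(at %*% t(ord$loadings[, axes, drop = FALSE]), 2L,
               ord$center, `+`)
  sm <- ord$shapes
  if (is.null(sm))
    stop("ordination carries no shape metadata", call. = FALSE)
  shape_matrix(rec, kind = sm$kind, k = sm$k, m = sm$m, h = sm$h,
               ids = paste0("t", seq_len(nrow(rec))))
}

#' Project shapes into a morphospace as scatter points
#'
#' Computes `scores = (x - center) %*% loadings` for any compatible shapes
#' (same landmarks or same number of harmonics as the ordinated data) —
#' the training sample, partitions of it, new empirical shapes, or
#' theoretical shapes — and records them as a scatter layer.
#'
#' @param canvas an `mspace_canvas`.
#' @param shapes a [shape_matrix], [landmark_set], [outline_coeffs], or a
#'   plain matrix of flattened rows.
#' @param pch,col,cex plotting attributes stored with the layer.
#' @return the canvas with a `"shapes"` layer appended; the layer holds the
#'   full `scores` matrix and `xy`, its restriction to the plotted plane.
#' @export
proj_shapes <- function(canvas, shapes, pch = 19, col = "black", cex = 0.8) {
  stopifnot(inherits(canvas, "mspace_canvas"))
  sc <- ordination_scores(canvas$ordination, shapes)
  add_layer(canvas, list(type = "shapes", scores = sc,
                         xy = sc[, canvas$axes, drop = FALSE],
                         pch = pch, col = col, cex = cex))
}
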