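#' Project group summaries (convex hulls or confidence ellipses)
#'
#' Delimits groups of projected shapes on the plotted plane either by the
#' convex hull of their scores (the full range; outlier-sensitive) or by a
#' quantile ellipse of their bivariate score distribution (default a data
#' ellipse at `level`; with `mean_ellipse = TRUE` the covariance is scaled
#' by 1/n to depict uncertainty of the group mean instead).
#'
#' @param canvas an `mspace_canvas`.
#' @param groups length-`n` labels aligned with `scores`.
#' @param scores optional `n x 2` positions on the plotted plane; defaults
#'   to the latest `"shapes"` layer.
#' @param style `"hull"` or `"ellipse"`.
#' @param level quantile level for ellipses (chi-squared with 2 df).
#' @param mean_ellipse scale the ellipse by 1/n (confidence region for the
#'   group mean rather than the data scatter)?
#' @param col per-group colours (recycled).
#' @return the canvas with a `"groups"` layer; per group the layer stores
#'   the hull vertex positions, or the ellipse mean, covariance and a
#'   closed polygon. Degenerate groups are skipped with a warning.
#' @export
proj_groups <- function(canvas, groups, scores = NULL,
                        style = c("hull", "ellipse"), level = 0.95,
                        mean_ellipse = FALSE, col = NULL) {
  stopifnot(inherits(canvas, "mspace_canvas"))
  style <- match.arg(style)
  if (is.null(scores)) {
    ly <- last_layer(canvas, "shapes")
    if (is.null(ly)) stop("no shapes layer to take scores from", call. = FALSE)
    scores <- ly$xy
  }
  scores <- as.matrix(scores)
  groups <- as.factor(groups)
  if (length(groups) != nrow(scores))
    stop("`groups` length mismatch", call. = FALSE)
  out <- list()
  for (g in levels(groups)) {
    pts <- scores[groups == g, , drop = FALSE]
    el <- tryCatch(
      if (style == "hull") {
        if (nrow(pts) < 3L) stop("fewer than 3 points")
        hull_idx <- grDevices::chull(pts)
        if (length(hull_idx) < 3L) stop("collinear points")
        list(group = g, style = "hull",
             polygon = pts[hull_idx, , drop = FALSE])
      } else {
        if (nrow(pts) < 3L) stop("fewer than 3 points")
        e <- conf_ellipse(pts, level = level, mean_ellipse = mean_ellipse)
        c(list(group = g, style = "ellipse"), e)
      },
      error = function(e) {
        warning("group '", g, "' skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (!is.null(el)) out[[g]] <- el
  }
  add_layer(canvas, list(type = "groups", style = style, level = level,
                         groups = out, col = col))
}

#' Quantile ellipse of a bivariate point cloud
#'
#' Data ellipse at `level`: centred on the sample mean, with axes from the
#' eigen-decomposition of the 2 x 2 score covariance scaled by
#' `sqrt(qchisq(level, 2))` (times `1/sqrt(n)` if `mean_ellipse`). For
#' bivariate normal data the data ellipse contains a `level` fraction of
#' the population.
#'
#' @param pts `n x 2` matrix (`n >= 3`).
#' @param level coverage level.
#' @param mean_ellipse scale by 1/n (uncertainty of the mean)?
#' @param n_out points on the returned polygon.
#' @return list with `mean`, `cov` (the scaled covariance used), `radius`
#'   (`sqrt(qchisq(level, 2))`) and `polygon` (closed `n_out x 2`).
#' @export
conf_ellipse <- function(pts, level = 0.95, mean_ellipse = FALSE,
                         n_out = 100L) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) stop("need at least 3 points", call. = FALSE)
  mu <- colMeans(pts)
  S <- stats::cov(pts)
  if (mean_ellipse) S <- S / nrow(pts)
  ee <- eigen(S, symmetric = TRUE)
  if (ee$values[2L] <= 0) stop("degenerate (collinear) points", call. = FALSE)
  r <- sqrt(stats::qchisq(level, df = 2L))
  th <- seq(0, 2 * pi, length.out = n_out)
  circ <- cbind(cos(th), sin(th))
  poly <- sweep(circ %*% diag(r * sqrt(ee$values)) %*% t(ee$vectors), 2L,
                mu, `+`)
  list(mean = mu, cov = S, radius = r, polygon = poly)
}

#' Project a morphometric axis into the plotted plane
#'
#' Maps the shape-space line `mean +/- extent * direction` to a segment on
#' the plotted axis pair, returning the endpoint shapes for optional
#' display. The direction may be any linear combination of shape variables:
#' an ordination loading, or a regression coefficient vector from a fitted
#' shape model (e.g. a within-species allometric axis).
#'
#' @param canvas an `mspace_canvas`.
#' @param direction length-`p` vector, or a `linear_shape_model` (the
#'   coefficient row named by `term`, default the first non-intercept row).
#' @param extent half-length of the segment in shape-space units.
#' @param term coefficient row to use when `direction` is a model.
#' @param center optional length-`p` shape at which to anchor the segment;
#'   defaults to the ordination centre (segment through the origin).
#' @param col,lwd plotting attributes.
#' @return the canvas with an `"axis"` layer holding the `2 x 2` segment
#'   endpoints on the plane and the two endpoint shapes (a [shape_matrix]).
#' @export
proj_axis <- function(canvas, direction, extent = 1, term = NULL,
                      center = NULL, col = "black", lwd = 2) {
  stopifnot(inherits(canvas, "mspace_canvas"))
  if (inherits(direction, "linear_shape_model")) {
    cf <- direction$coefficients
    rn <- rownames(cf)
    if (is.null(term)) {
      cand <- setdiff(rn, "(Intercept)")
      if (length(cand) == 0L) stop("model has no non-intercept term",
                                   call. = FALSE)
      term <- cand[1L]
    }
    direction <- as.numeric(cf[term, ])
  }
  direction <- as.numeric(direction)
  ord <- canvas$ordination
  if (length(direction) != length(ord$center))
    stop("direction must have p = ", length(ord$center), " entries",
         call. = FALSE)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("zero direction vector", call. = FALSE)
  if (is.null(center)) center <- ord$center
  ends <- rbind(center - extent * direction,
                center + extent * direction)
  sc <- ordination_scores(ord, ends)
  sm <- ord$shapes
  end_shapes <- shape_matrix(ends, kind = sm$kind, k = sm$k, m = sm$m,
                             h = sm$h, ids = c("neg", "pos"))
  add_layer(canvas, list(type = "axis",
                         segment = sc[, canvas$axes, drop = FALSE],
                         scores = sc, shapes = end_shapes,
                         col = col, lwd = lwd))
}

#' Project a phylogeny into morphospace (phylomorphospace)
#'
#' Estimates ancestral shapes at the internal nodes under Brownian motion
#' in the full shape space, projects tips and nodes with the shared affine
#' contract, and records parent-child edges between their score positions.
#' Because both the ancestral estimator and the projection are linear,
#' estimating then projecting equals projecting then estimating.
#'
#' @param canvas an `mspace_canvas`.
#' @param tree rooted `phylo`; tip labels must match `tip_shapes` ids.
#' @param tip_shapes [shape_matrix] of tip (species mean) shapes; defaults
#'   to the ordination's own training shapes.
#' @param col,cex plotting attributes.
#' @return the canvas with a `"phylogeny"` layer: `tip_scores`,
#'   `node_scores` (rownames are ape node numbers), `edges` (two-column
#'   matrix of ape vertex numbers) and the corresponding plane coordinates.
#' @export
proj_phylogeny <- function(canvas, tree, tip_shapes = NULL, col = "grey30",
                           cex = 0.9) {
  stopifnot(inherits(canvas, "mspace_canvas"))
  check_tree(tree)
  ord <- canvas$ordination
  if (is.null(tip_shapes)) tip_shapes <- ord$shapes
  tip_shapes <- as_shape_matrix(tip_shapes)
  tip_shapes <- match_tips(tip_shapes, tree)
  anc <- anc_states_bm(tree, tip_shapes$X)
  tip_sc <- ordination_scores(ord, tip_shapes$X)
  node_sc <- ordination_scores(ord, anc)
  rownames(tip_sc) <- tip_shapes$ids
  rownames(node_sc) <- rownames(anc)
  s <- length(tree$tip.label)
  all_xy <- rbind(tip_sc[, canvas$axes, drop = FALSE],
                  node_sc[, canvas$axes, drop = FALSE])
  add_layer(canvas, list(type = "phylogeny", tree = tree,
                         tip_scores = tip_sc, node_scores = node_sc,
                         edges = tree$edge, vertices_xy = all_xy,
                         n_tips = s, col = col, cex = cex))
}
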