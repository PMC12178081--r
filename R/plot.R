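#' Plot a morphospace canvas with its layers
#'
#' Draws the background shape models (wireframes/point clouds for landmark
#' data, silhouettes via inverse elliptic Fourier reconstruction for
#' outline data, warped template polylines when a template accessory is
#' present) and then the projection layers in the order they were added.
#'
#' @param x an `mspace_canvas`.
#' @param model_cex scale of the background models relative to grid spacing.
#' @param model_col colour of the background models.
#' @param ... passed to [graphics::plot()] for the empty canvas.
#' @return `x`, invisibly.
#' @export
plot.mspace_canvas <- function(x, model_cex = 0.9, model_col = "grey80",
                               ...) {
  ord <- x$ordination
  graphics::plot(NA, xlim = x$xlim, ylim = x$ylim,
                 xlab = colnames(ord$scores)[x$axes[1L]],
                 ylab = colnames(ord$scores)[x$axes[2L]], asp = NA, ...)
  draw_background_models(x, model_cex, model_col)
  for (ly in x$layers) draw_layer(x, ly)
  invisible(x)
}

draw_background_models <- function(canvas, model_cex, model_col) {
  gs <- canvas$grid_shapes
  sx <- diff(canvas$grid_x[1:2]) * model_cex / 2
  sy <- if (length(canvas$grid_y) > 1L)
    diff(canvas$grid_y[1:2]) * model_cex / 2 else sx
  for (i in seq_len(nrow(canvas$grid_scores))) {
    ctr <- canvas$grid_scores[i, ]
    if (gs$kind == "fourier") {
      oc <- unflatten_shapes(gs, gs$X[i, , drop = FALSE])
      pl <- efa_reconstruct(oc, 80L)
    } else {
      cfg <- unflatten_config(gs$X[i, ], gs$m)[, 1:2, drop = FALSE]
      pl <- NULL
      if (!is.null(canvas$template)) {
        src <- unflatten_config(colMeans(gs$X), gs$m)
        map <- tps_fit(src, unflatten_config(gs$X[i, ], gs$m))
        pl <- tps_warp(map, canvas$template)[, 1:2, drop = FALSE]
      }
    }
    scale_draw <- function(pts) {
      pts <- sweep(pts, 2L, colMeans(pts))
      half <- max(abs(pts)); if (half == 0) half <- 1
      cbind(ctr[1L] + pts[, 1L] / half * sx, ctr[2L] + pts[, 2L] / half * sy)
    }
    if (gs$kind == "fourier") {
      graphics::polygon(scale_draw(pl), border = NA, col = model_col)
    } else {
      pp <- scale_draw(cfg)
      if (!is.null(canvas$wireframe))
        graphics::segments(pp[canvas$wireframe[, 1L], 1L],
                           pp[canvas$wireframe[, 1L], 2L],
                           pp[canvas$wireframe[, 2L], 1L],
                           pp[canvas$wireframe[, 2L], 2L], col = model_col)
      if (!is.null(pl)) graphics::lines(scale_draw(pl), col = model_col)
      graphics::points(pp, pch = 16, cex = 0.3, col = model_col)
    }
  }
}

draw_layer <- function(canvas, ly) {
  switch(ly$type,
    shapes = graphics::points(ly$xy, pch = ly$pch, col = ly$col,
                              cex = ly$cex),
    groups = {
      cols <- ly$col
      if (is.null(cols))
        cols <- grDevices::hcl.colors(max(1L, length(ly$groups)), "Dark 3")
      for (i in seq_along(ly$groups))
        graphics::polygon(ly$groups[[i]]$polygon,
                          border = cols[(i - 1L) %% length(cols) + 1L])
    },
    axis = graphics::lines(ly$segment, col = ly$col, lwd = ly$lwd),
    phylogeny = {
      xy <- ly$vertices_xy
      graphics::segments(xy[ly$edges[, 1L], 1L], xy[ly$edges[, 1L], 2L],
                         xy[ly$edges[, 2L], 1L], xy[ly$edges[, 2L], 2L],
                         col = ly$col)
      graphics::points(xy[seq_len(ly$n_tips), , drop = FALSE], pch = 21,
                       bg = "white", cex = ly$cex)
    },
    landscape = {
      ls <- ly$landscape
      graphics::contour(ls$grid_x, ls$grid_y, ls$grid_values, add = TRUE,
                        col = "tomato")
    },
    pareto = graphics::points(ly$front_xy, pch = 8, col = "red3"),
    invisible(NULL))
}

#' @export
plot.phenogram_data <- function(x, xlab = "time", ylab = "axis score", ...) {
  v <- x$vertices
  graphics::plot(v$time, v$value, type = "n", xlab = xlab, ylab = ylab, ...)
  graphics::segments(v$time[x$edges[, 1L]], v$value[x$edges[, 1L]],
                     v$time[x$edges[, 2L]], v$value[x$edges[, 2L]],
                     col = "grey40")
  graphics::points(v$time[v$is_tip], v$value[v$is_tip], pch = 19)
  graphics::text(v$time[v$is_tip], v$value[v$is_tip], v$label[v$is_tip],
                 pos = 4, cex = 0.7)
  invisible(x)
}

#' @export
plot.hybrid_view <- function(x, xlab = "covariate", ylab = "axis score",
                             ...) {
  d <- x$data
  if (x$type == "scatter") {
    graphics::plot(d$x, d$y, pch = 19, cex = 0.7, xlab = xlab, ylab = ylab,
                   ...)
  } else {
    f <- as.factor(d$x)
    if (x$type == "box") {
      graphics::boxplot(d$y ~ f, xlab = xlab, ylab = ylab, ...)
    } else {
      graphics::plot(NA, xlim = c(0.5, nlevels(f) + 0.5),
                     ylim = range(d$y), xaxt = "n", xlab = xlab,
                     ylab = ylab, ...)
      graphics::axis(1, at = seq_len(nlevels(f)), labels = levels(f))
      for (i in seq_len(nlevels(f))) {
        dn <- x$summaries[[levels(f)[i]]]
        w <- dn$y / max(dn$y) * 0.35
        graphics::polygon(c(i - w, rev(i + w)), c(dn$x, rev(dn$x)),
                          col = "grey85")
      }
    }
  }
  invisible(x)
}
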