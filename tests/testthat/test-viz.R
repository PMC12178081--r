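# morphospace canvas, projections, landscapes, Pareto fronts, hybrid views

viz_ord <- function(seed = 401, n = 24, p = 8) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p) %*% diag(seq(2, 0.5, length.out = p))
  pca(shape_matrix(X, kind = "landmarks2d", k = p / 2))
}

test_that("canvas background models are the linear inverse mapping", {
  ord <- viz_ord()
  cv <- build_canvas(ord, grid = c(5, 5))
  # a grid point at the origin of the plane is exactly the mean shape
  at0 <- extract_shapes(ord, c(0, 0))
  expect_equal(as.numeric(at0$X), ord$center, tolerance = 1e-12)
  # background shape at a training specimen's plane scores
  s <- ord$scores[3, 1:2]
  bg <- extract_shapes(ord, s)
  manual <- ord$center + s[1] * ord$loadings[, 1] + s[2] * ord$loadings[, 2]
  expect_equal(as.numeric(bg$X), as.numeric(manual), tolerance = 1e-12)
  # shapes along one grid row differ by equal increments
  row1 <- cv$grid_shapes$X[1:5, ]
  second_diff <- diff(diff(row1))
  expect_lt(max(abs(second_diff)), 1e-10)
  # grid positions evenly spaced with the padding recorded
  expect_equal(diff(cv$grid_x), rep(diff(cv$grid_x)[1], 4), tolerance = 1e-12)
  expect_error(build_canvas(ord, axes = c(1, 99)), "range")
  expect_error(build_canvas(ord, axes = c(2, 2)), "distinct")
})

test_that("proj_shapes satisfies the affine contract and round-trips", {
  ord <- viz_ord()
  cv <- build_canvas(ord)
  cv <- proj_shapes(cv, ord$shapes)
  ly <- last_layer(cv, "shapes")
  expect_equal(ly$scores, ord$scores, tolerance = 1e-10)
  # projecting the mean shape lands on the origin
  expect_lt(max(abs(ordination_scores(ord, ord$center))), 1e-10)
  # extract then project closes the loop
  at <- matrix(c(1.2, -0.7, 0.3, 2.1), 2, 2, byrow = TRUE)
  sh <- extract_shapes(ord, at)
  back <- ordination_scores(ord, sh$X)
  expect_equal(back[, 1:2], at, tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(back[, -(1:2)])), 1e-9)
  expect_error(proj_shapes(cv, matrix(1, 2, 5)), "expected p")
})

test_that("layering never mutates the canvas ordination", {
  ord <- viz_ord()
  cv <- build_canvas(ord)
  cv2 <- proj_shapes(cv, ord$shapes)
  cv3 <- proj_axis(cv2, ord$loadings[, 1])
  expect_identical(cv3$ordination, cv$ordination)
  expect_identical(cv3$grid_shapes, cv$grid_shapes)
  expect_length(cv$layers, 0)
  expect_length(cv3$layers, 2)
})

test_that("group hulls are exact for a triangle; ellipses match chi-squared", {
  ord <- viz_ord()
  cv <- proj_shapes(build_canvas(ord), ord$shapes)
  tri <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  cvh <- proj_groups(cv, groups = rep("g", 3), scores = tri, style = "hull")
  hull <- last_layer(cvh, "groups")$groups$g$polygon
  expect_equal(hull[order(hull[, 1], hull[, 2]), ],
               tri[order(tri[, 1], tri[, 2]), ], ignore_attr = TRUE)
  # isotropic unit covariance at level 0.95: circle of radius sqrt(5.991)
  set.seed(402)
  pts <- matrix(rnorm(2000), 1000, 2)
  el <- conf_ellipse(pts, level = 0.95)
  expect_equal(el$radius, sqrt(stats::qchisq(0.95, 2)), tolerance = 1e-12)
  r_emp <- sqrt(rowSums(sweep(el$polygon, 2, el$mean)^2))
  # radii spread reflects sample covariance, not the nominal circle; only
  # the quantile scaling is closed-form
  expect_equal(mean(r_emp), sqrt(5.991), tolerance = 0.1)
})

test_that("0.95 data ellipse has Monte-Carlo coverage in [0.945, 0.955]", {
  set.seed(403)
  n <- 20000
  S <- matrix(c(2, 0.8, 0.8, 1), 2)
  L <- chol(S)
  pts <- matrix(rnorm(2 * n), n, 2) %*% L
  el <- conf_ellipse(pts, level = 0.95)
  Sinv <- solve(el$cov)
  d2 <- rowSums((sweep(pts, 2, el$mean) %*% Sinv) *
                  sweep(pts, 2, el$mean))
  cover <- mean(d2 <= el$radius^2)
  expect_gte(cover, 0.945)
  expect_lte(cover, 0.955)
})

test_that("degenerate groups are skipped with a warning", {
  ord <- viz_ord()
  cv <- proj_shapes(build_canvas(ord), ord$shapes)
  line_pts <- cbind(1:4, 2 * (1:4))
  expect_warning(
    cvg <- proj_groups(cv, groups = rep("bad", 4), scores = line_pts,
                       style = "ellipse"),
    "skipped")
  expect_length(last_layer(cvg, "groups")$groups, 0)
})

test_that("proj_axis maps loading columns to plane-aligned segments", {
  ord <- viz_ord()
  cv <- build_canvas(ord)
  cv1 <- proj_axis(cv, ord$loadings[, 1], extent = 2)
  seg <- last_layer(cv1, "axis")$segment
  expect_lt(max(abs(seg[, 2])), 1e-10)          # horizontal
  expect_equal(seg[, 1], c(-2, 2), tolerance = 1e-10, ignore_attr = TRUE)
  # direction orthogonal to both plotted axes collapses to the origin
  cv3 <- proj_axis(cv, ord$loadings[, 4], extent = 3)
  expect_lt(max(abs(last_layer(cv3, "axis")$segment)), 1e-10)
  expect_error(proj_axis(cv, rep(0, 8)), "zero")
})

test_that("an allometric-model axis tracks the size drift of scores", {
  set.seed(404)
  n <- 80; p <- 8
  size <- sort(rnorm(n))
  v <- rnorm(p); v <- v / sqrt(sum(v^2))
  X <- outer(size, v) + matrix(rnorm(n * p, sd = 0.05), n, p)
  sm <- shape_matrix(X, kind = "landmarks2d", k = 4)
  ord <- pca(sm)
  fit <- fit_shape_regression(sm, cbind("(Intercept)" = 1, size = size))
  cv <- proj_axis(build_canvas(ord), fit, extent = 1)
  seg <- last_layer(cv, "axis")$segment
  segdir <- seg[2, ] - seg[1, ]
  segdir <- segdir / sqrt(sum(segdir^2))
  # drift of size-ordered score centroids (low vs high size thirds)
  sc <- ord$scores[, 1:2]
  drift <- colMeans(sc[(2 * n / 3):n, ]) - colMeans(sc[1:(n / 3), ])
  drift <- drift / sqrt(sum(drift^2))
  expect_gt(abs(sum(segdir * drift)), 0.99)
})

test_that("phylomorphospace: fixed points, commutation, star-tree root", {
  set.seed(405)
  tr <- make_fixture_tree(s = 8, seed = 5)
  X <- make_bm_tips(tr, rate = 1, p = 6, seed = 6)
  sm <- shape_matrix(X, kind = "landmarks2d", k = 3, ids = rownames(X))
  ord <- pca(sm)
  cv <- proj_phylogeny(build_canvas(ord), tr, sm)
  ly <- last_layer(cv, "phylogeny")
  # commutation: ancestral states of scores == scores of ancestral shapes
  anc_scores <- anc_states_bm(tr, ord$scores)
  expect_equal(ly$node_scores, anc_scores, tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical tips collapse every node onto the same point
  X1 <- matrix(rep(X[1, ], 8), 8, 6, byrow = TRUE,
               dimnames = list(rownames(X), NULL))
  sm1 <- shape_matrix(X1, kind = "landmarks2d", k = 3, ids = rownames(X1))
  cv1 <- proj_phylogeny(build_canvas(ord), tr, sm1)
  ly1 <- last_layer(cv1, "phylogeny")
  expect_lt(max(apply(ly1$node_scores, 2, stats::sd)), 1e-10)
  expect_equal(as.numeric(ly1$node_scores[1, ]),
               as.numeric(ly1$tip_scores[1, ]), tolerance = 1e-9)
  # star tree: root sits at the GLS-weighted mean of tip scores
  star <- ape::stree(6, type = "star")
  star$edge.length <- c(1, 2, 1, 4, 1, 1)
  star$tip.label <- paste0("sp", 1:6)
  xs <- setNames(rnorm(6), star$tip.label)
  root <- anc_states_bm(star, xs)[1, 1]
  w <- 1 / star$edge.length
  expect_equal(root, sum(w * xs) / sum(w), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("landscapes interpolate exactly and reproduce planes", {
  ord <- viz_ord()
  cv <- build_canvas(ord)
  set.seed(406)
  pos <- matrix(runif(24, -2, 2), 12, 2)
  # affine surface reproduced everywhere
  vals <- 2 * pos[, 1] + 3 * pos[, 2] + 1
  cvl <- proj_landscape(cv, pos, vals)
  ls <- last_layer(cvl, "landscape")$landscape
  gq <- as.matrix(expand.grid(ls$grid_x, ls$grid_y))
  expect_equal(as.numeric(ls$grid_values),
               2 * gq[, 1] + 3 * gq[, 2] + 1, tolerance = 1e-6)
  # generic values: exact at supports
  vals2 <- sin(pos[, 1]) * cos(pos[, 2])
  ls2 <- shape_landscape(pos, vals2)
  expect_equal(ls2$interp(pos), vals2, tolerance = 1e-6)
  # constant values give a constant surface
  ls3 <- shape_landscape(pos, rep(7, 12))
  expect_equal(as.numeric(ls3$grid_values), rep(7, length(ls3$grid_values)),
               tolerance = 1e-6)
  # collinear supports rejected with guidance
  expect_error(shape_landscape(cbind(1:5, 2 * (1:5)), 1:5), "collinear")
})

test_that("Pareto front matches the brute-force domination oracle", {
  # closed-form cases
  p1 <- pareto_front(matrix(c(3, 4), 1, 2))
  expect_equal(p1$front, 1L)
  expect_equal(p1$rank, 1L)
  tri <- matrix(c(1, 0, 0, 1, 0.5, 0.5), 3, 2, byrow = TRUE)
  expect_equal(pareto_front(tri, "max")$front, 1:3)
  # 50 seeded random points against the O(q^2) oracle
  set.seed(407)
  W <- matrix(runif(100), 50, 2)
  res <- pareto_front(W, "max")
  expect_identical(res$front, brute_pareto(W))
  # minimisation flips the orientation
  res_min <- pareto_front(W, "min")
  expect_identical(res_min$front, brute_pareto(-W))
  # peeling partitions the set; ranks start at 1 and are contiguous
  expect_setequal(unique(res$rank), seq_len(max(res$rank)))
  expect_length(res$rank, 50)
  expect_true(all(res$optimality > 0 & res$optimality <= 1))
  # every non-front point is dominated by some front member
  for (i in setdiff(seq_len(50), res$front)) {
    dominated <- any(vapply(res$front, function(j)
      all(W[j, ] >= W[i, ]) && any(W[j, ] > W[i, ]), logical(1)))
    expect_true(dominated)
  }
  expect_error(pareto_front(matrix(c(1, NaN), 1, 2)), "finite")
})

test_that("phenogram places vertices at node heights and tip scores", {
  tr <- make_fixture_tree(s = 9, seed = 7)  # ultrametric, height 1
  xs <- setNames(rnorm(9), tr$tip.label)
  ph <- phenogram(tr, xs)
  v <- ph$vertices
  expect_equal(v$time[v$is_tip], rep(1, 9), tolerance = 1e-10)
  expect_equal(v$value[v$is_tip], as.numeric(xs[tr$tip.label]),
               tolerance = 1e-12)
  # node heights match a root-to-tip traversal oracle
  depths <- numeric(9 + tr$Nnode)
  for (e in seq_len(nrow(tr$edge)))
    depths[tr$edge[e, 2]] <- depths[tr$edge[e, 1]] + tr$edge.length[e]
  expect_equal(v$time, depths, tolerance = 1e-12)
  # constant tips give a flat phenogram
  flat <- phenogram(tr, setNames(rep(2, 9), tr$tip.label))
  expect_lt(stats::sd(flat$vertices$value), 1e-10)
  tr_nb <- tr; tr_nb$edge.length <- NULL
  expect_error(phenogram(tr_nb, xs), "branch lengths")
})

test_that("hybrid views pair axes with covariates faithfully", {
  ord <- viz_ord()
  sc1 <- ord$scores[, 1]
  # covariate = the scores themselves: identity scatter
  hv <- hybrid_view(sc1, sc1, type = "scatter")
  expect_equal(hv$data$x, hv$data$y)
  # box summaries equal direct group medians
  grp <- rep(c("u", "v"), each = 12)
  hb <- hybrid_view(sc1, grp, type = "box")
  expect_equal(hb$summaries$u[3], stats::median(sc1[grp == "u"]))
  expect_equal(hb$summaries$v[3], stats::median(sc1[grp == "v"]))
  # margin models equal extract_shapes along that axis
  hm <- hybrid_view(sc1, sc1, ord = ord, axis = 1, n_models = 4)
  man <- extract_shapes(ord, matrix(hm$margin$positions, ncol = 1), axes = 1)
  expect_equal(hm$margin$shapes$X, man$X, tolerance = 1e-12)
  expect_error(hybrid_view(sc1, 1:3), "length")
})

test_that("canvas and view plots render without error on a null device", {
  ord <- viz_ord()
  cv <- proj_shapes(build_canvas(ord), ord$shapes)
  cv <- proj_axis(cv, ord$loadings[, 1])
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_no_error(plot(cv))
  tr <- make_fixture_tree(s = 6, seed = 8)
  expect_no_error(plot(phenogram(tr, setNames(rnorm(6), tr$tip.label))))
  expect_no_error(plot(hybrid_view(rnorm(20), rep(c("a", "b"), 10),
                                   type = "violin")))
})
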