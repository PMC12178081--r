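# geometric substrate: centroid size, GPA, TPS, EFA, flattening

test_that("centroid size: closed form, homogeneity, direct formula", {
  sq <- matrix(c(-.5, -.5, .5, -.5, .5, .5, -.5, .5), ncol = 2, byrow = TRUE)
  expect_equal(centroid_size(sq), sqrt(2))
  set.seed(11)
  cfg <- rand_config(10, 3)
  direct <- sqrt(sum(sweep(cfg, 2, colMeans(cfg))^2))
  expect_equal(centroid_size(cfg), direct)
  expect_equal(centroid_size(cfg * 3.7), 3.7 * centroid_size(cfg))
  expect_error(centroid_size(matrix(1, 4, 2)), "coincide")
})

test_that("GPA is invariant to similarity transforms and centres/scales", {
  set.seed(21)
  cfg <- rand_config(6)
  copy <- sim_copy_2d(cfg, 1.2, 3.1, c(10, -4))
  expect_equal(procrustes_distance(cfg, copy), 0, tolerance = 1e-12)
  arr <- array(NA_real_, c(3, 6, 2))
  arr[1, , ] <- cfg
  arr[2, , ] <- copy
  arr[3, , ] <- sim_copy_2d(cfg, -0.4, 0.2, c(-1, 2))
  ga <- procrustes_align(landmark_set(arr))
  # identical underlying shapes: zero shape variance after alignment
  X <- as_shape_matrix(ga$aligned)$X
  expect_lt(sum(scale(X, scale = FALSE)^2), 1e-20)
  # every aligned configuration centred at origin with unit centroid size
  for (i in 1:3) {
    expect_lt(max(abs(colMeans(ga$aligned$coords[i, , ]))), 1e-8)
    expect_equal(centroid_size(ga$aligned$coords[i, , ]), 1,
                 tolerance = 1e-8)
  }
  expect_equal(centroid_size(ga$consensus), 1, tolerance = 1e-8)
})

test_that("Procrustes distance matches a brute-force rotation search", {
  set.seed(22)
  for (rep in 1:4) {
    a <- rand_config(3)
    b <- rand_config(3)
    expect_equal(procrustes_distance(a, b), brute_procrustes_2d(a, b),
                 tolerance = 1e-6)
  }
})

test_that("GPA residual sum of squares is non-increasing over iterations", {
  set.seed(23)
  ga <- procrustes_align(rand_landmark_set(12, 7))
  expect_true(all(diff(ga$ss_trace) <= 1e-12))
})

test_that("GPA rejects degenerate configurations by name", {
  arr <- array(rnorm(2 * 4 * 2), c(2, 4, 2))
  arr[2, , ] <- 1
  expect_error(procrustes_align(landmark_set(arr, ids = c("ok", "flat"))),
               "flat")
})

test_that("TPS: identity, affine reproduction, exact interpolation", {
  set.seed(31)
  src <- rand_config(8)
  m_id <- tps_fit(src, src)
  expect_lt(max(abs(m_id$weights)), 1e-10)
  expect_equal(m_id$affine[-1, ], diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(m_id$affine[1, ])), 1e-10)
  expect_equal(m_id$energy, 0, tolerance = 1e-10)

  A <- matrix(c(1.4, 0.3, -0.2, 0.8), 2)
  b <- c(2, -1)
  m_aff <- tps_fit(src, sweep(src %*% A, 2, b, `+`))
  expect_lt(max(abs(m_aff$weights)), 1e-8)
  expect_equal(m_aff$energy, 0, tolerance = 1e-10)
  grid <- as.matrix(expand.grid(seq(-2, 2, 0.5), seq(-2, 2, 0.5)))
  expect_equal(tps_warp(m_aff, grid), sweep(grid %*% A, 2, b, `+`),
               tolerance = 1e-8, ignore_attr = TRUE)

  for (m in 2:3) {
    src <- rand_config(10, m)
    tgt <- src + matrix(rnorm(10 * m, sd = 0.2), 10, m)
    mp <- tps_fit(src, tgt)
    expect_lt(max(abs(tps_warp(mp, src) - tgt)), 1e-8)
    expect_gte(mp$energy, 0)
  }
})

test_that("TPS errors: duplicates, collinear sources, dimension mismatch", {
  src <- rand_config(6)
  expect_error(tps_fit(rbind(src, src[1, ]), rbind(src, src[1, ])),
               "duplicated")
  line <- cbind(1:6, 2 * (1:6))
  expect_error(tps_fit(line, line), "collinear")
  mp <- tps_fit(src, src)
  expect_error(tps_warp(mp, matrix(1, 2, 3)), "dimension")
})

test_that("EFA of a circle is a pure first harmonic", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  r <- 1.7
  oc <- efa_decompose(cbind(r * cos(th), r * sin(th)), h = 6)
  expect_equal(as.numeric(oc$coeffs[1, 1, ]), c(r, 0, 0, r),
               tolerance = 1e-3)
  expect_lt(max(abs(oc$coeffs[1, 2:6, ])), 1e-3 * r)
  expect_lt(max(abs(oc$offset)), 1e-3 * r)
})

test_that("EFA reconstruction closed forms", {
  oc <- outline_coeffs(matrix(c(1, 0, 0, 1), 1, 4))
  rec <- efa_reconstruct(oc, 73)
  expect_equal(rowSums(rec^2), rep(1, 73), tolerance = 1e-9)
  expect_equal(rec[1, ], rec[73, ], tolerance = 1e-9, ignore_attr = TRUE)
  oc0 <- outline_coeffs(matrix(0, 1, 4), offset = c(3, -2))
  rec0 <- efa_reconstruct(oc0, 10)
  expect_true(all(abs(rec0[, 1] - 3) < 1e-12))
  expect_true(all(abs(rec0[, 2] + 2) < 1e-12))
})

test_that("EFA square round-trip error is small and decreases with h", {
  s <- seq(0, 1, length.out = 51)[-51]
  side <- function(a, b) cbind(seq(a[1], b[1], length.out = 51)[-51],
                               seq(a[2], b[2], length.out = 51)[-51])
  square <- rbind(side(c(0, 0), c(1, 0)), side(c(1, 0), c(1, 1)),
                  side(c(1, 1), c(0, 1)), side(c(0, 1), c(0, 0)))
  # exact distance from a point to the boundary of the unit square
  dist_unit_square <- function(p) {
    x <- p[1]; y <- p[2]
    if (x >= 0 && x <= 1 && y >= 0 && y <= 1) min(x, 1 - x, y, 1 - y)
    else sqrt(max(0, x - 1, -x)^2 + max(0, y - 1, -y)^2)
  }
  sq_err <- function(h) {
    rec <- efa_reconstruct(efa_decompose(square, h), 800)
    max(apply(rec, 1, dist_unit_square))
  }
  # frozen oracle: dense numerical Fourier integration of the exact square
  # path gives a truncation error of 0.0101237 at h = 20 (coefficients agree
  # with this implementation to ~1e-9)
  expect_equal(sq_err(20), 0.0101237, tolerance = 1e-3)
  errs <- vapply(c(2, 5, 10, 20), sq_err, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("EFA of an ellipse round-trips its semi-axes", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  oc <- efa_decompose(cbind(2.5 * cos(th), 0.9 * sin(th)), h = 25)
  rec <- efa_reconstruct(oc, 4000)
  expect_equal(max(abs(rec[, 1])), 2.5, tolerance = 1e-3)
  expect_equal(max(abs(rec[, 2])), 0.9, tolerance = 1e-3)
})

test_that("reversed outline traversal reconstructs the same point set", {
  set.seed(41)
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  wob <- cbind((1 + 0.2 * cos(3 * th)) * cos(th),
               (1 + 0.15 * sin(2 * th)) * sin(th))
  # reversing the traversal (keeping the starting point) reverses the
  # parameterisation: the curve evaluated at t equals the forward curve at
  # T - t, so the reconstructions coincide as point sets
  wob_rev <- wob[c(1, rev(seq_len(nrow(wob))[-1])), ]
  f <- efa_reconstruct(efa_decompose(wob, 8), 600)
  b <- efa_reconstruct(efa_decompose(wob_rev, 8), 600)
  expect_equal(b, f[rev(seq_len(600)), ], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("EFA rejects degenerate outlines and too few points", {
  expect_error(efa_decompose(matrix(1, 5, 2), 1), "perimeter")
  th <- seq(0, 2 * pi, length.out = 8)[-8]
  expect_error(efa_decompose(cbind(cos(th), sin(th)), h = 4), "2h \\+ 1")
})

test_that("flatten/unflatten is a bijection for both representations", {
  set.seed(51)
  lms <- rand_landmark_set(4, 5, 3)
  sm <- as_shape_matrix(lms)
  expect_identical(unflatten_shapes(sm)$coords, lms$coords)
  # landmark-major, coordinate-minor order
  expect_identical(sm$X[2, 1:6],
                   setNames(as.vector(t(lms$coords[2, 1:2, ])),
                            c("x1", "y1", "z1", "x2", "y2", "z2")))
  oc <- outline_coeffs(array(rnorm(3 * 7 * 4), c(3, 7, 4)))
  sm2 <- as_shape_matrix(oc)
  expect_identical(unflatten_shapes(sm2)$coeffs, oc$coeffs)
})
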