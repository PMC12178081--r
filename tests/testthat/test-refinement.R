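# linear-model detrending, expected shapes, Burnaby projection

make_sm <- function(X) shape_matrix(X, kind = "landmarks2d", k = ncol(X) / 2)

test_that("intercept-only regression recovers column means and centring", {
  set.seed(101)
  X <- matrix(rnorm(80), 10, 8)
  fit <- fit_shape_regression(make_sm(X), matrix(1, 10, 1))
  expect_equal(as.numeric(fit$coefficients), colMeans(X))
  expect_equal(fit$residuals, scale(X, scale = FALSE), ignore_attr = TRUE)
  expect_equal(fit$fitted + fit$residuals, X, ignore_attr = TRUE)
})

test_that("OLS matches a column-by-column solver and recovers a known slope", {
  set.seed(102)
  n <- 60; p <- 8
  size <- rnorm(n)
  v <- rnorm(p)
  X <- matrix(2, n, p, byrow = TRUE) + outer(size, v) +
    matrix(rnorm(n * p, sd = 0.3), n, p)
  des <- cbind(1, size)
  fit <- fit_shape_regression(make_sm(X), des)
  # per-column lm oracle
  for (j in c(1, 4, 8)) {
    co <- stats::lm.fit(des, X[, j])$coefficients
    expect_equal(as.numeric(fit$coefficients[, j]), as.numeric(co),
                 tolerance = 1e-9)
  }
  expect_equal(fit$fitted, des %*% fit$coefficients, tolerance = 1e-9)
  # slope recovery within 3 SE, component-wise
  rse <- sqrt(colSums(fit$residuals^2) / (n - 2))
  se <- rse / sqrt(sum((size - mean(size))^2))
  expect_true(all(abs(fit$coefficients[2, ] - v) <= 3 * se))
  # residuals orthogonal to the design
  expect_lt(max(abs(crossprod(des, fit$residuals))), 1e-8)
})

test_that("rank-deficient designs are rejected naming the column", {
  set.seed(103)
  x <- rnorm(20)
  des <- cbind(int = 1, a = x, b = 2 * x)
  expect_error(fit_shape_regression(make_sm(matrix(rnorm(80), 20, 4)), des),
               "b")
})

test_that("detrending removes the modelled effect and keeps the mean", {
  set.seed(104)
  n <- 40; p <- 8
  size <- rnorm(n)
  v <- rnorm(p)
  X <- matrix(5, n, p, byrow = TRUE) + outer(size, v)  # noise-free allometry
  des <- cbind(1, size)
  fit <- fit_shape_regression(make_sm(X), des)
  dt <- detrend_shapes(fit)
  refit <- fit_shape_regression(dt, des)
  expect_lt(sqrt(sum(refit$coefficients[2, ]^2)), 1e-9)
  expect_equal(colMeans(dt$X), colMeans(X), tolerance = 1e-9,
               ignore_attr = TRUE)
  # covariate with zero true effect on noise-free constant shapes: no-op
  X0 <- matrix(rep(rnorm(p), each = n), n, p)
  fit0 <- fit_shape_regression(make_sm(X0), des)
  expect_equal(detrend_shapes(fit0)$X, X0, tolerance = 1e-9,
               ignore_attr = TRUE)
  # displacement to the maximum observed size
  at <- c(1, max(size))
  dt_max <- detrend_shapes(fit, displace_to = at)
  expect_equal(colMeans(dt_max$X),
               as.numeric(at %*% fit$coefficients), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(detrend_shapes(fit, displace_to = c(1, 2, 3)), "length")
})

test_that("noisy detrend leaves a statistically null slope", {
  set.seed(105)
  n <- 80; p <- 6
  size <- rnorm(n)
  X <- outer(size, rnorm(p)) + matrix(rnorm(n * p, sd = 0.5), n, p)
  des <- cbind(1, size)
  dt <- detrend_shapes(fit_shape_regression(make_sm(X), des))
  refit <- fit_shape_regression(dt, des)
  rse <- sqrt(colSums(refit$residuals^2) / (n - 2))
  se <- rse / sqrt(sum((size - mean(size))^2))
  expect_true(all(abs(refit$coefficients[2, ]) <= 3 * se))
})

test_that("expected shapes: group means, fitted values, collinearity", {
  set.seed(106)
  n <- 30; p <- 8
  grp <- factor(rep(c("a", "b", "c"), each = 10))
  X <- matrix(rnorm(n * p), n, p)
  des <- design_matrix(~grp, data.frame(grp = grp))
  fit <- fit_shape_regression(make_sm(X), des)
  at <- unique(des)
  pred <- expected_shapes(fit, at)
  for (i in 1:3) {
    lev <- levels(grp)[i]
    expect_equal(as.numeric(pred$X[i, ]),
                 colMeans(X[grp == lev, , drop = FALSE]), tolerance = 1e-10)
  }
  expect_equal(expected_shapes(fit, fit$design)$X, fit$fitted,
               ignore_attr = TRUE)
  # size design: predictions at evenly spaced sizes lie on one line
  size <- rnorm(n)
  fit2 <- fit_shape_regression(make_sm(X), cbind(1, size))
  at2 <- cbind(1, seq(-2, 2, length.out = 7))
  sh <- expected_shapes(fit2, at2)$X
  dirs <- sweep(sh[-1, ], 2, sh[1, ])
  dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_lt(max(1 - abs(dirs %*% dirs[1, ])), 1e-9)
  expect_error(expected_shapes(fit2, c(1, 2, 3)), "columns")
})

test_that("per-group detrending removes within-group allometry", {
  set.seed(107)
  d <- make_landmark_dataset(n_groups = 3, n_ind_per_group = 4,
                             n_meas_per_ind = 4, noise_sd = 0,
                             ind_sd = 0, locality_disp = 0, age_disp = 0,
                             transform = FALSE, seed = 7)
  sm <- as_shape_matrix(d$landmarks)
  dt <- detrend_by_group(sm, ~ log(size), d$covariates,
                         d$covariates$species)
  for (g in levels(d$covariates$species)) {
    idx <- d$covariates$species == g
    sub <- make_sm(matrix(0, sum(idx), 4))  # placeholder kind; refit below
    des <- cbind(1, log(d$covariates$size[idx]))
    refit <- fit_shape_regression(
      shape_matrix(dt$X[idx, , drop = FALSE], kind = "landmarks2d", k = 9),
      des)
    expect_lt(sqrt(sum(refit$coefficients[2, ]^2)), 1e-6)
    # each group keeps its own mean
    expect_equal(colMeans(dt$X[idx, , drop = FALSE]),
                 colMeans(sm$X[idx, , drop = FALSE]), tolerance = 1e-9)
  }
})

test_that("Burnaby filter: nullspace, zero variance along F, idempotency", {
  set.seed(108)
  p <- 6
  F <- matrix(rnorm(p * 2), p, 2)
  # rows spanned by F (plus a common mean): filtered to the mean shape
  co <- matrix(rnorm(20), 10, 2)
  mu <- rnorm(p)
  X <- sweep(co %*% t(F), 2, mu, `+`)
  out <- burnaby_filter(make_sm(X + 0), F)
  expect_lt(max(abs(sweep(out$X, 2, colMeans(X)))), 1e-9)
  # generic data: zero variance along F, idempotent, variance reduced
  X2 <- matrix(rnorm(120), 20, 6)
  f1 <- burnaby_filter(make_sm(X2), F)
  expect_lt(max(apply(f1$X %*% F, 2, stats::var)), 1e-12)
  f2 <- burnaby_filter(f1, F)
  expect_equal(f2$X, f1$X, tolerance = 1e-12)
  expect_lt(sum(scale(f1$X, scale = FALSE)^2),
            sum(scale(X2, scale = FALSE)^2))
  expect_error(burnaby_filter(make_sm(X2), cbind(F[, 1], 2 * F[, 1])),
               "rank")
})

test_that("Burnaby projector matches a Gram-Schmidt completion oracle", {
  set.seed(109)
  p <- 6
  F <- matrix(rnorm(p * 2), p, 2)
  # oracle: orthonormal basis of the complement via QR completion
  Q <- qr.Q(qr(cbind(F, diag(p))))[, 3:p]
  P_oracle <- Q %*% t(Q)
  P <- diag(p) - F %*% solve(crossprod(F), t(F))
  expect_equal(P, P_oracle, tolerance = 1e-10)
})
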