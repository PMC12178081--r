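#' Fit a multivariate linear model to shape variables
#'
#' Ordinary least squares of every shape variable on a common design matrix,
#' solved by QR decomposition. The design should include an intercept column
#' unless the caller deliberately omits it; [design_matrix()] builds one from
#' a formula and a covariate table (categorical covariates are dummy-coded
#' against a first-level reference, which determines how the coefficient rows
#' are interpreted by [expected_shapes()]).
#'
#' @param shapes a [shape_matrix] (or an object coercible via
#'   [as_shape_matrix()]).
#' @param design `n x d` numeric design matrix, full column rank, `n > d`.
#' @return an object of class `linear_shape_model` with `design`,
#'   `coefficients` (`d x p`), `fitted`, `residuals` and the shape metadata.
#' @export
fit_shape_regression <- function(shapes, design) {
  shapes <- as_shape_matrix(shapes)
  X <- shapes$X
  design <- as.matrix(design)
  n <- nrow(X); d <- ncol(design)
  if (nrow(design) != n)
    stop("design has ", nrow(design), " rows; shapes have ", n, call. = FALSE)
  if (n <= d) stop("need n > d observations", call. = FALSE)
  qrd <- qr(design)
  if (qrd$rank < d) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):d]]
    if (is.null(bad)) bad <- qrd$pivot[(qrd$rank + 1L):d]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qrd, X)
  fitted <- design %*% coef
  res <- X - fitted
  structure(list(design = design, coefficients = coef, fitted = fitted,
                 residuals = res, shapes = shapes),
            class = "linear_shape_model")
}

#' @export
print.linear_shape_model <- function(x, ...) {
  cat("<linear_shape_model> ", nrow(x$design), " obs, ",
      ncol(x$design), " design column(s), ", ncol(x$coefficients),
      " shape variables\n", sep = "")
  invisible(x)
}

#' Build a design matrix from a formula and covariate table
#'
#' Thin wrapper over [stats::model.matrix()]: factors are dummy-coded with
#' the first level as reference (treatment contrasts).
#'
#' @param formula one-sided formula, e.g. `~ log(size) + locality`.
#' @param data data frame of covariates.
#' @return numeric design matrix with an intercept column.
#' @export
design_matrix <- function(formula, data) {
  stats::model.matrix(formula, data = data)
}

#' Remove modelled variation from shapes
#'
#' Detrending per the refinement step of the morphospace workflow: the
#' residuals of a fitted shape regression are retained and displaced back to
#' either the grand mean shape (default) or to the shape predicted at a
#' chosen design row (e.g. the maximum observed size, to study 'static'
#' adult morphology).
#'
#' @param model a `linear_shape_model`.
#' @param displace_to optional length-`d` design row at which the model
#'   prediction replaces the grand mean.
#' @return a [shape_matrix] with the same dimensions and metadata as the
#'   model input.
#' @export
detrend_shapes <- function(model, displace_to = NULL) {
  stopifnot(inherits(model, "linear_shape_model"))
  d <- ncol(model$design)
  if (is.null(displace_to)) {
    base <- colMeans(model$fitted + model$residuals)
  } else {
    if (length(displace_to) != d)
      stop("`displace_to` must have length d = ", d, call. = FALSE)
    base <- as.numeric(matrix(displace_to, 1L) %*% model$coefficients)
  }
  out <- sweep(model$residuals, 2L, base, `+`)
  sm <- model$shapes
  shape_matrix(out, kind = sm$kind, k = sm$k, m = sm$m, h = sm$h,
               ids = sm$ids)
}

#' Group-wise detrending with a common formula
#'
#' Convenience wrapper for the common case where a nuisance model is fitted
#' and removed for each group separately (e.g. per-species allometric
#' detrending). Each group's shapes are displaced back to that group's own
#' mean (or, via `displace_at`, to the group-specific prediction at chosen
#' covariate values, e.g. the group's maximum size).
#'
#' @param shapes a [shape_matrix].
#' @param formula one-sided model formula over columns of `data`.
#' @param data covariate data frame, `n` rows aligned with `shapes`.
#' @param groups length-`n` group labels.
#' @param displace_at optional function taking a group's covariate rows and
#'   returning a one-row data frame of covariate values at which to displace
#'   that group (e.g. `function(d) d[which.max(d$size), , drop = FALSE]`).
#' @return a [shape_matrix] of detrended shapes in the original row order.
#' @export
detrend_by_group <- function(shapes, formula, data, groups,
                             displace_at = NULL) {
  shapes <- as_shape_matrix(shapes)
  groups <- as.factor(groups)
  if (length(groups) != nrow(shapes$X))
    stop("`groups` length mismatch", call. = FALSE)
  out <- shapes$X
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- shape_matrix(shapes$X[idx, , drop = FALSE], kind = shapes$kind,
                        k = shapes$k, m = shapes$m, h = shapes$h,
                        ids = shapes$ids[idx])
    dsub <- droplevels(data[idx, , drop = FALSE])
    des <- design_matrix(formula, dsub)
    fit <- fit_shape_regression(sub, des)
    dt <- if (is.null(displace_at)) NULL else {
      at <- displace_at(dsub)
      as.numeric(design_matrix(formula, rbind(dsub, at))[nrow(dsub) + 1L, ])
    }
    out[idx, ] <- detrend_shapes(fit, displace_to = dt)$X
  }
  shape_matrix(out, kind = shapes$kind, k = shapes$k, m = shapes$m,
               h = shapes$h, ids = shapes$ids)
}

#' Model-expected shapes
#'
#' Predictions of a fitted shape regression at chosen design rows: group
#' mean shapes for a groups-only design, points on the allometric regression
#' line for a size design, and so on.
#'
#' @param model a `linear_shape_model`.
#' @param at `q x d` matrix of design rows (a length-`d` vector is one row).
#' @return a [shape_matrix] of `q` predicted shapes.
#' @export
expected_shapes <- function(model, at) {
  stopifnot(inherits(model, "linear_shape_model"))
  if (is.null(dim(at))) at <- matrix(at, nrow = 1L)
  at <- as.matrix(at)
  if (ncol(at) != ncol(model$design))
    stop("`at` must have d = ", ncol(model$design), " columns", call. = FALSE)
  pred <- at %*% model$coefficients
  sm <- model$shapes
  shape_matrix(pred, kind = sm$kind, k = sm$k, m = sm$m, h = sm$h,
               ids = rownames(at))
}

#' Burnaby orthogonal projection
#'
#' Projects centred shape variables onto the subspace orthogonal to a set of
#' nuisance directions F, using P = I - F (F'F)^-1 F', and adds the mean
#' shape back. After filtering, the data have exactly zero variance along
#' every column of F.
#'
#' @param shapes a [shape_matrix].
#' @param F `p x f` matrix of directions to remove (full column rank,
#'   `f < p`).
#' @return a filtered [shape_matrix].
#' @export
burnaby_filter <- function(shapes, F) {
  shapes <- as_shape_matrix(shapes)
  F <- as.matrix(F)
  p <- ncol(shapes$X)
  if (nrow(F) != p) stop("F must have p = ", p, " rows", call. = FALSE)
  if (ncol(F) >= p) stop("need fewer directions than variables", call. = FALSE)
  P <- burnaby_projector(F)
  mu <- colMeans(shapes$X)
  Xc <- sweep(shapes$X, 2L, mu)
  out <- sweep(Xc %*% P, 2L, mu, `+`)
  shape_matrix(out, kind = shapes$kind, k = shapes$k, m = shapes$m,
               h = shapes$h, ids = shapes$ids)
}

# P = I - F (F'F)^-1 F', with rank and idempotency checks
burnaby_projector <- function(F) {
  f <- ncol(F)
  if (qr(F)$rank < f)
    stop("nuisance directions F are rank deficient", call. = FALSE)
  P <- diag(nrow(F)) - F %*% solve(crossprod(F), t(F))
  if (max(abs(P %*% P - P)) > 1e-8)
    stop("projector failed idempotency check; F is ill-conditioned",
         call. = FALSE)
  P
}
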