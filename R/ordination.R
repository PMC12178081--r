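#' @title Ordination container
#' @description All ordination constructors return a `shape_ordination`:
#' a centre vector, a `p x q` loading matrix with unit-norm columns, the
#' `n x q` scores, a per-axis `explained` vector (variances for the
#' PCA-family methods, singular values for PLS), a method tag and
#' method-specific extras. For every linear method the stored scores satisfy
#' `scores = (X - center) %*% loadings`. A deterministic sign convention is
#' applied: each loading column is flipped so that its largest-magnitude
#' entry is positive.
#' @name shape_ordination
NULL

new_ordination <- function(center, loadings, scores, explained, method,
                           shapes = NULL, extras = list()) {
  q <- ncol(loadings)
  colnames(loadings) <- colnames(scores) <- axis_names(method, q)
  structure(list(center = as.numeric(center), loadings = loadings,
                 scores = scores, explained = explained, method = method,
                 shapes = shapes, extras = extras),
            class = "shape_ordination")
}

axis_names <- function(method, q) {
  pre <- switch(method, pca = "PC", bgpca = "bgPC", pls = "PLS",
                burnaby = "BPC", ppca = "pPC", paca = "PaC", "Ax")
  paste0(pre, seq_len(q))
}

# flip columns so the largest-|value| entry of each is positive;
# companion matrices (scores, paired loadings) are flipped in step
fix_signs <- function(loadings, ...) {
  others <- list(...)
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      others <- lapply(others, function(M) { M[, j] <- -M[, j]; M })
    }
  }
  c(list(loadings), others)
}

#' @export
print.shape_ordination <- function(x, ...) {
  cat("<shape_ordination> method: ", x$method, "; ", nrow(x$scores),
      " observations, ", ncol(x$loadings), " axes\n", sep = "")
  ex <- x$explained
  if (x$method != "pls" && sum(ex) > 0) {
    cat("  variance shares:",
        paste0(format(100 * ex[seq_len(min(5, length(ex)))] / sum(ex),
                      digits = 3), "%"), "\n")
  }
  invisible(x)
}

#' Project shape rows into an ordination
#'
#' The single affine contract every projection path shares:
#' `scores = (x - center) %*% loadings`. Works for any compatible shapes,
#' including shapes not used when the ordination was built.
#'
#' @param ord a `shape_ordination`.
#' @param x a [shape_matrix], or a plain matrix/vector of flattened rows.
#' @return `n x q` score matrix.
#' @export
ordination_scores <- function(ord, x) {
  if (inherits(x, c("landmark_set", "outline_coeffs", "shape_matrix")))
    x <- as_shape_matrix(x)$X
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  p <- length(ord$center)
  if (ncol(x) != p)
    stop("incompatible shapes: expected p = ", p, " variables, got ",
         ncol(x), call. = FALSE)
  sweep(x, 2L, ord$center) %*% ord$loadings
}

#' Principal component analysis of shape variables
#'
#' Eigen-decomposition of the sample covariance matrix (computed through the
#' singular value decomposition of the centred data), axes ordered by
#' decreasing eigenvalue, with the package-wide deterministic sign
#' convention. All axes up to `min(n - 1, p)` with non-degenerate variance
#' are retained, so the full score set is a rigid rotation of the centred
#' data.
#'
#' @param shapes a [shape_matrix] (or coercible).
#' @return a `shape_ordination` with `explained` holding eigenvalues
#'   (score variances).
#' @export
pca <- function(shapes) {
  shapes <- as_shape_matrix(shapes)
  X <- shapes$X
  n <- nrow(X)
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc)
  q <- min(n - 1L, ncol(X))
  V <- sv$v[, seq_len(q), drop = FALSE]
  ev <- (sv$d[seq_len(q)]^2) / (n - 1L)
  fx <- fix_signs(V)
  V <- fx[[1L]]
  new_ordination(mu, V, Xc %*% V, ev, "pca", shapes)
}

#' Between-groups principal component analysis
#'
#' PCA of the matrix of group mean shapes (each group counting once,
#' unweighted, unless `weighted`), followed by projection of all
#' observations onto the resulting axes; at most g - 1 axes. With
#' `loocv = TRUE` each observation's scores are computed from axes and
#' centre re-derived with that observation excluded from its own group mean
#' — the standard guard against spurious group separation when variables
#' outnumber observations.
#'
#' @param shapes a [shape_matrix].
#' @param groups length-`n` group labels (`>= 2` groups).
#' @param loocv leave-one-out cross-validated scores?
#' @param weighted weight group means by group size when averaging the
#'   grand centre? (The group-mean PCA itself always treats each group mean
#'   as one row.)
#' @return a `shape_ordination`; `extras$group_means` holds the g x p mean
#'   matrix and `extras$groups` the labels.
#' @export
bg_pca <- function(shapes, groups, loocv = FALSE, weighted = FALSE) {
  shapes <- as_shape_matrix(shapes)
  X <- shapes$X
  groups <- as.factor(groups)
  if (length(groups) != nrow(X)) stop("`groups` length mismatch", call. = FALSE)
  g <- nlevels(groups)
  if (g < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 1L)) stop("empty group", call. = FALSE)
  gm <- group_means(X, groups)
  ctr <- if (weighted) colMeans(X) else colMeans(gm)
  dec <- bgpca_axes(gm, ctr, ncol(X))
  V <- dec$V
  scores <- sweep(X, 2L, ctr) %*% V
  if (loocv) {
    for (i in seq_len(nrow(X))) {
      gi <- groups[i]
      idx <- which(groups == gi)
      if (length(idx) < 2L)
        stop("leave-one-out would empty group '", gi, "'", call. = FALSE)
      gm_i <- gm
      gm_i[gi, ] <- colMeans(X[setdiff(idx, i), , drop = FALSE])
      ctr_i <- if (weighted) colMeans(X[-i, , drop = FALSE]) else colMeans(gm_i)
      dec_i <- bgpca_axes(gm_i, ctr_i, ncol(X))
      Vi <- dec_i$V
      # align axis signs with the full-sample axes so scores are comparable
      for (j in seq_len(min(ncol(Vi), ncol(V))))
        if (sum(Vi[, j] * V[, j]) < 0) Vi[, j] <- -Vi[, j]
      si <- (X[i, ] - ctr_i) %*% Vi
      scores[i, ] <- 0
      scores[i, seq_len(ncol(si))] <- si
    }
  }
  new_ordination(ctr, V, scores, dec$ev, "bgpca", shapes,
                 extras = list(group_means = gm, groups = groups,
                               loocv = loocv))
}

group_means <- function(X, groups) {
  gm <- rowsum(X, groups) / as.vector(table(groups))
  gm[levels(groups), , drop = FALSE]
}

bgpca_axes <- function(gm, ctr, p) {
  Mc <- sweep(gm, 2L, ctr)
  sv <- svd(Mc)
  q <- min(nrow(gm) - 1L, p)
  V <- sv$v[, seq_len(q), drop = FALSE]
  ev <- (sv$d[seq_len(q)]^2) / (nrow(gm) - 1L)
  fx <- fix_signs(V)
  list(V = fx[[1L]], ev = ev)
}

#' Two-block partial least squares of shapes against external variables
#'
#' Singular value decomposition of the cross-covariance matrix between the
#' (column-centred) shape block and a second block of continuous variables,
#' yielding paired axes of maximal mutual covariation. The shape-side
#' loadings/scores populate the ordination; the second block's loadings and
#' scores sit in `extras`.
#'
#' @param shapes a [shape_matrix] (first block).
#' @param Y `n x py` numeric matrix (second block).
#' @return a `shape_ordination` with `explained` holding singular values
#'   (cross-covariances of paired scores); `extras$y_loadings`,
#'   `extras$y_scores`, `extras$y_center`.
#' @export
pls_shapes <- function(shapes, Y) {
  shapes <- as_shape_matrix(shapes)
  X <- shapes$X
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("blocks must share n", call. = FALSE)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  mux <- colMeans(X); muy <- colMeans(Y)
  Xc <- sweep(X, 2L, mux); Yc <- sweep(Y, 2L, muy)
  C <- crossprod(Xc, Yc) / (n - 1L)
  q <- min(ncol(X), ncol(Y), n - 1L)
  if (max(abs(C)) == 0)
    warning("zero cross-covariance between blocks; singular values are 0")
  sv <- svd(C, nu = q, nv = q)
  U <- sv$u; V <- sv$v
  fx <- fix_signs(U, V)
  U <- fx[[1L]]; V <- fx[[2L]]
  new_ordination(mux, U, Xc %*% U, sv$d[seq_len(q)], "pls", shapes,
                 extras = list(y_loadings = V, y_scores = Yc %*% V,
                               y_center = muy))
}

#' Burnaby ordination: PCA orthogonal to nuisance variation
#'
#' Removes the span of a set of nuisance directions before ordination.
#' When `nuisance` is an `n x d` covariate block, the directions are the
#' regression coefficient vectors of the shapes on those covariates
#' (intercept excluded); when it is a `p x f` matrix it is used directly.
#' PCA is then performed in the orthogonal complement, so all resulting
#' scores have exactly zero variance along the removed directions.
#'
#' @param shapes a [shape_matrix].
#' @param nuisance covariates (`n` rows) or directions (`p` rows).
#' @param type disambiguates when `n == p`; `"auto"` infers from row count.
#' @return a `shape_ordination`; `extras$removed` holds the `p x f`
#'   direction matrix.
#' @export
burnaby_ordination <- function(shapes, nuisance,
                               type = c("auto", "covariates", "directions")) {
  shapes <- as_shape_matrix(shapes)
  X <- shapes$X
  type <- match.arg(type)
  if (is.null(dim(nuisance))) nuisance <- matrix(nuisance, ncol = 1L)
  nuisance <- as.matrix(nuisance)
  n <- nrow(X); p <- ncol(X)
  if (type == "auto") {
    if (nrow(nuisance) == n && nrow(nuisance) == p)
      stop("n == p: pass type = 'covariates' or 'directions'", call. = FALSE)
    type <- if (nrow(nuisance) == n) "covariates" else "directions"
  }
  F <- if (type == "covariates") {
    if (nrow(nuisance) != n) stop("covariates must have n rows", call. = FALSE)
    fit <- fit_shape_regression(shapes, cbind(`(Intercept)` = 1, nuisance))
    t(fit$coefficients[-1L, , drop = FALSE])
  } else {
    if (nrow(nuisance) != p) stop("directions must have p rows", call. = FALSE)
    nuisance
  }
  P <- burnaby_projector(F)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu) %*% P
  sv <- svd(Xc)
  q <- min(n - 1L, p - ncol(F))
  V <- sv$v[, seq_len(q), drop = FALSE]
  ev <- (sv$d[seq_len(q)]^2) / (n - 1L)
  fx <- fix_signs(V)
  V <- fx[[1L]]
  new_ordination(mu, V, Xc %*% V, ev, "burnaby", shapes,
                 extras = list(removed = F))
}
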