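#' Phylogenetic (Brownian motion) covariance matrix
#'
#' For a rooted tree with branch lengths, `C[i, j]` is the shared path
#' length from the root to the most recent common ancestor of tips i and j
#' — the tip covariance structure implied by Brownian motion. Diagonal
#' entries are root-to-tip path lengths.
#'
#' @param tree an `ape::phylo` tree, rooted, with positive branch lengths.
#' @param tips optional character vector of labels that must all be present
#'   on the tree (e.g. the row ids of a shape matrix).
#' @return `s x s` matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree, tips = NULL) {
  check_tree(tree)
  if (!is.null(tips)) {
    miss <- setdiff(tips, tree$tip.label)
    if (length(miss) > 0L)
      stop("labels not on the tree: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  ape::vcv.phylo(tree)
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object",
                                     call. = FALSE)
  # a single root vertex (polytomies, incl. star trees, are fine)
  if (length(setdiff(tree$edge[, 1L], tree$edge[, 2L])) != 1L)
    stop("tree must be rooted", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths",
                                      call. = FALSE)
  invisible(tree)
}

# align a shape matrix's rows to the tree's tip order
match_tips <- function(shapes, tree) {
  miss <- setdiff(tree$tip.label, shapes$ids)
  extra <- setdiff(shapes$ids, tree$tip.label)
  if (length(miss) || length(extra))
    stop("shape ids and tree tips disagree; missing from shapes: ",
         paste(miss, collapse = ", "), "; not on tree: ",
         paste(extra, collapse = ", "), call. = FALSE)
  idx <- match(tree$tip.label, shapes$ids)
  shape_matrix(shapes$X[idx, , drop = FALSE], kind = shapes$kind,
               k = shapes$k, m = shapes$m, h = shapes$h,
               ids = shapes$ids[idx])
}

# GLS (BM) estimate of the root state: (1'C^-1 1)^-1 1'C^-1 X
gls_root <- function(X, Cinv) {
  as.numeric(colSums(Cinv %*% X) / sum(Cinv))
}

#' Phylogenetic principal component analysis
#'
#' PCA of the evolutionary (GLS, Brownian-motion weighted) covariance of
#' species mean shapes: the root state is estimated by generalized least
#' squares, the evolutionary covariance R = (X - 1a)' C^-1 (X - 1a)/(s - 1)
#' is eigen-decomposed, and scores are the GLS-centred data projected on
#' its eigenvectors. Covariance (not correlation) mode. Because the
#' eigenvectors spanning the data are all retained, the full score set
#' preserves the original inter-specimen distances.
#'
#' @param shapes [shape_matrix] of species mean shapes, ids matching tips.
#' @param tree rooted `phylo` with branch lengths.
#' @return a `shape_ordination` (method `"ppca"`); `extras$tree` keeps the
#'   tree, `extras$evol_vcv` the evolutionary covariance.
#' @export
ppca <- function(shapes, tree) {
  shapes <- as_shape_matrix(shapes)
  check_tree(tree)
  shapes <- match_tips(shapes, tree)
  X <- shapes$X
  s <- nrow(X)
  if (s < 3L) stop("need at least 3 species", call. = FALSE)
  C <- phylo_covariance(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance: ", conditionMessage(e),
         call. = FALSE))
  a <- gls_root(X, Cinv)
  Xc <- sweep(X, 2L, a)
  R <- crossprod(Xc, Cinv %*% Xc) / (s - 1L)
  ee <- eigen(R, symmetric = TRUE)
  keep <- which(ee$values > max(ee$values) * 1e-12)
  V <- ee$vectors[, keep, drop = FALSE]
  fx <- fix_signs(V)
  V <- fx[[1L]]
  new_ordination(a, V, Xc %*% V, ee$values[keep], "ppca", shapes,
                 extras = list(tree = tree, evol_vcv = R))
}

#' Phylogenetically aligned component analysis
#'
#' Orders axes by their alignment with phylogenetic signal rather than by
#' total variance: the GLS-centred data are decomposed along the
#' eigenvectors of Xc' C Xc, where C is the tip-space Brownian covariance,
#' so the first axis maximises the covariation between scores and the
#' phylogenetic structure over all unit directions. Loadings are orthonormal
#' and span the data, so full-axis scores preserve inter-specimen geometry.
#'
#' @inheritParams ppca
#' @return a `shape_ordination` (method `"paca"`); `explained` holds the
#'   alignment eigenvalues.
#' @export
paca <- function(shapes, tree) {
  shapes <- as_shape_matrix(shapes)
  check_tree(tree)
  shapes <- match_tips(shapes, tree)
  X <- shapes$X
  if (nrow(X) < 3L) stop("need at least 3 species", call. = FALSE)
  C <- phylo_covariance(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance: ", conditionMessage(e),
         call. = FALSE))
  a <- gls_root(X, Cinv)
  Xc <- sweep(X, 2L, a)
  M <- crossprod(Xc, C %*% Xc)
  ee <- eigen(M, symmetric = TRUE)
  keep <- which(ee$values > max(ee$values) * 1e-12)
  V <- ee$vectors[, keep, drop = FALSE]
  fx <- fix_signs(V)
  V <- fx[[1L]]
  new_ordination(a, V, Xc %*% V, ee$values[keep], "paca", shapes,
                 extras = list(tree = tree))
}

#' Brownian-motion ancestral state estimates
#'
#' Maximum-likelihood (GLS) estimates of the states at every internal node
#' under Brownian motion, obtained from the joint tip-plus-node covariance
#' system: with root state a estimated by GLS, node states are
#' a + C_nt C_tt^-1 (X - 1a), where C_nt and C_tt are the node-tip and
#' tip-tip blocks of the shared-path-length covariance over all vertices.
#' Applied independently per variable (column).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tip_values `s x p` matrix (or vector) of tip states; rownames (or
#'   names) must match the tip labels, else tip order is assumed.
#' @return `(internal nodes) x p` matrix; rownames are the ape node numbers
#'   (`s + 1` is the root).
#' @export
anc_states_bm <- function(tree, tip_values) {
  check_tree(tree)
  s <- length(tree$tip.label)
  if (is.null(dim(tip_values))) tip_values <- matrix(
    tip_values, ncol = 1L,
    dimnames = list(names(tip_values), NULL))
  X <- as.matrix(tip_values)
  if (nrow(X) != s) stop("need one row per tip", call. = FALSE)
  if (!is.null(rownames(X))) {
    miss <- setdiff(tree$tip.label, rownames(X))
    if (length(miss) > 0L)
      stop("tip values missing for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    X <- X[tree$tip.label, , drop = FALSE]
  }
  nn <- tree$Nnode
  depths <- ape::node.depth.edgelength(tree)      # distance from root
  M <- ape::mrca(tree, full = TRUE)               # all-vertex MRCA indices
  Cfull <- matrix(depths[M], nrow(M), ncol(M))
  tip_idx <- seq_len(s)
  node_idx <- s + seq_len(nn)
  Ctt <- Cfull[tip_idx, tip_idx]
  Cnt <- Cfull[node_idx, tip_idx, drop = FALSE]
  Cinv <- solve(Ctt)
  a <- gls_root(X, Cinv)
  Xc <- sweep(X, 2L, a)
  est <- sweep(Cnt %*% Cinv %*% Xc, 2L, a, `+`)
  rownames(est) <- as.character(node_idx)
  colnames(est) <- colnames(X)
  est
}
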