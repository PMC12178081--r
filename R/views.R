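#' Phenogram: an ordination axis against time along a phylogeny
#'
#' Positions every vertex of a time-calibrated tree at
#' (node height, axis score): tip heights are root-to-tip path lengths,
#' internal node scores default to Brownian-motion ancestral estimates of
#' the tip scores, and parent-child vertices are joined by straight
#' segments.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param axis_scores named length-`s` vector of tip scores on one
#'   ordination axis (names matching tip labels; tip order assumed if
#'   unnamed).
#' @param node_scores optional internal-node scores (ape node order);
#'   estimated with [anc_states_bm()] when absent.
#' @return an object of class `phenogram_data`: data frame `vertices`
#'   (`node`, `time`, `value`, `is_tip`, `label`) and matrix `edges`
#'   (ape vertex number pairs).
#' @export
phenogram <- function(tree, axis_scores, node_scores = NULL) {
  check_tree(tree)
  s <- length(tree$tip.label)
  axis_scores <- unlist(axis_scores)
  if (length(axis_scores) != s)
    stop("need one score per tip", call. = FALSE)
  if (!is.null(names(axis_scores))) {
    miss <- setdiff(tree$tip.label, names(axis_scores))
    if (length(miss) > 0L)
      stop("scores missing for tips: ", paste(miss, collapse = ", "),
           call. = FALSE)
    axis_scores <- axis_scores[tree$tip.label]
  }
  if (is.null(node_scores))
    node_scores <- as.numeric(anc_states_bm(tree, axis_scores))
  if (length(node_scores) != tree$Nnode)
    stop("need one score per internal node", call. = FALSE)
  times <- ape::node.depth.edgelength(tree)
  vertices <- data.frame(
    node = seq_len(s + tree$Nnode),
    time = times,
    value = c(as.numeric(axis_scores), node_scores),
    is_tip = c(rep(TRUE, s), rep(FALSE, tree$Nnode)),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)))
  structure(list(vertices = vertices, edges = tree$edge, tree = tree),
            class = "phenogram_data")
}

#' @export
print.phenogram_data <- function(x, ...) {
  cat("<phenogram_data> ", sum(x$vertices$is_tip), " tips, ",
      sum(!x$vertices$is_tip), " internal nodes\n", sep = "")
  invisible(x)
}

#' Hybrid morphospace: one shape axis against a non-shape variable
#'
#' Pairs the scores along a single ordination axis with an accompanying
#' variable — a scatter against a continuous covariate (size, time,
#' performance), or box/violin summaries across the levels of a
#' categorical covariate — optionally with background shape models along
#' the shape-axis margin, computed exactly as [extract_shapes()] along that
#' axis alone.
#'
#' @param axis_scores length-`n` scores on one ordination axis.
#' @param covariate length-`n` continuous or categorical variable.
#' @param type `"scatter"`, `"box"` or `"violin"`.
#' @param ord optional `shape_ordination` enabling margin shape models.
#' @param axis which ordination axis `axis_scores` came from.
#' @param n_models number of margin shape models.
#' @return an object of class `hybrid_view`: `data` (x = covariate,
#'   y = scores), per-level `summaries` (box: `stats::fivenum`; violin:
#'   kernel densities), and `margin` (model positions on the axis plus a
#'   [shape_matrix] of margin shapes) when `ord` is given.
#' @export
hybrid_view <- function(axis_scores, covariate,
                        type = c("scatter", "box", "violin"),
                        ord = NULL, axis = 1L, n_models = 5L) {
  type <- match.arg(type)
  axis_scores <- as.numeric(axis_scores)
  if (length(covariate) != length(axis_scores))
    stop("`covariate` length (", length(covariate),
         ") != scores length (", length(axis_scores), ")", call. = FALSE)
  summaries <- NULL
  if (type %in% c("box", "violin")) {
    f <- as.factor(covariate)
    summaries <- lapply(stats::setNames(levels(f), levels(f)), function(l) {
      y <- axis_scores[f == l]
      if (type == "box") stats::fivenum(y)
      else stats::density(y)
    })
  }
  margin <- NULL
  if (!is.null(ord)) {
    at <- seq(min(axis_scores), max(axis_scores), length.out = n_models)
    margin <- list(positions = at,
                   shapes = extract_shapes(ord, matrix(at, ncol = 1L),
                                           axes = axis))
  }
  structure(list(data = data.frame(x = covariate, y = axis_scores),
                 type = type, summaries = summaries, margin = margin,
                 axis = axis),
            class = "hybrid_view")
}

#' @export
print.hybrid_view <- function(x, ...) {
  cat("<hybrid_view> ", x$type, ", n = ", nrow(x$data),
      if (!is.null(x$margin)) paste0(", ", length(x$margin$positions),
                                     " margin models"),
      "\n", sep = "")
  invisible(x)
}
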