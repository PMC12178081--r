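#' Read landmark configurations from a TPS file
#'
#' Parses the de-facto landmark exchange format: records of `LM=k` (or
#' `LM3=k` for 3D) followed by `k` coordinate lines, with optional
#' `ID=label`, `IMAGE=` and `SCALE=factor` lines. Coordinates are
#' multiplied by the scale factor when present. All records must share the
#' same landmark count and dimensionality.
#'
#' @param path file path.
#' @return a [landmark_set]; specimen ids come from `ID=` lines when
#'   present, else `s1, s2, ...`.
#' @export
read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  starts <- grep("^LM3?\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L)
    stop("no LM= records found in '", path, "'", call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(lines))
  configs <- list(); ids <- character(); dims <- integer()
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    head <- block[1L]
    m <- if (grepl("^LM3", head, ignore.case = TRUE)) 3L else 2L
    k <- as.integer(sub("^LM3?\\s*=\\s*", "", head, ignore.case = TRUE))
    if (is.na(k) || k < 1L)
      stop("record ", r, ": malformed landmark count line '", head, "'",
           call. = FALSE)
    coord_lines <- block[-1L]
    coord_lines <- coord_lines[!grepl("^[A-Za-z]+\\s*=", coord_lines) &
                                 nzchar(coord_lines)]
    if (length(coord_lines) < k)
      stop("record ", r, ": expected ", k, " coordinate lines, found ",
           length(coord_lines), call. = FALSE)
    co <- do.call(rbind, lapply(coord_lines[seq_len(k)], function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1L]]))
      if (anyNA(v) || length(v) != m)
        stop("record ", r, ": malformed coordinate line '", l, "'",
             call. = FALSE)
      v
    }))
    idl <- grep("^ID\\s*=", block, ignore.case = TRUE, value = TRUE)
    id <- if (length(idl) > 0L) sub("^ID\\s*=\\s*", "", idl[1L],
                                    ignore.case = TRUE)
          else paste0("s", r)
    scl <- grep("^SCALE\\s*=", block, ignore.case = TRUE, value = TRUE)
    if (length(scl) > 0L) {
      fac <- as.numeric(sub("^SCALE\\s*=\\s*", "", scl[1L],
                            ignore.case = TRUE))
      if (is.na(fac)) stop("record ", r, ": malformed SCALE line",
                           call. = FALSE)
      co <- co * fac
    }
    configs[[r]] <- co; ids[r] <- id; dims[r] <- m
  }
  ks <- vapply(configs, nrow, integer(1L))
  if (length(unique(ks)) > 1L || length(unique(dims)) > 1L)
    stop("inconsistent landmark count/dimension across records (record ",
         which(ks != ks[1L] | dims != dims[1L])[1L], ")", call. = FALSE)
  arr <- array(NA_real_, c(length(configs), ks[1L], dims[1L]))
  for (i in seq_along(configs)) arr[i, , ] <- configs[[i]]
  landmark_set(arr, ids = ids)
}

#' Write landmark configurations to a TPS file
#'
#' @param lms a [landmark_set].
#' @param path destination path.
#' @param digits coordinate precision (default keeps full double precision).
#' @return `path`, invisibly.
#' @export
write_tps <- function(lms, path, digits = 17L) {
  stopifnot(inherits(lms, "landmark_set"))
  d <- dim(lms$coords)
  con <- file(path, "w"); on.exit(close(con))
  tag <- if (lms$dim == 3L) "LM3=" else "LM="
  for (i in seq_len(d[1L])) {
    writeLines(paste0(tag, d[2L]), con)
    cfg <- lms$coords[i, , , drop = TRUE]
    writeLines(apply(format(cfg, digits = digits, trim = TRUE,
                            scientific = FALSE), 1L, paste,
                     collapse = " "), con)
    writeLines(paste0("ID=", lms$ids[i]), con)
  }
  invisible(path)
}

#' Read shapes from a wide CSV (one row per specimen)
#'
#' Columns `x1, y1[, z1], x2, ...` hold landmark coordinates (when `dim` is
#' 2 or 3) or arbitrary shape variables (when `dim` is `NULL`, returning a
#' [shape_matrix] of kind `"fourier"` only if the header looks like
#' harmonic quadruples, otherwise an error asks for an explicit kind). An
#' optional leading `id` column supplies specimen labels.
#'
#' @param path file path.
#' @param dim 2 or 3 for landmark data; `NULL` to read Fourier-coefficient
#'   columns (`a1, b1, c1, d1, ...`).
#' @return a [landmark_set] (landmark columns) or [outline_coeffs].
#' @export
read_wide_csv <- function(path, dim = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- NULL
  if (tolower(names(df)[1L]) == "id") {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("non-numeric shape columns in '", path, "'",
                           call. = FALSE)
  if (is.null(dim)) {
    if (ncol(M) %% 4L != 0L)
      stop("cannot interpret ", ncol(M), " columns as harmonic quadruples; ",
           "pass dim = 2 or 3 for landmark data", call. = FALSE)
    sm <- shape_matrix(M, kind = "fourier", h = ncol(M) %/% 4L, ids = ids)
    return(unflatten_shapes(sm, ids = sm$ids))
  }
  if (!dim %in% c(2L, 3L)) stop("dim must be 2 or 3", call. = FALSE)
  if (ncol(M) %% dim != 0L)
    stop(ncol(M), " columns are not a multiple of dim = ", dim,
         call. = FALSE)
  sm <- shape_matrix(M, kind = if (dim == 2L) "landmarks2d" else
    "landmarks3d", k = ncol(M) %/% dim, ids = ids)
  unflatten_shapes(sm, ids = sm$ids)
}

#' Write shapes to a wide CSV
#'
#' @param x a [landmark_set], [outline_coeffs] or [shape_matrix].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_wide_csv <- function(x, path) {
  sm <- as_shape_matrix(x)
  df <- data.frame(id = sm$ids, sm$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read elliptic Fourier coefficients from CSV
#'
#' Expects harmonic-quadruple columns `a1, b1, c1, d1, a2, ...`, optional
#' `A0`/`C0` centre columns and an optional leading `id` column.
#'
#' @param path file path.
#' @return an [outline_coeffs].
#' @export
read_coeffs_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- NULL
  if (tolower(names(df)[1L]) == "id") {
    ids <- as.character(df[[1L]]); df <- df[, -1L, drop = FALSE]
  }
  off <- NULL
  oc_cols <- match(c("A0", "C0"), names(df))
  if (!anyNA(oc_cols)) {
    off <- as.matrix(df[, oc_cols]); df <- df[, -oc_cols, drop = FALSE]
  }
  M <- as.matrix(df)
  if (ncol(M) %% 4L != 0L)
    stop("coefficient columns are not harmonic quadruples in '", path, "'",
         call. = FALSE)
  h <- ncol(M) %/% 4L
  sm <- shape_matrix(M, kind = "fourier", h = h, ids = ids)
  oc <- unflatten_shapes(sm, ids = sm$ids)
  if (!is.null(off)) oc$offset <- off
  oc
}

#' Write elliptic Fourier coefficients to CSV
#'
#' @param oc an [outline_coeffs].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_coeffs_csv <- function(oc, path) {
  stopifnot(inherits(oc, "outline_coeffs"))
  sm <- as_shape_matrix(oc)
  df <- data.frame(id = sm$ids, sm$X, A0 = oc$offset[, 1L],
                   C0 = oc$offset[, 2L], check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a phylogeny from a Newick file
#'
#' Wrapper over `ape::read.tree` that additionally requires branch lengths
#' (the whole workflow's phylogenetic machinery assumes them).
#'
#' @param path Newick file.
#' @return an `ape::phylo`.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("failed to parse Newick file '", path, "'",
                          call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree in '", path, "' has no branch lengths", call. = FALSE)
  tree
}

#' Serialise an ordination to a CSV bundle
#'
#' Writes `center.csv`, `loadings.csv`, `scores.csv`, `explained.csv` and a
#' `meta.yaml` (method tag, shape kind and unflattening metadata, schema
#' version) into a directory; [read_ordination()] restores the object.
#'
#' @param ord a `shape_ordination`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ordination <- function(ord, dir) {
  stopifnot(inherits(ord, "shape_ordination"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(center = ord$center),
                   file.path(dir, "center.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ord$loadings),
                   file.path(dir, "loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = rownames(ord$scores),
                              as.data.frame(ord$scores),
                              check.names = FALSE),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(explained = ord$explained),
                   file.path(dir, "explained.csv"), row.names = FALSE)
  sm <- ord$shapes
  meta <- list(schema = 1L, method = ord$method,
               kind = if (!is.null(sm)) sm$kind else NA,
               k = if (!is.null(sm$k)) sm$k else NA,
               m = if (!is.null(sm$m)) sm$m else NA,
               h = if (!is.null(sm$h)) sm$h else NA)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Restore an ordination from a CSV bundle
#'
#' @param dir directory written by [write_ordination()].
#' @return a `shape_ordination` (without the original training shapes; the
#'   centre row stands in as shape metadata carrier for reconstruction).
#' @export
read_ordination <- function(dir) {
  ctr <- utils::read.csv(file.path(dir, "center.csv"))$center
  L <- as.matrix(utils::read.csv(file.path(dir, "loadings.csv"),
                                 check.names = FALSE))
  sdf <- utils::read.csv(file.path(dir, "scores.csv"), check.names = FALSE)
  ids <- as.character(sdf$id)
  S <- as.matrix(sdf[, -1L, drop = FALSE])
  rownames(S) <- ids
  ex <- utils::read.csv(file.path(dir, "explained.csv"))$explained
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  shapes <- NULL
  if (!is.na(meta$kind)) {
    shapes <- shape_matrix(matrix(ctr, nrow = 1L), kind = meta$kind,
                           k = if (is.na(meta$k)) NULL else meta$k,
                           m = if (is.na(meta$m)) NULL else meta$m,
                           h = if (is.na(meta$h)) NULL else meta$h,
                           ids = "center")
  }
  new_ordination(ctr, L, S, ex, meta$method, shapes)
}
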