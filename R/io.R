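#' Read / write FreeSurfer binary triangle surfaces
#'
#' The standard big-endian triangle-surface format (magic 16777214):
#' comment line, vertex and face counts, float32 vertex coordinates and
#' int32 0-based triangle indices (converted to 1-based in R).
#'
#' @param path surface file.
#' @return list with `vertices` (V x 3) and `triangles` (T x 3, 1-based).
#' @rdname surface_io
#' @export
read_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 3L, size = 1L, signed = FALSE)
  if (!identical(as.integer(magic), c(255L, 255L, 254L)))
    stop("not a FreeSurfer binary triangle surface: ", path)
  # comment terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    ch <- readBin(con, "raw", 1L)
    if (length(ch) == 0L) stop("unexpected end of surface file")
    if (ch == as.raw(10) && prev == as.raw(10)) break
    prev <- ch
  }
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  v <- readBin(con, "numeric", 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", 3L * nf, size = 4L, endian = "big")
  list(vertices = matrix(v, nv, 3L, byrow = TRUE),
       triangles = matrix(f, nf, 3L, byrow = TRUE) + 1L)
}

#' @param vertices V x 3 coordinates; @param triangles T x 3 1-based.
#' @rdname surface_io
#' @export
write_surface <- function(vertices, triangles, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255L, 255L, 254L)), con)
  writeBin(charToRaw("created by ficmap\n\n"), con)
  writeBin(as.integer(nrow(vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(nrow(triangles)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(triangles) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read / write FreeSurfer curvature (per-vertex scalar) files
#'
#' New-format curv files (magic 16777215, one float32 value per vertex).
#'
#' @param path curv file.
#' @rdname curv_io
#' @export
read_curv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 3L, size = 1L, signed = FALSE)
  if (!identical(as.integer(magic), c(255L, 255L, 255L)))
    stop("not a new-format FreeSurfer curv file: ", path)
  nv <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  readBin(con, "integer", 2L, size = 4L, endian = "big")  # fnum, vals/vertex
  readBin(con, "numeric", nv, size = 4L, endian = "big")
}

#' @param values numeric per-vertex vector (`NA` stored as NaN).
#' @rdname curv_io
#' @export
write_curv <- function(values, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255L, 255L, 255L)), con)
  writeBin(c(length(values), 0L, 1L), con, size = 4L, endian = "big")
  writeBin(as.numeric(ifelse(is.na(values), NaN, values)), con,
           size = 4L, endian = "big")
  invisible(path)
}

#' Read / write FreeSurfer label files (vertex index lists)
#'
#' ASCII label format; indices are 0-based on disk and 1-based in R.
#'
#' @param path label file.
#' @rdname label_io
#' @export
read_label <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[2L])
  tab <- read.table(text = lines[3:(2L + n)])
  as.integer(tab[[1L]]) + 1L
}

#' @param indices 1-based vertex indices; @param vertices optional V x 3
#'   coordinates written alongside the indices (zeros if omitted).
#' @rdname label_io
#' @export
write_label <- function(indices, path, vertices = NULL) {
  indices <- as.integer(indices)
  xyz <- if (is.null(vertices)) matrix(0, length(indices), 3L)
  else vertices[indices, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#!ascii label, from ficmap", con)
  writeLines(as.character(length(indices)), con)
  writeLines(sprintf("%d %.4f %.4f %.4f 0.0000", indices - 1L,
                     xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
  invisible(path)
}

#' Read a barycentric correspondence table
#'
#' CSV with columns `i1, i2, i3` (1-based subject vertex indices) and
#' `w1, w2, w3` (barycentric weights) — one row per atlas vertex.
#'
#' @param path CSV file.
#' @return data frame suitable for [resample_to_atlas()].
#' @export
read_correspondence <- function(path) {
  co <- read.csv(path)
  need <- c("i1", "i2", "i3", "w1", "w2", "w3")
  if (!all(need %in% names(co)))
    stop("correspondence CSV must have columns ", paste(need, collapse = ", "))
  co
}

#' Write a per-vertex map as CSV
#'
#' @param map a `vertex_map` or numeric vector.
#' @param path output CSV (columns `vertex`, `value`, and for `vertex_map`s
#'   also `sd`, `n_retained`, `missing`).
#' @export
write_vertex_map <- function(map, path) {
  if (inherits(map, "vertex_map")) {
    df <- data.frame(vertex = seq_len(map$n_vertices), value = map$mean,
                     sd = map$sd, n_retained = map$n_retained,
                     missing = map$missing)
  } else {
    df <- data.frame(vertex = seq_along(map), value = as.numeric(map))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
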