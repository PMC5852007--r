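#' Hierarchical part decomposition of an image
#'
#' Divides an image into the fixed four-level hierarchy used by the matching
#' cascade: Templates (`t` x `t`), Segments (`t/2`), Chunks (`t/4`) and
#' Windows (`t/8`). With the default `t = 16` the part sizes are 16/8/4/2
#' pixels. Templates tile the largest `t`-divisible sub-rectangle anchored at
#' the image origin; any border strip narrower than `t` is excluded and
#' recorded in the returned object.
#'
#' All coordinates in this package are 0-based `(row, col)` pixel positions,
#' so the origin of the first template is `(0, 0)` and a part of size `s` at
#' origin `(r, c)` covers rows `r .. r+s-1`.
#'
#' @param image_dims integer vector `(height, width)` in pixels, both >= `t`.
#' @param t base template side length in pixels; must be divisible by 8.
#' @return An object of class `part_grid`: a list with elements
#'   `t`, `image_dims`, `n_templates` (`(rows, cols)` of the template tiling),
#'   `template_origins` (matrix of 0-based `(row, col)` origins, row-major
#'   order), and `excluded` (sizes of the discarded bottom/right strips).
#' @seealso [window_points()], [parts_table()]
#' @examples
#' g <- part_grid(c(64, 64))
#' g$n_templates      # 4 x 4 templates
#' nrow(window_points(g))  # 1024 window points
#' @export
part_grid <- function(image_dims, t = 16L) {
  image_dims <- as.integer(image_dims)
  t <- as.integer(t)
  if (length(image_dims) != 2L || any(!is.finite(image_dims)))
    stop("image_dims must be (height, width)")
  if (t < 8L || t %% 8L != 0L)
    stop("t must be a positive multiple of 8 (got ", t, ")")
  if (any(image_dims < t))
    stop(sprintf("image (%d x %d) is smaller than the template size %d",
                 image_dims[1L], image_dims[2L], t))
  nr <- image_dims[1L] %/% t
  nc <- image_dims[2L] %/% t
  origins <- cbind(
    row = rep((seq_len(nr) - 1L) * t, each = nc),
    col = rep((seq_len(nc) - 1L) * t, times = nr)
  )
  structure(list(
    t = t,
    image_dims = image_dims,
    n_templates = c(rows = nr, cols = nc),
    template_origins = origins,
    excluded = c(bottom_rows = image_dims[1L] - nr * t,
                 right_cols  = image_dims[2L] - nc * t)
  ), class = "part_grid")
}

#' @export
print.part_grid <- function(x, ...) {
  cat(sprintf("Part grid: %d x %d image, t = %d\n",
              x$image_dims[1L], x$image_dims[2L], x$t))
  n_t <- prod(x$n_templates)
  cat(sprintf("  %d templates (%d x %d), %d segments, %d chunks, %d windows\n",
              n_t, x$n_templates[1L], x$n_templates[2L],
              4L * n_t, 16L * n_t, 64L * n_t))
  if (any(x$excluded > 0L))
    cat(sprintf("  excluded border: %d bottom rows, %d right cols\n",
                x$excluded[1L], x$excluded[2L]))
  invisible(x)
}

# Row-major 2x2 sub-part origins of a parent part: offsets (0,0),(0,h),(h,0),(h,h)
# with h = half the parent size. Used at every level of the hierarchy.
child_offsets <- function(size) {
  h <- size %/% 2L
  cbind(row = c(0L, 0L, h, h), col = c(0L, h, 0L, h))
}

#' Enumerate every part of a grid
#'
#' Materialises the full hierarchy as a data frame, mainly for inspection,
#' testing and JSON export. Parts are listed template-major, then segment,
#' chunk, window, each level in row-major order; the `(i, j, k, l)` address
#' gives the 1-based index of the part at each level (NA below the part's
#' own level).
#'
#' @param grid a [part_grid()] object.
#' @param levels character subset of
#'   `c("template", "segment", "chunk", "window")`.
#' @return data frame with columns `level`, `i`, `j`, `k`, `l`, `row`, `col`,
#'   `size`.
#' @export
parts_table <- function(grid, levels = c("template", "segment", "chunk", "window")) {
  stopifnot(inherits(grid, "part_grid"))
  levels <- match.arg(levels, several.ok = TRUE)
  t <- grid$t
  out <- vector("list", 0L)
  off_s <- child_offsets(t)
  off_c <- child_offsets(t %/% 2L)
  off_w <- child_offsets(t %/% 4L)
  n_t <- nrow(grid$template_origins)
  for (i in seq_len(n_t)) {
    to <- grid$template_origins[i, ]
    if ("template" %in% levels)
      out[[length(out) + 1L]] <- data.frame(level = "template", i = i, j = NA_integer_,
        k = NA_integer_, l = NA_integer_, row = to[1L], col = to[2L], size = t)
    if (!any(c("segment", "chunk", "window") %in% levels)) next
    for (j in 1:4) {
      so <- to + off_s[j, ]
      if ("segment" %in% levels)
        out[[length(out) + 1L]] <- data.frame(level = "segment", i = i, j = j,
          k = NA_integer_, l = NA_integer_, row = so[1L], col = so[2L], size = t %/% 2L)
      if (!any(c("chunk", "window") %in% levels)) next
      for (k in 1:4) {
        co <- so + off_c[k, ]
        if ("chunk" %in% levels)
          out[[length(out) + 1L]] <- data.frame(level = "chunk", i = i, j = j,
            k = k, l = NA_integer_, row = co[1L], col = co[2L], size = t %/% 4L)
        if (!("window" %in% levels)) next
        for (l in 1:4) {
          wo <- co + off_w[l, ]
          out[[length(out) + 1L]] <- data.frame(level = "window", i = i, j = j,
            k = k, l = l, row = wo[1L], col = wo[2L], size = t %/% 8L)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Dense window point set of a part grid
#'
#' Returns the first (top-left) pixel of every window, in the deterministic
#' template-major / segment / chunk / window enumeration order. With the
#' default hierarchy this is a dense uniform lattice of spacing 2 covering
#' the tiled area; it is the moving point set handed to the matcher.
#'
#' @param grid a [part_grid()] object.
#' @return numeric matrix with columns `row`, `col` (0-based) and attribute
#'   `spacing` (pixels).
#' @export
window_points <- function(grid) {
  stopifnot(inherits(grid, "part_grid"))
  tab <- window_origins_fast(grid)
  attr(tab, "spacing") <- grid$t %/% 8L
  tab
}

# window origins in i,j,k,l order without building the full parts table
window_origins_fast <- function(grid) {
  t <- grid$t
  off_s <- child_offsets(t)
  off_c <- child_offsets(t %/% 2L)
  off_w <- child_offsets(t %/% 4L)
  # per-template window offsets in j,k,l order (64 x 2)
  per <- matrix(0L, 64L, 2L)
  idx <- 1L
  for (j in 1:4) for (k in 1:4) for (l in 1:4) {
    per[idx, ] <- off_s[j, ] + off_c[k, ] + off_w[l, ]
    idx <- idx + 1L
  }
  n_t <- nrow(grid$template_origins)
  out <- matrix(0L, 64L * n_t, 2L)
  for (i in seq_len(n_t)) {
    out[((i - 1L) * 64L + 1L):(i * 64L), ] <-
      sweep(per, 2L, grid$template_origins[i, ], "+")
  }
  colnames(out) <- c("row", "col")
  out
}

#' Coarse representative point set
#'
#' First points of all parts at one level of the hierarchy (a uniform lattice
#' of spacing equal to the part size). Diagnostic companion of the dense
#' window set.
#'
#' @param grid a [part_grid()] object.
#' @param level one of `"template"`, `"segment"`, `"chunk"`, `"window"`.
#' @return numeric matrix with columns `row`, `col` and attribute `spacing`.
#' @export
coarse_points <- function(grid, level = "template") {
  level <- match.arg(level, c("template", "segment", "chunk", "window"))
  if (level == "window") return(window_points(grid))
  tab <- parts_table(grid, levels = level)
  out <- as.matrix(tab[, c("row", "col")])
  rownames(out) <- NULL
  attr(out, "spacing") <- tab$size[1L]
  out
}

#' Write a point set as CSV
#'
#' @param points matrix with columns `row`, `col` (0-based coordinates).
#' @param path output file; columns `id,row,col`.
#' @export
write_points <- function(points, path) {
  df <- data.frame(id = seq_len(nrow(points)),
                   row = points[, 1L], col = points[, 2L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a part grid to JSON
#'
#' @param grid a [part_grid()] object.
#' @param path output JSON file.
#' @param levels which levels to include (all four by default).
#' @export
write_part_grid <- function(grid, path,
                            levels = c("template", "segment", "chunk", "window")) {
  tab <- parts_table(grid, levels = levels)
  obj <- list(t = grid$t, image_dims = grid$image_dims,
              excluded = as.list(grid$excluded), parts = tab)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
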