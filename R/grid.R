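#' Regular analysis grid
#'
#' Planar 1 km-style grid in km coordinates. Cells are indexed row-major from
#' the bottom-left corner: `cell_id = (iy - 1) * nx + ix`, with `ix` increasing
#' eastward and `iy` northward. Cell boundaries follow the half-open convention
#' `[left, right) x [bottom, top)`, so a point on a shared edge belongs to the
#' cell to the right/above.
#'
#' @param nx,ny number of cells east-west / north-south.
#' @param cell_size cell edge length in km.
#' @param origin_x,origin_y coordinates (km) of the grid's lower-left corner.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(nx, ny, cell_size = 1, origin_x = 0, origin_y = 0) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || nx < 1L) stop_field("nx", "must be a positive integer")
  if (is.na(ny) || ny < 1L) stop_field("ny", "must be a positive integer")
  if (!is.finite(cell_size) || cell_size <= 0) stop_field("cell_size", "must be > 0")
  structure(
    list(nx = nx, ny = ny, cell_size = cell_size,
         origin_x = origin_x, origin_y = origin_y),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g km (origin %g, %g)\n",
              x$nx, x$ny, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

n_cells <- function(grid) grid$nx * grid$ny

#' Cell centroids of a grid
#'
#' @param grid a [grid_spec()].
#' @return `data.table` with columns `cell_id`, `ix`, `iy`, `x`, `y` (km),
#'   ordered by `cell_id`.
#' @export
cell_centroids <- function(grid) {
  ix <- rep(seq_len(grid$nx), times = grid$ny)
  iy <- rep(seq_len(grid$ny), each = grid$nx)
  data.table::data.table(
    cell_id = seq_len(grid$nx * grid$ny),
    ix = ix, iy = iy,
    x = grid$origin_x + (ix - 0.5) * grid$cell_size,
    y = grid$origin_y + (iy - 0.5) * grid$cell_size
  )
}

#' Assign points to their containing grid cell
#'
#' Half-open boundary convention: a point exactly on a shared edge falls in the
#' cell to the right/above. Points outside the grid are an error.
#'
#' @param x,y point coordinates in km.
#' @param grid a [grid_spec()].
#' @return integer vector of cell ids.
#' @export
assign_cell_id <- function(x, y, grid) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  fx <- (x - grid$origin_x) / grid$cell_size
  fy <- (y - grid$origin_y) / grid$cell_size
  ix <- floor(fx) + 1L
  iy <- floor(fy) + 1L
  bad <- ix < 1L | ix > grid$nx | iy < 1L | iy > grid$ny
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("point (%g, %g) lies outside the grid", x[i], y[i]), call. = FALSE)
  }
  as.integer((iy - 1L) * grid$nx + ix)
}

#' Link a coarse field to fine-grid cells by nearest centroid
#'
#' Every fine cell receives the value of the coarse pixel whose centroid is
#' nearest (Euclidean) to the cell centroid; exact ties go to the coarse pixel
#' with the smallest index.
#'
#' @param coarse_x,coarse_y coarse-pixel centroid coordinates (km).
#' @param grid fine [grid_spec()].
#' @return integer vector, length `nx*ny`: index into the coarse pixels for
#'   each fine cell (by `cell_id` order). Apply it to a coarse value vector to
#'   get per-cell values.
#' @export
link_nearest_centroid <- function(coarse_x, coarse_y, grid) {
  if (length(coarse_x) == 0L) stop("empty coarse field", call. = FALSE)
  cc <- cell_centroids(grid)
  # small numbers of coarse pixels: exact O(n_cells * n_coarse) search
  d2 <- outer(cc$x, coarse_x, "-")^2 + outer(cc$y, coarse_y, "-")^2
  # ties resolved to the lowest coarse index: max.col on negated distance with
  # ties.method "first" scans columns left to right
  idx <- max.col(-d2, ties.method = "first")
  as.integer(idx)
}

# Coarse-block index for aggregating the fine grid by an integer factor.
# Returns, per fine cell (cell_id order), the id of its containing block on a
# row-major coarse grid of ceiling(nx/f) x ceiling(ny/f) blocks.
block_index <- function(grid, factor) {
  cc <- cell_centroids(grid)
  bx <- (cc$ix - 1L) %/% factor + 1L
  by <- (cc$iy - 1L) %/% factor + 1L
  nbx <- (grid$nx - 1L) %/% factor + 1L
  as.integer((by - 1L) * nbx + bx)
}

# Per-block mean of a cells x days matrix; returns blocks x days matrix.
block_mean <- function(mat, blocks) {
  g <- rowsum(mat, group = blocks, reorder = TRUE)
  n <- as.vector(table(blocks))
  g / n
}

# Centroids (km) of the coarse blocks defined by block_index().
block_centroids <- function(grid, factor) {
  cc <- cell_centroids(grid)
  b <- block_index(grid, factor)
  data.table::data.table(block = b, x = cc$x, y = cc$y)[
    , .(x = mean(x), y = mean(y)), keyby = block]
}
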