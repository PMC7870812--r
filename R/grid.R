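#' Grid specification for planar rasters
#'
#' All rasters in a scenario live on one planar grid. Rasters are stored as
#' plain R matrices (`n_rows` x `n_cols`); a `grid_spec` carries the shared
#' geometry. Coordinates are planar: column index (0-based) runs along `x`,
#' row index (0-based) along `y`, and the centre of cell `(row, col)` is at
#' `(col + 0.5, row + 0.5)`. There is no projection; one cell covers
#' `cell_area` area units (km^2 by convention).
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param cell_area area of one cell (> 0), in km^2 by convention.
#' @param nodata_code integer code used for missing cells in categorical
#'   rasters and in files written to disk. Continuous rasters use `NA`
#'   in memory.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_area = 1, nodata_code = -9999L) {
  if (!is.numeric(n_rows) || length(n_rows) != 1 || n_rows < 1 ||
      !is.numeric(n_cols) || length(n_cols) != 1 || n_cols < 1) {
    stop("n_rows and n_cols must be positive integers")
  }
  if (!is.numeric(cell_area) || length(cell_area) != 1 || cell_area <= 0) {
    stop("cell_area must be a positive number")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_area = as.numeric(cell_area),
         nodata_code = as.integer(nodata_code)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, cell_area = %g, nodata = %d\n",
              x$n_rows, x$n_cols, x$cell_area, x$nodata_code))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

check_grid_matrix <- function(m, grid, what = "raster") {
  if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols) {
    stop(sprintf("%s does not match the grid (%d x %d expected)",
                 what, grid$n_rows, grid$n_cols))
  }
  invisible(m)
}

#' Validate a raster stack
#'
#' A stack is a named list of matrices sharing one [grid_spec()].
#'
#' @param stack named list of matrices.
#' @param grid a [grid_spec()].
#' @return `stack`, invisibly, after validation.
#' @export
check_stack <- function(stack, grid) {
  if (!is.list(stack) || is.null(names(stack)) || any(names(stack) == "")) {
    stop("a raster stack must be a fully named list of matrices")
  }
  for (nm in names(stack)) check_grid_matrix(stack[[nm]], grid, nm)
  invisible(stack)
}

## Cell indexing: internal linear indices are R's native column-major
## 1-based indices into the matrix.  Public coordinates are planar (x, y).

#' Convert planar coordinates to linear cell indices
#'
#' @param x,y planar coordinates (x along columns, y along rows).
#' @param grid a [grid_spec()].
#' @return Integer vector of 1-based linear (column-major) cell indices;
#'   `NA` for points off the grid.
#' @export
cell_from_xy <- function(x, y, grid) {
  col <- floor(x) + 1L
  row <- floor(y) + 1L
  off <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  idx <- row + (col - 1L) * grid$n_rows
  idx[off] <- NA_integer_
  as.integer(idx)
}

#' Cell-centre coordinates of linear cell indices
#'
#' @param cells 1-based linear cell indices.
#' @param grid a [grid_spec()].
#' @return data.frame with columns `x`, `y`.
#' @export
xy_from_cell <- function(cells, grid) {
  row <- (cells - 1L) %% grid$n_rows + 1L
  col <- (cells - 1L) %/% grid$n_rows + 1L
  data.frame(x = col - 0.5, y = row - 0.5)
}

#' Extract stack values at cells as a matrix
#'
#' @param stack named list of matrices.
#' @param cells linear cell indices.
#' @param layers layer names to extract (default all).
#' @return numeric matrix, one column per layer.
#' @export
stack_values <- function(stack, cells, layers = names(stack)) {
  missing_layers <- setdiff(layers, names(stack))
  if (length(missing_layers)) {
    stop("missing layer(s) in stack: ", paste(missing_layers, collapse = ", "))
  }
  out <- vapply(layers, function(nm) stack[[nm]][cells], numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, layers))
  out
}

## Run code under a given RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
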