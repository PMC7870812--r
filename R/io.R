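#' Write a raster to an ESRI ASCII grid file
#'
#' Plain-text raster format readable by standard GIS tools. Categorical
#' rasters should be passed as integer matrices; `NA` cells are written as
#' the grid's nodata code.
#'
#' @param m matrix (numeric or integer).
#' @param grid a [grid_spec()].
#' @param path output file path (conventionally `.asc`).
#' @param digits significant digits for continuous values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, grid, path, digits = 7) {
  check_grid_matrix(m, grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols         %d", grid$n_cols),
    sprintf("nrows         %d", grid$n_rows),
    "xllcorner     0",
    "yllcorner     0",
    "cellsize      1",
    sprintf("NODATA_value  %d", grid$nodata_code)
  ), con)
  vals <- m
  vals[is.na(vals)] <- grid$nodata_code
  # .asc rows run north to south: last matrix row (largest y) first
  for (r in grid$n_rows:1) {
    writeLines(paste(signif(vals[r, ], digits), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path file path.
#' @param integer logical; coerce values to integer (categorical raster).
#' @return list with elements `values` (matrix, nodata as `NA`) and
#'   `grid` (a [grid_spec()]; cell_area defaults to 1).
#' @export
read_ascii_grid <- function(path, integer = FALSE) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  get_num <- function(key) {
    ln <- hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]][2])
  }
  nc <- as.integer(get_num("ncols"))
  nr <- as.integer(get_num("nrows"))
  nodata <- get_num("NODATA_value")
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]              # undo north-to-south row order
  m[m == nodata] <- NA
  if (integer) storage.mode(m) <- "integer"
  list(values = m, grid = grid_spec(nr, nc, nodata_code = as.integer(nodata)))
}

#' Write a raster stack as one ASCII grid per layer
#'
#' @param stack named list of matrices.
#' @param grid a [grid_spec()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_stack <- function(stack, grid, dir, prefix = "") {
  check_stack(stack, grid)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(stack), function(nm) {
    p <- file.path(dir, paste0(prefix, nm, ".asc"))
    write_ascii_grid(stack[[nm]], grid, p)
    p
  }, character(1))
  invisible(paths)
}
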