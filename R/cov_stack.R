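#' Gridded covariate stack
#'
#' A `cov_stack` holds one numeric grid per covariate on a shared regular
#' grid. Grids are plain matrices: rows index northing (row 1 is the
#' southernmost row), columns index easting. Cell centres are at
#' `xmin + (col - 0.5) * cellsize` and `ymin + (row - 0.5) * cellsize`.
#' `NA` cells are treated as nodata throughout (masked, unsampled, offshore).
#'
#' @param layers named list of numeric matrices with identical dimensions,
#'   one per covariate.
#' @param xmin,ymin coordinates of the grid's lower-left corner (same length
#'   unit as `cellsize`, typically metres).
#' @param cellsize cell edge length (> 0).
#' @param scaling optional per-covariate scaling constants (see
#'   [standardize_covariates()]) carried along for prediction.
#' @return an object of class `cov_stack`.
#' @export
cov_stack <- function(layers, xmin = 0, ymin = 0, cellsize = 1,
                      scaling = NULL) {
  if (!is.list(layers) || length(layers) == 0L ||
      is.null(names(layers)) || anyDuplicated(names(layers)) ||
      any(!nzchar(names(layers)))) {
    stop("`layers` must be a non-empty list with unique non-empty names")
  }
  if (!all(vapply(layers, is.matrix, logical(1)))) {
    stop("every layer must be a matrix")
  }
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all layers must share the same dimensions")
  }
  stopifnot(is.numeric(cellsize), length(cellsize) == 1L, cellsize > 0)
  structure(
    list(layers = lapply(layers, function(m) {
      storage.mode(m) <- "double"
      m
    }),
    xmin = as.numeric(xmin), ymin = as.numeric(ymin),
    cellsize = as.numeric(cellsize), scaling = scaling),
    class = "cov_stack"
  )
}

#' @export
print.cov_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("<cov_stack> %d layer(s), %d x %d cells, cellsize %g\n",
              length(x$layers), d[1], d[2], x$cellsize))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname cov_stack
#' @param x a `cov_stack`.
#' @export
stack_names <- function(x) names(x$layers)

#' @rdname cov_stack
#' @export
stack_dim <- function(x) dim(x$layers[[1]])

# centre coordinates of every cell, in row-major (matrix) layout
cell_centres <- function(stack) {
  d <- stack_dim(stack)
  rows <- seq_len(d[1])
  cols <- seq_len(d[2])
  list(x = stack$xmin + (cols - 0.5) * stack$cellsize,
       y = stack$ymin + (rows - 0.5) * stack$cellsize)
}

# map coordinates to (row, col); NA where out of extent
coord_to_cell <- function(stack, x, y) {
  d <- stack_dim(stack)
  col <- floor((x - stack$xmin) / stack$cellsize) + 1L
  row <- floor((y - stack$ymin) / stack$cellsize) + 1L
  # points exactly on the top/right edge belong to the last cell
  col[x == stack$xmin + d[2] * stack$cellsize] <- d[2]
  row[y == stack$ymin + d[1] * stack$cellsize] <- d[1]
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Write / read a covariate stack as plain-text grids
#'
#' Each layer is written as a TSV grid of values (`NA` for nodata) next to a
#' JSON sidecar recording layer names, grid dimensions, origin, cell size and
#' any scaling constants.
#'
#' @param stack a [cov_stack()].
#' @param dir directory to write into (created if needed).
#' @return `write_cov_stack` returns `dir` invisibly; `read_cov_stack`
#'   returns the reconstructed `cov_stack`.
#' @export
write_cov_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    layers = stack_names(stack),
    n_rows = stack_dim(stack)[1], n_cols = stack_dim(stack)[2],
    xmin = stack$xmin, ymin = stack$ymin, cellsize = stack$cellsize,
    scaling = stack$scaling
  )
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in stack_names(stack)) {
    utils::write.table(stack$layers[[nm]],
                       file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cov_stack
#' @export
read_cov_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  layers <- lapply(meta$layers, function(nm) {
    as.matrix(utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                                sep = "\t", header = FALSE))
  })
  layers <- lapply(layers, function(m) {
    dimnames(m) <- NULL
    m
  })
  names(layers) <- meta$layers
  scaling <- meta$scaling
  if (!is.null(scaling)) {
    scaling <- list(mean = unlist(scaling$mean), sd = unlist(scaling$sd))
  }
  cov_stack(layers, xmin = meta$xmin, ymin = meta$ymin,
            cellsize = meta$cellsize, scaling = scaling)
}
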