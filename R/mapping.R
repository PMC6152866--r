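#' Predict an occupancy surface from a fitted model
#'
#' Standardises each covariate cell with the fitting-time scaling constants,
#' evaluates the inverse-logit occupancy linear predictor per cell, and
#' returns the resulting probability grid. Cells with any missing covariate
#' among those the model uses stay missing.
#'
#' @param fitted a `fitted_occu` with stored scaling constants (not needed
#'   for an intercept-only model).
#' @param stack a [cov_stack()] of raw-scale covariates.
#' @param species optional species label recorded on the surface.
#' @return an object of class `occupancy_surface`: list with `psi` (matrix
#'   in `[0,1]` or `NA`), grid georeferencing, `species`/`provenance`
#'   fields.
#' @export
predict_raster <- function(fitted, stack, species = NULL) {
  spec <- fitted$spec
  need <- if (is.null(spec$psi_terms)) character(0)
          else unique(spec$psi_terms$covariate)
  miss <- setdiff(need, stack_names(stack))
  if (length(miss)) {
    stop("raster stack is missing layer(s): ",
         paste(miss, collapse = ", "))
  }
  d <- stack_dim(stack)
  if (length(need) == 0L) {
    psi <- matrix(stats::plogis(fitted$coef[["(Intercept)"]]), d[1], d[2])
  } else {
    if (is.null(fitted$scaling)) {
      stop("fitted model has no scaling constants")
    }
    cells <- as.data.frame(lapply(stack$layers[need], as.numeric))
    cells <- apply_scaling(cells, fitted$scaling, need)
    cp <- coef_parts(fitted)
    ok <- stats::complete.cases(cells)
    psi_vec <- rep(NA_real_, nrow(cells))
    if (any(ok)) {
      X <- build_design(spec$psi_terms, cells[ok, , drop = FALSE])
      psi_vec[ok] <- stats::plogis(drop(X %*% cp$beta))
    }
    psi <- matrix(psi_vec, d[1], d[2])
  }
  structure(list(psi = psi, xmin = stack$xmin, ymin = stack$ymin,
                 cellsize = stack$cellsize, species = species,
                 provenance = list(spec = spec_string(spec),
                                   masks = character(0))),
            class = "occupancy_surface")
}

#' @export
print.occupancy_surface <- function(x, ...) {
  cat(sprintf("<occupancy_surface> %s, %d x %d cells, %d missing\n",
              x$species %||% "(unnamed)", nrow(x$psi), ncol(x$psi),
              sum(is.na(x$psi))))
  invisible(x)
}

#' Environmental-domain mask
#'
#' A cell passes the mask iff every selected covariate value lies within
#' the closed interval `[min, max]` observed at the sampled sites, so
#' predictions are not extrapolated far outside the sampled environmental
#' domain. Optional symmetric quantile trimming tightens the interval.
#'
#' @param stack a [cov_stack()] of raw-scale covariates.
#' @param sampled site covariate table of the fitted sites.
#' @param covariates which covariates define the domain (default: all
#'   covariates shared by stack and table).
#' @param trim symmetric quantile trimmed off each tail of the sampled
#'   values (default 0 = plain min/max).
#' @return an object of class `domain_mask`: list with `mask` (logical
#'   matrix; `NA` covariate cells are `FALSE`) and `bounds` (per-covariate
#'   min/max used).
#' @export
domain_mask <- function(stack, sampled, covariates = NULL, trim = 0) {
  if (nrow(sampled) == 0L) stop("empty site table")
  if (is.null(covariates)) {
    covariates <- intersect(stack_names(stack), cov_columns(sampled))
  }
  miss <- setdiff(covariates, stack_names(stack))
  if (length(miss)) stop("stack missing layer(s): ",
                         paste(miss, collapse = ", "))
  d <- stack_dim(stack)
  mask <- matrix(TRUE, d[1], d[2])
  bounds <- list()
  for (v in covariates) {
    vals <- sampled[[v]]
    lo <- stats::quantile(vals, trim, names = FALSE)
    hi <- stats::quantile(vals, 1 - trim, names = FALSE)
    m <- stack$layers[[v]]
    mask <- mask & !is.na(m) & m >= lo & m <= hi
    bounds[[v]] <- c(min = lo, max = hi)
  }
  structure(list(mask = mask, bounds = bounds), class = "domain_mask")
}

#' Geographic range mask by buffering a region
#'
#' Marks the cells whose centres lie within `buffer_distance` of any cell
#' of the region (distance between cell centres, same length unit as the
#' stack's cellsize). Used both to subset sites before fitting
#' restricted-range species and to clip their predictions.
#'
#' @param region logical matrix on the stack's grid (`TRUE` = inside the
#'   region), or a layer name in `stack` interpreted as `> 0`.
#' @param buffer_distance buffer radius (e.g. 5000 for a 5 km buffer on a
#'   metre grid); 0 returns the region itself.
#' @param stack the [cov_stack()] defining the grid.
#' @return logical matrix on the stack's grid.
#' @export
range_mask <- function(region, buffer_distance, stack) {
  d <- stack_dim(stack)
  if (is.character(region)) {
    region <- !is.na(stack$layers[[region]]) & stack$layers[[region]] > 0
  }
  if (!is.matrix(region) || !all(dim(region) == d)) {
    stop("region grid is not georeferenced consistently with the stack")
  }
  region[is.na(region)] <- FALSE
  if (!any(region)) return(region)
  if (buffer_distance < 0) stop("buffer_distance must be >= 0")
  if (buffer_distance == 0) return(region)
  cc <- cell_centres(stack)
  idx <- which(region, arr.ind = TRUE)
  rx <- cc$x[idx[, 2]]
  ry <- cc$y[idx[, 1]]
  out <- matrix(FALSE, d[1], d[2])
  # distance from every cell centre to the nearest in-region centre,
  # column blocks to bound memory
  for (col0 in seq(1, d[2], by = 64L)) {
    cols <- col0:min(col0 + 63L, d[2])
    gx <- rep(cc$x[cols], each = d[1])
    gy <- rep(cc$y, length(cols))
    dx2 <- outer(gx, rx, `-`)^2
    dy2 <- outer(gy, ry, `-`)^2
    near <- sqrt(apply(dx2 + dy2, 1, min)) <= buffer_distance
    out[, cols] <- matrix(near, d[1], length(cols))
  }
  out
}

#' Apply a mask to an occupancy surface
#'
#' Masking only removes cells (sets them missing); it never restores a
#' previously missing cell.
#'
#' @param surface an `occupancy_surface`.
#' @param mask a `domain_mask` or logical matrix on the same grid.
#' @param label provenance label recorded on the surface.
#' @return the masked `occupancy_surface`.
#' @export
apply_mask <- function(surface, mask, label = "mask") {
  m <- if (inherits(mask, "domain_mask")) mask$mask else mask
  if (!all(dim(m) == dim(surface$psi))) stop("mask grid mismatch")
  surface$psi[!m] <- NA_real_
  surface$provenance$masks <- c(surface$provenance$masks, label)
  surface
}

#' Stack per-species occupancy surfaces into a relative richness map
#'
#' Cellwise sum of predicted occupancy probabilities across species. The
#' result is a relative richness index (summed probability of occupancy),
#' not an expected species count. A cell is missing only where it is
#' missing in every input surface; where some surfaces are missing it is
#' the sum of the available ones, and a per-cell coverage count is
#' returned alongside. Species reduced to constant-occupancy null models
#' should be excluded by the caller.
#'
#' @param surfaces list of `occupancy_surface` on identical grids.
#' @return list with `richness` (matrix), `coverage` (integer matrix of
#'   contributing species per cell) and the grid georeferencing.
#' @export
stack_richness <- function(surfaces) {
  stopifnot(length(surfaces) >= 1L)
  d <- dim(surfaces[[1]]$psi)
  for (s in surfaces) {
    if (!all(dim(s$psi) == d) ||
        s$cellsize != surfaces[[1]]$cellsize ||
        s$xmin != surfaces[[1]]$xmin || s$ymin != surfaces[[1]]$ymin) {
      stop("surfaces are not on identical grids")
    }
  }
  total <- matrix(0, d[1], d[2])
  coverage <- matrix(0L, d[1], d[2])
  for (s in surfaces) {
    ok <- !is.na(s$psi)
    total[ok] <- total[ok] + s$psi[ok]
    coverage <- coverage + ok
  }
  total[coverage == 0L] <- NA_real_
  list(richness = total, coverage = coverage,
       xmin = surfaces[[1]]$xmin, ymin = surfaces[[1]]$ymin,
       cellsize = surfaces[[1]]$cellsize)
}

#' Write a surface or richness grid as a text grid with JSON sidecar
#'
#' @param grid numeric matrix (`NA` = nodata).
#' @param path TSV path; provenance JSON written at `<path>.json`.
#' @param meta list of provenance fields for the sidecar.
#' @export
write_surface <- function(grid, path, meta = list()) {
  if (inherits(grid, "occupancy_surface")) {
    meta <- utils::modifyList(
      list(species = grid$species, provenance = grid$provenance,
           xmin = grid$xmin, ymin = grid$ymin, cellsize = grid$cellsize),
      meta)
    grid <- grid$psi
  }
  utils::write.table(grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
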