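#' Covariates excluded from quadratic occupancy terms by default
#'
#' Neighbourhood fire-homogeneity metrics whose response is treated as
#' monotone; quadratic terms are refused for these.
#' @export
QUADRATIC_BANNED <- c("fire_extent", "fire_patchiness")

cov_columns <- function(table) {
  setdiff(names(table), c("site_id", "x", "y"))
}

#' Screen site covariates for collinearity (Spearman)
#'
#' Computes all pairwise Spearman rank correlations and iteratively discards
#' the lower-priority member of any retained pair with |rho| strictly above
#' the threshold, until no retained pair exceeds it. At each step the
#' offending pair with the largest |rho| is resolved first, so the result is
#' deterministic and invariant to the row order of the site table.
#'
#' @param table site covariate table (columns other than `site_id`, `x`,
#'   `y` are treated as covariates).
#' @param threshold discard threshold on |rho| (strict inequality; default
#'   0.7).
#' @param priority character vector ordering covariates from most to least
#'   preferred; members absent from it rank below all members present.
#'   Defaults to the table's column order.
#' @return list with `kept`, `discarded` (character vectors) and `rho` (the
#'   full Spearman matrix, for reporting).
#' @export
spearman_screen <- function(table, threshold = 0.7, priority = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  covs <- cov_columns(table)
  if (nrow(table) < 3L) stop("need at least 3 sites to screen")
  x <- as.matrix(table[, covs, drop = FALSE])
  const <- covs[apply(x, 2, function(v) stats::sd(v) == 0)]
  if (length(const)) {
    stop("constant covariate(s), Spearman undefined: ",
         paste(const, collapse = ", "))
  }
  rho <- stats::cor(x, method = "spearman")
  if (is.null(priority)) priority <- covs
  rank_of <- function(v) {
    r <- match(v, priority)
    r[is.na(r)] <- length(priority) + match(v[is.na(r)], covs)
    r
  }
  kept <- covs
  discarded <- character(0)
  repeat {
    sub <- abs(rho[kept, kept, drop = FALSE])
    diag(sub) <- 0
    if (all(sub <= threshold)) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- kept[worst]
    drop <- pair[which.max(rank_of(pair))]
    discarded <- c(discarded, drop)
    kept <- setdiff(kept, drop)
  }
  list(kept = kept, discarded = discarded, rho = rho)
}

#' Centre and standardise site covariates
#'
#' Transforms each covariate column to `(x - mean) / sd` (sample sd, n-1
#' denominator) and retains the constants so the identical transformation
#' can be applied at prediction time to new sites or raster cells.
#'
#' @param table site covariate table.
#' @return list with `table` (standardised) and `scaling` (list with named
#'   `mean` and `sd` vectors).
#' @export
standardize_covariates <- function(table) {
  covs <- cov_columns(table)
  mu <- vapply(covs, function(v) mean(table[[v]]), numeric(1))
  sdv <- vapply(covs, function(v) stats::sd(table[[v]]), numeric(1))
  zero <- covs[sdv == 0 | is.na(sdv)]
  if (length(zero)) {
    stop("zero or undefined sd for covariate(s): ",
         paste(zero, collapse = ", "))
  }
  out <- table
  for (v in covs) out[[v]] <- (table[[v]] - mu[[v]]) / sdv[[v]]
  list(table = out, scaling = list(mean = mu, sd = sdv))
}

#' Apply stored scaling constants
#'
#' @param table a site covariate table (or any data frame/list of raw-scale
#'   covariate vectors).
#' @param scaling scaling constants from [standardize_covariates()].
#' @param covariates which columns to transform (default: all covariates
#'   named in `scaling`and present in `table`).
#' @return `table` with the named columns standardised.
#' @export
apply_scaling <- function(table, scaling, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(names(scaling$mean), names(table))
  }
  for (v in covariates) {
    table[[v]] <- (table[[v]] - scaling$mean[[v]]) / scaling$sd[[v]]
  }
  table
}

#' Build an occupancy/detection design matrix with intercept
#'
#' Columns are `[1, x, x^2, ...]` in the stated term order; quadratics are
#' computed on the standardised scale and require their linear term
#' (marginality), and are refused for the covariates in `quadratic_banned`.
#'
#' @param terms `NULL` (intercept-only) or a data frame with columns
#'   `covariate` and `degree` (1 or 2).
#' @param table standardised covariate table.
#' @param quadratic_banned covariates for which degree 2 is refused.
#' @return numeric design matrix, one row per row of `table`.
#' @export
build_design <- function(terms, table,
                         quadratic_banned = QUADRATIC_BANNED) {
  n <- nrow(table)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(terms) || nrow(terms) == 0L) return(X)
  stopifnot(all(c("covariate", "degree") %in% names(terms)),
            all(terms$degree %in% c(1L, 2L)))
  quad <- terms$covariate[terms$degree == 2L]
  bad <- intersect(quad, quadratic_banned)
  if (length(bad)) {
    stop("quadratic terms not allowed for: ", paste(bad, collapse = ", "))
  }
  orphan <- setdiff(quad, terms$covariate[terms$degree == 1L])
  if (length(orphan)) {
    stop("quadratic term without its linear term (marginality): ",
         paste(orphan, collapse = ", "))
  }
  missing_cov <- setdiff(unique(terms$covariate), names(table))
  if (length(missing_cov)) {
    stop("covariate(s) not in table: ",
         paste(missing_cov, collapse = ", "))
  }
  cols <- lapply(seq_len(nrow(terms)), function(i) {
    table[[terms$covariate[i]]]^terms$degree[i]
  })
  names(cols) <- ifelse(terms$degree == 1L, terms$covariate,
                        paste0(terms$covariate, "^2"))
  cbind(X, do.call(cbind, cols))
}

#' Extract covariate values at point locations
#'
#' Returns the value of the containing grid cell for every covariate at
#' every coordinate.
#'
#' @param stack a [cov_stack()].
#' @param coords data frame with columns `x`, `y` (and optionally
#'   `site_id`; generated if absent).
#' @return a site covariate table.
#' @export
extract_at_sites <- function(stack, coords) {
  rc <- coord_to_cell(stack, coords$x, coords$y)
  bad <- which(is.na(rc$row))
  if (length(bad)) {
    stop("coordinate(s) outside raster extent for site(s): ",
         paste(if (!is.null(coords$site_id)) coords$site_id[bad]
               else bad, collapse = ", "))
  }
  idx <- cbind(rc$row, rc$col)
  vals <- lapply(stack$layers, function(m) m[idx])
  ids <- if (!is.null(coords$site_id)) coords$site_id
         else sprintf("site_%04d", seq_len(nrow(coords)))
  cbind(data.frame(site_id = ids, x = coords$x, y = coords$y,
                   stringsAsFactors = FALSE),
        as.data.frame(vals))
}

#' Coarsen a covariate stack by block aggregation
#'
#' Each coarse cell takes the mean of the finite fine cells in its block
#' (a block with no finite cell stays missing). Used to generate
#' lower-resolution prediction layers from fine-resolution input.
#'
#' @param stack a [cov_stack()].
#' @param factor integer coarsening factor (>= 1); trailing partial blocks
#'   aggregate the cells available.
#' @return the coarsened [cov_stack()].
#' @export
reclassify_raster <- function(stack, factor) {
  stopifnot(factor >= 1)
  factor <- as.integer(factor)
  d <- stack_dim(stack)
  if (factor > max(d)) {
    stop(sprintf("factor %d exceeds grid dimensions %d x %d",
                 factor, d[1], d[2]))
  }
  if (factor == 1L) return(stack)
  rgrp <- (seq_len(d[1]) - 1L) %/% factor + 1L
  cgrp <- (seq_len(d[2]) - 1L) %/% factor + 1L
  layers <- lapply(stack$layers, function(m) {
    agg <- tapply(as.numeric(m),
                  list(row = factor(rgrp[row(m)], levels = seq_len(max(rgrp))),
                       col = factor(cgrp[col(m)], levels = seq_len(max(cgrp)))),
                  function(v) if (all(is.na(v))) NA_real_
                              else mean(v, na.rm = TRUE))
    matrix(as.numeric(agg), nrow = max(rgrp), ncol = max(cgrp))
  })
  cov_stack(layers, xmin = stack$xmin, ymin = stack$ymin,
            cellsize = stack$cellsize * factor, scaling = stack$scaling)
}
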