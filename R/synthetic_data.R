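#' Known generating parameters for a simulated species
#'
#' Holds the occupancy and detection coefficients (logit scale) used to
#' simulate survey data, so downstream estimates can be checked against
#' truth. Occupancy is logit-linear (optionally quadratic) in site
#' covariates; detection has one intercept per sampling method plus optional
#' site-covariate slopes shared across methods.
#'
#' @param species_id species label.
#' @param beta_intercept occupancy intercept (logit scale).
#' @param beta_terms `NULL`, or a data frame with columns `covariate`,
#'   `degree` (1 or 2) and `coef`.
#' @param gamma_intercepts named numeric vector: one detection intercept per
#'   sampling method (logit scale, per sub-event).
#' @param gamma_terms `NULL`, or a data frame with columns `covariate` and
#'   `coef` (linear detection effects, site-level).
#' @return an object of class `true_parameters`.
#' @export
true_parameters <- function(species_id, beta_intercept, beta_terms = NULL,
                            gamma_intercepts, gamma_terms = NULL) {
  if (length(gamma_intercepts) < 1L || is.null(names(gamma_intercepts)) ||
      any(!nzchar(names(gamma_intercepts)))) {
    stop("at least one named method intercept is required")
  }
  if (!is.null(beta_terms)) {
    stopifnot(all(c("covariate", "degree", "coef") %in% names(beta_terms)),
              all(beta_terms$degree %in% c(1L, 2L)))
  }
  if (!is.null(gamma_terms)) {
    stopifnot(all(c("covariate", "coef") %in% names(gamma_terms)))
  }
  structure(list(species_id = species_id,
                 beta_intercept = as.numeric(beta_intercept),
                 beta_terms = beta_terms,
                 gamma_intercepts = gamma_intercepts,
                 gamma_terms = gamma_terms),
            class = "true_parameters")
}

#' Multi-method survey design
#'
#' Describes how sites are revisited: which methods are deployed, how many
#' repeat occasions each has, and how many sub-events make up one occasion
#' (e.g. three ten-minute bird surveys within one day; the occasion-level
#' history is the collapse of its sub-events).
#'
#' @param methods character vector of method names.
#' @param occasions_per_method integer vector (recycled or named by method):
#'   repeat occasions per method. Daily methods typically have 3-4
#'   occasions, weekly camera deployments 5.
#' @param sub_events_per_occasion integer vector as above; defaults to 1.
#' @return an object of class `survey_design`.
#' @export
survey_design <- function(methods, occasions_per_method,
                          sub_events_per_occasion = 1L) {
  stopifnot(length(methods) >= 1L, !anyDuplicated(methods))
  occ <- expand_per_method(occasions_per_method, methods,
                           "occasions_per_method")
  sub <- expand_per_method(sub_events_per_occasion, methods,
                           "sub_events_per_occasion")
  if (any(occ < 1L) || any(sub < 1L)) {
    stop("occasions and sub-events must each be >= 1")
  }
  structure(list(methods = methods, occasions_per_method = occ,
                 sub_events_per_occasion = sub),
            class = "survey_design")
}

expand_per_method <- function(x, methods, what) {
  if (!is.null(names(x))) {
    if (!all(methods %in% names(x))) {
      stop(sprintf("%s must name every method", what))
    }
    x <- x[methods]
  } else if (length(x) == 1L) {
    x <- rep(x, length(methods))
    names(x) <- methods
  } else if (length(x) == length(methods)) {
    names(x) <- methods
  } else {
    stop(sprintf("%s must have length 1 or length(methods)", what))
  }
  stats::setNames(as.integer(x), methods)
}

#' Default multi-method monitoring design
#'
#' Six methods emulating a northern-Australian vertebrate monitoring visit:
#' cage, Elliott and pit live-trapping over four nights, three daily bird
#' surveys of three ten-minute counts each, three nocturnal spotlight
#' searches, and motion-sensor cameras over five weekly occasions.
#'
#' @return a [survey_design()].
#' @export
default_design <- function() {
  survey_design(
    methods = c("bird_survey", "cage_trap", "camera", "elliott_trap",
                "pit_trap", "spotlight"),
    occasions_per_method = c(bird_survey = 3L, cage_trap = 4L, camera = 5L,
                             elliott_trap = 4L, pit_trap = 4L,
                             spotlight = 3L),
    sub_events_per_occasion = c(bird_survey = 3L, cage_trap = 1L,
                                camera = 1L, elliott_trap = 1L,
                                pit_trap = 1L, spotlight = 1L)
  )
}

# Gaussian blur of a matrix by separable convolution; edges handled by
# reflection padding so the smoothed field keeps its scale near borders.
smooth_matrix <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  r <- max(1L, ceiling(3 * sd_cells))
  k <- stats::dnorm(seq(-r, r), sd = sd_cells)
  k <- k / sum(k)
  pad_reflect <- function(v, r) {
    n <- length(v)
    left <- v[pmin(n, pmax(1L, (r + 1):2 - 1))]
    right <- v[pmin(n, pmax(1L, (n - 1):(n - r)))]
    c(left, v, right)
  }
  conv1 <- function(v) {
    p <- pad_reflect(v, r)
    out <- stats::filter(p, k, sides = 2)
    as.numeric(out[(r + 1):(r + length(v))])
  }
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

#' Generate a correlated synthetic covariate landscape
#'
#' Draws one grid per covariate from a multivariate Gaussian with the given
#' cross-covariate correlation, then smooths each layer with a shared
#' Gaussian kernel so neighbouring cells are similar (the shared linear
#' smoother preserves the cross-covariate correlation). Each layer is
#' re-standardised to mean 0, sd 1 over cells.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param covariate_names character vector of layer names.
#' @param correlation cross-covariate correlation matrix (symmetric positive
#'   definite, unit diagonal); defaults to the identity.
#' @param seed integer seed; the generator is a pure function of its inputs
#'   and the seed.
#' @param smooth_sd Gaussian kernel sd in cells (default 3).
#' @param cellsize,xmin,ymin grid georeferencing (default 1-unit cells at
#'   the origin).
#' @return a [cov_stack()].
#' @export
gen_landscape <- function(n_rows, n_cols, covariate_names,
                          correlation = NULL, seed, smooth_sd = 3,
                          cellsize = 1, xmin = 0, ymin = 0) {
  k <- length(covariate_names)
  stopifnot(k >= 1L, n_rows >= 1L, n_cols >= 1L)
  if (is.null(correlation)) correlation <- diag(k)
  correlation <- as.matrix(correlation)
  if (nrow(correlation) != k || ncol(correlation) != k ||
      max(abs(correlation - t(correlation))) > 1e-8 ||
      max(abs(diag(correlation) - 1)) > 1e-8) {
    stop("`correlation` must be a symmetric matrix with unit diagonal ",
         "matching the number of covariates")
  }
  ch <- tryCatch(chol(correlation),
                 error = function(e) stop(
                   "`correlation` is not positive definite: ",
                   conditionMessage(e)))
  with_seed(seed, {
    n_cells <- n_rows * n_cols
    white <- matrix(stats::rnorm(n_cells * k), n_cells, k) %*% ch
    layers <- lapply(seq_len(k), function(j) {
      m <- matrix(white[, j], n_rows, n_cols)
      if (n_rows > 1L && n_cols > 1L) m <- smooth_matrix(m, smooth_sd)
      if (n_cells > 1L && stats::sd(m) > 0) m <- (m - mean(m)) / stats::sd(m)
      m
    })
    names(layers) <- covariate_names
    cov_stack(layers, xmin = xmin, ymin = ymin, cellsize = cellsize)
  })
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Place survey sites on a landscape
#'
#' Samples `n_sites` distinct cells (among cells with no missing covariate)
#' and records each site's coordinates (cell centre) and covariate values.
#'
#' @param stack a [cov_stack()].
#' @param n_sites number of sites; must not exceed the number of complete
#'   cells.
#' @param seed integer seed.
#' @return a site covariate table: data frame with `site_id`, `x`, `y` and
#'   one column per covariate.
#' @export
gen_sites <- function(stack, n_sites, seed) {
  vals <- sapply(stack$layers, as.numeric)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L,
                                         dimnames = list(NULL,
                                                         stack_names(stack)))
  ok <- which(stats::complete.cases(vals))
  if (n_sites > length(ok)) {
    stop(sprintf("n_sites (%d) exceeds the %d available complete cells",
                 n_sites, length(ok)))
  }
  with_seed(seed, {
    pick <- if (length(ok) == 1L) ok else sample(ok, n_sites)
    d <- stack_dim(stack)
    row <- ((pick - 1L) %% d[1]) + 1L
    col <- ((pick - 1L) %/% d[1]) + 1L
    cc <- cell_centres(stack)
    out <- data.frame(site_id = sprintf("site_%04d", seq_len(n_sites)),
                      x = cc$x[col], y = cc$y[row],
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(vals[pick, , drop = FALSE]))
  })
}

# evaluate a true_parameters linear predictor over a site table
truth_linpred <- function(sites, intercept, terms, degree_col = TRUE) {
  lp <- rep(intercept, nrow(sites))
  if (!is.null(terms) && nrow(terms) > 0L) {
    missing_cov <- setdiff(unique(terms$covariate), names(sites))
    if (length(missing_cov)) {
      stop("covariate term(s) not found in site table: ",
           paste(missing_cov, collapse = ", "))
    }
    for (i in seq_len(nrow(terms))) {
      v <- sites[[terms$covariate[i]]]
      deg <- if (degree_col) terms$degree[i] else 1L
      lp <- lp + terms$coef[i] * v^deg
    }
  }
  lp
}

#' Simulate raw multi-method survey records
#'
#' Draws the latent occupancy state `z_i ~ Bernoulli(psi_i)` once per site,
#' then for every method, occasion and sub-event draws a detection
#' `~ Bernoulli(z_i * rho_i(method))`, where detection probability applies at
#' the sub-event level and site-level detection covariates are broadcast to
#' all occasions. Emits one raw record per site x method x occasion x
#' sub-event.
#'
#' @param sites site covariate table from [gen_sites()].
#' @param truth a [true_parameters()] whose covariate terms resolve against
#'   `sites` and whose method intercepts cover `design$methods`.
#' @param design a [survey_design()].
#' @param seed integer seed.
#' @return a list with `records` (data frame with columns `site_id`,
#'   `species`, `method`, `occasion_index`, `sub_event_index`, `detected`)
#'   and `z` (the latent occupancy states, for oracle use).
#' @export
simulate_surveys <- function(sites, truth, design, seed) {
  stopifnot(inherits(truth, "true_parameters"),
            inherits(design, "survey_design"))
  missing_m <- setdiff(design$methods, names(truth$gamma_intercepts))
  if (length(missing_m)) {
    stop("no detection intercept for method(s): ",
         paste(missing_m, collapse = ", "))
  }
  psi <- stats::plogis(
    truth_linpred(sites, truth$beta_intercept, truth$beta_terms))
  slope_lp <- truth_linpred(sites, 0, truth$gamma_terms, degree_col = FALSE)
  with_seed(seed, {
    n <- nrow(sites)
    z <- stats::rbinom(n, 1L, psi)
    per_method <- lapply(design$methods, function(m) {
      n_occ <- design$occasions_per_method[[m]]
      n_sub <- design$sub_events_per_occasion[[m]]
      rho <- stats::plogis(truth$gamma_intercepts[[m]] + slope_lp)
      grid <- expand.grid(site = seq_len(n),
                          occasion_index = seq_len(n_occ),
                          sub_event_index = seq_len(n_sub),
                          KEEP.OUT.ATTRS = FALSE)
      det <- stats::rbinom(nrow(grid), 1L, z[grid$site] * rho[grid$site])
      data.frame(site_id = sites$site_id[grid$site],
                 species = truth$species_id,
                 method = m,
                 occasion_index = grid$occasion_index,
                 sub_event_index = grid$sub_event_index,
                 detected = det,
                 stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, per_method)
    rownames(records) <- NULL
    list(records = records,
         z = stats::setNames(z, sites$site_id),
         psi = stats::setNames(psi, sites$site_id))
  })
}
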