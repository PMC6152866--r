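#' Occupancy-detection model specification
#'
#' Describes the covariate structure of a single-season occupancy-detection
#' model: which (standardised) covariates enter the occupancy component
#' (linear or linear+quadratic on the logit scale) and which enter the
#' detection component (linear only), plus whether the sampling method is an
#' observational-level factor in detection. By default detection covariates
#' are restricted to time since fire, fire frequency and terrain ruggedness
#' when candidate lists are enumerated; `model_spec` itself accepts any
#' names so synthetic studies can use their own covariates.
#'
#' @param psi_terms `NULL` (constant occupancy) or data frame with columns
#'   `covariate` and `degree` (1 or 2; quadratics require the linear term).
#' @param p_terms character vector of detection covariates (degree 1 only).
#' @param p_has_method_factor if `TRUE` (default) each sampling method gets
#'   its own detection intercept; otherwise a single shared intercept.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(psi_terms = NULL, p_terms = character(0),
                       p_has_method_factor = TRUE) {
  if (!is.null(psi_terms)) {
    stopifnot(is.data.frame(psi_terms),
              all(c("covariate", "degree") %in% names(psi_terms)))
    psi_terms$degree <- as.integer(psi_terms$degree)
  }
  structure(list(psi_terms = psi_terms, p_terms = as.character(p_terms),
                 p_has_method_factor = isTRUE(p_has_method_factor)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", spec_string(x), "\n")
  invisible(x)
}

#' One-line description of a model specification
#' @param spec a [model_spec()].
#' @return character scalar like `psi(~rugged+rugged^2) p(~method+tsf)`.
#' @export
spec_string <- function(spec) {
  pt <- if (is.null(spec$psi_terms) || nrow(spec$psi_terms) == 0L) "1" else
    paste(ifelse(spec$psi_terms$degree == 1L, spec$psi_terms$covariate,
                 paste0(spec$psi_terms$covariate, "^2")), collapse = "+")
  dt <- c(if (spec$p_has_method_factor) "method", spec$p_terms)
  if (length(dt) == 0L) dt <- "1"
  sprintf("psi(~%s) p(~%s)", pt, paste(dt, collapse = "+"))
}

# count of covariate terms (each linear or quadratic term = 1), excluding
# intercepts and the method factor — the unit of the 1:10 cap
n_covariate_terms <- function(spec) {
  n_psi <- if (is.null(spec$psi_terms)) 0L else nrow(spec$psi_terms)
  n_psi + length(spec$p_terms)
}

# Align design objects: occupancy design matrix X, detection slope matrix W,
# per-occasion method index. Sites with no non-missing occasion are dropped
# with a warning (they carry no information).
occu_matrices <- function(spec, history, covariates,
                          quadratic_banned = QUADRATIC_BANNED) {
  stopifnot(inherits(history, "multimethod_history"))
  idx <- match(history$site_ids, covariates$site_id)
  if (anyNA(idx)) {
    stop("covariate table is missing site(s): ",
         paste(history$site_ids[is.na(idx)], collapse = ", "))
  }
  tab <- covariates[idx, , drop = FALSE]
  y <- history$y
  keep <- rowSums(!is.na(y)) > 0L
  if (!all(keep)) {
    warning(sprintf("%d site(s) with no surveyed occasion excluded",
                    sum(!keep)))
    y <- y[keep, , drop = FALSE]
    tab <- tab[keep, , drop = FALSE]
  }
  X <- build_design(spec$psi_terms, tab, quadratic_banned)
  if (any(!is.finite(X))) stop("non-finite occupancy covariate value")
  if (length(spec$p_terms)) {
    miss <- setdiff(spec$p_terms, names(tab))
    if (length(miss)) {
      stop("detection covariate(s) not in table: ",
           paste(miss, collapse = ", "))
    }
    W <- as.matrix(tab[, spec$p_terms, drop = FALSE])
    if (any(!is.finite(W))) stop("non-finite detection covariate value")
  } else {
    W <- matrix(0, nrow(y), 0)
  }
  if (spec$p_has_method_factor) {
    levels <- unique(history$occasion_method)
    meth_idx <- match(history$occasion_method, levels)
  } else {
    levels <- "all"
    meth_idx <- rep(1L, ncol(y))
  }
  list(y = y, X = X, W = W, meth_idx = meth_idx, methods = levels,
       site_ids = rownames(y))
}

n_params_for <- function(spec, n_methods) {
  n_psi <- 1L + (if (is.null(spec$psi_terms)) 0L else nrow(spec$psi_terms))
  n_psi + n_methods + length(spec$p_terms)
}

# core likelihood: value and analytic gradient on prepared matrices.
# L_i = psi_i * prod_j rho_ij^y (1-rho_ij)^(1-y) + (1-psi_i) * 1[no detection]
nll_core <- function(params, mats, want_grad = TRUE) {
  y <- mats$y
  n <- nrow(y)
  M <- length(mats$methods)
  p_beta <- ncol(mats$X)
  kp <- ncol(mats$W)
  beta <- params[seq_len(p_beta)]
  gint <- params[p_beta + seq_len(M)]
  gsl <- if (kp) params[p_beta + M + seq_len(kp)] else numeric(0)

  psi <- stats::plogis(drop(mats$X %*% beta))
  lp_rho <- matrix(gint[mats$meth_idx], n, ncol(y), byrow = TRUE)
  if (kp) lp_rho <- lp_rho + drop(mats$W %*% gsl)
  rho <- stats::plogis(lp_rho)
  rho <- pmin(pmax(rho, 1e-12), 1 - 1e-12)

  obs <- !is.na(y)
  y0 <- y
  y0[!obs] <- 0L
  ll_terms <- (y0 * log(rho) + (1L - y0) * log1p(-rho)) * obs
  cp <- exp(rowSums(ll_terms))
  nodet <- rowSums(y0) == 0L
  L <- psi * cp + (1 - psi) * nodet
  L <- pmax(L, 1e-300)
  nll <- -sum(log(L))
  if (!want_grad) return(nll)

  A <- psi * (1 - psi) * (cp - nodet) / L
  g_beta <- -drop(crossprod(mats$X, A))
  B <- (psi * cp / L) * ((y0 - rho) * obs)
  g_int <- -vapply(seq_len(M), function(m) {
    sum(B[, mats$meth_idx == m, drop = FALSE])
  }, numeric(1))
  g_sl <- if (kp) -drop(crossprod(mats$W, rowSums(B))) else numeric(0)
  list(value = nll, gradient = c(g_beta, g_int, g_sl))
}

#' Negative log-likelihood of the occupancy-detection model
#'
#' The marginal likelihood of a detection history integrates the latent
#' occupancy state out analytically: a site contributes
#' `psi_i * prod_j rho_ij^y_ij (1-rho_ij)^(1-y_ij)` plus, when no detection
#' was observed, `(1 - psi_i)`. Missing occasions are excluded from the
#' product. `psi` and `rho` come from logit-linear predictors; each
#' occasion's detection intercept is that of its sampling method.
#'
#' @param params coefficient vector: occupancy coefficients (intercept +
#'   one per psi term), then one detection intercept per method, then
#'   detection slopes.
#' @param spec a [model_spec()].
#' @param history a `multimethod_history`.
#' @param covariates standardised site covariate table.
#' @return the negative log-likelihood (numeric scalar).
#' @export
neg_log_likelihood <- function(params, spec, history, covariates) {
  mats <- occu_matrices(spec, history, covariates)
  if (length(params) != n_params_for(spec, length(mats$methods))) {
    stop("params length does not match the model specification")
  }
  nll_core(params, mats, want_grad = FALSE)
}

#' Brute-force likelihood by latent-state enumeration (test oracle)
#'
#' Computes the same negative log-likelihood as [neg_log_likelihood()] by
#' explicitly summing the complete-data likelihood over the latent state
#' `z_i` in `{0, 1}` at every site, with no algebraic shortcut. Intended as
#' an independent oracle in tests; restricted to small problems.
#'
#' @inheritParams neg_log_likelihood
#' @return the negative log-likelihood (numeric scalar).
#' @export
brute_force_likelihood <- function(params, spec, history, covariates) {
  mats <- occu_matrices(spec, history, covariates)
  if (nrow(mats$y) > 20L) stop("oracle restricted to <= 20 sites")
  M <- length(mats$methods)
  p_beta <- ncol(mats$X)
  beta <- params[seq_len(p_beta)]
  gint <- params[p_beta + seq_len(M)]
  gsl <- if (ncol(mats$W)) params[p_beta + M + seq_len(ncol(mats$W))]
         else numeric(0)
  total <- 0
  for (i in seq_len(nrow(mats$y))) {
    psi_i <- stats::plogis(sum(mats$X[i, ] * beta))
    slope_lp <- if (length(gsl)) sum(mats$W[i, ] * gsl) else 0
    L_i <- 0
    for (z in c(0L, 1L)) {
      pz <- if (z == 1L) psi_i else 1 - psi_i
      pobs <- 1
      for (j in seq_len(ncol(mats$y))) {
        yij <- mats$y[i, j]
        if (is.na(yij)) next
        rho_ij <- stats::plogis(gint[mats$meth_idx[j]] + slope_lp)
        pobs <- pobs * stats::dbinom(yij, 1L, z * rho_ij)
      }
      L_i <- L_i + pz * pobs
    }
    total <- total - log(max(L_i, 1e-300))
  }
  total
}

#' Fit an occupancy-detection model by maximum likelihood
#'
#' Maximises the marginal likelihood over the unconstrained logit-scale
#' coefficients with quasi-Newton (BFGS) iterations using the analytic
#' gradient, from `n_starts` jittered initialisations (the best optimum is
#' kept). Standard errors come from the inverse observed information
#' (numerical Hessian at the optimum). The fit is flagged as a boundary fit
#' when every fitted occupancy (or every fitted detection) probability is
#' numerically at 0 or 1, or when the information matrix is singular.
#'
#' @param spec a [model_spec()].
#' @param history a `multimethod_history`.
#' @param covariates standardised site covariate table.
#' @param n_starts number of jittered starts (default 5).
#' @param seed seed for the start jitter.
#' @param scaling optional scaling constants (stored for prediction).
#' @return an object of class `fitted_occu` with elements `spec`, `coef`,
#'   `se`, `vcov`, `logL`, `n_params`, `aic`, `converged`,
#'   `boundary_flag`, `methods`, `site_ids`, `scaling`.
#' @export
fit_occu <- function(spec, history, covariates, n_starts = 5, seed = 1,
                     scaling = NULL) {
  mats <- occu_matrices(spec, history, covariates)
  if (max(rowSums(!is.na(mats$y))) < 2L) {
    warning("no site has 2+ occasions: occupancy and detectability are ",
            "confounded")
  }
  M <- length(mats$methods)
  kp <- ncol(mats$W)
  p_beta <- ncol(mats$X)

  # initial values: naive occupancy for the psi intercept, per-method
  # detection frequency among detected sites for the p intercepts
  det_site <- rowSums(mats$y == 1L, na.rm = TRUE) > 0L
  naive <- min(max(mean(det_site), 0.05), 0.95)
  init <- numeric(n_params_for(spec, M))
  init[1L] <- stats::qlogis(naive)
  for (m in seq_len(M)) {
    cols <- mats$meth_idx == m
    ysub <- mats$y[det_site, cols, drop = FALSE]
    f <- if (length(ysub) && any(!is.na(ysub))) mean(ysub, na.rm = TRUE)
         else 0.25
    init[p_beta + m] <- stats::qlogis(min(max(f, 0.05), 0.95))
  }

  fn <- function(p) nll_core(p, mats, want_grad = FALSE)
  gr <- function(p) nll_core(p, mats)$gradient
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      start <- if (s == 1L) init else
        init + stats::rnorm(length(init), sd = 0.5)
      opt <- tryCatch(
        stats::optim(start, fn, gr, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$value)) next
      if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
    }
  })
  coef_names <- c(colnames(mats$X), paste0("p:", mats$methods),
                  if (kp) paste0("p:", spec$p_terms))
  npar <- length(init)
  if (is.null(best)) {
    return(structure(list(spec = spec,
                          coef = stats::setNames(rep(NA_real_, npar),
                                                 coef_names),
                          se = NULL, vcov = NULL, logL = NA_real_,
                          n_params = npar, aic = NA_real_,
                          converged = FALSE, boundary_flag = TRUE,
                          methods = mats$methods,
                          site_ids = mats$site_ids, scaling = scaling),
                     class = "fitted_occu"))
  }
  par <- stats::setNames(best$par, coef_names)
  logL <- -best$value
  aic <- -2 * logL + 2 * npar

  hess <- tryCatch(stats::optimHess(best$par, fn, gr),
                   error = function(e) NULL)
  vc <- if (!is.null(hess)) tryCatch(solve(hess), error = function(e) NULL)
        else NULL
  se <- NULL
  singular <- is.null(vc) || any(!is.finite(vc)) || any(diag(vc) < 0)
  if (!singular) {
    dimnames(vc) <- list(coef_names, coef_names)
    se <- stats::setNames(sqrt(diag(vc)), coef_names)
  } else {
    vc <- NULL
  }

  psi_hat <- stats::plogis(drop(mats$X %*% best$par[seq_len(p_beta)]))
  lp_rho <- matrix(best$par[p_beta + mats$meth_idx],
                   nrow(mats$y), ncol(mats$y), byrow = TRUE)
  if (kp) lp_rho <- lp_rho +
      drop(mats$W %*% best$par[p_beta + M + seq_len(kp)])
  rho_hat <- stats::plogis(lp_rho)
  tol <- 1e-4
  boundary <- singular ||
    all(pmin(psi_hat, 1 - psi_hat) < tol) ||
    all(pmin(rho_hat, 1 - rho_hat) < tol)

  structure(list(spec = spec, coef = par, se = se, vcov = vc, logL = logL,
                 n_params = npar, aic = aic,
                 converged = best$convergence == 0,
                 boundary_flag = boundary, methods = mats$methods,
                 site_ids = mats$site_ids, scaling = scaling),
            class = "fitted_occu")
}

#' @export
print.fitted_occu <- function(x, ...) {
  cat("<fitted_occu>", spec_string(x$spec), "\n")
  cat(sprintf("  logL = %.4f, K = %d, AIC = %.4f, converged = %s%s\n",
              x$logL, x$n_params, x$aic, x$converged,
              if (x$boundary_flag) ", boundary" else ""))
  print(round(rbind(estimate = x$coef,
                    se = if (is.null(x$se)) rep(NA_real_, length(x$coef))
                         else x$se), 4))
  invisible(x)
}

# split a coefficient vector by model part
coef_parts <- function(fitted) {
  p_beta <- 1L + (if (is.null(fitted$spec$psi_terms)) 0L
                  else nrow(fitted$spec$psi_terms))
  M <- length(fitted$methods)
  kp <- length(fitted$spec$p_terms)
  list(beta = fitted$coef[seq_len(p_beta)],
       gint = fitted$coef[p_beta + seq_len(M)],
       gsl = if (kp) fitted$coef[p_beta + M + seq_len(kp)]
             else numeric(0),
       p_beta = p_beta, M = M, kp = kp)
}

#' Predict occupancy and detection probabilities for new units
#'
#' Applies the fitting-time scaling constants to raw-scale covariates, then
#' evaluates the inverse-logit linear predictors of the fitted model.
#'
#' @param fitted a `fitted_occu` with stored `scaling` (or pass
#'   `raw = FALSE` for already-standardised input).
#' @param covariates data frame of covariate values, raw scale by default.
#' @param raw whether `covariates` are on the raw scale (default `TRUE`).
#' @return list with `psi` (vector) and `rho` (unit x method matrix).
#' @export
predict_probabilities <- function(fitted, covariates, raw = TRUE) {
  spec <- fitted$spec
  need <- unique(c(if (!is.null(spec$psi_terms)) spec$psi_terms$covariate,
                   spec$p_terms))
  miss <- setdiff(need, names(covariates))
  if (length(miss)) {
    stop("covariate(s) missing from input: ", paste(miss, collapse = ", "))
  }
  if (raw && length(need)) {
    if (is.null(fitted$scaling)) {
      stop("fitted model has no scaling constants; pass raw = FALSE for ",
           "standardised input")
    }
    covariates <- apply_scaling(covariates, fitted$scaling, need)
  }
  cp <- coef_parts(fitted)
  X <- build_design(spec$psi_terms, covariates)
  psi <- stats::plogis(drop(X %*% cp$beta))
  slope_lp <- if (cp$kp) {
    drop(as.matrix(covariates[, spec$p_terms, drop = FALSE]) %*% cp$gsl)
  } else 0
  rho <- vapply(seq_len(cp$M), function(m) {
    stats::plogis(cp$gint[m] + slope_lp + 0 * psi)
  }, numeric(length(psi)))
  rho <- matrix(rho, ncol = cp$M,
                dimnames = list(NULL, fitted$methods))
  list(psi = psi, rho = rho)
}

#' Site-averaged occupancy and per-method detectability
#'
#' Averages the fitted site-level occupancy probabilities across fitted
#' sites, and the fitted detection probabilities across each method's
#' surveyed site-occasions, with delta-method standard errors from the
#' coefficient covariance. The spread (sd) of site-level estimates is
#' reported as a secondary column.
#'
#' @param fitted a `fitted_occu`.
#' @param history,covariates the data the model was fitted to
#'   (standardised covariates).
#' @return list with `psi` (data frame: mean, se, sd_sites) and `rho`
#'   (data frame: method, mean, se, sd_sites). `se` is `NA` when the
#'   covariance is unavailable (boundary fit).
#' @export
mean_estimates <- function(fitted, history, covariates) {
  mats <- occu_matrices(fitted$spec, history, covariates)
  cp <- coef_parts(fitted)
  psi <- stats::plogis(drop(mats$X %*% cp$beta))
  n <- length(psi)
  npar <- length(fitted$coef)

  g_psi <- numeric(npar)
  g_psi[seq_len(cp$p_beta)] <- colMeans(psi * (1 - psi) * mats$X)
  se_psi <- delta_se(g_psi, fitted$vcov)
  psi_out <- data.frame(mean = mean(psi), se = se_psi,
                        sd_sites = stats::sd(psi))

  slope_lp <- if (cp$kp) drop(mats$W %*% cp$gsl) else rep(0, n)
  rho_out <- do.call(rbind, lapply(seq_len(cp$M), function(m) {
    cols <- which(mats$meth_idx == m)
    obs <- !is.na(mats$y[, cols, drop = FALSE])
    nobs_site <- rowSums(obs)
    w <- nobs_site / sum(nobs_site)          # site weight = surveyed occasions
    rho_site <- stats::plogis(cp$gint[m] + slope_lp)
    g <- numeric(npar)
    g[cp$p_beta + m] <- sum(w * rho_site * (1 - rho_site))
    if (cp$kp) {
      g[cp$p_beta + cp$M + seq_len(cp$kp)] <-
        drop(crossprod(mats$W, w * rho_site * (1 - rho_site)))
    }
    data.frame(method = fitted$methods[m],
               mean = sum(w * rho_site),
               se = delta_se(g, fitted$vcov),
               sd_sites = stats::sd(rho_site[nobs_site > 0]))
  }))
  list(psi = psi_out, rho = rho_out)
}

delta_se <- function(g, vcov) {
  if (is.null(vcov)) return(NA_real_)
  v <- drop(t(g) %*% vcov %*% g)
  if (!is.finite(v) || v < 0) NA_real_ else sqrt(v)
}

#' Expected detections per surveyed site-occasion
#'
#' `yhat_ij = psi_i * rho_ij` for non-missing occasions; missing stays
#' missing. Input to the goodness-of-fit statistics.
#'
#' @inheritParams mean_estimates
#' @return site x occasion matrix matching `history$y`.
#' @export
fitted_values <- function(fitted, history, covariates) {
  mats <- occu_matrices(fitted$spec, history, covariates)
  cp <- coef_parts(fitted)
  psi <- stats::plogis(drop(mats$X %*% cp$beta))
  lp_rho <- matrix(cp$gint[mats$meth_idx], nrow(mats$y), ncol(mats$y),
                   byrow = TRUE)
  if (cp$kp) lp_rho <- lp_rho + drop(mats$W %*% cp$gsl)
  yhat <- psi * stats::plogis(lp_rho)
  yhat[is.na(mats$y)] <- NA_real_
  dimnames(yhat) <- dimnames(mats$y)
  yhat
}

#' Simulate a detection history from a fitted model
#'
#' Draws latent states and detections from the fitted probabilities on the
#' same design and missingness pattern; used by the parametric bootstrap.
#'
#' @inheritParams mean_estimates
#' @param seed integer seed.
#' @return a `multimethod_history` with the same shape as the input.
#' @export
simulate_history <- function(fitted, history, covariates, seed) {
  mats <- occu_matrices(fitted$spec, history, covariates)
  cp <- coef_parts(fitted)
  psi <- stats::plogis(drop(mats$X %*% cp$beta))
  lp_rho <- matrix(cp$gint[mats$meth_idx], nrow(mats$y), ncol(mats$y),
                   byrow = TRUE)
  if (cp$kp) lp_rho <- lp_rho + drop(mats$W %*% cp$gsl)
  rho <- stats::plogis(lp_rho)
  with_seed(seed, {
    z <- stats::rbinom(length(psi), 1L, psi)
    ysim <- matrix(stats::rbinom(length(rho), 1L, z * rho),
                   nrow(mats$y), ncol(mats$y))
    ysim[is.na(mats$y)] <- NA_integer_
    dimnames(ysim) <- dimnames(mats$y)
    structure(list(y = ysim,
                   occasion_method = history$occasion_method,
                   site_ids = rownames(mats$y)),
              class = "multimethod_history")
  })
}

#' Serialise / restore a fitted model as JSON
#'
#' Stores the specification, coefficients, covariance, log-likelihood, AIC,
#' flags and scaling constants so mapping can run without refitting.
#'
#' @param fitted a `fitted_occu`.
#' @param path JSON file path.
#' @export
write_fitted <- function(fitted, path) {
  obj <- list(
    spec = list(psi_terms = fitted$spec$psi_terms,
                p_terms = fitted$spec$p_terms,
                p_has_method_factor = fitted$spec$p_has_method_factor),
    coef = as.list(fitted$coef),
    se = if (is.null(fitted$se)) NULL else as.list(fitted$se),
    vcov = fitted$vcov, logL = fitted$logL, n_params = fitted$n_params,
    aic = fitted$aic, converged = fitted$converged,
    boundary_flag = fitted$boundary_flag, methods = fitted$methods,
    site_ids = fitted$site_ids,
    scaling = if (is.null(fitted$scaling)) NULL else
      list(mean = as.list(fitted$scaling$mean),
           sd = as.list(fitted$scaling$sd)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_fitted
#' @export
read_fitted <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  psi_terms <- o$spec$psi_terms
  if (!is.null(psi_terms) && length(psi_terms)) {
    psi_terms <- as.data.frame(psi_terms)
    psi_terms$degree <- as.integer(psi_terms$degree)
  } else psi_terms <- NULL
  spec <- model_spec(psi_terms,
                     p_terms = o$spec$p_terms %||% character(0),
                     p_has_method_factor = o$spec$p_has_method_factor)
  coef <- unlist(o$coef)
  vc <- o$vcov
  if (!is.null(vc)) {
    vc <- matrix(as.numeric(vc), length(coef), length(coef), byrow = TRUE)
    dimnames(vc) <- list(names(coef), names(coef))
  }
  scaling <- if (is.null(o$scaling)) NULL else
    list(mean = unlist(o$scaling$mean), sd = unlist(o$scaling$sd))
  structure(list(spec = spec, coef = coef,
                 se = if (is.null(o$se)) NULL else unlist(o$se),
                 vcov = vc, logL = o$logL, n_params = o$n_params,
                 aic = o$aic, converged = o$converged,
                 boundary_flag = o$boundary_flag, methods = o$methods,
                 site_ids = o$site_ids, scaling = scaling),
            class = "fitted_occu")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
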