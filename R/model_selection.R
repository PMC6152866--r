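#' Covariate cap from the number of detection sites
#'
#' To limit over-fitting, each candidate model may carry at most one
#' covariate term per `ratio` sites at which the species was detected
#' (default 1:10): `floor(n_detection_sites / ratio)`. Species below the
#' ratio get the cap 0, i.e. the constant-occupancy (null) model only.
#'
#' @param n_detection_sites count of sites with at least one detection.
#' @param ratio detections required per covariate term (default 10).
#' @return integer cap on the number of covariate terms.
#' @export
max_terms_for <- function(n_detection_sites, ratio = 10) {
  stopifnot(n_detection_sites >= 0, ratio >= 1)
  as.integer(floor(n_detection_sites / ratio))
}

#' Enumerate all candidate model specifications
#'
#' All-subsets enumeration of the occupancy candidates (each covariate
#' absent, linear, or linear+quadratic where allowed) crossed with all
#' subsets of the detection candidates, keeping specifications whose total
#' covariate-term count (linear and quadratic terms each count 1, over both
#' model parts; intercepts and the method factor do not count) is at most
#' `max_terms`. The null specification is always included.
#'
#' @param psi_candidates character vector of occupancy covariates.
#' @param p_candidates character vector of detection covariates (may be
#'   empty).
#' @param max_terms cap from [max_terms_for()] (default `Inf`).
#' @param quadratic_allowed named logical vector (default: allowed for all
#'   psi candidates except [QUADRATIC_BANNED]).
#' @param p_has_method_factor passed through to every [model_spec()].
#' @return list of `model_spec`, in deterministic enumeration order with
#'   the null model first.
#' @export
enumerate_models <- function(psi_candidates, p_candidates = character(0),
                             max_terms = Inf, quadratic_allowed = NULL,
                             p_has_method_factor = TRUE) {
  if (is.null(quadratic_allowed)) {
    quadratic_allowed <- !(psi_candidates %in% QUADRATIC_BANNED)
    names(quadratic_allowed) <- psi_candidates
  }
  k <- length(psi_candidates)
  # per-covariate state: 0 absent, 1 linear, 2 linear+quadratic
  states <- lapply(psi_candidates, function(v) {
    if (isTRUE(quadratic_allowed[[v]])) 0:2 else 0:1
  })
  psi_grid <- if (k) expand.grid(rev(states), KEEP.OUT.ATTRS = FALSE)[
    , k:1, drop = FALSE] else data.frame(row.names = 1)
  p_sets <- if (length(p_candidates)) {
    pg <- expand.grid(rep(list(0:1), length(p_candidates)),
                      KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(pg)), function(i) {
      p_candidates[pg[i, ] == 1]
    })
  } else list(character(0))

  specs <- list()
  for (i in seq_len(max(nrow(psi_grid), 1L))) {
    st <- if (k) as.integer(psi_grid[i, ]) else integer(0)
    psi_terms <- NULL
    if (any(st > 0L)) {
      rows <- lapply(which(st > 0L), function(j) {
        d <- if (st[j] == 2L) c(1L, 2L) else 1L
        data.frame(covariate = psi_candidates[j], degree = d)
      })
      psi_terms <- do.call(rbind, rows)
    }
    n_psi <- sum(st)
    for (ps in p_sets) {
      if (n_psi + length(ps) > max_terms) next
      specs[[length(specs) + 1L]] <-
        model_spec(psi_terms, p_terms = ps,
                   p_has_method_factor = p_has_method_factor)
    }
  }
  specs
}

#' Fit every candidate specification
#'
#' @param specs list of [model_spec()] from [enumerate_models()].
#' @inheritParams fit_occu
#' @return list of `fitted_occu`, one per spec (same order).
#' @export
fit_candidates <- function(specs, history, covariates, n_starts = 3,
                           seed = 1, scaling = NULL) {
  lapply(seq_along(specs), function(i) {
    fit_occu(specs[[i]], history, covariates, n_starts = n_starts,
             seed = seed + i, scaling = scaling)
  })
}

#' Rank fitted candidates by AIC
#'
#' Non-converged fits are excluded; the rest are sorted by AIC (ties broken
#' by fewer parameters, then enumeration order) and annotated with the AIC
#' difference to the best model. The retained confidence set is the models
#' with `delta_aic < cutoff` (strict; default 6).
#'
#' @param fits list of `fitted_occu` (enumeration order).
#' @param cutoff AIC-difference retention cutoff (default 6).
#' @return list with `records` (data frame: model_id, spec, logL, n_params,
#'   aic, delta_aic, boundary_flag, retained) and `fits` (the converged
#'   fits, in ranked order).
#' @export
rank_by_aic <- function(fits, cutoff = 6) {
  conv <- vapply(fits, function(f) isTRUE(f$converged) &&
                   is.finite(f$aic), logical(1))
  if (!any(conv)) {
    stop("no candidate model converged; fall back to the null model")
  }
  idx <- which(conv)
  aics <- vapply(fits[idx], `[[`, numeric(1), "aic")
  npars <- vapply(fits[idx], `[[`, integer(1), "n_params")
  ord <- order(aics, npars, idx)
  idx <- idx[ord]
  aics <- aics[ord]
  records <- data.frame(
    model_id = idx,
    spec = vapply(fits[idx], function(f) spec_string(f$spec),
                  character(1)),
    logL = vapply(fits[idx], `[[`, numeric(1), "logL"),
    n_params = npars[ord],
    aic = aics,
    delta_aic = aics - aics[1],
    boundary_flag = vapply(fits[idx], `[[`, logical(1), "boundary_flag"),
    stringsAsFactors = FALSE)
  records$retained <- records$delta_aic < cutoff
  list(records = records, fits = fits[idx])
}

#' Select the best acceptable model
#'
#' Walks the retained (`delta_aic < cutoff`) set in rank order and returns
#' the first model that is not boundary-flagged, passes every
#' goodness-of-fit statistic (when a GoF function is supplied) and is
#' accepted by every user screen (e.g. an expert map-realism predicate).
#' If the whole set is rejected, the constant-occupancy null model (with
#' the method factor) is fitted and returned as the fallback.
#'
#' @param ranked result of [rank_by_aic()].
#' @param history,covariates the fitting data (used for the null fallback
#'   and GoF).
#' @param gof_fun `NULL`, or `function(fit)` returning a `gof_result`; a
#'   candidate fails if any GoF p-value is `<= alpha`.
#' @param alpha GoF significance level (default 0.05).
#' @param screens list of `function(fit)` returning `TRUE` to accept.
#' @param scaling,seed passed to the null fallback fit.
#' @return list with `fit` (the selected `fitted_occu`), `is_null`
#'   (`TRUE` when the fallback was used), `gof` (the selected model's
#'   `gof_result`, if computed) and `rejected` (data frame of rejected
#'   candidates with reasons).
#' @export
select_best <- function(ranked, history, covariates, gof_fun = NULL,
                        alpha = 0.05, screens = list(), scaling = NULL,
                        seed = 1) {
  rejected <- data.frame(spec = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  keep <- which(ranked$records$retained)
  for (i in keep) {
    fit <- ranked$fits[[i]]
    if (fit$boundary_flag) {
      rejected <- rbind(rejected,
                        data.frame(spec = ranked$records$spec[i],
                                   reason = "boundary estimates"))
      next
    }
    gof <- NULL
    if (!is.null(gof_fun)) {
      gof <- gof_fun(fit)
      if (any(gof$p_value <= alpha)) {
        rejected <- rbind(rejected,
                          data.frame(spec = ranked$records$spec[i],
                                     reason = "failed goodness-of-fit"))
        next
      }
    }
    vetoed <- FALSE
    for (s in screens) {
      if (!isTRUE(s(fit))) {
        rejected <- rbind(rejected,
                          data.frame(spec = ranked$records$spec[i],
                                     reason = "rejected by screen"))
        vetoed <- TRUE
        break
      }
    }
    if (vetoed) next
    return(list(fit = fit, is_null = FALSE, gof = gof,
                rejected = rejected))
  }
  null_fit <- fit_occu(model_spec(), history, covariates, seed = seed,
                       scaling = scaling)
  if (!null_fit$converged) {
    stop("null model failed to converge; species cannot be modelled")
  }
  list(fit = null_fit, is_null = TRUE, gof = NULL, rejected = rejected)
}

#' Write a ranked model table as CSV
#'
#' @param records the `records` data frame from [rank_by_aic()].
#' @param species species label column to prepend.
#' @param path CSV path.
#' @export
write_model_table <- function(records, species, path) {
  utils::write.csv(cbind(species = species, records), path,
                   row.names = FALSE)
  invisible(path)
}
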