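#' Observation-level goodness-of-fit statistics
#'
#' Three discrepancy statistics between an observed 0/1 detection matrix
#' and its fitted expected values, summed over non-missing cells:
#' sum of squared errors `sum((y - yhat)^2)`, the Freeman-Tukey statistic
#' `sum((sqrt(y) - sqrt(yhat))^2)`, and Pearson's chi-squared with a
#' binomial-variance denominator `sum((y - yhat)^2 / (yhat (1 - yhat)))`
#' where `yhat` is clipped to `[1e-6, 1 - 1e-6]` in the denominator.
#'
#' @param y observed site x occasion 0/1/`NA` matrix.
#' @param y_hat fitted expected detections, same shape (`NA` pattern
#'   matching `y`).
#' @return named list: `sse`, `freeman_tukey`, `pearson`.
#' @export
gof_statistics <- function(y, y_hat) {
  if (!all(dim(y) == dim(y_hat))) {
    stop("observed and fitted matrices have different shapes")
  }
  obs <- !is.na(y) & !is.na(y_hat)
  yv <- as.numeric(y[obs])
  fv <- as.numeric(y_hat[obs])
  fden <- pmin(pmax(fv, 1e-6), 1 - 1e-6)
  list(sse = sum((yv - fv)^2),
       freeman_tukey = sum((sqrt(yv) - sqrt(fv))^2),
       pearson = sum((yv - fv)^2 / (fden * (1 - fden))))
}

#' Parametric-bootstrap goodness-of-fit test
#'
#' Simulates `B` detection histories from the fitted model on the observed
#' design and missingness pattern, refits the same specification to each
#' (warm-started from the fitted coefficients), and compares each
#' replicate's statistics (simulated data vs its own refit) with the
#' observed statistics. All three p-values come from the same replicate
#' stream and use the plug-in convention
#' `p = (1 + #\{t_sim >= t_obs\}) / (B + 1)`, which cannot reach 0 at
#' finite `B`. A replicate whose refit fails to converge is redrawn; if
#' more than 10% of replicates needed redrawing the result is flagged
#' unstable.
#'
#' @param fitted a converged `fitted_occu`.
#' @param history,covariates the fitting data (standardised covariates).
#' @param B number of bootstrap simulations (default 1000).
#' @param seed integer seed; identical seeds reproduce identical
#'   `t_sim` streams.
#' @return an object of class `gof_result`: list with `t_obs`, `t_sim`
#'   (B x 3 matrix), `p_value` (named vector), `B`, `seed`, `n_redraws`,
#'   `unstable`.
#' @export
parametric_bootstrap <- function(fitted, history, covariates, B = 1000,
                                 seed = 1) {
  if (!isTRUE(fitted$converged)) {
    stop("goodness-of-fit requires a converged fit")
  }
  mats <- occu_matrices(fitted$spec, history, covariates)
  yhat_obs <- fitted_values(fitted, history, covariates)
  t_obs <- unlist(gof_statistics(mats$y, yhat_obs))

  fn_for <- function(mats_b) function(p) nll_core(p, mats_b,
                                                  want_grad = FALSE)
  gr_for <- function(mats_b) function(p) nll_core(p, mats_b)$gradient

  t_sim <- matrix(NA_real_, B, 3,
                  dimnames = list(NULL, names(t_obs)))
  n_redraws <- 0L
  b <- 1L
  draw <- 0L
  while (b <= B) {
    draw <- draw + 1L
    if (draw > 20L * B) stop("bootstrap refits failing persistently")
    seed_b <- as.integer((as.numeric(seed) * 1000003 + draw) %% 2147483629)
    hist_b <- simulate_history(fitted, history, covariates, seed = seed_b)
    mats_b <- occu_matrices(fitted$spec, hist_b, covariates)
    opt <- tryCatch(
      stats::optim(unname(fitted$coef), fn_for(mats_b), gr_for(mats_b),
                   method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$convergence != 0) {
      n_redraws <- n_redraws + 1L
      next
    }
    refit <- fitted
    refit$coef[] <- opt$par
    yhat_b <- fitted_values(refit, hist_b, covariates)
    t_sim[b, ] <- unlist(gof_statistics(mats_b$y, yhat_b))
    b <- b + 1L
  }
  p <- (1 + colSums(t_sim >= rep(t_obs, each = B))) / (B + 1)
  structure(list(t_obs = t_obs, t_sim = t_sim, p_value = p, B = B,
                 seed = seed, n_redraws = n_redraws,
                 unstable = n_redraws > 0.1 * B),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof_result> B = %d%s\n", x$B,
              if (x$unstable) " (unstable: many refit redraws)" else ""))
  print(data.frame(statistic = names(x$t_obs), t_obs = x$t_obs,
                   p_value = x$p_value, row.names = NULL))
  invisible(x)
}

#' Serialise a goodness-of-fit result as JSON
#'
#' @param gof a `gof_result`.
#' @param path JSON path.
#' @export
write_gof <- function(gof, path) {
  jsonlite::write_json(
    list(t_obs = as.list(gof$t_obs), p_value = as.list(gof$p_value),
         B = gof$B, seed = gof$seed, n_redraws = gof$n_redraws,
         unstable = gof$unstable),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
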