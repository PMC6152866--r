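# small in-code fixtures shared across test files

# wrap a plain 0/1/NA matrix as a multimethod_history
make_history <- function(y, methods = rep("m1", ncol(y)),
                         site_ids = NULL) {
  if (is.null(site_ids)) site_ids <- sprintf("s%02d", seq_len(nrow(y)))
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  rownames(y) <- site_ids
  colnames(y) <- paste0(methods, ":occ", seq_len(ncol(y)))
  structure(list(y = y, occasion_method = methods, site_ids = site_ids),
            class = "multimethod_history")
}

# covariate table with no real covariates (constant models)
empty_sites <- function(n) {
  data.frame(site_id = sprintf("s%02d", seq_len(n)),
             x = seq_len(n), y = rep(0, n))
}

# site table with named standardised-scale covariates
sites_with <- function(...) {
  covs <- list(...)
  n <- length(covs[[1]])
  cbind(empty_sites(n), as.data.frame(covs))
}

# raw survey records data frame from vectors
make_records <- function(site_id, species, method, occasion, sub_event,
                         detected) {
  data.frame(site_id = site_id, species = species, method = method,
             occasion_index = occasion, sub_event_index = sub_event,
             detected = as.integer(detected), stringsAsFactors = FALSE)
}

# simulate one species on a fresh landscape; returns everything needed to fit
sim_dataset <- function(n_sites, truth, design, seed,
                        covariate_names = c("rugged", "tsf"),
                        grid = 40) {
  st <- gen_landscape(grid, grid, covariate_names, seed = seed)
  sites <- gen_sites(st, n_sites, seed = seed + 1)
  sim <- simulate_surveys(sites, truth, design, seed = seed + 2)
  hist <- build_history(sim$records, truth$species_id)
  std <- standardize_covariates(sites)
  list(stack = st, sites = sites, sim = sim, history = hist,
       std = std$table, scaling = std$scaling)
}

# true occupancy linear predictor evaluated over a stack's cells
truth_lp_on_stack <- function(truth, stack) {
  lp <- matrix(truth$beta_intercept, nrow(stack$layers[[1]]),
               ncol(stack$layers[[1]]))
  if (!is.null(truth$beta_terms)) {
    for (i in seq_len(nrow(truth$beta_terms))) {
      lp <- lp + truth$beta_terms$coef[i] *
        stack$layers[[truth$beta_terms$covariate[i]]] ^
          truth$beta_terms$degree[i]
    }
  }
  lp
}

# fitted_occu shell with chosen aic/flags, for ranking/selection tests
fake_fit <- function(aic, n_params = 2L, converged = TRUE,
                     boundary = FALSE, spec = model_spec()) {
  structure(list(spec = spec, coef = c(0, 0), se = NULL, vcov = NULL,
                 logL = -(aic - 2 * n_params) / 2, n_params = n_params,
                 aic = aic, converged = converged,
                 boundary_flag = boundary, methods = "m1",
                 site_ids = character(0), scaling = NULL),
            class = "fitted_occu")
}
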