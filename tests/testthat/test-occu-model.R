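# constant-model helper: parameters on the probability scale
const_params <- function(psi, rho) c(qlogis(psi), qlogis(rho))

test_that("the marginal likelihood matches hand-enumerated cases", {
  sites <- empty_sites(1)
  # history [1,0], psi = 0.6, rho = 0.5: L = 0.6 * 0.5 * 0.5 = 0.15
  h <- make_history(matrix(c(1L, 0L), 1))
  spec <- model_spec()
  expect_equal(neg_log_likelihood(const_params(0.6, 0.5), spec, h, sites),
               -log(0.15), tolerance = 1e-12)
  # history [0,0,0]: L = 0.6 * 0.125 + 0.4 = 0.475
  h0 <- make_history(matrix(0L, 1, 3))
  expect_equal(neg_log_likelihood(const_params(0.6, 0.5), spec, h0, sites),
               -log(0.475), tolerance = 1e-12)
  # psi -> 1, history [1,1,1,1], rho = 0.5: L = 0.0625
  h1 <- make_history(matrix(1L, 1, 4))
  expect_equal(neg_log_likelihood(c(50, qlogis(0.5)), spec, h1, sites),
               -log(0.0625), tolerance = 1e-9)
  # the enumeration oracle agrees on all three
  for (case in list(list(h, const_params(0.6, 0.5)),
                    list(h0, const_params(0.6, 0.5)),
                    list(h1, c(50, qlogis(0.5))))) {
    expect_equal(neg_log_likelihood(case[[2]], spec, case[[1]], sites),
                 brute_force_likelihood(case[[2]], spec, case[[1]], sites),
                 tolerance = 1e-12)
  }
})

test_that("missing occasions drop out of the likelihood", {
  sites <- empty_sites(2)
  h <- make_history(rbind(c(1L, NA, 0L), c(NA, NA, 0L)))
  p <- const_params(0.4, 0.3)
  # site 1: psi * rho * (1-rho); site 2: psi*(1-rho) + (1-psi)
  L1 <- 0.4 * 0.3 * 0.7
  L2 <- 0.4 * 0.7 + 0.6
  expect_equal(neg_log_likelihood(p, model_spec(), h, sites),
               -(log(L1) + log(L2)), tolerance = 1e-12)
  # a site with zero surveyed occasions is excluded with a warning
  h2 <- make_history(rbind(c(1L, 0L), c(NA, NA)))
  expect_warning(v <- neg_log_likelihood(p, model_spec(), h2, sites),
                 "no surveyed occasion")
  expect_equal(v, -log(0.4 * 0.3 * 0.7), tolerance = 1e-12)
})

test_that("analytic gradient matches central differences", {
  set.seed(201)
  tab <- sites_with(a = rnorm(8), b = rnorm(8))
  y <- matrix(rbinom(8 * 5, 1, 0.4), 8, 5)
  y[sample(length(y), 6)] <- NA
  h <- make_history(y, methods = c("m1", "m1", "m1", "m2", "m2"))
  spec <- model_spec(data.frame(covariate = "a", degree = 1L),
                     p_terms = "b")
  mats <- occumap:::occu_matrices(spec, h, tab)
  p <- c(0.3, -0.7, 0.2, 0.9, -0.4)
  g <- unname(occumap:::nll_core(p, mats)$gradient)
  eps <- 1e-6
  gn <- vapply(seq_along(p), function(i) {
    up <- p; up[i] <- up[i] + eps
    dn <- p; dn[i] <- dn[i] - eps
    (occumap:::nll_core(up, mats, FALSE) -
       occumap:::nll_core(dn, mats, FALSE)) / (2 * eps)
  }, numeric(1))
  expect_equal(g, gn, tolerance = 1e-6)
})

test_that("likelihood is invariant to site and within-method occasion permutation", {
  set.seed(202)
  tab <- sites_with(a = rnorm(10))
  y <- matrix(rbinom(60, 1, 0.3), 10, 6)
  meths <- c("m1", "m1", "m1", "m2", "m2", "m2")
  h <- make_history(y, meths)
  spec <- model_spec(data.frame(covariate = "a", degree = 1L))
  p <- c(0.2, 0.5, -0.3, 0.1)
  base <- neg_log_likelihood(p, spec, h, tab)

  perm <- sample(10)
  h_sites <- make_history(y[perm, ], meths,
                          site_ids = h$site_ids[perm])
  tab_perm <- tab
  expect_equal(neg_log_likelihood(p, spec, h_sites, tab_perm), base,
               tolerance = 1e-12)

  occ_perm <- c(3, 1, 2, 6, 4, 5)  # permutes occasions within each method
  h_occ <- make_history(y[, occ_perm], meths)
  expect_equal(neg_log_likelihood(p, spec, h_occ, tab), base,
               tolerance = 1e-12)
})

test_that("constant-model MLE recovers generating probabilities at large n", {
  truth <- true_parameters("sp", beta_intercept = qlogis(0.4),
                           gamma_intercepts = c(m1 = qlogis(0.3)))
  st <- gen_landscape(60, 60, "a", seed = 211)
  sites <- gen_sites(st, 2000, seed = 212)
  sim <- simulate_surveys(sites, truth, survey_design("m1", 5L),
                          seed = 213)
  h <- build_history(sim$records, "sp")
  f <- fit_occu(model_spec(), h, sites, seed = 1)
  expect_true(f$converged)
  expect_lt(abs(plogis(f$coef[[1]]) - 0.4), 0.05)
  expect_lt(abs(plogis(f$coef[[2]]) - 0.3), 0.05)
  # AIC identity
  expect_equal(f$aic, -2 * f$logL + 2 * f$n_params)
})

test_that("saturated histories trip the boundary flag", {
  h <- make_history(matrix(1L, 6, 4))
  f <- fit_occu(model_spec(), h, empty_sites(6), seed = 1)
  expect_true(f$boundary_flag)
})

test_that("single-occasion designs leave psi and rho confounded", {
  # profile likelihood is flat along psi * rho = const
  h <- make_history(matrix(c(1L, 0L, 1L, 0L, 0L), 5, 1))
  sites <- empty_sites(5)
  spec <- model_spec()
  prod_target <- 0.35
  nlls <- vapply(c(0.4, 0.6, 0.8), function(psi) {
    neg_log_likelihood(const_params(psi, prod_target / psi), spec, h,
                       sites)
  }, numeric(1))
  expect_lt(diff(range(nlls)), 1e-10)
  expect_warning(fit_occu(spec, h, sites, n_starts = 1, seed = 1),
                 "confounded")
})

test_that("probability predictions follow the inverse logit", {
  h <- make_history(matrix(c(1L, 0L), 2, 2))
  tab <- sites_with(rugged = c(-1, 1))
  f <- fit_occu(model_spec(data.frame(covariate = "rugged",
                                      degree = 1L)), h, tab, seed = 1)
  # overwrite coefficients with known values and predict
  f$coef[] <- c(0, 1, 0)
  pr <- predict_probabilities(f, data.frame(rugged = c(0, 2)),
                              raw = FALSE)
  expect_equal(pr$psi, plogis(c(0, 2)))
  expect_equal(unname(pr$rho[, 1]), c(0.5, 0.5))
  expect_error(predict_probabilities(f, data.frame(other = 1),
                                     raw = FALSE), "rugged")
})

test_that("mean estimates average site-level probabilities", {
  # constant model: mean psi equals psi-hat exactly
  set.seed(221)
  h <- make_history(matrix(rbinom(40, 1, 0.3), 10, 4))
  f <- fit_occu(model_spec(), h, empty_sites(10), seed = 1)
  me <- mean_estimates(f, h, empty_sites(10))
  expect_equal(me$psi$mean, plogis(f$coef[[1]]), tolerance = 1e-12)
  expect_true(is.finite(me$psi$se))

  # two sites with psi-hat 0.2 and 0.4 average to 0.3
  tab <- sites_with(a = c(-1, 1))
  h2 <- make_history(matrix(c(1L, 0L, 0L, 1L), 2, 2))
  f2 <- fit_occu(model_spec(data.frame(covariate = "a", degree = 1L)),
                 h2, tab, seed = 1)
  mid <- (qlogis(0.2) + qlogis(0.4)) / 2
  f2$coef[] <- c(mid, qlogis(0.4) - mid, 0)
  me2 <- mean_estimates(f2, h2, tab)
  expect_equal(me2$psi$mean, 0.3, tolerance = 1e-12)
})

test_that("fitted values multiply occupancy and detection", {
  h <- make_history(rbind(c(1L, NA), c(0L, 0L)))
  f <- fit_occu(model_spec(), h, empty_sites(2), seed = 1)
  f$coef[] <- const_params(0.5, 0.4)
  yhat <- fitted_values(f, h, empty_sites(2))
  expect_equal(yhat[1, 1], 0.2, tolerance = 1e-12)
  expect_true(is.na(yhat[1, 2]))
  expect_equal(yhat[2, ], c(0.2, 0.2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("total fitted detections match total observed under the truth", {
  truth <- true_parameters("sp", beta_intercept = 0,
                           beta_terms = data.frame(covariate = "rugged",
                                                   degree = 1L, coef = 1),
                           gamma_intercepts = c(m1 = qlogis(0.4)))
  d <- sim_dataset(1500, truth, survey_design("m1", 4L), seed = 231,
                   covariate_names = "rugged")
  spec <- model_spec(data.frame(covariate = "rugged", degree = 1L))
  f <- fit_occu(spec, d$history, d$std, seed = 1, scaling = d$scaling)
  yhat <- fitted_values(f, d$history, d$std)
  tot_obs <- sum(d$history$y, na.rm = TRUE)
  tot_hat <- sum(yhat, na.rm = TRUE)
  # moment check: within 3 sd of the total-detections distribution
  sd_tot <- sqrt(sum(yhat * (1 - yhat), na.rm = TRUE))
  expect_lt(abs(tot_hat - tot_obs), 3 * sd_tot)
})

test_that("fitted models round-trip through JSON", {
  truth <- true_parameters("sp", beta_intercept = 0,
                           beta_terms = data.frame(covariate = "rugged",
                                                   degree = 1L, coef = 1),
                           gamma_intercepts = c(m1 = 0, m2 = 0.5))
  d <- sim_dataset(150, truth,
                   survey_design(c("m1", "m2"), c(m1 = 4L, m2 = 5L)),
                   seed = 241, covariate_names = c("rugged", "tsf"))
  spec <- model_spec(data.frame(covariate = "rugged", degree = 1L),
                     p_terms = "tsf")
  f <- fit_occu(spec, d$history, d$std, seed = 1, scaling = d$scaling)
  path <- withr::local_tempfile(fileext = ".json")
  write_fitted(f, path)
  f2 <- read_fitted(path)
  expect_equal(f2$coef, f$coef, tolerance = 1e-12)
  expect_equal(f2$vcov, f$vcov, tolerance = 1e-10)
  expect_equal(f2$aic, f$aic, tolerance = 1e-12)
  expect_equal(spec_string(f2$spec), spec_string(f$spec))
  expect_equal(f2$scaling$mean, f$scaling$mean, tolerance = 1e-12)
})
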