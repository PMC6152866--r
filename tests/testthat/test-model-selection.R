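test_that("the detections cap is floor(n/ratio)", {
  expect_equal(max_terms_for(25), 2L)
  expect_equal(max_terms_for(9), 0L)
  expect_equal(max_terms_for(10), 1L)
  expect_equal(max_terms_for(0), 0L)
})

test_that("enumeration matches the combinatorial oracle under marginality", {
  specs <- enumerate_models(c("A", "B"))
  strings <- vapply(specs, spec_string, character(1))
  # each covariate absent / linear / linear+quadratic: 3 x 3 = 9
  expect_length(specs, 9)
  expect_setequal(strings, c(
    "psi(~1) p(~method)", "psi(~A) p(~method)", "psi(~A+A^2) p(~method)",
    "psi(~B) p(~method)", "psi(~B+B^2) p(~method)",
    "psi(~A+B) p(~method)", "psi(~A+A^2+B) p(~method)",
    "psi(~A+B+B^2) p(~method)", "psi(~A+A^2+B+B^2) p(~method)"))
  # capping at 2 terms drops the three specs with 3-4 terms
  specs2 <- enumerate_models(c("A", "B"), max_terms = 2)
  expect_length(specs2, 6)
  # cap 0 leaves exactly the null spec
  specs0 <- enumerate_models(c("A", "B"), max_terms = 0)
  expect_length(specs0, 1)
  expect_equal(spec_string(specs0[[1]]), "psi(~1) p(~method)")
  # quadratic ban respected in enumeration
  specs3 <- enumerate_models(c("A", "fire_extent"))
  expect_false(any(grepl("fire_extent\\^2",
                         vapply(specs3, spec_string, character(1)))))
  expect_length(specs3, 6)  # 3 states for A x 2 for fire_extent
  # detection candidates dredged alongside, counted against the cap
  specs4 <- enumerate_models("A", p_candidates = "tsf", max_terms = 1)
  strings4 <- vapply(specs4, spec_string, character(1))
  expect_setequal(strings4, c("psi(~1) p(~method)",
                              "psi(~1) p(~method+tsf)",
                              "psi(~A) p(~method)"))
  # independent count oracle for <= 4 linear-only candidates
  for (k in 1:4) {
    specs_k <- enumerate_models(LETTERS[1:k],
                                quadratic_allowed =
                                  setNames(rep(FALSE, k), LETTERS[1:k]))
    expect_length(specs_k, 2^k)
  }
})

test_that("AIC ranking, deltas and the strict dAIC<6 retention rule", {
  fits <- list(fake_fit(103), fake_fit(100), fake_fit(106.1))
  r <- rank_by_aic(fits)
  expect_equal(r$records$aic, c(100, 103, 106.1))
  expect_equal(r$records$delta_aic, c(0, 3, 6.1))
  expect_equal(r$records$retained, c(TRUE, TRUE, FALSE))
  # delta exactly 6.0 is excluded
  r2 <- rank_by_aic(list(fake_fit(100), fake_fit(106)))
  expect_equal(r2$records$retained, c(TRUE, FALSE))
  # AIC arithmetic: logL = -100, K = 3 -> AIC 206
  f <- fake_fit(206, n_params = 3L)
  expect_equal(-2 * f$logL + 2 * f$n_params, 206)
  # non-converged fits are excluded; all-non-converged signals fallback
  r3 <- rank_by_aic(list(fake_fit(100, converged = FALSE), fake_fit(104)))
  expect_equal(nrow(r3$records), 1L)
  expect_error(rank_by_aic(list(fake_fit(1, converged = FALSE))),
               "null")
  # ties broken by fewer parameters
  r4 <- rank_by_aic(list(fake_fit(100, n_params = 4L),
                         fake_fit(100, n_params = 2L)))
  expect_equal(r4$records$n_params, c(2L, 4L))
})

test_that("selection walks the ranked set and falls back to the null model", {
  set.seed(301)
  z <- rbinom(20, 1, 0.7)
  y <- matrix(rbinom(80, 1, 0.4), 20, 4) * z
  h <- make_history(y)
  sites <- empty_sites(20)

  # top model boundary-flagged, second clean: second returned
  f1 <- fake_fit(100, boundary = TRUE)
  f2 <- fit_occu(model_spec(), h, sites, seed = 1)
  f2$aic <- 101
  ranked <- list(records = data.frame(
    model_id = 1:2, spec = c("bad", "good"), logL = c(-48, -48.5),
    n_params = 2L, aic = c(100, 101), delta_aic = c(0, 1),
    boundary_flag = c(TRUE, FALSE), retained = TRUE),
    fits = list(f1, f2))
  sel <- select_best(ranked, h, sites)
  expect_false(sel$is_null)
  expect_equal(sel$fit$aic, 101)
  expect_equal(sel$rejected$reason, "boundary estimates")

  # all candidates flagged: constant-occupancy fallback
  ranked2 <- list(records = ranked$records[1, ], fits = list(f1))
  sel2 <- select_best(ranked2, h, sites)
  expect_true(sel2$is_null)
  expect_null(sel2$fit$spec$psi_terms)

  # single clean top model returned unchanged
  ranked3 <- list(records = ranked$records[2, ], fits = list(f2))
  sel3 <- select_best(ranked3, h, sites)
  expect_identical(sel3$fit, f2)

  # user screens veto candidates
  sel4 <- select_best(ranked3, h, sites,
                      screens = list(function(fit) FALSE))
  expect_true(sel4$is_null)
  expect_equal(sel4$rejected$reason, "rejected by screen")

  # a failing GoF function pushes selection onward
  sel5 <- select_best(ranked3, h, sites,
                      gof_fun = function(fit) {
                        structure(list(p_value = c(sse = 0.01,
                                                   freeman_tukey = 0.5,
                                                   pearson = 0.5)),
                                  class = "gof_result")
                      })
  expect_true(sel5$is_null)
  expect_equal(sel5$rejected$reason, "failed goodness-of-fit")
})

test_that("ranking is invariant to enumeration order up to exact ties", {
  set.seed(302)
  truth <- true_parameters("sp", beta_intercept = 0,
                           beta_terms = data.frame(covariate = "rugged",
                                                   degree = 1L, coef = 1),
                           gamma_intercepts = c(m1 = 0))
  d <- sim_dataset(120, truth, survey_design("m1", 4L), seed = 303,
                   covariate_names = c("rugged", "tsf"))
  specs <- enumerate_models(c("rugged", "tsf"), max_terms = 2)
  fits <- fit_candidates(specs, d$history, d$std, seed = 9)
  r1 <- rank_by_aic(fits)
  r2 <- rank_by_aic(rev(fits))
  expect_equal(r1$records$aic, r2$records$aic, tolerance = 1e-9)
  expect_equal(r1$records$spec, r2$records$spec)
})
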