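test_that("Spearman screening drops the lower-priority member of hot pairs", {
  set.seed(101)
  n <- 60
  rainfall <- rnorm(n)
  # monotone-transformed copy: Spearman rho = 1 > 0.7 up to noise
  min_temp <- rainfall + rnorm(n, sd = 0.2)
  rugged <- rnorm(n)
  tab <- sites_with(rainfall = rainfall, min_temp = min_temp,
                    rugged = rugged)
  out <- spearman_screen(tab, priority = c("rainfall", "rugged",
                                           "min_temp"))
  expect_true(abs(out$rho["rainfall", "min_temp"]) > 0.7)
  expect_setequal(out$kept, c("rainfall", "rugged"))
  expect_equal(out$discarded, "min_temp")
})

test_that("the 0.7 threshold is a strict inequality", {
  # ranks chosen so sum(d^2) = 50 at n = 10:
  # Spearman rho = 1 - 6*50/990 = 0.6970, in (0.69, 0.7) -> both kept
  a <- 1:10
  b <- c(6, 1, 2, 3, 4, 5, 10, 9, 8, 7)
  tab <- sites_with(a = a, b = b)
  expect_equal(cor(a, b, method = "spearman"), 1 - 300 / 990)
  out <- spearman_screen(tab)
  expect_setequal(out$kept, c("a", "b"))
  expect_length(out$discarded, 0)
})

test_that("three mutually correlated covariates leave exactly one", {
  set.seed(103)
  n <- 80
  base <- rnorm(n)
  tab <- sites_with(a = base + rnorm(n, sd = 0.1),
                    b = base + rnorm(n, sd = 0.1),
                    c = base + rnorm(n, sd = 0.1))
  out <- spearman_screen(tab)
  expect_length(out$kept, 1)
  expect_length(out$discarded, 2)
  # invariant to row order of the site table
  perm <- tab[sample(n), ]
  out2 <- spearman_screen(perm)
  expect_identical(out$kept, out2$kept)
})

test_that("screening rejects constant covariates and tiny tables", {
  tab <- sites_with(a = rnorm(10), flat = rep(3, 10))
  expect_error(spearman_screen(tab), "flat")
  expect_error(spearman_screen(sites_with(a = 1:2, b = 2:1)), "3 sites")
})

test_that("standardisation uses the sample sd and stores its constants", {
  tab <- sites_with(v = c(2, 4, 6))
  out <- standardize_covariates(tab)
  expect_equal(out$table$v, c(-1, 0, 1))
  expect_equal(out$scaling$mean[["v"]], 4)
  expect_equal(out$scaling$sd[["v"]], 2)
  # applying the stored constants to a new raw value
  newv <- apply_scaling(data.frame(v = 8), out$scaling)
  expect_equal(newv$v, 2)
  # idempotence up to floating tolerance
  out2 <- standardize_covariates(out$table)
  expect_equal(out2$table$v, out$table$v, tolerance = 1e-12)
  expect_error(standardize_covariates(sites_with(v = rep(1, 5))),
               "zero")
})

test_that("standardised columns have mean 0 and sample sd 1", {
  set.seed(104)
  tab <- sites_with(a = rexp(40), b = rnorm(40, 7, 3), c = runif(40))
  std <- standardize_covariates(tab)$table
  for (v in c("a", "b", "c")) {
    expect_lt(abs(mean(std[[v]])), 1e-10)
    expect_lt(abs(sd(std[[v]]) - 1), 1e-10)
  }
})

test_that("design matrices follow term order, marginality and the fire ban", {
  tab <- sites_with(ruggedness = 0.5, fire_extent = 1)
  X <- build_design(data.frame(covariate = "ruggedness",
                               degree = c(1L, 2L)), tab)
  expect_equal(unname(X[1, ]), c(1, 0.5, 0.25))
  expect_equal(colnames(X), c("(Intercept)", "ruggedness",
                              "ruggedness^2"))
  expect_error(build_design(data.frame(covariate = "fire_extent",
                                       degree = c(1L, 2L)), tab),
               "fire_extent")
  expect_error(build_design(data.frame(covariate = "ruggedness",
                                       degree = 2L), tab),
               "marginality")
  # empty term list: intercept-only
  X0 <- build_design(NULL, tab)
  expect_equal(dim(X0), c(1L, 1L))
  expect_equal(unname(X0[1, 1]), 1)
  # byte-for-byte reproducible
  terms <- data.frame(covariate = "ruggedness", degree = c(1L, 2L))
  expect_identical(build_design(terms, tab), build_design(terms, tab))
})

test_that("extraction returns the containing cell's value", {
  # analytic raster: covariate equals the cell-centre x coordinate
  vals <- matrix(rep((1:6 - 0.5) * 10, each = 4), 4, 6)
  st <- cov_stack(list(xcov = vals), cellsize = 10)
  cc <- occumap:::cell_centres(st)
  at_centre <- extract_at_sites(st, data.frame(x = cc$x[3], y = cc$y[2]))
  expect_equal(at_centre$xcov, cc$x[3])
  # off-centre point still takes its containing cell (quantized)
  off <- extract_at_sites(st, data.frame(x = 13.7, y = 2.2))
  expect_equal(off$xcov, 15)
  expect_error(extract_at_sites(st, data.frame(site_id = "far",
                                               x = 1000, y = 0)),
               "far")
})

test_that("raster coarsening takes block means of finite cells", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)  # one 2x2 block holding 1..4
  st <- cov_stack(list(v = m))
  expect_equal(reclassify_raster(st, 2)$layers$v[1, 1], 2.5)
  m2 <- matrix(c(1, 3, NA, NA), 2, 2)
  st2 <- cov_stack(list(v = m2))
  expect_equal(reclassify_raster(st2, 2)$layers$v[1, 1], 2)
  st3 <- cov_stack(list(v = matrix(NA_real_, 2, 2)))
  expect_true(is.na(reclassify_raster(st3, 2)$layers$v[1, 1]))
  # factor 1 is the identity; oversized factors are rejected
  expect_identical(reclassify_raster(st, 1), st)
  expect_error(reclassify_raster(st, 5), "exceeds")
  # cellsize scales with the factor
  expect_equal(reclassify_raster(st, 2)$cellsize, 2)
})

test_that("stacks round-trip through their text serialization", {
  st <- gen_landscape(6, 5, c("a", "b"), seed = 105, cellsize = 100,
                      xmin = 10, ymin = 20)
  st$layers$a[2, 3] <- NA
  d <- withr::local_tempdir()
  write_cov_stack(st, d)
  st2 <- read_cov_stack(d)
  expect_equal(st2$layers$a, st$layers$a, tolerance = 1e-12)
  expect_equal(st2$cellsize, 100)
  expect_equal(st2$xmin, 10)
})
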