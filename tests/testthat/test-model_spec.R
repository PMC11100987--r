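test_that("growth basis is the polynomial design matrix", {
  b <- build_growth_basis(0:4, 2)
  expect_equal(unname(b$loading_matrix),
               cbind(1, 0:4, (0:4)^2))
  expect_equal(qr(b$loading_matrix)$rank, 3L)

  b1 <- build_growth_basis(c(0, 1, 2), 1)
  expect_equal(unname(b1$loading_matrix), cbind(c(1, 1, 1), c(0, 1, 2)))

  expect_error(build_growth_basis(c(0, 1, 1, 2, 3), 2), "increasing")
  expect_error(build_growth_basis(0:2, 2), "waves")
})

test_that("implied moments follow the two-level growth decomposition", {
  m <- implied_moments(pop_spec)
  expect_equal(m$mean, c(49.96, 54.15, 58.08, 61.75, 65.16), tolerance = 1e-12)
  expect_equal(m$within_cov[1, 1], 73.25)
  expect_equal(m$between_cov[1, 1], 28.11)
  expect_true(isSymmetric(m$within_cov, tol = 1e-10))
  expect_true(isSymmetric(m$between_cov, tol = 1e-10))
  expect_gt(min(eigen(m$within_cov, only.values = TRUE)$values), 0)

  # degenerate: all latent variation off -> residual diagonal only
  z <- mlgm_spec(
    pop_spec$basis,
    within = level_params(rep(0, 3), matrix(0, 3, 3), rep(2, 5)),
    between = level_params(rep(0, 3), matrix(0, 3, 3), rep(0, 5))
  )
  mz <- implied_moments(z)
  expect_equal(mz$within_cov, diag(2, 5))
  expect_equal(mz$mean, rep(0, 5))
})

test_that("implied moments match empirical moments of a large simulation", {
  cond <- design_condition(2000, 25, 75)
  ds <- simulate_dataset(pop_spec, cond, 424242)
  m <- implied_moments(pop_spec)
  s_pw <- pooled_within_cov(ds)
  expect_lt(max(abs(s_pw - m$within_cov) / (abs(m$within_cov) + 1)), 0.02)
  y <- as.matrix(ds$data[, paste0("V", 1:5)])
  expect_lt(max(abs(colMeans(y) - m$mean) / m$mean), 0.02)
  # total variance at wave 1 within 2% of Sigma_B + Sigma_W
  expect_equal(var(y[, 1]), m$between_cov[1, 1] + m$within_cov[1, 1],
               tolerance = 0.02)
})

test_that("icc profile is the between share of total variance", {
  m <- implied_moments(pop_spec)
  expect_equal(icc_profile(m)[1], 28.11 / (28.11 + 73.25), tolerance = 1e-12)
  pd <- rand_pd(4)
  expect_equal(icc_profile(list(within_cov = pd, between_cov = pd)), rep(0.5, 4))
  expect_equal(icc_profile(list(within_cov = pd, between_cov = pd * 0)), rep(0, 4))
  expect_error(icc_profile(list(within_cov = matrix(0, 2, 2),
                                between_cov = matrix(0, 2, 2))), "positive")
})

test_that("degree-of-freedom accounting matches the saturation pattern", {
  tp <- template_catalog()
  got <- lapply(tp, model_df)
  expect_equal(got$H1, list(free_params = 35L, df = 0L))
  expect_equal(got$PS_B, list(free_params = 31L, df = 4L))
  expect_equal(got$PS_W, list(free_params = 31L, df = 4L))
  expect_equal(got$TS_COV, got$PS_B)
  expect_equal(got$TS_MEAN, list(free_params = 33L, df = 2L))
  expect_equal(got$BASE_B, list(free_params = 25L, df = 10L))
  expect_equal(got$BASE_W, list(free_params = 25L, df = 10L))
  expect_equal(got$BASE_MEAN, list(free_params = 31L, df = 4L))
  # df is additive over blocks: params + df == params(H1) always
  for (g in got) expect_equal(g$free_params + g$df, 35L)
  # fixing factor covariances at zero removes q(q-1)/2 parameters
  tpd <- model_template("x", "saturated", "structured", "saturated",
                        phi_offdiag_free = FALSE)
  expect_equal(model_df(tpd), list(free_params = 28L, df = 7L))
})

test_that("level parameter validation rejects bad inputs", {
  expect_error(level_params(0:2, diag(3), rep(-1, 5)), ">= 0")
  bad <- diag(3); bad[1, 1] <- -2
  expect_error(level_params(rep(0, 3), bad, rep(1, 5)), "semidefinite")
  expect_error(
    mlgm_spec(pop_spec$basis,
              within = level_params(c(1, 0, 0), diag(3), rep(1, 5)),
              between = pop_spec$between),
    "within-level"
  )
})

test_that("population model round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  write_mlgm_spec(pop_spec, path)
  back <- read_mlgm_spec(path)
  expect_equal(back$between$latent_cov, pop_spec$between$latent_cov)
  expect_equal(back$within$latent_cov, pop_spec$within$latent_cov)
  expect_equal(back$between$latent_mean, pop_spec$between$latent_mean)
  expect_equal(back$within$residual_var, pop_spec$within$residual_var)
  expect_equal(back$basis$loading_matrix, pop_spec$basis$loading_matrix)
  # the shipped default file reproduces the package default exactly
  shipped <- system.file("extdata", "population_model.yaml", package = "mlgmsim")
  expect_equal(implied_moments(read_mlgm_spec(shipped)),
               implied_moments(pop_spec))
})
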