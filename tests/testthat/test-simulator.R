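test_that("cluster sizes follow the half-small half-large design", {
  expect_equal(draw_cluster_sizes(design_condition(50, 5, 15)),
               rep(c(5L, 15L), each = 25))
  expect_equal(sum(draw_cluster_sizes(design_condition(50, 5, 15))), 500L)
  expect_equal(sum(draw_cluster_sizes(design_condition(200, 25, 75))), 10000L)
  expect_equal(draw_cluster_sizes(design_condition(2, 1, 3)), c(1L, 3L))
  expect_error(design_condition(51, 5, 15), "even")
})

test_that("size coefficient of variation is exactly 0.5 on the study grid", {
  for (cond in default_conditions()) {
    expect_identical(size_cv(cond), 0.5)
  }
  expect_identical(size_cv(design_condition(10, 7, 7)), 0)
})

test_that("simulation is seed-deterministic and degenerates correctly", {
  cond <- design_condition(10, 2, 6)
  d1 <- simulate_dataset(pop_spec, cond, 77)
  d2 <- simulate_dataset(pop_spec, cond, 77)
  expect_identical(d1$data, d2$data)
  d3 <- simulate_dataset(pop_spec, cond, 78)
  expect_false(identical(d1$data, d3$data))

  # byte-identical CSV under the same seed
  f1 <- tempfile(); f2 <- tempfile()
  write_dataset_csv(d1, f1); write_dataset_csv(d2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # all variances zero -> every row equals the mean curve
  z <- mlgm_spec(
    pop_spec$basis,
    within = level_params(rep(0, 3), matrix(0, 3, 3), rep(0, 5)),
    between = level_params(c(49.96, 4.32, -0.13), matrix(0, 3, 3), rep(0, 5))
  )
  dz <- simulate_dataset(z, cond, 1)
  mu <- implied_moments(pop_spec)$mean
  for (t in 1:5) expect_equal(dz$data[[paste0("V", t)]], rep(mu[t], 40))
})

test_that("pooled within covariance matches its defining formula", {
  # two clusters on T=1: {0,2} and {1,3}; scatter (2+2)/(4-2) = 2
  ds <- manual_dataset(matrix(c(0, 2, 1, 3), ncol = 1), c(1, 1, 2, 2))
  expect_equal(pooled_within_cov(ds), matrix(2, 1, 1), ignore_attr = TRUE)

  # every member at its cluster mean -> zero matrix
  ds0 <- manual_dataset(matrix(rep(c(1, 5), each = 3), ncol = 1), rep(1:2, each = 3))
  expect_equal(pooled_within_cov(ds0), matrix(0, 1, 1), ignore_attr = TRUE)
})

test_that("between covariance matches its defining formula", {
  # two clusters of 2 with means 0 and 2, grand mean 1: (2*1 + 2*1)/1 = 4
  ds <- manual_dataset(matrix(c(-1, 1, 1, 3), ncol = 1), c(1, 1, 2, 2))
  expect_equal(between_cov(ds), matrix(4, 1, 1), ignore_attr = TRUE)

  # equal cluster means -> zero
  ds0 <- manual_dataset(matrix(c(0, 2, -1, 3), ncol = 1), c(1, 1, 2, 2))
  expect_equal(between_cov(ds0), matrix(0, 1, 1), ignore_attr = TRUE)

  # balanced large simulation: E[S*_B] = n Sigma_B + Sigma_W
  cond <- design_condition(3000, 10, 10)
  ds_big <- simulate_dataset(pop_spec, cond, 909)
  m <- implied_moments(pop_spec)
  expected <- 10 * m$between_cov + m$within_cov
  scale <- sqrt(tcrossprod(diag(expected)))
  expect_lt(max(abs(between_cov(ds_big) - expected) / scale), 0.05)
})

test_that("sufficient statistics are an exact compression", {
  ds <- manual_dataset(matrix(rnorm(8), ncol = 2), c(1, 2, 2, 2))
  st <- sufficient_stats(ds)
  expect_equal(length(st$size_classes), 2L)
  expect_equal(vapply(st$size_classes, `[[`, 0L, "count"), c(1L, 1L))
  for (cls in st$size_classes) {
    expect_equal(cls$scatter, matrix(0, 2, 2), ignore_attr = TRUE)
  }

  # per-class scatter identity against direct computation
  set.seed(5)
  ds2 <- small_dataset(seed = 11, ng = 12, small = 3, large = 9)
  st2 <- sufficient_stats(ds2)
  expect_equal(sum(vapply(st2$size_classes, `[[`, 0L, "count")), 12L)
  expect_equal(sum(vapply(st2$size_classes, function(x) x$size * x$count, 0)),
               st2$n_total)
  y <- as.matrix(ds2$data[, paste0("V", 1:5)])
  cl <- ds2$data$cluster_id
  means <- rowsum(y, cl) / as.vector(table(cl))
  mu <- rnorm(5)
  for (cls in st2$size_classes) {
    sizes <- as.vector(table(cl))
    md <- means[sizes == cls$size, , drop = FALSE]
    direct <- crossprod(sweep(md, 2, mu))
    viastats <- cls$scatter + cls$count * tcrossprod(cls$mean - mu)
    expect_equal(direct, viastats, tolerance = 1e-10, ignore_attr = TRUE)
  }

  # pooled scatter ties out with the pooled covariance
  expect_equal(st2$pooled_within_scatter / (st2$n_total - 12),
               pooled_within_cov(ds2), ignore_attr = TRUE)
})

test_that("dataset CSV round-trips and validates", {
  ds <- small_dataset(seed = 3)
  path <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path)
  expect_equal(back$data$cluster_id, ds$data$cluster_id)
  expect_equal(as.matrix(back$data[, 3:7]), as.matrix(ds$data[, 3:7]),
               tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b,V1", "1,1,0.5"), bad)
  expect_error(read_dataset_csv(bad), "header")
})
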