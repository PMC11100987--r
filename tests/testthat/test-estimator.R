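test_that("sufficient-statistic likelihood equals the Kronecker oracle", {
  set.seed(42)
  for (i in 1:50) {
    p <- sample(2:5, 1)
    g <- sample(2:4, 1)
    sizes <- sample(1:3, g, replace = TRUE)
    y <- matrix(rnorm(sum(sizes) * p, sd = 2), ncol = p)
    ds <- manual_dataset(y, rep.int(seq_len(g), sizes))
    pr <- rand_params(p)
    expect_equal(
      mlgm_loglik(pr$sigma_w, pr$sigma_b, pr$mu, ds),
      mlgm_loglik_bruteforce(pr$sigma_w, pr$sigma_b, pr$mu, ds),
      tolerance = 1e-8
    )
  }
})

test_that("likelihood degenerates correctly at the boundaries", {
  set.seed(7)
  pr <- rand_params(3)
  # single cluster of size 1: density of one draw from N(mu, Sigma_B + Sigma_W)
  y1 <- rnorm(3)
  ds1 <- manual_dataset(matrix(y1, 1), 1L)
  v <- pr$sigma_b + pr$sigma_w
  ch <- chol(v)
  z <- backsolve(ch, y1 - pr$mu, transpose = TRUE)
  direct <- -0.5 * (3 * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  expect_equal(mlgm_loglik(pr$sigma_w, pr$sigma_b, pr$mu, ds1), direct,
               tolerance = 1e-10)

  # Sigma_B = 0: independent rows from N(mu, Sigma_W)
  y <- matrix(rnorm(12), 4, 3)
  ds <- manual_dataset(y, c(1, 1, 2, 2))
  indep <- sum(apply(y, 1, function(r) {
    chw <- chol(pr$sigma_w)
    zz <- backsolve(chw, r - pr$mu, transpose = TRUE)
    -0.5 * (3 * log(2 * pi) + 2 * sum(log(diag(chw))) + sum(zz^2))
  }))
  expect_equal(mlgm_loglik_bruteforce(pr$sigma_w, matrix(0, 3, 3), pr$mu, ds),
               indep, tolerance = 1e-8)

  # additivity: duplicating every cluster doubles the log-likelihood
  ds2 <- manual_dataset(rbind(y, y), c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_equal(mlgm_loglik(pr$sigma_w, pr$sigma_b, pr$mu, ds2),
               2 * mlgm_loglik(pr$sigma_w, pr$sigma_b, pr$mu, ds),
               tolerance = 1e-8)

  # exchangeability: permuting members within a cluster changes nothing
  dsp <- manual_dataset(y[c(2, 1, 4, 3), ], c(1, 1, 2, 2))
  expect_equal(mlgm_loglik_bruteforce(pr$sigma_w, pr$sigma_b, pr$mu, dsp),
               mlgm_loglik_bruteforce(pr$sigma_w, pr$sigma_b, pr$mu, ds),
               tolerance = 1e-10)
})

test_that("analytic gradient matches numerical differentiation", {
  ds <- small_dataset(seed = 19, ng = 8, small = 2, large = 6)
  st <- sufficient_stats(ds)
  for (nm in c("H1", "PS_B", "PS_W", "TS_MEAN", "BASE_W")) {
    tp <- template_catalog()[[nm]]
    map <- mlgmsim:::.param_map(tp, pop_spec$basis$loading_matrix)
    par <- start_values(tp, st, pop_spec$basis)
    d <- map$decode(par)
    gr <- mlgmsim:::.mlgm_loglik_grad(d$sigma_w, d$sigma_b, d$mu, st)
    ana <- map$grad(d$cache, gr$D_w, gr$D_b, gr$g_mu)
    num <- vapply(seq_along(par), function(i) {
      h <- 1e-7 * max(1, abs(par[i]))
      up <- par; up[i] <- up[i] + h
      dn <- par; dn[i] <- dn[i] - h
      du <- map$decode(up); dd <- map$decode(dn)
      (mlgm_loglik(du$sigma_w, du$sigma_b, du$mu, st) -
         mlgm_loglik(dd$sigma_w, dd$sigma_b, dd$mu, st)) / (2 * h)
    }, 0)
    expect_lt(max(abs(ana - num) / pmax(1, abs(num))), 1e-4)
  }
})

test_that("starting values reproduce the moment estimates", {
  ds <- small_dataset(seed = 23, ng = 20, small = 5, large = 15)
  st <- sufficient_stats(ds)
  tp <- template_catalog()
  lam <- pop_spec$basis$loading_matrix
  # saturated start holds S_PW exactly in the within block
  map <- mlgmsim:::.param_map(tp$H1, lam)
  d <- map$decode(start_values(tp$H1, st, pop_spec$basis))
  expect_equal(d$sigma_w, pooled_within_cov(ds), tolerance = 1e-12,
               ignore_attr = TRUE)
  # large balanced sample: between start lands near the truth
  big <- simulate_dataset(pop_spec, design_condition(2000, 20, 20), 5150)
  db <- map$decode(start_values(tp$H1, sufficient_stats(big), pop_spec$basis))
  truth <- implied_moments(pop_spec)$between_cov
  expect_lt(max(abs(diag(db$sigma_b) - diag(truth)) / diag(truth)), 0.10)
})

test_that("fitting ascends, nests monotonically, and flags convergence", {
  ds <- small_dataset(seed = 31, ng = 20, small = 5, large = 15)
  st <- sufficient_stats(ds)
  fits <- fit_catalog(st, pop_spec$basis)
  expect_true(all(vapply(fits, `[[`, TRUE, "converged")))

  # achieved loglik >= loglik at start values
  for (nm in names(fits)) {
    tp <- fits[[nm]]$template
    map <- mlgmsim:::.param_map(tp, pop_spec$basis$loading_matrix)
    d0 <- map$decode(start_values(tp, st, pop_spec$basis))
    expect_gte(fits[[nm]]$loglik,
               mlgm_loglik(d0$sigma_w, d0$sigma_b, d0$mu, st) - 1e-8)
  }

  # nesting lattice: H1 dominates everything; baselines sit below their models
  lls <- vapply(fits, `[[`, 0, "loglik")
  expect_true(all(lls["H1"] >= lls - 1e-6))
  expect_gte(lls["PS_B"], lls["BASE_B"] - 1e-6)
  expect_gte(lls["PS_W"], lls["BASE_W"] - 1e-6)
  expect_gte(lls["TS_MEAN"], lls["BASE_MEAN"] - 1e-6)
  # shared-pattern templates are fitted once
  expect_equal(lls[["TS_COV"]], lls[["PS_B"]])
})

test_that("balanced saturated fit matches the closed-form ML solution", {
  ds <- simulate_dataset(pop_spec, design_condition(40, 8, 8), 606)
  st <- sufficient_stats(ds)
  fit <- fit_mlgm(template_catalog()$H1, st, pop_spec$basis)
  n <- 8; g <- 40
  cls <- st$size_classes[[1]]
  mu_hat <- cls$mean
  sw_hat <- st$pooled_within_scatter / (st$n_total - g)
  v_hat <- cls$scatter / g
  sb_hat <- v_hat - sw_hat / n
  # the likelihood surface is quadratically flat near the optimum, so the
  # loglik comparison is far sharper than the parameter one
  expect_equal(fit$params$mu, mu_hat, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(fit$params$sigma_w, sw_hat, tolerance = 5e-3, ignore_attr = TRUE)
  expect_equal(fit$params$sigma_b, sb_hat, tolerance = 5e-3, ignore_attr = TRUE)
  ll_closed <- mlgm_loglik(sw_hat, sb_hat, mu_hat, st)
  expect_equal(fit$loglik, ll_closed, tolerance = 1e-8)
  expect_lte(fit$loglik, ll_closed + 1e-6)
})

test_that("location shifts move only the mean estimate", {
  ds <- small_dataset(seed = 47, ng = 16, small = 4, large = 12)
  shift <- c(3, -1, 2, 0.5, -2)
  ds2 <- ds
  for (t in 1:5) ds2$data[[paste0("V", t)]] <- ds$data[[paste0("V", t)]] + shift[t]
  f1 <- fit_catalog(sufficient_stats(ds), pop_spec$basis)
  f2 <- fit_catalog(sufficient_stats(ds2), pop_spec$basis)
  expect_equal(f2$H1$params$mu, f1$H1$params$mu + shift, tolerance = 1e-7)
  expect_equal(f2$H1$params$sigma_w, f1$H1$params$sigma_w, tolerance = 1e-7)
  expect_equal(f2$H1$params$sigma_b, f1$H1$params$sigma_b, tolerance = 1e-7)
  for (nm in c("PS_B", "PS_W", "BASE_B")) {
    dev1 <- 2 * (f1$H1$loglik - f1[[nm]]$loglik)
    dev2 <- 2 * (f2$H1$loglik - f2[[nm]]$loglik)
    expect_equal(dev1, dev2, tolerance = 1e-6)
  }
})
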