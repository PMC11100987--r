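# Full-information maximum likelihood for two-level mean-and-covariance
# structure models with unequal cluster sizes.
#
# The observed log-likelihood of cluster g (size n, outcome dimension p) is
#   -1/2 [ n p log 2pi + p log n + (n-1) log|S_W| + tr(S_W^-1 S_g)
#          + log|V_n| + (ybar_g - mu)' V_n^-1 (ybar_g - mu) ],
# with V_n = S_B + S_W / n, which depends on the data only through the
# pooled within scatter and the per-size-class cluster-mean statistics.
#
# Covariance blocks are parameterized linearly (unique elements of the
# symmetric matrix, residual variances as free reals). The likelihood is
# evaluated only where S_W and every V_n are positive definite; within that
# domain parameters are otherwise unconstrained, so boundary and
# Heywood-type solutions (negative residual variances, indefinite factor
# covariances) are reachable, exactly as in conventional SEM maximum
# likelihood. Whether the solution is PD-admissible is recorded on the fit
# result.

# ---- parameter blocks -------------------------------------------------------

.sym_block <- function(dim, diagonal_only = FALSE) {
  if (diagonal_only) {
    idx <- cbind(seq_len(dim), seq_len(dim))
    is_diag <- rep(TRUE, dim)
  } else {
    idx <- which(lower.tri(diag(dim), diag = TRUE), arr.ind = TRUE)
    is_diag <- idx[, 1] == idx[, 2]
  }
  idx_t <- idx[, 2:1, drop = FALSE]
  list(
    npar = nrow(idx),
    decode = function(par) {
      m <- matrix(0, dim, dim)
      m[idx] <- par
      m[idx_t] <- par
      m
    },
    # D is the independent-element derivative (symmetric); off-diagonal
    # unique elements pick up both mirror entries
    grad = function(m, D) {
      g <- D[idx]
      g[!is_diag] <- 2 * g[!is_diag]
      g
    },
    encode = function(m) m[idx]
  )
}

# Clamp eigenvalues from below so Cholesky always succeeds.
psd_project <- function(m, floor = 1e-6) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
}

.cov_block <- function(mode, lam, phi_offdiag_free = TRUE) {
  tt <- nrow(lam)
  q <- ncol(lam)
  switch(mode,
    saturated = {
      sb <- .sym_block(tt)
      list(
        npar = sb$npar,
        decode = function(par) {
          m <- sb$decode(par)
          list(sigma = m, cache = m)
        },
        grad = function(cache, D) sb$grad(cache, D),
        encode = function(start) sb$encode(start$sigma),
        extract = function(cache) list()
      )
    },
    structured = {
      sb <- .sym_block(q, diagonal_only = !phi_offdiag_free)
      list(
        npar = sb$npar + tt,
        decode = function(par) {
          phi <- sb$decode(par[seq_len(sb$npar)])
          theta <- par[sb$npar + seq_len(tt)]
          sig <- lam %*% phi %*% t(lam)
          diag(sig) <- diag(sig) + theta
          list(sigma = sig, cache = list(phi = phi, theta = theta))
        },
        grad = function(cache, D) {
          c(sb$grad(cache$phi, crossprod(lam, D %*% lam)), diag(D))
        },
        encode = function(start) c(sb$encode(start$phi), start$theta),
        extract = function(cache) list(phi = cache$phi, theta = cache$theta)
      )
    },
    diagonal = list(
      npar = tt,
      decode = function(par) list(sigma = diag(par, tt), cache = par),
      grad = function(cache, D) diag(D),
      encode = function(start) pmax(diag(start$sigma), 1e-4),
      extract = function(cache) list()
    )
  )
}

.mean_block <- function(mode, lam) {
  tt <- nrow(lam)
  q <- ncol(lam)
  switch(mode,
    saturated = list(
      npar = tt,
      decode = function(par) list(mu = par, cache = NULL),
      grad = function(cache, g_mu) g_mu,
      encode = function(mu) mu,
      extract = function(cache) list()
    ),
    structured = list(
      npar = q,
      decode = function(par) list(mu = as.numeric(lam %*% par), cache = par),
      grad = function(cache, g_mu) as.numeric(crossprod(lam, g_mu)),
      encode = function(mu) as.numeric(.pinv(lam) %*% mu),
      extract = function(cache) list(alpha = cache)
    ),
    equal = list(
      npar = 1L,
      decode = function(par) list(mu = rep(par, tt), cache = NULL),
      grad = function(cache, g_mu) sum(g_mu),
      encode = function(mu) mean(mu),
      extract = function(cache) list()
    )
  )
}

.pinv <- function(lam) solve(crossprod(lam), t(lam))

.param_map <- function(template, lam) {
  w <- .cov_block(template$within_cov, lam, template$phi_offdiag_free)
  b <- .cov_block(template$between_cov, lam, template$phi_offdiag_free)
  m <- .mean_block(template$mean, lam)
  i_w <- seq_len(w$npar)
  i_b <- w$npar + seq_len(b$npar)
  i_m <- w$npar + b$npar + seq_len(m$npar)
  list(
    npar = w$npar + b$npar + m$npar,
    decode = function(par) {
      dw <- w$decode(par[i_w]); db <- b$decode(par[i_b]); dm <- m$decode(par[i_m])
      list(sigma_w = dw$sigma, sigma_b = db$sigma, mu = dm$mu,
           cache = list(w = dw$cache, b = db$cache, m = dm$cache))
    },
    grad = function(cache, D_w, D_b, g_mu) {
      c(w$grad(cache$w, D_w), b$grad(cache$b, D_b), m$grad(cache$m, g_mu))
    },
    encode = function(start_w, start_b, mu) {
      c(w$encode(start_w), b$encode(start_b), m$encode(mu))
    },
    extract = function(cache) {
      out <- list()
      ew <- w$extract(cache$w)
      if (length(ew)) out[c("phi_w", "theta_w")] <- ew
      eb <- b$extract(cache$b)
      if (length(eb)) out[c("phi_b", "theta_b")] <- eb
      em <- m$extract(cache$m)
      if (length(em)) out["alpha_b"] <- em
      out
    }
  )
}

# ---- likelihood -------------------------------------------------------------

#' Two-level normal log-likelihood from sufficient statistics
#'
#' Evaluates the exact joint multivariate-normal log-likelihood of a
#' clustered dataset under within covariance `sigma_w`, between covariance
#' `sigma_b` and mean `mu`, using only the compressed statistics of
#' [sufficient_stats()]. Cost is independent of the number of clusters
#' given the number of distinct cluster sizes.
#'
#' @param sigma_w,sigma_b T x T covariance matrices (within must be
#'   positive definite).
#' @param mu Length-T mean vector.
#' @param stats A [sufficient_stats()] object (or a dataset, which is
#'   compressed on the fly).
#' @return The log-likelihood; `-Inf` if a covariance is numerically
#'   singular.
#' @export
mlgm_loglik <- function(sigma_w, sigma_b, mu, stats) {
  stats <- sufficient_stats(stats)
  p <- length(mu)
  ch_w <- tryCatch(chol(sigma_w), error = function(e) NULL)
  if (is.null(ch_w)) return(-Inf)
  inv_w <- chol2inv(ch_w)
  logdet_w <- 2 * sum(log(diag(ch_w)))
  n <- stats$n_total
  g <- stats$n_groups
  ll <- -0.5 * ((n - g) * logdet_w + sum(inv_w * stats$pooled_within_scatter))
  const <- n * p * log(2 * pi)
  for (cls in stats$size_classes) {
    v <- sigma_b + sigma_w / cls$size
    ch_v <- tryCatch(chol(v), error = function(e) NULL)
    if (is.null(ch_v)) return(-Inf)
    inv_v <- chol2inv(ch_v)
    dm <- cls$mean - mu
    bmat <- cls$scatter + cls$count * tcrossprod(dm)
    ll <- ll - 0.5 * (cls$count * 2 * sum(log(diag(ch_v))) + sum(inv_v * bmat))
    const <- const + cls$count * p * log(cls$size)
  }
  ll - 0.5 * const
}

# Gradient of mlgm_loglik with respect to the free elements of
# (sigma_w, sigma_b, mu), in the independent-element matrix convention.
.mlgm_loglik_grad <- function(sigma_w, sigma_b, mu, stats) {
  p <- length(mu)
  ch_w <- chol(sigma_w)
  inv_w <- chol2inv(ch_w)
  n <- stats$n_total
  g <- stats$n_groups
  D_w <- -0.5 * ((n - g) * inv_w - inv_w %*% stats$pooled_within_scatter %*% inv_w)
  D_b <- matrix(0, p, p)
  g_mu <- numeric(p)
  for (cls in stats$size_classes) {
    v <- sigma_b + sigma_w / cls$size
    inv_v <- chol2inv(chol(v))
    dm <- cls$mean - mu
    bmat <- cls$scatter + cls$count * tcrossprod(dm)
    core <- -0.5 * (cls$count * inv_v - inv_v %*% bmat %*% inv_v)
    D_b <- D_b + core
    D_w <- D_w + core / cls$size
    g_mu <- g_mu + cls$count * as.numeric(inv_v %*% dm)
  }
  list(D_w = D_w, D_b = D_b, g_mu = g_mu)
}

#' Brute-force log-likelihood from raw rows
#'
#' Independent cross-check of [mlgm_loglik()]: stacks each cluster's
#' observations into one long vector with covariance
#' \eqn{I_n \otimes \Sigma_W + J_n \otimes \Sigma_B} built explicitly, and
#' sums the exact multivariate-normal log-densities. Only feasible for
#' small clusters.
#'
#' @inheritParams mlgm_loglik
#' @param dataset A `clustered_dataset`.
#' @return The log-likelihood.
#' @export
mlgm_loglik_bruteforce <- function(sigma_w, sigma_b, mu, dataset) {
  y <- .dataset_matrix(dataset)
  cl <- dataset$data$cluster_id
  ll <- 0
  for (id in unique(cl)) {
    yg <- y[cl == id, , drop = FALSE]
    n <- nrow(yg)
    big <- kronecker(diag(n), sigma_w) + kronecker(matrix(1, n, n), sigma_b)
    vec <- as.numeric(t(yg)) - rep(mu, n)
    ch <- chol(big)
    z <- backsolve(ch, vec, transpose = TRUE)
    ll <- ll - 0.5 * (length(vec) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  ll
}

# ---- starting values --------------------------------------------------------

#' Moment-based starting values
#'
#' Within covariance starts at the pooled within-cluster covariance; the
#' between covariance at the PSD-projected moment estimate
#' \eqn{(S^*_B - S_{PW})/\bar n} with \eqn{\bar n} the mean cluster size;
#' the mean at the grand mean over individuals. Structured blocks project
#' those moment starts onto the growth structure through the pseudoinverse
#' of the loading matrix, with residual variances taken from the positive
#' part of the diagonal remainder (floored at 1e-4).
#'
#' @param template A [model_template()].
#' @param stats A [sufficient_stats()] object.
#' @param basis A [build_growth_basis()] object.
#' @return Numeric vector of unconstrained starting parameters.
#' @export
start_values <- function(template, stats, basis, diag_phi = FALSE) {
  stats <- sufficient_stats(stats)
  lam <- basis$loading_matrix
  map <- .param_map(template, lam)
  mom <- .moment_starts(stats)
  to_struct <- function(sigma) {
    pi_l <- .pinv(lam)
    phi <- psd_project(pi_l %*% sigma %*% t(pi_l), 1e-4)
    if (diag_phi) phi <- diag(diag(phi), nrow(phi))
    theta <- pmax(diag(sigma - lam %*% phi %*% t(lam)), 1e-4)
    list(sigma = sigma, phi = phi, theta = theta)
  }
  map$encode(to_struct(mom$sigma_w), to_struct(mom$sigma_b), mom$mu)
}

.moment_starts <- function(stats) {
  n <- stats$n_total
  g <- stats$n_groups
  p <- nrow(stats$pooled_within_scatter)
  s_pw <- stats$pooled_within_scatter / (n - g)
  grand <- numeric(p)
  for (cls in stats$size_classes) grand <- grand + cls$size * cls$count * cls$mean
  grand <- grand / n
  sb_star <- matrix(0, p, p)
  for (cls in stats$size_classes) {
    dm <- cls$mean - grand
    sb_star <- sb_star + cls$size * (cls$scatter + cls$count * tcrossprod(dm))
  }
  sb_star <- sb_star / (g - 1)
  nbar <- n / g
  sigma_b <- psd_project((sb_star - s_pw) / nbar, 1e-4)
  list(sigma_w = s_pw, sigma_b = sigma_b, mu = grand)
}

# ---- fitting ----------------------------------------------------------------

#' Optimizer settings
#'
#' @param tol Relative gradient tolerance: convergence requires the
#'   gradient sup-norm below `tol * max(1, |loglik|)`.
#' @param maxit BFGS iteration cap per attempt.
#' @param restarts Number of jittered restarts tried on non-convergence.
#' @return A `fit_control` list.
#' @export
fit_control <- function(tol = 1e-6, maxit = 500L, restarts = 1L) {
  list(tol = tol, maxit = as.integer(maxit), restarts = as.integer(restarts))
}

#' Fit one model template by maximum likelihood
#'
#' Maximizes [mlgm_loglik()] over the template's free parameters by
#' quasi-Newton iterations (PORT routines via [stats::nlminb()]) with
#' analytic gradients, starting from [start_values()]. Templates with a
#' structured covariance block are additionally fitted from a second,
#' diagonal-factor-covariance start and the better optimum kept, guarding
#' against the occasional spurious local maximum of the profile surface.
#' On non-convergence the optimizer is restarted from the current point and
#' then, if needed, from jittered starting values.
#'
#' @inheritParams start_values
#' @param control A [fit_control()] list.
#' @return A `fit_result`: `template`, `loglik`, decoded `params`
#'   (`sigma_w`, `sigma_b`, `mu`, plus `phi_*` / `theta_*` / `alpha_b` for
#'   structured blocks), `converged` (gradient criterion met), `admissible`
#'   (all fitted covariance components PSD — Heywood-type solutions are
#'   legal but flagged), `n_iter`, `grad_norm`, `df`, `free_params`.
#' @export
fit_mlgm <- function(template, stats, basis, control = fit_control()) {
  stats <- sufficient_stats(stats)
  lam <- basis$loading_matrix
  map <- .param_map(template, lam)
  negll <- function(par) {
    d <- map$decode(par)
    val <- mlgm_loglik(d$sigma_w, d$sigma_b, d$mu, stats)
    if (!is.finite(val)) return(.Machine$double.xmax / 2)
    -val
  }
  neggrad <- function(par) {
    d <- map$decode(par)
    if (!is.finite(mlgm_loglik(d$sigma_w, d$sigma_b, d$mu, stats))) {
      return(numeric(map$npar))  # infeasible plateau; line search backs off
    }
    gr <- .mlgm_loglik_grad(d$sigma_w, d$sigma_b, d$mu, stats)
    -map$grad(d$cache, gr$D_w, gr$D_b, gr$g_mu)
  }
  run <- function(par) {
    opt <- stats::nlminb(par, negll, neggrad,
                         control = list(iter.max = control$maxit,
                                        eval.max = 4L * control$maxit,
                                        rel.tol = 1e-12))
    gnorm <- max(abs(neggrad(opt$par)))
    list(par = opt$par, value = opt$objective, gnorm = gnorm,
         n_iter = opt$iterations)
  }
  scale_tol <- function(value) control$tol * max(1, abs(value))

  starts <- list(start_values(template, stats, basis))
  if (template$within_cov == "structured" || template$between_cov == "structured") {
    starts <- c(starts, list(start_values(template, stats, basis, diag_phi = TRUE)))
  }
  polish <- function(par) {
    # a BFGS pass from the PORT solution reliably grinds the gradient down
    # when nlminb's relative-decrease rule fires just short of stationarity
    opt <- stats::optim(par, negll, neggrad, method = "BFGS",
                        control = list(maxit = 200L, reltol = 1e-16))
    gnorm <- max(abs(neggrad(opt$par)))
    list(par = opt$par, value = opt$value, gnorm = gnorm,
         n_iter = opt$counts[["function"]])
  }

  attempts <- lapply(starts, run)
  n_iter <- sum(vapply(attempts, `[[`, 0L, "n_iter"))
  best <- attempts[[which.min(vapply(attempts, `[[`, 0, "value"))]]
  if (best$gnorm >= scale_tol(best$value)) {
    pol <- polish(best$par)
    n_iter <- n_iter + pol$n_iter
    if (pol$value <= best$value || pol$gnorm < best$gnorm) best <- pol
  }
  if (best$gnorm >= scale_tol(best$value)) {
    # restart the quasi-Newton iterations from the current point
    again <- run(best$par)
    n_iter <- n_iter + again$n_iter
    if (again$value <= best$value) best <- again
  }
  tries <- 0L
  while (best$gnorm >= scale_tol(best$value) && tries < control$restarts) {
    tries <- tries + 1L
    jit <- run(starts[[1]] * 1.1)
    n_iter <- n_iter + jit$n_iter
    if (jit$value < best$value || jit$gnorm < best$gnorm) best <- jit
  }

  d <- map$decode(best$par)
  counts <- model_df(template, T_waves = nrow(lam), q = ncol(lam))
  params <- c(list(sigma_w = d$sigma_w, sigma_b = d$sigma_b, mu = d$mu),
              map$extract(d$cache))
  min_eig <- function(m) {
    min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  }
  admissible <- min_eig(d$sigma_w) > 0 && min_eig(d$sigma_b) >= -1e-8 &&
    (is.null(params$theta_w) || all(params$theta_w >= -1e-8)) &&
    (is.null(params$theta_b) || all(params$theta_b >= -1e-8)) &&
    (is.null(params$phi_w) || min_eig(params$phi_w) >= -1e-8) &&
    (is.null(params$phi_b) || min_eig(params$phi_b) >= -1e-8)
  structure(
    list(
      template = template,
      loglik = -best$value,
      params = params,
      converged = best$gnorm < scale_tol(best$value),
      admissible = admissible,
      n_iter = n_iter,
      grad_norm = best$gnorm,
      free_params = counts$free_params,
      df = counts$df
    ),
    class = "fit_result"
  )
}

#' Fit the whole template catalog
#'
#' Fits every template of [template_catalog()] on one set of sufficient
#' statistics. Templates whose saturation pattern coincides (TS_COV is the
#' same model as PS_B under the literal target-saturation construction)
#' are fitted once and stored under both names.
#'
#' @inheritParams fit_mlgm
#' @param templates Named list of templates (defaults to
#'   [template_catalog()]).
#' @return Named list of `fit_result`s.
#' @export
fit_catalog <- function(stats, basis, control = fit_control(),
                        templates = template_catalog()) {
  stats <- sufficient_stats(stats)
  out <- vector("list", length(templates))
  names(out) <- names(templates)
  sig <- vapply(templates, function(tp) {
    paste(tp$within_cov, tp$between_cov, tp$mean, tp$phi_offdiag_free)
  }, "")
  for (i in seq_along(templates)) {
    prev <- match(sig[i], sig[seq_len(i - 1L)])
    if (!is.na(prev)) {
      res <- out[[prev]]
      res$template <- templates[[i]]
      out[[i]] <- res
    } else {
      out[[i]] <- fit_mlgm(templates[[i]], stats, basis, control)
    }
  }
  out
}
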